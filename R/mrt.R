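#' Multivariate regression tree of community composition on topography
#'
#' Partitions the plot's analysis cells by binary recursive splits on the four
#' topographic variables so as to minimise the total within-node sum of
#' squared Euclidean distances of the (optionally Hellinger-transformed)
#' species abundance profiles. Growth is best-first: at each step the single
#' split, over all current leaves and all variables/thresholds, with the
#' largest reduction in the objective is applied, until exactly `n_leaves`
#' leaves exist. For a fixed leaf budget this is the greedy CART tree pruned
#' to that size. Ties are broken toward the lowest-index variable, then the
#' smallest threshold. Cells with undefined (flat) aspect are routed as a
#' common low sentinel value.
#'
#' @param community numeric site x species abundance matrix; rows must align
#'   1:1 with the rows of `topo` (row-major, south-west origin).
#' @param topo a `topo_grid` from [quadrat_topography()].
#' @param n_leaves number of leaves to grow (default 4 habitat types).
#' @param min_node minimum cells per leaf (default 5).
#' @param transform `"hellinger"` (square root of row-relative abundances,
#'   the default) or `"raw"`.
#' @return A `habitat_tree`: list with `nodes` (split table), `leaf` (leaf id
#'   per input row), `variables`, `transform`, `objective` (within-SS after
#'   each split).
#' @export
fit_mrt <- function(community, topo, n_leaves = 4, min_node = 5,
                    transform = c("hellinger", "raw")) {
  transform <- match.arg(transform)
  community <- as.matrix(community)
  if (nrow(community) != nrow(topo))
    stop("community rows must align with topo cells")
  vars <- c("elevation", "slope", "aspect", "convexity")
  X <- as.matrix(topo[, vars])
  X[is.na(X[, "aspect"]), "aspect"] <- -1  # flat cells: common sentinel
  Y <- if (transform == "hellinger") {
    rs <- rowSums(community)
    rs[rs == 0] <- 1
    sqrt(community / rs)
  } else community

  node_ss <- function(idx) {
    if (length(idx) < 2) return(0)
    Yi <- Y[idx, , drop = FALSE]
    sum(Yi^2) - sum(colSums(Yi)^2) / length(idx)
  }
  # best split of one node: returns list(var, threshold, reduction, left idx)
  best_split <- function(idx) {
    n <- length(idx)
    if (n < 2 * min_node) return(NULL)
    parent <- node_ss(idx)
    best <- NULL
    for (v in seq_along(vars)) {
      xv <- X[idx, v]
      ord <- order(xv)
      xs <- xv[ord]
      Ys <- Y[idx[ord], , drop = FALSE]
      cs <- apply(Ys, 2, cumsum)
      cq <- cumsum(rowSums(Ys^2))
      tot <- cs[n, ]; totq <- cq[n]
      ks <- which(diff(xs) > 0)
      ks <- ks[ks >= min_node & (n - ks) >= min_node]
      for (k in ks) {
        ssl <- cq[k] - sum(cs[k, ]^2) / k
        ssr <- (totq - cq[k]) - sum((tot - cs[k, ])^2) / (n - k)
        red <- parent - ssl - ssr
        thr <- (xs[k] + xs[k + 1]) / 2
        if (red > 1e-12 &&
            (is.null(best) || red > best$reduction + 1e-12))
          best <- list(var = v, threshold = thr, reduction = red,
                       left = idx[ord][seq_len(k)])
      }
    }
    best
  }

  leaf <- rep(1L, nrow(Y))
  nodes <- data.frame(node = 1L, var = NA_character_,
                      threshold = NA_real_, n = nrow(Y),
                      stringsAsFactors = FALSE)
  splits <- list()
  cand <- list(`1` = best_split(seq_len(nrow(Y))))
  objective <- node_ss(seq_len(nrow(Y)))
  next_id <- 1L
  while (length(unique(leaf)) < n_leaves) {
    reds <- vapply(cand, function(b) if (is.null(b)) -Inf else b$reduction,
                   numeric(1))
    if (!length(reds) || all(!is.finite(reds)))
      stop("no valid split available before reaching ", n_leaves, " leaves")
    pick <- names(cand)[which.max(reds)]
    b <- cand[[pick]]
    pid <- as.integer(pick)
    lid <- next_id + 1L; rid <- next_id + 2L; next_id <- next_id + 2L
    in_node <- which(leaf == pid)
    leaf[in_node] <- rid
    leaf[b$left] <- lid
    splits[[length(splits) + 1L]] <-
      data.frame(node = pid, var = vars[b$var], threshold = b$threshold,
                 left = lid, right = rid, reduction = b$reduction)
    objective <- c(objective, objective[length(objective)] - b$reduction)
    cand[[pick]] <- NULL
    cand[[as.character(lid)]] <- best_split(which(leaf == lid))
    cand[[as.character(rid)]] <- best_split(which(leaf == rid))
  }
  structure(list(splits = if (length(splits)) do.call(rbind, splits)
                          else NULL,
                 leaf = leaf, variables = vars, transform = transform,
                 objective = objective),
            class = "habitat_tree")
}

#' @export
print.habitat_tree <- function(x, ...) {
  nl <- length(unique(x$leaf))
  cat(sprintf("Multivariate regression tree: %d leaves, %s response\n",
              nl, x$transform))
  if (!is.null(x$splits)) {
    s <- x$splits
    for (i in seq_len(nrow(s)))
      cat(sprintf("  node %d: %s < %.3f -> %d | %d  (SS reduction %.4f)\n",
                  s$node[i], s$var[i], s$threshold[i], s$left[i], s$right[i],
                  s$reduction[i]))
  }
  invisible(x)
}

# route topo rows through a fitted tree; returns leaf id per row
route_tree <- function(tree, topo) {
  X <- as.matrix(topo[, tree$variables])
  X[is.na(X[, "aspect"]), "aspect"] <- -1
  leaf <- rep(1L, nrow(X))
  s <- tree$splits
  if (is.null(s)) return(leaf)
  for (i in seq_len(nrow(s))) {
    at <- leaf == s$node[i]
    lt <- X[, s$var[i]] < s$threshold[i]
    leaf[at & lt] <- s$left[i]
    leaf[at & !lt] <- s$right[i]
  }
  leaf
}

#' Habitat map from a fitted tree
#'
#' Routes every cell through the tree and names the leaves by their terrain:
#' the leaf with the highest mean convexity is `hilltop`, the lowest is
#' `depression`, and of the remaining two the steeper is `steep_slope` and
#' the gentler `gentle_slope`. With fewer than four leaves the available
#' labels are assigned in the same spirit (convexity extremes first).
#'
#' @param tree a `habitat_tree`.
#' @param topo the `topo_grid` to label (same variables as used for fitting).
#' @return A `habitat_map`: ny x nx character matrix (row 1 = south) with
#'   attributes `cell_size` and `tree`.
#' @export
assign_habitats <- function(tree, topo) {
  leaf <- route_tree(tree, topo)
  ids <- sort(unique(leaf))
  conv <- vapply(ids, function(l) mean(topo$convexity[leaf == l]), numeric(1))
  slp <- vapply(ids, function(l) mean(topo$slope[leaf == l]), numeric(1))
  lab <- rep(NA_character_, length(ids))
  if (length(ids) == 1) {
    lab <- "gentle_slope"
  } else {
    lab[which.max(conv)] <- "hilltop"
    lab[which.min(conv)] <- "depression"
    rest <- which(is.na(lab))
    if (length(rest) == 1) {
      lab[rest] <- "gentle_slope"
    } else if (length(rest) == 2) {
      lab[rest[order(-slp[rest])]] <- c("steep_slope", "gentle_slope")
    }
  }
  m <- matrix(NA_character_, attr(topo, "ny"), attr(topo, "nx"))
  m[cbind(topo$row, topo$col)] <- lab[match(leaf, ids)]
  structure(m, cell_size = attr(topo, "cell_size"), tree = tree,
            class = "habitat_map")
}

#' @export
print.habitat_map <- function(x, ...) {
  cat(sprintf("Habitat map %d x %d cells (%g m):\n", nrow(x), ncol(x),
              attr(x, "cell_size")))
  print(table(c(unclass(x))))
  invisible(x)
}

#' Write a habitat map
#' @param habitat a `habitat_map`.
#' @param path output CSV path (cell row, cell col, habitat; row 1 = south).
#' @export
write_habitat_map <- function(habitat, path) {
  ny <- nrow(habitat); nx <- ncol(habitat)
  df <- data.frame(row = rep(seq_len(ny), each = nx),
                   col = rep(seq_len(nx), ny),
                   habitat = as.vector(t(unclass(habitat))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
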