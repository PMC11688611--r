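# Gene x (parameter x screen) profile matrix, average-linkage
# hierarchical clustering, optimal leaf ordering and heatmap export.

#' Build the gene-by-(parameter x screen) profile matrix
#'
#' One row per gene, one column per (parameter, screen) combination
#' (5 x 3 = 15 columns by default), filled with the per-screen
#' Z-scores. The control treatments (`control_siRNA`, `TLN1`,
#' `polyL-lysine`) are collapsed to a single row each by averaging
#' their well scores per (parameter, screen). Missing (gene, screen)
#' entries are `NA`.
#'
#' @param ztab Z-score table from [score_wells()].
#' @param genes genes to include as rows (default: every non-control
#'   gene in the table; pass the hit genes from [call_hits()] to
#'   reproduce the usual hits-only clustering input).
#' @param include_controls append the averaged control rows (default
#'   `TRUE`).
#' @return numeric matrix with genes (and controls) as row names.
#' @export
build_profile_matrix <- function(ztab, genes = NULL,
                                 include_controls = TRUE) {
  screens <- sort(unique(ztab$screen_id))
  cols <- as.vector(t(outer(PARAM_NAMES, screens,
                            function(p, s) paste0(p, "_S", s))))
  if (is.null(genes))
    genes <- sort(unique(ztab$gene[!ztab$gene %in% CONTROL_TREATMENTS]))
  rows <- c(genes,
            if (include_controls)
              intersect(CONTROL_TREATMENTS, unique(ztab$gene)))
  m <- matrix(NA_real_, nrow = length(rows), ncol = length(cols),
              dimnames = list(rows, cols))
  agg <- stats::aggregate(z ~ gene + parameter + screen_id,
                          data = ztab[ztab$gene %in% rows, ], FUN = mean)
  m[cbind(match(agg$gene, rows),
          match(paste0(agg$parameter, "_S", agg$screen_id), cols))] <- agg$z
  empty <- rowSums(!is.na(m)) == 0L
  if (any(empty)) {
    warnf("%d gene(s) absent from all screens dropped from the profile matrix",
          sum(empty))
    m <- m[!empty, , drop = FALSE]
  }
  m
}

#' Pairwise row distances tolerating missing entries
#'
#' Euclidean (default) or correlation distance computed over the
#' columns two rows share, rescaled by `sqrt(n_total / n_shared)` so
#' rows with few shared columns are not artificially close.
#'
#' @param m numeric matrix (rows = profiles).
#' @param metric `"euclidean"` or `"correlation"` (1 - Pearson r).
#' @return a `dist` object.
#' @export
profile_dist <- function(m, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  n <- nrow(m)
  if (n < 2L) stopf("need at least 2 rows")
  if (!anyNA(m) && metric == "euclidean") return(stats::dist(m))
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    sh <- which(!is.na(m[i, ]) & !is.na(m[j, ]))
    if (!length(sh))
      stopf("rows %s and %s share no observed columns",
            rownames(m)[i], rownames(m)[j])
    if (metric == "euclidean") {
      d[i, j] <- sqrt(sum((m[i, sh] - m[j, sh])^2) * ncol(m) / length(sh))
    } else {
      if (length(sh) < 3L || stats::sd(m[i, sh]) == 0 ||
          stats::sd(m[j, sh]) == 0)
        stopf("correlation distance undefined for rows %s and %s",
              rownames(m)[i], rownames(m)[j])
      d[i, j] <- 1 - stats::cor(m[i, sh], m[j, sh])
    }
    d[j, i] <- d[i, j]
  }
  stats::as.dist(d)
}

# min-plus matrix product with argmin bookkeeping:
# out$val[i,j] = min_k X[i,k] + Y[k,j]; out$arg[i,j] = the minimizing k
minplus <- function(X, Y) {
  a <- nrow(X); b <- ncol(X); cc <- ncol(Y)
  val <- matrix(Inf, a, cc)
  arg <- matrix(1L, a, cc)
  for (j in seq_len(cc)) {
    S <- X + rep(Y[, j], each = a)
    k <- max.col(-S, ties.method = "first")
    arg[, j] <- k
    val[, j] <- S[cbind(seq_len(a), k)]
  }
  list(val = val, arg = arg)
}

#' Optimal leaf ordering for an hclust tree
#'
#' Reorders the leaves of a dendrogram, among the orderings consistent
#' with its topology (subtree flips only), to minimize the total
#' dissimilarity between adjacent leaves (the Bar-Joseph dynamic
#' program). The tree itself is unchanged.
#'
#' @param hc an [stats::hclust] object.
#' @param d the `dist` the tree was built from.
#' @return integer leaf permutation (like `hc$order`), with attribute
#'   `"cost"` giving the minimized sum of adjacent-leaf distances.
#' @export
optimal_leaf_order <- function(hc, d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n == 1L) return(structure(1L, cost = 0))
  merge <- hc$merge
  leaves_of <- vector("list", n - 1L)
  Mstore <- vector("list", n - 1L)     # square min-cost matrices
  Kstore <- vector("list", n - 1L)     # argmin k (left child endpoint)
  Lstore <- vector("list", n - 1L)     # argmin l (right child endpoint)
  child_leaves <- function(id)
    if (id < 0L) -id else leaves_of[[id]]
  child_M <- function(id)
    if (id < 0L) matrix(0, 1, 1) else Mstore[[id]]

  for (v in seq_len(n - 1L)) {
    A <- merge[v, 1L]; B <- merge[v, 2L]
    LA <- child_leaves(A); LB <- child_leaves(B)
    MA <- child_M(A); MB <- child_M(B)
    # B1[k, w] = min_l d[k, l] + MB[l, w]
    p1 <- minplus(dm[LA, LB, drop = FALSE], MB)
    # M[u, w] = min_k MA[u, k] + B1[k, w]
    p2 <- minplus(MA, p1$val)
    K <- matrix(LA[p2$arg], nrow(p2$arg))                 # leaf ids
    L <- matrix(LB[p1$arg[cbind(as.vector(p2$arg),
                                rep(seq_along(LB),
                                    each = nrow(p2$arg)))]],
                nrow(p2$arg))
    all_lv <- c(LA, LB)
    M <- matrix(Inf, length(all_lv), length(all_lv),
                dimnames = list(all_lv, all_lv))
    M[seq_along(LA), length(LA) + seq_along(LB)] <- p2$val
    M[length(LA) + seq_along(LB), seq_along(LA)] <- t(p2$val)
    leaves_of[[v]] <- all_lv
    Mstore[[v]] <- M
    rownames(K) <- LA; colnames(K) <- LB
    rownames(L) <- LA; colnames(L) <- LB
    Kstore[[v]] <- K; Lstore[[v]] <- L
    # children's cost matrices are no longer needed
    if (A > 0L) Mstore[[A]] <- NA
    if (B > 0L) Mstore[[B]] <- NA
  }

  backtrack <- function(id, u, w) {
    if (id < 0L) return(-id)
    A <- merge[id, 1L]; B <- merge[id, 2L]
    LA <- child_leaves(A); LB <- child_leaves(B)
    K <- Kstore[[id]]; L <- Lstore[[id]]
    if (u %in% LA) {
      k <- K[as.character(u), as.character(w)]
      l <- L[as.character(u), as.character(w)]
      c(backtrack(A, u, k), backtrack(B, l, w))
    } else {
      k <- K[as.character(w), as.character(u)]
      l <- L[as.character(w), as.character(u)]
      c(backtrack(B, u, l), backtrack(A, k, w))
    }
  }

  Mroot <- Mstore[[n - 1L]]
  best <- which(Mroot == min(Mroot), arr.ind = TRUE)[1L, ]
  lv <- leaves_of[[n - 1L]]
  ord <- backtrack(n - 1L, lv[best[1L]], lv[best[2L]])
  structure(as.integer(ord), cost = min(Mroot))
}

#' Cluster morphology profiles with average linkage
#'
#' Rows are sorted lexicographically by label before clustering so the
#' result is invariant to input row order; rows observed in fewer than
#' half of the columns are excluded. The tree is built with
#' average-linkage (UPGMA) agglomeration on the chosen metric and its
#' leaves are rearranged by [optimal_leaf_order()].
#'
#' @param m profile matrix from [build_profile_matrix()].
#' @param metric passed to [profile_dist()].
#' @param min_coverage minimum fraction of observed columns a row needs
#'   (default 0.5).
#' @return object of class `polarity_clustering`: `hclust`, the
#'   optimally ordered leaf permutation `order`, `labels`, `dist`, and
#'   the clustered `matrix`.
#' @export
cluster_profiles <- function(m, metric = "euclidean", min_coverage = 0.5) {
  if (is.null(rownames(m))) rownames(m) <- seq_len(nrow(m))
  cov_ok <- rowMeans(!is.na(m)) >= min_coverage
  if (any(!cov_ok)) {
    warnf("%d row(s) observed in fewer than %.0f%% of columns excluded",
          sum(!cov_ok), 100 * min_coverage)
    m <- m[cov_ok, , drop = FALSE]
  }
  if (nrow(m) < 2L) stopf("need at least 2 rows to cluster")
  m <- m[order(rownames(m)), , drop = FALSE]
  d <- profile_dist(m, metric)
  hc <- stats::hclust(d, method = "average")
  ord <- optimal_leaf_order(hc, d)
  structure(list(hclust = hc, order = as.integer(ord),
                 cost = attr(ord, "cost"),
                 labels = rownames(m), dist = d, matrix = m,
                 metric = metric),
            class = "polarity_clustering")
}

# Newick serialization of an hclust tree whose children are rotated to
# follow `order`; branch lengths are height differences
newick_from_hclust <- function(hc, order = hc$order) {
  pos <- integer(length(hc$labels))
  pos[order] <- seq_along(order)
  build <- function(id, parent_h) {
    if (id < 0L) {
      lab <- gsub("[,;:() ]", "_", hc$labels[-id])
      return(list(str = sprintf("%s:%g", lab, parent_h), first = pos[-id]))
    }
    h <- hc$height[id]
    a <- build(hc$merge[id, 1L], h)
    b <- build(hc$merge[id, 2L], h)
    if (a$first > b$first) { tmp <- a; a <- b; b <- tmp }
    list(str = sprintf("(%s,%s):%g", a$str, b$str, parent_h - h),
         first = min(a$first, b$first))
  }
  root <- build(nrow(hc$merge), hc$height[nrow(hc$merge)])
  paste0(sub(":[^:]*$", "", root$str), ";")
}

#' Export the clustered profile matrix, tree and heatmap
#'
#' Writes `profile_matrix.csv` (rows in optimal leaf order),
#' `leaf_order.txt`, and the dendrogram as a Newick tree with branch
#' lengths (`dendrogram.nwk`, children rotated to match the leaf
#' order). Optionally renders a heatmap PNG via pheatmap.
#'
#' @param clust a [cluster_profiles()] result.
#' @param out_dir output directory (created if needed).
#' @param heatmap_file heatmap image path, or `NULL` to skip rendering.
#' @return invisibly, the reordered matrix.
#' @export
export_heatmap <- function(clust, out_dir,
                           heatmap_file = file.path(out_dir, "heatmap.png")) {
  if (!inherits(clust, "polarity_clustering"))
    stopf("`clust` must come from cluster_profiles()")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- clust$matrix[clust$order, , drop = FALSE]
  utils::write.csv(m, file.path(out_dir, "profile_matrix.csv"))
  writeLines(rownames(m), file.path(out_dir, "leaf_order.txt"))
  writeLines(newick_from_hclust(clust$hclust, clust$order),
             file.path(out_dir, "dendrogram.nwk"))
  if (!is.null(heatmap_file)) {
    tryCatch(
      pheatmap::pheatmap(m, cluster_rows = FALSE, cluster_cols = FALSE,
                         filename = heatmap_file, silent = TRUE),
      error = function(e) warnf("heatmap rendering failed: %s",
                                conditionMessage(e)))
  }
  invisible(m)
}
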