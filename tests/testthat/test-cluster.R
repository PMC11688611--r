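# Profile matrix construction, average-linkage clustering, optimal
# leaf ordering, Newick/heatmap export.

test_that("profile matrix has 5 x 3 structure and averages controls", {
  scr <- small_screen(n_genes = 40, seed = 31, cells_per_well = 20)
  z <- score_wells(scr$wells)
  m <- build_profile_matrix(z)
  expect_equal(ncol(m), 15L)
  expect_true(all(c("control_siRNA", "TLN1") %in% rownames(m)))
  # control row equals the mean of that screen's control wells
  zc <- z[z$gene == "control_siRNA" & z$screen_id == 1 &
            z$parameter == "area", ]
  expect_equal(m["control_siRNA", "area_S1"], mean(zc$z))
  # library rows are complete
  expect_true(all(!is.na(m[setdiff(rownames(m), "polyL-lysine"), ])))
})

test_that("missing screens are masked, absent genes dropped", {
  scr <- small_screen(n_genes = 40, seed = 37, cells_per_well = 20)
  z <- score_wells(scr$wells)
  z3 <- z[!(z$gene == "G001" & z$screen_id == 3), ]
  m <- build_profile_matrix(z3)
  expect_equal(sum(is.na(m["G001", ])), 5L)
  expect_true(all(is.na(m["G001", paste0(PARAMS, "_S3")])))
  expect_warning(m2 <- build_profile_matrix(z, genes = c("G001", "NOPE")),
                 "absent")
  expect_false("NOPE" %in% rownames(m2))
})

test_that("identical rows merge at height zero; two rows are the base case", {
  m <- rbind(a = c(1, 2, 3), b = c(1, 2, 3), c = c(5, 5, 5))
  cl <- cluster_profiles(m)
  expect_equal(min(cl$hclust$height), 0)
  m2 <- m[1:2, ]
  m2[2, ] <- c(4, 6, 3)
  cl2 <- cluster_profiles(m2)
  expect_equal(max(cl2$hclust$height), sqrt(sum((m2[1, ] - m2[2, ])^2)))
  expect_setequal(cl2$order, 1:2)
})

test_that("planted opposite-phenotype groups split at the 2-cluster cut", {
  set.seed(7)
  m <- rbind(matrix(-3 + rnorm(12 * 15, sd = 0.4), 12),
             matrix(3 + rnorm(9 * 15, sd = 0.4), 9))
  rownames(m) <- c(paste0("dn", 1:12), paste0("up", 1:9))
  cl <- cluster_profiles(m)
  k2 <- stats::cutree(cl$hclust, 2)
  expect_equal(length(unique(k2[grep("dn", names(k2))])), 1L)
  expect_equal(length(unique(k2[grep("up", names(k2))])), 1L)
  expect_false(k2[["dn1"]] == k2[["up1"]])
})

test_that("optimal leaf ordering matches brute-force enumeration, n <= 8", {
  set.seed(123)
  for (n in c(2, 3, 4, 6, 8)) {
    m <- matrix(rnorm(n * 5), n)
    rownames(m) <- paste0("r", seq_len(n))
    d <- dist(m)
    hc <- hclust(d, "average")
    ord <- optimal_leaf_order(hc, d)
    expect_setequal(as.integer(ord), seq_len(n))
    best <- min(vapply(tree_orderings(hc), adjacent_cost, numeric(1),
                       d = d))
    expect_equal(adjacent_cost(ord, d), best, tolerance = 1e-12)
    expect_equal(attr(ord, "cost"), best, tolerance = 1e-12)
    # never worse than the default hclust order
    expect_lte(adjacent_cost(ord, d), adjacent_cost(hc$order, d) + 1e-12)
  }
})

test_that("clustering is invariant to input row order", {
  set.seed(11)
  m <- matrix(rnorm(9 * 15), 9)
  rownames(m) <- paste0("g", 1:9)
  cl1 <- cluster_profiles(m)
  perm <- sample(9)
  cl2 <- cluster_profiles(m[perm, ])
  expect_identical(cl1$labels[cl1$order], cl2$labels[cl2$order])
  expect_equal(stats::cophenetic(cl1$hclust), stats::cophenetic(cl2$hclust))
})

test_that("average-linkage heights are monotone non-decreasing", {
  scr <- small_screen(n_genes = 60, seed = 41, cells_per_well = 20)
  z <- score_wells(scr$wells)
  h <- call_hits(z)
  cl <- cluster_profiles(build_profile_matrix(z, genes = h$gene[h$hit]))
  expect_true(all(diff(cl$hclust$height) >= -1e-12))
  # on an exactly ultrametric input, average linkage recovers the
  # cophenetic distances and dominance holds with equality
  du <- matrix(4, 6, 6, dimnames = list(letters[1:6], letters[1:6]))
  du[1:3, 1:3] <- 1; du[4:6, 4:6] <- 1.5
  diag(du) <- 0
  hcu <- hclust(as.dist(du), "average")
  expect_equal(as.vector(stats::cophenetic(hcu)), as.vector(as.dist(du)))
})

test_that("pairwise-complete distances rescale by shared-column count", {
  m <- rbind(a = c(1, 2, 3, 4), b = c(2, 3, NA, 6), c = c(0, 0, 0, 0))
  d <- as.matrix(profile_dist(m))
  expect_equal(d["a", "b"], sqrt((1 + 1 + 4) * 4 / 3))
  expect_equal(d["a", "c"], sqrt(sum(m["a", ]^2)))
  m2 <- rbind(a = c(1, NA), b = c(NA, 1))
  expect_error(profile_dist(m2), "share no observed columns")
})

test_that("export writes leaf-ordered matrix, Newick and round-trips", {
  scr <- small_screen(n_genes = 40, seed = 43, cells_per_well = 20)
  z <- score_wells(scr$wells)
  h <- call_hits(z)
  cl <- cluster_profiles(build_profile_matrix(z, genes = h$gene[h$hit]))
  td <- withr::local_tempdir()
  out <- export_heatmap(cl, td, heatmap_file = NULL)
  # CSV row order equals the dendrogram leaf order
  csv <- read.csv(file.path(td, "profile_matrix.csv"), row.names = 1)
  expect_identical(rownames(csv), cl$labels[cl$order])
  expect_identical(rownames(csv),
                   readLines(file.path(td, "leaf_order.txt")))
  # re-imported matrix reproduces the pairwise distances
  d2 <- profile_dist(as.matrix(csv)[order(rownames(csv)), ])
  expect_equal(as.vector(d2), as.vector(cl$dist), tolerance = 1e-9)
  # the Newick tree parses, has the right tips in leaf order, and its
  # tip-to-tip path lengths equal twice the hclust merge heights
  # (both tips descend from the merge node at its height)
  tr <- ape::read.tree(file.path(td, "dendrogram.nwk"))
  expect_setequal(tr$tip.label, cl$labels)
  tip_order <- tr$tip.label[tr$edge[tr$edge[, 2] <= length(tr$tip.label), 2]]
  expect_identical(tip_order, cl$labels[cl$order])
  co <- stats::cophenetic(cl$hclust)
  ca <- ape::cophenetic.phylo(tr)[labels(co), labels(co)]
  expect_equal(as.vector(as.dist(ca)), 2 * as.vector(co), tolerance = 1e-6)
})
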