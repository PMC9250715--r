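two_pairs_matrix <- function() {
  # two tight pairs far apart: (p1,p2) and (p3,p4)
  pts <- c(0, 0.1, 10, 10.1)
  d <- abs(outer(pts, pts, "-"))
  dimnames(d) <- list(paste0("p", 1:4), paste0("p", 1:4))
  d
}

test_that("two observations merge at their distance", {
  d <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  tree <- hac_linkage(d)
  expect_equal(tree$height, 3)
})

test_that("tight pairs merge first and are recovered at k = 2", {
  d <- two_pairs_matrix()
  tree <- hac_linkage(d)
  # the two lowest merges join the pairs
  expect_equal(sort(tree$height[1:2]), c(0.1, 0.1), tolerance = 1e-12)
  cl <- cut_tree(tree, 2)
  expect_equal(cl$cluster[1], cl$cluster[2])
  expect_equal(cl$cluster[3], cl$cluster[4])
  expect_true(cl$cluster[1] != cl$cluster[3])
})

test_that("invalid distance matrices and k are rejected", {
  d <- two_pairs_matrix()
  bad <- d; bad[1, 2] <- 99
  expect_error(hac_linkage(bad), "symmetric")
  neg <- d; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(hac_linkage(neg), "non-negative")
  tree <- hac_linkage(d)
  expect_error(cut_tree(tree, 1), "k must be")
  expect_error(cut_tree(tree, 5), "k must be")
  expect_equal(sort(unique(cut_tree(tree, 4)$cluster)), 1:4) # k = n
})

test_that("linkage trees match a naive O(n^3) agglomerator", {
  set.seed(10)
  for (r in 1:12) {
    n <- sample(4:12, 1)
    p <- matrix(runif(n * 3), n)
    d <- as.matrix(dist(p))
    dimnames(d) <- list(paste0("x", 1:n), paste0("x", 1:n))
    for (lk in c("single", "average", "complete")) {
      tree <- hac_linkage(d, lk)
      expect_equal(unname(as.matrix(cophenetic(tree))[rownames(d),
                                                      rownames(d)]),
                   unname(naive_hac_cophenetic(d, lk)),
                   tolerance = 1e-9,
                   info = paste("linkage", lk, "rep", r))
    }
  }
})

test_that("cluster ids are ordered by size then smallest member", {
  cl <- c(2, 2, 1, 2, 3, 3)
  relabeled <- sofatraj:::.relabel_by_size(cl)
  expect_equal(relabeled, c(1, 1, 3, 1, 2, 2))
})

test_that("index report finds two well-separated blobs", {
  set.seed(11)
  pts <- c(rnorm(15, 0, 0.2), rnorm(15, 20, 0.2))
  d <- abs(outer(pts, pts, "-"))
  diag(d) <- 0
  tree <- hac_linkage(d)
  rep_ <- select_k(d, tree, 2:6)
  expect_equal(attr(rep_, "chosen_k"), 2)
  expect_gt(rep_$silhouette[rep_$k == 2], 0.8)
  expect_true(all(rep_$silhouette >= -1 & rep_$silhouette <= 1))
  expect_true(all(rep_$dunn >= 0))
  expect_true(all(rep_$c_index >= 0 & rep_$c_index <= 1, na.rm = TRUE))
})

test_that("silhouette values agree with the definitional double loop", {
  set.seed(12)
  pts <- matrix(rnorm(20 * 2), 20)
  d <- as.matrix(dist(pts))
  tree <- hac_linkage(d)
  for (k in 2:4) {
    cl <- sofatraj:::.relabel_by_size(cutree(tree, k))
    sil_pkg <- mean(cluster::silhouette(cl, dmatrix = d)[, "sil_width"])
    expect_equal(sil_pkg, silhouette_double_loop(d, cl), tolerance = 1e-12)
  }
})

test_that("degenerate inputs are handled", {
  d0 <- matrix(0, 6, 6)
  tree <- hclust(as.dist(d0 + 1e-9), "average")
  expect_error(select_k(d0, tree, 2:3), "degenerate")
  # near-duplicate points: report is well-formed, silhouette near 0
  set.seed(13)
  pts <- rnorm(10, 0, 1e-6) + 5
  d <- abs(outer(pts, pts, "-")); diag(d) <- 0
  tree <- hac_linkage(d)
  rep_ <- select_k(d, tree, 2:4)
  expect_true(all(is.finite(rep_$silhouette)))
  expect_lt(max(abs(rep_$silhouette)), 0.9)
})

test_that("archetype labeling matches the four reference shapes", {
  curves <- rbind(
    seq(4.5, 7.2, length.out = 12),            # rising -> RW
    approx(c(1, 8, 12), c(5.2, 3.7, 4.8), 1:12)$y, # fall then rise -> DW
    seq(5.5, 2.8, length.out = 12),            # falling -> RI
    approx(c(1, 6, 12), c(4.0, 5.2, 3.5), 1:12)$y  # rise then fall -> DI
  )
  # four "clusters" of one patient each, trajectories = the mean curves
  m <- curves
  rownames(m) <- paste0("p", 1:4)
  assign <- structure(data.frame(patient_id = rownames(m), cluster = 1:4),
                      class = c("cluster_assignment", "data.frame"), k = 4)
  lab <- label_archetypes(assign, m)
  expect_equal(unname(lab$labels), c("RW", "DW", "RI", "DI"))
  expect_equal(lab$status, "ok")
  expect_equal(lab$deltas[, "early"], unname(curves[, 8] - curves[, 1]),
               ignore_attr = TRUE)
})

test_that("duplicate labels are disambiguated by net change magnitude", {
  curves <- rbind(
    seq(4, 8, length.out = 12),   # strong rise
    seq(5, 5.8, length.out = 12), # weak rise -> demoted to DW
    seq(6, 2, length.out = 12),   # strong fall
    seq(5, 4.4, length.out = 12)  # weak fall -> demoted to DI
  )
  rownames(curves) <- paste0("p", 1:4)
  assign <- structure(data.frame(patient_id = rownames(curves),
                                 cluster = 1:4),
                      class = c("cluster_assignment", "data.frame"), k = 4)
  lab <- label_archetypes(assign, curves)
  expect_equal(unname(lab$labels), c("RW", "DW", "RI", "DI"))
})

test_that("labeling is skipped with a warning when k != 4", {
  m <- matrix(runif(36, 0, 10), 3, 12, dimnames = list(paste0("p", 1:3)))
  assign <- structure(data.frame(patient_id = rownames(m), cluster = 1:3),
                      class = c("cluster_assignment", "data.frame"), k = 3)
  expect_warning(lab <- label_archetypes(assign, m), "k = 4")
  expect_null(lab$labels)
  expect_equal(lab$status, "skipped")
})

test_that("permuting patients permutes assignments identically", {
  ch <- small_cohort(n = 24, seed = 14)
  traj <- build_trajectories(ch)
  D <- pairwise_dtw(traj)
  a1 <- cut_tree(hac_linkage(D), 4)
  perm <- sample(nrow(D))
  Dp <- D[perm, perm]
  a2 <- cut_tree(hac_linkage(Dp), 4)
  m1 <- setNames(a1$cluster, a1$patient_id)
  m2 <- setNames(a2$cluster, a2$patient_id)
  expect_equal(adjusted_rand_index(m1[names(m2)], m2), 1)
})
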