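test_that("standardization follows the sample-sd z-score definition", {
  m <- cbind(a = c(1, 3), b = c(10, 20))
  z <- standardize(m)
  expect_equal(unname(z[, "a"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  # every column has mean 0 and sd 1
  set.seed(1)
  z2 <- standardize(matrix(rnorm(60), 12, 5))
  expect_true(all(abs(colMeans(z2)) < 1e-9))
  expect_true(all(abs(apply(z2, 2, sd) - 1) < 1e-9))
  # idempotent on already-standardized input
  expect_equal(unclass(standardize(z2))[, ], z2[, ], tolerance = 1e-9)
})

test_that("standardization refuses constant or invalid columns by name", {
  m <- cbind(ok = c(1, 2, 3), flat = c(5, 5, 5))
  expect_error(standardize(m), "flat")
  m2 <- cbind(ok = c(1, 2, 3), holed = c(1, NA, 2))
  expect_error(standardize(m2), "holed")
  expect_error(standardize(matrix(1, 1, 2)), "at least 2")
})

test_that("two identical points merge at height zero", {
  z <- matrix(c(1, 1, 2, 2), 2, 2, byrow = TRUE) * 0
  h <- ward_linkage(z)
  expect_equal(h$height, 0)
})

test_that("Ward linkage equals the brute-force variance-increase oracle for n <= 7", {
  set.seed(99)
  for (rep in 1:8) {
    n <- sample(4:7, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    h <- ward_linkage(X)
    expect_equal(sort(h$height), sort(ward_oracle(X)), tolerance = 1e-10)
    expect_true(all(diff(h$height) >= -1e-10))
  }
})

test_that("clustering is invariant to row permutation up to label renaming", {
  set.seed(5)
  X <- matrix(rnorm(40), 10, 4)
  rownames(X) <- paste0("c", 1:10)
  a <- cluster_cut(ward_linkage(standardize(X)), 3)
  perm <- sample(10)
  b <- cluster_cut(ward_linkage(standardize(X[perm, ])), 3)
  # same partition: co-membership matrices agree after reordering
  co <- function(l) outer(l, l, "==")
  expect_equal(unname(co(a$labels[rownames(X)])),
               unname(co(b$labels[rownames(X)])))
})

test_that("cuts at k = 1 and k = n are the trivial partitions", {
  set.seed(6)
  X <- matrix(rnorm(24), 8, 3)
  tree <- ward_linkage(X)
  expect_equal(unname(cluster_cut(tree, 1)$labels), rep(1, 8))
  expect_length(unique(cluster_cut(tree, 8)$labels), 8)
  expect_error(cluster_cut(tree, 0), "k must be")
  expect_error(cluster_cut(tree, 9), "k must be")
})

test_that("well-separated groups are recovered exactly at k = number of groups", {
  set.seed(8)
  X <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
             matrix(rnorm(20, 5, 0.1), 10, 2),
             matrix(rnorm(16, -5, 0.1), 8, 2))
  truth <- rep(c("a", "b", "c"), c(10, 10, 8))
  asg <- cluster_cut(ward_linkage(standardize(X)), 3)
  expect_equal(misclassification(asg$labels, truth)$count, 0)
})

test_that("a one-stage plan equals direct standardize + Ward + cut", {
  set.seed(9)
  rec <- data.frame(cell_id = paste0("c", 1:12),
                    group = rep(c("x", "y"), 6),
                    f1 = rnorm(12), f2 = rnorm(12), f3 = rnorm(12))
  staged <- sequential_cluster(rec, list(list(features = c("f1", "f2", "f3"),
                                              exclude_groups = character(0),
                                              k = 2)))
  m <- as.matrix(rec[, c("f1", "f2", "f3")])
  rownames(m) <- rec$cell_id
  direct <- cluster_cut(ward_linkage(standardize(m)), 2)
  expect_equal(staged[[1]]$assignment$labels, direct$labels)
})

test_that("sequential stages drop groups and re-standardize on the survivors", {
  set.seed(10)
  # three synthetic classes along one axis; G42-like far off
  rec <- data.frame(
    cell_id = sprintf("c%02d", 1:24),
    group = rep(c("G42", "RS", "FS1", "FS2"), each = 6),
    f1 = c(rnorm(6, 20), rnorm(6, 5), rnorm(6, 0), rnorm(6, 1.5)),
    f2 = c(rnorm(6, 10), rnorm(6, 6), rnorm(6, 0), rnorm(6, 3)))
  plan <- list(
    list(features = c("f1", "f2"), exclude_groups = character(0), k = 2),
    list(features = c("f1", "f2"), exclude_groups = "G42", k = 2),
    list(features = c("f1", "f2"), exclude_groups = "RS", k = 2))
  stages <- sequential_cluster(rec, plan)
  expect_length(stages, 3)
  expect_equal(length(stages[[2]]$kept), 18)
  expect_equal(length(stages[[3]]$kept), 12)
  # standardization is recomputed on the survivors at every stage
  expect_true(all(abs(colMeans(stages[[3]]$z)) < 1e-9))
  # final stage separates the two FS classes
  truth <- rec$group[stages[[3]]$kept]
  expect_lte(misclassification(stages[[3]]$assignment$labels, truth)$count, 2)
  expect_error(sequential_cluster(rec, list(list(features = "f1",
                                                 exclude_groups = c("G42", "RS", "FS1", "FS2"),
                                                 k = 1))),
               "excluded all cells")
})

test_that("benchmark cells name their cluster and strays are flagged", {
  labels <- c(1, 1, 1, 2, 2, 2)
  asg <- structure(list(labels = stats::setNames(labels, paste0("c", 1:6)),
                        k = 2), class = "cluster_assignment")
  bench <- c("PV", "PV", NA, NA, NA, NA)
  named <- benchmark_assign(asg, bench)
  expect_equal(unname(named$cluster_names["1"]), "PV")
  expect_equal(named$n_misclassified, 0)

  # a known PV cell sitting in the unnamed cluster is misclassified
  known <- c("PV", "PV", NA, "PV", NA, NA)
  named2 <- benchmark_assign(asg, bench, known)
  expect_equal(named2$n_misclassified, 1)
  expect_equal(unname(named2$misclassified), 4L)

  # majority tie is an error, never silently broken
  bench_tie <- c("PV", "SST", NA, NA, NA, NA)
  expect_error(benchmark_assign(asg, bench_tie), "tie")
})

test_that("misclassification equals the confusion-matrix off-diagonal oracle", {
  set.seed(11)
  truth <- rep(c("A", "B"), c(8, 7))
  labels <- c(rep(1, 6), 2, 2, rep(2, 5), 1, 1)
  tab <- table(labels, truth)
  oracle <- sum(tab) - max(tab[1, "A"] + tab[2, "B"],
                           tab[1, "B"] + tab[2, "A"])
  expect_equal(misclassification(labels, truth)$count, oracle)
})

test_that("dendrograms export as valid Newick with all leaves", {
  set.seed(12)
  X <- matrix(rnorm(18), 6, 3)
  rownames(X) <- paste0("cell", 1:6)
  tree <- ward_linkage(X)
  nwk <- export_newick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_setequal(phy$tip.label, rownames(X))
  f <- tempfile(fileext = ".nwk")
  export_newick(tree, f)
  expect_setequal(ape::read.tree(f)$tip.label, rownames(X))
})
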