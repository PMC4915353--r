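dist_mat <- function(d, labels) {
  structure(list(labels = labels, d = d), class = "dist_matrix")
}

test_that("two taxa at distance d sit at depth d/2", {
  d <- matrix(c(0, 0.3, 0.3, 0), 2, dimnames = NULL)
  tr <- upgma_tree(dist_mat(d, c("A", "B")))
  expect_equal(unname(coalbias:::tip_depths(tr)), c(0.15, 0.15))
})

test_that("three-taxon UPGMA reproduces the hand calculation", {
  # d(A,B) = 2, d(A,C) = d(B,C) = 6: (A,B) join at height 1, C joins at 3
  d <- matrix(c(0, 2, 6, 2, 0, 6, 6, 6, 0), 3)
  tr <- upgma_tree(dist_mat(d, c("A", "B", "C")))
  expect_equal(sort(unname(ape::branching.times(tr))), c(1, 3))
  ab <- ape::getMRCA(tr, c("A", "B"))
  expect_equal(unname(ape::branching.times(tr)[as.character(ab)]), 1)
})

test_that("UPGMA trees are ultrametric and binary for random inputs", {
  set.seed(101)
  for (rep in 1:5) {
    smp <- random_alignment(n = 15, L = 120)
    tr <- upgma_tree(distance_matrix(smp))
    expect_true(ape::is.binary(tr))
    depths <- coalbias:::tip_depths(tr)
    expect_lt(diff(range(depths)), 1e-9)
    expect_silent(coalescent_intervals(tr))
  }
})

test_that("coalescent intervals come from sorted node heights", {
  tr <- ape::read.tree(text = "(A:1,B:1);")
  ci <- coalescent_intervals(tr)
  expect_equal(ci$k, 2)
  expect_equal(ci$duration, 1)

  # merges at heights 1, 1.5 and 4
  tr4 <- ape::read.tree(text = "((A:1,B:1):3,(C:1.5,D:1.5):2.5);")
  ci4 <- coalescent_intervals(tr4)
  expect_equal(ci4$k, c(4, 3, 2))
  expect_equal(ci4$duration, c(1, 0.5, 2.5))
  expect_equal(attr(ci4, "depth"), 4)
})

test_that("interval extraction matches the ape reference on Kingman trees", {
  set.seed(102)
  for (rep in 1:5) {
    tr <- simulate_kingman_tree(12, 0.05)
    ci <- coalescent_intervals(tr)
    ref <- ape::coalescent.intervals(tr)
    expect_equal(ci$duration, ref$interval.length, tolerance = 1e-9)
    expect_equal(ci$k, ref$lineages)
    expect_equal(sum(ci$duration), max(ape::branching.times(tr)), tolerance = 1e-9)
  }
})

test_that("non-ultrametric and non-binary trees are rejected", {
  expect_error(coalescent_intervals(ape::read.tree(text = "(A:1,B:2);")),
               "ultrametric")
  multi <- ape::read.tree(text = "(A:1,B:1,C:1);")
  expect_error(coalescent_intervals(multi), "binary")
})

test_that("Kingman simulation matches coalescent expectations", {
  set.seed(103)
  d2 <- replicate(4000, sum(coalescent_intervals(simulate_kingman_tree(2, 0.02))$duration))
  expect_equal(mean(d2), 0.02, tolerance = 0.05)

  tmrca <- replicate(800, sum(coalescent_intervals(simulate_kingman_tree(10, 0.02))$duration))
  expect_equal(mean(tmrca), 2 * 0.02 * (1 - 1 / 10), tolerance = 0.05)

  tr <- simulate_kingman_tree(25, 0.01)
  expect_true(ape::is.binary(tr))
  expect_lt(diff(range(coalbias:::tip_depths(tr))), 1e-9)
})

test_that("Newick files round-trip and gate non-binary trees", {
  path <- withr::local_tempfile(fileext = ".nwk")
  tr <- ape::read.tree(text = "(A:1,B:1);")
  write_newick(tr, path)
  expect_equal(read_newick(path)$edge.length, tr$edge.length)

  set.seed(104)
  big <- simulate_kingman_tree(100, 0.01)
  write_newick(big, path)
  back <- read_newick(path)
  expect_equal(sort(back$tip.label), sort(big$tip.label))
  expect_equal(sum(back$edge.length), sum(big$edge.length), tolerance = 1e-10)
  expect_equal(unname(sort(ape::branching.times(back))),
               unname(sort(ape::branching.times(big))), tolerance = 1e-10)

  writeLines("(A:1,B:1,C:1);", path)
  expect_error(read_newick(path), "not binary")
  expect_silent(read_newick(path, require_binary = FALSE))
})
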