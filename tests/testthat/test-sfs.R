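test_that("a singleton site lands in the first frequency class", {
  anc <- rep(1L, 20)
  geno <- matrix(c(2L, 1L, 1L, 1L), ncol = 1)
  sfs <- unfolded_sfs(sample_alignment(geno, 5, anc))
  expect_equal(sfs$xi, c(1, 0, 0))
  expect_equal(sfs$S, 1)
})

test_that("the SFS matches a site-by-site brute-force tally on random alignments", {
  set.seed(81)
  for (rep in 1:6) {
    smp <- random_alignment(n = 6, L = 20, n_var = 12)
    full <- match(coalbias:::alignment_matrix(smp), c("a", "c", "g", "t"))
    full <- matrix(full, nrow = 6)
    sfs <- unfolded_sfs(smp)
    expect_equal(sfs$xi, oracle_sfs(full, smp$ancestral))
    expect_equal(sfs$S, sum(oracle_sfs(full, smp$ancestral)))
  }
})

test_that("the SFS is invariant under relabeling of individuals", {
  set.seed(82)
  smp <- random_alignment(n = 10, L = 50)
  perm <- sample(10)
  smp2 <- sample_alignment(smp$geno[perm, ], smp$positions, smp$ancestral)
  expect_equal(unfolded_sfs(smp)$xi, unfolded_sfs(smp2)$xi)
})

test_that("the transformed SFS is flat for a 1/i spectrum and sums to one", {
  n <- 30
  sfs <- sfs_from_counts(840 / seq_len(n - 1), n) # xi ~ theta/i exactly
  tr <- transform_normalize(sfs)
  expect_equal(tr, rep(1 / (n - 1), n - 1))
  expect_equal(transform_normalize(sfs_from_counts(c(4, 1), 3)), c(2 / 3, 1 / 3))
  set.seed(83)
  r <- sfs_from_counts(rpois(19, 10), 20)
  expect_equal(sum(transform_normalize(r)), 1)
  empty <- sfs_from_counts(numeric(19), 20)
  expect_error(transform_normalize(empty), "no segregating sites")
})

test_that("Watterson's expectation equals the harmonic-sum closed form", {
  expect_equal(watterson_expected_S(0.02, 20000, 100),
               0.02 * 20000 * sum(1 / 1:99))
  expect_equal(watterson_expected_S(0.02, 20000, 100), 2070.9, tolerance = 1e-4)
  expect_equal(watterson_expected_S(0.5, 100, 2), 50)
  expect_equal(watterson_expected_S(0, 1000, 10), 0)
})

test_that("Tajima's D matches an independent from-scratch evaluation", {
  # n = 4, sites with derived counts {1, 1, 2}
  anc <- rep(1L, 40)
  geno <- cbind(c(2L, 1L, 1L, 1L), c(1L, 3L, 1L, 1L), c(2L, 2L, 1L, 1L))
  smp <- sample_alignment(geno, c(5, 9, 22), anc)
  full <- matrix(match(coalbias:::alignment_matrix(smp), c("a", "c", "g", "t")),
                 nrow = 4)
  pi_bf <- oracle_pi(full)
  expect_equal(tajimas_d(smp), oracle_tajima(pi_bf, 3, 4), tolerance = 1e-12)

  set.seed(84)
  for (rep in 1:4) {
    smp <- random_alignment(n = 8, L = 60, n_var = 25)
    sfs <- unfolded_sfs(smp)
    if (sfs$n_multiallelic > 0 || sfs$S == 0) next
    full <- matrix(match(coalbias:::alignment_matrix(smp), c("a", "c", "g", "t")),
                   nrow = 8)
    expect_equal(tajimas_d(smp), oracle_tajima(oracle_pi(full), sfs$S, 8),
                 tolerance = 1e-10)
  }
})

test_that("Tajima's D is undefined without polymorphism", {
  anc <- rep(2L, 30)
  smp <- sample_alignment(matrix(2L, 5, 1), 3, anc)
  expect_true(is.na(tajimas_d(smp)))
})

test_that("multiallelic and fixed-derived sites are excluded and logged", {
  anc <- rep(1L, 30)
  geno <- cbind(c(2L, 3L, 1L, 1L),   # three alleles with ancestor
                c(2L, 2L, 2L, 2L),   # fixed derived
                c(4L, 4L, 1L, 1L))   # clean biallelic, i = 2
  sfs <- unfolded_sfs(sample_alignment(geno, c(2, 9, 15), anc))
  expect_equal(sfs$S, 1)
  expect_equal(sfs$xi, c(0, 1, 0))
  expect_equal(sfs$n_multiallelic, 1L)
  expect_equal(sfs$n_fixed_derived, 1L)
})
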