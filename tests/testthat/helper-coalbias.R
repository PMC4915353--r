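# Shared fixtures and independent oracles. Simulations used by several test
# files are cached per session so the suite stays fast.

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, maker) {
  if (!exists(key, .sim_cache)) assign(key, maker(), .sim_cache)
  get(key, .sim_cache)
}

# full N x L allele matrix of a population (small scale only)
pop_matrix <- function(pop) {
  m <- matrix(rep(pop$background, each = pop$N), nrow = pop$N)
  if (length(pop$positions)) m[, pop$positions] <- pop$geno
  m
}

# hand-built population with a single polymorphic column
make_pop_one_column <- function(N, L, site, carriers, derived = 2L,
                                anc = 1L, s_val = 0) {
  pop <- new_population(N, L, background = rep(anc, L))
  geno <- rep(anc, N)
  geno[carriers] <- derived
  pop$positions <- as.integer(site)
  pop$geno <- matrix(as.integer(geno), ncol = 1)
  pop$anc <- as.integer(anc)
  s <- rep(NA_real_, 4); s[anc] <- 0; s[derived] <- s_val
  pop$s <- matrix(s, ncol = 1)
  pop$logfit <- log1p(ifelse(geno == derived, s_val, 0))
  pop
}

# population of g haplotype groups differing at many sites: guaranteed
# cluster structure for the sampling-bias tests
make_structured_pop <- function(N, L, groups, sites_per_group = 8) {
  pop <- new_population(N, L, background = rep(1L, L))
  grp <- rep(seq_len(groups), length.out = N)
  pos <- sample.int(L, groups * sites_per_group)
  geno <- matrix(1L, N, length(pos))
  for (g in seq_len(groups)) {
    cols <- (g - 1) * sites_per_group + seq_len(sites_per_group)
    geno[grp == g, cols] <- 3L
  }
  pop$positions <- sort(pos)
  pop$geno <- geno[, order(pos), drop = FALSE]
  pop$anc <- rep(1L, length(pos))
  pop$s <- matrix(rep(c(0, NA, 0, NA), length(pos)), nrow = 4)
  attr(pop, "group") <- grp
  pop
}

# random sample_alignment fixture
random_alignment <- function(n, L, n_var = max(2, L %/% 4)) {
  anc <- sample.int(4L, L, replace = TRUE)
  pos <- sort(sample.int(L, n_var))
  geno <- matrix(rep(anc[pos], each = n), nrow = n)
  flips <- matrix(runif(n * n_var) < 0.4, n, n_var)
  alt <- matrix(sample.int(4L, n * n_var, replace = TRUE), n, n_var)
  geno[flips] <- alt[flips]
  sample_alignment(geno, pos, anc)
}

# --- independent oracles ------------------------------------------------

# site-by-site SFS tally from the full character matrices
oracle_sfs <- function(full, anc_full) {
  n <- nrow(full)
  xi <- integer(n - 1)
  for (j in seq_len(ncol(full))) {
    alle <- full[, j]
    if (length(union(unique(alle), anc_full[j])) != 2) next
    i <- sum(alle != anc_full[j])
    if (i >= 1 && i <= n - 1) xi[i] <- xi[i] + 1L
  }
  xi
}

# all-pairs mismatch mean (pi) from a full matrix
oracle_pi <- function(full) {
  n <- nrow(full)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(full[i, ] != full[j, ])
  tot / choose(n, 2)
}

# Tajima's D from first principles (constants recomputed independently)
oracle_tajima <- function(pi, S, n) {
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (pi - S / a1) / sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

# exhaustive PAM cost minimisation over all medoid subsets
oracle_pam_best <- function(d, k) {
  n <- nrow(d)
  combos <- utils::combn(n, k)
  best <- NULL; best_cost <- Inf
  for (col in seq_len(ncol(combos))) {
    meds <- combos[, col]
    cost <- sum(apply(d[, meds, drop = FALSE], 1, min))
    if (cost < best_cost) { best_cost <- cost; best <- meds }
  }
  list(medoids = best, cost = best_cost)
}
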