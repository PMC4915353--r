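#' Population state
#'
#' A haploid population over a finite-sites locus, held sparsely: a
#' monomorphic background sequence plus one column per currently polymorphic
#' site. Each column records the allele carried by every individual, the
#' ancestral (pre-mutation) allele, and the selection coefficient attached to
#' each of the four nucleotides at that site (0 for the ancestral allele).
#' Alleles are coded 1..4 for a, c, g, t. `logfit` is the incrementally
#' tracked log-fitness of every individual; [population_fitness()] recomputes
#' it from scratch.
#'
#' @param N population size.
#' @param L locus length (nt).
#' @param background optional integer vector (1..4) of length `L`; drawn
#'   uniformly if missing.
#' @return A `wf_population`: the monomorphic starting state (no polymorphic
#'   columns, generation 0).
#' @export
new_population <- function(N, L, background = NULL) {
  if (is.null(background)) background <- sample.int(4L, L, replace = TRUE)
  stopifnot(length(background) == L, all(background %in% 1:4), N >= 2)
  structure(list(
    N = as.integer(N), L = as.integer(L),
    background = as.integer(background),
    positions = integer(0),
    geno = matrix(integer(0), nrow = N, ncol = 0),
    anc = integer(0),
    s = matrix(numeric(0), nrow = 4, ncol = 0),
    logfit = numeric(N),
    generation = 0L
  ), class = "wf_population")
}

#' @export
print.wf_population <- function(x, ...) {
  cat(sprintf("<wf_population> N = %d, L = %d, generation %d, %d polymorphic site(s)\n",
              x$N, x$L, x$generation, length(x$positions)))
  invisible(x)
}

#' Recompute log-fitness from scratch
#'
#' Fitness is multiplicative across sites, a factor (1 + s) per carried
#' allele, so log-fitness is the sum of `log1p(s)` over the population's
#' polymorphic columns. Used to verify the incremental bookkeeping in
#' `$logfit`.
#'
#' @param pop a `wf_population`.
#' @return numeric vector of length `N`.
#' @export
population_fitness <- function(pop) {
  P <- length(pop$positions)
  lf <- numeric(pop$N)
  if (P == 0) return(lf)
  for (cc in seq_len(P)) lf <- lf + log1p(pop$s[pop$geno[, cc], cc])
  lf
}

#' Draw a mutation's fitness class
#'
#' Each new derived allele is deleterious, neutral or adaptive with the
#' configured probabilities (the three-point-mass model of fitness effects),
#' and carries the corresponding selection coefficient.
#'
#' @param class_probs probabilities (deleterious, neutral, adaptive).
#' @param s_del,s_adv coefficients for the two selected classes.
#' @param n number of draws.
#' @return data.frame with columns `class` (factor) and `s`.
#' @export
assign_mutation_class <- function(class_probs, s_del = 0, s_adv = 0, n = 1) {
  stopifnot(length(class_probs) == 3, abs(sum(class_probs) - 1) < 1e-8)
  cls <- sample(c("deleterious", "neutral", "adaptive"), n, replace = TRUE,
                prob = class_probs)
  s <- c(deleterious = s_del, neutral = 0, adaptive = s_adv)[cls]
  data.frame(class = factor(cls, levels = c("deleterious", "neutral", "adaptive")),
             s = unname(s))
}

# Insert a new polymorphic column for site j (1-based); all individuals carry
# the current background allele, which becomes the column's ancestral state.
add_column <- function(pop, j) {
  bg <- pop$background[j]
  pop$positions <- c(pop$positions, j)
  pop$geno <- cbind(pop$geno, rep.int(bg, pop$N))
  pop$anc <- c(pop$anc, bg)
  pop$s <- cbind(pop$s, rep(NA_real_, 4))
  pop$s[bg, ncol(pop$s)] <- 0
  pop
}

#' One generation of mutation
#'
#' The number of events is Poisson(N L u); each event hits a uniform
#' (individual, site) pair and replaces the current nucleotide by one of the
#' other three uniformly (JC69). A derived allele seen for the first time at
#' its site is assigned a fitness class by `class_probs`; back-mutations to
#' the ancestral allele are neutral by definition.
#'
#' @param pop a `wf_population`.
#' @param u_site per-site per-generation mutation probability.
#' @param class_probs,s_del,s_adv see [assign_mutation_class()].
#' @return the mutated `wf_population`.
#' @export
mutate_generation <- function(pop, u_site, class_probs = c(0, 1, 0),
                              s_del = 0, s_adv = 0) {
  stopifnot(u_site >= 0, u_site < 1)
  if (u_site == 0) return(pop)
  nm <- stats::rpois(1, pop$N * pop$L * u_site)
  if (nm == 0) return(pop)
  for (e in seq_len(nm)) {
    i <- sample.int(pop$N, 1)
    j <- sample.int(pop$L, 1)
    cc <- match(j, pop$positions)
    if (is.na(cc)) {
      pop <- add_column(pop, j)
      cc <- length(pop$positions)
    }
    cur <- pop$geno[i, cc]
    a <- setdiff(1:4, cur)[sample.int(3, 1)]
    if (is.na(pop$s[a, cc])) {
      pop$s[a, cc] <- if (a == pop$anc[cc]) 0 else
        assign_mutation_class(class_probs, s_del, s_adv)$s
    }
    pop$logfit[i] <- pop$logfit[i] + log1p(pop$s[a, cc]) - log1p(pop$s[cur, cc])
    pop$geno[i, cc] <- a
  }
  pop
}

# geometric tract lengths on {1, 2, ...} with the given mean
rtract <- function(n, tract_mean) 1L + stats::rgeom(n, 1 / tract_mean)

#' One generation of gene conversion
#'
#' Initiation events number Poisson(N L rho), rho = `conv_init_ratio * u_site`
#' per site. Each event picks a recipient (individual, site), a donor uniform
#' among the other N - 1 individuals, and a geometric tract length with mean
#' `tract_mean`, placed from the initiation site towards the locus end and
#' clipped there. Donor alleles overwrite recipient alleles inside the tract;
#' conversion copies existing alleles and never creates new ones.
#'
#' @param pop a `wf_population`.
#' @param conv_init_ratio initiation rate over mutation rate (rho/mu).
#' @param u_site per-site mutation probability.
#' @param tract_mean mean tract length (nt).
#' @return the converted `wf_population`.
#' @export
gene_conversion_step <- function(pop, conv_init_ratio, u_site, tract_mean = 542) {
  stopifnot(conv_init_ratio >= 0, tract_mean >= 1)
  if (conv_init_ratio == 0 || length(pop$positions) == 0) return(pop)
  nc <- stats::rpois(1, pop$N * pop$L * conv_init_ratio * u_site)
  for (e in seq_len(nc)) {
    i <- sample.int(pop$N, 1)
    j <- sample.int(pop$L, 1)
    d <- sample.int(pop$N - 1, 1)
    if (d >= i) d <- d + 1
    len <- rtract(1, tract_mean)
    cols <- which(pop$positions >= j & pop$positions <= min(j + len - 1, pop$L))
    for (cc in cols) {
      da <- pop$geno[d, cc]; ra <- pop$geno[i, cc]
      if (da != ra) {
        pop$logfit[i] <- pop$logfit[i] + log1p(pop$s[da, cc]) - log1p(pop$s[ra, cc])
        pop$geno[i, cc] <- da
      }
    }
  }
  pop
}

#' One generation of selection and reproduction
#'
#' Wright-Fisher resampling: the next generation's N individuals choose
#' parents multinomially with probabilities proportional to fitness
#' (multiplicative across sites). Columns that become monomorphic are folded
#' into the background.
#'
#' @param pop a `wf_population`.
#' @return the next-generation `wf_population`.
#' @export
select_reproduce <- function(pop) {
  w <- exp(pop$logfit - max(pop$logfit))
  if (any(!is.finite(w)) || sum(w) <= 0)
    stop("degenerate fitness values; cannot form reproduction probabilities")
  parents <- sample.int(pop$N, pop$N, replace = TRUE, prob = w)
  pop$geno <- pop$geno[parents, , drop = FALSE]
  pop$logfit <- pop$logfit[parents]
  pop$generation <- pop$generation + 1L
  compact_population(pop)
}

# Fold monomorphic columns into the background (rebasing fitness for fixed
# selected alleles, which have become a constant factor).
compact_population <- function(pop) {
  P <- length(pop$positions)
  if (P == 0) return(pop)
  mono <- vapply(seq_len(P), function(cc) {
    all(pop$geno[, cc] == pop$geno[1, cc])
  }, logical(1))
  if (!any(mono)) return(pop)
  for (cc in which(mono)) {
    a <- pop$geno[1, cc]
    pop$background[pop$positions[cc]] <- a
    sa <- pop$s[a, cc]
    if (!is.na(sa) && sa != 0) pop$logfit <- pop$logfit - log1p(sa)
  }
  keep <- !mono
  pop$positions <- pop$positions[keep]
  pop$geno <- pop$geno[, keep, drop = FALSE]
  pop$anc <- pop$anc[keep]
  pop$s <- pop$s[, keep, drop = FALSE]
  pop
}

#' Evolve a population one full generation (R reference path)
#'
#' Mutation, then gene conversion, then selection/reproduction — the same
#' event order as the compiled engine.
#'
#' @param pop a `wf_population`.
#' @param cfg a `scenario_config`.
#' @return the evolved `wf_population`.
#' @export
step_generation <- function(pop, cfg) {
  pop <- mutate_generation(pop, cfg$u_site, cfg$class_probs, cfg$s_del, cfg$s_adv)
  pop <- gene_conversion_step(pop, cfg$conv_init_ratio, cfg$u_site, cfg$tract_mean)
  select_reproduce(pop)
}
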