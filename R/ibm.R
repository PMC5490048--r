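# Stochastic individual-based simulation of the annual life cycle.
#
# Each individual carries three loci (z1, z2, h) with continuous allelic
# values in [0, 1], expressed in codominance (phenotype = mean of carried
# alleles).  Females are diploid; males are haploid under haplodiploidy
# and diploid under diploidy.  Sex-ratio loci are expressed by
# reproductive females only; the helping locus by spring-born daughters.
#
# Genome layout: females (and diploid males) are rows of a 6-column
# matrix (z1a, z1b, z2a, z2b, ha, hb); haploid males are rows of a
# 3-column matrix (z1, z2, h).  "Sperm" stores the father's genome; a
# fresh gamete (with mutation) is drawn from it at each fertilisation.

#' Settings for the individual-based simulation
#'
#' Defaults are the simulation parameters of the study design: 5,000
#' nests, mutation probability 0.01 per allele per transmission, mutation
#' step s.d. 0.01, 25,000 simulated years with helping-locus mutation
#' switched on after year 10,000.
#'
#' @param N Number of nests (founding females) each spring.
#' @param mu Mutation probability per allele per transmission.
#' @param sigma Standard deviation of the normal mutation step.
#' @param T_years Number of simulated years.
#' @param h_mutation_start Year after which the helping locus mutates.
#' @param seed RNG seed.
#' @return A list of class `"sim_settings"`.
#' @export
sim_settings <- function(N = 5000, mu = 0.01, sigma = 0.01,
                         T_years = 25000, h_mutation_start = 10000,
                         seed = 1) {
  if (N < 2) stop("N < 2: need at least two nests")
  structure(list(N = as.integer(N), mu = mu, sigma = sigma,
                 T_years = as.integer(T_years),
                 h_mutation_start = as.integer(h_mutation_start),
                 seed = as.integer(seed)),
            class = "sim_settings")
}

#' Mutate allelic values
#'
#' With probability `mu` per allele, adds a normal deviate with s.d.
#' `sigma` and clips the result to `[0, 1]`.
#'
#' @param value Numeric vector of allelic values in `[0, 1]`.
#' @param mu Mutation probability per allele.
#' @param sigma Mutation step s.d.
#' @return The mutated vector.
#' @export
mutate_allele <- function(value, mu, sigma) {
  if (mu <= 0 || length(value) == 0) return(value)
  hit <- stats::runif(length(value)) < mu
  if (any(hit))
    value[hit] <- pmin(1, pmax(0, value[hit] +
                                 stats::rnorm(sum(hit), 0, sigma)))
  value
}

# mutate a 3-column gamete matrix; the h locus (column 3) has its own rate
mutate_gametes <- function(gam, mu, sigma, mu_h) {
  n <- nrow(gam)
  if (n == 0 || (mu <= 0 && mu_h <= 0)) return(gam)
  hit <- which(stats::runif(3L * n) < rep(c(mu, mu, mu_h), each = n))
  if (length(hit))
    gam[hit] <- pmin(1, pmax(0, gam[hit] +
                               stats::rnorm(length(hit), 0, sigma)))
  gam
}

# one gamete per requested row of a 6-column diploid genome matrix
gametes_diploid <- function(G, rows, mu, sigma, mu_h) {
  n <- length(rows)
  gam <- matrix(0, n, 3)
  if (n > 0) {
    pick <- (stats::runif(3L * n) < 0.5) + 1L  # which homologue, per locus
    gam[] <- G[cbind(rep.int(rows, 3L),
                     rep(c(0L, 2L, 4L), each = n) + pick)]
  }
  mutate_gametes(gam, mu, sigma, mu_h)
}

# haploid fathers transmit their whole (single-copy) genome
gametes_haploid <- function(M, rows, mu, sigma, mu_h) {
  mutate_gametes(M[rows, , drop = FALSE], mu, sigma, mu_h)
}

expressed <- function(G)
  cbind(z1 = (G[, 1] + G[, 2]) / 2,
        z2 = (G[, 3] + G[, 4]) / 2,
        h = (G[, 5] + G[, 6]) / 2)

# paternity shares over ceiling(m_e) males such that the sum of squared
# shares equals 1/m_e (equal shares, with one adjusted share when m_e is
# not an integer)
paternity_shares <- function(m_e) {
  k <- ceiling(m_e)
  if (k <= 1) return(1)
  a <- k - 1
  disc <- 1 - (1 + a) * (1 - 1 / m_e) / a
  q <- (1 + sqrt(max(disc, 0))) / (1 + a)
  c(rep(q, a), 1 - a * q)
}

# each of n females draws `k` (distinct where possible) mates from the
# male genome matrix; returns a list of k sperm matrices
draw_mates <- function(males, n, k) {
  nm <- nrow(males)
  if (nm == 0 || n == 0) return(NULL)
  draw <- matrix(sample.int(nm, n * k, replace = TRUE), n, k)
  if (k > 1 && nm >= k) {
    for (it in 1:10) {
      bad <- which(apply(draw, 1, anyDuplicated) > 0)
      if (!length(bad)) break
      draw[bad, ] <- sample.int(nm, length(bad) * k, replace = TRUE)
    }
  }
  lapply(seq_len(k), function(j) males[draw[, j], , drop = FALSE])
}

# Poisson brood of all mothers at their expressed sex ratio (compiled
# inner loop; one gamete with mutation per transmission).
# Gm: mothers' genomes; sperm: list of sperm matrices; shares: paternity
# shares; fec: per-mother fecundity; z: per-mother proportion sons.
make_brood <- function(Gm, sperm, shares, fec, z, haplo, mu, sigma, mu_h) {
  if (nrow(Gm) == 0 || length(sperm) == 0)
    return(list(daughters = matrix(0, 0, 6), d_mother = integer(0),
                sons = matrix(0, 0, if (haplo) 3 else 6),
                s_mother = integer(0)))
  .brood_cpp(Gm, sperm, as.numeric(shares), as.numeric(fec),
             as.numeric(z), haplo, mu, sigma, mu_h)
}

#' Initialise the simulated population
#'
#' All sex-ratio alleles start at 0.5 and all helping alleles at 0.  FH
#' populations start as `N` mated foundresses (with stored sperm of the
#' configured number of males); LD populations start as `N` unmated
#' females plus `N` overwintered males.
#'
#' @param settings A [sim_settings()].
#' @inheritParams helper_effect
#' @return A population list (`G` plus `sperm`/`shares` for FH, `G` plus
#'   `males` for LD).
#' @export
initialize_population <- function(settings, config) {
  config <- validate_config(config)
  N <- settings$N
  haplo <- config$ploidy == "haplodiploid"
  G <- matrix(rep(c(0.5, 0.5, 0.5, 0.5, 0, 0), each = N), N, 6)
  male0 <- function(n) {
    if (haplo) matrix(rep(c(0.5, 0.5, 0), each = n), n, 3)
    else matrix(rep(c(0.5, 0.5, 0.5, 0.5, 0, 0), each = n), n, 6)
  }
  shares <- if (config$mating == "polyandry") paternity_shares(config$m_e)
            else 1
  if (config$life_cycle == "FH") {
    sperm <- lapply(seq_along(shares), function(j) male0(N))
    list(G = G, sperm = sperm, shares = shares)
  } else {
    list(G = G, males = male0(N), shares = shares)
  }
}

#' Advance the simulation by one year
#'
#' Executes one full annual cycle: spring reproduction (Poisson offspring
#' numbers, offspring sex from the mother's expressed sex ratio,
#' unfertilised eggs male under haplodiploidy), the helping decision of
#' spring daughters (probability = their own expressed `h`), spring/summer
#' matings from the males currently available, female survival `S_f` with
#' helper-boosted summer fecundity, male survival `S_m` across broods,
#' the life-cycle-specific overwintering, and density-dependent
#' re-establishment of exactly `N` nests.  Females facing an empty mate
#' pool remain unmated and do not reproduce.
#'
#' @param pop Population from [initialize_population()] or a previous
#'   year.
#' @inheritParams helper_effect
#' @param settings A [sim_settings()].
#' @param year Current year (gates helping-locus mutation).
#' @return A list with the next `pop` (or `NULL` on extinction),
#'   `n_helpers`, and `extinct`.
#' @export
run_year <- function(pop, config, settings, year) {
  config <- validate_config(config)
  N <- settings$N
  mu <- settings$mu; sigma <- settings$sigma
  mu_h <- if (year > settings$h_mutation_start) mu else 0
  haplo <- config$ploidy == "haplodiploid"
  F1 <- config$F1; F3 <- config$F3
  S_f <- config$S_f; S_m <- config$S_m; b <- config$b
  dead_end <- list(pop = NULL, n_helpers = 0L, extinct = TRUE)

  if (config$life_cycle == "FH") {
    G <- pop$G
    n0 <- nrow(G)
    ex <- expressed(G)
    # spring brood (fathered by the stored sperm)
    br1 <- make_brood(G, pop$sperm, pop$shares, rep(F1, n0), ex[, "z1"],
                      haplo, mu, sigma, mu_h)
    hd <- (br1$daughters[, 5] + br1$daughters[, 6]) / 2
    helper <- stats::runif(length(hd)) < hd
    n_helpers_nest <- tabulate(br1$d_mother[helper], n0)
    G3 <- br1$daughters[!helper, , drop = FALSE]
    males1 <- br1$sons
    # spring mating: each new breeder takes a single spring male
    sperm3 <- draw_mates(males1, nrow(G3), 1)
    if (is.null(sperm3)) G3 <- G3[0, , drop = FALSE]
    # foundress survival; helpers of dead mothers are lost
    alive <- which(stats::runif(n0) < S_f)
    G5 <- G[alive, , drop = FALSE]
    F5v <- F1 * (1 + b * n_helpers_nest[alive])
    if (config$mating == "serial_monogamy") {
      sperm5 <- draw_mates(males1, length(alive), 1)  # fresh single mate
      shares5 <- 1
      if (is.null(sperm5)) G5 <- G5[0, , drop = FALSE]
      F5v <- F5v[seq_len(nrow(G5))]
    } else {
      sperm5 <- lapply(pop$sperm, function(S) S[alive, , drop = FALSE])
      shares5 <- pop$shares
    }
    brS <- make_brood(G3, sperm3, 1, rep(F3, nrow(G3)),
                      expressed(G3)[, "z2"], haplo, mu, sigma, mu_h)
    brF <- make_brood(G5, sperm5, shares5, F5v, ex[alive, "z2"],
                      haplo, mu, sigma, mu_h)
    autumn_d <- rbind(brS$daughters, brF$daughters)
    autumn_s <- rbind(brS$sons, brF$sons)
    # autumn pool: summer-brood sons plus surviving spring males
    surv7 <- males1[stats::runif(nrow(males1)) < S_m, , drop = FALSE]
    pool <- rbind(autumn_s, surv7)
    nd <- nrow(autumn_d)
    if (nd == 0 || nrow(pool) == 0) return(dead_end)
    k <- length(pop$shares)
    sperm_new <- draw_mates(pool, nd, k)
    keep <- if (nd > N) sample.int(nd, N) else seq_len(nd)
    list(pop = list(G = autumn_d[keep, , drop = FALSE],
                    sperm = lapply(sperm_new, function(S)
                      S[keep, , drop = FALSE]),
                    shares = pop$shares),
         n_helpers = sum(helper), extinct = FALSE)
  } else {
    G <- pop$G
    n0 <- nrow(G)
    if (nrow(pop$males) == 0) return(dead_end)
    ex <- expressed(G)
    k <- length(pop$shares)
    # spring mating of the overwintered, as-yet unmated females
    sperm1 <- draw_mates(pop$males, n0, k)
    br1 <- make_brood(G, sperm1, pop$shares, rep(F1, n0), ex[, "z1"],
                      haplo, mu, sigma, mu_h)
    hd <- (br1$daughters[, 5] + br1$daughters[, 6]) / 2
    helper <- stats::runif(length(hd)) < hd
    n_helpers_nest <- tabulate(br1$d_mother[helper], n0)
    G3 <- br1$daughters[!helper, , drop = FALSE]
    # summer male pool: surviving overwintered males + spring-born sons
    survm <- pop$males[stats::runif(nrow(pop$males)) < S_m, , drop = FALSE]
    pool2 <- rbind(survm, br1$sons)
    sperm3 <- draw_mates(pool2, nrow(G3), 1)
    if (is.null(sperm3)) G3 <- G3[0, , drop = FALSE]
    alive <- which(stats::runif(n0) < S_f)
    G5 <- G[alive, , drop = FALSE]
    F5v <- F1 * (1 + b * n_helpers_nest[alive])
    sperm5 <- lapply(sperm1, function(S) S[alive, , drop = FALSE])
    brS <- make_brood(G3, sperm3, 1, rep(F3, nrow(G3)),
                      expressed(G3)[, "z2"], haplo, mu, sigma, mu_h)
    brF <- make_brood(G5, sperm5, pop$shares, F5v, ex[alive, "z2"],
                      haplo, mu, sigma, mu_h)
    autumn_d <- rbind(brS$daughters, brF$daughters)
    autumn_s <- rbind(brS$sons, brF$sons)
    nd <- nrow(autumn_d)
    if (nd == 0) return(dead_end)
    # common winter survival for both sexes re-establishes N nests
    frac <- min(1, N / nd)
    keep_d <- if (nd > N) sample.int(nd, N) else seq_len(nd)
    keep_s <- which(stats::runif(nrow(autumn_s)) < frac)
    list(pop = list(G = autumn_d[keep_d, , drop = FALSE],
                    males = autumn_s[keep_s, , drop = FALSE],
                    shares = pop$shares),
         n_helpers = sum(helper), extinct = FALSE)
  }
}

#' Run the individual-based simulation
#'
#' Simulates `T_years` annual cycles, recording each spring the mean and
#' s.d. of the expressed traits among that year's foundresses.
#' Helping-locus mutation is disabled until `h_mutation_start`, so the
#' sex ratios equilibrate first.  With a fixed seed the output is
#' reproducible bit for bit.
#'
#' @inheritParams helper_effect
#' @param settings A [sim_settings()].
#' @param out Optional CSV path; the file carries the full configuration
#'   and seed as `#`-prefixed header comments.
#' @return A data frame of yearly records: `year`, `z1_mean`, `z1_sd`,
#'   `z2_mean`, `z2_sd`, `h_mean`, `h_sd`, `n_foundresses`, `n_helpers`,
#'   `extinct`.
#' @export
run_simulation <- function(config, settings = sim_settings(), out = NULL) {
  config <- validate_config(config)
  set.seed(settings$seed)
  pop <- initialize_population(settings, config)
  T_years <- settings$T_years
  rec <- matrix(NA_real_, T_years, 9)
  colnames(rec) <- c("year", "z1_mean", "z1_sd", "z2_mean", "z2_sd",
                     "h_mean", "h_sd", "n_foundresses", "n_helpers")
  extinct_at <- NA_integer_
  for (year in seq_len(T_years)) {
    ex <- expressed(pop$G)
    rec[year, ] <- c(year, mean(ex[, 1]), stats::sd(ex[, 1]),
                     mean(ex[, 2]), stats::sd(ex[, 2]),
                     mean(ex[, 3]), stats::sd(ex[, 3]),
                     nrow(pop$G), NA)
    step <- run_year(pop, config, settings, year)
    rec[year, "n_helpers"] <- step$n_helpers
    if (step$extinct) {
      extinct_at <- year
      break
    }
    pop <- step$pop
  }
  res <- as.data.frame(rec[!is.na(rec[, 1]), , drop = FALSE])
  res$extinct <- !is.na(extinct_at) & res$year == extinct_at
  if (!is.null(out)) {
    hdr <- c(sprintf("# eusocia individual-based simulation"),
             sprintf("# life_cycle=%s ploidy=%s mating=%s m_e=%g",
                     config$life_cycle, config$ploidy, config$mating,
                     config$m_e),
             sprintf("# F1=%g F3=%g S_f=%g S_m=%g b=%g",
                     config$F1, config$F3, config$S_f, config$S_m,
                     config$b),
             sprintf("# N=%d mu=%g sigma=%g T_years=%d h_mutation_start=%d seed=%d",
                     settings$N, settings$mu, settings$sigma,
                     settings$T_years, settings$h_mutation_start,
                     settings$seed))
    con <- file(out, "w")
    writeLines(hdr, con)
    utils::write.csv(res, con, row.names = FALSE)
    close(con)
  }
  res
}
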