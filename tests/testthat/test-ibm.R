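test_that("initial populations have the prescribed allelic values", {
  cfg <- fig2_config()
  pop <- initialize_population(sim_settings(N = 100), cfg)
  ex <- eusocia:::expressed(pop$G)
  expect_true(all(ex[, "z1"] == 0.5) && all(ex[, "z2"] == 0.5))
  expect_true(all(ex[, "h"] == 0))
  # haplodiploid stored sperm is a single allele per locus
  expect_equal(ncol(pop$sperm[[1]]), 3)
  expect_equal(ncol(initialize_population(
    sim_settings(N = 50), fig3_config(ploidy = "diploid"))$sperm[[1]]), 6)
  expect_error(sim_settings(N = 1), "N < 2")
})

test_that("fixed seeds reproduce runs bit for bit", {
  cfg <- fig2_config()
  st <- sim_settings(N = 60, T_years = 40, h_mutation_start = 10, seed = 99)
  r1 <- run_simulation(cfg, st)
  r2 <- run_simulation(cfg, st)
  expect_identical(r1, r2)
  r3 <- run_simulation(cfg, sim_settings(N = 60, T_years = 40,
                                         h_mutation_start = 10, seed = 100))
  expect_false(identical(r1, r3))
})

test_that("mutation operator hits at the nominal rate and clips", {
  set.seed(5)
  n <- 1e6
  v <- mutate_allele(rep(0.5, n), mu = 0.01, sigma = 0.01)
  hits <- sum(v != 0.5)
  se <- sqrt(n * 0.01 * 0.99)
  expect_lt(abs(hits - n * 0.01), 3 * se)
  expect_equal(mutate_allele(rep(0.3, 100), mu = 0, sigma = 0.01),
               rep(0.3, 100))
  # boundary clipping
  set.seed(6)
  low <- mutate_allele(rep(0, 1e4), mu = 1, sigma = 5)
  expect_true(all(low >= 0 & low <= 1))
  expect_gt(mean(low == 0), 0.2)  # large negative draws clip to zero
})

test_that("all-male spring broods produce no daughters", {
  cfg <- fig2_config()
  pop <- initialize_population(sim_settings(N = 200), cfg)
  pop$G[, 1:2] <- 1  # z1 alleles fixed at 1
  set.seed(1)
  step <- run_year(pop, cfg, sim_settings(N = 200), year = 1)
  expect_equal(step$n_helpers, 0L)
})

test_that("haplodiploid sons carry only maternal alleles", {
  cfg <- fig2_config()
  N <- 50
  pop <- initialize_population(sim_settings(N = N), cfg)
  # give mothers recognisable alleles, fathers different ones
  pop$G[, 1:2] <- matrix(runif(2 * N, 0.6, 0.7), N)
  pop$sperm[[1]][, 1] <- runif(N, 0.1, 0.2)
  set.seed(2)
  br <- eusocia:::make_brood(pop$G, pop$sperm, 1, rep(5, N), rep(0.5, N),
                            haplo = TRUE, mu = 0, sigma = 0, mu_h = 0)
  expect_true(all(br$sons[, 1] >= 0.6 & br$sons[, 1] <= 0.7))
  # daughters carry one maternal and one paternal allele
  expect_true(all(br$daughters[, 1] >= 0.6 & br$daughters[, 1] <= 0.7))
  expect_true(all(br$daughters[, 2] >= 0.1 & br$daughters[, 2] <= 0.2))
  # sons trace to the recorded mothers
  expect_true(all(br$s_mother %in% seq_len(N)))
})

test_that("winter density dependence restores exactly N nests", {
  cfg <- fig2_config()
  st <- sim_settings(N = 150, T_years = 25, h_mutation_start = 5, seed = 3)
  r <- run_simulation(cfg, st)
  expect_true(all(r$n_foundresses == 150))
  # LD cycle regulates to N too
  ld <- model_config("LD", "haplodiploid", "monogamy", F1 = 3, F3 = 3,
                     S_f = 0.9, S_m = 0.6, b = 1.5)
  rl <- run_simulation(ld, st)
  expect_true(all(rl$n_foundresses == 150))
  expect_false(any(rl$extinct))
})

test_that("helping stays exactly absent before its mutation release", {
  cfg <- fig2_config()
  r <- run_simulation(cfg, sim_settings(N = 100, T_years = 60,
                                        h_mutation_start = 40, seed = 8))
  expect_true(all(r$h_mean[r$year <= 40] == 0))
})

test_that("neutral runs show no directional trait change", {
  cfg <- fig3_config(S_m = 0)  # no overlap: sex ratios neutral at 1/2
  cfg$b <- 0
  cfg <- validate_config(unclass(cfg))
  st <- sim_settings(N = 300, mu = 0, T_years = 80,
                     h_mutation_start = 1e9, seed = 12)
  r <- run_simulation(cfg, st)
  # without mutation there is no variance to select on
  expect_true(all(r$z1_mean == 0.5))
  expect_true(all(r$z1_sd == 0))
})

test_that("simulated class counts match the analytic stable distribution", {
  # helper-free population held at the initial traits (mu = 0): per-year
  # spring brood counts against u3 + u4 = F1 (1 - z1) and u7 = F1 z1 per
  # foundress, over 100 replicate years
  cfg <- model_config("FH", "haplodiploid", "monogamy", F1 = 4, F3 = 4,
                      S_f = 0.9, S_m = 0.6, b = 0)
  N <- 2000
  u <- stable_classes(cfg, trait_state(0.5, 0.5, 0))$u
  set.seed(21)
  pop <- initialize_population(sim_settings(N = N, mu = 0), cfg)
  daughters <- sons <- numeric(100)
  for (i in 1:100) {
    br <- eusocia:::make_brood(pop$G, pop$sperm, 1, rep(cfg$F1, N),
                              rep(0.5, N), TRUE, 0, 0, 0)
    daughters[i] <- length(br$d_mother)
    sons[i] <- length(br$s_mother)
  }
  tol_d <- 3 * sd(daughters) / sqrt(100)
  tol_s <- 3 * sd(sons) / sqrt(100)
  expect_lt(abs(mean(daughters) -
                  N * unname(u["daughter_breeder"] + u["daughter_helper"])),
            tol_d)
  expect_lt(abs(mean(sons) - N * unname(u["male_spring"])), tol_s)
})

test_that("polyandrous paternity shares satisfy the effective-mates identity", {
  for (me in c(1, 1.5, 2, 2.5, 3.7, 6)) {
    p <- eusocia:::paternity_shares(me)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_equal(sum(p^2), 1 / me, tolerance = 1e-12)
    expect_true(all(p >= -1e-12))
    expect_equal(length(p), ceiling(me))
  }
})

test_that("serial monogamy and polyandry cycles run and regulate", {
  st <- sim_settings(N = 120, T_years = 15, h_mutation_start = 5, seed = 17)
  r1 <- run_simulation(fig3_config(mating = "serial_monogamy"), st)
  expect_true(all(r1$n_foundresses == 120))
  r2 <- run_simulation(fig3_config(mating = "polyandry", m_e = 2.5), st)
  expect_true(all(r2$n_foundresses == 120))
})

test_that("sex-ratio means settle near the analytic equilibria", {
  # helper-free haplodiploid FH populations; long-run mean of the
  # expressed spring sex ratio against the inclusive-fitness equilibrium
  for (sm in c(0, 0.6)) {
    cfg <- model_config("FH", "haplodiploid", "monogamy", F1 = 4, F3 = 4,
                        S_f = 0.9, S_m = sm, b = 0)
    eq <- sex_ratio_equilibrium(cfg, h_fixed = 0)
    st <- sim_settings(N = 800, T_years = 7000, h_mutation_start = 1e9,
                       seed = 30 + round(10 * sm))
    r <- run_simulation(cfg, st)
    z1_hat <- mean(r$z1_mean[r$year > 5000])
    z2_hat <- mean(r$z2_mean[r$year > 5000])
    expect_lt(abs(z1_hat - eq$z1), 0.03)
    expect_lt(abs(z2_hat - eq$z2), 0.03)
  }
})
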