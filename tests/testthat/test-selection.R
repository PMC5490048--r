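test_that("relatedness coefficients match the classic values", {
  rh <- relatedness_coefficients(fig3_config())
  expect_equal(rh$r_sis, 3 / 4)
  expect_equal(rh$r_dau, 1 / 2)
  expect_equal(rh$r_bro, 1 / 2)
  expect_equal(rh$r_son, 1)
  rd <- relatedness_coefficients(fig3_config(ploidy = "diploid"))
  expect_equal(rd$r_sis, 1 / 2)
  expect_equal(rd$r_bro, 1 / 2)
  expect_equal(rd$r_son, 1 / 2)
  # polyandry dilutes paternal sibship: p = 1/m_e
  r2 <- relatedness_coefficients(fig3_config(mating = "polyandry", m_e = 2))
  expect_equal(r2$r_sis, 1 / 4 + 1 / 4)
  rinf <- relatedness_coefficients(fig3_config(mating = "polyandry",
                                               m_e = 1e9))
  expect_equal(rinf$r_sis, 1 / 4, tolerance = 1e-8)
  # serial monogamy: cross-brood siblings are maternal half-siblings
  rs <- relatedness_coefficients(fig3_config(mating = "serial_monogamy"))
  expect_equal(rs$p, 0)
  expect_equal(rs$r_sis, 1 / 4)
  expect_equal(rs$r_bro, 1 / 2)
})

test_that("inclusive fitness is well-defined at the resident", {
  st <- resident_state(fig2_config(), trait_state(0.6, 0.4, 0.2))
  w_res <- inclusive_fitness_sex_ratio(st$traits, st)
  expect_true(is.finite(w_res) && w_res > 0)
  # linearity in the mutant traits makes the finite differences exact
  w_up <- inclusive_fitness_sex_ratio(list(z1 = 0.7, z2 = 0.4), st)
  w_dn <- inclusive_fitness_sex_ratio(list(z1 = 0.5, z2 = 0.4), st)
  mid <- inclusive_fitness_sex_ratio(list(z1 = 0.6, z2 = 0.4), st)
  expect_equal((w_up + w_dn) / 2, mid, tolerance = 1e-12)
  wh <- inclusive_fitness_helping(st$traits$h, st)
  expect_true(is.finite(wh) && wh > 0)
})

test_that("finite-difference gradients match the closed forms", {
  set.seed(31)
  for (i in 1:10) {
    cfg <- random_config()
    tr <- random_traits()
    st <- resident_state(cfg, tr)
    for (id in c("z1", "z2", "h")) {
      g_fd <- selection_gradient(id, state = st)
      g_cf <- eusocia:::selection_gradient_closed(id, st)
      expect_equal(g_fd, g_cf, tolerance = 1e-6)
    }
  }
})

test_that("sex ratios are unbiased without male generation overlap", {
  for (pl in c("haplodiploid", "diploid")) {
    st <- resident_state(fig3_config(ploidy = pl, S_m = 0),
                         trait_state(0.5, 0.5, 0))
    # gradients vanish up to the 1e-9 boundary clamp on resident traits
    # and the finite-difference noise floor
    expect_lt(abs(eusocia:::selection_gradient_closed("z1", st)), 1e-8)
    expect_lt(abs(eusocia:::selection_gradient_closed("z2", st)), 1e-8)
    expect_lt(abs(selection_gradient("z1", state = st)), 1e-8)
    expect_lt(abs(selection_gradient("z2", state = st)), 1e-8)
    eq <- sex_ratio_equilibrium(fig3_config(ploidy = pl, S_m = 0),
                                h_fixed = 0)
    expect_equal(eq$z1, 0.5, tolerance = 1e-7)
    expect_equal(eq$z2, 0.5, tolerance = 1e-7)
  }
})

test_that("overlap biases equilibrium sex ratios by life cycle", {
  # female hibernation: male-biased spring, female-biased summer
  st <- resident_state(fig3_config(S_m = 0.6), trait_state(0.5, 0.5, 0))
  expect_gt(selection_gradient("z1", state = st), 0)
  eq <- sex_ratio_equilibrium(fig3_config(S_m = 0.6), h_fixed = 0)
  expect_gt(eq$z1, 0.5)
  expect_lt(eq$z2, 0.5)
  # larval diapause: the reverse
  eql <- sex_ratio_equilibrium(
    model_config("LD", "haplodiploid", "monogamy", F1 = 2, F3 = 2,
                 S_f = 0.9, S_m = 0.6, b = 1.5), h_fixed = 0)
  expect_lt(eql$z1, 0.5)
  expect_gt(eql$z2, 0.5)
})

test_that("helping is never favoured without benefit", {
  set.seed(41)
  for (i in 1:5) {
    cfg <- random_config()
    cfg$b <- 0
    st <- resident_state(validate_config(cfg), random_traits())
    expect_lt(selection_gradient("h", state = st), 0)
  }
})

test_that("diploid helping is neutral exactly at B = 1 for any overlap", {
  for (sm in c(0, 0.5, 0.9)) {
    cfg <- fig3_config(ploidy = "diploid", S_m = sm)
    cfg$b <- 1 / cfg$S_f  # B = S_f * b = 1
    eq <- sex_ratio_equilibrium(cfg, h_fixed = 0)
    st <- resident_state(cfg, list(z1 = eq$z1, z2 = eq$z2, h = 0))
    expect_lt(abs(selection_gradient("h", state = st)), 1e-9)
  }
})

test_that("threshold limits reproduce the printed anchor values", {
  # haplodiploid FH monogamy: 1 without overlap, 2/3 at full overlap
  expect_equal(eusociality_threshold(fig3_config(S_m = 0))$B_min, 1,
               tolerance = 1e-4)
  expect_equal(eusociality_threshold(fig3_config(), om = 1 - 1e-9)$B_min,
               2 / 3, tolerance = 1e-4)
  # sign change brackets are reported when absent
  cfg_low <- fig3_config(S_m = 0)
  expect_error(eusociality_threshold(cfg_low, bracket = c(2, 10)),
               "no sign change")
})

test_that("threshold is monotone in polyandry and ordered across life cycles", {
  me_grid <- c(1, 1.5, 2, 3, 6)
  th <- vapply(me_grid, function(me)
    eusociality_threshold(
      fig3_config(mating = if (me == 1) "monogamy" else "polyandry",
                  m_e = me, S_m = 0.6))$B_min, numeric(1))
  expect_true(all(diff(th) > -1e-9))
  for (sm in c(0.3, 0.6)) {
    b_fh <- eusociality_threshold(fig3_config(S_m = sm))$B_min
    b_ld <- eusociality_threshold(
      model_config("LD", "haplodiploid", "monogamy", F1 = 2, F3 = 2,
                   S_f = 0.9, S_m = sm, b = 1.5))$B_min
    expect_gte(b_ld, b_fh - 1e-9)
  }
})

test_that("low polyandry with overlap can push the threshold below one", {
  # m_e < 2 plus strong male generation overlap is the only region with
  # B_min < 1
  th <- eusociality_threshold(fig3_config(mating = "polyandry", m_e = 1.5),
                              om = 0.9)$B_min
  expect_lt(th, 1)
  th2 <- eusociality_threshold(fig3_config(mating = "polyandry", m_e = 2.5),
                               om = 0.9)$B_min
  expect_gt(th2, 1)
})

test_that("coevolved-mode threshold is no larger than the fixed-ratio one", {
  cfg <- fig2_config()
  fixed <- eusociality_threshold(cfg, "fixed_sex_ratios")$B_min
  coev <- eusociality_threshold(cfg, "coevolved_sex_ratios")$B_min
  expect_lte(coev, fixed + 1e-4)
})
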