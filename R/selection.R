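# Relatedness, inclusive fitness, selection gradients, sex-ratio
# equilibria and the eusociality threshold.
#
# Relatedness coefficients are on the gene-contribution ("life-for-life")
# scale that matches the gene-flow credit rules: a coefficient is the
# expected share of the recipient's genome contributed by / identical to
# the focal female's, so coefficients toward haploid recipients (sons,
# brothers under haplodiploidy) are twice the diploid-normalised
# regression values.  On this scale, paired with reproductive values
# normalised to v_f2 = 1, maternal sex-ratio control gives unbiased
# equilibria whenever male generations do not overlap, for both ploidies.

#' Relatedness coefficients
#'
#' Returns the focal female's relatedness to her daughters, sons, sisters
#' and brothers under the configured genetics and mating system.  `p` is
#' the probability that two maternal sisters *in the brood a helper
#' rears* (the mother's summer brood, i.e. the helper's cross-brood
#' siblings) share a father: 1 under lifetime monogamy, `1/m_e` under
#' polyandry with lifetime sperm storage, and 0 under serial monogamy
#' (the two broods have different fathers).
#'
#' Haplodiploid: `r_dau = 1/2`, `r_son = 1`, `r_sis = 1/4 + p/2`,
#' `r_bro = 1/2` (brothers are purely maternal).  Diploid: `r_dau =
#' r_son = 1/2`, `r_sis = r_bro = (1 + p)/4 * 2 / 2` — i.e. `(1 + p)/4`
#' on the per-genome-share scale for diploid recipients, which gives full
#' sisters 1/2 and maternal half-sisters 1/4.
#'
#' @inheritParams helper_effect
#' @return A list with `r_dau`, `r_son`, `r_sis`, `r_bro`, `p`, `m_e`.
#' @export
relatedness_coefficients <- function(config) {
  config <- validate_config(config)
  p <- switch(config$mating,
              monogamy = 1,
              polyandry = 1 / config$m_e,
              serial_monogamy = 0)
  if (config$ploidy == "haplodiploid") {
    out <- list(r_dau = 0.5, r_son = 1,
                r_sis = 0.25 + p / 2, r_bro = 0.5)
  } else {
    out <- list(r_dau = 0.5, r_son = 0.5,
                r_sis = (1 + p) / 4, r_bro = (1 + p) / 4)
  }
  out$p <- p
  out$m_e <- if (config$mating == "serial_monogamy") Inf else config$m_e
  out
}

#' Resident population state
#'
#' Bundles everything needed to evaluate mutant inclusive fitness: the
#' resident demographic equilibrium, reproductive values and relatedness
#' coefficients, all at the resident trait values (clamped inward by
#' `eps` so boundary traits are evaluated as limits).
#'
#' @inheritParams helper_effect
#' @param om Optional prescribed male generation overlap (see
#'   [stable_classes()]).
#' @param eps Inward clamp for boundary traits.
#' @return A list with `config`, `traits`, `dem`, `rv`, `rel`.
#' @export
resident_state <- function(config, traits, om = NULL, eps = 1e-9) {
  config <- validate_config(config)
  tr <- clamp_traits(traits, eps)
  dem <- stable_classes(config, tr, om = om, check = FALSE)
  rv <- reproductive_values(config, tr, dem)
  list(config = config, traits = tr, dem = dem, rv = rv,
       rel = relatedness_coefficients(config))
}

# value of one own offspring produced at sex ratio z (autumn brood)
own_offspring_value <- function(state, z) {
  (1 - z) * state$rel$r_dau * state$rv$v_f2 +
    z * state$rel$r_son * state$rv$v_m2
}

# value of one extra sibling in the mother's summer brood
sibling_value <- function(state, z) {
  (1 - z) * state$rel$r_sis * state$rv$v_f2 +
    z * state$rel$r_bro * state$rv$v_m2
}

#' Inclusive fitness of a sex-ratio mutant
#'
#' Lifetime inclusive fitness of a focal spring (class-1) female with
#' mutant sex ratios `z1`, `z2` in a resident population at the state's
#' trait values: her `F1` spring offspring (daughters weighted by their
#' breeding prospects `(1 - h) v_f1`, sons by `v_m1`, each with the
#' appropriate relatedness), plus — if she survives with probability
#' `S_f` — her helper-boosted summer brood at mutant `z2`, where the
#' expected number of helpers responds to her mutant `z1`.  All
#' resident-dependent quantities (reproductive values, mate counts, class
#' frequencies) are held at their resident values.
#'
#' @param mutant_traits A [trait_state()]; `z1` and `z2` are the mutant
#'   values (its `h` is ignored — the focal's daughters help at the
#'   resident tendency).
#' @param resident_state A state from [resident_state()].
#' @return Scalar inclusive fitness.
#' @export
inclusive_fitness_sex_ratio <- function(mutant_traits, resident_state) {
  st <- resident_state
  cfg <- st$config; tr <- st$traits; rel <- st$rel; rv <- st$rv
  z1 <- mutant_traits$z1; z2 <- mutant_traits$z2
  h <- tr$h
  F5_mut <- cfg$F1 * (1 + cfg$b * h * (1 - z1) * cfg$F1)
  spring <- cfg$F1 * ((1 - z1) * (1 - h) * rel$r_dau * rv$v_f1 +
                        z1 * rel$r_son * rv$v_m1)
  summer <- cfg$S_f * F5_mut * own_offspring_value(st, z2)
  spring + summer
}

#' Inclusive fitness of a helping mutant
#'
#' Inclusive fitness of a focal spring-born daughter with mutant helping
#' tendency `h`: with probability `1 - h` she breeds independently
#' (`F3` offspring at the resident summer sex ratio, valued through
#' daughters and sons), and with probability `h` she stays, adding
#' `B = S_f * b` extra offspring per baseline offspring (`F1`) to her
#' mother's summer brood — extra sisters and brothers at the resident
#' summer sex ratio, weighted by sibling relatedness.
#'
#' @param mutant_h Mutant helping tendency in `[0, 1]`.
#' @inheritParams inclusive_fitness_sex_ratio
#' @return Scalar inclusive fitness.
#' @export
inclusive_fitness_helping <- function(mutant_h, resident_state) {
  st <- resident_state
  cfg <- st$config; z2 <- st$traits$z2
  B <- cfg$S_f * cfg$b
  (1 - mutant_h) * cfg$F3 * own_offspring_value(st, z2) +
    mutant_h * B * cfg$F1 * sibling_value(st, z2)
}

# class-3 female's inclusive fitness in her own summer brood (the second
# class expressing z2; the class-5 expression sits inside the class-1
# lifetime fitness)
if_z2_class3 <- function(z2_mut, state) {
  state$config$F3 * own_offspring_value(state, z2_mut)
}

# central finite difference with one-sided fallback at the [0,1] edges
fd_gradient <- function(f, x, step = 1e-6) {
  lo <- max(0, x - step); hi <- min(1, x + step)
  (f(hi) - f(lo)) / (hi - lo)
}

#' Selection gradient for one trait
#'
#' The derivative of mutant inclusive fitness in the mutant trait,
#' evaluated at the resident (central finite differences, step 1e-6,
#' one-sided at trait boundaries).  `z2` is expressed by two classes
#' (class-3 breeders and class-5 surviving foundresses); their gradients
#' are combined with normalised class-frequency weights.
#'
#' @param trait_id One of `"z1"`, `"z2"`, `"h"`.
#' @inheritParams resident_state
#' @param state Optional precomputed [resident_state()] (overrides
#'   `config`/`traits`).
#' @param step Finite-difference step on the trait scale.
#' @return Scalar selection gradient.
#' @export
selection_gradient <- function(trait_id, config, traits, om = NULL,
                               state = NULL, step = 1e-6) {
  if (is.null(state)) state <- resident_state(config, traits, om = om)
  tr <- state$traits
  switch(trait_id,
    z1 = fd_gradient(function(x)
      inclusive_fitness_sex_ratio(list(z1 = x, z2 = tr$z2), state),
      tr$z1, step),
    z2 = {
      u <- state$dem$u
      u3 <- u["daughter_breeder"]; u5 <- u["foundress_summer"]
      g3 <- fd_gradient(function(x) if_z2_class3(x, state), tr$z2, step)
      # class-5 gradient per surviving foundress: F5 offspring at mutant z2
      g5 <- fd_gradient(function(x)
        state$dem$F5 * own_offspring_value(state, x), tr$z2, step)
      w <- u3 + u5
      if (w == 0) 0 else as.numeric((u3 * g3 + u5 * g5) / w)
    },
    h = fd_gradient(function(x) inclusive_fitness_helping(x, state),
                    tr$h, step),
    stop("unknown trait_id: ", trait_id))
}

# closed-form gradients (cross-check path for the finite differences)
selection_gradient_closed <- function(trait_id, state) {
  cfg <- state$config; tr <- state$traits
  rel <- state$rel; rv <- state$rv
  switch(trait_id,
    z1 = cfg$F1 * (-(1 - tr$h) * rel$r_dau * rv$v_f1 +
                     rel$r_son * rv$v_m1) -
      cfg$S_f * cfg$b * tr$h * cfg$F1^2 * own_offspring_value(state, tr$z2),
    z2 = {
      u <- state$dem$u
      u3 <- u["daughter_breeder"]; u5 <- u["foundress_summer"]
      fbar <- if (u3 + u5 > 0) (u3 * cfg$F3 + u5 * state$dem$F5) / (u3 + u5)
              else 0
      as.numeric(fbar * (rel$r_son * rv$v_m2 - rel$r_dau * rv$v_f2))
    },
    h = -cfg$F3 * own_offspring_value(state, tr$z2) +
      cfg$S_f * cfg$b * cfg$F1 * sibling_value(state, tr$z2),
    stop("unknown trait_id: ", trait_id))
}

all_gradients <- function(state) {
  c(dW_dz1 = selection_gradient("z1", state = state),
    dW_dz2 = selection_gradient("z2", state = state),
    dW_dh = selection_gradient("h", state = state))
}

#' Joint equilibrium of the two brood sex ratios
#'
#' Solves `dW/dz1 = dW/dz2 = 0` at a fixed helping tendency by nested
#' root bracketing: for each candidate `z1` the summer ratio `z2` is
#' rooted first, then `z1` is rooted along that curve.  When a gradient
#' points outward over the whole interior, the corresponding boundary
#' value (0 or 1) is returned.
#'
#' @inheritParams resident_state
#' @param h_fixed Helping tendency at which the sex ratios equilibrate.
#' @param tol Root tolerance on the trait scale.
#' @param interior_eps Bracket ends used to probe the interior.
#' @return A list with `z1`, `z2`, the gradients at the solution, and
#'   `boundary` flags.
#' @export
sex_ratio_equilibrium <- function(config, h_fixed = 0, om = NULL,
                                  tol = 1e-10, interior_eps = 1e-7) {
  config <- validate_config(config)
  lo <- interior_eps; hi <- 1 - interior_eps
  g2 <- function(z1, z2)
    selection_gradient("z2", state = resident_state(
      config, list(z1 = z1, z2 = z2, h = h_fixed), om = om))
  z2_of_z1 <- function(z1) {
    flo <- g2(z1, lo); fhi <- g2(z1, hi)
    if (flo <= 0 && fhi <= 0) return(list(z2 = 0, boundary = TRUE))
    if (flo >= 0 && fhi >= 0) return(list(z2 = 1, boundary = TRUE))
    r <- stats::uniroot(function(z2) g2(z1, z2), c(lo, hi), tol = tol)
    list(z2 = r$root, boundary = FALSE)
  }
  g1 <- function(z1) {
    z2 <- z2_of_z1(z1)$z2
    selection_gradient("z1", state = resident_state(
      config, list(z1 = z1, z2 = z2, h = h_fixed), om = om))
  }
  flo <- g1(lo); fhi <- g1(hi)
  if (flo <= 0 && fhi <= 0) {
    z1 <- 0; b1 <- TRUE
  } else if (flo >= 0 && fhi >= 0) {
    z1 <- 1; b1 <- TRUE
  } else {
    z1 <- stats::uniroot(g1, c(lo, hi), tol = tol)$root
    b1 <- FALSE
  }
  s2 <- z2_of_z1(max(min(z1, hi), lo))
  st <- resident_state(config, list(z1 = z1, z2 = s2$z2, h = h_fixed),
                       om = om)
  list(z1 = z1, z2 = s2$z2,
       gradients = all_gradients(st),
       boundary = c(z1 = b1, z2 = s2$boundary))
}

#' Eusociality threshold
#'
#' The minimal helper benefit `B = S_f * b` at which selection starts to
#' favour helping (`dW/dh >= 0` at `h = 0`), found by bisection on `B`.
#' In mode `"fixed_sex_ratios"` the sex ratios are held at their
#' equilibrium for a helper-free population; in mode
#' `"coevolved_sex_ratios"` they are re-equilibrated at an incipient
#' helping tendency `h_eps` for every candidate `B`, capturing the
#' first-order feedback of helping on sex-ratio selection.
#'
#' @inheritParams resident_state
#' @param mode `"fixed_sex_ratios"` or `"coevolved_sex_ratios"`.
#' @param om Optional prescribed male generation overlap in `[0, 1)`,
#'   substituted for the demographic paternity share so the threshold can
#'   be evaluated as a function of `O_m`.
#' @param bracket Bisection bracket for `B`.
#' @param tol Bisection tolerance on `B`.
#' @param h_eps Incipient helping tendency used by the coevolved mode.
#' @return A list with `B_min`, `mode`, the equilibrium sex ratios
#'   `z1_star`, `z2_star` (at `h = 0`), and the overlap `O_m` there.
#' @export
eusociality_threshold <- function(config,
                                  mode = c("fixed_sex_ratios",
                                           "coevolved_sex_ratios"),
                                  om = NULL, bracket = c(1e-3, 10),
                                  tol = 1e-6, h_eps = 1e-4) {
  config <- validate_config(config)
  mode <- match.arg(mode)
  if (config$S_f <= 0)
    stop("the eusociality threshold needs S_f > 0 (with S_f = 0 helpers ",
         "can never assist a surviving mother, B = S_f * b = 0)")
  eq0 <- sex_ratio_equilibrium(config, h_fixed = 0, om = om)
  with_B <- function(B) {
    cfg <- config; cfg$b <- B / cfg$S_f
    cfg
  }
  gh <- if (mode == "fixed_sex_ratios") {
    function(B) selection_gradient("h", state = resident_state(
      with_B(B), list(z1 = eq0$z1, z2 = eq0$z2, h = 0), om = om))
  } else {
    function(B) {
      cfg <- with_B(B)
      eq <- sex_ratio_equilibrium(cfg, h_fixed = h_eps, om = om)
      selection_gradient("h", state = resident_state(
        cfg, list(z1 = eq$z1, z2 = eq$z2, h = h_eps), om = om))
    }
  }
  lo <- bracket[1]; hi <- bracket[2]
  glo <- gh(lo); ghi <- gh(hi)
  if (glo >= 0 || ghi <= 0)
    stop(sprintf(paste0("no sign change of dW/dh over B in [%g, %g]: ",
                        "gradient %g at lower end, %g at upper end"),
                 lo, hi, glo, ghi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (gh(mid) < 0) lo <- mid else hi <- mid
  }
  st0 <- resident_state(config, list(z1 = eq0$z1, z2 = eq0$z2, h = 0),
                        om = om)
  list(B_min = (lo + hi) / 2, mode = mode,
       z1_star = eq0$z1, z2_star = eq0$z2,
       O_m = st0$rv$O_m)
}
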