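# Demography of the partially bivoltine annual cycle.
#
# Class numbering follows the life-cycle diagrams:
#
# FH (female hibernation), 7 classes
#   spring generation: 1 overwintered mated foundresses, 2 their stored sperm
#   summer generation: 3 non-helping spring-born daughters, 4 helper
#     daughters, 5 surviving foundresses, 6 their stored sperm,
#     7 spring-born males
#
# LD (larval diapause), 8 classes
#   spring generation: 1 overwintered (unmated) females, 2 overwintered males
#   summer generation: 3 non-helping daughters, 4 helpers, 5 surviving
#     foundresses, 6 their stored sperm, 7 surviving overwintered males,
#     8 spring-born sons
#
# Sperm classes (2 and 6) never receive reproduction credit in the
# demographic matrices: offspring are counted through their mothers only,
# to prevent double counting.

FH_CLASSES <- c("foundress", "sperm_spring", "daughter_breeder",
                "daughter_helper", "foundress_summer", "sperm_summer",
                "male_spring")
LD_CLASSES <- c("female_spring", "male_spring", "daughter_breeder",
                "daughter_helper", "foundress_summer", "sperm_summer",
                "male_overwintered", "son_spring")

n_classes <- function(config) if (config$life_cycle == "FH") 7L else 8L
spring_idx <- function(config) 1:2
summer_idx <- function(config) 3:n_classes(config)

#' Effect of helpers on maternal fecundity
#'
#' The expected number of helpers at the nest of a surviving foundress is
#' `h * (1 - z1) * F1` (her spring daughters that stayed).  Her summer
#' fecundity rises linearly with that number, `F5 = F1 * (1 + b *
#' n_helpers)`, so each helper adds `b * F1` offspring.  At the moment a
#' daughter decides to stay, her expected per-offspring contribution is
#' conditional on the mother surviving to breed again: `B = S_f * b`.
#'
#' @param config A [model_config()].
#' @param traits A [trait_state()].
#' @return A list with `n_helpers`, `F5` (helper-boosted summer fecundity
#'   of class-5 females) and `B` (expected helper benefit on the scale
#'   used for eusociality thresholds).
#' @export
helper_effect <- function(config, traits) {
  n_helpers <- traits$h * (1 - traits$z1) * config$F1
  list(n_helpers = n_helpers,
       F5 = config$F1 * (1 + config$b * n_helpers),
       B = config$S_f * config$b)
}

#' Seasonal transition matrices
#'
#' Builds the spring-to-summer matrix `M1` (summer classes from spring
#' classes) and the summer-to-spring matrix `M2` (next spring's classes
#' from summer classes, including autumn reproduction, mating and
#' density-dependent overwintering scaled by `alpha`), plus the annual
#' block matrix `D = [[0, M2], [M1, 0]]` acting on the stacked
#' spring+summer class vector.
#'
#' @inheritParams helper_effect
#' @param alpha Winter-survival scaling; when `NULL` (default) the value
#'   that makes the dominant eigenvalue of `D` exactly 1 is used.
#' @return A list with `M1`, `M2`, `D`, `alpha`, `F5` and `F_A` (total
#'   autumn offspring per spring female).
#' @export
transition_matrices <- function(config, traits, alpha = NULL) {
  config <- validate_config(config)
  z1 <- traits$z1; z2 <- traits$z2; h <- traits$h
  F1 <- config$F1; F3 <- config$F3
  S_f <- config$S_f; S_m <- config$S_m
  F5 <- helper_effect(config, traits)$F5
  nc <- n_classes(config)
  serial <- config$mating == "serial_monogamy"

  u3 <- F1 * (1 - z1) * (1 - h)
  u5 <- S_f
  F_A <- F3 * u3 + F5 * u5
  if (F_A * (1 - z2) <= 0)
    stop("population cannot close its annual cycle: no autumn daughters ",
         "(F_A * (1 - z2) = 0)")
  if (is.null(alpha)) alpha <- 1 / (F_A * (1 - z2))

  if (config$life_cycle == "FH") {
    M1 <- matrix(0, 5, 2, dimnames = list(FH_CLASSES[3:7], FH_CLASSES[1:2]))
    M1["daughter_breeder", 1] <- F1 * (1 - z1) * (1 - h)
    M1["daughter_helper", 1] <- F1 * (1 - z1) * h
    M1["foundress_summer", 1] <- S_f
    if (!serial) M1["sperm_summer", 1] <- S_f
    M1["male_spring", 1] <- F1 * z1
    M2 <- matrix(0, 2, 5, dimnames = list(FH_CLASSES[1:2], FH_CLASSES[3:7]))
    M2[1, "daughter_breeder"] <- alpha * F3 * (1 - z2)
    M2[1, "foundress_summer"] <- alpha * F5 * (1 - z2)
    M2[2, ] <- M2[1, ]  # one stored ejaculate per overwintering female
  } else {
    M1 <- matrix(0, 6, 2, dimnames = list(LD_CLASSES[3:8], LD_CLASSES[1:2]))
    M1["daughter_breeder", 1] <- F1 * (1 - z1) * (1 - h)
    M1["daughter_helper", 1] <- F1 * (1 - z1) * h
    M1["foundress_summer", 1] <- S_f
    M1["sperm_summer", 1] <- S_f
    M1["son_spring", 1] <- F1 * z1
    M1["male_overwintered", 2] <- S_m
    M2 <- matrix(0, 2, 6, dimnames = list(LD_CLASSES[1:2], LD_CLASSES[3:8]))
    M2[1, "daughter_breeder"] <- alpha * F3 * (1 - z2)
    M2[1, "foundress_summer"] <- alpha * F5 * (1 - z2)
    M2[2, "daughter_breeder"] <- alpha * F3 * z2
    M2[2, "foundress_summer"] <- alpha * F5 * z2
  }

  D <- matrix(0, nc, nc)
  cls <- if (config$life_cycle == "FH") FH_CLASSES else LD_CLASSES
  dimnames(D) <- list(cls, cls)
  D[1:2, 3:nc] <- M2
  D[3:nc, 1:2] <- M1
  list(M1 = M1, M2 = M2, D = D, alpha = alpha, F5 = F5, F_A = F_A)
}

#' Stable class distribution and mating statistics
#'
#' Computes the demographic equilibrium of the annual cycle: the stable
#' class-frequency vector `u` (normalised to `u1 = 1`), the
#' density-dependent winter-survival scale `alpha` that pins the dominant
#' eigenvalue of the annual matrix at 1, the mean mates per male `Q1`
#' (autumn pool for FH, spring pool for LD) and `Q2` (summer pool), and
#' the male generation-overlap measure `O_m` (plus `O_f` for LD).
#'
#' `u` is obtained in closed form by forward cohort bookkeeping; when
#' `check = TRUE` it is verified against the dominant right eigenvector of
#' `D` (relative tolerance 1e-8) and `lambda = 1` is verified to 1e-10.
#'
#' @inheritParams helper_effect
#' @param om Optional prescribed male generation overlap in `[0, 1)`.
#'   When supplied it replaces the demographically computed paternity
#'   share of the overlapping male brood throughout the mate-count and
#'   gene-flow bookkeeping, so thresholds can be evaluated as functions of
#'   `O_m` (continuous-limit device; the class frequencies themselves are
#'   unchanged).
#' @param check Verify the eigen-identities (default `TRUE`).
#' @return An object of class `"demographic_state"`: a list with `u`,
#'   `u_eigen`, `lambda`, `alpha`, `Q1`, `Q2`, `O_m`, `O_f`, `F_A`, `F5`,
#'   `M1`, `M2`, `D`, and the `unmated` flag (`TRUE` when receptive
#'   females face an empty male pool).
#' @export
stable_classes <- function(config, traits, om = NULL, check = TRUE) {
  config <- validate_config(config)
  if (!is.null(om) && (om < 0 || om >= 1))
    stop("om must lie in [0, 1)")
  tm <- transition_matrices(config, traits)
  z1 <- traits$z1; z2 <- traits$z2; h <- traits$h
  F1 <- config$F1; F3 <- config$F3
  S_f <- config$S_f; S_m <- config$S_m
  F5 <- tm$F5; F_A <- tm$F_A; alpha <- tm$alpha
  serial <- config$mating == "serial_monogamy"

  if (config$life_cycle == "FH") {
    u <- c(1, 1,
           F1 * (1 - z1) * (1 - h), F1 * (1 - z1) * h,
           S_f, if (serial) 0 else S_f, F1 * z1)
    names(u) <- FH_CLASSES
    u7 <- u["male_spring"]
    pool1 <- z2 * F_A + S_m * u7          # autumn male pool per foundress
    O_m <- if (!is.null(om)) om
           else if (pool1 > 0) as.numeric(S_m * u7 / pool1) else 0
    pool1_eff <- if (!is.null(om)) z2 * F_A / (1 - om) else pool1
    receptive1 <- (1 - z2) * F_A          # autumn daughters seeking mates
    Q1 <- if (pool1_eff > 0) receptive1 / pool1_eff
          else if (receptive1 > 0) Inf else 0
    receptive2 <- u["daughter_breeder"] + if (serial) u["foundress_summer"] else 0
    Q2 <- if (u7 > 0) as.numeric(receptive2 / u7)
          else if (receptive2 > 0) Inf else 0
    O_f <- 0
    unmated <- (receptive1 > 0 && pool1_eff == 0) ||
               (receptive2 > 0 && u7 == 0)
  } else {
    u2 <- z2 / (1 - z2)
    u <- c(1, u2,
           F1 * (1 - z1) * (1 - h), F1 * (1 - z1) * h,
           S_f, S_f, S_m * u2, F1 * z1)
    names(u) <- LD_CLASSES
    u7 <- u["male_overwintered"]; u8 <- u["son_spring"]
    pool2 <- u7 + u8                      # summer male pool
    O_m <- if (!is.null(om)) om
           else if (pool2 > 0) as.numeric(u7 / pool2) else 0
    Q1 <- if (u2 > 0) 1 / u2 else Inf     # spring: u1 females per male
    receptive2 <- u["daughter_breeder"]
    Q2 <- if (pool2 > 0) as.numeric(receptive2 / pool2)
          else if (receptive2 > 0) Inf else 0
    den_f <- S_f * F5 + u["daughter_breeder"] * F3
    O_f <- if (den_f > 0) as.numeric(S_f * F5 / den_f) else 0
    unmated <- (u2 == 0) || (receptive2 > 0 && pool2 == 0)
  }

  lambda <- NA_real_
  u_eigen <- NULL
  if (check) {
    eg <- eigen(tm$D)
    i <- which.min(abs(eg$values - 1))
    lam <- eg$values[i]
    if (abs(Im(lam)) > 1e-12)
      stop("dominant eigenvalue has a non-negligible imaginary part")
    lambda <- Re(lam)
    if (abs(lambda - 1) > 1e-10)
      stop(sprintf("annual matrix eigenvalue %.12f != 1 after alpha scaling",
                   lambda))
    vec <- Re(eg$vectors[, i])
    if (abs(vec[1]) < 1e-300)
      stop("degenerate stable distribution: class-1 frequency is zero")
    u_eigen <- vec / vec[1]
    u_eigen[abs(u_eigen) < 1e-12] <- 0
    names(u_eigen) <- names(u)
  }

  structure(
    list(u = u, u_eigen = u_eigen, lambda = lambda,
         alpha = alpha, Q1 = as.numeric(Q1), Q2 = Q2,
         O_m = as.numeric(O_m), O_f = as.numeric(O_f),
         F_A = F_A, F5 = F5, M1 = tm$M1, M2 = tm$M2, D = tm$D,
         unmated = unmated, om_override = !is.null(om),
         config = config, traits = traits),
    class = "demographic_state")
}

#' Mean mates per male
#'
#' Head-count ratios of receptive females to competing males in the two
#' mating seasons.  For FH, `Q1` is autumn (summer-brood sons plus
#' spring males surviving with probability `S_m`, competing for all autumn
#' daughters) and `Q2` is summer (spring males competing for class-3 — and
#' under serial monogamy also class-5 — females).  For LD, `Q1` is spring
#' (overwintered males, all overwintered females) and `Q2` is summer
#' (surviving overwintered males plus spring-born sons, class-3 females).
#'
#' When a male pool is empty but females would require mates from it, the
#' state is flagged `unmated` and the corresponding `Q` is `Inf`; an empty
#' pool with no receptive females gives `Q = 0`.
#'
#' @param dem A `demographic_state` from [stable_classes()].
#' @return A list with `Q1`, `Q2` and `unmated`.
#' @export
mate_counts <- function(dem) {
  stopifnot(inherits(dem, "demographic_state"))
  list(Q1 = dem$Q1, Q2 = dem$Q2, unmated = dem$unmated)
}

#' @export
print.demographic_state <- function(x, ...) {
  cat(sprintf("<demographic_state> %s / %s / %s\n",
              x$config$life_cycle, x$config$ploidy, x$config$mating))
  cat("  u:", paste(sprintf("%s=%.4g", names(x$u), x$u), collapse = ", "),
      "\n")
  cat(sprintf("  alpha = %.6g, Q1 = %.4g, Q2 = %.4g, O_m = %.4g, O_f = %.4g\n",
              x$alpha, x$Q1, x$Q2, x$O_m, x$O_f))
  if (x$unmated) cat("  [flagged: receptive females without mates]\n")
  invisible(x)
}
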