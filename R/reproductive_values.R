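# Gene-flow matrices and class-specific reproductive values.
#
# The gene-flow matrix A has the same block structure as the demographic
# matrix D, but each inflow is credited to the classes whose genes it
# carries: a survivor credits 100% to itself; under haplodiploidy a
# mother gets 100% credit for sons and mother and father 50% each for
# daughters; under diploidy both parents get 50% credit for offspring of
# either sex.  Columns of male (and sperm) classes carry the mean number
# of mates per male, so that the parental credits for every class sum to
# exactly that class's demographic inflow (A u = u).

#' Gene-flow matrix
#'
#' Assembles the gene-flow matrix `A` for the configured life cycle and
#' genetic system at the resident demographic equilibrium.  The dominant
#' left eigenvector of `A` holds the class-specific individual
#' reproductive values.
#'
#' @inheritParams helper_effect
#' @param dem A `demographic_state` from [stable_classes()]; computed on
#'   the fly when `NULL`.
#' @return A square matrix with the block structure of the annual matrix.
#' @export
gene_flow_matrix <- function(config, traits, dem = NULL) {
  config <- validate_config(config)
  if (is.null(dem)) dem <- stable_classes(config, traits, check = FALSE)
  z1 <- traits$z1; z2 <- traits$z2; h <- traits$h
  F1 <- config$F1; F3 <- config$F3
  S_f <- config$S_f; S_m <- config$S_m
  F5 <- dem$F5; F_A <- dem$F_A; alpha <- dem$alpha
  O_m <- dem$O_m
  haplo <- config$ploidy == "haplodiploid"
  serial <- config$mating == "serial_monogamy"
  u <- dem$u
  nc <- n_classes(config)
  A <- matrix(0, nc, nc, dimnames = dimnames(dem$D))
  # mother's credit for a son; father's credit for a son
  cm <- if (haplo) 1 else 0.5
  cp <- if (haplo) 0 else 0.5

  if (config$life_cycle == "FH") {
    if (z2 <= 0)
      stop("reproductive values need z2 > 0 (evaluate the boundary as a ",
           "limit via clamped traits)")
    u7 <- u["male_spring"]
    # per-mating sperm survival into next spring's class 2: each autumn son
    # obtains Q1 matings; Q1 * alpha reduces to (1 - O_m) / (z2 * F_A)
    q1a <- (1 - O_m) / (z2 * F_A)
    d1 <- 0.5 * F1 * (1 - z1) * (1 - h)   # spring daughters, per parent
    d2 <- 0.5 * F1 * (1 - z1) * h
    A[3, 1] <- d1; A[4, 1] <- d2
    A[3, 2] <- d1; A[4, 2] <- d2
    A[5, 1] <- S_f
    if (!serial) A[6, 2] <- S_f
    A[7, 1] <- cm * F1 * z1
    A[7, 2] <- cp * F1 * z1
    # summer generation -> next spring
    A[1, 3] <- 0.5 * alpha * F3 * (1 - z2)
    A[2, 3] <- cm * F3 * z2 * q1a
    A[1, 5] <- 0.5 * alpha * F5 * (1 - z2)
    A[2, 5] <- cm * F5 * z2 * q1a
    if (!serial) {
      A[1, 6] <- 0.5 * alpha * F5 * (1 - z2)
      A[2, 6] <- cp * F5 * z2 * q1a
    }
    if (u7 > 0) {
      # summer matings of spring males: class-3 females (plus re-mating
      # class-5 foundresses under serial monogamy)
      sired <- if (serial) F_A else u["daughter_breeder"] * F3
      A[1, 7] <- 0.5 * alpha * (1 - z2) * sired / u7
      A[2, 7] <- cp * z2 * q1a * sired / u7 + O_m / u7
    }
  } else {
    u2 <- u["male_spring"]
    u7 <- u["male_overwintered"]; u8 <- u["son_spring"]
    u3 <- u["daughter_breeder"]
    if (u2 <= 0)
      stop("reproductive values need overwintered males (z2 > 0); evaluate ",
           "the boundary as a limit via clamped traits")
    Q1 <- 1 / u2
    d1 <- 0.5 * F1 * (1 - z1) * (1 - h)
    d2 <- 0.5 * F1 * (1 - z1) * h
    A[3, 1] <- d1; A[4, 1] <- d2
    A[3, 2] <- Q1 * d1; A[4, 2] <- Q1 * d2
    A[5, 1] <- S_f
    A[6, 2] <- Q1 * S_f
    A[7, 2] <- S_m
    A[8, 1] <- cm * F1 * z1
    A[8, 2] <- cp * Q1 * F1 * z1
    # summer matings split between surviving overwintered males (share O_m)
    # and spring-born sons (share 1 - O_m)
    m7 <- if (u7 > 0) O_m * u3 / u7 else 0
    m8 <- if (u8 > 0) (1 - O_m) * u3 / u8 else 0
    A[1, 3] <- 0.5 * alpha * F3 * (1 - z2)
    A[2, 3] <- cm * alpha * F3 * z2
    A[1, 5] <- 0.5 * alpha * F5 * (1 - z2)
    A[2, 5] <- cm * alpha * F5 * z2
    A[1, 6] <- 0.5 * alpha * F5 * (1 - z2)
    A[2, 6] <- cp * alpha * F5 * z2
    A[1, 7] <- 0.5 * m7 * alpha * F3 * (1 - z2)
    A[2, 7] <- cp * m7 * alpha * F3 * z2
    A[1, 8] <- 0.5 * m8 * alpha * F3 * (1 - z2)
    A[2, 8] <- cp * m8 * alpha * F3 * z2
  }
  A
}

#' Class-specific reproductive values
#'
#' Computes the dominant left eigenvector `v` of the gene-flow matrix at
#' the resident demographic equilibrium, normalised so that the
#' reproductive value of a daughter born in summer is 1 (`v_f2 = 1`), and
#' derives brood-level reproductive values of daughters and sons born in
#' spring (`v_f1`, `v_m1`) and in summer (`v_f2`, `v_m2`), together with
#' the generation-overlap measures `O_m` (and `O_f`, LD only).
#'
#' At trait boundaries where a contributing class has zero frequency
#' (e.g. no spring males at `z1 = 0`), values are defined by the limit
#' from strictly positive frequency: the resident traits are perturbed
#' inward by 1e-9 before the eigencomputation.
#'
#' @inheritParams gene_flow_matrix
#' @return An object of class `"reproductive_values"`: list with `v`,
#'   `v_f1`, `v_m1`, `v_f2`, `v_m2`, `O_m`, `O_f`, `A`.
#' @export
reproductive_values <- function(config, traits, dem = NULL) {
  config <- validate_config(config)
  degenerate <- function(d) {
    u <- d$u
    if (config$life_cycle == "FH")
      u["male_spring"] == 0 || u["daughter_breeder"] == 0 || d$traits$z2 <= 0
    else
      u["male_spring"] == 0 || u["son_spring"] == 0 ||
        u["daughter_breeder"] == 0 || d$traits$z2 <= 0
  }
  if (is.null(dem)) dem <- stable_classes(config, traits, check = FALSE)
  if (degenerate(dem)) {
    traits <- clamp_traits(traits)
    dem <- stable_classes(config, traits,
                          om = if (dem$om_override) dem$O_m else NULL,
                          check = FALSE)
  }
  A <- gene_flow_matrix(config, traits, dem)
  eg <- eigen(t(A))
  i <- which.min(abs(eg$values - 1))
  lam <- eg$values[i]
  if (abs(Im(lam)) > 1e-12 || abs(Re(lam) - 1) > 1e-8)
    stop(sprintf("gene-flow matrix has no eigenvalue 1 (closest: %s)",
                 format(lam)))
  v <- Re(eg$vectors[, i])
  if (sum(v) < 0) v <- -v
  if (min(v) < -1e-8 * max(abs(v)))
    stop("reproductive-value eigenvector is not sign-definite; ",
         "degenerate configuration")
  v[v <= 0] <- 0  # zap negative-zero and rounding dust
  # normalise: RV of a summer-born daughter (alpha * v1) equals 1
  if (dem$alpha * v[1] <= 0)
    stop("cannot normalise reproductive values: class-1 value is zero")
  v <- v / (dem$alpha * v[1])
  names(v) <- rownames(A)

  if (config$life_cycle == "FH") {
    q1a <- (1 - dem$O_m) / (traits$z2 * dem$F_A)
    out <- list(v = v,
                v_f1 = as.numeric(v["daughter_breeder"]),
                v_m1 = as.numeric(v["male_spring"]),
                v_f2 = 1,
                v_m2 = as.numeric(q1a * v["sperm_spring"]))
  } else {
    out <- list(v = v,
                v_f1 = as.numeric(v["daughter_breeder"]),
                v_m1 = as.numeric(v["son_spring"]),
                v_f2 = 1,
                v_m2 = as.numeric(dem$alpha * v["male_spring"]))
  }
  out$O_m <- dem$O_m
  out$O_f <- dem$O_f
  out$A <- A
  structure(out, class = "reproductive_values")
}

#' Generation-overlap measures
#'
#' `O_m` is the paternity share that the earlier male brood captures in
#' the later mating pool: for FH, spring males surviving with probability
#' `S_m` into the autumn pool; for LD, overwintered males surviving into
#' the summer pool.  `O_f` is the analogous maternity share of surviving
#' spring females in the summer brood, defined for LD (0 for FH, whose
#' broods share one autumn mating pool).
#'
#' @inheritParams gene_flow_matrix
#' @return Named numeric vector `c(O_m =, O_f =)`.
#' @export
generation_overlap <- function(config, traits, dem = NULL) {
  if (is.null(dem)) dem <- stable_classes(config, traits, check = FALSE)
  c(O_m = dem$O_m, O_f = dem$O_f)
}

#' @export
print.reproductive_values <- function(x, ...) {
  cat("<reproductive_values>\n  v:",
      paste(sprintf("%s=%.4g", names(x$v), x$v), collapse = ", "), "\n")
  cat(sprintf("  brood RVs: v_f1 = %.4g, v_m1 = %.4g, v_f2 = 1, v_m2 = %.4g\n",
              x$v_f1, x$v_m1, x$v_m2))
  cat(sprintf("  overlap: O_m = %.4g, O_f = %.4g\n", x$O_m, x$O_f))
  invisible(x)
}
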