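#' Scenario configuration
#'
#' A `model_config` bundles everything that defines one modelled scenario:
#' the life cycle (female hibernation `"FH"`, where only mated females
#' overwinter, or larval diapause `"LD"`, where both sexes overwinter as
#' diapause larvae), the genetic system, the mating system, and the
#' demographic parameters of the annual two-brood cycle.
#'
#' Under `"polyandry"` a female stores sperm of several males for life;
#' `m_e` is the effective number of mates, the inverse of the probability
#' that two maternal sisters share a father.  Under `"serial_monogamy"`
#' (female hibernation only) a surviving foundress takes a new single mate
#' for her summer brood and sperm from the first mating is not carried
#' over, so the two broods are maternal half-siblings.
#'
#' @param life_cycle `"FH"` (female hibernation) or `"LD"` (larval diapause).
#' @param ploidy `"haplodiploid"` or `"diploid"`.
#' @param mating `"monogamy"`, `"serial_monogamy"` or `"polyandry"`.
#' @param m_e Effective number of mates per female (>= 1).  Forced to 1
#'   under monogamy; ignored under serial monogamy (cross-brood paternity
#'   is zero by construction).
#' @param F1 Fecundity of class-1 females (spring foundresses), > 0.
#' @param F3 Fecundity of class-3 females (non-helping spring-born
#'   breeders), > 0.
#' @param S_f Probability that an adult spring female survives to breed
#'   again in summer.
#' @param S_m Male survival: spring-to-summer for overwintered LD males,
#'   summer-to-autumn for FH spring males.
#' @param b Benefit of help: additional offspring added to the mother's
#'   summer brood per helper, per baseline offspring (>= 0).
#'
#' @return A validated object of class `"model_config"`.
#' @seealso [validate_config()], [trait_state()]
#' @examples
#' model_config("FH", "haplodiploid", "monogamy",
#'              F1 = 2, F3 = 2, S_f = 0.9, S_m = 0.6, b = 1.5)
#' @export
model_config <- function(life_cycle = c("FH", "LD"),
                         ploidy = c("haplodiploid", "diploid"),
                         mating = c("monogamy", "serial_monogamy", "polyandry"),
                         m_e = 1,
                         F1 = 2, F3 = 2,
                         S_f = 0.9, S_m = 0.6,
                         b = 1.5) {
  cfg <- structure(
    list(life_cycle = match.arg(life_cycle),
         ploidy = match.arg(ploidy),
         mating = match.arg(mating),
         m_e = as.numeric(m_e),
         F1 = as.numeric(F1), F3 = as.numeric(F3),
         S_f = as.numeric(S_f), S_m = as.numeric(S_m),
         b = as.numeric(b)),
    class = "model_config")
  validate_config(cfg)
}

#' Validate a scenario configuration
#'
#' Checks all field invariants (probabilities in \[0, 1\], positive
#' fecundities, `m_e >= 1`, monogamy implying `m_e = 1`, serial monogamy
#' restricted to the FH life cycle) and returns the configuration
#' unchanged.  Validation is idempotent.
#'
#' @param config A `model_config` (or a bare list with the same fields).
#' @return The validated `model_config`.
#' @export
validate_config <- function(config) {
  if (inherits(config, "model_config") && isTRUE(attr(config, "validated")))
    return(config)
  if (!is.list(config))
    stop("config must be a model_config or a list of fields")
  need <- c("life_cycle", "ploidy", "mating", "m_e",
            "F1", "F3", "S_f", "S_m", "b")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("missing config fields: ", paste(miss, collapse = ", "))
  chk_enum <- function(field, allowed) {
    if (!(config[[field]] %in% allowed))
      stop(sprintf("%s must be one of: %s", field,
                   paste(allowed, collapse = ", ")))
  }
  chk_enum("life_cycle", c("FH", "LD"))
  chk_enum("ploidy", c("haplodiploid", "diploid"))
  chk_enum("mating", c("monogamy", "serial_monogamy", "polyandry"))
  chk_num <- function(field, lo, hi, lo_ok = TRUE) {
    x <- config[[field]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop(sprintf("%s must be a finite number", field))
    if (x > hi || x < lo || (!lo_ok && x == lo))
      stop(sprintf("%s out of %s%g,%g]", field, if (lo_ok) "[" else "(",
                   lo, hi))
  }
  chk_num("S_f", 0, 1)
  chk_num("S_m", 0, 1)
  chk_num("F1", 0, Inf, lo_ok = FALSE)
  chk_num("F3", 0, Inf, lo_ok = FALSE)
  chk_num("b", 0, Inf)
  if (!is.numeric(config$m_e) || length(config$m_e) != 1L ||
      !is.finite(config$m_e) || config$m_e < 1)
    stop("m_e < 1: the effective number of mates must be at least 1")
  if (config$mating == "monogamy" && config$m_e != 1)
    stop("monogamy requires m_e = 1")
  if (config$mating == "serial_monogamy" && config$life_cycle == "LD")
    stop("serial_monogamy is only defined for the FH life cycle")
  structure(config[need], class = "model_config", validated = TRUE)
}

#' Evolvable traits of the model
#'
#' The three jointly evolving female traits: `z1`, the proportion of sons
#' in the spring brood; `z2`, the proportion of sons in the summer brood;
#' and `h`, the probability that a spring-born daughter stays at her natal
#' nest as a helper.  All are probabilities.
#'
#' @param z1,z2 Spring and summer brood sex ratios (proportion sons).
#' @param h Helping tendency of spring daughters.
#' @return An object of class `"trait_state"`.
#' @export
trait_state <- function(z1 = 0.5, z2 = 0.5, h = 0) {
  tr <- list(z1 = as.numeric(z1), z2 = as.numeric(z2), h = as.numeric(h))
  for (nm in names(tr)) {
    x <- tr[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0 || x > 1)
      stop(sprintf("%s out of [0,1]", nm))
  }
  structure(tr, class = "trait_state")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> %s / %s / %s (m_e = %g)\n",
              x$life_cycle, x$ploidy, x$mating, x$m_e))
  cat(sprintf("  F1 = %g, F3 = %g, S_f = %g, S_m = %g, b = %g\n",
              x$F1, x$F3, x$S_f, x$S_m, x$b))
  invisible(x)
}

#' @export
print.trait_state <- function(x, ...) {
  cat(sprintf("<trait_state> z1 = %g, z2 = %g, h = %g\n", x$z1, x$z2, x$h))
  invisible(x)
}

# Pull traits into [eps, 1 - eps] so that mate counts and reproductive
# values stay defined at trait boundaries (boundary classes are handled as
# the limit from strictly positive frequency).
clamp_traits <- function(traits, eps = 1e-9) {
  trait_state(z1 = min(max(traits$z1, eps), 1 - eps),
              z2 = min(max(traits$z2, eps), 1 - eps),
              h  = min(max(traits$h, eps), 1 - eps))
}
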