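#' Threshold sweep over a demographic parameter
#'
#' Recomputes the eusociality threshold along a grid of one demographic
#' parameter (by default male survival `S_m`) for one or several
#' scenarios, producing the threshold curve families across scenarios.
#' Scenario-level failures (e.g. no sign change in the bisection
#' bracket) are recorded per row in the `error` column rather than
#' aborting the sweep.
#'
#' @param configs A [model_config()] or a list of them (one per
#'   scenario).
#' @param param Name of the swept `model_config` field.
#' @param from,to,steps Grid definition (inclusive; `steps` points).
#' @param mode Threshold mode, see [eusociality_threshold()].
#' @return A data frame with one row per (scenario, parameter value):
#'   scenario descriptors, the parameter value, `B_min`, `z1_star`,
#'   `z2_star`, `O_m`, `error`.
#' @export
threshold_sweep <- function(configs, param = "S_m", from = 0, to = 1,
                            steps = 11,
                            mode = c("fixed_sex_ratios",
                                     "coevolved_sex_ratios")) {
  mode <- match.arg(mode)
  if (inherits(configs, "model_config")) configs <- list(configs)
  grid <- seq(from, to, length.out = steps)
  rows <- list()
  for (cfg in configs) {
    for (x in grid) {
      cfg_x <- unclass(cfg)
      cfg_x[[param]] <- x
      row <- data.frame(life_cycle = cfg$life_cycle, ploidy = cfg$ploidy,
                        mating = cfg$mating, m_e = cfg$m_e,
                        param = param, value = x,
                        B_min = NA_real_, z1_star = NA_real_,
                        z2_star = NA_real_, O_m = NA_real_,
                        error = NA_character_,
                        stringsAsFactors = FALSE)
      res <- tryCatch(
        eusociality_threshold(validate_config(cfg_x), mode = mode),
        error = function(e) e)
      if (inherits(res, "error")) {
        row$error <- conditionMessage(res)
      } else {
        row$B_min <- res$B_min
        row$z1_star <- res$z1_star
        row$z2_star <- res$z2_star
        row$O_m <- res$O_m
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  do.call(rbind, rows)
}
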