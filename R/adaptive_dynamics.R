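# Adaptive dynamics: dx/dt = K * dW/dx for x in (z1, z2, h), with the
# helping trait released at a set time (mirroring the individual-based
# simulations, where helping-locus mutation starts only after the sex
# ratios have equilibrated).

#' Settings for the coevolutionary integration
#'
#' @param K Scaling constant of the trait-substitution rate law (time is
#'   in arbitrary evolutionary-time units; `K` only rescales it).  The
#'   default makes the sex-ratio equilibration phase span a few thousand
#'   time units, commensurate with the individual-based simulations at
#'   their default mutation parameters, so trajectories can be laid over
#'   simulated ones on a shared axis.
#' @param T_total Total integration time.
#' @param h_release_time Time at which the helping tendency becomes
#'   evolvable; before it the `h` gradient is masked to zero.
#' @param record_every Spacing of recorded trajectory points.
#' @param rtol,atol Adaptive step-control tolerances.
#' @param clip Inward clip keeping traits in `[clip, 1 - clip]`.
#' @return A list of class `"ad_settings"`.
#' @export
ad_settings <- function(K = 3e-4, T_total = 25000, h_release_time = 10000,
                        record_every = 25, rtol = 1e-8, atol = 1e-8,
                        clip = 1e-9) {
  structure(list(K = K, T_total = T_total,
                 h_release_time = h_release_time,
                 record_every = record_every,
                 rtol = rtol, atol = atol, clip = clip),
            class = "ad_settings")
}

#' Integrate the coevolution of sex ratios and helping
#'
#' Integrates `dx/dt = K * dW/dx` for the three traits with gradients
#' recomputed at the current resident each step (adaptive-step
#' integration via deSolve's `lsoda`).  Boundaries are handled by
#' projection: a trait pinned at 0 or 1 keeps an outward gradient masked
#' until it points inward, and states are clipped to `[clip, 1 - clip]`.
#' The helping gradient is masked before `h_release_time`.
#'
#' @inheritParams resident_state
#' @param initial A [trait_state()] with the starting trait values.
#' @param settings An [ad_settings()].
#' @return A `trajectory` data frame with columns `time`, `z1`, `z2`,
#'   `h`, `dW_dz1`, `dW_dz2`, `dW_dh`, `O_m`.
#' @export
integrate_coevolution <- function(config, initial = trait_state(),
                                  settings = ad_settings()) {
  config <- validate_config(config)
  clip <- settings$clip
  clipv <- function(y) pmin(1 - clip, pmax(clip, y))
  grads <- function(y) {
    st <- resident_state(config,
                         list(z1 = y[1], z2 = y[2], h = y[3]))
    c(all_gradients(st), O_m = unname(st$rv$O_m))
  }
  rhs_factory <- function(h_active) {
    delta <- 1e-6  # boundary-layer width of the continuous projection
    function(t, y, parms) {
      y <- clipv(y)
      g <- grads(y)[1:3]
      if (!h_active) g[3] <- 0
      # projected gradient: an outward gradient is ramped down to zero
      # across a thin boundary layer, so a pinned trait stays pinned but
      # the right-hand side remains continuous
      out_lo <- g < 0
      out_hi <- g > 0
      g[out_lo] <- g[out_lo] * pmin(1, (y[out_lo] - clip) / delta)
      g[out_hi] <- g[out_hi] * pmin(1, (1 - clip - y[out_hi]) / delta)
      list(settings$K * g)
    }
  }
  run_phase <- function(y0, t0, t1, h_active) {
    times <- unique(c(seq(t0, t1, by = settings$record_every), t1))
    out <- deSolve::ode(y = y0, times = times, func = rhs_factory(h_active),
                        parms = NULL, method = "lsoda", maxsteps = 1e5,
                        rtol = settings$rtol, atol = settings$atol)
    out <- as.data.frame(out)
    names(out) <- c("time", "z1", "z2", "h")
    out[, 2:4] <- clipv(as.matrix(out[, 2:4]))
    out
  }
  y0 <- clipv(c(initial$z1, initial$z2, initial$h))
  t_rel <- min(settings$h_release_time, settings$T_total)
  ph1 <- run_phase(y0, 0, t_rel, h_active = FALSE)
  if (t_rel < settings$T_total) {
    y1 <- as.numeric(ph1[nrow(ph1), c("z1", "z2", "h")])
    ph2 <- run_phase(y1, t_rel, settings$T_total, h_active = TRUE)
    traj <- rbind(ph1[-nrow(ph1), ], ph2)
  } else traj <- ph1
  gm <- t(vapply(seq_len(nrow(traj)), function(i)
    grads(as.numeric(traj[i, c("z1", "z2", "h")])), numeric(4)))
  traj$dW_dz1 <- gm[, 1]; traj$dW_dz2 <- gm[, 2]; traj$dW_dh <- gm[, 3]
  traj$dW_dh[traj$time <= settings$h_release_time] <- 0
  traj$O_m <- gm[, 4]
  class(traj) <- c("trajectory", "data.frame")
  attr(traj, "settings") <- settings
  attr(traj, "config") <- config
  traj
}

#' Detect a coevolutionary equilibrium
#'
#' Inspects the final state of a trajectory: every active trait must
#' either have a gradient smaller than `grad_tol` in absolute value or be
#' pinned at a boundary with the gradient pointing outward.
#'
#' @param trajectory Output of [integrate_coevolution()].
#' @param grad_tol Gradient tolerance.
#' @return A [trait_state()] with attribute `converged`; traits within
#'   `1e-6` of a boundary are reported as the boundary value.
#' @export
detect_equilibrium <- function(trajectory, grad_tol = 1e-7) {
  stopifnot(nrow(trajectory) >= 1)
  last <- trajectory[nrow(trajectory), ]
  settings <- attr(trajectory, "settings")
  released <- is.null(settings) ||
    last$time > settings$h_release_time
  vals <- c(z1 = last$z1, z2 = last$z2, h = last$h)
  grads <- c(z1 = last$dW_dz1, z2 = last$dW_dz2, h = last$dW_dh)
  active <- c(TRUE, TRUE, released)
  edge <- 1e-6
  ok <- !active | abs(grads) < grad_tol |
    (vals <= edge & grads < 0) | (vals >= 1 - edge & grads > 0)
  snap <- function(x) if (x <= edge) 0 else if (x >= 1 - edge) 1 else x
  out <- trait_state(snap(vals[["z1"]]), snap(vals[["z2"]]),
                     snap(vals[["h"]]))
  attr(out, "converged") <- all(ok)
  out
}
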