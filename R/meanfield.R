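#' Expected gains at a mean-field state
#'
#' In the well-mixed (mean-field) picture the system state is the pair
#' `(m, r)`: the proportion of SRSs playing the positive participation
#' strategy and the proportion of GRSs playing the positive mobilization
#' strategy. Each role's expected gain mixes the two strategy-conditional
#' expectations:
#'
#' * `He1 = r*(pi_e - c_e + gamma) + (1 - r)*(pi_e - c_e)` — positive SRS,
#' * `He2 = r*(pi_e - delta) + (1 - r)*pi_e` — negative SRS,
#' * `Hg1 = m*(pi_g - c_g) + (1 - m)*(pi_g - c_g + beta*delta)` — positive GRS,
#' * `Hg2 = m*(-c_v) + (1 - m)*(-c_v - c_s)` — negative GRS,
#'
#' with `He = m*He1 + (1 - m)*He2` and `Hg = r*Hg1 + (1 - r)*Hg2`.
#'
#' @param m Proportion of SRSs playing positive, in \[0, 1\].
#' @param r Proportion of GRSs playing positive, in \[0, 1\].
#' @param params A [game_params()] object.
#' @return A list with elements `He`, `He1`, `He2`, `Hg`, `Hg1`, `Hg2`.
#' @seealso [replicator_rhs()], [find_fixed_points()]
#' @export
expected_gains <- function(m, r, params) {
  check_state(m, r)
  stopifnot(inherits(params, "game_params"))
  p <- params
  He1 <- r * (p$pi_e - p$c_e + p$gamma) + (1 - r) * (p$pi_e - p$c_e)
  He2 <- r * (p$pi_e - p$delta) + (1 - r) * p$pi_e
  Hg1 <- m * (p$pi_g - p$c_g) + (1 - m) * (p$pi_g - p$c_g + p$beta * p$delta)
  Hg2 <- m * (-p$c_v) + (1 - m) * (-p$c_v - p$c_s)
  list(He = m * He1 + (1 - m) * He2, He1 = He1, He2 = He2,
       Hg = r * Hg1 + (1 - r) * Hg2, Hg1 = Hg1, Hg2 = Hg2)
}

check_state <- function(m, r) {
  if (!is.numeric(m) || length(m) != 1L || !is.finite(m) || m < 0 || m > 1)
    stop("m must be a single number in [0, 1]", call. = FALSE)
  if (!is.numeric(r) || length(r) != 1L || !is.finite(r) || r < 0 || r > 1)
    stop("r must be a single number in [0, 1]", call. = FALSE)
  invisible(TRUE)
}

#' Replicator dynamics of the positive-strategy proportions
#'
#' Right-hand side of the two coupled replicator equations
#' \deqn{dm/dt = m (1 - m) (r (\gamma + \delta) - c_e)}
#' \deqn{dr/dt = r (1 - r) (\pi_g - c_g + \beta\delta + c_s + c_v - m (c_s + \beta\delta))}
#' which equal `m * (He1 - He)` and `r * (Hg1 - Hg)` with the expected gains
#' of [expected_gains()].
#'
#' @inheritParams expected_gains
#' @return Named numeric vector `c(dm_dt, dr_dt)`.
#' @export
replicator_rhs <- function(m, r, params) {
  check_state(m, r)
  stopifnot(inherits(params, "game_params"))
  p <- params
  c(dm_dt = m * (1 - m) * (r * (p$gamma + p$delta) - p$c_e),
    dr_dt = r * (1 - r) *
      (p$pi_g - p$c_g + p$beta * p$delta + p$c_s + p$c_v -
         m * (p$c_s + p$beta * p$delta)))
}

# analytic Jacobian of replicator_rhs at (m, r)
replicator_jacobian <- function(m, r, params) {
  p <- params
  A <- p$pi_g - p$c_g + p$beta * p$delta + p$c_s + p$c_v
  B <- p$c_s + p$beta * p$delta
  matrix(c((1 - 2 * m) * (r * (p$gamma + p$delta) - p$c_e),
           m * (1 - m) * (p$gamma + p$delta),
           -r * (1 - r) * B,
           (1 - 2 * r) * (A - m * B)),
         nrow = 2, byrow = TRUE)
}

#' Candidate equilibria of the replicator dynamics
#'
#' Enumerates the five fixed-point candidates of the mean-field system: the
#' four corners of the unit square plus the interior point
#' \deqn{m^* = (\pi_g - c_g + \beta\delta + c_v + c_s) / (\beta\delta + c_s),
#'       \quad r^* = c_e / (\gamma + \delta),}
#' and classifies each by the sign pattern of the Jacobian determinant and
#' trace (`STABLE` if `Det > 0, Tr < 0`; `UNSTABLE` if `Det > 0, Tr > 0`;
#' `SADDLE` if `Det < 0`; `NONHYPERBOLIC` if `Det = 0` or `Det > 0, Tr = 0`
#' within `tol`). The interior candidate is flagged `exists = TRUE` only
#' when both coordinates are defined and lie in \[0, 1\]; when
#' `gamma + delta = 0` the coordinate `r*` is undefined and the candidate
#' is reported with `exists = FALSE` (coordinates `NA`, unclassified).
#'
#' @param params A [game_params()] object.
#' @param tol Tolerance for the zero tests on `Det` and `Tr`.
#' @return A data frame with one row per candidate and columns
#'   `point` (label), `m`, `r`, `exists`, `det_j`, `tr_j`, `stability`.
#' @examples
#' find_fixed_points(game_params(delta = 2.4))
#' @export
find_fixed_points <- function(params, tol = 1e-9) {
  stopifnot(inherits(params, "game_params"))
  p <- params
  corners <- data.frame(point = c("(0,0)", "(0,1)", "(1,0)", "(1,1)"),
                        m = c(0, 0, 1, 1), r = c(0, 1, 0, 1),
                        exists = TRUE)
  gd <- p$gamma + p$delta
  A <- p$pi_g - p$c_g + p$beta * p$delta + p$c_s + p$c_v
  B <- p$c_s + p$beta * p$delta
  m_star <- if (B > 0) A / B else NA_real_
  r_star <- if (gd > 0) p$c_e / gd else NA_real_
  inside <- !is.na(m_star) && !is.na(r_star) &&
    m_star >= 0 && m_star <= 1 && r_star >= 0 && r_star <= 1
  interior <- data.frame(point = "interior",
                         m = if (inside) m_star else NA_real_,
                         r = if (inside) r_star else NA_real_,
                         exists = inside)
  fps <- rbind(corners, interior)
  fps$det_j <- NA_real_
  fps$tr_j <- NA_real_
  fps$stability <- NA_character_
  for (i in seq_len(nrow(fps))) {
    if (!fps$exists[i]) next
    J <- replicator_jacobian(fps$m[i], fps$r[i], p)
    fps$det_j[i] <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
    fps$tr_j[i] <- J[1, 1] + J[2, 2]
    fps$stability[i] <- classify_detr(fps$det_j[i], fps$tr_j[i], tol)
  }
  fps
}

classify_detr <- function(det_j, tr_j, tol = 1e-9) {
  if (abs(det_j) <= tol) return("NONHYPERBOLIC")
  if (det_j < 0) return("SADDLE")
  if (abs(tr_j) <= tol) return("NONHYPERBOLIC")
  if (tr_j < 0) "STABLE" else "UNSTABLE"
}

#' Stability classification of a single point
#'
#' Computes the analytic Jacobian of [replicator_rhs()] at `(m, r)` and
#' classifies the point by its determinant/trace sign pattern. Intended for
#' the five candidates enumerated by [find_fixed_points()], but works at any
#' state.
#'
#' @inheritParams expected_gains
#' @param tol Zero tolerance for the sign tests.
#' @return A list with `m`, `r`, `det_j`, `tr_j`, `stability`.
#' @export
classify_stability <- function(m, r, params, tol = 1e-9) {
  check_state(m, r)
  J <- replicator_jacobian(m, r, params)
  det_j <- J[1, 1] * J[2, 2] - J[1, 2] * J[2, 1]
  tr_j <- J[1, 1] + J[2, 2]
  list(m = m, r = r, det_j = det_j, tr_j = tr_j,
       stability = classify_detr(det_j, tr_j, tol))
}

#' Integrate the mean-field replicator trajectory
#'
#' Fixed-step fourth-order Runge-Kutta integration of [replicator_rhs()]
#' from `(m0, r0)`. The flow leaves the closed unit square invariant;
#' states are clipped back into it only within `clip_tol`, and a larger
#' excursion (or a non-finite state) aborts with a diagnostic.
#'
#' @param m0,r0 Initial proportions, in \[0, 1\].
#' @param params A [game_params()] object.
#' @param horizon Integration end time (time units of the replicator ODE).
#' @param step Fixed integrator step; the default `0.01` is small relative
#'   to the dynamics' payoff-scale rates.
#' @param clip_tol Largest out-of-square excursion that is silently clipped.
#' @return A data frame with columns `t`, `m`, `r`.
#' @examples
#' traj <- integrate_replicator(0.1, 0.4, game_params(), horizon = 20)
#' tail(traj, 1)   # approaches the stable corner (0, 1)
#' @export
integrate_replicator <- function(m0, r0, params, horizon = 50, step = 0.01,
                                 clip_tol = 1e-8) {
  check_state(m0, r0)
  stopifnot(inherits(params, "game_params"),
            is.numeric(horizon), horizon > 0,
            is.numeric(step), step > 0)
  rhs <- function(t, y, parms) {
    v <- replicator_rhs(min(max(y[1], 0), 1), min(max(y[2], 0), 1), parms)
    list(as.numeric(v))
  }
  times <- seq(0, horizon, by = step)
  sol <- deSolve::ode(c(m = m0, r = r0), times, rhs, params, method = "rk4")
  out <- data.frame(t = sol[, "time"], m = sol[, "m"], r = sol[, "r"])
  if (any(!is.finite(out$m)) || any(!is.finite(out$r)))
    stop("replicator integration produced a non-finite state; ",
         "reduce the step size", call. = FALSE)
  ex <- max(0, max(out$m) - 1, max(out$r) - 1, -min(out$m), -min(out$r))
  if (ex > clip_tol)
    stop("replicator trajectory left the unit square by ", format(ex),
         " (> clip_tol); reduce the step size", call. = FALSE)
  out$m <- pmin(pmax(out$m, 0), 1)
  out$r <- pmin(pmax(out$r, 0), 1)
  out
}
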