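#' Parameters of the 3-DOF damped body model
#'
#' The supine body striking the floor is modelled as three independent
#' damped single-degree-of-freedom oscillators for hip, back and head
#' (concentrated masses `m`, stiffnesses `k`, damping `c`), in the spirit
#' of the ISO 5982 whole-body vertical-vibration impedance model. Mass not
#' assigned to the three oscillators (`body_mass - sum(m)`) is carried
#' statically.
#'
#' @param m Length-3 positive masses (kg): hip, back, head.
#' @param k Length-3 positive stiffnesses (N/m).
#' @param c Length-3 nonnegative damping coefficients (N*s/m).
#' @param body_mass Total body mass M (kg), `>= sum(m)`.
#' @param h Height of the body centre of gravity when standing (m).
#' @param g Gravitational acceleration (m/s^2).
#' @return An object of class `body_model_params`.
#' @seealso [default_body_params()], [fall_force()]
#' @export
body_model_params <- function(m, k, c, body_mass, h, g = 9.81) {
  stopifnot(length(m) == 3, length(k) == 3, length(c) == 3,
            all(m > 0), all(k > 0), all(c >= 0),
            body_mass > 0, h > 0, g > 0)
  if (sum(m) > body_mass + 1e-9)
    stop("body_model_params: sum(m) exceeds body_mass")
  structure(list(m = as.numeric(m), k = as.numeric(k), c = as.numeric(c),
                 body_mass = as.numeric(body_mass), h = as.numeric(h),
                 g = as.numeric(g)),
            class = "body_model_params")
}

#' Default body-model parameter set
#'
#' A documented, overridable parameter set in the style of the ISO 5982
#' vertical whole-body model: the hip, back and head oscillators carry
#' 34%, 46% and 8% of body mass (the remaining 12% is static), with
#' natural frequencies near 5, 6 and 8 Hz and damping ratios 0.30, 0.35
#' and 0.25. Stiffness and damping scale proportionally with mass, so the
#' modal frequencies and damping ratios are mass-invariant. These are
#' package defaults, not values transcribed from a standard; every
#' downstream computation accepts an explicit [body_model_params()].
#'
#' @param mass_kg Total body mass (kg).
#' @param height_m Standing height (m); the centre of gravity is taken at
#'   `0.55 * height_m`, a standard anthropometric fraction.
#' @param g Gravitational acceleration (m/s^2).
#' @return A [body_model_params] object.
#' @export
default_body_params <- function(mass_kg, height_m = 1.7, g = 9.81) {
  frac <- c(hip = 0.34, back = 0.46, head = 0.08)
  f_n <- c(5, 6, 8)                     # Hz
  zeta <- c(0.30, 0.35, 0.25)
  m <- frac * mass_kg
  wn <- 2 * pi * f_n
  k <- m * wn^2
  c <- 2 * zeta * sqrt(k * m)
  body_model_params(m = m, k = k, c = c, body_mass = mass_kg,
                    h = 0.55 * height_m, g = g)
}

#' Stage schedule of the four-stage fall
#'
#' Boundary times of the standing / falling / impact / resting stages.
#' Defaults describe a two-second unconscious backward fall: standing to
#' 0.25 s, falling to 0.75 s, impact to 1.75 s, resting to 2 s.
#'
#' @param t_stand,t_fall,t_impact,t_rest Stage end times (s),
#'   `0 < t_stand < t_fall < t_impact <= t_rest`.
#' @return An object of class `stage_schedule`.
#' @export
stage_schedule <- function(t_stand = 0.25, t_fall = 0.75,
                           t_impact = 1.75, t_rest = 2.0) {
  stopifnot(0 < t_stand, t_stand < t_fall, t_fall < t_impact,
            t_impact <= t_rest)
  structure(list(t_stand = t_stand, t_fall = t_fall,
                 t_impact = t_impact, t_rest = t_rest),
            class = "stage_schedule")
}

# Closed-form free vibration of one damped SDOF oscillator.
# Returns functions of t for x, xdot; xddot follows from the ODE.
sdof_free_vibration <- function(m, k, c, x0, v0) {
  wn <- sqrt(k / m)
  zeta <- c / (2 * sqrt(k * m))
  if (zeta < 1 - 1e-12) {               # underdamped
    wd <- wn * sqrt(1 - zeta^2)
    A <- x0
    B <- (v0 + zeta * wn * x0) / wd
    x <- function(t) exp(-zeta * wn * t) * (A * cos(wd * t) + B * sin(wd * t))
    xd <- function(t) {
      e <- exp(-zeta * wn * t)
      e * ((-zeta * wn * A + B * wd) * cos(wd * t) +
             (-zeta * wn * B - A * wd) * sin(wd * t))
    }
  } else if (zeta > 1 + 1e-12) {        # overdamped
    s <- wn * sqrt(zeta^2 - 1)
    r1 <- -zeta * wn + s
    r2 <- -zeta * wn - s
    A <- (v0 - r2 * x0) / (r1 - r2)
    B <- x0 - A
    x <- function(t) A * exp(r1 * t) + B * exp(r2 * t)
    xd <- function(t) A * r1 * exp(r1 * t) + B * r2 * exp(r2 * t)
  } else {                              # critically damped
    A <- x0
    B <- v0 + wn * x0
    x <- function(t) exp(-wn * t) * (A + B * t)
    xd <- function(t) exp(-wn * t) * (B - wn * (A + B * t))
  }
  list(x = x, xdot = xd,
       xddot = function(t) -(c * xd(t) + k * x(t)) / m)
}

#' Impact-stage response of the 3-DOF body model
#'
#' Solves, in closed form, the free vibration `m_i x'' + c_i x' + k_i x = 0`
#' for each of the three oscillators with initial velocity
#' `v0 = sqrt(2 g h)` (touchdown velocity from a fall of the centre of
#' gravity through height `h`) and initial displacement
#' `x0 = -(m_i g + c_i v0) / k_i`, the unique displacement for which the
#' equation of motion yields the stated initial acceleration `x''(0) = g`.
#' Handles under-, critically and overdamped oscillators.
#'
#' @param p A [body_model_params] object.
#' @param duration Length of the returned response (s).
#' @param fs Sampling rate (Hz).
#' @return List with `t` (time grid from 0) and 3-column matrices `x`,
#'   `xdot`, `xddot` (one column per DOF: hip, back, head).
#' @export
impact_response <- function(p, duration, fs) {
  stopifnot(inherits(p, "body_model_params"), duration > 0, fs > 0)
  t <- seq(0, duration, by = 1 / fs)
  v0 <- sqrt(2 * p$g * p$h)
  sol <- lapply(1:3, function(i) {
    x0 <- -(p$m[i] * p$g + p$c[i] * v0) / p$k[i]
    sdof_free_vibration(p$m[i], p$k[i], p$c[i], x0, v0)
  })
  list(t = t,
       x = vapply(sol, function(s) s$x(t), numeric(length(t))),
       xdot = vapply(sol, function(s) s$xdot(t), numeric(length(t))),
       xddot = vapply(sol, function(s) s$xddot(t), numeric(length(t))))
}

#' Vertical floor force of a four-stage unconscious backward fall
#'
#' Assembles the force the body exerts on the floor, piecewise over the
#' four stages (axis pointing up, compressive force positive):
#' \describe{
#'   \item{standing `[0, t_stand]`}{equilibrium, `F = M g`.}
#'   \item{falling `(t_stand, t_fall]`}{parabolic decay
#'     `F = M g ((t - t_fall) / (t_stand - t_fall))^2` — anchored at
#'     `M g` when the fall starts, zero with zero slope at lift-off, so
#'     the force dips smoothly to zero as floor contact is lost.}
#'   \item{impact `(t_fall, t_impact]`}{`F = sum_i m_i (g - x''_i) +
#'     (M - sum_i m_i) g`, the per-oscillator contact-force balance in
#'     the down-positive axis of [impact_response()]: zero contact force
#'     at touchdown (`x''(0) = g`, still in free fall), a compressive
#'     shock spike as the body decelerates, decay toward the static
#'     weight. Oscillation may briefly cross zero; no clipping is
#'     applied.}
#'   \item{resting `(t_impact, t_rest]`}{full floor contact, `F = M g`.}
#' }
#'
#' @param p A [body_model_params] object.
#' @param sched A [stage_schedule] object.
#' @param fs Sampling rate (Hz).
#' @return An object of class `force_profile`: list with `t` (s), `F` (N),
#'   `params`. Negative excursions during impact ringing are preserved
#'   (no clipping by default).
#' @export
fall_force <- function(p, sched = stage_schedule(), fs = 1652) {
  stopifnot(inherits(p, "body_model_params"),
            inherits(sched, "stage_schedule"), fs > 0)
  t <- seq(0, sched$t_rest, by = 1 / fs)
  M <- p$body_mass
  G <- M * p$g
  F <- rep(G, length(t))
  falling <- t > sched$t_stand & t <= sched$t_fall
  F[falling] <- G * ((t[falling] - sched$t_fall) /
                       (sched$t_stand - sched$t_fall))^2
  impact <- t > sched$t_fall & t <= sched$t_impact
  if (any(impact)) {
    # evaluate the closed form at the exact offsets of the global grid
    ti <- t[impact] - sched$t_fall
    v0 <- sqrt(2 * p$g * p$h)
    Fi <- rep((M - sum(p$m)) * p$g, length(ti))
    for (i in 1:3) {
      x0 <- -(p$m[i] * p$g + p$c[i] * v0) / p$k[i]
      s <- sdof_free_vibration(p$m[i], p$k[i], p$c[i], x0, v0)
      # force balance in the down-positive axis of the initial conditions:
      # the contact force each oscillator presses on the floor is
      # m (g - xddot); it is 0 at touchdown (xddot(0) = g) and tends to
      # the weight m g as the ringing decays
      Fi <- Fi + p$m[i] * (p$g - s$xddot(ti))
    }
    F[impact] <- Fi
  }
  force_profile(t, F, params = list(body = p, schedule = sched, fs = fs))
}

#' @rdname fall_force
#' @param t Time grid (s, uniform step).
#' @param F Force samples (N).
#' @param params Provenance list.
#' @export
force_profile <- function(t, F, params = list()) {
  stopifnot(length(t) == length(F), all(is.finite(F)))
  structure(list(t = as.numeric(t), F = as.numeric(F), params = params),
            class = "force_profile")
}

#' @export
print.force_profile <- function(x, ...) {
  cat(sprintf("<force_profile> %d samples, %.3f s, peak %.1f N\n",
              length(x$t), max(x$t), max(x$F)))
  invisible(x)
}

#' Fall floor-force profile from mass and height alone
#'
#' Convenience wrapper: builds [default_body_params()] for the given mass
#' and height and runs [fall_force()] with the default stage schedule.
#'
#' @param mass_kg Body mass, must lie in `[30, 150]` kg.
#' @param height_m Standing height (m).
#' @param fs Sampling rate (Hz).
#' @param sched A [stage_schedule].
#' @return A `force_profile`.
#' @examples
#' fp <- fall_force_default(71, fs = 500)
#' plot(fp$t, fp$F, type = "l", xlab = "time (s)", ylab = "floor force (N)")
#' @export
fall_force_default <- function(mass_kg, height_m = 1.7, fs = 1652,
                               sched = stage_schedule()) {
  if (mass_kg < 30 || mass_kg > 150)
    stop("fall_force_default: mass_kg must lie in [30, 150]")
  fall_force(default_body_params(mass_kg, height_m), sched = sched, fs = fs)
}

#' Export a force profile as CSV
#' @param fp A `force_profile`.
#' @param path Output path; header `time,force_N`.
#' @return `path`, invisibly.
#' @export
write_force_csv <- function(fp, path) {
  stopifnot(inherits(fp, "force_profile"))
  utils::write.csv(data.frame(time = fp$t, force_N = fp$F), path,
                   row.names = FALSE)
  invisible(path)
}
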