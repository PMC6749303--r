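#' Closed-form modal model of a rectangular floor plate
#'
#' A simply supported rectangular plate with mass-normalized sinusoidal
#' mode shapes, used to turn point-force time series into multi-sensor
#' floor accelerations by modal superposition. This is a lightweight,
#' fully specified stand-in for a finite-element floor model: it captures
#' the distance- and position-dependence of sensor responses and the
#' resonant ringing of a real slab without any meshing.
#'
#' Mode shapes are `phi_pq(x, y) = sin(p pi x / a) sin(q pi y / b)`
#' normalized by the modal mass `rho_s a b / 4`; modal frequencies follow
#' the thin-plate law `f_pq = f11 ((p/a)^2 + (q/b)^2) / ((1/a)^2 + (1/b)^2)`.
#'
#' @param a,b Plate dimensions (m).
#' @param f11 Fundamental frequency (Hz); default 16.7 Hz, typical of a
#'   stiff laboratory slab.
#' @param zeta Modal damping ratio, one value for all modes, in (0, 0.2].
#' @param n_modes_x,n_modes_y Number of half-waves retained per direction
#'   (total modes = product).
#' @param rho_s Effective surface density of the floor (kg/m^2). The
#'   default 1200 is higher than a bare slab's: it stands for the
#'   effective modal mass of the slab plus participating beams, walls and
#'   finishes, and places fall peaks near 0.2 g and walking peaks near
#'   0.01 g at the default layouts — the orders of magnitude of the
#'   feature tables reported for instrumented laboratory floors.
#' @return An object of class `floor_model` with a `modes` data frame
#'   (p, q, f_hz, omega, zeta) sorted by frequency.
#' @export
floor_model <- function(a = 4, b = 5, f11 = 16.7, zeta = 0.03,
                        n_modes_x = 5, n_modes_y = 5, rho_s = 1200) {
  stopifnot(a > 0, b > 0, f11 > 0, zeta > 0, zeta <= 0.2,
            n_modes_x >= 1, n_modes_y >= 1, rho_s > 0)
  grid <- expand.grid(p = seq_len(n_modes_x), q = seq_len(n_modes_y))
  lam <- (grid$p / a)^2 + (grid$q / b)^2
  f <- f11 * lam / ((1 / a)^2 + (1 / b)^2)
  ord <- order(f)
  modes <- data.frame(p = grid$p[ord], q = grid$q[ord], f_hz = f[ord],
                      omega = 2 * pi * f[ord], zeta = zeta)
  structure(list(a = a, b = b, rho_s = rho_s, modes = modes,
                 modal_mass = rho_s * a * b / 4),
            class = "floor_model")
}

# mass-normalized mode shapes at a point; returns vector over modes
mode_shape <- function(fm, xy) {
  if (xy[1] < 0 || xy[1] > fm$a || xy[2] < 0 || xy[2] > fm$b)
    stop("mode_shape: point (", xy[1], ", ", xy[2], ") outside plate")
  sin(fm$modes$p * pi * xy[1] / fm$a) * sin(fm$modes$q * pi * xy[2] / fm$b) /
    sqrt(fm$modal_mass)
}

# Padded FFTs of each mode's displacement and velocity unit-impulse
# responses, reused across events of equal length. Modes at or above a
# quarter of the sampling rate are excluded from the response: they
# cannot be resolved on the sampling grid and would alias; the
# fundamental is always retained.
mode_irf_fft <- function(fm, n, fs) {
  keep <- which(fm$modes$f_hz < 0.25 * fs)  # >= 4 samples per period
  if (length(keep) == 0) keep <- 1L
  m <- stats::nextn(2L * n)
  t <- (seq_len(m) - 1) / fs
  irfs <- lapply(keep, function(j) {
    w <- fm$modes$omega[j]
    z <- fm$modes$zeta[j]
    wd <- w * sqrt(1 - z^2)
    e <- exp(-z * w * t)
    h <- e * sin(wd * t) / wd
    hd <- e * (cos(wd * t) - z * w * sin(wd * t) / wd)
    list(Hh = stats::fft(h), Hhd = stats::fft(hd), w = w, z = z, m = m)
  })
  list(irfs = irfs, keep = keep)
}

#' Floor acceleration response at sensor locations
#'
#' Modal superposition: each retained mode is a mass-normalized damped
#' single-degree-of-freedom oscillator driven by the point force scaled
#' by the mode shape at the source; sensor acceleration is the sum over
#' modes of the modal acceleration scaled by the mode shape at the
#' sensor. Only modes below a quarter of the sampling rate participate
#' (at least four samples per period); faster modes cannot be resolved on
#' the grid and would alias. Modal responses are computed by discrete
#' Duhamel convolution
#' (FFT) with each mode's unit-impulse response; the modal acceleration is
#' recovered exactly from the equation of motion
#' `qddot = f - 2 zeta omega qdot - omega^2 q`. Output is strictly linear
#' in the force; optional zero-mean Gaussian noise (in g) is added per
#' sample using the current RNG state.
#'
#' @param fm A [floor_model].
#' @param fp A `force_profile` sampled at `fs` (N).
#' @param source_xy Length-2 numeric, force location (m), inside the plate.
#' @param sensor_xy Matrix or list of sensor coordinates (rows/elements =
#'   sensors), inside the plate.
#' @param fs Sampling rate (Hz); must match the force grid.
#' @param noise_sd Gaussian noise SD in g (0 = off).
#' @param label,meta Passed to the returned [accel_record].
#' @param irf Precomputed [mode_irf_fft()] output (internal reuse).
#' @return An [accel_record] in g.
#' @export
floor_response <- function(fm, fp, source_xy, sensor_xy, fs,
                           noise_sd = 0, label = "unlabeled", meta = list(),
                           irf = NULL) {
  stopifnot(inherits(fm, "floor_model"), inherits(fp, "force_profile"))
  if (nrow(fm$modes) < 1) stop("floor_response: empty mode set")
  if (is.list(sensor_xy) && !is.matrix(sensor_xy))
    sensor_xy <- do.call(rbind, sensor_xy)
  sensor_xy <- as.matrix(sensor_xy)
  n <- length(fp$F)
  acc <- floor_accel(fm, fp$F, source_xy, sensor_xy, fs, irf = irf)
  if (noise_sd > 0)
    acc <- acc + matrix(stats::rnorm(length(acc), sd = noise_sd),
                        nrow = n)
  accel_record(acc, fs = fs, label = label, meta = meta)
}

# core linear response, in g; no noise, no record wrapper
floor_accel <- function(fm, F, source_xy, sensor_xy, fs, irf = NULL) {
  n <- length(F)
  if (is.null(irf)) irf <- mode_irf_fft(fm, n, fs)
  phi_s <- mode_shape(fm, source_xy)[irf$keep]
  phi_r <- matrix(apply(sensor_xy, 1, function(xy) mode_shape(fm, xy)),
                  ncol = nrow(sensor_xy))[irf$keep, , drop = FALSE]
  m <- irf$irfs[[1]]$m
  Hf <- stats::fft(c(F, rep(0, m - n)))
  dt <- 1 / fs
  qdd <- matrix(0, n, length(irf$irfs))
  for (j in seq_along(irf$irfs)) {
    ir <- irf$irfs[[j]]
    f_j <- phi_s[j] * F
    Hfj <- phi_s[j] * Hf
    q <- Re(stats::fft(Hfj * ir$Hh, inverse = TRUE))[1:n] / m * dt
    qd <- Re(stats::fft(Hfj * ir$Hhd, inverse = TRUE))[1:n] / m * dt
    qdd[, j] <- f_j - 2 * ir$z * ir$w * qd - ir$w^2 * q
  }
  (qdd %*% phi_r) / 9.81
}

half_sine <- function(t, t0, width, peak) {
  inside <- t >= t0 & t <= t0 + width
  f <- numeric(length(t))
  f[inside] <- peak * sin(pi * (t[inside] - t0) / width)
  f
}

#' Vertical floor-force profile for one activity event
#'
#' Generates the point-force time series driving the plate model for each
#' of the six activity types. Falls delegate to the four-stage
#' biomechanical model ([fall_force_default()]); walking is a train of
#' half-sine footstep pulses at the step rate; free jumping is a small
#' number of irregular landing impulses; rhythmic jumping is a metronomic
#' impulse train (default 90 beats per minute, i.e. 1.5 Hz); bag and ball
#' drops are single short impulses with peak proportional to
#' `mass * sqrt(2 g drop_height)` (momentum transfer over the contact
#' time), the ball adding restitution bounces. Timing jitter and jump
#' landings use the current RNG state.
#'
#' @param kind Activity, one of the six labels in [ACTIVITY_LABELS]
#'   (not `"unlabeled"`).
#' @param params Named list of activity parameters; see Details.
#' @param fs Sampling rate (Hz).
#' @param duration Profile length (s).
#' @return A `force_profile` of `round(duration * fs)` samples starting at
#'   t = 0. Walking profiles carry a `steps` attribute (per-step time,
#'   width, peak and path fraction) so the plate simulator can move the
#'   source along the walking path.
#' @details Recognized `params` by kind (defaults in parentheses):
#' \describe{
#'   \item{fall}{`mass_kg` (71), `height_m` (1.7), `damping_mult` (1) —
#'     impact-stage damping multiplier distinguishing fall styles.}
#'   \item{walk}{`mass_kg` (70), `step_rate_hz` (2), `jitter_s` (0.05),
#'     `contact_s` (0.25), `amp_frac` (0.3) — dynamic peak as fraction of
#'     body weight; `n_steps` overrides the rate-derived step count.}
#'   \item{free_jump}{`mass_kg` (70), `n_jumps` (2), `jump_height_m`
#'     (0.3), `contact_s` (0.08).}
#'   \item{rhythmic_jump}{`mass_kg` (70), `rate_hz` (1.5), `jitter_s` (0),
#'     `jump_height_m` (0.15), `contact_s` (0.08).}
#'   \item{bag_drop}{`mass_kg` (5), `drop_height_m` (0.6), `contact_s`
#'     (0.03).}
#'   \item{ball_drop}{`mass_kg` (0.6), `drop_height_m` (1.45),
#'     `restitution` (0.6), `contact_s` (0.02), `n_bounces` (4).}
#' }
#' @export
activity_force <- function(kind, params = list(), fs, duration) {
  kind <- match.arg(kind, setdiff(ACTIVITY_LABELS, "unlabeled"))
  stopifnot(fs > 0, duration > 0, round(duration * fs) >= 2)
  n <- round(duration * fs)
  t <- (seq_len(n) - 1) / fs
  g <- 9.81
  p <- function(name, default) if (!is.null(params[[name]])) params[[name]] else default
  F <- switch(kind,
    fall = {
      mass <- p("mass_kg", 71)
      bp <- default_body_params(mass, p("height_m", 1.7))
      bp$c <- bp$c * p("damping_mult", 1)
      fp <- fall_force(bp, stage_schedule(), fs = fs)
      if (length(fp$F) >= n) fp$F[1:n]
      else c(fp$F, rep(mass * g, n - length(fp$F)))
    },
    walk = {
      mass <- p("mass_kg", 70)
      rate <- p("step_rate_hz", 2)
      contact <- p("contact_s", 0.25)
      n_steps <- p("n_steps", max(0L, floor((duration - 0.3) * rate)))
      F <- numeric(n)
      if (n_steps > 0) {
        t0 <- 0.15 + (seq_len(n_steps) - 1) / rate +
          stats::rnorm(n_steps, sd = p("jitter_s", 0.05))
        for (i in seq_len(n_steps))
          F <- F + half_sine(t, t0[i], contact, p("amp_frac", 0.3) * mass * g)
        attr(F, "steps") <- data.frame(
          t0 = t0, width = contact, peak = p("amp_frac", 0.3) * mass * g,
          frac = (seq_len(n_steps) - 0.5) / n_steps)
      }
      F
    },
    free_jump = {
      mass <- p("mass_kg", 70)
      contact <- p("contact_s", 0.08)
      n_jumps <- p("n_jumps", 2)
      F <- numeric(n)
      if (n_jumps > 0) {
        t0 <- sort(stats::runif(n_jumps, 0.1, max(0.2, duration - 0.3)))
        h <- p("jump_height_m", 0.3) * stats::runif(n_jumps, 0.6, 1.4)
        for (i in seq_len(n_jumps)) {
          v <- sqrt(2 * g * h[i])
          F <- F + half_sine(t, t0[i], contact, pi * mass * v / (2 * contact))
        }
      }
      F
    },
    rhythmic_jump = {
      mass <- p("mass_kg", 70)
      rate <- p("rate_hz", 1.5)
      contact <- p("contact_s", 0.08)
      jitter <- p("jitter_s", 0)
      v <- sqrt(2 * g * p("jump_height_m", 0.15))
      peak <- pi * mass * v / (2 * contact)
      t0 <- seq(0.1, duration - contact, by = 1 / rate)
      if (jitter > 0) t0 <- t0 + stats::rnorm(length(t0), sd = jitter)
      F <- numeric(n)
      for (ti in t0) F <- F + half_sine(t, ti, contact, peak)
      F
    },
    bag_drop = {
      mass <- p("mass_kg", 5)
      contact <- p("contact_s", 0.03)
      v <- sqrt(2 * g * p("drop_height_m", 0.6))
      half_sine(t, 0.1, contact, pi * mass * v / (2 * contact))
    },
    ball_drop = {
      mass <- p("mass_kg", 0.6)
      contact <- p("contact_s", 0.02)
      e <- p("restitution", 0.6)
      v <- sqrt(2 * g * p("drop_height_m", 1.45))
      F <- numeric(n)
      ti <- 0.1
      for (b in 0:p("n_bounces", 4)) {
        vb <- v * e^b
        F <- F + half_sine(t, ti, contact, pi * mass * vb / (2 * contact))
        ti <- ti + 2 * vb * e / g   # flight time to next bounce
      }
      F
    })
  steps <- attr(F, "steps")
  fp <- force_profile(t, as.numeric(F),
                      params = c(list(kind = kind, fs = fs), params))
  attr(fp, "steps") <- steps
  fp
}

#' Dominant repetition frequency of a force profile
#'
#' Frequency of the largest non-DC peak of the magnitude spectrum of the
#' (mean-removed) force series — e.g. the metronome rate of a rhythmic
#' jumping profile.
#'
#' @param fp A `force_profile`.
#' @param f_min Frequencies below this (Hz) are ignored to exclude
#'   spectral leakage around DC.
#' @return Frequency in Hz, at the resolution `1 / duration`.
#' @examples
#' fp <- activity_force("rhythmic_jump", list(jitter_s = 0),
#'                      fs = 400, duration = 10)
#' dominant_frequency(fp)  # 1.5
#' @export
dominant_frequency <- function(fp, f_min = 0.2) {
  stopifnot(inherits(fp, "force_profile"))
  x <- fp$F - mean(fp$F)
  n <- length(x)
  fs <- 1 / (fp$t[2] - fp$t[1])
  spec <- Mod(stats::fft(x))[1:(n %/% 2)]
  freq <- (seq_len(n %/% 2) - 1) * fs / n
  keep <- freq >= f_min
  freq[keep][which.max(spec[keep])]
}
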