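#' Double pendulum parameters
#'
#' Standard planar double pendulum, both angles measured from the downward
#' vertical. Defaults are unit masses and lengths with a 0.01 rad displacement
#' of the upper joint: a small-amplitude regime where the motion is a
#' superposition of the two analytic normal modes.
#'
#' @param m1,m2 point masses (kg).
#' @param l1,l2 rod lengths (m).
#' @param g gravitational acceleration (m/s^2).
#' @param damping viscous damping on each joint velocity (1/s); 0 = conservative.
#' @param theta0 initial angles (rad), length 2.
#' @param omega0 initial angular velocities (rad/s), length 2.
#' @return A `pendulum_params` list.
#' @export
pendulum_params <- function(m1 = 1, m2 = 1, l1 = 1, l2 = 1, g = 9.81,
                            damping = 0,
                            theta0 = c(0.01, 0), omega0 = c(0, 0)) {
  stopifnot(m1 > 0, m2 > 0, l1 > 0, l2 > 0, g > 0, damping >= 0,
            length(theta0) == 2L, length(omega0) == 2L)
  structure(list(m1 = m1, m2 = m2, l1 = l1, l2 = l2, g = g,
                 damping = damping, theta0 = theta0, omega0 = omega0),
            class = "pendulum_params")
}

## total mechanical energy of the pendulum state (theta1, theta2, w1, w2)
pendulum_energy <- function(state, par) {
  th1 <- state[1]; th2 <- state[2]; w1 <- state[3]; w2 <- state[4]
  kin <- 0.5 * (par$m1 + par$m2) * par$l1^2 * w1^2 +
    0.5 * par$m2 * par$l2^2 * w2^2 +
    par$m2 * par$l1 * par$l2 * w1 * w2 * cos(th1 - th2)
  pot <- -(par$m1 + par$m2) * par$g * par$l1 * cos(th1) -
    par$m2 * par$g * par$l2 * cos(th2)
  kin + pot
}

pendulum_deriv <- function(t, state, par) {
  th1 <- state[1]; th2 <- state[2]; w1 <- state[3]; w2 <- state[4]
  d <- th1 - th2
  den <- 2 * par$m1 + par$m2 - par$m2 * cos(2 * d)
  a1 <- (-par$g * (2 * par$m1 + par$m2) * sin(th1) -
           par$m2 * par$g * sin(th1 - 2 * th2) -
           2 * sin(d) * par$m2 *
             (w2^2 * par$l2 + w1^2 * par$l1 * cos(d))) / (par$l1 * den)
  a2 <- (2 * sin(d) *
           (w1^2 * par$l1 * (par$m1 + par$m2) +
              par$g * (par$m1 + par$m2) * cos(th1) +
              w2^2 * par$l2 * par$m2 * cos(d))) / (par$l2 * den)
  a1 <- a1 - par$damping * w1
  a2 <- a2 - par$damping * w2
  list(c(w1, w2, a1, a2))
}

#' Simulate a planar double pendulum
#'
#' Fixed-step 4th-order Runge-Kutta integration (via \pkg{deSolve}) at a fine
#' internal step (default 1 ms), decimated to the requested sampling
#' interval. For the undamped pendulum the run aborts if total mechanical
#' energy drifts by more than 1%, which signals an unstable step size.
#'
#' @param params a [pendulum_params()] object.
#' @param duration simulated time (s).
#' @param dt output sampling interval (s).
#' @param internal_dt integration step (s); must divide `dt` evenly.
#' @return An `angle_series` with channels `theta1`, `theta2` (rad).
#' @examples
#' s <- simulate_double_pendulum(pendulum_params(), duration = 2, dt = 0.01)
#' @export
simulate_double_pendulum <- function(params, duration, dt,
                                     internal_dt = min(dt, 1e-3)) {
  stopifnot(inherits(params, "pendulum_params"), duration / dt >= 2)
  dec <- dt / internal_dt
  if (abs(dec - round(dec)) > 1e-9)
    stop("simulate_double_pendulum: internal_dt must divide dt", call. = FALSE)
  y0 <- c(params$theta0, params$omega0)
  times <- seq(0, duration, by = internal_dt)
  sol <- deSolve::ode(y0, times, pendulum_deriv, params, method = "rk4")
  if (params$damping == 0 && any(y0 != 0)) {
    e0 <- pendulum_energy(y0, params)
    e1 <- pendulum_energy(sol[nrow(sol), -1L], params)
    scale <- abs(e0) + (params$m1 + params$m2) * params$g *
      (params$l1 + params$l2)
    if (abs(e1 - e0) / scale > 0.01)
      stop("simulate_double_pendulum: energy drift > 1%; use a smaller internal_dt",
           call. = FALSE)
  }
  keep <- seq(1L, nrow(sol), by = round(dec))
  angle_series(t(sol[keep, c(2L, 3L), drop = FALSE]), dt = dt,
               labels = c("theta1", "theta2"))
}

#' Analytic small-angle normal-mode frequencies of the double pendulum
#'
#' Linearizes the conservative pendulum about the hanging equilibrium and
#' solves the generalized eigenproblem of the mass and stiffness matrices.
#' For equal masses and lengths this reduces to
#' \eqn{\omega_\pm = \sqrt{(2 \mp \sqrt 2)\, g/l}}.
#'
#' @param params a [pendulum_params()] with `damping = 0`.
#' @return Sorted numeric vector of the two frequencies in Hz.
#' @examples
#' analytic_pendulum_frequencies(pendulum_params())  # 0.38153, 0.92110 Hz
#' @export
analytic_pendulum_frequencies <- function(params) {
  stopifnot(inherits(params, "pendulum_params"))
  if (params$damping != 0)
    stop("analytic_pendulum_frequencies: defined for the undamped pendulum only",
         call. = FALSE)
  M <- matrix(c((params$m1 + params$m2) * params$l1^2,
                params$m2 * params$l1 * params$l2,
                params$m2 * params$l1 * params$l2,
                params$m2 * params$l2^2), 2, 2)
  K <- diag(c((params$m1 + params$m2) * params$g * params$l1,
              params$m2 * params$g * params$l2))
  w2 <- eigen(solve(M, K), only.values = TRUE)$values
  sort(sqrt(Re(w2)) / (2 * pi))
}

#' Configuration for the harmonic gait generator
#'
#' Describes a d-channel limit-cycle signal: each channel is a sum of `K`
#' harmonics of a fundamental `f0` with per-channel complex coefficients,
#' plus optional white measurement noise. The defaults emulate sagittal
#' segmental elevation angles during walking: three channels (thigh, shank,
#' foot), fundamental 0.8 Hz, five harmonics with magnitudes decaying as
#' (1, 0.6, 0.4, 0.25, 0.15) and a foot-dominant channel scaling
#' (0.35, 0.45, 0.70) rad.
#'
#' @param d number of channels.
#' @param f0 fundamental (gait) frequency, Hz.
#' @param harmonics number of harmonics K.
#' @param coefficients complex d x K matrix of per-channel harmonic
#'   coefficients; default as described above with a fixed phase table.
#' @param noise_sd standard deviation of additive Gaussian noise (rad).
#' @param dt sampling interval (s).
#' @param duration length of the recording (s).
#' @param seed RNG seed for the noise (NULL = use current RNG state).
#' @return A `gait_config` list.
#' @export
gait_config <- function(d = 3, f0 = 0.8, harmonics = 5,
                        coefficients = default_gait_coefficients(d, harmonics),
                        noise_sd = 0, dt = 0.01, duration = 10, seed = NULL) {
  stopifnot(f0 > 0, harmonics >= 1, dt > 0, noise_sd >= 0,
            nrow(coefficients) == d, ncol(coefficients) == harmonics)
  if (harmonics * f0 >= 1 / (2 * dt))
    stop(sprintf("gait_config: K*f0 = %.3g Hz violates Nyquist (%.3g Hz)",
                 harmonics * f0, 1 / (2 * dt)), call. = FALSE)
  structure(list(d = d, f0 = f0, harmonics = harmonics,
                 coefficients = coefficients, noise_sd = noise_sd,
                 dt = dt, duration = duration, seed = seed),
            class = "gait_config")
}

#' @rdname gait_config
#' @export
default_gait_coefficients <- function(d = 3, harmonics = 5) {
  hmag <- c(1, 0.6, 0.4, 0.25, 0.15, 0.1, 0.07, 0.05)[seq_len(harmonics)]
  hmag[is.na(hmag)] <- 0.05
  cmag <- rep_len(c(0.35, 0.45, 0.70), d)
  mag <- outer(cmag, hmag)
  ph <- outer(seq_len(d) - 1, seq_len(harmonics) - 1,
              function(i, k) 1.3 * i + 0.7 * k)
  mag * exp(1i * ph)
}

#' Generate a synthetic harmonic "gait" signal
#'
#' Channel \eqn{i} at frame \eqn{t} is
#' \eqn{\sum_k \mathrm{Re}[c_{i,k} e^{i 2\pi k f_0 t \Delta t}] + \epsilon},
#' \eqn{\epsilon \sim N(0, \sigma^2)}. There is no DC term, so the noise-free
#' signal has zero temporal mean by construction.
#'
#' @param config a [gait_config()].
#' @return An `angle_series` with cycle events at every fundamental period.
#' @examples
#' s <- generate_harmonic_gait(gait_config(duration = 5, seed = 1))
#' @export
generate_harmonic_gait <- function(config) {
  stopifnot(inherits(config, "gait_config"))
  nf <- floor(config$duration / config$dt) + 1L
  tt <- (seq_len(nf) - 1) * config$dt
  vals <- matrix(0, config$d, nf)
  for (k in seq_len(config$harmonics)) {
    carrier <- exp(1i * 2 * pi * k * config$f0 * tt)    # length nf
    vals <- vals + Re(config$coefficients[, k, drop = FALSE] %*% t(carrier))
  }
  if (config$noise_sd > 0) {
    vals <- vals + with_seed(config$seed,
      matrix(rnorm(length(vals), sd = config$noise_sd), nrow(vals)))
  }
  Tcyc <- round(1 / (config$f0 * config$dt))
  ev <- seq(0L, nf - 1L, by = Tcyc)
  labels <- if (config$d == 3) c("thigh", "shank", "foot")
            else paste0("ch", seq_len(config$d))
  angle_series(vals, dt = config$dt, labels = labels,
               events = if (length(ev) >= 2) ev else NULL)
}

#' Noise level corresponding to a target signal-to-noise ratio
#'
#' @param config a [gait_config()]; its `noise_sd` is ignored.
#' @param snr_db target SNR in decibels (20 dB = noise sd at 1/10 of the
#'   overall signal RMS).
#' @return Numeric noise standard deviation (rad).
#' @export
gait_noise_sd_for_snr <- function(config, snr_db) {
  clean <- gait_config(d = config$d, f0 = config$f0,
                       harmonics = config$harmonics,
                       coefficients = config$coefficients, noise_sd = 0,
                       dt = config$dt, duration = config$duration)
  rms <- sqrt(mean(generate_harmonic_gait(clean)$values^2))
  rms / 10^(snr_db / 20)
}

#' Simulate a linear discrete-time system
#'
#' \eqn{y_t = A^t x_0}: the basic correctness fixture for DMD (whose
#' eigenvalues must recover those of `A`).
#'
#' @param A square matrix.
#' @param x0 initial state.
#' @param steps number of steps (output has `steps + 1` frames).
#' @param dt nominal sampling interval (s).
#' @return An `angle_series`.
#' @export
simulate_linear_system <- function(A, x0, steps, dt = 1) {
  stopifnot(is.matrix(A), nrow(A) == ncol(A), length(x0) == nrow(A),
            steps >= 1)
  vals <- matrix(0, nrow(A), steps + 1L)
  vals[, 1L] <- x0
  for (t in seq_len(steps)) vals[, t + 1L] <- A %*% vals[, t]
  angle_series(vals, dt = dt)
}

#' Simulate a Van der Pol oscillator
#'
#' Fixed-step RK4 integration of \eqn{x'' - \mu(1 - x^2)x' + x = 0}; for
#' \eqn{\mu > 0} the trajectory converges to a limit cycle of amplitude near 2.
#'
#' @param mu nonlinearity parameter, >= 0 (0 = harmonic oscillator).
#' @param dt output sampling interval (s).
#' @param duration simulated time (s).
#' @param init initial `(x, x')`.
#' @param internal_dt integration step (s).
#' @return An `angle_series` with channels `x`, `xdot`.
#' @export
simulate_van_der_pol <- function(mu, dt, duration, init = c(1, 0),
                                 internal_dt = min(dt, 1e-3)) {
  stopifnot(mu >= 0, length(init) == 2L, duration / dt >= 2)
  dec <- dt / internal_dt
  if (abs(dec - round(dec)) > 1e-9)
    stop("simulate_van_der_pol: internal_dt must divide dt", call. = FALSE)
  deriv <- function(t, s, p) list(c(s[2], mu * (1 - s[1]^2) * s[2] - s[1]))
  times <- seq(0, duration, by = internal_dt)
  sol <- deSolve::ode(init, times, deriv, NULL, method = "rk4")
  if (any(!is.finite(sol)))
    stop("simulate_van_der_pol: integration unstable; use a smaller internal_dt",
         call. = FALSE)
  keep <- seq(1L, nrow(sol), by = round(dec))
  angle_series(t(sol[keep, c(2L, 3L), drop = FALSE]), dt = dt,
               labels = c("x", "xdot"))
}
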