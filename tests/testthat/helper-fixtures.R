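## shared fixtures, all generated in code

## scalar sinusoid as an angle series
sinusoid_series <- function(freq, dt = 0.01, duration = 4, phase = 0,
                            amplitude = 1) {
  tt <- seq(0, duration, by = dt)
  angle_series(matrix(amplitude * cos(2 * pi * freq * tt + phase), 1),
               dt = dt)
}

## the 90-degree rotation snapshot sequence [cos(pi t/2), sin(pi t/2)], t=0..4
rotation_series <- function(dt = 1) {
  tt <- 0:4
  angle_series(rbind(cos(pi * tt / 2), sin(pi * tt / 2)), dt = dt)
}

## random diagonalizable real matrix with conjugate-stable spectrum,
## built from rotation/scale blocks so eigenvalues are known exactly
random_block_matrix <- function(dim, seed) {
  set.seed(seed)
  blocks <- list()
  eigs <- complex(0)
  left <- dim
  while (left > 0) {
    if (left >= 2 && runif(1) < 0.7) {
      r <- runif(1, 0.85, 1.05); th <- runif(1, 0.1, pi - 0.1)
      blocks <- c(blocks, list(r * matrix(c(cos(th), sin(th),
                                            -sin(th), cos(th)), 2)))
      eigs <- c(eigs, r * exp(1i * th), r * exp(-1i * th))
      left <- left - 2
    } else {
      a <- runif(1, -1, 1)
      blocks <- c(blocks, list(matrix(a, 1, 1)))
      eigs <- c(eigs, as.complex(a))
      left <- left - 1
    }
  }
  A0 <- matrix(0, dim, dim)
  pos <- 1L
  for (B in blocks) {
    k <- nrow(B)
    A0[pos:(pos + k - 1L), pos:(pos + k - 1L)] <- B
    pos <- pos + k
  }
  Q <- qr.Q(qr(matrix(rnorm(dim^2), dim)))
  list(A = Q %*% A0 %*% t(Q), eigenvalues = eigs)
}

## the study-condition synthetic gait: 3 channels, 5 harmonics of 0.8 Hz,
## 100 Hz sampling; optionally 20 dB SNR noise
study_gait <- function(noise = FALSE, seed = 1, duration = 6) {
  cfg <- gait_config(duration = duration)
  sdn <- if (noise) gait_noise_sd_for_snr(cfg, 20) else 0
  generate_harmonic_gait(gait_config(duration = duration, noise_sd = sdn,
                                     seed = seed))
}

## one mean-centered gait cycle (T = 125 frames at 0.8 Hz, 100 Hz)
study_cycle <- function(series, Tcyc = 125) {
  subtract_mean_posture(
    angle_series(series$values[, seq_len(Tcyc), drop = FALSE],
                 dt = series$dt, labels = series$labels))
}

expect_close <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)), tol)
}
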