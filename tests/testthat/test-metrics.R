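test_that("VAF and reconstruction error follow their defining formulas", {
  o <- diag(2)
  expect_equal(vaf(o, o), 1)
  expect_equal(vaf(o, 0 * o), 0)
  expect_equal(vaf(o, matrix(c(1, 0, 0, 0), 2)), 0.5)
  expect_error(vaf(0 * o, o), "all zero")
  expect_error(vaf(o, diag(3)), "shapes")

  a <- matrix(1, 2, 3)
  expect_equal(reconstruction_error(a, a), 0)
  expect_equal(reconstruction_error(a, 0 * a), 1)
  b <- a; b[1, 1] <- a[1, 1] + 0.6
  expect_equal(reconstruction_error(a, b), 0.1)
})

test_that("VAF = 1 exactly when the reconstruction error is 0 (consistency)", {
  set.seed(5)
  o <- matrix(rnorm(12), 3)
  r <- o + 0.01 * matrix(rnorm(12), 3)
  expect_lt(vaf(o, r), 1)
  expect_gt(reconstruction_error(o, r), 0)
  expect_equal(vaf(o, o), 1)
  expect_equal(reconstruction_error(o, o), 0)
})

test_that("DMD spectrum collapses conjugate pairs and finds generator harmonics", {
  ## single real mode at lambda = 1: one point at 0 Hz
  cst <- angle_series(matrix(rep(2, 6), 1), dt = 0.1)
  f0 <- exact_dmd(build_snapshot_pair(cst), p = 1)
  sp0 <- dmd_spectrum(f0)
  expect_equal(nrow(sp0), 1L)
  expect_equal(sp0$frequency, 0)

  ## pure 1 Hz pair collapses to a single point at 1 Hz with amplitude ~1
  s <- sinusoid_series(1, dt = 0.01, duration = 4)
  f1 <- column_type_hankel_dmd(s, m = 100, n = 100, p = 2)
  sp1 <- dmd_spectrum(f1)
  expect_equal(nrow(sp1), 1L)
  expect_close(sp1$frequency, 1, 1e-3)
  expect_close(sp1$magnitude, 1, 0.05)

  ## 5-harmonic gait: the 5 strongest points sit at k*f0
  g <- study_gait(noise = TRUE, seed = 3)
  fc <- column_type_hankel_dmd(g, m = 125, n = 125, p = 50)
  sp <- dmd_spectrum(fc)
  top5 <- sort(sp$frequency[order(-sp$magnitude)][1:5])
  expect_close(top5, 0.8 * (1:5), 0.01)
})

test_that("Fourier spectrum uses the amplitude convention and channel averaging", {
  ## integer number of periods: single nonzero bin at the tone frequency
  tt <- (0:399) * 0.01
  s <- angle_series(matrix(2 * cos(2 * pi * 1 * tt), 1), dt = 0.01)
  sp <- fourier_spectrum(s)
  peak <- sp$frequency[which.max(sp$magnitude)]
  expect_equal(peak, 1)
  expect_close(max(sp$magnitude), 2, 1e-10)
  expect_lt(sort(sp$magnitude, decreasing = TRUE)[2], 1e-10)

  ## constant series: energy only at DC
  sc <- fourier_spectrum(angle_series(matrix(rep(3, 10), 1), dt = 0.1))
  expect_equal(sc$magnitude[sc$frequency == 0], 3)
  expect_lt(max(sc$magnitude[sc$frequency > 0]), 1e-12)

  ## channel amplitudes 1 and 3 average to twice the unit peak
  v <- rbind(cos(2 * pi * tt), 3 * cos(2 * pi * tt))
  sp2 <- fourier_spectrum(angle_series(v, dt = 0.01))
  expect_close(max(sp2$magnitude), 2, 1e-10)
})

test_that("spectrum normalization rescales magnitude and axis idempotently", {
  sp <- koopgait:::new_spectrum_table(c(0.8, 1.6, 2.4), c(4, 2, 1))
  ns <- normalize_and_rescale_spectrum(sp, gait_freq = 0.8)
  expect_equal(max(ns$magnitude), 1)
  expect_equal(ns$frequency, c(1, 2, 3))
  expect_true(attr(ns, "normalized") && attr(ns, "relative"))
  ## idempotent on an already-normalized relative spectrum
  ns2 <- normalize_and_rescale_spectrum(ns, gait_freq = 0.8)
  expect_equal(as.data.frame(ns2), as.data.frame(ns))
  ## all-zero magnitudes rejected
  z <- koopgait:::new_spectrum_table(1, 0)
  expect_error(normalize_and_rescale_spectrum(z, 1), "zero")
})

test_that("harmonic deviation matches within half-harmonic windows", {
  mk <- function(freqs_hz, dt = 0.01) {
    lam <- exp(1i * 2 * pi * freqs_hz * dt)
    koopgait:::new_dmd(lam, matrix(1 + 0i, 1, length(lam)),
                       rep(1 + 0i, length(lam)), dt = dt, method = "exact")
  }
  ## exact harmonics: all zeros
  hd0 <- harmonic_deviation(mk(c(1, 2, 3)), 1, 3)
  expect_equal(hd0$deviation, c(0, 0, 0))
  ## fixed offsets: 2% each
  hd1 <- harmonic_deviation(mk(c(1.02, 2.04, 3.06)), 1, 3)
  expect_close(hd1$deviation, rep(0.02, 3), 1e-10)
  ## empty window at k = 4 marked missing, not an error
  hd2 <- harmonic_deviation(mk(c(1, 2, 3)), 1, 4)
  expect_true(is.na(hd2$deviation[4]))
  expect_equal(hd2$deviation[1:3], c(0, 0, 0))
  ## top-vaf retention needs the original data
  expect_error(harmonic_deviation(mk(1), 1, 1, retain = "top-vaf"),
               "original")
})

test_that("Fourier average recovers eigenfunction values with prior frequency", {
  dt <- 0.01
  tt <- (0:499) * dt
  ## complex exponential observable queried at its own frequency
  sig <- exp(1i * 2 * pi * 2 * tt)
  attr(sig, "dt") <- dt
  phi <- fourier_average_eigenfunction(sig, 2)
  expect_close(Mod(attr(phi, "average")), 1, 1e-10)
  expect_close(koopgait:::wrap_phase(Arg(phi) - 2 * pi * 2 * tt), rep(0, 500),
               1e-8)
  ## wrong frequency over full periods of both: average cancels
  expect_error(fourier_average_eigenfunction(sig, 4), "not present")
  ## constant signal queried at 0 returns the constant
  cs <- angle_series(matrix(rep(0.7, 100), 1), dt = dt)
  phic <- fourier_average_eigenfunction(cs, 0)
  expect_close(Re(attr(phic, "average")), 0.7, 1e-12)
  ## sub-period series rejected
  short <- angle_series(matrix(cos(2 * pi * 0.5 * (0:9) * dt), 1), dt = dt)
  expect_error(fourier_average_eigenfunction(short, 0.5), "one period")
})

test_that("phase difference removes the initial offset and averages drift", {
  th <- seq(0, 4 * pi, length.out = 200)
  expect_equal(phase_difference(th, th, 0.01)$mean_abs, 0)
  ## constant offset removed circularly
  expect_lt(phase_difference(koopgait:::wrap_phase(th + pi / 4),
                             koopgait:::wrap_phase(th), 0.01)$mean_abs, 1e-12)
  ## linear drift 0.01 rad/frame over 100 frames: mean |0.01 t| = 0.495
  a <- 0.01 * (0:99)
  b <- rep(0, 100)
  pd <- phase_difference(a, b, dt = 0.01)
  expect_close(pd$mean_abs, 0.495, 1e-12)
  expect_close(pd$per_second, 0.495 / 0.99, 1e-10)
  ## all-NA input rejected
  expect_error(phase_difference(c(NA, NA), c(0, 0), 0.01), "no defined")
})

test_that("SVD baseline explains planar data and fixes signs deterministically", {
  ## data exactly in a 2-plane
  tt <- seq(0, 2, by = 0.01)
  B <- qr.Q(qr(matrix(c(1, 2, 3, -1, 0, 1), 3)))
  coords <- rbind(cos(2 * pi * tt), sin(2 * pi * tt))
  s <- angle_series(B %*% coords, dt = 0.01)
  sb <- svd_baseline(s, 2)
  expect_close(sum(sb$explained), 1, 1e-12)
  ## sign convention: largest-magnitude entry positive
  expect_true(all(apply(sb$basis, 2, function(u) u[which.max(abs(u))] > 0)))
  ## basis spans the generating plane
  proj <- sb$basis %*% t(sb$basis) %*% B
  expect_close(proj, B, 1e-8)
  ## rank-1 data: first temporal coordinate proportional to the waveform
  w <- sin(2 * pi * tt)
  s1 <- angle_series(rbind(w, 2 * w, -w), dt = 0.01)
  sb1 <- svd_baseline(s1, 1)
  cc <- abs(stats::cor(sb1$temporal[1, ], w))
  expect_gt(cc, 1 - 1e-10)
  expect_error(svd_baseline(s1, 5), "exceeds")
})

test_that("isotropic noise spreads explained variance evenly (property)", {
  set.seed(8)
  s <- angle_series(matrix(rnorm(4 * 4000), 4), dt = 0.01)
  sb <- svd_baseline(s, 4)
  expect_close(sb$explained, rep(0.25, 4), 0.03)
})

test_that("planar deviation measures PC3 leakage", {
  B <- diag(3)
  tt <- seq(0, 1, by = 0.01)
  inplane <- rbind(cos(2 * pi * tt), sin(2 * pi * tt), 0 * tt)
  expect_equal(planar_deviation(inplane, B), 0)
  spike <- inplane; spike[3, 5] <- 0.2
  expect_equal(planar_deviation(spike, B), 0.2)
  expect_error(planar_deviation(inplane, B * 2), "orthonormal")
})

test_that("harmonic reconstruction suppresses off-plane noise (PC3 comparison)", {
  ## near-planar 3-channel limit cycle with noise injected off-plane only
  tt <- (0:599) * 0.01
  B <- qr.Q(qr(matrix(c(1, 1, 0, -1, 1, 1, 1, -1, 2), 3)))
  coords <- rbind(0.5 * cos(2 * pi * 0.8 * tt),
                  0.5 * sin(2 * pi * 0.8 * tt) + 0.1 * sin(2 * pi * 1.6 * tt))
  set.seed(4)
  off <- 0.05 * rnorm(length(tt))
  v <- B[, 1:2] %*% coords + B[, 3, drop = FALSE] %*% t(off)
  s <- angle_series(v, dt = 0.01)
  sb <- svd_baseline(s, 3)
  fc <- column_type_hankel_dmd(s, m = 125, n = 125, p = 50)
  rk <- rank_conjugate_pairs_by_vaf(fc, s$values[, 1:125])
  rec <- reconstruct(fc, unlist(utils::head(rk$modes, 2)), t = 0:124)
  centered <- s$values[, 1:125] - rowMeans(s$values[, 1:125])
  expect_lt(planar_deviation(rec - rowMeans(rec), sb$basis),
            planar_deviation(centered, sb$basis))
})

test_that("prefix VAF is monotone over VAF-ranked conjugate pairs (property)", {
  prefix_vafs <- function(g, kmax) {
    cyc <- study_cycle(g)
    fc <- suppressWarnings(column_type_hankel_dmd(g, m = 125, n = 125, p = 50))
    rk <- rank_conjugate_pairs_by_vaf(fc, cyc$values)
    vapply(seq_len(min(kmax, nrow(rk))), function(k)
      vaf(cyc$values,
          reconstruct(fc, unlist(rk$modes[seq_len(k)]), t = 0:124)),
      numeric(1))
  }
  ## noise-free: monotone over every ranked prefix
  expect_true(all(diff(prefix_vafs(study_gait(noise = FALSE), 10)) >= -1e-8))
  ## 20 dB noise: monotone over the prefixes that add signal pairs
  expect_true(all(diff(prefix_vafs(study_gait(noise = TRUE, seed = 6), 5)) > 0))
})
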