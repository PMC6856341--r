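test_that("snapshot pairs index the sequence correctly and reject short input", {
  s <- angle_series(matrix(0:3, nrow = 1), dt = 1)
  pr <- build_snapshot_pair(s)
  expect_equal(as.vector(pr$X), c(0, 1, 2))
  expect_equal(as.vector(pr$Y), c(1, 2, 3))
  expect_identical(pr$meta$assembly, "plain")

  s2 <- angle_series(matrix(c(1, 2, 3, 4), 2), dt = 1)
  pr2 <- build_snapshot_pair(s2)
  expect_equal(dim(pr2$X), c(2L, 1L))

  expect_error(angle_series(matrix(1, 1, 1), dt = 1), "at least 2 frames")
})

test_that("exact DMD recovers the rotation spectrum and scalar dynamics", {
  fit <- exact_dmd(build_snapshot_pair(rotation_series()), p = 2)
  expect_close(sort(Im(fit$eigenvalues)), c(-1, 1), 1e-10)
  expect_close(abs(Re(fit$eigenvalues)), c(0, 0), 1e-10)

  geo <- angle_series(matrix(2^(0:3), 1), dt = 1)
  fg <- exact_dmd(build_snapshot_pair(geo), p = 1)
  expect_close(fg$eigenvalues, 2 + 0i, 1e-10)
  expect_close(Mod(fg$modes[1, 1]) * Mod(fg$amplitudes[1]), 1, 1e-10)

  cst <- angle_series(matrix(rep(3, 5), 1), dt = 1)
  fc <- exact_dmd(build_snapshot_pair(cst), p = 1)
  expect_close(fc$eigenvalues, 1 + 0i, 1e-10)
})

test_that("exact DMD clamps p to the numerical rank with a warning", {
  s <- angle_series(rbind(2^(0:4), 2^(0:4)), dt = 1)   # rank 1 in 2 channels
  expect_warning(fit <- exact_dmd(build_snapshot_pair(s), p = 2),
                 "clamped")
  expect_equal(fit$p, 1L)
  expect_true(glance(fit)$rank_clamped)
})

test_that("exact DMD recovers known spectra of random linear systems", {
  for (seed in 1:5) {
    dim <- sample(2:5, 1)
    sys <- random_block_matrix(dim, seed = seed)
    set.seed(seed + 100)
    s <- simulate_linear_system(sys$A, rnorm(dim), steps = 2 * dim + 5)
    fit <- exact_dmd(build_snapshot_pair(s), p = dim)
    err <- max(vapply(sys$eigenvalues, function(l)
      min(Mod(fit$eigenvalues - l)), numeric(1)))
    expect_lt(err, 1e-6)
  }
})

test_that("companion DMD finds true eigenvalues and agrees with exact DMD", {
  ## rotation sequence: +-i among the spectrum
  fit <- suppressWarnings(companion_dmd(build_snapshot_pair(rotation_series())))
  expect_lt(min(Mod(fit$eigenvalues - 1i)), 1e-8)
  expect_lt(min(Mod(fit$eigenvalues + 1i)), 1e-8)

  ## scalar geometric sequence, N = 2
  geo <- angle_series(matrix(2^(0:2), 1), dt = 1)
  fg <- suppressWarnings(companion_dmd(build_snapshot_pair(geo)))
  expect_lt(min(Mod(fg$eigenvalues - 2)), 1e-8)

  ## scalar sinusoid: e^{+-i 2 pi f dt} among the roots
  s <- sinusoid_series(2, dt = 0.01, duration = 0.5)
  fs <- suppressWarnings(companion_dmd(build_snapshot_pair(s)))
  tgt <- exp(1i * 2 * pi * 2 * 0.01)
  expect_lt(min(Mod(fs$eigenvalues - tgt)), 1e-8)
  expect_lt(min(Mod(fs$eigenvalues - Conj(tgt))), 1e-8)

  ## full-rank noise-free linear system: nonspurious roots match exact DMD
  sys <- random_block_matrix(4, seed = 11)
  set.seed(11)
  s4 <- simulate_linear_system(sys$A, rnorm(4), steps = 12)
  fe <- exact_dmd(build_snapshot_pair(s4), p = 4)
  fc <- suppressWarnings(companion_dmd(build_snapshot_pair(s4)))
  err <- max(vapply(fe$eigenvalues, function(l)
    min(Mod(fc$eigenvalues - l)), numeric(1)))
  expect_lt(err, 1e-6)
})

test_that("eigenvalue-to-frequency transform matches closed forms and round-trips", {
  expect_equal(eigen_to_frequency(1 + 0i, 0.37), 0 + 0i)
  expect_close(eigen_to_frequency(exp(1i * pi / 2), 0.01), 25i, 1e-12)
  expect_close(eigen_to_frequency(0.5 + 0i, 1), log(0.5) / (2 * pi) + 0i,
               1e-12)
  expect_error(eigen_to_frequency(0 + 0i, 0.01), "lambda = 0")

  lam <- c(0.9 * exp(1i * 0.3), exp(-1i * 2), 1.05 + 0i)
  w <- eigen_to_frequency(lam, 0.02)
  expect_close(exp(2 * pi * w * 0.02), lam, 1e-12)
})

test_that("mode amplitudes solve the least-squares initial-value problem", {
  expect_equal(mode_amplitudes(diag(2) + 0i, c(3, 4)), c(3 + 0i, 4 + 0i))

  ## orthonormal modes: b0 = conjugate transpose applied to y0
  Q <- qr.Q(qr(matrix(rnorm(9), 3)))
  y0 <- rnorm(3)
  expect_close(mode_amplitudes(Q + 0i, y0), Conj(t(Q)) %*% y0, 1e-12)

  ## rank-1 modes with y0 in span: exact reconstruction
  psi <- matrix(c(1, 2, 2, 4) + 0i, 2)   # rank 1
  y0 <- c(2, 4)
  b <- mode_amplitudes(psi, y0)
  expect_close(psi %*% b, y0 + 0i, 1e-10)

  expect_error(mode_amplitudes(diag(2) + 0i, 1:3), "length")
})

test_that("reconstruction is exact on rank-p data, real, and guards overflow", {
  sys <- random_block_matrix(4, seed = 3)
  set.seed(3)
  s <- simulate_linear_system(sys$A, rnorm(4), steps = 20)
  fit <- exact_dmd(build_snapshot_pair(s), p = 4)
  rec <- reconstruct(fit, t = 0:20)
  expect_lt(max(abs(rec - s$values)), 1e-6)
  expect_true(is.numeric(rec) && !is.complex(rec))

  ## empty subset: zeros
  expect_equal(reconstruct(fit, integer(0), t = 0:5),
               matrix(0, 4, 6))

  ## conjugate-pair subset on real data is real to 1e-10
  groups <- koopgait:::conjugate_groups(fit$eigenvalues)
  pair <- groups[[which(lengths(groups) == 2)[1]]]
  ## imaginary part discarded after summation: compare against complex sum
  dyn <- outer(fit$eigenvalues[pair], 0:20, `^`) * fit$amplitudes[pair]
  cplx <- fit$modes[, pair] %*% dyn
  expect_lt(max(abs(Im(cplx))), 1e-10)

  ## overflow guard
  grow <- angle_series(matrix(10^(0:5), 1), dt = 1)
  fg <- exact_dmd(build_snapshot_pair(grow), p = 1)
  expect_error(reconstruct(fg, t = 0:200), "overflow")
})

test_that("VAF ranking orders conjugate pairs by explanatory power", {
  ## two-harmonic signal, amplitudes 1 and 0.1: fundamental pair first
  tt <- seq(0, 4, by = 0.01)
  v <- rbind(cos(2 * pi * tt) + 0.1 * cos(2 * pi * 3 * tt + 0.4),
             sin(2 * pi * tt) + 0.1 * sin(2 * pi * 3 * tt))
  s <- angle_series(v, dt = 0.01)
  fit <- column_type_hankel_dmd(s, m = 100, n = 100, p = 4)
  rk <- rank_conjugate_pairs_by_vaf(fit, s$values[, 1:100])
  expect_equal(nrow(rk), 2L)
  expect_close(rk$frequency_hz[1], 1, 1e-3)
  expect_close(rk$frequency_hz[2], 3, 1e-3)
  expect_true(all(diff(rk$vaf) <= 0))

  ## all-real spectrum: singleton groups
  A <- diag(c(0.9, 0.5))
  sr <- simulate_linear_system(A, c(1, 1), steps = 10)
  fr <- exact_dmd(build_snapshot_pair(sr), p = 2)
  rkr <- rank_conjugate_pairs_by_vaf(fr, sr$values)
  expect_true(all(lengths(rkr$modes) == 1L))
})

test_that("real input gives a conjugation-closed spectrum (property)", {
  for (seed in 1:4) {
    set.seed(seed)
    v <- matrix(rnorm(3 * 30), 3)
    fit <- exact_dmd(build_snapshot_pair(angle_series(v, dt = 0.01)), p = 3)
    err <- max(vapply(fit$eigenvalues, function(l)
      min(Mod(fit$eigenvalues - Conj(l))), numeric(1)))
    expect_lt(err, 1e-8)
  }
})

test_that("plain exact DMD returns at most d eigenvalues (dimension ceiling)", {
  g <- study_gait(noise = TRUE, seed = 7)
  cyc <- study_cycle(g)
  fit <- suppressWarnings(exact_dmd(build_snapshot_pair(cyc), p = 50))
  expect_lte(fit$p, 3L)
  expect_lte(length(fit$eigenvalues), 3L)
})
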