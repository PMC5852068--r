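test_that("frame equations vanish at the interictal fixed point", {
  for (variant in c("full", "reduced")) {
    fp <- epifield:::frame_fixed_point(3.0, 1, -1, variant)
    d <- traveling_frame_rhs(fp, c1 = 0.05, Vbar = 3.0, variant = variant)
    expect_lt(max(abs(d)), 1e-9)
  }
  expect_error(traveling_frame_rhs(rep(0, 5), 0, 3.0), "nonzero")
})

test_that("the simulated front is a traveling wave: time derivative equals speed times profile slope", {
  # coarse finite-difference check of the co-moving-frame representation
  # du1/dt = c1 du1/dx on the leading edge of a frozen-v front
  N <- 512; L <- 12 * pi
  x <- (seq_len(N) - 1) * L / N
  u1r <- epifield:::frozen_rest_u1(3.0, 1, -1)
  u1u <- epifield:::frozen_upper_u1(3.0, 1, -1)
  u1_0 <- rep(u1r, N); u2_0 <- 1 - 5 * u1_0^2
  ign <- abs(x - L / 2) < 4
  u1_0[ign] <- u1u; u2_0[ign] <- 1 - 5 * u1u^2
  r <- simulate_fast_subsystem_cpp(u1_0, u2_0, 3.0, 3.1, 1, -1, L,
                                   0.025, 6000, 20, 1L)
  it <- nrow(r$u1) - 1
  dt_rec <- r$time[2] - r$time[1]
  dudt <- (r$u1[it + 1, ] - r$u1[it - 1, ]) / (2 * dt_rec)
  dudx <- (r$u1[it, c(2:N, 1)] - r$u1[it, c(N, 1:(N - 1))]) / (2 * L / N)
  # leading edge of the rightward front: monotone rise, no oscillation yet
  edge <- which(r$u1[it, ] > u1r + 0.1 & r$u1[it, ] < -1.2 & x > L / 2)
  expect_gt(length(edge), 3)
  c_est <- stats::median(-dudt[edge] / dudx[edge])
  expect_equal(abs(c_est), 0.053, tolerance = 0.25)
})

test_that("SNIC threshold matches the analytic value and a brute-force scan", {
  expect_equal(snic_threshold(0.45), 2 / (3 * sqrt(3)) - 0.45,
               tolerance = 1e-12)
  expect_equal(snic_threshold(0.45), -0.0651, tolerance = 1e-3)
  # brute force: smallest K (step 1e-4) for which the left-branch rest state
  # q1 < -1/sqrt(3) of q1 - q1^3 + I2 + K = 0 disappears
  has_rest <- function(K) {
    r <- polyroot(c(0.45 + K, 1, 0, -1))
    any(abs(Im(r)) < 1e-8 & Re(r) < -1 / sqrt(3) - 1e-7)
  }
  Ks <- seq(-0.1, 0, by = 1e-4)
  brute <- Ks[which(!vapply(Ks, has_rest, TRUE))[1]]
  expect_lt(abs(snic_threshold(0.45) - brute), 2e-4)
  # oscillatory at K = 1.5, rest state far below threshold
  expect_false(has_rest(1.5))
  expect_true(has_rest(snic_threshold(0.45) - 1))
})

test_that("transit-time quadrature matches a fine midpoint-rule oracle", {
  p <- field_params()
  expect_equal(swd_transit_time(-1 / sqrt(3), 1.5, p), 0)
  q0 <- -1.2; K <- 1.5
  T1 <- swd_transit_time(q0, K, p)
  # brute-force midpoint rule, 1e6 panels
  n <- 1e6
  qs <- q0 + (seq_len(n) - 0.5) / n * (-1 / sqrt(3) - q0)
  f <- p$tau2 * (1 - 3 * qs^2) / (-qs + qs^3 - p$I2 - K)
  T2 <- mean(f) * (-1 / sqrt(3) - q0)
  expect_equal(T1, T2, tolerance = 1e-6)
  expect_gt(T1, 0)
  # strictly decreasing in K
  Ts <- vapply(c(0.5, 1.0, 1.5), function(K) swd_transit_time(q0, K, p),
               numeric(1))
  expect_true(all(diff(Ts) < 0))
  expect_error(swd_transit_time(-0.2, 1.5, p), "left branch")
  expect_error(swd_transit_time(-1.2, snic_threshold() - 0.5, p), "singular")
})

test_that("transit time agrees with direct integration of the isolated oscillator", {
  # oracle: the two-variable relaxation oscillator (gamma22 = 0) run from
  # the left branch to the knee
  p <- field_params()
  K <- 1.5; q0 <- -1.3
  q2_0 <- q0 - q0^3 + p$I2 + K      # on the q1-nullcline
  q1 <- q0; q2 <- q2_0
  dt <- 1e-4; tmax <- 100; tknee <- NA
  rhs <- function(q1, q2) c(-q2 + q1 - q1^3 + p$I2 + K,
                            (-q2 + f2(q1)) / p$tau2)
  for (i in seq_len(tmax / dt)) {
    k1 <- rhs(q1, q2)
    k2 <- rhs(q1 + dt / 2 * k1[1], q2 + dt / 2 * k1[2])
    q1n <- q1 + dt * k2[1]; q2 <- q2 + dt * k2[2]
    if (q1n >= -1 / sqrt(3)) { tknee <- i * dt; break }
    q1 <- q1n
  }
  expect_false(is.na(tknee))
  expect_equal(swd_transit_time(q0, K, p), tknee, tolerance = 0.05 * tknee)
})

test_that("discharge speed between oscillators follows the phase-lag formula", {
  p <- field_params()
  dx <- 6 * pi / 256
  expect_error(swd_speed(-1.2, -1.2, dx, 1.5, p), "undefined")
  c2 <- swd_speed(-1.2, -1.21, dx, 1.5, p)
  expect_true(is.finite(c2))
  # direction: the site closer to the knee fires first, so the discharge
  # travels from i toward j (positive) when q1_i is closer to the knee
  expect_gt(c2, 0)
  expect_lt(swd_speed(-1.21, -1.2, dx, 1.5, p), 0)
  # speed magnitude grows as phases approach each other
  expect_gt(abs(swd_speed(-1.2, -1.201, dx, 1.5, p)), abs(c2))
})

test_that("c2 varies smoothly and stays one-signed over the oscillatory K range", {
  p <- field_params()
  Ks <- seq(snic_threshold() + 0.15, 2, length.out = 12)
  c2s <- vapply(Ks, function(K) swd_speed(-1.2, -1.25, 6 * pi / 256, K, p),
                numeric(1))
  expect_true(all(is.finite(c2s)))
  expect_true(all(sign(c2s) == sign(c2s[1])))
  # smooth: successive ratios bounded
  expect_true(all(abs(diff(log(abs(c2s)))) < 1))
})

test_that("snapshot phase pairs yield admissible speeds only", {
  p <- field_params()
  snap <- c(-1.3, -1.2, -0.5, -1.25, -1.25)
  out <- swd_snapshot_speeds(snap, 0.07, 1.5, p)
  # pairs involving the site above the knee or with equal phases are dropped
  expect_true(all(out$site %in% c(1)))
  expect_true(all(is.finite(out$c2)))
})

test_that("reduced-variant shooting runs and reports a faster front than the full variant window", {
  red <- shoot_front_speed(3.0, 1, -1, "reduced")
  expect_gt(red$c1, 0)
  expect_equal(red$c1, 0.668, tolerance = 0.02)
  expect_error(shoot_front_speed(3.0, 0, -1), "gamma11")
})
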