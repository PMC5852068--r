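test_that("printed model constants are the package defaults", {
  p <- field_params()
  expect_equal(p$I1, 3.1)
  expect_equal(p$I2, 0.45)
  expect_equal(p$tau0, 2857)
  expect_equal(p$tau2, 10)
  expect_equal(p$tau12, 100)
  expect_equal(p$theta11, -1)
  expect_equal(p$theta22, -0.5)
  expect_equal(p$theta12, -1)
  expect_equal(p$theta_het, -1)
  expect_equal(p$a12, 3)
  expect_equal(p$gamma11, 1)
  expect_equal(p$gamma22, 1)
  expect_equal(p$gamma12, 10)
  expect_equal(p$L, 6 * pi)
  expect_true(p$tau0 > p$tau12 && p$tau12 > p$tau2 && p$tau2 > 1)
  expect_error(field_params(N = 32), "N")
  expect_error(field_params(tau2 = 500), "time-scale")
})

test_that("Heaviside firing rate uses the H(0)=1 boundary convention", {
  expect_equal(heaviside(0, -1), 1)
  expect_equal(heaviside(-2, -1), 0)
  expect_equal(heaviside(-1, -1), 1)
  expect_equal(heaviside(c(-3, 0, 3), 0), c(0, 1, 1))
})

test_that("population nonlinearities match their piecewise definitions and are continuous", {
  expect_equal(f1(-1, 5, 7), -4)
  expect_equal(f1(0, 2, 3), 0)
  expect_equal(f1(1, 0.6, 3), 0)
  # continuity of f1 at u1 = 0 for arbitrary (q1, v)
  eps <- 1e-9
  for (qv in list(c(0.3, 3.5), c(-1, 4), c(2, 2))) {
    expect_equal(f1(-eps, qv[1], qv[2]), f1(eps, qv[1], qv[2]),
                 tolerance = 1e-7)
  }
  expect_equal(f2(-0.5), 0)
  expect_equal(f2(-0.25), 0)
  expect_equal(f2(0.25), 3)
  expect_equal(f2(-0.25 - 1e-12), f2(-0.25 + 1e-12), tolerance = 1e-10)
})

test_that("connectivity kernels have the stated pointwise values and Fourier transform", {
  expect_equal(kernel_values("laplacian", 0), 0.5)
  expect_equal(kernel_values("gaussian_het", 0), 1 / sqrt(8 * pi))
  expect_error(kernel_values("boxcar", 0), "unknown kernel")
  # even functions
  xs <- c(0.3, 1.7, 4.2)
  expect_equal(kernel_values("laplacian", xs), kernel_values("laplacian", -xs))
  expect_equal(kernel_values("gaussian_het", xs),
               kernel_values("gaussian_het", -xs))
  # discrete FT of the sampled Laplacian kernel matches (1+k^2)^-1 at
  # resolved wavenumbers (k=1 gives exactly 1/2)
  N <- 4096; L <- 6 * pi
  k <- epifield:::periodic_kernel("laplacian", N, L)
  khat <- Re(stats::fft(k)) * (L / N)
  kn <- 2 * pi * (0:(N - 1)) / L
  resolved <- which(kn > 0 & kn < 20)
  expect_lt(max(abs(khat[resolved] - 1 / (1 + kn[resolved]^2)) /
                (1 / (1 + kn[resolved]^2))), 1e-3)
  i1 <- which.min(abs(kn - 1))
  expect_equal(khat[i1], 0.5, tolerance = 2e-3)
})

test_that("kernels integrate to one on the periodic grid and preserve constants", {
  for (kind in c("laplacian", "gaussian_het")) {
    for (N in c(128, 256)) {
      k <- epifield:::periodic_kernel(kind, N, 6 * pi)
      expect_equal(sum(k) * 6 * pi / N, 1, tolerance = 1e-6)
    }
    out <- convolve_periodic(rep(2.7, 256), kind)
    expect_lt(max(abs(out - 2.7)), 1e-10)
  }
})

test_that("field rhs vanishes at the interictal equilibrium and respects symmetry and coupling linearity", {
  p <- field_params(u0 = -2.5, N = 128)
  fp <- interictal_fixed_point(-2.5, p)
  st <- uniform_state(fp, 128)
  d <- field_rhs(st, p)
  expect_lt(max(abs(unlist(d))), 1e-10)

  # translation invariance: uniform state gives identical derivative at
  # every grid point, even with active coupling
  st2 <- uniform_state(c(u1 = -0.5, u2 = 0.2, v = 3, q1 = -0.3, q2 = 0.1,
                         q3 = 0), 128)
  d2 <- field_rhs(st2, p)
  for (v in d2) expect_lt(diff(range(v)), 1e-12)

  # doubling gamma11 doubles the homogeneous contribution to du1
  set.seed(7)
  st3 <- list(u1 = rnorm(128), u2 = rnorm(128), v = rnorm(128, 3),
              q1 = rnorm(128), q2 = rnorm(128), q3 = rnorm(128))
  p1 <- field_params(u0 = -2.5, N = 128, gamma11 = 1)
  p2 <- field_params(u0 = -2.5, N = 128, gamma11 = 2)
  p0 <- field_params(u0 = -2.5, N = 128, gamma11 = 0)
  d1 <- field_rhs(st3, p1)$u1
  dd2 <- field_rhs(st3, p2)$u1
  d0 <- field_rhs(st3, p0)$u1
  expect_equal(dd2 - d0, 2 * (d1 - d0), tolerance = 1e-9)

  expect_error(field_rhs(st3[c("u1", "u2")], p1), "length|state")
})

test_that("K diagnostic follows its closed formula", {
  expect_equal(k_field(0, 3.5), 0)
  expect_equal(k_field(0.75, 3.5), 1.5)
  q3 <- matrix(runif(12), 3); v <- matrix(runif(12, 3, 4), 3)
  K <- k_field(q3, v)
  expect_equal(K, 2 * q3 - 0.3 * (v - 3.5))
  expect_equal(which.max(K[2, ]), which.max(2 * q3[2, ] - 0.3 * (v[2, ] - 3.5)))
})

test_that("interictal equilibrium exists below the knee and fails above it", {
  fp <- interictal_fixed_point(-2.5)
  expect_equal(fp[["u1"]], -1.6944, tolerance = 1e-3)
  expect_lt(fp[["u1"]], -4 / 3)
  # analytic knee: u0c = -4/3 - h(-4/3)/4 with h(u) = -u^3 - 2u^2 + 4.1
  h_knee <- -(-4 / 3)^3 - 2 * (-4 / 3)^2 + 4.1
  expect_equal(epileptogenic_threshold(), -4 / 3 - h_knee / 4,
               tolerance = 1e-12)
  expect_equal(epileptogenic_threshold(), -2.062, tolerance = 1e-3)
  expect_error(interictal_fixed_point(-1.6), "epileptogenic")
})
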