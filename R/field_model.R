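#' Heaviside firing-rate function
#'
#' The coupling (firing-rate) function of the field model,
#' \eqn{S(u,\theta) = H(u - \theta)}, with the boundary convention
#' \eqn{H(0) = 1} (upper semicontinuous; threshold hits have measure zero in
#' simulation).
#'
#' @param u membrane-like state value(s).
#' @param theta firing threshold.
#' @return 0/1 vector of the same length as \code{u}.
#' @export
heaviside <- function(u, theta) {
  stopifnot(all(is.finite(u)), is.finite(theta))
  as.numeric(u >= theta)
}

#' Fast-population nonlinearity
#'
#' Piecewise cubic/quadratic nonlinearity of the fast population:
#' \eqn{f_1 = u_1^3 - 3u_1^2} for \eqn{u_1 < 0} and
#' \eqn{f_1 = (q_1 - 0.6 (v-4)^2)\, u_1} for \eqn{u_1 \ge 0}.
#' Continuous at \eqn{u_1 = 0}.
#'
#' @param u1,q1,v state values (vectorised, recycled to a common length).
#' @export
f1 <- function(u1, q1, v) {
  n <- max(length(u1), length(q1), length(v))
  u1 <- rep_len(u1, n); q1 <- rep_len(q1, n); v <- rep_len(v, n)
  ifelse(u1 < 0, u1^3 - 3 * u1^2, (q1 - 0.6 * (v - 4)^2) * u1)
}

#' Spike-wave population nonlinearity
#'
#' \eqn{f_2 = 0} for \eqn{q_1 < -0.25}, \eqn{f_2 = 6(q_1 + 0.25)} otherwise.
#'
#' @param q1 state value(s).
#' @export
f2 <- function(q1) {
  ifelse(q1 < -0.25, 0, 6 * (q1 + 0.25))
}

#' Connectivity kernel values
#'
#' Pointwise values of the two connectivity kernels of the model: the
#' Laplacian local kernel \eqn{w(x) = e^{-|x|}/2} (used for all three
#' homogeneous couplings) and the Gaussian heterogeneous kernel
#' \eqn{w_{het}(x) = e^{-x^2/8}/\sqrt{8\pi}}.  Both integrate to 1 over the
#' real line.
#'
#' @param kind \code{"laplacian"} or \code{"gaussian_het"}.
#' @param x offsets (a.u.).
#' @export
kernel_values <- function(kind, x) {
  switch(kind,
         laplacian = exp(-abs(x)) / 2,
         gaussian_het = exp(-x^2 / 8) / sqrt(8 * pi),
         stop("unknown kernel kind: ", kind))
}

# kernel sampled on the periodic grid (offsets 0, dx, ..., (N-1) dx wrapped to
# [-L/2, L/2)), periodised over images and normalised so that sum * dx = 1;
# the normalisation makes convolution of a constant exactly the constant.
periodic_kernel <- function(kind, N, L, n_images = 3) {
  dx <- L / N
  off <- (seq_len(N) - 1) * dx
  off <- ifelse(off > L / 2, off - L, off)
  k <- rep(0, N)
  for (m in -n_images:n_images) k <- k + kernel_values(kind, off + m * L)
  k / (sum(k) * dx)
}

# FFT of the discretised kernel scaled by dx, ready for circular convolution
kernel_fft <- function(kind, N, L) {
  stats::fft(periodic_kernel(kind, N, L)) * (L / N)
}

#' Circular convolution on the periodic grid
#'
#' FFT-based circular convolution of a field against one of the model's
#' connectivity kernels (or an arbitrary sampled kernel), matching the direct
#' Riemann sum \eqn{\sum_j w(x_i - x_j)\, s(x_j)\, \Delta x} to near machine
#' precision.
#'
#' @param values field samples (length \code{N}).
#' @param kernel kernel kind (\code{"laplacian"}, \code{"gaussian_het"}) or a
#'   numeric vector of kernel samples on the grid offsets.
#' @param L field length (a.u.).
#' @export
convolve_periodic <- function(values, kernel = "laplacian", L = 6 * pi) {
  N <- length(values)
  khat <- if (is.character(kernel)) kernel_fft(kernel, N, L)
          else {
            if (length(kernel) != N) stop("kernel/values length mismatch")
            stats::fft(kernel) * (L / N)
          }
  Re(stats::fft(stats::fft(values) * khat, inverse = TRUE)) / N
}

#' Right-hand side of the Epileptor field equations
#'
#' Reference (R-level) implementation of the time-derivatives of all state
#' arrays for one or more coupled fields, with the temporal convolution
#' \code{g(u1)} represented by the auxiliary variable \code{q3}
#' (\eqn{2 q_3 \equiv 0.002\, g(u_1)}, exact ODE recast).  The compiled
#' integrator used by [simulate_field()] implements the same equations; this
#' function is the single-step oracle used for testing and for fixed-point
#' verification.
#'
#' @param state a single field state — a list with numeric vectors
#'   \code{u1,u2,v,q1,q2,q3} of length \code{N} — or a list of such states
#'   (one per field).
#' @param params a [field_params()] object.
#' @param conn a [connectivity_spec()]; \code{NULL} means one isolated field.
#' @param stimulus optional matrix (\code{N} x n_fields) of currents added to
#'   \code{I1}.
#' @return derivatives in the same shape as \code{state}.
#' @export
field_rhs <- function(state, params, conn = NULL, stimulus = NULL) {
  single <- !is.null(state$u1)
  fields <- if (single) list(state) else state
  nf <- length(fields)
  if (is.null(conn)) conn <- connectivity_spec(n_fields = nf)
  if (conn$n_fields != nf) stop("connectivity spec is for ", conn$n_fields,
                                " fields, state has ", nf)
  N <- params$N
  for (f in fields) {
    if (!all(lengths(f[c("u1", "u2", "v", "q1", "q2", "q3")]) == N))
      stop("state arrays must all have length N = ", N)
    if (!all(vapply(f[c("u1", "u2", "v", "q1", "q2", "q3")],
                    function(a) all(is.finite(a)), TRUE)))
      stop("non-finite state")
  }
  x <- field_grid(params)
  u0 <- u0_profile(params)
  dxg <- params$L / params$N
  khat <- kernel_fft("laplacian", N, params$L)
  cfft <- function(s) Re(stats::fft(stats::fft(s) * khat, inverse = TRUE)) / N

  # heterogeneous drive: Gaussian-weighted sampling at the source center,
  # Gaussian-shaped injection at the target center
  hdrive <- matrix(0, N, nf)
  for (h in conn$het) {
    wsrc <- kernel_values("gaussian_het", wrap_dist(x - h$source_center, params$L)) * dxg
    wtgt <- kernel_values("gaussian_het", wrap_dist(x - h$target_center, params$L))
    act <- sum(wsrc * heaviside(fields[[h$source_field]]$u1, params$theta_het))
    hdrive[, h$target_field] <- hdrive[, h$target_field] + h$gamma * act * wtgt
  }

  out <- vector("list", nf)
  for (fi in seq_len(nf)) {
    s <- fields[[fi]]
    stim <- if (is.null(stimulus)) 0 else stimulus[, fi]
    c11 <- cfft(heaviside(s$u1, params$theta11))
    c22 <- cfft(heaviside(s$q1, params$theta22))
    c12 <- cfft(heaviside(s$u1, params$theta12))
    out[[fi]] <- list(
      u1 = s$u2 - f1(s$u1, s$q1, s$v) - s$v + params$I1 + stim +
        params$gamma11 * c11 + hdrive[, fi],
      u2 = 1 - 5 * s$u1^2 - s$u2,
      v  = (4 * (s$u1 - u0) - s$v) / params$tau0,
      q1 = -s$q2 + s$q1 - s$q1^3 + params$I2 + 2 * s$q3 -
        0.3 * (s$v - 3.5) + params$gamma22 * c22,
      q2 = (-s$q2 + f2(s$q1)) / params$tau2,
      q3 = -s$q3 / params$tau12 +
        0.001 * (params$a12 * s$u1 + params$gamma12 * c12))
  }
  if (single) out[[1]] else out
}

# shortest signed offset on the periodic domain
wrap_dist <- function(d, L) {
  ((d + L / 2) %% L) - L / 2
}

#' Slow-drive diagnostic K
#'
#' The lumped constant \eqn{K = 2 q_3 - 0.3 (v - 3.5)} combining the slow
#' drive of the fast population on the spike-wave population with the
#' permittivity variable.  Under time-scale averaging, K parameterises the
#' spike-wave oscillator: its maximum over space at a given time predicts the
#' source of the next spike-and-wave discharge.
#'
#' @param q3,v state arrays (any matching shape), or a single field state
#'   list passed as \code{q3} with \code{v} missing.
#' @return K with the shape of the inputs.
#' @export
k_field <- function(q3, v) {
  if (missing(v) && is.list(q3)) { v <- q3$v; q3 <- q3$q3 }
  2 * q3 - 0.3 * (v - 3.5)
}

# value of the reduced interictal cubic h(u1) = -u1^3 - 2 u1^2 + 4.1
interictal_cubic <- function(u1) -u1^3 - 2 * u1^2 + 4.1

#' Critical excitability for autonomous seizures
#'
#' The knee of the interictal branch: the full-system equilibrium satisfies
#' \eqn{h(u_1) = 4 (u_1 - u_0)} with \eqn{h(u_1) = -u_1^3 - 2u_1^2 + 4.1},
#' and loses stability through a saddle-node when the root reaches the local
#' minimum of \eqn{h} at \eqn{u_1 = -4/3}.  Solving at the knee gives
#' \deqn{u_{0c} = -4/3 - h(-4/3)/4 \approx -2.0620.}
#' For \eqn{u_0 > u_{0c}} the Epileptor has no interictal equilibrium and
#' transitions into seizures autonomously (epileptogenic site).
#'
#' @return the critical excitability (a.u.).
#' @export
epileptogenic_threshold <- function() {
  -4 / 3 - interictal_cubic(-4 / 3) / 4
}

#' Interictal equilibrium of the space-clamped Epileptor
#'
#' Full 6-variable fixed point (u1, u2, v, q1, q2, q3) of a single site under
#' zero spatial coupling.  Exists only for \code{u0} below
#' [epileptogenic_threshold()]; above it the site is epileptogenic and the
#' function signals an error.
#'
#' @param u0 excitability of the site (a.u.).
#' @param params a [field_params()] object (only the scalar constants are
#'   used).
#' @return named numeric vector \code{c(u1, u2, v, q1, q2, q3)}.
#' @export
interictal_fixed_point <- function(u0, params = field_params()) {
  if (u0 > epileptogenic_threshold())
    stop("epileptogenic: no interictal equilibrium (u0 = ", u0,
         " above critical excitability ", signif(epileptogenic_threshold(), 6), ")")
  # unique real root of -u1^3 - 2u1^2 - 4u1 + 4.1 + 4 u0 = 0 (monotone)
  g <- function(u1) interictal_cubic(u1) - 4 * (u1 - u0)
  u1 <- stats::uniroot(g, c(-10, 10), tol = 1e-14)$root
  u2 <- 1 - 5 * u1^2
  v <- 4 * (u1 - u0)
  q3 <- 0.001 * params$tau12 * params$a12 * u1
  # left-branch root (q1 < -0.25, hence q2* = f2 = 0) of q1 - q1^3 + C = 0
  C <- params$I2 + 2 * q3 - 0.3 * (v - 3.5)
  r <- polyroot(c(C, 1, 0, -1))          # C + q - q^3 = 0
  r <- sort(Re(r[abs(Im(r)) < 1e-8]))
  r <- r[r < -0.25]
  if (length(r) == 0)
    stop("epileptogenic: no interictal equilibrium of the spike-wave ",
         "subsystem (left-branch root absent)")
  q1 <- r[1]
  c(u1 = u1, u2 = u2, v = v, q1 = q1, q2 = 0, q3 = q3)
}
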