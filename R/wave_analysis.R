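#' Right-hand side of the co-moving-frame equations
#'
#' The traveling-wave equations of the ictal wavefront in the frame
#' coordinate \eqn{\xi = x + c_1 t}, after averaging the slow permittivity to
#' a constant \eqn{\bar V}.  The \code{"full"} variant keeps both fast
#' variables and is the 5-dimensional first-order system
#' \eqn{(U_1, E_1, H_1, U_2, E_2)} with \eqn{E_1 = U_1'}, \eqn{H_1 = U_1''},
#' \eqn{E_2 = U_2'}; the \code{"reduced"} variant averages out the fast
#' oscillation (\eqn{\dot u_2 = 0}) leaving the 3-dimensional system
#' \eqn{(U_1, E_1, H_1)}.
#'
#' @param state numeric state vector (length 5 for full, 3 for reduced).
#' @param c1 frame speed (a.u. space/time, nonzero).
#' @param Vbar frozen permittivity (a.u.).
#' @param gamma11,theta11 local coupling strength and firing threshold of the
#'   fast population.
#' @param variant \code{"full"} or \code{"reduced"}.
#' @param I1 drive current (a.u.).
#' @return derivative of \code{state} with respect to \eqn{\xi}.
#' @export
traveling_frame_rhs <- function(state, c1, Vbar, gamma11 = 1, theta11 = -1,
                                variant = c("full", "reduced"), I1 = 3.1) {
  variant <- match.arg(variant)
  if (c1 == 0) stop("frame speed c1 must be nonzero")
  U1 <- state[1]; E1 <- state[2]; H1 <- state[3]
  S <- heaviside(U1, theta11)
  if (variant == "full") {
    U2 <- state[4]; E2 <- state[5]
    c(E1, H1,
      -(1 / c1) * (U1 * H1 * (3 * U1 - 6) +
                   E1 * (6 * E1 * (U1 - 1) - c1 + 10 * U1 / c1) +
                   U2 + E2 / c1 - U1^3 + 3 * U1^2 + I1 - Vbar +
                   gamma11 * S),
      E2,
      (1 / c1) * (-10 * E1 * U1 - E2))
  } else {
    c(E1, H1,
      -(1 / c1) * (U1 * H1 * (3 * U1 + 4) +
                   E1 * (E1 * (6 * U1 + 4) - c1) -
                   U1^3 - 2 * U1^2 + 4.1 - Vbar + gamma11 * S))
  }
}

# rest (interictal) value of U1 for the frozen-permittivity fast subsystem:
# left-branch root of -u^3 - 2u^2 + 4.1 - Vbar + gamma11 S(u, theta11) = 0,
# with the Heaviside branch chosen self-consistently
frozen_rest_u1 <- function(Vbar, gamma11, theta11) {
  for (S in c(0, 1)) {
    g <- function(u) -u^3 - 2 * u^2 + 4.1 - Vbar + gamma11 * S
    if (g(-4 / 3) > 0) next                      # no left-branch crossing
    r <- tryCatch(stats::uniroot(g, c(-6, -4 / 3), tol = 1e-13)$root,
                  error = function(e) NULL)
    if (!is.null(r) && heaviside(r, theta11) == S) return(r)
  }
  stop("no interictal rest state for Vbar = ", Vbar)
}

# upper (ictal) U1 of the frozen fast subsystem: right-branch root with the
# self-consistent Heaviside branch
frozen_upper_u1 <- function(Vbar, gamma11, theta11) {
  for (S in c(1, 0)) {
    g <- function(u) -u^3 - 2 * u^2 + 4.1 - Vbar + gamma11 * S
    r <- tryCatch(stats::uniroot(g, c(0, 6), tol = 1e-13)$root,
                  error = function(e) NULL)
    if (!is.null(r) && heaviside(r, theta11) == S) return(r)
  }
  stop("no upper state for Vbar = ", Vbar)
}

# fixed point of the frame system (derivatives zero)
frame_fixed_point <- function(Vbar, gamma11, theta11, variant = "full") {
  u1 <- frozen_rest_u1(Vbar, gamma11, theta11)
  if (variant == "full") c(u1, 0, 0, 1 - 5 * u1^2, 0) else c(u1, 0, 0)
}

# ictal attractor of the space-clamped frozen-permittivity fast subsystem:
# for the full variant, the stable limit cycle as a polyline in (u1, u2)
# (long RK2 integration, transient discarded); for the reduced variant, the
# upper fixed point
fast_attractor <- function(Vbar, gamma11, theta11, variant = "full",
                           dt = 0.002, horizon = 400) {
  if (variant == "reduced")
    return(frozen_upper_u1(Vbar, gamma11, theta11))
  u1 <- frozen_upper_u1(Vbar, gamma11, theta11)
  u2 <- 1 - 5 * u1^2
  u1 <- u1 + 0.2                      # start off the focus
  n <- round(horizon / dt)
  keep <- matrix(NA_real_, floor(n / 20), 2)
  ki <- 0
  rhs <- function(u1, u2) {
    S <- heaviside(u1, theta11)
    c(u2 - u1^3 + 3 * u1^2 + 3.1 - Vbar + gamma11 * S,
      1 - 5 * u1^2 - u2)
  }
  for (i in seq_len(n)) {
    k1 <- rhs(u1, u2)
    k2 <- rhs(u1 + dt / 2 * k1[1], u2 + dt / 2 * k1[2])
    u1 <- u1 + dt * k2[1]; u2 <- u2 + dt * k2[2]
    if (i > 0.75 * n && i %% 20 == 0) {
      ki <- ki + 1
      keep[ki, ] <- c(u1, u2)
    }
  }
  keep[seq_len(ki), , drop = FALSE]
}

# launch the frame trajectory from the rest fixed point along its (1-D)
# unstable eigendirection and integrate until |U1| escapes; returns the
# escape sign relative to rest, the number of windings around the ictal
# attractor, and the closest terminal approach to the attractor
frame_probe <- function(c1, Vbar, gamma11, theta11, variant, attractor,
                        h = NULL, xi_max = NULL, perturb = 1e-6) {
  fp <- frame_fixed_point(Vbar, gamma11, theta11, variant)
  vn <- if (variant == "full") 1L else 2L
  f <- function(y) traveling_frame_rhs(y, c1, Vbar, gamma11, theta11, variant)
  n <- length(fp)
  J <- matrix(0, n, n)
  for (j in seq_len(n)) {
    e <- replace(numeric(n), j, 1e-6)
    J[, j] <- (f(fp + e) - f(fp - e)) / 2e-6
  }
  ev <- eigen(J)
  iu <- which(Re(ev$values) > 1e-8 & abs(Im(ev$values)) < 1e-8)
  if (length(iu) == 0) stop("no front found: rest state has no real unstable direction")
  vec <- Re(ev$vectors[, iu[which.max(Re(ev$values)[iu])]])
  if (vec[1] < 0) vec <- -vec
  if (is.null(h)) h <- max(1e-7, 2e-4 * c1)
  if (is.null(xi_max)) xi_max <- 15 + 450 * c1
  # integrate until the trajectory actually escapes (the terminal direction
  # of a truncated, still-captured trajectory carries no information)
  repeat {
    nsteps <- min(ceiling(xi_max / h), 5e7)
    r <- integrate_frame_cpp(fp + perturb * vec, c1, Vbar, 3.1, gamma11,
                             theta11, h, nsteps, 10, vn, 2000L)
    if (r$escaped || nsteps >= 5e7 || xi_max >= 500) break
    xi_max <- xi_max * 3
  }
  tr <- r$traj
  U1 <- tr[, 1]
  term <- tr[seq(max(1, floor(0.7 * nrow(tr))), nrow(tr)), , drop = FALSE]
  dist <- if (variant == "full") {
    min(sqrt(outer(term[, 1], attractor[, 1], "-")^2 +
             outer(term[, 4], attractor[, 2], "-")^2))
  } else min(abs(term[, 1] - attractor))
  list(sign = sign(U1[length(U1)] - fp[1]),
       loops = sum(diff(sign(U1 - 0.5)) > 0),
       escaped = r$escaped,
       dist = dist)
}

#' Ictal wavefront speed by the shooting method
#'
#' Locates the speed \eqn{c_1} of the slow traveling wavefront that recruits
#' tissue from the interictal state into the ictal state, by shooting in the
#' co-moving frame: the frame equations are integrated (Euler scheme in
#' \eqn{\xi}) from the interictal fixed point along its unstable
#' eigendirection, and the heteroclinic connection to the ictal attractor is
#' bracketed by the direction in which the trajectory ultimately escapes.
#' The speed axis is scanned for escape-direction sign changes; around the
#' connection the trajectory is captured by the ictal attractor (the frozen
#' fast-subsystem limit cycle for the \code{"full"} variant, the upper fixed
#' point for the \code{"reduced"} averaged variant) and winds around it
#' many times before escaping, so among the sign-change brackets the one
#' with maximal winding is refined by bisection.
#'
#' @param Vbar frozen permittivity (a.u.).
#' @param gamma11,theta11 fast-population coupling strength and threshold.
#' @param variant \code{"full"} (5-variable frame system, LVFA oscillations
#'   present, slow front) or \code{"reduced"} (averaged 3-variable system,
#'   roughly an order of magnitude faster front).
#' @param c1_range speed interval scanned (a.u.).
#' @param n_scan number of log-spaced scan points.
#' @param tol_rel relative bisection tolerance on the speed.
#' @return list with the front speed \code{c1}, the achieved \code{objective}
#'   (terminal distance of the shooting trajectory to the attractor), the
#'   bracketing \code{window}, and the scan diagnostics.
#' @export
shoot_front_speed <- function(Vbar = 3.0, gamma11 = 1, theta11 = -1,
                              variant = c("full", "reduced"),
                              c1_range = NULL, n_scan = 25,
                              tol_rel = 2e-3) {
  variant <- match.arg(variant)
  if (gamma11 <= 0) stop("no front found: gamma11 must be positive")
  if (is.null(c1_range))
    c1_range <- if (variant == "full") c(0.004, 0.4) else c(0.05, 4)
  attractor <- fast_attractor(Vbar, gamma11, theta11, variant)
  cs <- exp(seq(log(c1_range[1]), log(c1_range[2]), length.out = n_scan))
  pr <- lapply(cs, function(c1)
    tryCatch(frame_probe(c1, Vbar, gamma11, theta11, variant, attractor),
             error = function(e) NULL))
  ok <- !vapply(pr, is.null, TRUE)
  if (!any(ok)) stop("no front found: all frame probes failed")
  cs <- cs[ok]; pr <- pr[ok]
  sg <- vapply(pr, `[[`, numeric(1), "sign")
  lo <- vapply(pr, `[[`, numeric(1), "loops")
  flips <- which(diff(sg) != 0)
  if (length(flips) == 0)
    stop("no front found: escape direction does not change over the scan range")
  refine <- function(k) {
    a <- cs[k]; b <- cs[k + 1]; sa <- sg[k]
    while ((b - a) / b > tol_rel) {
      m <- sqrt(a * b)
      pm <- frame_probe(m, Vbar, gamma11, theta11, variant, attractor)
      if (pm$sign == sa) a <- m else b <- m
    }
    sqrt(a * b)
  }
  # the connection is captured by the attractor over a window of speeds
  # bounded by the outermost escape-direction flips; the speed estimate is
  # the window midpoint, with the window width as its uncertainty
  lo_edge <- refine(flips[1])
  hi_edge <- if (length(flips) > 1) refine(flips[length(flips)]) else lo_edge
  c1 <- (lo_edge + hi_edge) / 2
  pf <- frame_probe(c1, Vbar, gamma11, theta11, variant, attractor)
  list(c1 = c1, objective = pf$dist, window = c(lo_edge, hi_edge),
       loops = pf$loops, variant = variant,
       scan = data.frame(c1 = cs, sign = sg, loops = lo))
}

#' Speed-up of the ictal wavefront under averaging
#'
#' Ratio of the shooting speed of the reduced (averaged, no fast
#' oscillations) frame system to the full 5-variable frame system at the
#' same parameters.  Fast oscillations on the wavefront intermittently
#' silence the Heaviside coupling and slow recruitment, so the ratio is
#' expected to be about an order of magnitude.
#'
#' @inheritParams shoot_front_speed
#' @return list with \code{ratio} and the two component fits.
#' @export
reduced_vs_full_speed_ratio <- function(Vbar = 3.0, gamma11 = 1,
                                        theta11 = -1) {
  full <- shoot_front_speed(Vbar, gamma11, theta11, variant = "full")
  red <- shoot_front_speed(Vbar, gamma11, theta11, variant = "reduced")
  list(ratio = red$c1 / full$c1, full = full, reduced = red)
}

#' Empirical wavefront speed from a frozen-permittivity field simulation
#'
#' Integrates the frozen-\eqn{v} fast-subsystem field from rest with an
#' ignited central patch and measures the asymptotic front speed from the
#' recruitment-onset map (least-squares fit of onset time against distance).
#' Serves as the direct-simulation cross-check of [shoot_front_speed()].
#'
#' @inheritParams shoot_front_speed
#' @param N,L grid size and field length (a.u.).
#' @param dt integration step (a.u.).
#' @param duration simulated time (a.u.); defaults to the time the front
#'   needs to cross a third of the field at a conservative speed guess.
#' @return list with \code{c1} (a.u.), the fit \code{r2} and the onset map.
#' @export
front_speed_simulation <- function(Vbar = 3.0, gamma11 = 1, theta11 = -1,
                                   variant = c("full", "reduced"),
                                   N = 1024, L = 24 * pi, dt = 0.025,
                                   duration = NULL) {
  variant <- match.arg(variant)
  x <- (seq_len(N) - 1) * L / N
  u1r <- frozen_rest_u1(Vbar, gamma11, theta11)
  u1u <- frozen_upper_u1(Vbar, gamma11, theta11)
  u1_0 <- rep(u1r, N); u2_0 <- 1 - 5 * u1_0^2
  ign <- abs(x - L / 2) < 4
  u1_0[ign] <- u1u; u2_0[ign] <- 1 - 5 * u1u^2
  if (is.null(duration))
    duration <- if (variant == "full") 1500 else 150
  vn <- if (variant == "full") 1L else 2L
  r <- simulate_fast_subsystem_cpp(u1_0, u2_0, Vbar, 3.1, gamma11, theta11,
                                   L, dt, round(duration / dt),
                                   max(1L, round(0.5 / dt)), vn)
  tt <- r$time
  onset <- apply(r$u1, 2, function(col) {
    i <- which(col > theta11)
    if (length(i)) tt[i[1]] else NA_real_
  })
  right <- x > L / 2 + 5 & x < L - 3 & !is.na(onset) & onset > 2 * dt
  if (sum(right) < 5) stop("front did not propagate (", sum(right),
                           " recruited sites)")
  fit <- stats::lm(onset[right] ~ x[right])
  list(c1 = 1 / stats::coef(fit)[[2]], r2 = summary(fit)$r.squared,
       onset = onset, x = x)
}

#' Saddle-node (SNIC) threshold of the spike-wave oscillator
#'
#' The isolated spike-wave population, parameterised by the lumped constant
#' \eqn{K}, rests on the left branch of its cubic nullcline where
#' \eqn{q_2 = 0} and \eqn{f_2 = 0}.  Its fixed points solve
#' \eqn{q_1 - q_1^3 + I_2 + K = 0}; the saddle-node on the invariant circle
#' occurs when the left-branch root collides with the middle root at
#' \eqn{q_1 = -1/\sqrt{3}}, giving analytically
#' \deqn{K_c = q^3 - q - I_2 |_{q = -1/\sqrt 3} = \frac{2}{3\sqrt 3} - I_2.}
#' For \eqn{K > K_c} the rest state is gone and the oscillator chain
#' produces spike-and-wave discharges.
#'
#' @param I2 drive current of the spike-wave population (a.u.).
#' @return the critical value \eqn{K_c} (a.u.).
#' @export
snic_threshold <- function(I2 = 0.45) {
  q <- -1 / sqrt(3)
  q^3 - q - I2
}

#' Transit time of a spike-wave oscillator along the left nullcline branch
#'
#' Time for the isolated relaxation oscillator at constant \eqn{K} to drift
#' from \eqn{q_1 =} \code{q1_start} to the knee of the left branch of its
#' cubic nullcline at \eqn{q_1^c = -1/\sqrt 3}, where the spike fires.
#' Along the branch \eqn{q_2} follows the nullcline and
#' \deqn{T = \int_{q_1^{start}}^{-1/\sqrt 3}
#'   \frac{\tau_2 (1 - 3 q_1^2)}{-q_1 + q_1^3 - I_2 - K}\, dq_1,}
#' evaluated by adaptive quadrature.
#'
#' @param q1_start start coordinate on the left branch
#'   (\eqn{\le -1/\sqrt 3}).
#' @param K lumped slow-drive constant (a.u.), above [snic_threshold()].
#' @param params a [field_params()] object (uses \code{tau2}, \code{I2}).
#' @return transit time (a.u.), nonnegative.
#' @export
swd_transit_time <- function(q1_start, K, params = field_params()) {
  q1c <- -1 / sqrt(3)
  if (q1_start > q1c + 1e-12)
    stop("q1_start must lie on the left branch (q1 <= -1/sqrt(3))")
  if (q1_start == q1c) return(0)
  den <- function(q) -q + q^3 - params$I2 - K
  # the quadrature is singular if the denominator vanishes in range
  qs <- seq(q1_start, q1c, length.out = 512)
  if (any(abs(den(qs)) < 1e-12) || any(diff(sign(den(qs))) != 0))
    stop("singular quadrature: K too close to the SNIC threshold ",
         "(denominator vanishes between q1_start and the knee)")
  f <- function(q) params$tau2 * (1 - 3 * q^2) / den(q)
  stats::integrate(f, q1_start, q1c, rel.tol = 1e-10,
                   abs.tol = 1e-12)$value
}

#' Spike-and-wave discharge propagation speed between two oscillators
#'
#' Under the chain-of-uncoupled-relaxation-oscillators approximation, the
#' discharge reaches each site when that site's oscillator arrives at the
#' knee of its nullcline, so the apparent propagation speed between two
#' neighboring sites with phases \code{q1_i}, \code{q1_j} a distance
#' \code{dx} apart is
#' \deqn{c_2 = \frac{\Delta x}{T(q_1^j) - T(q_1^i)}.}
#' The sign of \eqn{c_2} indicates the direction of apparent motion.
#'
#' @param q1_i,q1_j left-branch phase coordinates of the two oscillators.
#' @param dx site separation (a.u.), positive from i to j.
#' @param K lumped slow-drive constant (a.u.).
#' @param params a [field_params()] object.
#' @return signed speed (a.u. space/time).
#' @export
swd_speed <- function(q1_i, q1_j, dx, K, params = field_params()) {
  if (q1_i == q1_j)
    stop("undefined speed: equal phases give zero phase lag")
  dT <- swd_transit_time(q1_j, K, params) - swd_transit_time(q1_i, K, params)
  dx / dT
}

#' Discharge-to-wavefront speed ratio of a simulated seizure
#'
#' Pools the admissible neighbor phase pairs of the \code{q1} field over
#' recorded snapshots spanning the discharge-active part of a seizure,
#' evaluates the relaxation-oscillator quadrature speed [swd_speed()] at the
#' given \eqn{K} for every pair, and reports the median magnitude together
#' with its ratio to the slow ictal wavefront speed.  Snapshots taken while
#' a discharge is mid-sweep carry staggered phases (apparent speed close to
#' the sweep speed); between discharges and late in the seizure the phases
#' are nearly synchronous and the apparent speed is far higher, so the
#' pooled median is the representative summary.
#'
#' @param sim an \code{"epi_sim"} object containing a seizure.
#' @param K lumped slow-drive constant at which the quadrature is evaluated.
#' @param c1 wavefront speed used in the denominator (e.g. from
#'   [shoot_front_speed()]); when \code{NULL} only the median discharge
#'   speed is returned.
#' @param field 1-based field index.
#' @param t_range time range of snapshots; default: from seizure onset to
#'   offset as detected on \code{u1}.
#' @param min_pairs snapshots with fewer admissible pairs are skipped.
#' @return list with \code{c2_median}, \code{n_pairs}, \code{ratio} (NULL
#'   without \code{c1}).
#' @export
swd_speed_ratio <- function(sim, K = 1.5, c1 = NULL, field = 1,
                            t_range = NULL, min_pairs = 10) {
  tt <- sim$time
  q1 <- sim$fields[[field]]$q1
  if (is.null(t_range)) {
    det <- detect_onset_offset(sim$fields[[field]]$u1, tt)
    t_range <- c(min(det$onset, na.rm = TRUE), max(det$offset, na.rm = TRUE))
  }
  dx <- sim$params$L / sim$params$N
  # transit times evaluated through a dense cumulative-quadrature spline
  # (equals swd_transit_time to ~1e-8; avoids one adaptive quadrature per
  # phase pair)
  q1c <- -1 / sqrt(3)
  margin <- 0.02
  lo <- min(q1, -1.5) - 0.05
  qs <- seq(lo, q1c - margin / 2, length.out = 4001)
  f <- sim$params$tau2 * (1 - 3 * qs^2) /
    (-qs + qs^3 - sim$params$I2 - K)
  mid <- (f[-1] + f[-length(f)]) / 2
  Tcum <- c(rev(cumsum(rev(mid * diff(qs)))), 0)  # integral from qs to knee
  Tcum <- Tcum + swd_transit_time(qs[length(qs)], K, sim$params)
  Tfun <- stats::splinefun(qs, Tcum)
  pool <- c()
  idx <- which(tt >= t_range[1] & tt <= t_range[2])
  for (it in idx) {
    snap <- q1[it, ]
    a <- snap[-length(snap)]; b <- snap[-1]
    adm <- a < q1c - margin & b < q1c - margin & abs(a - b) > 1e-9
    if (sum(adm) >= min_pairs)
      pool <- c(pool, abs(dx / (Tfun(b[adm]) - Tfun(a[adm]))))
  }
  if (!length(pool)) stop("no admissible phase pairs in the time range")
  med <- stats::median(pool)
  list(c2_median = med, n_pairs = length(pool),
       ratio = if (is.null(c1)) NULL else med / c1)
}

#' Spike-and-wave speeds from a field snapshot
#'
#' Extracts neighbor phase pairs from a snapshot of the \code{q1} field
#' (both sites on the left nullcline branch, distinct phases) and evaluates
#' [swd_speed()] at the given \eqn{K} for each admissible pair.
#'
#' @param q1_snapshot numeric vector: \code{q1} across the field at one
#'   recorded time.
#' @param dx grid spacing (a.u.).
#' @param K lumped slow-drive constant (a.u.).
#' @param params a [field_params()] object.
#' @param margin exclusion margin below the knee, keeping the quadrature
#'   well-conditioned.
#' @return data.frame with site index, phases and signed speeds.
#' @export
swd_snapshot_speeds <- function(q1_snapshot, dx, K,
                                params = field_params(), margin = 0.02) {
  q1c <- -1 / sqrt(3)
  n <- length(q1_snapshot)
  i <- seq_len(n - 1)
  a <- q1_snapshot[i]; b <- q1_snapshot[i + 1]
  admissible <- a < q1c - margin & b < q1c - margin & abs(a - b) > 1e-9
  i <- i[admissible]
  if (length(i) == 0)
    return(data.frame(site = integer(), q1_i = numeric(),
                      q1_j = numeric(), c2 = numeric()))
  c2 <- vapply(i, function(k)
    swd_speed(q1_snapshot[k], q1_snapshot[k + 1], dx, K, params),
    numeric(1))
  data.frame(site = i, q1_i = q1_snapshot[i], q1_j = q1_snapshot[i + 1],
             c2 = c2)
}
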