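#' Simulate the Epileptor neural field
#'
#' Integrates the field equations with a fixed-step 4th-order Runge-Kutta
#' scheme; spatial convolutions are evaluated by FFT against the periodic
#' grid.  Zero-mean white Gaussian noise of variance \code{noise_sigma2} is
#' added to \code{q1} and \code{q2} after each deterministic step
#' (Euler-Maruyama convention, increment sd \eqn{\sqrt{\sigma^2 dt}}).
#'
#' The initial condition is the interictal equilibrium of the local
#' excitability at every site; where the local \code{u0} exceeds
#' [epileptogenic_threshold()] (no equilibrium exists) the site is placed at
#' the equilibrium of an excitability clamped just below threshold, from
#' which the slow permittivity drift takes over.
#'
#' @param params a [field_params()] object.
#' @param conn a [connectivity_spec()]; default one isolated field.
#' @param stimuli list of [stimulus_spec()] pulses; the default is the
#'   standard protocol (one pulse of strength 1, width 1.57, at t = 400 for
#'   10 time units, at mid-field).  Use \code{list()} for no stimulation.
#' @param duration total simulated time (a.u.).
#' @param dt integration step (a.u.).
#' @param seed RNG seed; required when \code{noise_sigma2 > 0}.
#' @param record_dt recording interval (a.u.); states are stored every
#'   \code{round(record_dt/dt)} steps.
#' @param init optional initial state: list (per field) of lists with
#'   numeric vectors \code{u1,u2,v,q1,q2,q3}.
#' @param u0_fields optional per-field excitability overrides (list of
#'   scalar / vector / function, one per field); default: every field uses
#'   \code{params$u0}.
#' @param freeze_v if \code{TRUE} the permittivity variable is frozen at its
#'   initial value (used for wavefront-speed measurements).
#' @param init_margin how far below the critical excitability the reference
#'   equilibrium used to seat epileptogenic sites is taken (a.u.).  The
#'   default 0.6 places the permittivity so that the standard t = 400
#'   stimulus ignites a front well before any autonomous transition;
#'   smaller values shorten the autonomous latency.
#' @return An object of class \code{"epi_sim"} with elements \code{time},
#'   \code{x}, \code{fields} (per field, matrices time x space for
#'   \code{u1,u2,v,q1,q2,q3}), and the resolved configuration.
#' @examples
#' \donttest{
#' p <- field_params(u0 = -2.5, N = 64)
#' sim <- simulate_field(p, stimuli = list(), duration = 50)
#' max(abs(sim$fields[[1]]$u1[nrow(sim$fields[[1]]$u1), ] -
#'         sim$fields[[1]]$u1[1, ]))
#' }
#' @export
simulate_field <- function(params, conn = NULL,
                           stimuli = list(stimulus_spec()),
                           duration = 2500, dt = 0.025, seed = NULL,
                           record_dt = 1, init = NULL, u0_fields = NULL,
                           freeze_v = FALSE, init_margin = 0.6) {
  stopifnot(dt > 0, duration > dt)
  if (is.null(conn)) conn <- connectivity_spec(n_fields = 1)
  nf <- conn$n_fields
  N <- params$N
  x <- field_grid(params)
  dx <- params$L / N

  if (params$noise_sigma2 > 0 && is.null(seed))
    stop("seed must be given when noise_sigma2 > 0")
  if (!is.null(seed)) set.seed(seed)

  u0m <- resolve_u0_fields(params, u0_fields, nf)

  stimuli <- lapply(stimuli, function(s) {
    if (is.null(s$center)) s$center <- params$L / 2
    if (s$onset >= duration) stop("stimulus onset beyond simulation duration")
    s
  })

  if (is.null(init)) init <- initial_state(params, u0m, init_margin)
  state0 <- matrix(0, 6, N * nf)
  vars <- c("u1", "u2", "v", "q1", "q2", "q3")
  for (f in seq_len(nf))
    for (k in seq_along(vars))
      state0[k, ((f - 1) * N + 1):(f * N)] <- init[[f]][[vars[k]]]

  het_list <- lapply(conn$het, function(h) {
    list(source_field = h$source_field, target_field = h$target_field,
         gamma = h$gamma,
         wsrc = kernel_values("gaussian_het",
                              wrap_dist(x - h$source_center, params$L)) * dx,
         wtgt = kernel_values("gaussian_het",
                              wrap_dist(x - h$target_center, params$L)))
  })

  nsteps <- round(duration / dt)
  stride <- max(1L, as.integer(round(record_dt / dt)))
  raw <- simulate_field_cpp(unclass(params), u0m, x, params$L,
                            het_list, lapply(stimuli, unclass), state0,
                            dt, nsteps, stride, params$noise_sigma2,
                            freeze_v)
  fields <- lapply(raw$fields, function(f) {
    f <- lapply(f, function(m) { dimnames(m) <- NULL; m }); f
  })
  structure(list(time = as.numeric(raw$time), x = x, fields = fields,
                 params = params, conn = conn, stimuli = stimuli,
                 seed = seed, dt = dt, record_dt = record_dt,
                 freeze_v = freeze_v, u0 = u0m),
            class = "epi_sim")
}

resolve_u0_fields <- function(params, u0_fields, nf) {
  x <- field_grid(params)
  one <- function(u0) {
    out <- if (is.function(u0)) u0(x, params$L)
           else if (length(u0) == 1) rep(u0, params$N) else u0
    stopifnot(length(out) == params$N, all(is.finite(out)))
    out
  }
  if (is.null(u0_fields)) {
    matrix(rep(u0_profile(params), nf), ncol = nf)
  } else {
    stopifnot(length(u0_fields) == nf)
    vapply(u0_fields, one, numeric(params$N))
  }
}

# per-site interictal equilibrium; epileptogenic sites (no equilibrium of
# their own) are seated on the interictal branch at the equilibrium of a
# fixed sub-threshold reference excitability, leaving the slow permittivity
# drift a long run-up before any autonomous transition
initial_state <- function(params, u0m, init_margin = 0.6) {
  thr <- epileptogenic_threshold()
  lapply(seq_len(ncol(u0m)), function(f) {
    u0 <- ifelse(u0m[, f] > thr - 0.05, thr - init_margin, u0m[, f])
    vals <- vapply(unique(u0), function(u)
      interictal_fixed_point(u, params), numeric(6))
    idx <- match(u0, unique(u0))
    s <- lapply(seq_len(6), function(k) vals[k, idx])
    names(s) <- c("u1", "u2", "v", "q1", "q2", "q3")
    s
  })
}

#' @export
print.epi_sim <- function(x, ...) {
  cat("Epileptor field simulation:", length(x$fields), "field(s), N =",
      length(x$x), ", t in [0,", max(x$time), "], recorded",
      length(x$time), "frames\n")
  invisible(x)
}

#' Local-field-potential proxy of a simulated field
#'
#' The LFP proxy of the model is \code{-u1 + q1}, recomputed exactly from the
#' stored state arrays.
#'
#' @param sim an \code{"epi_sim"} object.
#' @param field 1-based field index.
#' @return matrix (time x space).
#' @export
lfp <- function(sim, field = 1) {
  -sim$fields[[field]]$u1 + sim$fields[[field]]$q1
}

#' Additive state noise (Euler-Maruyama convention)
#'
#' Adds independent \eqn{N(0, \sigma^2 dt)} increments to \code{q1} and
#' \code{q2} of a field state; all other variables are untouched.  Uses the
#' current R RNG stream.
#'
#' @param state a field state list with vectors \code{q1}, \code{q2}.
#' @param noise_sigma2 noise variance (a.u.^2).
#' @param dt time step (a.u.).
#' @export
add_noise <- function(state, noise_sigma2, dt) {
  stopifnot(noise_sigma2 >= 0, dt > 0)
  if (noise_sigma2 == 0) return(state)
  sd <- sqrt(noise_sigma2 * dt)
  state$q1 <- state$q1 + stats::rnorm(length(state$q1), 0, sd)
  state$q2 <- state$q2 + stats::rnorm(length(state$q2), 0, sd)
  state
}

#' Simulate the space-clamped (zero-coupling) Epileptor
#'
#' Runs the single Epileptor mass model: the 6-variable site ODE obtained
#' from the field equations with all spatial couplings set to zero.  Used
#' for bifurcation scans (e.g. locating the critical excitability) and as
#' the uniform-field reference.
#'
#' @param u0 site excitability (a.u.).
#' @param params a [field_params()] object supplying the remaining constants.
#' @param duration,dt,record_dt integration settings (a.u.).
#' @param init optional named 6-vector initial state; default: interictal
#'   equilibrium (clamped below threshold when \code{u0} is epileptogenic).
#' @return list with \code{time} and a matrix \code{state} (time x 6,
#'   columns \code{u1,u2,v,q1,q2,q3}).
#' @export
simulate_mass_model <- function(u0, params = field_params(),
                                duration = 4 * params$tau0, dt = 0.05,
                                record_dt = 1, init = NULL) {
  p <- unclass(params)
  p$gamma11 <- 0; p$gamma22 <- 0; p$gamma12 <- 0
  p$N <- 8L; p$u0 <- u0; p$noise_sigma2 <- 0
  Nn <- p$N
  x <- (seq_len(Nn) - 1) * p$L / Nn
  if (is.null(init)) {
    thr <- epileptogenic_threshold()
    init <- interictal_fixed_point(min(u0, thr - 0.05), params)
  }
  state0 <- matrix(rep(init, each = Nn), 6, Nn, byrow = TRUE)
  nsteps <- round(duration / dt)
  stride <- max(1L, as.integer(round(record_dt / dt)))
  raw <- simulate_field_cpp(p, matrix(u0, Nn, 1), x, p$L,
                            list(), list(), state0, dt, nsteps, stride, 0,
                            FALSE)
  st <- vapply(raw$fields[[1]], function(m) m[, 1], numeric(length(raw$time)))
  colnames(st) <- c("u1", "u2", "v", "q1", "q2", "q3")
  list(time = as.numeric(raw$time), state = st)
}

#' Locate the autonomous-seizure excitability boundary by bisection
#'
#' Bisects the excitability \code{u0} on the space-clamped Epileptor between
#' a value that stays at equilibrium and one that seizes autonomously.  At
#' each candidate the 6-variable site ODE is integrated from its (clamped)
#' interictal equilibrium over \code{horizon} time units and sustained
#' oscillation is detected from the range of \code{u1} over the final
#' quarter of the run.
#'
#' @param lower,upper bracketing excitabilities (a.u.).
#' @param params a [field_params()] object.
#' @param horizon integration horizon (a.u.); default four permittivity time
#'   constants.
#' @param tol bisection tolerance on \code{u0}.
#' @param dt integration step (a.u.).
#' @return list with the located \code{boundary}, the analytic knee value
#'   \code{knee}, and the bisection history.
#' @export
autonomy_threshold_bisect <- function(lower = -3, upper = -1,
                                      params = field_params(),
                                      horizon = 4 * params$tau0,
                                      tol = 0.01, dt = 0.05) {
  oscillates <- function(u0) {
    run <- simulate_mass_model(u0, params, duration = horizon, dt = dt,
                               record_dt = 2)
    tail_idx <- run$time >= 0.75 * horizon
    diff(range(run$state[tail_idx, "u1"])) > 0.5
  }
  if (oscillates(lower) || !oscillates(upper))
    stop("bracket does not straddle the autonomy boundary")
  hist <- list()
  lo <- lower; hi <- upper
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    osc <- oscillates(mid)
    hist[[length(hist) + 1]] <- c(u0 = mid, oscillates = osc)
    if (osc) hi <- mid else lo <- mid
  }
  list(boundary = (lo + hi) / 2, knee = epileptogenic_threshold(),
       history = do.call(rbind, hist))
}
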