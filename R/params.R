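#' Model parameters for the Epileptor neural field
#'
#' Collects every constant of the Epileptor field equations together with the
#' spatial excitability profile \code{u0} and the discretisation of the
#' periodic domain.  Defaults are the canonical published values of the
#' Epileptor field model; the time unit is the arbitrary unit (a.u.) of the
#' model throughout, with no mapping to seconds or millimetres.
#'
#' @param I1,I2 constant drive currents of the fast and spike-wave
#'   populations (a.u.).
#' @param tau0 time constant of the slow permittivity variable \code{v}
#'   (a.u.; the slowest scale of the model).
#' @param tau2 time constant of \code{q2} (a.u.).
#' @param tau12 time constant of the temporal convolution \code{g(u1)}
#'   (a.u.; equals 1/0.01).
#' @param theta11,theta22,theta12,theta_het firing thresholds of the
#'   Heaviside rate function for the four coupling terms (a.u.).
#' @param a12 direct-drive gain of \code{u1} inside the temporal
#'   convolution \code{g} (dimensionless).
#' @param gamma11,gamma22,gamma12 homogeneous coupling strengths
#'   (dimensionless).
#' @param u0 excitability: a scalar (uniform field), a numeric vector of
#'   length \code{N}, or a function of position \code{x}.  Sites with
#'   \code{u0} above [epileptogenic_threshold()] can seize autonomously.
#'   The default is a uniform epileptogenic field at -1.8; see
#'   [u0_profile_epileptogenic()] for a profile with low-excitability
#'   boundary guards.
#' @param noise_sigma2 variance of the additive white Gaussian noise applied
#'   to \code{q1} and \code{q2} (a.u.^2); 0 disables noise.
#' @param L field length (a.u.).
#' @param N number of grid points (>= 64).
#' @return An object of class \code{"field_params"} (a validated list).
#' @examples
#' p <- field_params()
#' p$tau0
#' @export
field_params <- function(I1 = 3.1, I2 = 0.45, tau0 = 2857, tau2 = 10,
                         tau12 = 100, theta11 = -1, theta22 = -0.5,
                         theta12 = -1, theta_het = -1, a12 = 3,
                         gamma11 = 1, gamma22 = 1, gamma12 = 10,
                         u0 = -1.8,
                         noise_sigma2 = 0, L = 6 * pi, N = 256) {
  p <- list(I1 = I1, I2 = I2, tau0 = tau0, tau2 = tau2, tau12 = tau12,
            theta11 = theta11, theta22 = theta22, theta12 = theta12,
            theta_het = theta_het, a12 = a12, gamma11 = gamma11,
            gamma22 = gamma22, gamma12 = gamma12, u0 = u0,
            noise_sigma2 = noise_sigma2, L = L, N = as.integer(N))
  validate_field_params(p)
  class(p) <- "field_params"
  p
}

validate_field_params <- function(p) {
  stopifnot(p$L > 0, p$N >= 64, p$noise_sigma2 >= 0)
  if (!(p$tau0 > p$tau12 && p$tau12 > p$tau2 && p$tau2 > 1))
    stop("time-scale separation violated: need tau0 > tau12 > tau2 > 1")
  num <- c("I1", "I2", "tau0", "tau2", "tau12", "theta11", "theta22",
           "theta12", "theta_het", "a12", "gamma11", "gamma22", "gamma12",
           "noise_sigma2", "L")
  for (f in num)
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1 || !is.finite(p[[f]]))
      stop("parameter '", f, "' must be a finite scalar")
  invisible(p)
}

#' @export
print.field_params <- function(x, ...) {
  cat("Epileptor field parameters: N =", x$N, ", L =", format(x$L), "\n")
  cat("  I1 =", x$I1, " I2 =", x$I2, " tau0 =", x$tau0,
      " tau2 =", x$tau2, " tau12 =", x$tau12, "\n")
  cat("  gamma11 =", x$gamma11, " gamma22 =", x$gamma22,
      " gamma12 =", x$gamma12, " noise_sigma2 =", x$noise_sigma2, "\n")
  invisible(x)
}

#' Spatial grid of the periodic field
#'
#' @param params a [field_params()] object (or anything with `N`, `L`).
#' @return numeric vector of the \code{N} site positions in \code{[0, L)}.
#' @export
field_grid <- function(params) {
  (seq_len(params$N) - 1) * params$L / params$N
}

#' Resolve the excitability profile to one value per grid point
#'
#' @param params a [field_params()] object.
#' @return numeric vector of length \code{N}.
#' @export
u0_profile <- function(params) {
  u0 <- params$u0
  x <- field_grid(params)
  out <- if (is.function(u0)) u0(x, params$L)
         else if (length(u0) == 1) rep(u0, params$N)
         else u0
  if (length(out) != params$N || !all(is.finite(out)))
    stop("u0 profile must resolve to ", params$N, " finite values")
  out
}

#' Tapered epileptogenic excitability profile
#'
#' Constant epileptogenic excitability in the interior of the field with a
#' smooth (raised-cosine) taper down to a low-excitability value over the
#' outermost fraction of the domain on each side.  The taper emulates brain
#' regions of low excitability near the field boundaries, which confine the
#' seizure and act as an absorbing guard for the periodic grid.  Note that
#' taper sites recruited by the wavefront carry a faster permittivity drift
#' and terminate earlier than the interior, so this profile produces a
#' graded, not synchronous, offset map; the uniform default is used when
#' studying termination synchrony.
#'
#' @param x positions (a.u.).
#' @param L field length (a.u.).
#' @param interior excitability of the interior (default -1.8, epileptogenic).
#' @param edge excitability at the boundaries (default -2.5, healthy).
#' @param frac fraction of the domain tapered on each side (default 0.1).
#' @return numeric vector of excitabilities, one per position.
#' @export
u0_profile_epileptogenic <- function(x, L, interior = -1.8, edge = -2.5,
                                     frac = 0.1) {
  w <- frac * L
  d <- pmin(x, L - x)                 # distance to nearest boundary
  ramp <- ifelse(d >= w, 1, 0.5 * (1 - cos(pi * d / w)))
  edge + (interior - edge) * ramp
}

#' Connectivity specification
#'
#' Describes the spatial couplings of one or more Epileptor fields: the
#' homogeneous (translation-invariant) kernel used for the three local
#' coupling terms, and a list of long-range heterogeneous connections, each
#' linking a Gaussian-sampled source location in one field to a
#' Gaussian-shaped injection site in another.
#'
#' @param n_fields number of coupled fields (>= 1).
#' @param kernel homogeneous kernel identifier; only \code{"laplacian"}
#'   (\eqn{e^{-|x|}/2}) is defined.
#' @param het list of heterogeneous connections; each element is a list with
#'   fields \code{source_field}, \code{source_center}, \code{target_field},
#'   \code{target_center}, \code{gamma} (default 0.3).  Use
#'   [het_connection()] to build elements.
#' @return An object of class \code{"connectivity_spec"}.
#' @export
connectivity_spec <- function(n_fields = 1, kernel = "laplacian",
                              het = list()) {
  stopifnot(n_fields >= 1, identical(kernel, "laplacian"))
  het <- lapply(het, function(h) {
    stopifnot(is.list(h),
              all(c("source_field", "source_center", "target_field",
                    "target_center", "gamma") %in% names(h)))
    if (h$source_field > n_fields || h$target_field > n_fields)
      stop("heterogeneous connection references a field beyond n_fields")
    h
  })
  structure(list(n_fields = as.integer(n_fields), kernel = kernel, het = het),
            class = "connectivity_spec")
}

#' Build one heterogeneous (long-range) connection
#'
#' @param source_field,target_field 1-based field indices.
#' @param source_center,target_center positions (a.u.) of the Gaussian
#'   sampling/injection centers.
#' @param gamma coupling strength (default 0.3).
#' @export
het_connection <- function(source_field, source_center,
                           target_field, target_center, gamma = 0.3) {
  list(source_field = as.integer(source_field),
       source_center = source_center,
       target_field = as.integer(target_field),
       target_center = target_center,
       gamma = gamma)
}

#' Stimulation pulse specification
#'
#' A boxcar current pulse added to the drive \code{I1} of one field: constant
#' amplitude within a spatial window of the given width centered at
#' \code{center}, between \code{onset} and \code{onset + duration}.
#' Defaults are the published stimulation protocol (strength 1, spatial
#' width 1.57, onset t = 400, duration 10).
#'
#' @param field 1-based index of the stimulated field.
#' @param amplitude pulse strength added to \code{I1} (a.u.).
#' @param width spatial width of the boxcar (a.u.).
#' @param center center position (a.u.); default mid-field placement is
#'   resolved by [simulate_field()] when \code{NULL}.
#' @param onset,duration pulse timing (a.u.).
#' @export
stimulus_spec <- function(field = 1, amplitude = 1, width = 1.57,
                          center = NULL, onset = 400, duration = 10) {
  stopifnot(amplitude > 0, width > 0, duration > 0, onset >= 0)
  structure(list(field = as.integer(field), amplitude = amplitude,
                 width = width, center = center, onset = onset,
                 duration = duration),
            class = "stimulus_spec")
}
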