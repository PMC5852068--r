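#' Specification of a surrogate intracranial recording
#'
#' Parameters of the synthetic multichannel generator used to exercise the
#' termination-analysis path without running the field simulator: channels
#' are organised in clusters that stop seizing at given offset times; within
#' a cluster every channel mixes a shared band-limited oscillation (weight
#' \code{w}, controlling within-cluster correlation) with an independent
#' band-limited component and broadband noise.
#'
#' @param channels_per_cluster integer vector, one entry per cluster.
#' @param offsets cluster seizure-offset times (seconds), nonnegative.
#' @param band oscillation band (Hz), default 1-10 (spike-wave range).
#' @param w shared-component weight in [0, 1].
#' @param noise_level broadband noise SD relative to unit signal power.
#' @param fs sampling rate (Hz).
#' @param duration recording length (seconds); default covers the last
#'   offset plus 10 s.
#' @param seed RNG seed.
#' @export
surrogate_spec <- function(channels_per_cluster = c(8, 8),
                           offsets = c(30, 70), band = c(1, 10),
                           w = 0.8, noise_level = 0.1, fs = 256,
                           duration = NULL, seed = 1) {
  stopifnot(length(channels_per_cluster) == length(offsets),
            all(offsets >= 0), w >= 0, w <= 1, noise_level >= 0, fs > 0)
  if (is.null(duration)) duration <- max(offsets) + 10
  structure(list(channels_per_cluster = as.integer(channels_per_cluster),
                 offsets = offsets, band = band, w = w,
                 noise_level = noise_level, fs = fs, duration = duration,
                 seed = seed),
            class = "surrogate_spec")
}

#' Generate a surrogate multichannel recording
#'
#' Band-limited oscillatory channels with cluster-structured seizure offset
#' times: each cluster shares a common component with weight \code{w}
#' (within-cluster pre-offset correlation approaches \code{w^2 /
#' (w^2 + (1-w)^2 + noise)}), and every channel is silenced (smooth 0.5-s
#' taper) after its cluster's offset.  Ground truth is returned for testing
#' the analysis pipeline.
#'
#' @param spec a [surrogate_spec()].
#' @return list with \code{signals} (time x channels), \code{times},
#'   \code{fs}, and ground truth \code{offsets}, \code{cluster} (per
#'   channel), \code{spec}.
#' @export
make_surrogate_seeg <- function(spec = surrogate_spec()) {
  set.seed(spec$seed)
  n <- round(spec$duration * spec$fs)
  times <- (seq_len(n) - 1) / spec$fs
  nch <- sum(spec$channels_per_cluster)
  bandlim <- function() {
    # white noise filtered into the band, unit variance
    z <- bandpass_zero_phase(stats::rnorm(n), spec$fs,
                             spec$band[1], spec$band[2])
    z / stats::sd(z)
  }
  signals <- matrix(0, n, nch)
  cluster <- integer(nch)
  offsets <- numeric(nch)
  ch <- 0
  for (k in seq_along(spec$channels_per_cluster)) {
    shared <- bandlim()
    taper <- silence_after(times, spec$offsets[k], spec$fs)
    for (c in seq_len(spec$channels_per_cluster[k])) {
      ch <- ch + 1
      cluster[ch] <- k
      offsets[ch] <- spec$offsets[k]
      sig <- spec$w * shared + (1 - spec$w) * bandlim()
      signals[, ch] <- sig * taper + spec$noise_level * stats::rnorm(n)
    }
  }
  list(signals = signals, times = times, fs = spec$fs, offsets = offsets,
       cluster = cluster, spec = spec)
}

# smooth silencing after the offset time (0.5 s cosine taper)
silence_after <- function(times, offset, fs, ramp = 0.5) {
  ifelse(times <= offset, 1,
         ifelse(times >= offset + ramp, 0,
                0.5 * (1 + cos(pi * (times - offset) / ramp))))
}
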