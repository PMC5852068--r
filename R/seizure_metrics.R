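#' Per-channel seizure onset and offset detection
#'
#' Thresholds a detection statistic (the \code{u1} field for simulations, a
#' band-power envelope for recordings) and returns, per channel, the first
#' and last time the statistic is sustained above threshold.  Suprathreshold
#' runs separated by gaps shorter than \code{merge_gap} are merged into one
#' episode, so a seizure whose tail consists of intermittent spike-and-wave
#' discharges keeps the last discharge as its offset; episodes shorter than
#' \code{debounce} are discarded as transients.
#'
#' @param signals numeric matrix, time by channels.
#' @param times time stamps (a.u. or seconds), uniformly sampled.
#' @param threshold detection threshold (default 0, the \code{u1} ictal
#'   crossing).
#' @param debounce minimal episode duration (default 5 time units).
#' @param merge_gap maximal silent gap bridged within one episode (default
#'   30 time units, several discharge cycles).
#' @param episode which suprathreshold episode to report when a recording
#'   contains recurrent seizures: \code{"first"} (default, the analysed
#'   seizure) or \code{"last"}.
#' @return data.frame with one row per channel: \code{onset}, \code{offset}
#'   (NA when the channel never exceeds threshold) and \code{n_episodes}.
#' @export
detect_onset_offset <- function(signals, times, threshold = 0,
                                debounce = 5, merge_gap = 30,
                                episode = c("first", "last")) {
  episode <- match.arg(episode)
  signals <- as.matrix(signals)
  stopifnot(nrow(signals) == length(times))
  out <- lapply(seq_len(ncol(signals)), function(j) {
    ep <- signal_episodes(signals[, j], times, threshold, debounce, merge_gap)
    if (is.null(ep)) data.frame(channel = j, onset = NA_real_,
                                offset = NA_real_, n_episodes = 0L)
    else {
      k <- if (episode == "first") 1 else nrow(ep)
      data.frame(channel = j, onset = ep[k, "on"],
                 offset = ep[k, "off"], n_episodes = nrow(ep))
    }
  })
  do.call(rbind, out)
}

# suprathreshold episodes of one channel: matrix with columns on, off
signal_episodes <- function(x, times, threshold, debounce, merge_gap) {
  above <- which(x > threshold)
  if (!length(above)) return(NULL)
  t <- times[above]
  br <- which(diff(t) > merge_gap)
  on <- t[c(1, br + 1)]
  off <- t[c(br, length(t))]
  keep <- off - on >= debounce
  if (!any(keep)) return(NULL)
  cbind(on = on[keep], off = off[keep])
}

#' Zero-phase Butterworth band-pass filter
#'
#' Fifth-order forward-backward (zero-phase) Butterworth band-pass, the
#' standard pre-processing for extracting spike-and-wave activity from
#' intracranial recordings.
#'
#' @param x numeric vector or time-by-channels matrix.
#' @param fs sampling rate (samples per time unit).
#' @param low,high band edges (same frequency unit as \code{fs}).
#' @param order filter order (per pass).
#' @return filtered signal, same shape as \code{x}.
#' @export
bandpass_zero_phase <- function(x, fs, low = 1, high = 10, order = 5) {
  if (!(low > 0 && high > low && fs > 2 * high))
    stop("invalid band: need 0 < low < high < fs/2")
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  if (is.matrix(x)) apply(x, 2, function(col) signal::filtfilt(bf, col))
  else signal::filtfilt(bf, x)
}

#' Pairwise termination delays and pre-offset correlations
#'
#' For every admissible channel pair, the absolute difference of seizure
#' offset times and the Pearson correlation of the two signals over a
#' shared window ending at the earlier of the two offsets.  When electrode
#' labels are available, same-electrode pairs are excluded (contacts on one
#' shaft oversample one locus).
#'
#' @param signals numeric matrix, time by channels (already filtered as
#'   desired).
#' @param times time stamps.
#' @param offsets per-channel offset times (e.g. from
#'   [detect_onset_offset()]); NA channels are skipped.
#' @param window window length before the earlier offset.
#' @param electrodes optional per-channel electrode labels.
#' @return data.frame with rows \code{chan_i, chan_j, delay, correlation};
#'   pairs whose window would start before the recording begins are skipped
#'   and counted in \code{attr(, "n_skipped")}.
#' @export
pairwise_termination_metrics <- function(signals, times, offsets,
                                         window = 50, electrodes = NULL) {
  signals <- as.matrix(signals)
  nc <- ncol(signals)
  stopifnot(length(offsets) == nc, nrow(signals) == length(times))
  skipped <- 0L
  rows <- list()
  for (i in seq_len(nc - 1)) {
    for (j in seq((i + 1), nc)) {
      if (is.na(offsets[i]) || is.na(offsets[j])) next
      if (!is.null(electrodes) && electrodes[i] == electrodes[j]) next
      t_end <- min(offsets[i], offsets[j])
      if (t_end - window < times[1]) { skipped <- skipped + 1L; next }
      w <- times >= t_end - window & times <= t_end
      rows[[length(rows) + 1]] <- data.frame(
        chan_i = i, chan_j = j,
        delay = abs(offsets[i] - offsets[j]),
        correlation = stats::cor(signals[w, i], signals[w, j]))
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(chan_i = integer(), chan_j = integer(),
                         delay = numeric(), correlation = numeric())
  if (skipped) warning(skipped, " pair(s) skipped: window precedes recording start")
  attr(out, "n_skipped") <- skipped
  out
}

#' One-dimensional mean-shift clustering
#'
#' Flat-kernel mean-shift on scalar values (termination delays): every point
#' iterates to the mean of its bandwidth neighborhood until convergence;
#' converged modes within one bandwidth of a stronger mode are merged and
#' points are labelled by their nearest surviving mode.  Deterministic for
#' fixed input.
#'
#' @param x numeric values.
#' @param bandwidth kernel radius; default Silverman's rule of thumb on
#'   \code{x}.
#' @return list with integer \code{labels} (1 = cluster with the smallest
#'   mode), \code{modes}, and the \code{bandwidth} used.
#' @export
mean_shift_1d <- function(x, bandwidth = NULL) {
  stopifnot(length(x) >= 1, all(is.finite(x)))
  if (is.null(bandwidth)) {
    s <- min(stats::sd(x), stats::IQR(x) / 1.34)
    if (!is.finite(s) || s == 0) s <- stats::sd(x)
    bandwidth <- 0.9 * s * length(x)^(-1 / 5)
    if (!is.finite(bandwidth) || bandwidth == 0) bandwidth <- 1
  }
  if (bandwidth <= 0) stop("bandwidth must be positive")
  conv <- vapply(x, function(m) {
    for (it in 1:500) {
      m2 <- mean(x[abs(x - m) <= bandwidth])
      if (abs(m2 - m) < 1e-10 * max(bandwidth, 1)) break
      m <- m2
    }
    m2
  }, numeric(1))
  # merge converged modes within the bandwidth, strongest support first
  um <- sort(unique(round(conv / (1e-8 * bandwidth)) * (1e-8 * bandwidth)))
  support <- vapply(um, function(m) sum(abs(x - m) <= bandwidth), numeric(1))
  keep <- numeric(0)
  for (m in um[order(-support)])
    if (!length(keep) || all(abs(m - keep) > bandwidth)) keep <- c(keep, m)
  keep <- sort(keep)
  labels <- vapply(conv, function(m) which.min(abs(m - keep)), integer(1))
  list(labels = labels, modes = keep, bandwidth = bandwidth)
}

#' Empirical wavefront speed from a recruitment-onset map
#'
#' Least-squares estimate of the slow ictal wavefront speed from per-site
#' seizure onset times: on the side of the source with the most recruited
#' sites, onset time is regressed on distance from the source over the
#' central 60% of the recruited span, and the speed is the inverse slope.
#'
#' @param onset per-site onset times (NA = never recruited).
#' @param x site positions (a.u.).
#' @param source source position; default the position of the earliest
#'   onset.
#' @return list with \code{speed} (a.u.), \code{slope}, fit \code{r2} (a
#'   diagnostic for non-monotone onset maps), and \code{n} sites used.
#' @export
empirical_front_speed <- function(onset, x, source = NULL) {
  stopifnot(length(onset) == length(x))
  rec <- is.finite(onset)
  if (is.null(source)) source <- x[rec][which.min(onset[rec])]
  d <- x - source
  side <- if (sum(rec & d > 0) >= sum(rec & d < 0)) rec & d > 0 else rec & d < 0
  if (sum(side) < 5)
    stop("need at least 5 recruited sites on one side of the source")
  dist <- abs(d[side]); ons <- onset[side]
  span <- range(dist)
  core <- dist >= span[1] + 0.2 * diff(span) & dist <= span[1] + 0.8 * diff(span)
  if (sum(core) < 5) core <- rep(TRUE, length(dist))
  fit <- stats::lm(ons[core] ~ dist[core])
  slope <- stats::coef(fit)[[2]]
  r2 <- suppressWarnings(summary(fit)$r.squared)   # exact fits warn
  list(speed = 1 / slope, slope = slope, r2 = r2, n = sum(core))
}

#' Catalog of spike-and-wave discharge events in a simulated field
#'
#' Finds, per site, the local maxima of \code{q1} above threshold (the
#' spike of each discharge), groups peaks across sites into events by
#' temporal adjacency, and summarises each event: participating sites,
#' source site (earliest peak), spatial extent, and a propagation-speed
#' estimate from the regression of peak time on position over the larger
#' side of the source.  The source trajectory across events is classified
#' \code{"stationary"} when the span of source positions is below 10% of
#' the recruited extent, else \code{"moving"}.
#'
#' @param q1 matrix, time by space, of the spike-wave variable.
#' @param times recorded time stamps.
#' @param x site positions.
#' @param threshold peak amplitude threshold (default 0).
#' @param gap temporal gap separating events (default 5 time units, well
#'   below the inter-discharge interval).
#' @return list with \code{events} (data.frame), \code{peaks} (long form),
#'   \code{classification}, and \code{source_positions}.
#' @export
swd_catalog <- function(q1, times, x, threshold = 0, gap = 5) {
  stopifnot(nrow(q1) == length(times), ncol(q1) == length(x))
  dt_rec <- stats::median(diff(times))
  pk <- list()
  for (j in seq_len(ncol(q1))) {
    col <- q1[, j]
    im <- which(diff(sign(diff(col))) == -2) + 1
    im <- im[col[im] > threshold]
    if (length(im)) {
      # parabolic interpolation sharpens peak times below the record stride
      y0 <- col[im - 1]; y1 <- col[im]; y2 <- col[im + 1]
      den <- y0 - 2 * y1 + y2
      frac <- ifelse(abs(den) > 1e-12, 0.5 * (y0 - y2) / den, 0)
      frac <- pmax(-0.5, pmin(0.5, frac))
      pk[[length(pk) + 1]] <- data.frame(time = times[im] + frac * dt_rec,
                                         site = j, xpos = x[j], amp = y1)
    }
  }
  if (!length(pk)) stop("no spike-and-wave events above threshold")
  peaks <- do.call(rbind, pk)
  peaks <- peaks[order(peaks$time), ]
  ev_id <- cumsum(c(1, diff(peaks$time) > gap))
  peaks$event <- ev_id
  events <- do.call(rbind, lapply(split(peaks, peaks$event), function(g) {
    # one (earliest) peak per participating site
    g <- g[order(g$time), ]
    g <- g[!duplicated(g$site), ]
    src <- g$xpos[1]
    speed <- NA_real_
    if (nrow(g) >= 3) {
      d <- g$xpos - src
      side <- if (sum(d > 0) >= sum(d < 0)) d >= 0 else d <= 0
      if (sum(side) >= 3) {
        fit <- stats::lm(g$time[side] ~ abs(d[side]))
        sl <- stats::coef(fit)[[2]]
        if (is.finite(sl) && sl != 0) speed <- 1 / sl
      }
    }
    data.frame(event = g$event[1], t_source = g$time[1], source_x = src,
               source_site = g$site[1], n_sites = nrow(g),
               extent = diff(range(g$xpos)), speed = speed)
  }))
  rownames(events) <- NULL
  recruited_extent <- diff(range(peaks$xpos))
  span <- diff(range(events$source_x))
  classification <- if (nrow(events) < 2 ||
                        span < 0.1 * max(recruited_extent, 1e-12))
    "stationary" else "moving"
  list(events = events, peaks = peaks, classification = classification,
       source_positions = events$source_x,
       recruited_extent = recruited_extent)
}

#' Predict discharge sources from the maximum of the K field
#'
#' The maximum of \eqn{K(x,t) = 2 q_3 - 0.3 (v - 3.5)} across the field
#' just before a discharge predicts the site that fires first.  For every
#' event in a discharge catalog the predicted source (argmax of K at the
#' last recorded time before the event) is compared with the detected
#' source; agreement means the two positions lie within \code{tol_frac} of
#' the recruited extent.
#'
#' @param sim an \code{"epi_sim"} object with recorded \code{q3} and
#'   \code{v}.
#' @param catalog result of [swd_catalog()] on the same field.
#' @param field 1-based field index.
#' @param tol_frac agreement tolerance as a fraction of the recruited
#'   extent.
#' @return list with per-event \code{predictions} (data.frame including an
#'   \code{ambiguous} flag for spatially uniform K) and the overall
#'   \code{agreement} rate.
#' @export
k_source_prediction <- function(sim, catalog, field = 1, tol_frac = 0.1) {
  K <- k_field(sim$fields[[field]])
  x <- sim$x; tt <- sim$time
  tol <- tol_frac * max(catalog$recruited_extent, 1e-12)
  rows <- lapply(seq_len(nrow(catalog$events)), function(r) {
    ev <- catalog$events[r, ]
    it <- which(tt < ev$t_source)
    it <- if (length(it)) max(it) else 1L
    kx <- K[it, ]
    amb <- diff(range(kx)) < 1e-9
    pred <- x[which.max(kx)]
    data.frame(event = ev$event, predicted_x = pred,
               detected_x = ev$source_x, ambiguous = amb,
               agree = !amb & abs(pred - ev$source_x) <= tol)
  })
  predictions <- do.call(rbind, rows)
  list(predictions = predictions,
       agreement = mean(predictions$agree[!predictions$ambiguous]))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples.  For combined sample
#' sizes up to \code{exact_max} the two-sided p-value is computed by exact
#' enumeration of all assignments of the pooled values (ties handled
#' exactly); larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param a,b numeric samples.
#' @param exact_max largest combined size for which enumeration is used.
#' @return list with \code{U} (statistic of sample \code{a}: number of
#'   (a, b) pairs with a > b, ties counting half), two-sided \code{p}, and
#'   the \code{method} used.
#' @export
mann_whitney_u <- function(a, b, exact_max = 12) {
  stopifnot(length(a) >= 1, length(b) >= 1,
            all(is.finite(a)), all(is.finite(b)))
  n1 <- length(a); n2 <- length(b)
  ustat <- function(xa, xb)
    sum(outer(xa, xb, ">")) + 0.5 * sum(outer(xa, xb, "=="))
  U <- ustat(a, b)
  if (n1 + n2 <= exact_max) {
    pool <- c(a, b)
    idx <- utils::combn(n1 + n2, n1)
    Us <- apply(idx, 2, function(ii) ustat(pool[ii], pool[-ii]))
    eps <- 1e-9
    p <- min(1, 2 * min(mean(Us <= U + eps), mean(Us >= U - eps)))
    list(U = U, p = p, method = "exact enumeration")
  } else {
    mu <- n1 * n2 / 2
    nt <- n1 + n2
    ties <- table(c(a, b))
    sig2 <- n1 * n2 / 12 * ((nt + 1) - sum(ties^3 - ties) / (nt * (nt - 1)))
    if (sig2 <= 0) return(list(U = U, p = 1, method = "normal approximation"))
    z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
    list(U = U, p = min(1, 2 * stats::pnorm(-abs(z))),
         method = "normal approximation")
  }
}
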