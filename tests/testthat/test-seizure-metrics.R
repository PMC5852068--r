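test_that("onset/offset detection recovers constructed seizure windows", {
  fs <- 64; times <- seq(0, 60, by = 1 / fs)
  osc <- sin(2 * pi * 3 * times)
  gate <- as.numeric(times >= 10 & times <= 40)
  sig <- cbind(a = osc * gate, b = 0.01 * sin(2 * pi * 3 * times),
               c = osc * as.numeric(times >= 12 & times <= 42))
  det <- detect_onset_offset(abs(sig), times, threshold = 0.5,
                             debounce = 1, merge_gap = 1)
  expect_equal(det$onset[1], 10, tolerance = 1)
  expect_equal(det$offset[1], 40, tolerance = 1)
  expect_true(is.na(det$onset[2]))
  # a pure time shift moves onset and offset by exactly the shift
  expect_equal(det$offset[3] - det$offset[1], 2, tolerance = 1 / fs * 4)
  expect_equal(det$onset[3] - det$onset[1], 2, tolerance = 1 / fs * 4)
})

test_that("zero-phase Butterworth band-pass has the expected magnitude response", {
  fs <- 256; times <- seq(0, 20, by = 1 / fs)
  pass <- sin(2 * pi * 5 * times)
  out <- bandpass_zero_phase(pass, fs)
  core <- times > 5 & times < 15
  expect_equal(max(abs(out[core])), 1, tolerance = 0.05)
  stopb <- sin(2 * pi * 0.1 * times)
  expect_lt(max(abs(bandpass_zero_phase(stopb, fs)[core])), 0.1)
  # zero phase: cross-correlation with the input peaks at zero lag
  cc <- stats::ccf(out[core], pass[core], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  expect_error(bandpass_zero_phase(pass, fs, high = 200), "invalid band")
})

test_that("pairwise termination metrics behave on constructed channels", {
  fs <- 64; times <- seq(0, 30, by = 1 / fs)
  base <- sin(2 * pi * 4 * times) + 0.1 * sin(2 * pi * 7 * times)
  sig <- cbind(base, base, -base)
  offs <- c(20, 20, 25)
  pm <- pairwise_termination_metrics(sig, times, offs, window = 5)
  expect_equal(nrow(pm), 3)
  r12 <- pm[pm$chan_i == 1 & pm$chan_j == 2, ]
  expect_equal(r12$delay, 0)
  expect_equal(r12$correlation, 1)
  r13 <- pm[pm$chan_i == 1 & pm$chan_j == 3, ]
  expect_equal(r13$delay, 5)
  expect_equal(r13$correlation, -1)
  # same-electrode pairs excluded when labels are given
  pm2 <- pairwise_termination_metrics(sig, times, offs, window = 5,
                                      electrodes = c("A", "A", "B"))
  expect_equal(nrow(pm2), 2)
  # window extending before the recording start is skipped with a warning
  expect_warning(
    pm3 <- pairwise_termination_metrics(sig, times, c(2, 20, 25), window = 5),
    "skipped")
  expect_equal(attr(pm3, "n_skipped"), 2L)
})

test_that("pre-offset correlations of independent noise stay near zero", {
  set.seed(99)
  inside <- replicate(300, {
    sig <- matrix(rnorm(1024), 512, 2)
    abs(cor(sig[, 1], sig[, 2])) < 0.2
  })
  expect_gte(mean(inside), 0.95)
})

test_that("mean-shift clustering separates well-spaced delay groups", {
  ms <- mean_shift_1d(c(0.0, 0.1, 30.0, 30.2), bandwidth = 1)
  expect_equal(ms$labels, c(1, 1, 2, 2))
  expect_equal(length(ms$modes), 2)
  one <- mean_shift_1d(5)
  expect_equal(one$labels, 1L)
  expect_equal(one$modes, 5)
  expect_error(mean_shift_1d(1:3, bandwidth = -1), "bandwidth")
  # synthetic clusters with gap >> bandwidth are recovered exactly
  set.seed(21)
  x <- c(runif(40, 0, 1), runif(40, 50, 51), runif(40, 200, 201))
  ms3 <- mean_shift_1d(x, bandwidth = 2)
  expect_equal(ms3$labels, rep(1:3, each = 40))
})

test_that("mean-shift labels match the scikit-learn reference implementation", {
  set.seed(42)
  x <- c(rnorm(250, 0, 1), rnorm(250, 40, 1))
  ms <- mean_shift_1d(x, 3)
  tf <- tempfile()
  writeLines(sprintf("%.17g", x), tf)
  pf <- tempfile(fileext = ".py")
  writeLines(c("import numpy as np",
               "from sklearn.cluster import MeanShift",
               sprintf("x = np.loadtxt(%s).reshape(-1, 1)", deparse(tf)),
               "ms = MeanShift(bandwidth=3, bin_seeding=False).fit(x)",
               "print(' '.join(map(str, ms.labels_)))"), pf)
  out <- system2("python", pf, stdout = TRUE)
  skl <- as.integer(strsplit(out[1], " ")[[1]])
  tab <- table(ms$labels, skl)
  expect_gte(sum(apply(tab, 1, max)) / length(x), 0.99)
})

test_that("empirical front speed inverts a linear onset map exactly", {
  x <- seq(0, 10, by = 0.1)
  onset <- 100 + 2 * abs(x - 5)       # slope 2 away from source at x = 5
  es <- empirical_front_speed(onset, x)
  expect_equal(es$speed, 0.5, tolerance = 1e-12)
  expect_equal(es$r2, 1, tolerance = 1e-12)
  # a non-monotone random map is flagged by poor fit quality
  set.seed(8)
  es2 <- empirical_front_speed(100 + runif(length(x), 0, 50), x, source = 5)
  expect_lt(es2$r2, 0.5)
  expect_error(empirical_front_speed(c(1, 2, NA, NA, NA, NA), 1:6), "5 recruited")
})

test_that("discharge catalog classifies a fixed-source pulse train as stationary", {
  # constructed traveling pulses always emitted from site 20
  times <- seq(0, 100, by = 0.25)
  x <- seq(0, 18, by = 0.5)
  q1 <- matrix(-1.5, length(times), length(x))
  for (t0 in seq(10, 90, by = 10)) {
    for (j in seq_along(x)) {
      tp <- t0 + abs(x[j] - x[20]) / 5     # speed 5 away from source
      q1[, j] <- q1[, j] + 2 * exp(-((times - tp) / 0.4)^2)
    }
  }
  cat_ <- swd_catalog(q1, times, x, threshold = 0, gap = 4)
  expect_equal(cat_$classification, "stationary")
  expect_equal(nrow(cat_$events), 9)
  expect_true(all(abs(cat_$events$source_x - x[20]) < 0.51))
  expect_equal(median(cat_$events$speed), 5, tolerance = 0.2)
  expect_error(swd_catalog(q1 * 0 - 2, times, x), "no spike")
})

test_that("Mann-Whitney exact p matches full enumeration and handles degenerate input", {
  mw <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$U, 0)
  expect_equal(mw$p, 0.1, tolerance = 1e-12)
  expect_gte(mann_whitney_u(c(2, 2, 3), c(2, 2, 3))$p, 0.99)
  # independent oracle: R's exact Wilcoxon path for tie-free samples
  set.seed(13)
  for (rep in 1:5) {
    a <- sample(100, 4); b <- sample(setdiff(1:100, a), 5)
    mw <- mann_whitney_u(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(mw$p, ref$p.value, tolerance = 1e-12)
  }
  # large samples: consistent with the R implementation's normal path
  set.seed(14)
  a <- rnorm(30); b <- rnorm(30, 1)
  mw <- mann_whitney_u(a, b)
  ref <- wilcox.test(a, b, exact = FALSE, correct = TRUE)
  expect_equal(mw$p, ref$p.value, tolerance = 1e-6)
  expect_error(mann_whitney_u(numeric(0), 1))
})

test_that("pairwise metrics are invariant to channel order permutations", {
  set.seed(31)
  fs <- 64; times <- seq(0, 30, by = 1 / fs)
  sig <- matrix(rnorm(length(times) * 4), ncol = 4)
  offs <- c(20, 22, 25, 28)
  pm <- pairwise_termination_metrics(sig, times, offs, window = 5)
  perm <- c(3, 1, 4, 2)
  pm2 <- pairwise_termination_metrics(sig[, perm], times, offs[perm],
                                      window = 5)
  key <- function(df, map) {
    i <- pmin(map[df$chan_i], map[df$chan_j])
    j <- pmax(map[df$chan_i], map[df$chan_j])
    o <- order(i, j)
    data.frame(i = i[o], j = j[o], delay = df$delay[o],
               correlation = df$correlation[o])
  }
  expect_equal(key(pm, 1:4), key(pm2, perm), tolerance = 1e-12)
})
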