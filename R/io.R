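#' Serialise a run configuration to JSON
#'
#' A run configuration bundles model parameters, connectivity, stimuli and
#' integration/analysis settings with the RNG seed, and round-trips
#' losslessly through JSON.  Function-valued excitability profiles are
#' resolved to per-site vectors before writing.
#'
#' @param params a [field_params()] object.
#' @param conn a [connectivity_spec()].
#' @param stimuli list of [stimulus_spec()] objects.
#' @param integration list of integration settings (duration, dt,
#'   record_dt).
#' @param analysis list of analysis settings (window, band, bandwidth, ...).
#' @param seed RNG seed.
#' @return object of class \code{"run_config"}.
#' @export
run_config <- function(params = field_params(), conn = connectivity_spec(),
                       stimuli = list(stimulus_spec()),
                       integration = list(duration = 2500, dt = 0.025,
                                          record_dt = 1),
                       analysis = list(window = 50, band = c(1, 10),
                                       bandwidth = NULL),
                       seed = 1) {
  if (is.function(params$u0)) params$u0 <- u0_profile(params)
  structure(list(schema = "epifield-config-1", params = params, conn = conn,
                 stimuli = stimuli, integration = integration,
                 analysis = analysis, seed = seed),
            class = "run_config")
}

#' @rdname run_config
#' @param config a \code{"run_config"} object.
#' @param path file path.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(unclass_deep(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(raw$schema, "epifield-config-1"))
    stop("unrecognised config schema: ", raw$schema %||% "<missing>")
  known <- c("schema", "params", "conn", "stimuli", "integration",
             "analysis", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop("unknown configuration key: ",
                          paste(extra, collapse = ", "))
  pk <- c("I1", "I2", "tau0", "tau2", "tau12", "theta11", "theta22",
          "theta12", "theta_het", "a12", "gamma11", "gamma22", "gamma12",
          "u0", "noise_sigma2", "L", "N")
  extra <- setdiff(names(raw$params), pk)
  if (length(extra)) stop("unknown parameter key: ",
                          paste(extra, collapse = ", "))
  params <- do.call(field_params, raw$params)
  het <- raw$conn$het
  if (is.data.frame(het)) het <- lapply(seq_len(nrow(het)), function(i) as.list(het[i, ]))
  conn <- connectivity_spec(raw$conn$n_fields, raw$conn$kernel,
                            het %||% list())
  stimuli <- raw$stimuli
  if (is.data.frame(stimuli))
    stimuli <- lapply(seq_len(nrow(stimuli)), function(i) as.list(stimuli[i, ]))
  stimuli <- lapply(stimuli, function(s) do.call(stimulus_spec, s))
  run_config(params, conn, stimuli, as.list(raw$integration),
             as.list(raw$analysis), raw$seed)
}

# full-precision numeric CSV helpers (lossless round-trip)
write_matrix_csv <- function(m, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(m)))
    writeLines(paste(sprintf("%.17g", m[i, ]), collapse = ","), con)
  invisible(path)
}

read_matrix_csv <- function(path) {
  rows <- strsplit(readLines(path), ",")
  n <- unique(lengths(rows))
  if (length(n) != 1) stop("ragged CSV matrix in ", path)
  matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
}

#' Persist a simulation result
#'
#' Writes an \code{"epi_sim"} object as a directory of full-precision CSV
#' arrays (\code{time}, \code{x}, and per field \code{u1,...,q3} plus the
#' LFP proxy) together with a JSON metadata file holding the resolved
#' configuration and seed.  [read_simulation()] restores the object with
#' bit-identical arrays.
#'
#' @param sim an \code{"epi_sim"} object.
#' @param dir output directory (created if absent).
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_csv(cbind(sim$time), file.path(dir, "time.csv"))
  write_matrix_csv(cbind(sim$x), file.path(dir, "x.csv"))
  write_matrix_csv(sim$u0, file.path(dir, "u0.csv"))
  for (f in seq_along(sim$fields)) {
    fd <- file.path(dir, sprintf("field%d", f))
    dir.create(fd, showWarnings = FALSE)
    for (v in names(sim$fields[[f]]))
      write_matrix_csv(sim$fields[[f]][[v]], file.path(fd, paste0(v, ".csv")))
    write_matrix_csv(lfp(sim, f), file.path(fd, "lfp.csv"))
  }
  params <- sim$params
  if (is.function(params$u0)) params$u0 <- u0_profile(params)
  meta <- list(schema = "epifield-sim-1", params = unclass_deep(params),
               conn = unclass_deep(sim$conn),
               stimuli = unclass_deep(sim$stimuli),
               seed = sim$seed, dt = sim$dt, record_dt = sim$record_dt,
               freeze_v = sim$freeze_v,
               n_fields = length(sim$fields))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(dir)
}

#' @rdname write_simulation
#' @export
read_simulation <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  if (!identical(meta$schema, "epifield-sim-1"))
    stop("unrecognised simulation schema: ", meta$schema %||% "<missing>")
  params <- do.call(field_params, meta$params)
  fields <- lapply(seq_len(meta$n_fields), function(f) {
    fd <- file.path(dir, sprintf("field%d", f))
    vars <- c("u1", "u2", "v", "q1", "q2", "q3")
    stats::setNames(lapply(vars, function(v)
      read_matrix_csv(file.path(fd, paste0(v, ".csv")))), vars)
  })
  het <- meta$conn$het
  if (is.data.frame(het)) het <- lapply(seq_len(nrow(het)), function(i) as.list(het[i, ]))
  conn <- connectivity_spec(meta$conn$n_fields, meta$conn$kernel,
                            het %||% list())
  stimuli <- meta$stimuli
  if (is.data.frame(stimuli))
    stimuli <- lapply(seq_len(nrow(stimuli)), function(i) as.list(stimuli[i, ]))
  structure(list(time = as.numeric(read_matrix_csv(file.path(dir, "time.csv"))),
                 x = as.numeric(read_matrix_csv(file.path(dir, "x.csv"))),
                 fields = fields, params = params, conn = conn,
                 stimuli = stimuli, seed = meta$seed, dt = meta$dt,
                 record_dt = meta$record_dt, freeze_v = meta$freeze_v,
                 u0 = read_matrix_csv(file.path(dir, "u0.csv"))),
            class = "epi_sim")
}

#' Read a square region matrix from CSV
#'
#' CSV with a header row of region ids and one row per region; must be
#' square.
#'
#' @param path file path.
#' @return numeric matrix with region ids as dimnames.
#' @export
read_region_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m))
    stop("region matrix in ", path, " is not square (",
         nrow(m), "x", ncol(m), ")")
  rownames(m) <- colnames(m)
  storage.mode(m) <- "double"
  m
}

#' Write pairwise analysis results
#'
#' Tidy CSV of pairwise rows plus a JSON cluster summary.
#'
#' @param pairs data.frame of pairwise rows (delay, correlation, cluster,
#'   features).
#' @param stats optional result of [cluster_feature_stats()].
#' @param csv_path,json_path output paths (either may be NULL).
#' @export
write_pairs <- function(pairs, stats = NULL, csv_path = NULL,
                        json_path = NULL) {
  if (!is.null(csv_path)) utils::write.csv(pairs, csv_path, row.names = FALSE)
  if (!is.null(json_path) && !is.null(stats))
    jsonlite::write_json(list(schema = "epifield-clusters-1",
                              summary = stats$summary, tests = stats$tests,
                              cluster_one = stats$cluster_one),
                         json_path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  invisible(NULL)
}
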