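#' Region graph: proximity and streamline-count matrices
#'
#' Container for the two region-level connectivity summaries consumed by the
#' contact-pair analysis: a binary proximity (adjacency) matrix marking
#' contiguous regions, and a symmetric matrix of tractography streamline
#' counts.  Both use the same region ordering and have nonzero diagonals
#' (two contacts in one region are contiguous and share that region's
#' self-connection count).
#'
#' @param adjacency square 0/1 matrix with nonzero diagonal.
#' @param tracks square nonnegative matrix, symmetric, same dimension.
#' @param region_ids optional region identifiers (default: row names or
#'   sequence).
#' @return object of class \code{"region_graph"}.
#' @export
region_graph <- function(adjacency, tracks, region_ids = NULL) {
  adjacency <- as.matrix(adjacency); tracks <- as.matrix(tracks)
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  if (nrow(tracks) != ncol(tracks)) stop("tracks must be square")
  if (!all(dim(adjacency) == dim(tracks)))
    stop("adjacency and tracks must have the same dimension")
  if (!all(adjacency %in% c(0, 1))) stop("adjacency must be binary")
  if (!isTRUE(all.equal(adjacency, t(adjacency), tolerance = 0)) ||
      !isTRUE(all.equal(tracks, t(tracks), tolerance = 0)))
    stop("matrices must be symmetric")
  if (any(tracks < 0)) stop("track counts must be nonnegative")
  if (is.null(region_ids))
    region_ids <- rownames(adjacency) %||% as.character(seq_len(nrow(adjacency)))
  dimnames(adjacency) <- dimnames(tracks) <- list(region_ids, region_ids)
  structure(list(adjacency = adjacency, tracks = tracks,
                 region_ids = as.character(region_ids)),
            class = "region_graph")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Contact table
#'
#' One row per implanted contact: identifier, electrode (shaft) label,
#' assigned brain region, and tissue class.  Only contacts in cortical gray
#' matter or in the hippocampus/amygdala enter the pair analysis.
#'
#' @param contact contact identifiers (unique).
#' @param electrode electrode labels.
#' @param region region ids (must exist in the region graph used later).
#' @param tissue tissue class, one of \code{"gray"},
#'   \code{"hippocampus_amygdala"}, \code{"other"}.
#' @return data.frame of class \code{"contact_table"}.
#' @export
contact_table <- function(contact, electrode, region, tissue) {
  stopifnot(!anyDuplicated(contact),
            all(tissue %in% c("gray", "hippocampus_amygdala", "other")))
  structure(data.frame(contact = as.character(contact),
                       electrode = as.character(electrode),
                       region = as.character(region),
                       tissue = as.character(tissue),
                       stringsAsFactors = FALSE),
            class = c("contact_table", "data.frame"))
}

#' Admissible contact pairs
#'
#' Unordered contact pairs eligible for the termination-delay analysis:
#' both contacts in admissible tissue (cortical gray or
#' hippocampus/amygdala) and on different stereotactic electrodes.
#'
#' @param contacts a [contact_table()].
#' @return data.frame with columns \code{contact_i}, \code{contact_j}.
#' @export
admissible_pairs <- function(contacts) {
  ok <- contacts$tissue %in% c("gray", "hippocampus_amygdala")
  cc <- contacts[ok, ]
  out <- list()
  n <- nrow(cc)
  if (n >= 2) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (cc$electrode[i] == cc$electrode[j]) next
      out[[length(out) + 1]] <- data.frame(contact_i = cc$contact[i],
                                           contact_j = cc$contact[j])
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(contact_i = character(), contact_j = character())
}

#' Connectivity features of contact pairs
#'
#' For each pair, the binary proximity of the two assigned regions and the
#' number of streamlines linking them, read from the region graph.  Pairs
#' within one region use the (nonzero) diagonal entries.
#'
#' @param pairs data.frame with \code{contact_i}, \code{contact_j} (e.g.
#'   from [admissible_pairs()]).
#' @param contacts a [contact_table()].
#' @param graph a [region_graph()].
#' @return the pairs with added columns \code{proximity} and
#'   \code{n_tracks}.
#' @export
pair_features <- function(pairs, contacts, graph) {
  reg <- stats::setNames(contacts$region, contacts$contact)
  ri <- reg[pairs$contact_i]; rj <- reg[pairs$contact_j]
  if (any(is.na(ri)) || any(is.na(rj)))
    stop("pair references a contact missing from the contact table")
  if (!all(c(ri, rj) %in% graph$region_ids))
    stop("unknown region id: ",
         paste(setdiff(c(ri, rj), graph$region_ids), collapse = ", "))
  pairs$proximity <- graph$adjacency[cbind(ri, rj)]
  pairs$n_tracks <- graph$tracks[cbind(ri, rj)]
  pairs
}

#' Per-cluster feature summaries and first-vs-rest comparisons
#'
#' Summarises correlation, streamline count and proximity per termination
#' cluster, and compares cluster one (the cluster with the smallest mean
#' delay) against all other clusters pooled, with two-sided Mann-Whitney
#' U tests for each feature.
#'
#' @param pairs data.frame holding at least \code{delay}, \code{cluster},
#'   and any of \code{correlation}, \code{n_tracks}, \code{proximity}.
#' @return list with \code{summary} (per-cluster means/SDs), \code{tests}
#'   (data.frame feature/U/p, NULL when only one cluster), and
#'   \code{cluster_one} (the label identified as smallest-delay cluster).
#' @export
cluster_feature_stats <- function(pairs) {
  stopifnot(all(c("delay", "cluster") %in% names(pairs)))
  feats <- intersect(c("correlation", "n_tracks", "proximity"), names(pairs))
  sp <- split(pairs, pairs$cluster)
  summary <- do.call(rbind, lapply(sp, function(g) {
    row <- data.frame(cluster = g$cluster[1], n = nrow(g),
                      delay_mean = mean(g$delay), delay_sd = stats::sd(g$delay))
    for (f in feats) {
      row[[paste0(f, "_mean")]] <- mean(g[[f]])
      row[[paste0(f, "_sd")]] <- stats::sd(g[[f]])
    }
    row
  }))
  rownames(summary) <- NULL
  cluster_one <- summary$cluster[which.min(summary$delay_mean)]
  tests <- NULL
  if (nrow(summary) >= 2) {
    in1 <- pairs$cluster == cluster_one
    tests <- do.call(rbind, lapply(feats, function(f) {
      mw <- mann_whitney_u(pairs[[f]][in1], pairs[[f]][!in1])
      data.frame(feature = f, U = mw$U, p = mw$p, method = mw$method)
    }))
  }
  list(summary = summary, tests = tests, cluster_one = cluster_one,
       tests_skipped = is.null(tests))
}

#' Synthetic region connectome with implanted contacts
#'
#' Deterministic (seeded) generator of a block-structured region graph and
#' a matching contact table, emulating the situation where some electrodes
#' sample one densely connected module and others a weakly connected
#' distant module: streamline counts are high within blocks and low
#' between, adjacency follows the blocks, diagonals are nonzero.
#'
#' @param n_regions number of regions (>= 1).
#' @param n_electrodes number of electrodes.
#' @param contacts_per_electrode contacts implanted per electrode.
#' @param n_blocks number of connectivity modules.
#' @param within_tracks,between_tracks Poisson means of streamline counts
#'   within / between blocks.
#' @param seed RNG seed.
#' @return list with \code{graph} (a [region_graph()]) and \code{contacts}
#'   (a [contact_table()]; electrode k samples regions of block
#'   \code{(k-1) \%\% n_blocks + 1}).
#' @export
synth_connectome <- function(n_regions = 12, n_electrodes = 4,
                             contacts_per_electrode = 4, n_blocks = 2,
                             within_tracks = 800, between_tracks = 3,
                             seed = 1) {
  stopifnot(n_regions >= 1, n_electrodes >= 1, contacts_per_electrode >= 1,
            n_blocks >= 1, n_blocks <= n_regions)
  set.seed(seed)
  block <- rep(seq_len(n_blocks), length.out = n_regions)
  same <- outer(block, block, "==")
  lam <- ifelse(same, within_tracks, between_tracks)
  tracks <- matrix(stats::rpois(n_regions^2, lam), n_regions)
  tracks[lower.tri(tracks)] <- t(tracks)[lower.tri(tracks)]
  diag(tracks) <- stats::rpois(n_regions, within_tracks) + 1
  adjacency <- (same & (tracks > stats::quantile(tracks[same], 0.1))) * 1
  adjacency[lower.tri(adjacency)] <- t(adjacency)[lower.tri(adjacency)]
  diag(adjacency) <- 1
  graph <- region_graph(adjacency, tracks,
                        region_ids = paste0("R", seq_len(n_regions)))
  rows <- list()
  for (e in seq_len(n_electrodes)) {
    bl <- (e - 1) %% n_blocks + 1
    cand <- which(block == bl)
    reg <- sample(cand, contacts_per_electrode, replace = TRUE)
    rows[[e]] <- data.frame(
      contact = paste0("E", e, "c", seq_len(contacts_per_electrode)),
      electrode = paste0("E", e),
      region = paste0("R", reg),
      tissue = "gray")
  }
  ct <- do.call(rbind, rows)
  contacts <- contact_table(ct$contact, ct$electrode, ct$region, ct$tissue)
  list(graph = graph, contacts = contacts, block = block)
}
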