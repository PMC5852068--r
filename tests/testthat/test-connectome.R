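make_contacts <- function() {
  contact_table(contact = c("A1", "A2", "B1", "B2", "B3"),
                electrode = c("A", "A", "B", "B", "B"),
                region = c("R1", "R2", "R1", "R3", "R2"),
                tissue = c("gray", "gray", "hippocampus_amygdala", "gray",
                           "other"))
}

make_graph <- function() {
  adj <- matrix(c(1, 1, 0,
                  1, 1, 0,
                  0, 0, 1), 3, byrow = TRUE)
  trk <- matrix(c(500, 120, 0,
                  120, 400, 0,
                  0,   0, 300), 3, byrow = TRUE)
  region_graph(adj, trk, region_ids = c("R1", "R2", "R3"))
}

test_that("admissible pairs cross electrodes and admissible tissue only", {
  ap <- admissible_pairs(make_contacts())
  # B3 is 'other' tissue: excluded; A1-A2 same electrode: excluded
  expect_equal(nrow(ap), 4)
  expect_false(any(ap$contact_i == "B3" | ap$contact_j == "B3"))
  expect_false(any(paste(ap$contact_i, ap$contact_j) %in% c("A1 A2")))
  # two electrodes x two admissible contacts each -> all four cross pairs
  ct <- contact_table(c("A1", "A2", "B1", "B2"), c("A", "A", "B", "B"),
                      rep("R1", 4), rep("gray", 4))
  expect_equal(nrow(admissible_pairs(ct)), 4)
  # all contacts on one electrode -> no pairs
  ct1 <- contact_table(c("A1", "A2"), c("A", "A"), c("R1", "R2"),
                       c("gray", "gray"))
  expect_equal(nrow(admissible_pairs(ct1)), 0)
})

test_that("pair features read the region matrices, including nonzero self-connections", {
  ap <- admissible_pairs(make_contacts())
  pf <- pair_features(ap, make_contacts(), make_graph())
  same_region <- pf[pf$contact_i == "A1" & pf$contact_j == "B1", ]
  expect_equal(same_region$proximity, 1)       # diagonal is nonzero
  expect_equal(same_region$n_tracks, 500)
  zero <- pf[pf$contact_i == "A1" & pf$contact_j == "B2", ]  # R1 - R3
  expect_equal(zero$proximity, 0)
  expect_equal(zero$n_tracks, 0)
  # symmetry: reversed pairs carry identical features
  rev <- ap[, c(2, 1)]
  names(rev) <- c("contact_i", "contact_j")
  pf2 <- pair_features(rev, make_contacts(), make_graph())
  expect_equal(pf$proximity, pf2$proximity)
  expect_equal(pf$n_tracks, pf2$n_tracks)
  bad <- data.frame(contact_i = "A1", contact_j = "ZZ")
  expect_error(pair_features(bad, make_contacts(), make_graph()), "missing")
})

test_that("features are invariant under simultaneous region permutation", {
  syn <- synth_connectome(seed = 5)
  ap <- admissible_pairs(syn$contacts)
  pf <- pair_features(ap, syn$contacts, syn$graph)
  # permute region indices everywhere
  n <- length(syn$graph$region_ids)
  set.seed(1); perm <- sample(n)
  g2 <- region_graph(syn$graph$adjacency[perm, perm],
                     syn$graph$tracks[perm, perm],
                     region_ids = syn$graph$region_ids[perm])
  pf2 <- pair_features(ap, syn$contacts, g2)
  expect_equal(pf$proximity, pf2$proximity)
  expect_equal(pf$n_tracks, pf2$n_tracks)
})

test_that("cluster one versus rest separates constructed connectivity differences", {
  set.seed(4)
  n <- 20
  pairs <- data.frame(
    delay = c(runif(n, 0, 2), runif(n, 50, 60)),
    cluster = rep(1:2, each = n),
    correlation = c(runif(n, 0.7, 1), runif(n, 0, 0.3)),
    n_tracks = c(rpois(n, 1000), rpois(n, 1)),
    proximity = c(rbinom(n, 1, 0.95), rbinom(n, 1, 0.05)))
  st <- cluster_feature_stats(pairs)
  expect_equal(st$cluster_one, 1)
  expect_false(st$tests_skipped)
  expect_true(all(st$tests$p < 0.01))
  s1 <- st$summary[st$summary$cluster == 1, ]
  s2 <- st$summary[st$summary$cluster == 2, ]
  expect_gt(s1$n_tracks_mean, s2$n_tracks_mean)
  expect_gt(s1$correlation_mean, s2$correlation_mean)

  # identical feature distributions: no separation, p typically large
  set.seed(6)
  ps <- replicate(100, {
    pr <- data.frame(delay = c(runif(15, 0, 2), runif(15, 50, 60)),
                     cluster = rep(1:2, each = 15),
                     n_tracks = rpois(30, 100))
    cluster_feature_stats(pr)$tests$p
  })
  expect_gte(median(ps), 0.5)

  # a single cluster yields summaries only
  one <- cluster_feature_stats(data.frame(delay = runif(10), cluster = 1,
                                          correlation = runif(10)))
  expect_true(one$tests_skipped)
  expect_null(one$tests)
})

test_that("synthetic connectome is deterministic and block structured", {
  a <- synth_connectome(seed = 9)
  b <- synth_connectome(seed = 9)
  expect_identical(a$graph$tracks, b$graph$tracks)
  expect_identical(a$contacts, b$contacts)
  same <- outer(a$block, a$block, "==")
  off <- !diag(nrow(same))
  expect_gt(mean(a$graph$tracks[same & off]), mean(a$graph$tracks[!same]))
  expect_true(all(diag(a$graph$adjacency) == 1))
  expect_true(all(diag(a$graph$tracks) > 0))
  # one region: everything contiguous
  s1 <- synth_connectome(n_regions = 1, n_blocks = 1, seed = 2)
  pf <- pair_features(admissible_pairs(s1$contacts), s1$contacts, s1$graph)
  expect_true(all(pf$proximity == 1))
})

test_that("region graph validation rejects malformed matrices", {
  expect_error(region_graph(matrix(0:3, 2), matrix(1, 2, 2)), "binary")
  expect_error(region_graph(matrix(1, 2, 2), matrix(1, 3, 3)), "dimension")
  expect_error(region_graph(matrix(1, 2, 2), matrix(c(1, 2, 3, 4), 2)),
               "symmetric")
})
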