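test_that("MPD reproduces hand and degenerate cases", {
  D <- matrix(c(0, 1, 2, 1, 0, 3, 2, 3, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  D <- species_dist(D)
  # counts (1,2,3): (2*(1*2*1 + 1*3*2 + 2*3*3)) / (2*(1*2 + 1*3 + 2*3)) = 52/22
  expect_equal(mpd(c(A = 1, B = 2, C = 3), D), 52 / 22)

  # two species: MPD is their distance whatever the abundances
  expect_equal(mpd(c(A = 7, B = 2, C = 0), D), 1)

  # constant distances: exclude-conspecific gives c, include gives < c
  Dc <- species_dist(matrix(c(0, 2, 2, 2, 0, 2, 2, 2, 0), 3,
                            dimnames = dimnames(D)))
  f <- c(A = 3, B = 1, C = 2)
  expect_equal(mpd(f, Dc), 2)
  expect_lt(mpd(f, Dc, include_conspecific = TRUE), 2)

  expect_true(is.na(mpd(c(A = 5, B = 0, C = 0), D)))
})

test_that("vectorised MPD equals the naive double loop on random draws", {
  set.seed(99)
  for (i in 1:200) {
    n <- sample(2:8, 1)
    D <- rand_species_dist(n)
    f <- stats::rpois(n, 3)
    names(f) <- rownames(D)
    inc <- i %% 2 == 0
    expect_equal(mpd(f, D, include_conspecific = inc),
                 mpd_naive(f, D, include_conspecific = inc),
                 tolerance = 1e-12)
  }
  # and the grid-vectorised path agrees with the scalar path
  ds <- shared_dataset()
  D <- rand_species_dist(21, labels = colnames(ds$community$abund))
  m <- ses_mpd_map(ds$community, D, n_null = 5, seed = 1)
  idx <- sample(nrow(ds$community$abund), 25)
  for (q in idx) {
    f <- ds$community$abund[q, ]
    expect_equal(m$mpd_obs[q], mpd_naive(f, D), tolerance = 1e-12)
  }
})

test_that("MPD agrees with picante's abundance-weighted implementation", {
  skip_if_not_installed("picante")
  set.seed(5)
  D <- rand_species_dist(6)
  samp <- matrix(stats::rpois(5 * 6, 2), 5, dimnames = list(NULL, rownames(D)))
  # picante's abundance-weighted MPD averages over the full f_i f_j weight
  # matrix including the diagonal, i.e. the conspecific-inclusive double sum
  ours <- apply(samp, 1, function(f)
    mpd(stats::setNames(f, colnames(samp)), D, include_conspecific = TRUE))
  theirs <- picante::mpd(samp, D, abundance.weighted = TRUE)
  expect_equal(unname(ours), unname(theirs), tolerance = 1e-12)
})

test_that("ses null moments match exhaustive label-permutation enumeration", {
  set.seed(17)
  D <- rand_species_dist(3, labels = c("A", "B", "C"))
  ab <- matrix(c(1, 2, 3,
                 4, 0, 2,
                 2, 2, 2,
                 0, 5, 1), 4, 3, byrow = TRUE,
               dimnames = list(NULL, c("A", "B", "C")))
  comm <- tiny_community(ab)
  perms <- all_perms(3)
  exact <- sapply(seq_len(nrow(ab)), function(q) {
    vals <- sapply(perms, function(p) {
      Dp <- D[p, p]; dimnames(Dp) <- dimnames(D)
      mpd(ab[q, ], Dp)
    })
    c(mean = mean(vals), sd = stats::sd(vals))
  })
  m <- ses_mpd_map(comm, D, n_null = 9999, seed = 3)
  for (q in 1:nrow(ab)) {
    # MC error of the null mean is sd/sqrt(n); allow 4x
    tol_mean <- 4 * exact["sd", q] / sqrt(9999)
    expect_lt(abs(m$null_mean[q] - exact["mean", q]), tol_mean + 1e-12)
    expect_lt(abs(m$null_sd[q] - exact["sd", q]), 0.05 * exact["sd", q] + 0.02)
  }
})

test_that("ses is missing for depauperate subplots and degenerate distances", {
  D <- rand_species_dist(3, labels = c("A", "B", "C"))
  ab <- matrix(c(5, 0, 0,
                 1, 1, 1), 2, 3, byrow = TRUE,
               dimnames = list(NULL, c("A", "B", "C")))
  m <- ses_mpd_map(tiny_community(ab), D, n_null = 99, seed = 1)
  expect_true(is.na(m$ses[1]))      # single-species subplot
  expect_false(is.na(m$ses[2]))
  expect_error(ses_mpd_map(tiny_community(ab), D, n_null = 1), "n_null")

  Dc <- species_dist(matrix(c(0, 1, 1, 1, 0, 1, 1, 1, 0), 3,
                            dimnames = list(c("A", "B", "C"),
                                            c("A", "B", "C"))))
  expect_warning(mc <- ses_mpd_map(tiny_community(ab), Dc, n_null = 99,
                                   seed = 1),
                 "degenerate")
  expect_true(all(is.na(mc$ses)))
})

test_that("per-GO ses equals the generic route on the 0/1 dissimilarity", {
  ds <- shared_dataset()
  sig <- matrix(c(TRUE, TRUE, FALSE), 21, 3)
  set.seed(8)
  sig[, 2] <- sample(c(TRUE, FALSE), 21, replace = TRUE)
  sig[, 3] <- TRUE  # monomorphic
  rownames(sig) <- colnames(ds$community$abund)
  colnames(sig) <- c("GO:a", "GO:b", "GO:c")
  maps <- per_go_ses(ds$community, sig, n_null = 49, seed = 77)

  for (j in 1:2) {
    D <- binary_state_distances(sig[, j])
    ref <- ses_mpd_map(ds$community, D, n_null = 49,
                       seed = as.integer(77 + j - 1))
    expect_equal(maps[[j]]$mpd_obs, ref$mpd_obs, tolerance = 1e-9)
    expect_equal(maps[[j]]$null_mean, ref$null_mean, tolerance = 1e-9)
    expect_equal(maps[[j]]$ses, ref$ses, tolerance = 1e-6)
  }
  # monomorphic column: all missing
  expect_true(all(is.na(maps[[3]]$ses)))
  # complemented column: identical ses map
  maps_c <- per_go_ses(ds$community,
                       cbind(`GO:a` = !sig[, 1]), n_null = 49, seed = 77)
  expect_equal(maps_c[[1]]$ses, maps[[1]]$ses, tolerance = 1e-12)
})

test_that("GO ranking orders terms by mean ses with stable ties", {
  ds <- truth_dataset()
  prof <- truth_profile()
  sig <- prof$significant
  maps <- per_go_ses(ds$community, sig, n_null = 99, seed = 5)
  rk <- rank_go_terms(maps, namespaces = prof$namespaces)
  expect_identical(rk$rank, seq_len(nrow(rk)))
  ok <- !rk$degenerate
  expect_true(all(diff(rk$mean_ses[ok]) >= -1e-12))  # ascending

  # guild-active terms sit above (more negative than) inactive ones
  active <- intersect(unlist(ds$guilds$active_go), rk$go_id)
  inactive <- setdiff(rk$go_id[ok], active)
  expect_lt(mean(rk$mean_ses[rk$go_id %in% active]),
            mean(rk$mean_ses[rk$go_id %in% inactive]))

  # permuting the input leaves the ranking unchanged
  rk2 <- rank_go_terms(rev(maps), namespaces = prof$namespaces)
  expect_identical(rk2$go_id, rk$go_id)

  single <- rank_go_terms(maps[1])
  expect_identical(single$rank, 1L)
})

test_that("subplot aggregation sums blocks and drops ragged edges", {
  ds <- shared_dataset()
  comm <- ds$community  # 35 x 18
  expect_identical(aggregate_subplots(comm, 1)$abund, comm$abund)

  agg2 <- aggregate_subplots(comm, 2)
  expect_equal(c(agg2$nx, agg2$ny), c(17, 9))
  expect_equal(attr(agg2, "dropped_subplots"), 18)  # one 1 x 18 column
  expect_equal(agg2$cell, 40)
  expect_equal(sum(agg2$abund) + sum(comm$abund[comm$x_index == 35, ]),
               sum(comm$abund))
  # block content check: block (1,1) = subplots (1..2, 1..2)
  sel <- comm$x_index <= 2 & comm$y_index <= 2
  expect_equal(agg2$abund[1, ], colSums(comm$abund[sel, ]))

  agg5 <- aggregate_subplots(comm, 5)
  expect_equal(c(agg5$nx, agg5$ny), c(7, 3))
  expect_error(aggregate_subplots(comm, 40), "exceed")
})
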