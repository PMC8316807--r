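test_that("win matrix tallies decided bouts and ignores undecided ones", {
  b <- make_bouts(rep("A", 4), rep("B", 4))
  w <- build_win_matrix(b)
  expect_equal(w$s["A", "B"], 4L, ignore_attr = TRUE)
  expect_equal(w$n["A", "B"], 4L, ignore_attr = TRUE)

  b2 <- make_bouts(c("A", "A", "B"), c("B", "B", "A"), decided = c(1L, 0L, 1L))
  w2 <- build_win_matrix(b2)
  expect_equal(sum(w2$s), 2L)

  expect_error(build_win_matrix(make_bouts("A", "B", decided = 0L)),
               "rank undeterminable")
})

test_that("win matrix equals a brute-force tally on random fixtures", {
  set.seed(101)
  for (rep in 1:20) {
    b <- random_bouts(5, 60)
    ids <- sort(unique(c(b$aggressor_id[b$decided == 1],
                         b$victim_id[b$decided == 1])))
    w <- build_win_matrix(b)
    expect_identical(w$s, oracle_tally(b, ids))
    expect_identical(w$n, w$s + t(w$s))
  }
})

test_that("modified David's scores match the two-individual hand-worked case", {
  # A beats B 4-0: P_AB = 1, D_AB = 1 - 0.5/5 = 0.9, D_BA = 0.1,
  # DS_A = 0.9 + 0.9*0.1 - 0.1 - 0.1*0.9 = 0.8; normDS = (DS + 1)/2
  rt <- modified_davids_score(build_win_matrix(make_bouts(rep("A", 4), rep("B", 4))))
  expect_equal(rt$DS, c(0.8, -0.8))
  expect_equal(rt$normDS, c(0.9, 0.1))
})

test_that("David's scores sum to zero and normDS has mean (N-1)/2", {
  set.seed(202)
  for (rep in 1:50) {
    n_ind <- sample(3:8, 1)
    b <- random_bouts(n_ind, sample(20:150, 1))
    rt <- modified_davids_score(build_win_matrix(b))
    N <- nrow(rt)
    expect_lt(abs(sum(rt$DS)), 1e-9)
    expect_lt(abs(mean(rt$normDS) - (N - 1) / 2), 1e-9)
    expect_true(all(rt$normDS >= -1e-9 & rt$normDS <= N - 1 + 1e-9))
  }
})

test_that("a perfectly symmetric win matrix gives all-zero scores", {
  b <- rbind(make_bouts(rep("A", 3), rep("B", 3)),
             make_bouts(rep("B", 3), rep("A", 3)),
             make_bouts(rep("B", 2), rep("C", 2)),
             make_bouts(rep("C", 2), rep("B", 2)))
  b$bout_id <- sprintf("b%03d", seq_len(nrow(b)))
  rt <- modified_davids_score(build_win_matrix(b))
  expect_equal(rt$DS, rep(0, 3))
})

test_that("rank assignment orders by normDS with flagged lexicographic ties", {
  rt <- data.frame(individual_id = c("A", "B"), DS = c(0.8, -0.8),
                   normDS = c(0.9, 0.1))
  rk <- assign_ranks(rt)
  expect_equal(rk$rank[rk$individual_id == "A"], 1L)
  expect_false(any(rk$tied))

  tie <- data.frame(individual_id = c("Z", "A", "M"), DS = 0,
                    normDS = c(0.5, 0.5, 0.5))
  rk2 <- assign_ranks(tie)
  expect_equal(rk2$individual_id, c("A", "M", "Z"))
  expect_true(all(rk2$tied))

  set.seed(9)
  rnd <- data.frame(individual_id = sprintf("i%02d", 1:10), DS = 0,
                    normDS = runif(10))
  rk3 <- assign_ranks(rnd)
  expect_equal(rk3$individual_id,
               rnd$individual_id[order(rnd$normDS, decreasing = TRUE)])
  expect_equal(sort(rk3$rank), 1:10)
})

test_that("dyadic DII matches direct proportions and is relabel-invariant", {
  b <- make_bouts(c(rep("A", 7), rep("B", 3)), c(rep("B", 7), rep("A", 3)))
  expect_equal(dyad_dii(b), 0.3)
  expect_equal(dyad_dii(make_bouts(rep("A", 5), rep("B", 5))), 0)
  b2 <- make_bouts(c(rep("A", 3), rep("B", 3)), c(rep("B", 3), rep("A", 3)))
  expect_equal(dyad_dii(b2), 0.5)
  # swapping the labels of the two individuals leaves the DII unchanged
  b_sw <- b
  b_sw$aggressor_id <- chartr("AB", "BA", b$aggressor_id)
  b_sw$victim_id <- chartr("AB", "BA", b$victim_id)
  expect_equal(dyad_dii(b_sw), dyad_dii(b))
  expect_error(dyad_dii(b[0, ]), "no bouts")
})

test_that("tolerance profile reproduces the single-dyad hand example", {
  # focal A dominant over B, 10 bouts: 7 A->B / 3 B->A, 4 counter, 2 contact
  b <- make_bouts(c(rep("A", 7), rep("B", 3)), c(rep("B", 7), rep("A", 3)),
                  counter = c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0),
                  contact = c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0))
  ranks <- davids_ranks(b)
  pg <- tolerance_profile(b, ranks, "given", min_bouts = 10)
  a_row <- pg[pg$individual_id == "A", ]
  expect_equal(a_row$dii, 0.3)
  expect_equal(a_row$counter_pct, 40)
  expect_equal(a_row$intensity_pct, 20)
  # the top-ranked individual has no higher-ranking partners
  pr <- tolerance_profile(b, ranks, "received", min_bouts = 1)
  expect_true(all(is.na(unlist(pr[pr$individual_id == "A",
                                  c("dii", "counter_pct", "intensity_pct")]))))
})

test_that("tolerance profile equals per-dyad brute-force enumeration", {
  set.seed(303)
  for (rep in 1:25) {
    b <- random_bouts(sample(4:7, 1), sample(40:120, 1))
    ranks <- davids_ranks(b)
    b <- b[b$aggressor_id %in% ranks$individual_id &
             b$victim_id %in% ranks$individual_id, ]
    for (dir in c("given", "received", "all")) {
      prof <- tolerance_profile(b, ranks, dir, min_bouts = 1)
      prof_dm <- tolerance_profile(b, ranks, dir, min_bouts = 1,
                                   dii_mode = "dyad_mean")
      for (focal in ranks$individual_id) {
        o <- oracle_profile(b, ranks, focal, dir, min_bouts = 1)
        row <- prof[prof$individual_id == focal, ]
        expect_equal(row$dii, o$dii)
        expect_equal(row$counter_pct, o$counter_pct)
        expect_equal(row$intensity_pct, o$intensity_pct)
        expect_equal(row$n_bouts, o$n_bouts)
        expect_equal(prof_dm[prof_dm$individual_id == focal, ]$dii,
                     o$dii_dyad_mean)
      }
    }
  }
})

test_that("every rank-restricted bout is counted in exactly one direction per participant", {
  set.seed(404)
  b <- random_bouts(6, 150)
  ranks <- davids_ranks(b)
  b <- b[b$aggressor_id %in% ranks$individual_id &
           b$victim_id %in% ranks$individual_id, ]
  pg <- tolerance_profile(b, ranks, "given", min_bouts = 1)
  pr <- tolerance_profile(b, ranks, "received", min_bouts = 1)
  pa <- tolerance_profile(b, ranks, "all", min_bouts = 1)
  # with no ties, given + received bouts partition each individual's bouts
  expect_false(any(duplicated(ranks$normDS)))
  merged <- merge(merge(pg, pr, by = "individual_id"), pa, by = "individual_id")
  expect_equal(merged$n_bouts.x + merged$n_bouts.y, merged$n_bouts)
  # total given bouts equal total received bouts (each bout is given by its
  # dominant participant and received by its subordinate participant)
  expect_equal(sum(pg$n_bouts), sum(pr$n_bouts))
})

test_that("feeding proximity uses only feeding scans", {
  scans <- data.frame(group_id = "g1", focal_id = "A", time = 1:40 * 10,
                      feeding = rep(c(1L, 0L), each = 20),
                      neighbor_within_1m = c(rep(1L, 5), rep(0L, 15),
                                             rep(1L, 20)))
  expect_equal(feeding_proximity(scans, "A"), 25)
  none <- scans[scans$feeding == 0L, ]
  expect_true(is.na(feeding_proximity(none, "A")))
  tab <- feeding_proximity(scans, min_scans = 10)
  expect_equal(tab$n_feeding, 20L)
  expect_equal(tab$prox_pct, 25)
})

test_that("composite index z-scores species means and points toward tolerance", {
  prof <- data.frame(
    individual_id = sprintf("i%d", 1:6),
    group_id = sprintf("g%d", 1:6),
    dii = c(0, 1, 2, 0, 1, 2) / 10,
    counter_pct = c(5, 10, 15, 5, 10, 15),
    intensity_pct = c(30, 20, 10, 30, 20, 10))
  meta <- data.frame(group_id = sprintf("g%d", 1:6),
                     species_id = rep(c("s1", "s2", "s3"), 2),
                     group_size = 5)
  idx <- composite_index(prof, meta)
  expect_equal(idx$z_dii, c(-1, 0, 1))
  expect_equal(idx$z_counter, c(-1, 0, 1))
  # intensity decreases with tolerance, so it is negated before z-scoring
  expect_equal(idx$z_intensity, c(-1, 0, 1))
  expect_equal(idx$composite, c(-1, 0, 1))
  expect_lt(abs(mean(idx$z_dii)), 1e-9)
  expect_lt(abs(sd(idx$z_dii) - 1), 1e-9)
})

test_that("composite index matches an independent spreadsheet-style computation", {
  set.seed(55)
  n_sp <- 4
  prof <- expand.grid(sp = 1:n_sp, gr = 1:2, ind = 1:3)
  prof$group_id <- paste0("s", prof$sp, "_g", prof$gr)
  prof$individual_id <- paste0(prof$group_id, "_i", prof$ind)
  prof$dii <- runif(nrow(prof), 0, 0.5)
  prof$counter_pct <- runif(nrow(prof), 0, 60)
  prof$intensity_pct <- runif(nrow(prof), 0, 80)
  meta <- unique(data.frame(group_id = prof$group_id,
                            species_id = paste0("s", prof$sp), group_size = 6))
  idx <- composite_index(prof, meta)
  # independent route: matrix means and scale()
  for (m in c("dii", "counter_pct", "intensity_pct")) {
    gmean <- tapply(prof[[m]], prof$group_id, mean)
    smean <- tapply(gmean, sub("_g.*", "", names(gmean)), mean)
    col <- c(dii = "mean_dii", counter_pct = "mean_counter",
             intensity_pct = "mean_intensity")[[m]]
    expect_equal(idx[[col]], as.numeric(smean[idx$species_id]))
  }
  z <- scale(cbind(idx$mean_dii, idx$mean_counter, -idx$mean_intensity))
  expect_equal(idx$composite, rowMeans(z), ignore_attr = TRUE)
})

test_that("composite index is invariant to positive affine rescaling", {
  set.seed(66)
  prof <- data.frame(individual_id = sprintf("i%d", 1:12),
                     group_id = rep(sprintf("g%d", 1:6), 2),
                     dii = runif(12, 0, 0.5),
                     counter_pct = runif(12, 0, 50),
                     intensity_pct = runif(12, 0, 80))
  meta <- data.frame(group_id = sprintf("g%d", 1:6),
                     species_id = rep(c("s1", "s2", "s3"), each = 2),
                     group_size = 8)
  idx <- composite_index(prof, meta)
  prof2 <- prof
  prof2$dii <- 7.3 * prof$dii + 0.2
  prof2$intensity_pct <- 0.01 * prof$intensity_pct + 5
  idx2 <- composite_index(prof2, meta)
  expect_equal(idx2$composite, idx$composite)
})

test_that("degenerate composite inputs are rejected", {
  prof <- data.frame(individual_id = c("a", "b"), group_id = c("g1", "g2"),
                     dii = c(0.1, 0.1), counter_pct = c(10, 20),
                     intensity_pct = c(30, 40))
  meta <- data.frame(group_id = c("g1", "g2"), species_id = c("s1", "s2"),
                     group_size = 5)
  expect_error(composite_index(prof, meta), "zero cross-species variance in dii")
  expect_error(composite_index(prof[1, ], meta[1, ]), "at least 2 species")
})
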