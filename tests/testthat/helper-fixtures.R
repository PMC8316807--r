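# Fixture builders and independent brute-force oracles.  Oracles are kept
# deliberately naive (per-dyad enumeration, single-linkage clustering,
# whitened OLS) so they share no code path with the implementation.

make_bouts <- function(aggressor, victim, contact = 0L, counter = 0L,
                       decided = 1L, winner = NULL, group = "g1") {
  n <- length(aggressor)
  rec <- function(x) rep_len(x, n)
  winner <- if (is.null(winner)) {
    ifelse(rec(decided) == 1L, aggressor, NA_character_)
  } else rec(winner)
  data.frame(group_id = group, bout_id = sprintf("b%03d", seq_len(n)),
             time = seq_len(n) * 10, aggressor_id = rec(aggressor),
             victim_id = rec(victim), contact = rec(as.integer(contact)),
             counter = rec(as.integer(counter)),
             decided = rec(as.integer(decided)), winner_id = winner,
             stringsAsFactors = FALSE)
}

# random bout table among n_ind individuals; returns validated table
random_bouts <- function(n_ind, n_bouts, p_decided = 0.8) {
  ids <- LETTERS[seq_len(n_ind)]
  pair <- t(replicate(n_bouts, sample(ids, 2)))
  decided <- rbinom(n_bouts, 1, p_decided)
  winner <- ifelse(decided == 1L,
                   ifelse(rbinom(n_bouts, 1, 0.7) == 1L, pair[, 1], pair[, 2]),
                   NA_character_)
  data.frame(group_id = "g1", bout_id = sprintf("b%04d", seq_len(n_bouts)),
             time = seq_len(n_bouts), aggressor_id = pair[, 1],
             victim_id = pair[, 2], contact = rbinom(n_bouts, 1, 0.4),
             counter = rbinom(n_bouts, 1, 0.3), decided = decided,
             winner_id = winner, stringsAsFactors = FALSE)
}

# brute-force win tally: loop over every ordered pair
oracle_tally <- function(bouts, individuals) {
  N <- length(individuals)
  s <- matrix(0L, N, N, dimnames = list(individuals, individuals))
  for (k in seq_len(nrow(bouts))) {
    if (bouts$decided[k] != 1L) next
    w <- bouts$winner_id[k]
    l <- if (w == bouts$aggressor_id[k]) bouts$victim_id[k] else bouts$aggressor_id[k]
    s[w, l] <- s[w, l] + 1L
  }
  s
}

# brute-force tolerance profile for one focal: explicit per-dyad enumeration
oracle_profile <- function(bouts, ranks, focal, direction, min_bouts) {
  nds <- setNames(ranks$normDS, ranks$individual_id)
  others <- setdiff(ranks$individual_id, focal)
  mins <- 0; tot <- 0; counter <- 0; contact <- 0; dyad_diis <- numeric(0)
  for (j in others) {
    keep <- switch(direction,
                   given = nds[j] < nds[focal],
                   received = nds[j] > nds[focal],
                   all = TRUE)
    if (!keep) next
    sel <- (bouts$aggressor_id == focal & bouts$victim_id == j) |
      (bouts$aggressor_id == j & bouts$victim_id == focal)
    b <- bouts[sel, , drop = FALSE]
    if (nrow(b) == 0L) next
    a <- sum(b$aggressor_id == focal)
    mins <- mins + min(a, nrow(b) - a)
    tot <- tot + nrow(b)
    dyad_diis <- c(dyad_diis, min(a, nrow(b) - a) / nrow(b))
    counter <- counter + sum(b$counter)
    contact <- contact + sum(b$contact)
  }
  list(
    dii = if (tot >= min_bouts) mins / tot else NA_real_,
    dii_dyad_mean = if (tot >= min_bouts) mean(dyad_diis) else NA_real_,
    counter_pct = if (tot >= min_bouts) 100 * counter / tot else NA_real_,
    intensity_pct = if (tot >= min_bouts) 100 * contact / tot else NA_real_,
    n_bouts = tot
  )
}

# independent bout count: single-linkage clustering cut at the threshold
oracle_segment <- function(times, ibi) {
  n <- length(times)
  if (n == 0L) return(0L)
  if (n == 1L) return(1L)
  cl <- cutree(hclust(dist(times), method = "single"), h = ibi + 1e-9)
  length(unique(cl))
}

# small self-consistent study for pipeline tests
tiny_study <- function(seed = 11) {
  simulate_study(sim_config(n_species = 4, groups_per_species = 2,
                            individuals_per_group = 5:7, seed = seed))
}
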