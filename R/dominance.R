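## Dominance ranks and dominance-style statistics.
##
## Ranks come from modified David's scores computed on decided bouts only
## (winner determined by the victim fleeing or submitting).  Style measures
## are the directional inconsistency index (DII) of aggression, the
## counteraggression percentage and the aggression-intensity (contact)
## percentage, each computed over dyads with lower-ranking partners
## ("given" tolerance), higher-ranking partners ("received" tolerance), or
## all partners (species-level input).

#' Tally decided bouts into a win matrix
#'
#' @param bouts validated bout table from one group; only decided bouts
#'   contribute.
#' @param individuals optional character vector fixing the individual set
#'   and order; defaults to all individuals appearing in decided bouts,
#'   sorted.
#' @return an object of class `win_matrix`: a list with `individuals`,
#'   `s` (wins of row over column) and `n = s + t(s)`.
#' @export
build_win_matrix <- function(bouts, individuals = NULL) {
  dec <- bouts[bouts$decided == 1L, , drop = FALSE]
  if (nrow(dec) == 0L) stop("rank undeterminable: no decided bouts", call. = FALSE)
  if (is.null(individuals)) {
    individuals <- sort(unique(c(dec$aggressor_id, dec$victim_id)))
  }
  N <- length(individuals)
  s <- matrix(0L, N, N, dimnames = list(individuals, individuals))
  loser <- ifelse(dec$winner_id == dec$aggressor_id, dec$victim_id, dec$aggressor_id)
  keep <- dec$winner_id %in% individuals & loser %in% individuals
  for (k in which(keep)) {
    s[dec$winner_id[k], loser[k]] <- s[dec$winner_id[k], loser[k]] + 1L
  }
  structure(list(individuals = individuals, s = s, n = s + t(s)),
            class = "win_matrix")
}

#' @export
print.win_matrix <- function(x, ...) {
  cat("Win matrix:", length(x$individuals), "individuals,",
      sum(x$s), "decided bouts\n")
  print(x$s)
  invisible(x)
}

#' Modified David's scores from a win matrix
#'
#' Dyadic win proportions `P[i,j] = s[i,j]/n[i,j]` are corrected for the
#' number of interactions, `D[i,j] = P[i,j] - (P[i,j] - 0.5)/(n[i,j] + 1)`
#' (0 for unobserved dyads), and combined as
#' `DS_i = w1_i + w2_i - l1_i - l2_i` with `w1 = rowSums(D)`,
#' `w2 = D %*% w1`, `l1 = colSums(D)`, `l2 = t(D) %*% l1`.  The normalized
#' score `normDS = (DS + N(N-1)/2)/N` lies in `[0, N-1]` with mean
#' `(N-1)/2`; scores sum to zero.
#'
#' @param w a `win_matrix`.
#' @return data frame with columns `individual_id`, `DS`, `normDS`.
#' @export
modified_davids_score <- function(w) {
  N <- length(w$individuals)
  if (N < 2L) stop("modified David's score requires at least 2 individuals", call. = FALSE)
  P <- ifelse(w$n > 0, w$s / ifelse(w$n > 0, w$n, 1), 0)
  D <- ifelse(w$n > 0, P - (P - 0.5) / (w$n + 1), 0)
  w1 <- rowSums(D)
  l1 <- colSums(D)
  w2 <- as.vector(D %*% w1)
  l2 <- as.vector(t(D) %*% l1)
  DS <- w1 + w2 - l1 - l2
  data.frame(individual_id = w$individuals,
             DS = DS,
             normDS = (DS + N * (N - 1) / 2) / N,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Ordinal ranks from normalized David's scores
#'
#' Rank 1 is the highest `normDS`; exact ties are broken by identifier
#' (lexicographic) and flagged in the `tied` column.
#'
#' @param rt data frame from [modified_davids_score()].
#' @return the same table with `rank` and `tied` columns appended, sorted
#'   by rank.
#' @export
assign_ranks <- function(rt) {
  o <- order(-rt$normDS, rt$individual_id)
  rt <- rt[o, , drop = FALSE]
  rt$rank <- seq_len(nrow(rt))
  rt$tied <- duplicated(rt$normDS) | duplicated(rt$normDS, fromLast = TRUE)
  rownames(rt) <- NULL
  rt
}

#' @rdname modified_davids_score
#' @param bouts validated bout table from one group.
#' @param individuals optional fixed individual set, see [build_win_matrix()].
#' @export
davids_ranks <- function(bouts, individuals = NULL) {
  assign_ranks(modified_davids_score(build_win_matrix(bouts, individuals)))
}

#' Directional inconsistency index of one dyad
#'
#' The proportion of the dyad's bouts (decided or not) in which the roles
#' of aggressor and victim occurred in the less frequent direction:
#' `min(a, b)/(a + b)` for directed counts `a`, `b`.  0 means fully
#' one-sided aggression, 0.5 maximal symmetry.
#'
#' @param bouts bout table containing only bouts between two individuals.
#' @return a proportion in `[0, 0.5]`.
#' @export
dyad_dii <- function(bouts) {
  if (nrow(bouts) == 0L) stop("dyad_dii: no bouts supplied", call. = FALSE)
  ids <- unique(c(bouts$aggressor_id, bouts$victim_id))
  if (length(ids) != 2L) {
    stop("dyad_dii: bouts must involve exactly two individuals", call. = FALSE)
  }
  a <- sum(bouts$aggressor_id == ids[1])
  b <- nrow(bouts) - a
  min(a, b) / (a + b)
}

#' Individual tolerance profiles over rank-restricted dyads
#'
#' For each ranked individual, bouts are restricted to dyads with
#' lower-ranking partners (`direction = "given"`, tolerance the focal
#' gives), higher-ranking partners (`"received"`), or all partners
#' (`"all"`, the unrestricted measure used for the species-level index).
#' Partners tied on `normDS` belong to neither the given nor the received
#' set.  Over the restricted bouts three measures are computed:
#'
#' * `dii` — pooled directional inconsistency `sum(min(a_d, b_d)) /
#'   sum(a_d + b_d)` over dyads `d` (`dii_mode = "bout_weighted"`, the
#'   default), or the unweighted mean of dyadic DIIs (`"dyad_mean"`);
#' * `counter_pct` — percent of bouts in which the victim retaliated;
#' * `intensity_pct` — percent of bouts in which the aggressor used
#'   physical contact.
#'
#' A measure is `NA` when its denominator is below `min_bouts`.
#'
#' @param bouts validated bout table from one group.
#' @param ranks rank table from [davids_ranks()]; must cover every
#'   individual appearing in `bouts`.
#' @param direction `"given"`, `"received"` or `"all"`.
#' @param min_bouts minimum number of restricted bouts backing a measure.
#' @param dii_mode aggregation of dyadic DIIs, see above.
#' @param initiator_only if `TRUE`, counteraggression and intensity use
#'   only bouts initiated by the focal; by default all bouts within the
#'   restricted dyads count.
#' @return data frame with one row per ranked individual: `individual_id`,
#'   `direction`, `dii`, `counter_pct`, `intensity_pct`, `n_bouts` (DII
#'   denominator) and `n_bouts_ci` (counter/intensity denominator).
#' @export
tolerance_profile <- function(bouts, ranks,
                              direction = c("given", "received", "all"),
                              min_bouts = 10,
                              dii_mode = c("bout_weighted", "dyad_mean"),
                              initiator_only = FALSE) {
  direction <- match.arg(direction)
  dii_mode <- match.arg(dii_mode)
  in_bouts <- unique(c(bouts$aggressor_id, bouts$victim_id))
  unranked <- setdiff(in_bouts, ranks$individual_id)
  if (length(unranked) > 0L) {
    stop("tolerance_profile: unranked individual(s) in bouts: ",
         paste(unranked, collapse = ", "), call. = FALSE)
  }
  nds <- setNames(ranks$normDS, ranks$individual_id)
  out <- lapply(ranks$individual_id, function(focal) {
    partners <- switch(direction,
                       given    = names(nds)[nds < nds[focal]],
                       received = names(nds)[nds > nds[focal]],
                       all      = setdiff(names(nds), focal))
    sel <- (bouts$aggressor_id == focal & bouts$victim_id %in% partners) |
      (bouts$victim_id == focal & bouts$aggressor_id %in% partners)
    b <- bouts[sel, , drop = FALSE]
    n <- nrow(b)
    if (n > 0L) {
      partner <- ifelse(b$aggressor_id == focal, b$victim_id, b$aggressor_id)
      init <- tapply(b$aggressor_id == focal, partner, sum)
      tot <- tapply(rep(1L, n), partner, sum)
      mins <- pmin(init, tot - init)
      dii <- if (n >= min_bouts) {
        if (dii_mode == "bout_weighted") sum(mins) / sum(tot) else mean(mins / tot)
      } else NA_real_
    } else {
      dii <- NA_real_
    }
    bc <- if (initiator_only) b[b$aggressor_id == focal, , drop = FALSE] else b
    nci <- nrow(bc)
    counter <- if (nci >= min_bouts) 100 * mean(bc$counter) else NA_real_
    intensity <- if (nci >= min_bouts) 100 * mean(bc$contact) else NA_real_
    data.frame(individual_id = focal, direction = direction, dii = dii,
               counter_pct = counter, intensity_pct = intensity,
               n_bouts = n, n_bouts_ci = nci, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Feeding-proximity tolerance from instantaneous scans
#'
#' Percent of an individual's feeding scans in which its nearest neighbour
#' was an independent individual within 1 m.  Missing when the individual
#' has fewer than `min_scans` feeding scans.  Non-feeding scans never
#' contribute.
#'
#' @param scans validated scan table from one group.
#' @param focal_id optionally a single focal; if `NULL` a table for all
#'   focals appearing in `scans` is returned.
#' @param min_scans minimum number of feeding scans backing the measure.
#' @return a single percent (with `focal_id`) or a data frame with
#'   `focal_id`, `n_feeding`, `prox_pct`.
#' @export
feeding_proximity <- function(scans, focal_id = NULL, min_scans = 10) {
  one <- function(id) {
    f <- scans[scans$focal_id == id & scans$feeding == 1L, , drop = FALSE]
    if (nrow(f) < min_scans) NA_real_ else 100 * mean(f$neighbor_within_1m)
  }
  if (!is.null(focal_id)) return(one(focal_id))
  ids <- sort(unique(scans$focal_id))
  data.frame(focal_id = ids,
             n_feeding = vapply(ids, function(id) {
               sum(scans$focal_id == id & scans$feeding == 1L)
             }, integer(1)),
             prox_pct = vapply(ids, one, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Species-level composite dominance-style index
#'
#' Aggregates individual aggression-based style measures to a single index
#' per species: (i) mean over the individuals of each group, (ii) mean over
#' the groups of each species, (iii) cross-species z-scores of the three
#' measures (sample SD), and (iv) the mean of the three z-scores.  Before
#' z-scoring, aggression intensity is negated so that all three components
#' increase with tolerance: positive index values indicate a tolerant
#' dominance style, negative values a despotic one.
#'
#' @param profiles individual profile table (typically
#'   `tolerance_profile(..., direction = "all")` stacked over groups) with
#'   columns `individual_id`, `group_id`, `dii`, `counter_pct`,
#'   `intensity_pct`.
#' @param group_meta validated group metadata mapping `group_id` to
#'   `species_id`.
#' @return data frame with one row per species: raw species means, their
#'   z-scores (`z_intensity` of the negated measure) and `composite`, the
#'   mean of the three z-scores.  Species missing any measure are excluded
#'   with a message; fewer than 2 complete species is an error, as is a
#'   measure with zero cross-species variance.
#' @export
composite_index <- function(profiles, group_meta) {
  profiles <- merge(profiles, group_meta[c("group_id", "species_id")], by = "group_id")
  gm <- aggregate(profiles[c("dii", "counter_pct", "intensity_pct")],
                  by = profiles[c("group_id", "species_id")],
                  FUN = function(x) mean(x, na.rm = TRUE))
  sm <- aggregate(gm[c("dii", "counter_pct", "intensity_pct")],
                  by = gm["species_id"],
                  FUN = function(x) mean(x, na.rm = TRUE))
  names(sm) <- c("species_id", "mean_dii", "mean_counter", "mean_intensity")
  complete <- complete.cases(sm) & is.finite(sm$mean_dii) &
    is.finite(sm$mean_counter) & is.finite(sm$mean_intensity)
  if (any(!complete)) {
    message("composite_index: excluding species with missing measures: ",
            paste(sm$species_id[!complete], collapse = ", "))
    sm <- sm[complete, , drop = FALSE]
  }
  if (nrow(sm) < 2L) {
    stop("composite_index requires at least 2 species with complete measures",
         call. = FALSE)
  }
  zcol <- function(x, name) {
    s <- sd(x)
    if (s == 0) stop("composite_index: zero cross-species variance in ", name,
                     call. = FALSE)
    (x - mean(x)) / s
  }
  sm$z_dii <- zcol(sm$mean_dii, "dii")
  sm$z_counter <- zcol(sm$mean_counter, "counteraggression")
  sm$z_intensity <- zcol(-sm$mean_intensity, "intensity")
  sm$composite <- (sm$z_dii + sm$z_counter + sm$z_intensity) / 3
  rownames(sm) <- NULL
  sm
}
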