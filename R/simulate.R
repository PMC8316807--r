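## Synthetic-study generator with known ground truth.
##
## Each species carries a latent tolerance tau in [-1, 1]; individuals
## deviate around it (tau_i = tau_s + N(0, sigma_tau_ind), clamped), so
## dominance style varies both between and within species.  Tolerance
## drives: the probability that a bout within a dyad is initiated by the
## subordinate (p_up, from the dominant partner's tau, since tolerance is
## "given" by the dominant), counteraggression and contact probabilities,
## feeding proximity, and the species repertoire of hierarchy-related
## calls (rate declining in tau).  Vocal-bout rates follow the mixed model
## the estimator assumes, with the individual's *expected* given-DII as
## the true predictor, so fitting the realized (measured) DII carries
## measurement error exactly as in a real study.

.clamp <- function(x, lo, hi) pmin(hi, pmax(lo, x))

p_up_fun <- function(tau) .clamp(0.05 + 0.20 * (tau + 1), 0, 1)
p_counter_fun <- function(tau) .clamp(0.05 + 0.25 * (tau + 1), 0, 1)
p_contact_fun <- function(tau) .clamp(0.60 - 0.25 * (tau + 1), 0, 1)
p_near_fun <- function(tau) .clamp(0.1 + 0.3 * (tau + 1) / 2, 0, 1)

#' Configuration for [simulate_study()]
#'
#' Defaults describe a medium-sized multi-site comparative study: 16
#' species, 2-3 groups each, 6-15 individuals per group, a mean of 8
#' aggression bouts per dyad, and a vocal-rate model
#' `log10(rate) = 0.3 + 0.42 * E(given DII) + u_species + u_group + e`
#' with SDs 0.25 / 0.20 / 0.15.
#'
#' @param n_species number of species.
#' @param groups_per_species,individuals_per_group integer ranges sampled
#'   uniformly per species / group.
#' @param tau optional fixed per-species tolerance in `[-1, 1]`; drawn
#'   uniform by default.
#' @param sigma_tau_ind SD of the individual tolerance deviation around
#'   the species value (clamped back to `[-1, 1]`).
#' @param bouts_per_dyad Poisson mean of bouts per dyad.
#' @param p_decided probability a bout has a clear winner.
#' @param p_winner_aggressor probability the aggressor wins a decided bout.
#' @param beta0,beta1 intercept and expected-given-DII slope of the
#'   log10 vocal-rate model.
#' @param sigma_species,sigma_group,sigma_resid random-effect and residual
#'   SDs of the vocal-rate model.
#' @param focal_hours range (hours) of focal observation per individual.
#' @param feeding_scans integer range of feeding scans per individual.
#' @param explode_bouts if `TRUE` each generated vocal bout is emitted as
#'   1-4 calls less than 30 s apart, exercising bout segmentation.
#' @param phylo_species_effects if `TRUE`, species intercepts are drawn
#'   MVN(0, sigma_species^2 * C) from the simulated tree (scaled to unit
#'   diagonal) instead of independently.
#' @param birth_rate,tree_height Yule birth rate (1/Myr) and the height
#'   (Myr) the tree is rescaled to.
#' @param repertoire_hier_intercept,repertoire_hier_slope hierarchy-call
#'   counts are Poisson with log mean `intercept + slope * tau`.
#' @param repertoire_extra_log log mean of the non-hierarchy call count.
#' @param seed integer seed; the full bundle is reproducible given it.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_species = 16,
                       groups_per_species = 2:3,
                       individuals_per_group = 6:15,
                       tau = NULL,
                       sigma_tau_ind = 0.5,
                       bouts_per_dyad = 8,
                       p_decided = 0.8,
                       p_winner_aggressor = 0.9,
                       beta0 = 0.3, beta1 = 0.42,
                       sigma_species = 0.25, sigma_group = 0.2,
                       sigma_resid = 0.15,
                       focal_hours = c(2, 10),
                       feeding_scans = c(30, 100),
                       explode_bouts = TRUE,
                       phylo_species_effects = FALSE,
                       birth_rate = 0.2, tree_height = 40,
                       repertoire_hier_intercept = 1.5,
                       repertoire_hier_slope = -0.6,
                       repertoire_extra_log = 2.2,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_species >= 2, all(cfg$individuals_per_group >= 2))
  if (!is.null(tau)) stopifnot(length(tau) == n_species, all(abs(tau) <= 1))
  structure(cfg, class = "sim_config")
}

#' Expected pooled directional inconsistency index
#'
#' The expectation of `min(a, b)/(a + b)` pooled over dyads when the
#' subordinate initiates each bout independently with probability `p` and
#' dyadic bout counts are Poisson(`mean_bouts`) truncated at 1, computed
#' as `E[min(B, n - B)] / E[n]` by exact enumeration.  This is the
#' generator's ground-truth given-DII for an individual with
#' subordinate-initiation probability `p`.
#'
#' @param p subordinate-initiation probability (vectorized).
#' @param mean_bouts Poisson mean of bouts per dyad.
#' @return expected pooled DII, same length as `p`.
#' @export
expected_dii <- function(p, mean_bouts = 8) {
  nmax <- max(2, qpois(1 - 1e-10, mean_bouts))
  wn <- dpois(1:nmax, mean_bouts)
  wn <- wn / sum(wn)
  vapply(p, function(pp) {
    emin <- vapply(1:nmax, function(n) {
      b <- 0:n
      sum(dbinom(b, n, pp) * pmin(b, n - b))
    }, numeric(1))
    sum(wn * emin) / sum(wn * (1:nmax))
  }, numeric(1))
}

#' Simulate an ultrametric Yule phylogeny
#'
#' A pure-birth tree rescaled so all root-to-tip depths equal
#' `height` Myr.
#'
#' @param n_species number of tips.
#' @param birth_rate Yule speciation rate per Myr.
#' @param height tree height in Myr.
#' @param tip_labels optional tip labels (default `sp01`, `sp02`, ...).
#' @return an `ape::phylo` tree.
#' @export
simulate_tree <- function(n_species, birth_rate = 0.2, height = 40,
                          tip_labels = NULL) {
  stopifnot(n_species >= 2)
  tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
  depths <- ape::node.depth.edgelength(tree)
  tree$edge.length <- tree$edge.length * height / max(depths)
  tree$tip.label <- if (is.null(tip_labels)) {
    sprintf("sp%02d", seq_len(n_species))
  } else tip_labels
  tree
}

#' Simulate a complete synthetic study with known ground truth
#'
#' Generates species, groups, individuals, directed aggression bouts,
#' feeding-proximity scans, focal sessions, vocal events, species
#' repertoires and an ultrametric phylogeny, all drawn from the
#' statistical structure the downstream estimators assume.  Every table
#' passes the package validators, and the bundle is byte-reproducible
#' given `cfg$seed`.
#'
#' Within each group, individuals are ordered by latent ability (index 1
#' dominant); for each dyad the dominant partner's individual tolerance
#' sets the probability that a bout is initiated upward by the
#' subordinate.  By construction the species-level slope of
#' log-hierarchy-call counts on the composite index is negative, and the
#' individual-level effect of expected given-DII on log10 vocal rate is
#' `cfg$beta1`.
#'
#' @param cfg a [sim_config()].
#' @return a list of class `sim_study` with the six tables, `tree`, and
#'   `truth` (species and individual ground-truth tables plus the model
#'   parameters).
#' @export
simulate_study <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  S <- cfg$n_species
  species_id <- sprintf("sp%02d", 1:S)
  tau_s <- if (is.null(cfg$tau)) runif(S, -1, 1) else cfg$tau
  tree <- simulate_tree(S, cfg$birth_rate, cfg$tree_height, species_id)

  if (cfg$phylo_species_effects) {
    C <- phylo_covariance(tree, species_id, lambda = 1)
    C <- C / mean(diag(C))
    L <- chol(C)
    u_sp <- as.vector(t(L) %*% rnorm(S)) * cfg$sigma_species
  } else {
    u_sp <- rnorm(S, 0, cfg$sigma_species)
  }

  bouts <- list(); scans <- list(); sessions <- list(); events <- list()
  groups <- list(); ind_truth <- list()
  bn <- 0L

  for (s in 1:S) {
    ngr <- sample(cfg$groups_per_species, 1)
    for (g in 1:ngr) {
      gid <- sprintf("%s_g%d", species_id[s], g)
      m <- sample(cfg$individuals_per_group, 1)
      if (m < 2L) stop("simulate_study: group with fewer than 2 individuals",
                       call. = FALSE)
      ids <- sprintf("%s_i%02d", gid, 1:m)  # index 1 = top latent ability
      tau_i <- .clamp(tau_s[s] + rnorm(m, 0, cfg$sigma_tau_ind), -1, 1)
      u_g <- rnorm(1, 0, cfg$sigma_group)
      groups[[gid]] <- data.frame(group_id = gid, species_id = species_id[s],
                                  group_size = m, stringsAsFactors = FALSE)

      ## aggression bouts, one dyad at a time (i dominant over j)
      gb <- list()
      for (i in 1:(m - 1)) {
        for (j in (i + 1):m) {
          nb <- rpois(1, cfg$bouts_per_dyad)
          if (nb == 0L) next
          up <- rbinom(nb, 1, p_up_fun(tau_i[i]))
          decided <- rbinom(nb, 1, cfg$p_decided)
          agg_wins <- rbinom(nb, 1, cfg$p_winner_aggressor)
          aggressor <- ifelse(up == 1L, ids[j], ids[i])
          victim <- ifelse(up == 1L, ids[i], ids[j])
          winner <- ifelse(decided == 1L,
                           ifelse(agg_wins == 1L, aggressor, victim),
                           NA_character_)
          gb[[length(gb) + 1L]] <- data.frame(
            group_id = gid, bout_id = NA_character_, time = NA_real_,
            aggressor_id = aggressor, victim_id = victim,
            contact = rbinom(nb, 1, p_contact_fun(tau_s[s])),
            counter = rbinom(nb, 1, p_counter_fun(tau_s[s])),
            decided = decided, winner_id = winner, stringsAsFactors = FALSE)
        }
      }
      if (length(gb) > 0L) {
        gb <- do.call(rbind, gb)
        gb <- gb[sample.int(nrow(gb)), , drop = FALSE]
        gb$time <- seq_len(nrow(gb)) * 60
        gb$bout_id <- sprintf("%s_b%04d", gid, seq_len(nrow(gb)))
        bn <- bn + nrow(gb)
        bouts[[gid]] <- gb
      }

      ## vocal model: truth predictor is the expected given-DII of tau_i
      x_true <- expected_dii(p_up_fun(tau_i), cfg$bouts_per_dyad)
      log_rate <- cfg$beta0 + cfg$beta1 * x_true + u_sp[s] + u_g +
        rnorm(m, 0, cfg$sigma_resid)
      rate <- 10^log_rate
      hours <- runif(m, cfg$focal_hours[1], cfg$focal_hours[2])

      gsess <- list(); gev <- list()
      t0 <- 0
      for (k in 1:m) {
        nses <- sample(2:4, 1)
        w <- runif(nses, 0.5, 1.5)
        dur <- hours[k] * w / sum(w)
        st <- numeric(nses)
        for (q in 1:nses) {
          st[q] <- t0
          t0 <- t0 + dur[q] * 3600 + 600
        }
        gsess[[k]] <- data.frame(group_id = gid, focal_id = ids[k],
                                 start = st, duration = dur,
                                 stringsAsFactors = FALSE)
        nb <- rpois(1, rate[k] * hours[k])
        if (nb > 0L) {
          ses <- sample.int(nses, nb, replace = TRUE, prob = dur)
          ev <- numeric(0)
          for (b in seq_len(nb)) {
            span <- dur[ses[b]] * 3600
            onset <- st[ses[b]] + runif(1, 0, max(1, span - 120))
            calls <- if (cfg$explode_bouts) sample(1:4, 1) else 1L
            tt <- onset + cumsum(c(0, runif(max(0, calls - 1), 1, 29)))
            ev <- c(ev, pmin(tt, st[ses[b]] + span))
          }
          gev[[k]] <- data.frame(group_id = gid, focal_id = ids[k],
                                 time = sort(ev), stringsAsFactors = FALSE)
        }
      }
      sessions[[gid]] <- do.call(rbind, gsess)
      if (length(gev) > 0L) events[[gid]] <- do.call(rbind, gev)

      ## feeding-proximity scans (plus non-feeding scans, never counted)
      gs <- list()
      ts0 <- 0
      for (k in 1:m) {
        nf <- sample(cfg$feeding_scans[1]:cfg$feeding_scans[2], 1)
        nn <- sample(10:40, 1)
        feeding <- c(rep(1L, nf), rep(0L, nn))
        near <- rbinom(nf + nn, 1, p_near_fun(tau_s[s]))
        gs[[k]] <- data.frame(group_id = gid, focal_id = ids[k],
                              time = ts0 + seq_len(nf + nn) * 300,
                              feeding = feeding, neighbor_within_1m = near,
                              stringsAsFactors = FALSE)
        ts0 <- ts0 + (nf + nn) * 300 + 300
      }
      scans[[gid]] <- do.call(rbind, gs)

      ind_truth[[gid]] <- data.frame(
        individual_id = ids, group_id = gid, species_id = species_id[s],
        latent_rank = 1:m, tau = tau_i, p_up = p_up_fun(tau_i),
        expected_given_dii = x_true, u_group = u_g,
        true_log10_rate = log_rate, stringsAsFactors = FALSE)
    }
  }

  hier_rate <- exp(cfg$repertoire_hier_intercept + cfg$repertoire_hier_slope * tau_s)
  hier <- rpois(S, hier_rate)
  extra <- rpois(S, exp(cfg$repertoire_extra_log))
  repertoires <- data.frame(species_id = species_id,
                            total_calls = hier + extra,
                            hierarchy_calls = hier, stringsAsFactors = FALSE)

  study <- list(
    bouts = do.call(rbind, unname(bouts)),
    scans = do.call(rbind, unname(scans)),
    sessions = do.call(rbind, unname(sessions)),
    vocal_events = do.call(rbind, unname(events)),
    groups = do.call(rbind, unname(groups)),
    repertoires = repertoires,
    tree = tree,
    truth = list(
      species = data.frame(species_id = species_id, tau = tau_s,
                           u_species = u_sp, hier_rate = hier_rate,
                           stringsAsFactors = FALSE),
      individuals = do.call(rbind, unname(ind_truth)),
      params = list(beta0 = cfg$beta0, beta1 = cfg$beta1,
                    sigma_species = cfg$sigma_species,
                    sigma_group = cfg$sigma_group,
                    sigma_resid = cfg$sigma_resid,
                    sigma_tau_ind = cfg$sigma_tau_ind,
                    seed = cfg$seed)
    ),
    config = cfg
  )
  rownames(study$bouts) <- rownames(study$scans) <- rownames(study$sessions) <-
    rownames(study$vocal_events) <- rownames(study$groups) <- NULL
  if (!is.null(study$vocal_events)) rownames(study$vocal_events) <- NULL
  class(study) <- c("sim_study", "list")
  study
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Synthetic study:",
      nrow(x$truth$species), "species,",
      nrow(x$groups), "groups,",
      nrow(x$truth$individuals), "individuals\n")
  cat(sprintf("  %d aggression bouts, %d scans, %d vocal events; seed %d\n",
              nrow(x$bouts), nrow(x$scans),
              if (is.null(x$vocal_events)) 0L else nrow(x$vocal_events),
              x$config$seed))
  invisible(x)
}

#' Parameter-recovery summary against ground truth
#'
#' Compares a fitted individual-level model and a species-level PGLS fit
#' with the generating truth of a simulated study: bias and credible
#' interval coverage of the expected-given-DII effect, and sign agreement
#' of the hierarchy-calls-on-composite-index slope (true sign negative:
#' the hierarchy-call rate declines with tolerance).
#'
#' @param truth the `truth` element of a [simulate_study()] bundle.
#' @param lmm_fit a `vocal_lmm` fit whose second coefficient is the
#'   aggression-symmetry (DII) effect, or `NULL`.
#' @param pgls_fit_obj a `pgls` fit of log hierarchy calls on the
#'   composite index (slope = second coefficient), or `NULL`.
#' @return a data frame with one row per checked parameter: estimate,
#'   truth, bias, and a coverage/sign flag.
#' @export
truth_report <- function(truth, lmm_fit = NULL, pgls_fit_obj = NULL) {
  rows <- list()
  if (!is.null(lmm_fit)) {
    co <- lmm_fit$coefficients
    i <- grep("dii", co$term, ignore.case = TRUE)[1]
    if (is.na(i)) i <- 2L
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = "beta_given_dii", estimate = co$post_mean[i],
      truth = truth$params$beta1, bias = co$post_mean[i] - truth$params$beta1,
      ok = co$ci_lower[i] <= truth$params$beta1 &
        truth$params$beta1 <= co$ci_upper[i],
      check = "95% CI covers truth", stringsAsFactors = FALSE)
  }
  if (!is.null(pgls_fit_obj)) {
    slope <- pgls_fit_obj$coefficients$beta[2]
    rows[[length(rows) + 1L]] <- data.frame(
      parameter = "pgls_hierarchy_slope", estimate = slope,
      truth = NA_real_, bias = NA_real_,
      ok = slope < 0, check = "negative sign", stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
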