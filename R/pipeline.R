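## End-to-end orchestration: from validated tables to the individual-level
## mixed models and the species-level PGLS models, with an exclusion log at
## every filter so differing per-model sample sizes are auditable.

#' Pipeline configuration
#'
#' @param min_bouts minimum restricted bouts backing each tolerance
#'   measure (default 10).
#' @param min_decided minimum decided bouts per individual for ranking
#'   (default 3).
#' @param min_scans minimum feeding scans for the proximity measure.
#' @param ibi inter-bout interval (s) for vocal-bout segmentation.
#' @param min_focal_hours minimum focal observation (h) for inclusion.
#' @param offset log10 offset for zero vocal rates (bouts/h).
#' @param lambda fixed Pagel's lambda of the PGLS models.
#' @param log_offset offset inside the log10 repertoire transform.
#' @param dii_mode,initiator_only see [tolerance_profile()].
#' @param chain a [chain_config()] used for every mixed model; per-model
#'   seeds are derived from `seed`.
#' @param seed integer master seed recorded in all outputs.
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_bouts = 10, min_decided = 3, min_scans = 10,
                            ibi = 30, min_focal_hours = 2, offset = 0.01,
                            lambda = 1, log_offset = 1,
                            dii_mode = "bout_weighted", initiator_only = FALSE,
                            chain = chain_config(), seed = 1) {
  structure(as.list(environment()), class = "pipeline_config")
}

.log_add <- function(log, stage, id, reason) {
  rbind(log, data.frame(stage = stage, id = id, reason = reason,
                        stringsAsFactors = FALSE))
}

## Shared derivation of the per-individual analysis table.
prepare_individual_table <- function(study, config = pipeline_config()) {
  log <- data.frame(stage = character(), id = character(), reason = character(),
                    stringsAsFactors = FALSE)
  groups <- validate_group_meta(study$groups)
  bouts <- validate_bouts(study$bouts)
  sessions <- validate_sessions(study$sessions)
  events <- validate_vocal_events(study$vocal_events, NULL)
  scans <- validate_scans(study$scans)

  prof_g <- list(); prof_r <- list(); prof_a <- list()
  ranks_all <- list(); wins <- list()
  for (gid in groups$group_id) {
    gb <- bouts[bouts$group_id == gid, , drop = FALSE]
    if (nrow(gb[gb$decided == 1L, ]) == 0L) {
      log <- .log_add(log, "ranking", gid, "no decided bouts in group")
      next
    }
    dec <- gb[gb$decided == 1L, ]
    cnt <- table(c(dec$aggressor_id, dec$victim_id))
    keep <- names(cnt)[cnt >= config$min_decided]
    dropped <- setdiff(names(cnt), keep)
    for (id in dropped) {
      log <- .log_add(log, "ranking", id,
                      sprintf("fewer than %d decided bouts", config$min_decided))
    }
    if (length(keep) < 2L) {
      log <- .log_add(log, "ranking", gid, "fewer than 2 rankable individuals")
      next
    }
    gb_r <- gb[gb$aggressor_id %in% keep & gb$victim_id %in% keep, , drop = FALSE]
    w <- build_win_matrix(gb_r, individuals = sort(keep))
    ranks <- davids_ranks(gb_r, individuals = sort(keep))
    wins[[gid]] <- w
    ranks$group_id <- gid
    ranks_all[[gid]] <- ranks
    args <- list(bouts = gb_r, ranks = ranks, min_bouts = config$min_bouts,
                 dii_mode = config$dii_mode,
                 initiator_only = config$initiator_only)
    pg <- do.call(tolerance_profile, c(args, direction = "given"))
    pr <- do.call(tolerance_profile, c(args, direction = "received"))
    pa <- do.call(tolerance_profile, c(args, direction = "all"))
    pg$group_id <- pr$group_id <- pa$group_id <- gid
    prof_g[[gid]] <- pg; prof_r[[gid]] <- pr; prof_a[[gid]] <- pa
  }
  if (length(ranks_all) == 0L) stop("no rankable groups", call. = FALSE)

  prox <- feeding_proximity(scans, min_scans = config$min_scans)
  rates <- vocal_rate(events, sessions, ibi = config$ibi,
                      min_hours = config$min_focal_hours)
  for (i in which(!rates$included)) {
    log <- .log_add(log, "vocal_rate", rates$focal_id[i],
                    sprintf("only %.2f h focal observation (minimum %g h)",
                            rates$obs_hours[i], config$min_focal_hours))
  }

  tab <- rates[rates$included, c("focal_id", "group_id", "n_bouts",
                                 "obs_hours", "rate")]
  names(tab)[1] <- "individual_id"
  tab <- merge(tab, groups[c("group_id", "species_id", "group_size")],
               by = "group_id")
  rn <- function(p, pre) {
    p <- p[c("individual_id", "group_id", "dii", "counter_pct", "intensity_pct")]
    names(p)[3:5] <- paste0(pre, c("dii", "counter", "intensity"))
    p
  }
  tab <- merge(tab, rn(do.call(rbind, prof_g), "given_"),
               by = c("individual_id", "group_id"), all.x = TRUE)
  tab <- merge(tab, rn(do.call(rbind, prof_r), "received_"),
               by = c("individual_id", "group_id"), all.x = TRUE)
  tab <- merge(tab, prox[c("focal_id", "prox_pct")],
               by.x = "individual_id", by.y = "focal_id", all.x = TRUE)
  tab$log_rate <- prepare_response(tab$rate, config$offset)
  list(table = tab,
       profiles_all = do.call(rbind, prof_a),
       ranks = do.call(rbind, ranks_all),
       win_matrices = wins,
       rates = rates, prox = prox, log = log, groups = groups)
}

.fit_one <- function(tab, predictors, label, config, seed_offset, log) {
  keep <- complete.cases(tab[predictors])
  excl <- tab$individual_id[!keep]
  for (id in excl) {
    log <- .log_add(log, paste0("model_", label), id,
                    "missing tolerance measure(s)")
  }
  d <- tab[keep, , drop = FALSE]
  if (length(unique(d$species_id)) < 2L) {
    stop("model ", label, ": fewer than 2 species after exclusions",
         call. = FALSE)
  }
  ch <- config$chain
  ch$seed <- config$seed + seed_offset
  f <- as.formula(paste("log_rate ~", paste(predictors, collapse = " + ")))
  fit <- fit_lmm(f, d, species = "species_id", group = "group_id",
                 chain = ch)
  fit$n_used <- c(individuals = nrow(d),
                  groups = length(unique(d$group_id)),
                  species = length(unique(d$species_id)))
  list(fit = fit, log = log)
}

#' Fit the three individual-level vocal-rate models
#'
#' Model `given`: the three given-tolerance measures (aggression DII,
#' counteraggression, aggression intensity) plus group size; `received`:
#' the received-tolerance versions; `feeding`: feeding proximity plus
#' group size.  Responses are log10 vocal-bout rates of individuals with
#' at least the minimum focal observation time; every exclusion is
#' logged.
#'
#' @param study a study bundle ([simulate_study()] or [load_study()]).
#' @param config a [pipeline_config()].
#' @return a list with elements `given`, `received`, `feeding`
#'   (`vocal_lmm` fits), the per-individual `table`, and the exclusion
#'   `log`.
#' @export
run_individual <- function(study, config = pipeline_config()) {
  prep <- prepare_individual_table(study, config)
  log <- prep$log
  r1 <- .fit_one(prep$table, c("given_dii", "given_counter", "given_intensity",
                               "group_size"), "given", config, 1L, log)
  r2 <- .fit_one(prep$table, c("received_dii", "received_counter",
                               "received_intensity", "group_size"),
                 "received", config, 2L, r1$log)
  r3 <- .fit_one(prep$table, c("prox_pct", "group_size"), "feeding",
                 config, 3L, r2$log)
  list(given = r1$fit, received = r2$fit, feeding = r3$fit,
       table = prep$table, log = r3$log)
}

#' Fit the species-level PGLS repertoire models
#'
#' Builds the composite dominance-style index (from unrestricted
#' individual profiles), joins it with mean group size and the repertoire
#' counts, and fits five fixed-lambda PGLS models: log10 total repertoire
#' and log10 hierarchy-related calls on the composite index plus group
#' size, and three single-measure follow-ups of hierarchy calls on each
#' raw style measure plus group size (plus a group-size-only model).
#'
#' @inheritParams run_individual
#' @return a list with the `index`, the joined `species` table, the `pgls`
#'   fits (`total`, `hierarchy`, `dii`, `counter`, `intensity`,
#'   `group_size`) and the exclusion `log`.
#' @export
run_species <- function(study, config = pipeline_config()) {
  prep <- prepare_individual_table(study, config)
  log <- prep$log
  idx <- composite_index(prep$profiles_all, prep$groups)
  dropped <- setdiff(prep$groups$species_id, idx$species_id)
  for (sp in dropped) {
    log <- .log_add(log, "composite_index", sp, "missing species-level measure")
  }
  st <- species_table(idx, study$repertoires, prep$groups,
                      log_offset = config$log_offset)
  missing_tips <- setdiff(st$species_id, study$tree$tip.label)
  if (length(missing_tips) > 0L) {
    stop("species absent from the tree: ", paste(missing_tips, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(st) < 3L) stop("fewer than 3 species with complete rows", call. = FALSE)
  lam <- config$lambda
  fits <- list(
    total = pgls(log_total ~ composite + group_size, st, study$tree, lam),
    hierarchy = pgls(log_hierarchy ~ composite + group_size, st, study$tree, lam),
    dii = pgls(log_hierarchy ~ mean_dii + group_size, st, study$tree, lam),
    counter = pgls(log_hierarchy ~ mean_counter + group_size, st, study$tree, lam),
    intensity = pgls(log_hierarchy ~ mean_intensity + group_size, st,
                     study$tree, lam),
    group_size = pgls(log_hierarchy ~ group_size, st, study$tree, lam)
  )
  c(list(index = idx, species = st, log = log), fits)
}

#' Run the full two-level analysis
#'
#' Orchestrates [run_individual()] and [run_species()] over one study
#' bundle, sharing the derived tables, and optionally writes every
#' intermediate and result table as CSV into `out_dir` (win-matrix free
#' audit trail: ranks, profiles, rates, composite index, species table,
#' coefficient tables, variance partitions and the exclusion log).
#' Rerunning with the same config and seed reproduces identical outputs.
#'
#' @inheritParams run_individual
#' @param out_dir optional output directory for the CSV artifacts.
#' @return a list of class `domstyle_run` combining the individual- and
#'   species-level results.
#' @export
run_study <- function(study, config = pipeline_config(), out_dir = NULL) {
  prep <- prepare_individual_table(study, config)
  log <- prep$log
  r1 <- .fit_one(prep$table, c("given_dii", "given_counter", "given_intensity",
                               "group_size"), "given", config, 1L, log)
  r2 <- .fit_one(prep$table, c("received_dii", "received_counter",
                               "received_intensity", "group_size"),
                 "received", config, 2L, r1$log)
  r3 <- .fit_one(prep$table, c("prox_pct", "group_size"), "feeding",
                 config, 3L, r2$log)
  log <- r3$log

  idx <- composite_index(prep$profiles_all, prep$groups)
  st <- species_table(idx, study$repertoires, prep$groups,
                      log_offset = config$log_offset)
  missing_tips <- setdiff(st$species_id, study$tree$tip.label)
  if (length(missing_tips) > 0L) {
    stop("species absent from the tree: ", paste(missing_tips, collapse = ", "),
         call. = FALSE)
  }
  lam <- config$lambda
  sp_fits <- list(
    total = pgls(log_total ~ composite + group_size, st, study$tree, lam),
    hierarchy = pgls(log_hierarchy ~ composite + group_size, st, study$tree, lam),
    dii = pgls(log_hierarchy ~ mean_dii + group_size, st, study$tree, lam),
    counter = pgls(log_hierarchy ~ mean_counter + group_size, st, study$tree, lam),
    intensity = pgls(log_hierarchy ~ mean_intensity + group_size, st,
                     study$tree, lam),
    group_size = pgls(log_hierarchy ~ group_size, st, study$tree, lam)
  )
  run <- structure(list(
    individual = list(given = r1$fit, received = r2$fit, feeding = r3$fit),
    species = sp_fits, index = idx, species_table = st,
    table = prep$table, ranks = prep$ranks, rates = prep$rates,
    log = log, config = config, seed = config$seed
  ), class = "domstyle_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

#' @export
print.domstyle_run <- function(x, ...) {
  cat("domstyle run (seed ", x$seed, ")\n\n", sep = "")
  for (m in names(x$individual)) {
    cat("--- individual-level model:", m, "---\n")
    print(x$individual[[m]])
    cat("\n")
  }
  cat("--- species-level PGLS: hierarchy-related calls ~ composite index ---\n")
  print(x$species$hierarchy)
  invisible(x)
}

.coef_csv <- function(fit) {
  co <- fit$coefficients
  co$n_individuals <- fit$n_used[["individuals"]]
  co$n_groups <- fit$n_used[["groups"]]
  co$n_species <- fit$n_used[["species"]]
  co
}

#' Write all run artifacts as CSV
#'
#' @param run a `domstyle_run`.
#' @param out_dir output directory, created if needed.
#' @return `out_dir`, invisibly.
#' @export
write_run <- function(run, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  wcsv <- function(df, name) {
    write.csv(df, file.path(out_dir, name), row.names = FALSE, na = "")
  }
  wcsv(run$ranks, "ranks.csv")
  wcsv(run$rates, "vocal_rates.csv")
  wcsv(run$table, "individual_table.csv")
  wcsv(run$index[order(-run$index$composite), ], "composite_index.csv")
  wcsv(run$species_table, "species_table.csv")
  for (m in names(run$individual)) {
    wcsv(.coef_csv(run$individual[[m]]), sprintf("lmm_%s_coefficients.csv", m))
    vp <- run$individual[[m]]$variance_partition
    wcsv(data.frame(component = names(vp), proportion = as.numeric(vp)),
         sprintf("lmm_%s_variance_partition.csv", m))
  }
  for (m in names(run$species)) {
    co <- run$species[[m]]$coefficients
    co$n_species <- run$species[[m]]$n
    wcsv(co, sprintf("pgls_%s_coefficients.csv", m))
  }
  wcsv(run$log, "exclusion_log.csv")
  wcsv(data.frame(key = "seed", value = run$seed), "run_info.csv")
  invisible(out_dir)
}

#' Human-readable summary of a finished run directory
#'
#' Reads the CSV artifacts written by [run_study()] / [write_run()] and
#' assembles a single markdown document: coefficient tables for all
#' models, variance partitions, the species composite-index ranking
#' (descending), and the hierarchy-calls versus composite-index scatter
#' data.  Every number is re-read from the emitted CSVs.
#'
#' @param out_dir directory written by [run_study()].
#' @param file optional path to also write the summary to.
#' @return the summary as a character vector of lines, invisibly printed.
#' @export
report <- function(out_dir, file = NULL) {
  need <- file.path(out_dir, "composite_index.csv")
  if (!dir.exists(out_dir) || !file.exists(need)) {
    stop("report: no run artifacts found in ", out_dir, call. = FALSE)
  }
  fmt_tab <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, paste, collapse = " | "))
  }
  lines <- c("# Dominance style and vocal communication: run summary", "")
  info <- read.csv(file.path(out_dir, "run_info.csv"))
  lines <- c(lines, paste0("Seed: ", info$value[info$key == "seed"]), "")
  for (m in c("given", "received", "feeding")) {
    f <- file.path(out_dir, sprintf("lmm_%s_coefficients.csv", m))
    if (!file.exists(f)) next
    lines <- c(lines, sprintf("## Individual-level model: %s tolerance", m), "",
               fmt_tab(read.csv(f)), "")
    vp <- read.csv(file.path(out_dir, sprintf("lmm_%s_variance_partition.csv", m)))
    lines <- c(lines, "Variance partition:", "", fmt_tab(vp), "")
  }
  for (m in c("total", "hierarchy", "dii", "counter", "intensity", "group_size")) {
    f <- file.path(out_dir, sprintf("pgls_%s_coefficients.csv", m))
    if (!file.exists(f)) next
    lines <- c(lines, sprintf("## Species-level PGLS: %s", m), "",
               fmt_tab(read.csv(f)), "")
  }
  idx <- read.csv(file.path(out_dir, "composite_index.csv"))
  lines <- c(lines, "## Species composite dominance-style index (descending)",
             "", fmt_tab(idx[c("species_id", "composite")]), "")
  stf <- file.path(out_dir, "species_table.csv")
  if (file.exists(stf)) {
    st <- read.csv(stf)
    lines <- c(lines, "## Hierarchy-related calls vs composite index", "",
               fmt_tab(st[c("species_id", "composite", "hierarchy_calls",
                            "log_hierarchy")]), "")
  }
  if (!is.null(file)) writeLines(lines, file)
  invisible(lines)
}
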