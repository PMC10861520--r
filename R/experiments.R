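PASSIVE_DOMAINS <- c("TVDA", "SLEEP", "MORN", "NTR", "AF")
ACTIVE_DOMAINS <- c("WRT", "WLK", "PEG", "STS", "LTS")

# cheap structural hash of a configuration for reproducibility audits
config_hash <- function(cfg) {
  s <- paste(deparse(cfg), collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", as.integer(sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647))
}

#' Simulate a complete synthetic study
#'
#' End-to-end data generation: cohort with PROs, per-participant true
#' activity sequences, per-epoch movement magnitudes, passive daily
#' features, and guided-test recordings with their active daily features.
#' Per-day dropout (missing wear) removes whole participant-days at the
#' configured probability.
#'
#' @param cfg an [effect_config()].
#' @param n_hc,n_ra_mod,n_ra_sev group sizes (defaults: the 30 / 13 / 15
#'   split of the reference study population).
#' @param n_days study length in days.
#' @param keep_sequences keep the per-participant activity sequences and
#'   magnitudes in the result (memory-heavier).
#' @return object of class `ra_study`: list with `cohort`, `pro` (long),
#'   `daily` (long feature table across passive + active + DEM domains),
#'   `n_days`, `config_hash`, `seed`, and optionally `sequences`.
#' @export
simulate_study <- function(cfg = effect_config(), n_hc = 30, n_ra_mod = 13,
                           n_ra_sev = 15, n_days = 14,
                           keep_sequences = FALSE) {
  cohort <- generate_cohort(n_hc, n_ra_mod, n_ra_sev, cfg)
  seqs <- list()
  daily <- vector("list", nrow(cohort))
  for (i in seq_len(nrow(cohort))) {
    p <- cohort[i, ]
    sq <- simulate_activity_days(p, n_days, cfg)
    mg <- epoch_magnitudes(sq, p, cfg)
    enmo <- pmax(mg - 1, 0)           # movement magnitude, gravity removed
    pass <- passive_daily_features(sq, enmo, p)
    gt <- simulate_guided_tests(p, n_days, cfg)
    act <- active_daily_features(gt)
    block <- rbind(pass, act)
    if (cfg$dropout_prob > 0) {
      set.seed(derive_seed(cfg$seed, "dropout", p$participant_id))
      drop_days <- which(stats::runif(n_days) < cfg$dropout_prob)
      block <- block[!(block$day_index %in% drop_days) |
                       block$domain == "DEM", ]
    }
    daily[[i]] <- block
    if (keep_sequences) seqs[[p$participant_id]] <- list(seq = sq, mags = mg)
  }
  structure(list(cohort = cohort, pro = pro_table(cohort),
                 daily = do.call(rbind, daily), n_days = n_days,
                 seed = cfg$seed, config_hash = config_hash(cfg),
                 sequences = if (keep_sequences) seqs else NULL),
            class = "ra_study")
}

#' @export
print.ra_study <- function(x, ...) {
  cat(sprintf("Synthetic RA study: %d participants, %d days, %d daily feature rows\n",
              nrow(x$cohort), x$n_days, nrow(x$daily)))
  cat("  config hash:", x$config_hash, " seed:", x$seed, "\n")
  invisible(x)
}

#' Build a design matrix from selected outcome sources
#'
#' Filters the study's daily feature table to the requested sources
#' (`"passive"`, `"active"`, `"PRO"`; demographics are always included),
#' aggregates sensor features at the requested level, and appends the
#' per-participant PRO scores as period-constant columns.
#'
#' @param study an [simulate_study()] result.
#' @param sources character subset of `c("PRO", "active", "passive")`.
#' @param level aggregation level for [aggregate_features()].
#' @param participants optional subset of participant ids.
#' @return a `feature_matrix`.
#' @export
build_design <- function(study, sources, level = "weekly",
                         participants = NULL) {
  if (!length(sources)) stopf("sources must be non-empty")
  domains <- "DEM"
  if ("passive" %in% sources) domains <- c(domains, PASSIVE_DOMAINS)
  if ("active" %in% sources) domains <- c(domains, ACTIVE_DOMAINS)
  daily <- study$daily[study$daily$domain %in% domains, , drop = FALSE]
  if (!is.null(participants))
    daily <- daily[daily$participant_id %in% participants, , drop = FALSE]
  fm <- aggregate_features(daily, level)
  if ("PRO" %in% sources) {
    pro_cols <- grep("^pro_", names(study$cohort), value = TRUE)
    pm <- as.matrix(study$cohort[match(fm$participant_id,
                                       study$cohort$participant_id),
                                 pro_cols, drop = FALSE])
    colnames(pm) <- pro_cols
    fm$x <- cbind(fm$x, pm)
    fm$domains <- c(fm$domains,
                    stats::setNames(rep("PRO", length(pro_cols)), pro_cols))
  }
  fm
}

ra_labels <- function(cohort) {
  stats::setNames(ifelse(cohort$group == "HC", "HC", "RA"),
                  cohort$participant_id)
}

#' RA identification experiment
#'
#' Binary RA-vs-HC classification from active features, passive features,
#' and their combination, each evaluated by subject-wise cross-validation;
#' reports the per-source metrics and the misclassified participants per
#' source.
#'
#' @param study an [simulate_study()] result.
#' @param level aggregation level.
#' @param penalty penalty spec for [run_cv()].
#' @param k folds.
#' @param seed integer seed.
#' @return list of class `experiment_report` with one entry per source.
#' @export
run_ra_identification <- function(study, level = "weekly",
                                  penalty = list(family = "elastic_net",
                                                 alpha = 0.5),
                                  k = 5, seed = 1) {
  labels <- ra_labels(study$cohort)
  sources <- list(active = "active", passive = "passive",
                  combined = c("active", "passive"))
  out <- lapply(sources, function(src) {
    fm <- build_design(study, src, level)
    cv <- run_cv(fm, labels, penalty, "classification", k, seed)
    miscl <- cv$subjects$participant_id[cv$subjects$pred != cv$subjects$y]
    list(cv = cv, metrics = cv$metrics_subject, misclassified = miscl)
  })
  structure(list(task = "ra_identification", sources = out,
                 seed = seed, config_hash = study$config_hash),
            class = "experiment_report")
}

#' RA severity stratification experiment
#'
#' Moderate vs severe RA classification within the RA subgroup, comparing
#' PRO-only with PRO plus sensor-based sources.
#'
#' @inheritParams run_ra_identification
#' @return `experiment_report` with entries `pro`, `pro_active`,
#'   `pro_passive`, `pro_active_passive`.
#' @export
run_severity_stratification <- function(study, level = "weekly",
                                        penalty = list(family = "elastic_net",
                                                       alpha = 0.5),
                                        k = 5, seed = 1) {
  co <- study$cohort
  ra <- co$participant_id[co$group != "HC"]
  if (!any(co$group == "RA_mod") || !any(co$group == "RA_sev"))
    stopf("both RA severity groups must be present")
  labels <- stats::setNames(as.character(co$group), co$participant_id)[ra]
  sources <- list(pro = "PRO", pro_active = c("PRO", "active"),
                  pro_passive = c("PRO", "passive"),
                  pro_active_passive = c("PRO", "active", "passive"))
  out <- lapply(sources, function(src) {
    fm <- build_design(study, src, level, participants = ra)
    cv <- run_cv(fm, labels, penalty, "classification", k, seed)
    miscl <- cv$subjects$participant_id[cv$subjects$pred != cv$subjects$y]
    list(cv = cv, metrics = cv$metrics_subject, misclassified = miscl)
  })
  structure(list(task = "severity_stratification", sources = out,
                 seed = seed, config_hash = study$config_hash),
            class = "experiment_report")
}

#' RAPID-3 estimation experiment
#'
#' Elastic-net regression of the baseline RAPID-3 score (healthy controls
#' fixed at zero) on PRO and sensor features, evaluated subject-wise.
#'
#' @inheritParams run_ra_identification
#' @return list with the `cv_report`, regression metrics, Pearson and
#'   Spearman correlation of predicted vs actual subject scores, and the
#'   median absolute prediction among HC.
#' @export
run_rapid3_regression <- function(study, level = "weekly",
                                  penalty = list(family = "elastic_net",
                                                 alpha = 0.5),
                                  k = 5, seed = 1) {
  co <- study$cohort
  y <- stats::setNames(co$rapid3_baseline, co$participant_id)
  fm <- build_design(study, c("PRO", "active", "passive"), level)
  cv <- run_cv(fm, y, penalty, "regression", k, seed)
  s <- cv$subjects
  pear <- correlation(s$y, s$pred, "pearson")
  spear <- correlation(s$y, s$pred, "spearman")
  hc <- co$participant_id[co$group == "HC"]
  structure(list(task = "rapid3_regression", cv = cv,
                 metrics = cv$metrics_subject,
                 pearson_r = pear$r, spearman_rho = spear$r,
                 hc_median_abs_pred = stats::median(abs(s$pred[s$participant_id
                                                               %in% hc])),
                 seed = seed, config_hash = study$config_hash),
            class = "experiment_report")
}

#' Data-volume sufficiency experiment
#'
#' For each d in the grid, repeats P times: sample d distinct (possibly
#' non-contiguous) days per participant, average the daily sensor features
#' over the sampled days, run the subject-wise CV, and record the
#' subject-wise macro-F1 of RA identification. Folds are re-drawn per
#' permutation from derived seeds. A fixed penalty strength keeps each of
#' the many refits comparable.
#'
#' @param study an [simulate_study()] result.
#' @param d_grid day counts to evaluate.
#' @param permutations number of random day subsets per d.
#' @param sources feature sources (default: both sensor-based sets).
#' @param penalty penalty spec; the default fixes `lambda = 0.05`.
#' @param k,seed folds and master seed.
#' @return list of class `days_report`: `curve` (d, median_f1, q1, q3) and
#'   the raw per-permutation `f1` matrix.
#' @export
run_days_subsampling <- function(study, d_grid = c(2, 4, 7, 10, 14),
                                 permutations = 100,
                                 sources = c("active", "passive"),
                                 penalty = list(family = "elastic_net",
                                                alpha = 0.5, lambda = 0.05),
                                 k = 5, seed = 1) {
  if (permutations < 1) stopf("permutation count must be >= 1")
  labels <- ra_labels(study$cohort)
  domains <- "DEM"
  if ("passive" %in% sources) domains <- c(domains, PASSIVE_DOMAINS)
  if ("active" %in% sources) domains <- c(domains, ACTIVE_DOMAINS)
  daily <- study$daily[study$daily$domain %in% domains, , drop = FALSE]
  avail <- sort(unique(daily$day_index))
  d_grid <- d_grid[d_grid <= length(avail)]
  if (!length(d_grid)) stopf("no d in grid is <= available days")
  pids <- unique(daily$participant_id)
  f1 <- matrix(NA_real_, permutations, length(d_grid),
               dimnames = list(NULL, paste0("d", d_grid)))
  for (di in seq_along(d_grid)) {
    d <- d_grid[di]
    for (perm in seq_len(permutations)) {
      pseed <- derive_seed(seed, "days", d, perm)
      set.seed(pseed)
      keep <- do.call(rbind, lapply(pids, function(pid) {
        data.frame(participant_id = pid,
                   day_index = sort(sample(avail, d)),
                   stringsAsFactors = FALSE)
      }))
      sub <- merge(daily, keep, by = c("participant_id", "day_index"))
      fm <- aggregate_features(sub, "fortnightly")
      cv <- run_cv(fm, labels, penalty, "classification", k, pseed)
      f1[perm, di] <- cv$metrics_subject$macro_f1
    }
  }
  curve <- data.frame(
    d = d_grid,
    median_f1 = apply(f1, 2, stats::median, na.rm = TRUE),
    q1 = apply(f1, 2, stats::quantile, 0.25, na.rm = TRUE),
    q3 = apply(f1, 2, stats::quantile, 0.75, na.rm = TRUE),
    iqr = apply(f1, 2, function(v) stats::IQR(v, na.rm = TRUE)))
  structure(list(task = "days_subsampling", curve = curve, f1 = f1,
                 permutations = permutations, seed = seed,
                 config_hash = study$config_hash),
            class = "days_report")
}

#' @export
print.days_report <- function(x, ...) {
  cat("Data-volume sufficiency (", x$permutations, "permutations per d)\n")
  print(round(x$curve, 3), row.names = FALSE)
  invisible(x)
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("Experiment:", x$task, "(config", x$config_hash, ")\n")
  if (!is.null(x$sources)) {
    for (nm in names(x$sources)) {
      m <- x$sources[[nm]]$metrics
      cat(sprintf("  %-20s F1 = %.3f kappa = %.3f AUROC = %.3f\n", nm,
                  m$macro_f1, m$kappa, m$auroc %||% NA))
    }
  } else if (x$task == "rapid3_regression") {
    m <- x$metrics
    cat(sprintf("  r2 = %.3f MAE = %.3f RMSE = %.3f rho = %.3f (HC median |pred| = %.2f)\n",
                m$r2, m$mae, m$rmse, x$spearman_rho, x$hc_median_abs_pred))
  }
  invisible(x)
}

#' Write study tables to a run directory
#'
#' Emits `cohort.csv`, `pro.csv`, `daily_features.csv` and a `manifest.json`
#' recording the seed and configuration hash.
#'
#' @param study an [simulate_study()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(as.data.frame(study$cohort),
                   file.path(dir, "cohort.csv"), row.names = FALSE)
  utils::write.csv(study$pro, file.path(dir, "pro.csv"), row.names = FALSE)
  utils::write.csv(study$daily, file.path(dir, "daily_features.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(seed = study$seed, config_hash = study$config_hash,
                            n_participants = nrow(study$cohort),
                            n_days = study$n_days),
                       file.path(dir, "manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}
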