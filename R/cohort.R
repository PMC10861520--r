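#' Generate a synthetic study cohort
#'
#' Draws participant records for healthy controls (HC) and moderate/severe RA
#' groups. PRO scores are drawn from per-group truncated normals clipped to
#' each instrument's range; HC participants are assigned a baseline RAPID-3
#' of exactly zero. Each record also carries latent per-participant symptom
#' parameters (MVPA multiplier, morning attenuation factor, night-episode
#' rate, transition duration, wrist ROM, cadence, peg interval) drawn around
#' the group means, which the downstream simulators consume so that repeated
#' days from one participant are correlated.
#'
#' @param n_hc,n_ra_mod,n_ra_sev group sizes (nonnegative counts).
#' @param cfg an [effect_config()].
#' @return a `data.frame` of class `cohort`; one row per participant with
#'   demographics, `rapid3_baseline`, `pro_*` score columns and `lat_*`
#'   latent symptom-parameter columns.
#' @export
generate_cohort <- function(n_hc, n_ra_mod, n_ra_sev, cfg = effect_config()) {
  validate_effect_config(cfg)
  counts <- c(HC = n_hc, RA_mod = n_ra_mod, RA_sev = n_ra_sev)
  if (any(counts < 0)) stopf("group counts must be nonnegative")
  n <- sum(counts)
  group <- factor(rep(names(counts), counts), levels = names(counts))

  set.seed(derive_seed(cfg$seed, "cohort"))
  d <- data.frame(
    participant_id = sprintf("P%03d", seq_len(n)),
    group = group,
    stringsAsFactors = FALSE
  )

  dem <- cfg$demographics
  draw_grp <- function(spec) {
    out <- numeric(n)
    for (g in levels(group)) {
      idx <- group == g
      out[idx] <- rtnorm(sum(idx), spec$mean[[g]], spec$sd[[g]],
                         spec$range[1], spec$range[2])
    }
    out
  }
  d$age <- round(draw_grp(dem$age), 1)
  d$bmi <- round(draw_grp(dem$bmi), 1)
  d$sex <- ifelse(stats::runif(n) < dem$female_prob[as.character(group)], "F", "M")

  r3 <- cfg$rapid3
  d$rapid3_baseline <- draw_grp(r3)
  d$rapid3_baseline[group == "HC"] <- 0   # HC assigned zero by design

  for (nm in names(cfg$pro)) {
    d[[paste0("pro_", nm)]] <- draw_grp(cfg$pro[[nm]])
  }

  sym <- cfg$symptoms
  act <- cfg$activity
  gch <- as.character(group)
  pos <- function(x, lo = 1e-6) pmax(x, lo)
  d$lat_mvpa_mult  <- exp(stats::rnorm(n, -act$mvpa_rel_sd^2 / 2, act$mvpa_rel_sd))
  d$lat_light_mult <- exp(stats::rnorm(n, -act$light_rel_sd^2 / 2, act$light_rel_sd))
  d$lat_morning_factor <- pmin(1, pos(
    stats::rnorm(n, sym$morning_factor[gch], sym$morning_factor_sd)))
  d$lat_night_rate <- pos(sym$night_rate_per_h[gch] *
    exp(stats::rnorm(n, -sym$night_rate_rel_sd^2 / 2, sym$night_rate_rel_sd)))
  d$lat_transition_s <- pos(stats::rnorm(n, sym$transition_s[gch], sym$transition_sd_s), 0.3)
  d$lat_rom_deg <- pos(stats::rnorm(n, sym$rom_deg[gch], sym$rom_sd_deg), 10)
  d$lat_cadence_hz <- pos(stats::rnorm(n, sym$cadence_hz[gch], sym$cadence_sd_hz), 0.5)
  d$lat_peg_s <- pos(stats::rnorm(n, sym$peg_interval_s[gch], sym$peg_sd_s), 0.3)

  class(d) <- c("cohort", "data.frame")
  d
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants (%s)\n", nrow(x),
              paste(sprintf("%s=%d", levels(x$group), table(x$group)),
                    collapse = ", ")))
  NextMethod()
}

#' Long-format PRO table for a cohort
#'
#' @param cohort a [generate_cohort()] result.
#' @return data.frame with columns `participant_id`, `instrument`, `score`.
#' @export
pro_table <- function(cohort) {
  pro_cols <- grep("^pro_", names(cohort), value = TRUE)
  out <- do.call(rbind, lapply(pro_cols, function(cl) {
    data.frame(participant_id = cohort$participant_id,
               instrument = sub("^pro_", "", cl),
               score = cohort[[cl]], stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
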