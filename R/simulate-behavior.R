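#' Behavioural parameters for the feeder-visit generator
#'
#' Defaults give realistic electronic-feeder days for growing pigs: about
#' 6 visits/day of about 10 min each with about 0.3 kg intake per visit
#' (so roughly 1.8 kg/day and 60 min/day, inside the day-level QC bounds),
#' linear growth, and a displacement rule in which the probability that the
#' next entrant displaces the previous occupant (entering within 2 s of
#' its exit) is `displacement_base * plogis(displacement_scale * (dom_next
#' - dom_prev))` — monotone in the dominance difference.
#'
#' @param visits_per_day Mean visits per animal per day (Poisson).
#' @param duration_mean_min,duration_shape Gamma visit duration (minutes).
#' @param intake_mean_kg,intake_shape Gamma intake per visit (kg).
#' @param displacement_base Maximal displacement probability scale in
#'   `[0, 1]`; 0 disables displacement events entirely.
#' @param displacement_scale Logistic slope on the dominance difference.
#' @param gap_mean_s Mean idle gap (s) between non-displacement visits;
#'   non-displacement gaps are at least 3 s so they can never be mistaken
#'   for displacement at 1 s timestamp resolution.
#' @param growth_kg_day Daily body-weight gain (kg).
#' @param weight_sd_kg SD of per-visit scale noise (kg).
#' @param day_start_hour Local hour at which feeding activity starts.
#' @return A named list of class `visit_params`.
#' @export
visit_params <- function(visits_per_day = 6, duration_mean_min = 10,
                         duration_shape = 4, intake_mean_kg = 0.3,
                         intake_shape = 8, displacement_base = 0.4,
                         displacement_scale = 1.5, gap_mean_s = 300,
                         growth_kg_day = 0.92, weight_sd_kg = 0.5,
                         day_start_hour = 5) {
  p <- list(visits_per_day = visits_per_day,
            duration_mean_min = duration_mean_min,
            duration_shape = duration_shape,
            intake_mean_kg = intake_mean_kg, intake_shape = intake_shape,
            displacement_base = displacement_base,
            displacement_scale = displacement_scale,
            gap_mean_s = gap_mean_s, growth_kg_day = growth_kg_day,
            weight_sd_kg = weight_sd_kg, day_start_hour = day_start_hour)
  pos <- c("visits_per_day", "duration_mean_min", "duration_shape",
           "intake_mean_kg", "intake_shape", "gap_mean_s")
  if (any(vapply(p[pos], function(x) x <= 0, logical(1))))
    stop("rates, durations and intakes must be positive")
  if (p$displacement_base < 0 || p$displacement_base > 1)
    stop("displacement_base must lie in [0, 1]")
  class(p) <- "visit_params"
  p
}

#' Simulate an electronic-feeder visit log
#'
#' One feeder per pen, occupied sequentially, so occupancy intervals within
#' a pen are disjoint by construction. Each day every animal makes a
#' Poisson number of visits in random order; after each exit the next
#' entrant either displaces the previous occupant (entry within 2 s, with
#' the dominance-dependent probability described in [visit_params()]) or
#' arrives after an idle gap. Timestamps have 1 s resolution (UTC);
#' intakes and durations are positive gamma draws; per-visit weights track
#' linear growth plus scale noise.
#'
#' @param animals Data frame with columns `animal_id`, `pen_id`,
#'   `dominance` (finite latent score) and optionally `weight0` (kg,
#'   default 33.6).
#' @param n_days Number of recording days.
#' @param params A [visit_params()] object.
#' @param seed Integer seed; same seed, same log.
#' @param start_date First day (UTC).
#' @return A visit-log data frame (`animal_id, pen_id, entry_ts, exit_ts,
#'   intake_kg, weight_kg`) sorted by pen and entry time.
#' @export
simulate_visit_log <- function(animals, n_days, params = visit_params(),
                               seed = 1, start_date = "2023-01-01") {
  stopifnot(inherits(params, "visit_params"))
  need <- c("animal_id", "pen_id", "dominance")
  if (!all(need %in% names(animals)))
    stop("animals needs columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(animals$dominance)))
    stop("dominance scores must be finite")
  if (n_days < 1) stop("n_days must be at least 1")
  w0 <- if ("weight0" %in% names(animals)) animals$weight0 else
    rep(33.6, nrow(animals))
  t0 <- as.numeric(as.POSIXct(start_date, tz = "UTC"))
  .set_seed(.sub_seed(seed, "visits"))
  out <- vector("list", length(unique(animals$pen_id)) * n_days)
  slot <- 0L
  for (pen in unique(animals$pen_id)) {
    rows <- which(animals$pen_id == pen)
    aid <- animals$animal_id[rows]
    dom <- animals$dominance[rows]
    wt0 <- w0[rows]
    for (day in seq_len(n_days)) {
      counts <- stats::rpois(length(aid), params$visits_per_day)
      nv <- sum(counts)
      if (nv == 0L) next
      seq_idx <- rep(seq_along(aid), counts)
      if (nv > 1L) seq_idx <- sample(seq_idx)
      durations <- stats::rgamma(nv, shape = params$duration_shape,
                                 rate = params$duration_shape /
                                   (params$duration_mean_min * 60))
      intakes <- stats::rgamma(nv, shape = params$intake_shape,
                               rate = params$intake_shape /
                                 params$intake_mean_kg)
      entries <- numeric(nv)
      exits <- numeric(nv)
      t <- t0 + (day - 1) * 86400 + params$day_start_hour * 3600 +
        stats::runif(1, 0, 600)
      prev <- 0L
      for (k in seq_len(nv)) {
        a <- seq_idx[k]
        if (prev != 0L && prev != a &&
            stats::runif(1) < params$displacement_base *
              stats::plogis(params$displacement_scale *
                              (dom[a] - dom[prev]))) {
          gap <- stats::runif(1, 0, 2)
        } else {
          gap <- 3 + stats::rexp(1, 1 / params$gap_mean_s)
        }
        entries[k] <- t + gap
        exits[k] <- entries[k] + durations[k]
        t <- exits[k]
        prev <- a
      }
      wts <- wt0[seq_idx] + params$growth_kg_day * (day - 1) +
        stats::rnorm(nv, 0, params$weight_sd_kg)
      out[[slot <- slot + 1L]] <- data.frame(
        animal_id = aid[seq_idx], pen_id = pen,
        entry_ts = round(entries), exit_ts = round(exits),
        intake_kg = round(intakes, 3),
        weight_kg = round(pmax(wts, 1), 1),
        stringsAsFactors = FALSE)
    }
  }
  log <- do.call(rbind, out[seq_len(slot)])
  log <- log[order(log$pen_id, log$entry_ts), , drop = FALSE]
  log$entry_ts <- as.POSIXct(log$entry_ts, tz = "UTC",
                             origin = "1970-01-01")
  log$exit_ts <- as.POSIXct(log$exit_ts, tz = "UTC", origin = "1970-01-01")
  rownames(log) <- NULL
  log
}

#' Simulate a paired mRNA/protein fold-change table
#'
#' A `frac_concordant` share of features carries a shared-sign true effect
#' (`effect_size` on the mRNA log2FC scale, attenuated by
#' `prot_attenuation` on the protein scale, emulating the compressed
#' protein fold changes typical of labelled proteomics); the remainder are
#' null. Observed log2 fold changes add `N(0, noise_sd^2)` noise and
#' two-sided p-values are computed from the known noise scale, so null
#' p-values are uniform. FDR columns are Benjamini-Hochberg adjusted
#' within the table.
#'
#' @param n_features Number of features (0 gives an empty table).
#' @param frac_concordant Share of features with a concordant true effect.
#' @param effect_size True mRNA |log2FC| for concordant features.
#' @param noise_sd Observation noise SD on the log2FC scale.
#' @param seed Integer seed.
#' @param prot_attenuation Protein-to-mRNA effect ratio (default 0.3).
#' @param tissue Tissue label written into the table.
#' @return Data frame `feature_id, tissue, mrna_log2fc, mrna_p, mrna_fdr,
#'   prot_log2fc, prot_p, prot_fdr, concordant_truth`.
#' @export
simulate_omics_table <- function(n_features, frac_concordant = 0.1,
                                 effect_size = 2, noise_sd = 0.3, seed = 1,
                                 prot_attenuation = 0.3,
                                 tissue = "simulated") {
  if (frac_concordant < 0 || frac_concordant > 1)
    stop("frac_concordant must lie in [0, 1]")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  empty <- data.frame(feature_id = character(), tissue = character(),
                      mrna_log2fc = numeric(), mrna_p = numeric(),
                      mrna_fdr = numeric(), prot_log2fc = numeric(),
                      prot_p = numeric(), prot_fdr = numeric(),
                      concordant_truth = logical(),
                      stringsAsFactors = FALSE)
  if (n_features == 0L) return(empty)
  .set_seed(.sub_seed(seed, "omics"))
  n_conc <- round(frac_concordant * n_features)
  conc <- seq_len(n_features) <= n_conc
  sgn <- sample(c(-1, 1), n_features, replace = TRUE)
  mu_m <- ifelse(conc, sgn * effect_size, 0)
  mu_p <- ifelse(conc, sgn * effect_size * prot_attenuation, 0)
  m_obs <- mu_m + stats::rnorm(n_features, 0, noise_sd)
  p_obs <- mu_p + stats::rnorm(n_features, 0, noise_sd)
  m_p <- 2 * stats::pnorm(-abs(m_obs) / noise_sd)
  p_p <- 2 * stats::pnorm(-abs(p_obs) / noise_sd)
  data.frame(feature_id = sprintf("feat%05d", seq_len(n_features)),
             tissue = tissue,
             mrna_log2fc = m_obs, mrna_p = m_p, mrna_fdr = bh_adjust(m_p),
             prot_log2fc = p_obs, prot_p = p_p, prot_fdr = bh_adjust(p_p),
             concordant_truth = conc, stringsAsFactors = FALSE)
}
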