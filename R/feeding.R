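#' Read or write an electronic feeder visit log
#'
#' Visit logs are CSV files with one row per feeder visit and columns
#' `animal_id, pen_id, entry_ts, exit_ts, intake_kg, weight_kg`, timestamps
#' in ISO-8601 UTC at 1 s resolution. Column names can be remapped for logs
#' exported by other systems.
#'
#' @param file Path to the CSV.
#' @param columns Named character vector mapping the canonical names to the
#'   columns present in `file`.
#' @return A data frame with canonical columns; `entry_ts`/`exit_ts` are
#'   `POSIXct` (UTC).
#' @export
read_visit_log <- function(file,
                           columns = c(animal_id = "animal_id",
                                       pen_id = "pen_id",
                                       entry_ts = "entry_ts",
                                       exit_ts = "exit_ts",
                                       intake_kg = "intake_kg",
                                       weight_kg = "weight_kg")) {
  raw <- utils::read.csv(file, stringsAsFactors = FALSE)
  miss <- setdiff(unname(columns), names(raw))
  if (length(miss)) stop("visit log lacks column(s): ",
                         paste(miss, collapse = ", "))
  parse_ts <- function(x) {
    out <- as.POSIXct(x, tz = "UTC",
                      tryFormats = c("%Y-%m-%dT%H:%M:%OS",
                                     "%Y-%m-%d %H:%M:%OS",
                                     "%Y-%m-%d"))
    if (anyNA(out) && !anyNA(x)) stop("unparseable timestamp in visit log")
    out
  }
  out <- data.frame(
    animal_id = as.character(raw[[columns[["animal_id"]]]]),
    pen_id = as.character(raw[[columns[["pen_id"]]]]),
    entry_ts = parse_ts(raw[[columns[["entry_ts"]]]]),
    exit_ts = parse_ts(raw[[columns[["exit_ts"]]]]),
    intake_kg = as.numeric(raw[[columns[["intake_kg"]]]]),
    weight_kg = as.numeric(raw[[columns[["weight_kg"]]]]),
    stringsAsFactors = FALSE)
  .validate_visits(out)
  out
}

#' @rdname read_visit_log
#' @param visits A visit-log data frame.
#' @export
write_visit_log <- function(visits, file) {
  out <- visits
  out$entry_ts <- format(out$entry_ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  out$exit_ts <- format(out$exit_ts, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

.validate_visits <- function(visits) {
  need <- c("animal_id", "pen_id", "entry_ts", "exit_ts",
            "intake_kg", "weight_kg")
  miss <- setdiff(need, names(visits))
  if (length(miss)) stop("visit log lacks column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(visits)) {
    if (any(visits$exit_ts < visits$entry_ts))
      stop("visit with exit before entry")
    if (any(!is.finite(visits$intake_kg)) || any(visits$intake_kg < 0))
      stop("intakes must be finite and non-negative")
  }
  invisible(visits)
}

#' Per-day feeding summaries
#'
#' Collapses a visit log to one row per animal and calendar date with at
#' least one visit: total intake (kg), number of visits, total feeder
#' occupation (minutes) and a day weight (median of the day's visit
#' weights, which damps scale noise). A visit spanning midnight belongs to
#' its entry date. Overlapping visits by the same animal are merged for the
#' duration sum with a warning.
#'
#' @param visits A visit-log data frame (see [read_visit_log()]).
#' @param tz Timezone used to cut days at local midnight; default UTC.
#' @return Data frame with columns `animal_id, date, total_intake, n_visits,
#'   total_duration, day_weight`.
#' @export
summarize_daily <- function(visits, tz = "UTC") {
  .validate_visits(visits)
  if (!nrow(visits)) {
    return(data.frame(animal_id = character(), date = as.Date(character()),
                      total_intake = numeric(), n_visits = integer(),
                      total_duration = numeric(), day_weight = numeric(),
                      stringsAsFactors = FALSE))
  }
  v <- visits[order(visits$animal_id, visits$entry_ts), , drop = FALSE]
  v$date <- as.Date(v$entry_ts, tz = tz)
  key <- interaction(v$animal_id, v$date, drop = TRUE)
  dur_min <- vapply(split(seq_len(nrow(v)), key), function(idx) {
    en <- as.numeric(v$entry_ts[idx])
    ex <- as.numeric(v$exit_ts[idx])
    if (length(idx) > 1L && any(en[-1L] < ex[-length(ex)] - 1e-9)) {
      warning("overlapping visits by one animal within a day; merged",
              call. = FALSE)
      # union of intervals
      o <- order(en)
      en <- en[o]; ex <- ex[o]
      tot <- 0
      cur_s <- en[1L]; cur_e <- ex[1L]
      for (k in seq_along(en)[-1L]) {
        if (en[k] <= cur_e) cur_e <- max(cur_e, ex[k]) else {
          tot <- tot + (cur_e - cur_s)
          cur_s <- en[k]; cur_e <- ex[k]
        }
      }
      (tot + (cur_e - cur_s)) / 60
    } else sum(ex - en) / 60
  }, numeric(1))
  first <- !duplicated(key)
  out <- data.frame(
    animal_id = v$animal_id[first],
    date = v$date[first],
    total_intake = as.numeric(tapply(v$intake_kg, key, sum)[levels(key)]),
    n_visits = as.integer(tapply(rep(1L, nrow(v)), key, sum)[levels(key)]),
    total_duration = as.numeric(dur_min[levels(key)]),
    day_weight = as.numeric(tapply(v$weight_kg, key,
                                   stats::median)[levels(key)]),
    stringsAsFactors = FALSE)
  # `first` follows the (animal, entry) sort so rows already align with
  # levels(key); reorder defensively anyway
  ord <- match(levels(key), interaction(out$animal_id, out$date, drop = TRUE))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Day-level quality-control thresholds
#'
#' Inclusive per-day retention bounds: daily intake 0.5--4.5 kg, 2--20
#' visits, 5--120 min at the feeder. A failing day is dropped for that
#' animal only; the animal keeps its other days.
#'
#' @param intake_min,intake_max Daily intake bounds, kg.
#' @param visits_min,visits_max Daily visit-count bounds.
#' @param duration_min,duration_max Daily feeder-occupation bounds, minutes.
#' @return A named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(intake_min = 0.5, intake_max = 4.5,
                          visits_min = 2, visits_max = 20,
                          duration_min = 5, duration_max = 120) {
  th <- list(intake_min = intake_min, intake_max = intake_max,
             visits_min = visits_min, visits_max = visits_max,
             duration_min = duration_min, duration_max = duration_max)
  if (th$intake_min > th$intake_max || th$visits_min > th$visits_max ||
      th$duration_min > th$duration_max)
    stop("each QC minimum must not exceed its maximum")
  class(th) <- "qc_thresholds"
  th
}

#' Apply day-level quality control
#'
#' Retains a daily summary iff intake, visit count and duration all fall
#' inside the (inclusive) thresholds. Idempotent.
#'
#' @param summaries Output of [summarize_daily()].
#' @param thresholds A [qc_thresholds()] object.
#' @return The retained rows of `summaries`.
#' @export
apply_qc <- function(summaries, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  keep <- summaries$total_intake >= thresholds$intake_min &
    summaries$total_intake <= thresholds$intake_max &
    summaries$n_visits >= thresholds$visits_min &
    summaries$n_visits <= thresholds$visits_max &
    summaries$total_duration >= thresholds$duration_min &
    summaries$total_duration <= thresholds$duration_max
  out <- summaries[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Derive per-animal feeding-behaviour and growth traits
#'
#' From QC-retained daily summaries: `test_days` is the number of retained
#' days; `W1`/`W2` are the day weights of the first/last retained day; total
#' feed intake `TFI` (kg) is the sum of retained daily intakes;
#' `ADFI = 1000 * TFI / test_days` (g/day);
#' `ADG = 1000 * (W2 - W1) / test_days` (g/day); `TPD` and `NVD` are mean
#' minutes and mean visits per retained day; `AFI = ADFI / NVD` (g/visit).
#' Animals with fewer than two retained days are excluded with a message.
#'
#' @param retained QC-retained daily summaries ([apply_qc()]).
#' @param backfat Optional data frame `animal_id, bf_mm` (end-of-test
#'   ultrasound backfat); joined as column `bf_mm` when supplied.
#' @return One row per animal with the trait columns above.
#' @export
derive_traits <- function(retained, backfat = NULL) {
  sp <- split(retained, retained$animal_id)
  few <- names(sp)[vapply(sp, nrow, integer(1)) < 2L]
  if (length(few)) {
    message("excluded (fewer than 2 retained days): ",
            paste(few, collapse = ", "))
    sp <- sp[setdiff(names(sp), few)]
  }
  rows <- lapply(sp, function(d) {
    d <- d[order(d$date), , drop = FALSE]
    td <- nrow(d)
    tfi <- sum(d$total_intake)
    adfi <- 1000 * tfi / td
    nvd <- mean(d$n_visits)
    data.frame(animal_id = d$animal_id[1L],
               W1 = d$day_weight[1L],
               W2 = d$day_weight[td],
               test_days = td,
               TFI = tfi,
               ADFI = adfi,
               ADG = 1000 * (d$day_weight[td] - d$day_weight[1L]) / td,
               TPD = mean(d$total_duration),
               NVD = nvd,
               AFI = adfi / nvd,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(backfat)) {
    if (!all(c("animal_id", "bf_mm") %in% names(backfat)))
      stop("backfat table needs columns animal_id, bf_mm")
    out$bf_mm <- backfat$bf_mm[match(out$animal_id,
                                     as.character(backfat$animal_id))]
  }
  out
}

#' Displacement success
#'
#' A succession event is an entry by one animal within `gap_s` seconds
#' (inclusive; ties at 0 s count) of a *different* animal's exit at the same
#' pen's feeder. For animal i, `S_i` counts events where i is the entrant
#' (i displaced someone) and `B_i` events where i is the exiter (i was
#' displaced). `DS = 100 * S / (S + B)`, missing when an animal is involved
#' in no event. Every event increments one S and one B, so the pen-level
#' sums of S and B are equal. Computed on raw visits (no QC), since the
#' statistic is event-based.
#'
#' @param visits A visit-log data frame.
#' @param gap_s Maximum exit-to-entry gap in seconds (default 2).
#' @return Data frame `animal_id, succeeded, was_succeeded, DS` with one row
#'   per animal appearing in the log.
#' @export
displacement_success <- function(visits, gap_s = 2) {
  if (!is.numeric(gap_s) || length(gap_s) != 1L || gap_s < 0)
    stop("gap_s must be a non-negative scalar")
  .validate_visits(visits)
  animals <- sort(unique(visits$animal_id))
  S <- stats::setNames(numeric(length(animals)), animals)
  B <- S
  for (pen in unique(visits$pen_id)) {
    v <- visits[visits$pen_id == pen, , drop = FALSE]
    en <- as.numeric(v$entry_ts)
    ex <- as.numeric(v$exit_ts)
    o <- order(ex)
    ex_s <- ex[o]
    ex_who <- v$animal_id[o]
    # for each entry, exits of other animals with 0 <= entry - exit <= gap_s
    lo <- findInterval(en - gap_s, ex_s, left.open = TRUE)  # exits > en - gap
    hi <- findInterval(en, ex_s)                            # exits <= en
    for (k in seq_along(en)) {
      if (hi[k] <= lo[k]) next
      idx <- (lo[k] + 1L):hi[k]
      idx <- idx[ex_who[idx] != v$animal_id[k]]
      if (length(idx)) {
        S[v$animal_id[k]] <- S[v$animal_id[k]] + length(idx)
        tb <- table(ex_who[idx])
        B[names(tb)] <- B[names(tb)] + as.numeric(tb)
      }
    }
  }
  tot <- S + B
  data.frame(animal_id = animals,
             succeeded = as.numeric(S),
             was_succeeded = as.numeric(B),
             DS = ifelse(tot > 0, 100 * S / tot, NA_real_),
             stringsAsFactors = FALSE)
}
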