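#' Symmetric HPD interval for social breeding values
#'
#' Under an approximately normal distribution of estimated social breeding
#' values centred at zero, the 95% highest-posterior-density region is the
#' symmetric interval `(-z * s, +z * s)` with `z = qnorm(1 - (1-level)/2)`
#' (1.96 at the default level) and `s` a scale derived from the estimated
#' social genetic variance.
#'
#' Three scale conventions are available via `variant`:
#' \describe{
#'   \item{`"sqrtN"` (default)}{`s = sqrt(sigma2_as) / sqrt(N)` with `N` the
#'     number of phenotyped animals. This is the convention that reproduces
#'     the reference bound of 4.304 from `sigma2_as = 1007.688`, `N = 209`.}
#'   \item{`"N"`}{`s = sqrt(sigma2_as) / N` (reading the divisor as the
#'     animal count applied to the SD).}
#'   \item{`"pen"`}{`s = sqrt(sigma2_as) / n_pen` (reading the divisor as
#'     mean pen size; supply `n_pen`).}
#' }
#'
#' @param sigma2_as Estimated social genetic variance (>= 0).
#' @param N Number of phenotyped animals (>= 1).
#' @param level Interval probability, default 0.95.
#' @param variant Scale convention, see Details.
#' @param n_pen Mean pen size, required for `variant = "pen"`.
#' @return A list of class `hpd_interval` with `lower`, `upper`, `level`,
#'   `n_used`.
#' @examples
#' hpd_interval(1007.688, 209)  # upper ~ 4.304
#' @export
hpd_interval <- function(sigma2_as, N, level = 0.95,
                         variant = c("sqrtN", "N", "pen"), n_pen = NULL) {
  variant <- match.arg(variant)
  if (!is.numeric(sigma2_as) || sigma2_as < 0)
    stop("sigma2_as must be non-negative")
  if (!is.numeric(N) || N < 1) stop("N must be at least 1")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  z <- stats::qnorm(1 - (1 - level) / 2)
  s <- sqrt(sigma2_as)
  denom <- switch(variant,
                  sqrtN = sqrt(N),
                  N = N,
                  pen = {
                    if (is.null(n_pen)) stop("variant 'pen' needs n_pen")
                    n_pen
                  })
  up <- z * s / denom
  structure(list(lower = -up, upper = up, level = level, n_used = N),
            class = "hpd_interval")
}

#' @export
print.hpd_interval <- function(x, ...) {
  cat(sprintf("HPD%d%% interval: (%.4f, %.4f), N = %d\n",
              round(100 * x$level), x$lower, x$upper, as.integer(x$n_used)))
  invisible(x)
}

#' Classify animals with extreme social breeding values
#'
#' Animals whose social breeding value lies outside the HPD interval are
#' extreme; among those above the upper bound the `k` largest form the HS
#' (high social) group and among those below the lower bound the `k`
#' smallest form the LS (low social) group. Ties are broken by animal id so
#' the result is invariant to input order. If fewer than `k` animals lie on
#' a side, all of them are taken with a warning.
#'
#' @param sge Data frame `animal_id, sge` (or a named numeric vector).
#' @param interval An [hpd_interval()].
#' @param k Group size, default 4.
#' @return Data frame `animal_id, sge_value, group` with `group` in
#'   `c("HS", "LS", "neither")`, ordered by animal id.
#' @export
classify_extremes <- function(sge, interval, k = 4) {
  stopifnot(inherits(interval, "hpd_interval"))
  if (k < 1) stop("k must be at least 1")
  if (is.numeric(sge) && !is.null(names(sge)))
    sge <- data.frame(animal_id = names(sge), sge = as.numeric(sge),
                      stringsAsFactors = FALSE)
  stopifnot(all(c("animal_id", "sge") %in% names(sge)))
  d <- data.frame(animal_id = as.character(sge$animal_id),
                  sge_value = as.numeric(sge$sge),
                  group = "neither", stringsAsFactors = FALSE)
  d <- d[order(d$animal_id), , drop = FALSE]
  hi <- which(d$sge_value > interval$upper)
  lo <- which(d$sge_value < interval$lower)
  if (length(hi)) {
    if (length(hi) < k)
      warning(sprintf("only %d animal(s) above the interval; taking all",
                      length(hi)))
    take <- hi[order(-d$sge_value[hi], d$animal_id[hi])][seq_len(min(k, length(hi)))]
    d$group[take] <- "HS"
  }
  if (length(lo)) {
    if (length(lo) < k)
      warning(sprintf("only %d animal(s) below the interval; taking all",
                      length(lo)))
    take <- lo[order(d$sge_value[lo], d$animal_id[lo])][seq_len(min(k, length(lo)))]
    d$group[take] <- "LS"
  }
  rownames(d) <- NULL
  d
}

#' Compare traits between the HS and LS groups
#'
#' For each numeric trait column, reports the group means and SDs and a
#' two-sided Student's t-test. The pooled-variance (classical Student)
#' test is the default; Welch's unequal-variance test is available.
#' Nominal p-values are reported without multiple-testing correction.
#' The degenerate case of zero variance in both groups with equal means is
#' reported as `t = 0, p = 1`.
#'
#' @param traits Data frame with `animal_id` and numeric trait columns.
#' @param assignment Output of [classify_extremes()].
#' @param welch Use Welch's t instead of pooled Student's t.
#' @return Data frame with one row per trait: `trait, mean_HS, sd_HS, n_HS,
#'   mean_LS, sd_LS, n_LS, t, p`.
#' @export
group_compare <- function(traits, assignment, welch = FALSE) {
  stopifnot("animal_id" %in% names(traits))
  grp <- assignment$group[match(as.character(traits$animal_id),
                                assignment$animal_id)]
  hs <- traits[!is.na(grp) & grp == "HS", , drop = FALSE]
  ls <- traits[!is.na(grp) & grp == "LS", , drop = FALSE]
  cols <- names(traits)[vapply(traits, is.numeric, logical(1))]
  rows <- lapply(cols, function(cn) {
    x <- hs[[cn]][is.finite(hs[[cn]])]
    y <- ls[[cn]][is.finite(ls[[cn]])]
    if (length(x) < 2L || length(y) < 2L)
      stop("need at least 2 animals per group for trait ", cn)
    if (stats::sd(x) == 0 && stats::sd(y) == 0 && mean(x) == mean(y)) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- stats::t.test(x, y, var.equal = !welch)
    }
    data.frame(trait = cn,
               mean_HS = mean(x), sd_HS = stats::sd(x), n_HS = length(x),
               mean_LS = mean(y), sd_LS = stats::sd(y), n_LS = length(y),
               t = unname(tt$statistic), p = tt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
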