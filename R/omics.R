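#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment,
#' `q_(i) = min_(j >= i) ( p_(j) * m / j )` capped at 1, returned in the
#' input order. Delegates to [stats::p.adjust()] after validating the
#' inputs.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return FDR-adjusted values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) && (any(!is.finite(p)) || any(p < 0) || any(p > 1)))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression thresholds
#'
#' Significance is `fdr < fdr_cut` (strict). The effect-size cutoff on the
#' log2 fold change is `mrna_abs_log2fc` for the mRNA axis. For the protein
#' axis the declared cutoff of 1.2 is interpreted as a *fold change* (i.e.
#' `|log2FC| > log2(1.2)`), because published protein log2 fold changes
#' declared differentially expressed in this setting lie well below 1.2 on
#' the log2 scale; set `prot_literal_log2 = TRUE` for the literal
#' `|log2FC| > 1.2` reading.
#'
#' @param mrna_abs_log2fc Absolute log2FC cutoff for mRNA (default 1).
#' @param prot_fold_change Protein fold-change cutoff (default 1.2).
#' @param fdr_cut FDR significance cutoff (default 0.05).
#' @param prot_literal_log2 Treat `prot_fold_change` as a log2FC cutoff.
#' @return A named list of class `de_thresholds`.
#' @export
de_thresholds <- function(mrna_abs_log2fc = 1.0, prot_fold_change = 1.2,
                          fdr_cut = 0.05, prot_literal_log2 = FALSE) {
  if (mrna_abs_log2fc <= 0 || prot_fold_change <= 0 || fdr_cut <= 0)
    stop("thresholds must be positive")
  structure(list(mrna_abs_log2fc = mrna_abs_log2fc,
                 prot_fold_change = prot_fold_change,
                 fdr_cut = fdr_cut,
                 prot_literal_log2 = prot_literal_log2),
            class = "de_thresholds")
}

.de_cutoff <- function(axis, thresholds) {
  switch(axis,
         mrna = thresholds$mrna_abs_log2fc,
         protein = if (thresholds$prot_literal_log2)
           thresholds$prot_fold_change else log2(thresholds$prot_fold_change),
         stop("axis must be 'mrna' or 'protein'"))
}

#' Classify a feature as up-, down-regulated or not significant
#'
#' `up` iff `fdr < fdr_cut` and `log2fc > cutoff`; `down` iff
#' `fdr < fdr_cut` and `log2fc < -cutoff`; otherwise `ns`. Inequalities are
#' strict, so a value exactly at a threshold is not significant.
#' Vectorised.
#'
#' @param log2fc Log2 fold change(s).
#' @param fdr FDR-adjusted significance value(s).
#' @param axis `"mrna"` or `"protein"` (selects the effect-size cutoff).
#' @param thresholds A [de_thresholds()] object.
#' @return Character vector in `c("up", "down", "ns")`.
#' @export
classify_de <- function(log2fc, fdr, axis = c("mrna", "protein"),
                        thresholds = de_thresholds()) {
  axis <- match.arg(axis)
  stopifnot(inherits(thresholds, "de_thresholds"))
  if (any(!is.finite(log2fc)) || any(!is.finite(fdr)))
    stop("log2fc and fdr must be finite")
  cut <- .de_cutoff(axis, thresholds)
  out <- rep("ns", length(log2fc))
  sig <- fdr < thresholds$fdr_cut
  out[sig & log2fc > cut] <- "up"
  out[sig & log2fc < -cut] <- "down"
  out
}

#' Nine-quadrant classification of joint mRNA/protein status
#'
#' Maps the pair (mRNA status, protein status) onto the 1..9 grid used in
#' transcriptome-proteome concordance plots: quadrants 1, 2 and 4 have
#' protein abundance lower than transcript abundance, quadrants 3 (both up)
#' and 7 (both down) are concordant, quadrant 5 is neutral on both axes,
#' and quadrants 6, 8 and 9 have protein higher than transcript.
#' Vectorised; the mapping is a bijection over the 9 status pairs.
#'
#' @param mrna_status,prot_status Character vectors in
#'   `c("up", "ns", "down")`.
#' @return Integer vector of quadrant labels 1..9.
#' @export
nine_quadrant <- function(mrna_status, prot_status) {
  ok <- c("up", "ns", "down")
  if (!all(mrna_status %in% ok) || !all(prot_status %in% ok))
    stop("statuses must be 'up', 'ns' or 'down'")
  map <- matrix(c(1L, 2L, 3L,   # mrna up:   prot down, ns, up
                  4L, 5L, 6L,   # mrna ns
                  7L, 8L, 9L),  # mrna down
                nrow = 3, byrow = TRUE,
                dimnames = list(c("up", "ns", "down"),
                                c("down", "ns", "up")))
  map[cbind(mrna_status, prot_status)]
}

#' Count concordant features per tissue
#'
#' Counts features whose mRNA and protein are both up-regulated (quadrant
#' 3, "co-up") or both down-regulated (quadrant 7, "co-down") in each
#' tissue.
#'
#' With `thresholds = NULL` (default) the table is taken as a curated list
#' of significant features and concordance is judged by fold-change sign
#' alone — appropriate for published tables whose membership already
#' encodes significance. Supplying a [de_thresholds()] object instead
#' re-derives each status with [classify_de()] from the `mrna_fdr` and
#' `prot_fdr` columns.
#'
#' @param table Data frame with columns `tissue`, `mrna_log2fc`,
#'   `prot_log2fc` and, when re-thresholding, `mrna_fdr`, `prot_fdr`.
#' @param thresholds `NULL` or a [de_thresholds()] object.
#' @return Data frame `tissue, co_up, co_down`.
#' @export
concordant_counts <- function(table, thresholds = NULL) {
  stopifnot(all(c("tissue", "mrna_log2fc", "prot_log2fc") %in% names(table)))
  if (is.null(thresholds)) {
    ms <- ifelse(table$mrna_log2fc > 0, "up",
                 ifelse(table$mrna_log2fc < 0, "down", "ns"))
    ps <- ifelse(table$prot_log2fc > 0, "up",
                 ifelse(table$prot_log2fc < 0, "down", "ns"))
  } else {
    ms <- classify_de(table$mrna_log2fc, table$mrna_fdr, "mrna", thresholds)
    ps <- classify_de(table$prot_log2fc, table$prot_fdr, "protein",
                      thresholds)
  }
  q <- nine_quadrant(ms, ps)
  tis <- sort(unique(as.character(table$tissue)))
  data.frame(tissue = tis,
             co_up = vapply(tis, function(t)
               sum(q == 3L & table$tissue == t), integer(1)),
             co_down = vapply(tis, function(t)
               sum(q == 7L & table$tissue == t), integer(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pearson correlation between mRNA and protein fold changes
#'
#' @param table Data frame with `mrna_log2fc`, `prot_log2fc` and (if
#'   `tissue` is given) a `tissue` column.
#' @param tissue Optional tissue to subset to.
#' @return The Pearson product-moment correlation. Errors when fewer than 3
#'   pairs remain; `NA` with a warning when either axis has zero variance.
#' @export
expression_correlation <- function(table, tissue = NULL) {
  d <- table
  if (!is.null(tissue)) d <- d[d$tissue == tissue, , drop = FALSE]
  x <- d$mrna_log2fc
  y <- d$prot_log2fc
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero variance on one axis; correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Fold change from a delta-delta-Ct value
#'
#' qPCR relative quantification: fold change `= 2^(-ddct)`.
#'
#' @param ddct Delta-delta-Ct value(s).
#' @return `2^(-ddct)`, vectorised.
#' @examples
#' ddct_fold_change(c(0, 1, -2))  # 1, 0.5, 4
#' @export
ddct_fold_change <- function(ddct) {
  if (any(!is.finite(ddct))) stop("ddct must be finite")
  2^(-ddct)
}
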