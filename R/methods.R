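#' @export
print.sge_reml <- function(x, digits = 4, ...) {
  cat("Direct-social animal model (REML)\n")
  if (!is.null(x$call)) {
    cat("Call: ")
    print(x$call)
  }
  cat(sprintf("n = %d records, mean pen size %.2f\n", x$n, x$mean_pen_size))
  cat(sprintf("Restricted logLik %.4f after %d iterations (%s)\n",
              x$loglik, x$iterations,
              if (x$converged) "converged" else "NOT converged"))
  if (isTRUE(x$boundary))
    cat("Note: at least one variance is at the zero boundary\n")
  cat("\nVariance components:\n")
  print(round(x$components, digits))
  invisible(x)
}

#' Summarise a fitted direct-social animal model
#'
#' Reports the variance components with their approximate (inverse
#' average-information) standard errors, the direct-social genetic
#' correlation, and the total genetic variance at the observed mean pen
#' size.
#'
#' @param object A fitted [sge_reml()] / [reml_fit()] object.
#' @param ... Unused.
#' @return An object of class `summary.sge_reml`.
#' @export
summary.sge_reml <- function(object, ...) {
  comp <- object$components
  tab <- data.frame(estimate = comp, se = object$se[names(comp)])
  r <- if (comp[["sigma2_ad"]] > 0 && comp[["sigma2_as"]] > 0)
    genetic_correlation(comp) else NA_real_
  out <- list(components = tab, r_ads = r,
              sigma2_tbv = total_genetic_variance(comp,
                                                  object$mean_pen_size),
              mean_pen_size = object$mean_pen_size,
              loglik = object$loglik, n = object$n,
              converged = object$converged, boundary = object$boundary,
              iterations = object$iterations, fixed = object$fixed)
  class(out) <- "summary.sge_reml"
  out
}

#' @export
print.summary.sge_reml <- function(x, digits = 4, ...) {
  cat("Direct-social animal model (REML)\n\n")
  cat("Variance components (estimate +/- approx. SE):\n")
  print(round(x$components, digits))
  cat(sprintf("\nGenetic correlation r_Ads: %.3f\n", x$r_ads))
  cat(sprintf("Total genetic variance at mean pen size %.2f: %.2f\n",
              x$mean_pen_size, x$sigma2_tbv))
  cat(sprintf("Restricted logLik %.4f (n = %d, %d iterations, %s%s)\n",
              x$loglik, x$n, x$iterations,
              if (x$converged) "converged" else "not converged",
              if (isTRUE(x$boundary)) ", boundary" else ""))
  if (!is.null(x$fixed)) {
    cat("\nFixed effects:\n")
    print(round(x$fixed, digits))
  }
  invisible(x)
}

#' @export
coef.sge_reml <- function(object, ...) {
  if (is.null(object$fixed))
    stop("fit was run with blup = FALSE; refit to obtain solutions")
  object$fixed
}

#' Extract estimated breeding values
#'
#' @param object A fitted model.
#' @param phenotyped_only Restrict to animals with records.
#' @return Data frame `animal, ad_hat, as_hat` (direct and social
#'   estimated breeding values).
#' @export
breeding_values <- function(object, phenotyped_only = FALSE) {
  stopifnot(inherits(object, "sge_reml"))
  if (is.null(object$ad_hat))
    stop("fit was run with blup = FALSE; refit to obtain solutions")
  out <- data.frame(animal = names(object$ad_hat),
                    ad_hat = unname(object$ad_hat),
                    as_hat = unname(object$as_hat),
                    stringsAsFactors = FALSE)
  if (phenotyped_only)
    out <- out[out$animal %in% object$design$animal, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Predict from a fitted direct-social animal model
#'
#' @param object A fitted model.
#' @param type `"tbv"` (total breeding value `a_d + (n - 1) a_s` at group
#'   size `n`), `"direct"`, `"social"`, or `"fitted"` (in-sample fitted
#'   values `y - e_hat`).
#' @param n Group size for `type = "tbv"`; defaults to the observed mean
#'   pen size.
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
predict.sge_reml <- function(object, type = c("tbv", "direct", "social",
                                              "fitted"),
                             n = NULL, ...) {
  type <- match.arg(type)
  if (is.null(object$ad_hat) && type != "fitted")
    stop("fit was run with blup = FALSE; refit to obtain solutions")
  switch(type,
         fitted = stats::setNames(object$fitted, object$design$animal),
         direct = object$ad_hat,
         social = object$as_hat,
         tbv = {
           if (is.null(n)) n <- object$mean_pen_size
           object$ad_hat + (n - 1) * object$as_hat
         })
}

#' @export
fitted.sge_reml <- function(object, ...) {
  stats::setNames(object$fitted, object$design$animal)
}

#' @export
residuals.sge_reml <- function(object, ...) {
  stats::setNames(object$residuals, object$design$animal)
}

#' Simulate responses from a fitted direct-social animal model
#'
#' Draws new phenotype vectors at the estimated parameters: breeding
#' values are resampled over the pedigree from the estimated genetic
#' covariance, litter, pen and residual effects from their estimated
#' variances, and the fixed part is kept at the estimates.
#'
#' @param object A fitted model (with `blup = TRUE`).
#' @param nsim Number of response vectors.
#' @param seed Optional integer seed.
#' @param ... Unused.
#' @return A data frame with `nsim` columns, one row per record.
#' @export
simulate.sge_reml <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) .set_seed(as.integer(seed))
  des <- object$design
  comp <- object$components
  g0 <- matrix(comp[c("sigma2_ad", "sigma_ads", "sigma_ads", "sigma2_as")],
               2, 2)
  xb <- drop(des$X %*% object$fixed)
  n <- length(des$y)
  ped <- data.frame(animal = des$pedigree_ids, stringsAsFactors = FALSE)
  out <- matrix(NA_real_, n, nsim)
  for (s in seq_len(nsim)) {
    eff_seed <- sample.int(2147483000L, 1L)
    eff <- simulate_true_effects(object$pedigree %||% .design_ped(object),
                                 g0, seed = eff_seed)
    adv <- eff$a_d[match(des$pedigree_ids, eff$animal)]
    asv <- eff$a_s[match(des$pedigree_ids, eff$animal)]
    l <- stats::rnorm(ncol(des$W), 0, sqrt(comp[["sigma2_l"]]))
    g <- stats::rnorm(ncol(des$V), 0, sqrt(comp[["sigma2_g"]]))
    e <- stats::rnorm(n, 0, sqrt(comp[["sigma2_e"]]))
    out[, s] <- xb + drop(des$Zd %*% adv) + drop(des$Zs %*% asv) +
      drop(des$W %*% l) + drop(des$V %*% g) + e
  }
  out <- as.data.frame(out)
  names(out) <- paste0("sim_", seq_len(nsim))
  attr(out, "seed") <- seed
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Fallback pedigree for resimulation when the fit was made through
# reml_fit() directly and no pedigree object was attached.
.design_ped <- function(object) {
  # treat pedigree ids as founders (correct marginal variance for
  # unrelated animals only) and warn
  warning("original pedigree not attached; simulating as if unrelated")
  sort_pedigree(data.frame(animal = object$design$pedigree_ids,
                           sire = NA_character_, dam = NA_character_,
                           stringsAsFactors = FALSE))
}

#' Plot estimated direct against social breeding values
#'
#' @param x A fitted model.
#' @param hpd Optional [hpd_interval()]; drawn as horizontal reference
#'   lines on the social axis.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.sge_reml <- function(x, hpd = NULL, ...) {
  bv <- breeding_values(x, phenotyped_only = TRUE)
  graphics::plot(bv$ad_hat, bv$as_hat,
                 xlab = "direct EBV", ylab = "social EBV",
                 pch = 19, col = "#00000080", ...)
  graphics::abline(h = 0, v = 0, col = "grey70")
  if (!is.null(hpd))
    graphics::abline(h = c(hpd$lower, hpd$upper), lty = 2, col = "red3")
  invisible(bv)
}

#' @export
logLik.sge_reml <- function(object, ...) {
  structure(object$loglik, df = length(object$active),
            class = "logLik")
}
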