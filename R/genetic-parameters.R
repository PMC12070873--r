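#' Total genetic variance for a group of size n
#'
#' Variance of the total breeding value `TBV = a_d + (n - 1) a_s` for an
#' animal in a group of `n`:
#' `sigma2_TBV = sigma2_Ad + 2 (n - 1) sigma_Ads + (n - 1)^2 sigma2_As`.
#' `n` is conventionally the mean group (pen) size when pens are unequal;
#' pass a vector of pen sizes to obtain the per-pen variant.
#'
#' @param components Named variance components or a fitted [sge_reml()]
#'   object.
#' @param n Group size(s); `n = 1` returns the direct variance alone.
#' @return `sigma2_TBV` (vectorised over `n`).
#' @examples
#' total_genetic_variance(
#'   c(sigma2_ad = 2594.808, sigma_ads = 206.75063, sigma2_as = 1007.688,
#'     sigma2_l = 0, sigma2_g = 0, sigma2_e = 0), n = 10.9)
#' @export
total_genetic_variance <- function(components, n) {
  if (inherits(components, "sge_reml")) components <- components$components
  sigma <- .vc(components)
  if (any(n < 1)) stop("group size must be at least 1")
  sigma[["sigma2_ad"]] + 2 * (n - 1) * sigma[["sigma_ads"]] +
    (n - 1)^2 * sigma[["sigma2_as"]]
}

#' Genetic correlation between direct and social effects
#'
#' `r_Ads = sigma_Ads / sqrt(sigma2_Ad * sigma2_As)`, in `[-1, 1]` for any
#' admissible covariance matrix. Undefined (returned as `NA` with a
#' warning) when either variance is zero.
#'
#' @inheritParams total_genetic_variance
#' @return The correlation, or `NA` when undefined.
#' @export
genetic_correlation <- function(components) {
  if (inherits(components, "sge_reml")) components <- components$components
  sigma <- .vc(components)
  if (sigma[["sigma2_ad"]] <= 0 || sigma[["sigma2_as"]] <= 0) {
    warning("a genetic variance is zero; correlation undefined")
    return(NA_real_)
  }
  sigma[["sigma_ads"]] /
    sqrt(sigma[["sigma2_ad"]] * sigma[["sigma2_as"]])
}
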