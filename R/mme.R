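#' Solve Henderson's mixed-model equations
#'
#' Builds and solves the mixed-model equations of the direct-social animal
#' model at given variance components:
#' `[X'X/se  X'Z/se; Z'X/se  Z'Z/se + Sigma^{-1}] [b; u] = [X'y; Z'y]/se`
#' with `Z = [Zd  Zs  W  V]`, `Sigma = blockdiag(G0 kron A, I sl, I sg)`
#' and `se` the residual variance. Components must be strictly admissible
#' (`G0` positive definite, positive residual); a litter or pen variance of
#' exactly zero drops that block (its effects are identically zero in the
#' infinite-shrinkage limit), and `sigma2_as = sigma_ads = 0` reduces to
#' the direct-only animal model.
#'
#' @param y Response vector (defaults to `design$y`).
#' @param design An [build_design()] object.
#' @param A Additive relationship matrix.
#' @param components Named variance components (see [reml_loglik()]).
#' @return List with `b` (fixed-effect solutions), `ad_hat`, `as_hat`
#'   (breeding values over the whole pedigree; `as_hat` all zero when the
#'   social block is dropped), `litter_hat`, `pen_hat`, and the relative
#'   residual `resid_norm` of the solved linear system.
#' @export
solve_mme <- function(y = NULL, design, A, components) {
  stopifnot(inherits(design, "sge_design"))
  sigma <- .vc(components)
  if (is.null(y)) y <- design$y
  se <- sigma[["sigma2_e"]]
  if (se <= 0) stop("residual variance must be strictly positive")
  q <- length(design$pedigree_ids)
  social <- sigma[["sigma2_as"]] > 0 || sigma[["sigma_ads"]] != 0
  G0 <- matrix(c(sigma[["sigma2_ad"]], sigma[["sigma_ads"]],
                 sigma[["sigma_ads"]], sigma[["sigma2_as"]]), 2, 2)
  if (social) {
    if (min(eigen(G0, symmetric = TRUE, only.values = TRUE)$values) <= 0)
      stop("genetic covariance matrix must be positive definite")
  } else if (sigma[["sigma2_ad"]] <= 0) {
    stop("direct genetic variance must be strictly positive")
  }
  Ainv <- tryCatch(chol2inv(chol(A)), error = function(e)
    stop("relationship matrix is singular; check the pedigree"))
  Zlist <- list(Zd = design$Zd)
  Ginv_blocks <- list()
  if (social) {
    Zlist$Zs <- design$Zs
    Ginv_blocks$genetic <- kronecker(solve(G0), Ainv)
  } else {
    Ginv_blocks$genetic <- Ainv / sigma[["sigma2_ad"]]
  }
  if (sigma[["sigma2_l"]] > 0) {
    Zlist$W <- design$W
    Ginv_blocks$litter <- diag(1 / sigma[["sigma2_l"]], ncol(design$W))
  }
  if (sigma[["sigma2_g"]] > 0) {
    Zlist$V <- design$V
    Ginv_blocks$pen <- diag(1 / sigma[["sigma2_g"]], ncol(design$V))
  }
  Z <- do.call(cbind, if (social)
    c(Zlist["Zd"], Zlist["Zs"], Zlist[setdiff(names(Zlist), c("Zd", "Zs"))])
    else Zlist)
  X <- design$X
  M <- cbind(X, Z)
  C <- crossprod(M) / se
  p <- ncol(X)
  nu <- ncol(Z)
  # ridge on the random-effect blocks
  Gi <- matrix(0, nu, nu)
  at <- 0L
  ng <- if (social) 2L * q else q
  Gi[seq_len(ng), seq_len(ng)] <- Ginv_blocks$genetic
  at <- ng
  for (nm in c("litter", "pen")) {
    if (!is.null(Ginv_blocks[[nm]])) {
      k <- ncol(Ginv_blocks[[nm]])
      Gi[at + seq_len(k), at + seq_len(k)] <- Ginv_blocks[[nm]]
      at <- at + k
    }
  }
  C[p + seq_len(nu), p + seq_len(nu)] <-
    C[p + seq_len(nu), p + seq_len(nu)] + Gi
  rhs <- crossprod(M, y) / se
  sol <- tryCatch(solve(C, rhs), error = function(e)
    stop("mixed-model equations are singular; the fixed effects are ",
         "likely rank-deficient or a variance is degenerate"))
  resid_norm <- sqrt(sum((C %*% sol - rhs)^2)) / max(sqrt(sum(rhs^2)),
                                                     .Machine$double.eps)
  b <- stats::setNames(sol[seq_len(p)], colnames(X))
  ad <- stats::setNames(sol[p + seq_len(q)], design$pedigree_ids)
  if (social) {
    as_ <- stats::setNames(sol[p + q + seq_len(q)], design$pedigree_ids)
    at <- p + 2L * q
  } else {
    as_ <- stats::setNames(rep(0, q), design$pedigree_ids)
    at <- p + q
  }
  if (sigma[["sigma2_l"]] > 0) {
    lit <- stats::setNames(sol[at + seq_len(ncol(design$W))],
                           colnames(design$W))
    at <- at + ncol(design$W)
  } else lit <- stats::setNames(rep(0, ncol(design$W)), colnames(design$W))
  if (sigma[["sigma2_g"]] > 0) {
    g <- stats::setNames(sol[at + seq_len(ncol(design$V))],
                         colnames(design$V))
  } else g <- stats::setNames(rep(0, ncol(design$V)), colnames(design$V))
  list(b = b, ad_hat = ad, as_hat = as_, litter_hat = lit, pen_hat = g,
       resid_norm = resid_norm)
}
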