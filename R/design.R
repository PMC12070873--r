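#' Build incidence matrices for the direct-social animal model
#'
#' Constructs the design of
#' `y = X b + Zd a_d + Zs a_s + W l + V g + e`:
#' `X` codes the fixed contemporary-group factor with an intercept and
#' drop-first (treatment) contrasts; `Zd` has one 1 per row at the
#' phenotyped animal's pedigree position; row i of `Zs` has 1 exactly at
#' the pedigree positions of i's pen mates (and 0 at i itself), so it sums
#' to `pen_size(i) - 1`; `W` and `V` are one-hot litter and pen incidence.
#' A pen of size 1 is permitted (its `Zs` row is all zero) with a warning.
#'
#' @param phenotypes Data frame with one row per phenotyped animal,
#'   containing the id, pen, litter and fixed-factor columns and the
#'   response.
#' @param ped The pedigree (defines the column space of `Zd`/`Zs`); every
#'   phenotyped animal must appear in it.
#' @param response,id,pen,litter,fixed Column names in `phenotypes`.
#'   `fixed = NULL` gives an intercept-only `X`.
#' @return A list of class `sge_design`: `X, Zd, Zs, W, V, y`, plus
#'   `animal`, `pen`, `litter` (per-row labels), `idx_d` (pedigree
#'   position per row) and `pedigree_ids`.
#' @export
build_design <- function(phenotypes, ped, response = "y", id = "animal",
                         pen = "pen", litter = "litter", fixed = "batch") {
  ped <- if (inherits(ped, "sge_pedigree")) ped else sort_pedigree(ped)
  for (col in c(response, id, pen, litter))
    if (!col %in% names(phenotypes))
      stop("phenotypes lacks column '", col, "'")
  ids <- as.character(phenotypes[[id]])
  ped_ids <- ped$animal
  idx <- match(ids, ped_ids)
  if (anyNA(idx))
    stop("animal(s) absent from pedigree: ",
         paste(ids[is.na(idx)], collapse = ", "))
  if (anyNA(phenotypes[[pen]]) || anyNA(phenotypes[[litter]]))
    stop("every phenotyped animal needs a pen and a litter")
  n <- nrow(phenotypes)
  q <- length(ped_ids)
  pen_f <- factor(as.character(phenotypes[[pen]]))
  lit_f <- factor(as.character(phenotypes[[litter]]))
  if (any(table(pen_f) == 1L))
    warning("pen(s) of size 1: social incidence row(s) all zero")
  if (is.null(fixed)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    if (!fixed %in% names(phenotypes))
      stop("phenotypes lacks fixed-factor column '", fixed, "'")
    f <- factor(phenotypes[[fixed]])
    if (nlevels(f) < 2L) {
      # a single contemporary group is absorbed by the intercept
      X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
    } else {
      X <- stats::model.matrix(~f, data.frame(f = f))
      colnames(X) <- sub("^f", fixed, colnames(X))
      attr(X, "assign") <- NULL
      attr(X, "contrasts") <- NULL
    }
  }
  Zd <- matrix(0, n, q, dimnames = list(NULL, ped_ids))
  Zd[cbind(seq_len(n), idx)] <- 1
  Zs <- matrix(0, n, q, dimnames = list(NULL, ped_ids))
  for (p in levels(pen_f)) {
    rows <- which(pen_f == p)
    cols <- idx[rows]
    Zs[rows, cols] <- 1
  }
  Zs[cbind(seq_len(n), idx)] <- 0
  W <- matrix(0, n, nlevels(lit_f), dimnames = list(NULL, levels(lit_f)))
  W[cbind(seq_len(n), as.integer(lit_f))] <- 1
  V <- matrix(0, n, nlevels(pen_f), dimnames = list(NULL, levels(pen_f)))
  V[cbind(seq_len(n), as.integer(pen_f))] <- 1
  structure(list(X = X, Zd = Zd, Zs = Zs, W = W, V = V,
                 y = as.numeric(phenotypes[[response]]),
                 animal = ids, pen = pen_f, litter = lit_f,
                 idx_d = idx, pedigree_ids = ped_ids),
            class = "sge_design")
}

# Quadratic-form matrices M_k with V(sigma) = sum_k sigma_k M_k, computed
# by index arithmetic (Zd and Zs are selection-type), never via n x q BLAS:
#   Mdd = Zd A Zd',  Mds = Zd A Zs' + Zs A Zd',  Mss = Zs A Zs',
#   Ml = W W',  Mg = V V',  Me = I.
.sge_prepare <- function(design, A) {
  idx <- design$idx_d
  n <- length(idx)
  pen_f <- design$pen
  ZdA <- A[idx, , drop = FALSE]
  pen_rows <- rowsum(ZdA, pen_f)                  # pens x q
  ZsA <- pen_rows[as.integer(pen_f), , drop = FALSE] - ZdA
  U <- ZsA[, idx, drop = FALSE]                   # Zs A Zd'
  Mdd <- ZdA[, idx, drop = FALSE]
  Mds <- U + t(U)
  PS <- t(rowsum(t(U), pen_f))                    # n x pens
  Mss <- PS[, as.integer(pen_f), drop = FALSE] - U
  Mss <- (Mss + t(Mss)) / 2                       # symmetrise roundoff
  list(Mdd = Mdd, Mds = Mds, Mss = Mss,
       Ml = tcrossprod(design$W), Mg = tcrossprod(design$V),
       X = design$X, y = design$y, n = n)
}

.sigma_names <- c("sigma2_ad", "sigma_ads", "sigma2_as",
                  "sigma2_l", "sigma2_g", "sigma2_e")

.vc <- function(components) {
  x <- unlist(components)
  if (is.null(names(x)) && length(x) == 6L) names(x) <- .sigma_names
  miss <- setdiff(.sigma_names, names(x))
  if (length(miss)) stop("missing variance component(s): ",
                         paste(miss, collapse = ", "))
  x[.sigma_names]
}

.build_V <- function(sigma, prep) {
  V <- sigma[["sigma2_ad"]] * prep$Mdd
  if (sigma[["sigma_ads"]] != 0) V <- V + sigma[["sigma_ads"]] * prep$Mds
  if (sigma[["sigma2_as"]] != 0) V <- V + sigma[["sigma2_as"]] * prep$Mss
  if (sigma[["sigma2_l"]] != 0) V <- V + sigma[["sigma2_l"]] * prep$Ml
  if (sigma[["sigma2_g"]] != 0) V <- V + sigma[["sigma2_g"]] * prep$Mg
  diag(V) <- diag(V) + sigma[["sigma2_e"]]
  V
}

# Restricted log-likelihood and (optionally) the REML projection pieces.
.reml_eval <- function(sigma, prep, want_P = FALSE) {
  V <- .build_V(sigma, prep)
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  X <- prep$X
  y <- prep$y
  n <- prep$n
  p <- ncol(X)
  Vinv <- chol2inv(ch)
  VinvX <- Vinv %*% X
  XtVinvX <- crossprod(X, VinvX)
  chx <- tryCatch(chol(XtVinvX), error = function(e) NULL)
  if (is.null(chx)) stop("X'V^{-1}X is singular: fixed effects not estimable")
  XtVinvX_inv <- chol2inv(chx)
  Vinvy <- Vinv %*% y
  beta <- XtVinvX_inv %*% crossprod(X, Vinvy)
  Py <- Vinvy - VinvX %*% (XtVinvX_inv %*% crossprod(VinvX, y))
  yPy <- sum(y * Py)
  ll <- -0.5 * (2 * sum(log(diag(ch))) + 2 * sum(log(diag(chx))) +
                  yPy + (n - p) * log(2 * pi))
  out <- list(loglik = ll, beta = drop(beta), XtVinvX_inv = XtVinvX_inv)
  if (want_P) {
    P <- Vinv - VinvX %*% tcrossprod(XtVinvX_inv, VinvX)
    out$P <- P
    out$Py <- drop(Py)
  }
  out
}

#' Restricted log-likelihood of the direct-social animal model
#'
#' Evaluates the REML objective
#' `-0.5 * ( log|V| + log|X'V^{-1}X| + y'Py + (n - p) log 2*pi )`
#' with `V = sigma2_ad Zd A Zd' + sigma_ads (Zd A Zs' + Zs A Zd') +
#' sigma2_as Zs A Zs' + sigma2_l W W' + sigma2_g V V' + sigma2_e I` and `P`
#' the REML projection matrix.
#'
#' @param components Named vector or list with `sigma2_ad, sigma_ads,
#'   sigma2_as, sigma2_l, sigma2_g, sigma2_e`.
#' @param y Response vector (taken from `design` when omitted).
#' @param design An [build_design()] object.
#' @param A Additive relationship matrix over the pedigree.
#' @return The restricted log-likelihood (scalar). Errors if `V` or
#'   `X'V^{-1}X` is singular.
#' @export
reml_loglik <- function(components, y = NULL, design, A) {
  sigma <- .vc(components)
  prep <- .sge_prepare(design, A)
  if (!is.null(y)) prep$y <- as.numeric(y)
  ev <- .reml_eval(sigma, prep)
  if (is.null(ev)) stop("V is singular or not positive definite")
  ev$loglik
}
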