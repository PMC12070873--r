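#' Control parameters for the REML fitter
#'
#' @param max_iter Maximum average-information iterations.
#' @param tol_loglik Relative restricted-log-likelihood change declaring
#'   convergence (default 1e-8).
#' @param tol_grad Gradient-norm threshold (unconstrained scale) that must
#'   also be met (default 1e-4).
#' @param max_halvings Step-halvings tried before the fallback.
#' @param nm_fallback Polish with Nelder-Mead when an AI step cannot
#'   increase the likelihood.
#' @param verbose Print the likelihood path.
#' @return A list of class `sge_control`.
#' @export
sge_control <- function(max_iter = 100L, tol_loglik = 1e-8, tol_grad = 1e-4,
                        max_halvings = 30L, nm_fallback = TRUE,
                        verbose = FALSE) {
  structure(list(max_iter = as.integer(max_iter), tol_loglik = tol_loglik,
                 tol_grad = tol_grad, max_halvings = as.integer(max_halvings),
                 nm_fallback = nm_fallback, verbose = verbose),
            class = "sge_control")
}

# Unconstrained parameterization: log-Cholesky for the 2x2 genetic block
# (guarantees positive semi-definiteness, hence |r_Ads| <= 1 at every
# iterate) and log variances for litter, pen, residual.
.theta_pack <- function(sigma, act) {
  th <- numeric(0)
  if (act$social) {
    t1 <- 0.5 * log(max(sigma[["sigma2_ad"]], 1e-12))
    t2 <- sigma[["sigma_ads"]] / exp(t1)
    rest <- max(sigma[["sigma2_as"]] - t2^2, 1e-12)
    th <- c(th, t1, t2, 0.5 * log(rest))
  } else {
    th <- c(th, 0.5 * log(max(sigma[["sigma2_ad"]], 1e-12)))
  }
  if (act$litter) th <- c(th, log(max(sigma[["sigma2_l"]], 1e-12)))
  if (act$pen) th <- c(th, log(max(sigma[["sigma2_g"]], 1e-12)))
  c(th, log(max(sigma[["sigma2_e"]], 1e-12)))
}

.theta_unpack <- function(theta, act) {
  sigma <- stats::setNames(numeric(6), .sigma_names)
  J <- matrix(0, 6, length(theta),
              dimnames = list(.sigma_names, NULL))
  k <- 0L
  if (act$social) {
    t1 <- theta[1L]; t2 <- theta[2L]; t3 <- theta[3L]
    e1 <- exp(t1); e3 <- exp(t3)
    sigma[c("sigma2_ad", "sigma_ads", "sigma2_as")] <-
      c(e1^2, e1 * t2, t2^2 + e3^2)
    J["sigma2_ad", 1L] <- 2 * e1^2
    J["sigma_ads", 1L] <- e1 * t2
    J["sigma_ads", 2L] <- e1
    J["sigma2_as", 2L] <- 2 * t2
    J["sigma2_as", 3L] <- 2 * e3^2
    k <- 3L
  } else {
    e1 <- exp(theta[1L])
    sigma["sigma2_ad"] <- e1^2
    J["sigma2_ad", 1L] <- 2 * e1^2
    k <- 1L
  }
  for (nm in c(if (act$litter) "sigma2_l", if (act$pen) "sigma2_g",
               "sigma2_e")) {
    k <- k + 1L
    sigma[nm] <- exp(theta[k])
    J[nm, k] <- sigma[nm]
  }
  list(sigma = sigma, J = J)
}

# Gradient and average-information matrix on the variance-component scale.
.reml_score <- function(ev, prep) {
  P <- ev$P
  Py <- ev$Py
  Ms <- list(prep$Mdd, prep$Mds, prep$Mss, prep$Ml, prep$Mg)
  w <- lapply(Ms, function(M) drop(M %*% Py))
  w[[6L]] <- Py
  trPM <- c(vapply(Ms, function(M) sum(P * M), numeric(1)),
            sum(diag(P)))
  yPMPy <- vapply(w, function(wk) sum(Py * wk), numeric(1))
  grad <- -0.5 * (trPM - yPMPy)
  Pw <- lapply(w, function(wk) drop(P %*% wk))
  AI <- matrix(0, 6, 6)
  for (j in 1:6)
    for (l in j:6)
      AI[j, l] <- AI[l, j] <- 0.5 * sum(w[[j]] * Pw[[l]])
  names(grad) <- .sigma_names
  dimnames(AI) <- list(.sigma_names, .sigma_names)
  list(grad = grad, AI = AI)
}

#' Fit the direct-social animal model by REML
#'
#' Estimates the six variance components of
#' `y = X b + Zd a_d + Zs a_s + W l + V g + e`, with
#' `(a_d, a_s) ~ N(0, G0 kron A)`, by maximising the restricted likelihood
#' with average-information (AI) updates in an unconstrained log-Cholesky
#' parameterization of the genetic block (so the estimated `G0` is
#' positive semi-definite at every iterate). The AI step is damped
#' Levenberg-Marquardt style: the damping is raised until a step does not
#' decrease the restricted log-likelihood and relaxed after clear
#' improvements; if no damped step improves, a derivative-free
#' (Nelder-Mead) pass is tried before declaring convergence, and small
#' problems (n <= 300) always receive a final derivative-free polish.
#' The response is standardised internally (all reported quantities are on
#' the original scale), which conditions the iteration and makes the fit
#' exactly equivariant under rescaling of the response. Approximate
#' standard errors come from the inverse of the average-information matrix
#' at the optimum.
#'
#' Initialisation is an equal split of the phenotypic variance across the
#' active variance components with zero direct-social covariance, unless
#' `init` is supplied.
#'
#' @param design An [build_design()] object.
#' @param A Additive relationship matrix over the design's pedigree.
#' @param init Optional named vector of starting components.
#' @param control An [sge_control()].
#' @param social Include the social genetic effect (and its covariance
#'   with the direct effect). `FALSE` reduces the fit to a standard animal
#'   model.
#' @param litter,pen Include the random litter / pen effect.
#' @param blup Also solve for fixed effects and breeding values at the
#'   estimates (via the REML projection; identical to Henderson's
#'   mixed-model equations).
#' @return An object of class `sge_reml`; see [summary.sge_reml()].
#' @seealso [sge_reml()] for the formula interface, [solve_mme()].
#' @export
reml_fit <- function(design, A, init = NULL, control = sge_control(),
                     social = TRUE, litter = TRUE, pen = TRUE,
                     blup = TRUE) {
  stopifnot(inherits(design, "sge_design"), inherits(control, "sge_control"))
  act <- list(social = social, litter = litter, pen = pen)
  prep <- .sge_prepare(design, A)
  n <- prep$n
  if (n <= ncol(prep$X)) stop("need more records than fixed effects")
  # standardise the response: conditions the AI iteration and makes the
  # fit exactly equivariant under rescaling of y
  y_scale <- stats::sd(prep$y)
  if (!is.finite(y_scale) || y_scale == 0)
    stop("response is constant or non-finite")
  prep$y <- prep$y / y_scale
  vy <- 1
  if (is.null(init)) {
    n_active <- 2L + social + litter + pen  # ad, e + optional as, l, g
    s0 <- vy / n_active
    init <- stats::setNames(c(s0, 0, if (social) s0 else 0,
                              if (litter) s0 else 0, if (pen) s0 else 0,
                              s0), .sigma_names)
  } else init <- .vc(init) / y_scale^2
  theta <- .theta_pack(init, act)
  up <- .theta_unpack(theta, act)
  ev <- .reml_eval(up$sigma, prep, want_P = TRUE)
  if (is.null(ev)) stop("initial V not positive definite")
  ll <- ev$loglik
  converged <- FALSE
  used_fallback <- FALSE
  iter <- 0L
  stall <- 0L
  sc <- NULL
  lambda <- 1e-3  # Levenberg-Marquardt damping on the AI matrix
  while (iter < control$max_iter) {
    iter <- iter + 1L
    sc <- .reml_score(ev, prep)
    J <- up$J
    g_th <- drop(crossprod(J, sc$grad))
    AI_th <- crossprod(J, sc$AI %*% J)
    D <- pmax(diag(AI_th), 1e-8)
    accepted <- FALSE
    for (try in seq_len(control$max_halvings)) {
      step <- tryCatch(solve(AI_th + diag(lambda * D, nrow(AI_th)), g_th),
                       error = function(e) NULL)
      if (!is.null(step) && all(is.finite(step))) {
        big <- max(abs(step))
        if (big > 10) step <- step * (10 / big)
        theta_new <- pmin(pmax(theta + step, -30), 30)
        up_new <- .theta_unpack(theta_new, act)
        ev_new <- .reml_eval(up_new$sigma, prep, want_P = TRUE)
        if (!is.null(ev_new) && is.finite(ev_new$loglik) &&
            ev_new$loglik >= ll - 1e-10) {
          accepted <- TRUE
          # relax damping only when the step clearly paid off
          if (ev_new$loglik > ll + 1e-6) lambda <- max(lambda / 5, 1e-10)
          break
        }
      }
      lambda <- lambda * 10
      if (lambda > 1e12) break
    }
    if (!accepted && control$nm_fallback && !used_fallback) {
      used_fallback <- TRUE
      nm <- stats::optim(theta, function(th) {
        e <- .reml_eval(.theta_unpack(th, act)$sigma, prep)
        if (is.null(e) || !is.finite(e$loglik)) 1e30 else -e$loglik
      }, method = "Nelder-Mead", control = list(maxit = 500))
      if (-nm$value > ll + 1e-10) {
        theta_new <- nm$par
        up_new <- .theta_unpack(theta_new, act)
        ev_new <- .reml_eval(up_new$sigma, prep, want_P = TRUE)
        accepted <- !is.null(ev_new)
        lambda <- 1e-3
      }
    }
    if (!accepted) {
      converged <- max(abs(g_th)) < control$tol_grad
      break
    }
    rel <- abs(ev_new$loglik - ll) / (abs(ll) + 1)
    theta <- theta_new
    up <- up_new
    ev <- ev_new
    ll <- ev$loglik
    if (control$verbose)
      message(sprintf("iter %3d  logLik %.6f", iter, ll))
    if (rel < control$tol_loglik) {
      sc <- .reml_score(ev, prep)
      g_th <- drop(crossprod(up$J, sc$grad))
      if (max(abs(g_th)) < control$tol_grad) {
        converged <- TRUE
        break
      }
      stall <- stall + 1L
      if (stall >= 3L) break  # flat likelihood, gradient criterion unmet
    } else stall <- 0L
  }
  # small problems have cheap likelihood evaluations and the roughest
  # surfaces: polish with derivative-free rounds until no further gain
  if (control$nm_fallback && n <= 300L) {
    for (round in 1:3) {
      nm <- stats::optim(theta, function(th) {
        e <- .reml_eval(.theta_unpack(th, act)$sigma, prep)
        if (is.null(e) || !is.finite(e$loglik)) 1e30 else -e$loglik
      }, method = "Nelder-Mead",
      control = list(maxit = 1000, reltol = 1e-12))
      if (-nm$value <= ll + 1e-9) break
      theta <- nm$par
      up <- .theta_unpack(theta, act)
      ev <- .reml_eval(up$sigma, prep, want_P = TRUE)
      ll <- ev$loglik
      used_fallback <- TRUE
    }
    sc <- .reml_score(ev, prep)
    converged <- converged ||
      max(abs(drop(crossprod(up$J, sc$grad)))) < control$tol_grad
  }
  sigma <- up$sigma
  boundary <- any(sigma[c("sigma2_ad",
                          if (social) "sigma2_as",
                          if (litter) "sigma2_l",
                          if (pen) "sigma2_g")] < 1e-6 * vy)
  # SEs from the inverse AI matrix over the active components
  if (is.null(sc)) sc <- .reml_score(ev, prep)
  active <- c("sigma2_ad", if (social) c("sigma_ads", "sigma2_as"),
              if (litter) "sigma2_l", if (pen) "sigma2_g", "sigma2_e")
  se <- stats::setNames(rep(NA_real_, 6), .sigma_names)
  covA <- tryCatch(solve(sc$AI[active, active, drop = FALSE]),
                   error = function(e) NULL)
  if (!is.null(covA)) {
    d <- diag(covA)
    se[active] <- ifelse(d > 0, sqrt(d), NA_real_)
  }
  # map everything back to the original response scale
  s2 <- y_scale^2
  fit <- structure(list(
    components = sigma * s2, se = se * s2,
    loglik = ll - (n - ncol(prep$X)) * log(y_scale),
    iterations = iter,
    converged = converged, boundary = boundary,
    used_fallback = used_fallback, active = active,
    design = design, A = A, control = control,
    n = n, mean_pen_size = mean(table(design$pen))),
    class = "sge_reml")
  if (blup) {
    fit$fixed <- stats::setNames(ev$beta * y_scale, colnames(design$X))
    fit$vcov_fixed <- ev$XtVinvX_inv * s2
    bl <- .blup_from_projection(sigma, ev, design, A)
    fit[names(bl)] <- lapply(bl, function(u) u * y_scale)
    fit$fitted <- design$y - y_scale * sigma[["sigma2_e"]] * ev$Py
    fit$residuals <- y_scale * sigma[["sigma2_e"]] * ev$Py
  }
  fit
}

# BLUP of all random effects from the REML projection:
# u_hat = Cov(u, y) P y, which coincides with the Henderson MME solution.
.blup_from_projection <- function(sigma, ev, design, A) {
  Py <- ev$Py
  q <- length(design$pedigree_ids)
  zd <- numeric(q)
  agg <- rowsum(Py, design$idx_d)
  zd[as.integer(rownames(agg))] <- agg
  pen_sum <- rowsum(Py, design$pen)
  zs <- numeric(q)
  contrib <- pen_sum[as.integer(design$pen)] - Py
  aggs <- rowsum(contrib, design$idx_d)
  zs[as.integer(rownames(aggs))] <- aggs
  ad <- drop(A %*% (sigma[["sigma2_ad"]] * zd + sigma[["sigma_ads"]] * zs))
  as_ <- drop(A %*% (sigma[["sigma_ads"]] * zd + sigma[["sigma2_as"]] * zs))
  names(ad) <- names(as_) <- design$pedigree_ids
  lit <- sigma[["sigma2_l"]] * drop(rowsum(Py, design$litter))
  names(lit) <- levels(design$litter)
  g <- sigma[["sigma2_g"]] * drop(rowsum(Py, design$pen))
  names(g) <- levels(design$pen)
  list(ad_hat = ad, as_hat = as_, litter_hat = lit, pen_hat = g)
}

#' Direct-social animal model: formula interface
#'
#' Fits the animal model with correlated direct and social genetic
#' effects, random litter and pen effects, and a fixed contemporary-group
#' factor given by the formula, e.g. `sge_reml(rfi ~ batch, data, ped)`.
#' The fixed factor is coded intercept + drop-first contrasts. See
#' [reml_fit()] for the estimation algorithm.
#'
#' @param formula `response ~ fixed effects`; terms are looked up in
#'   `data`.
#' @param data Phenotype data frame; must also contain the `id`, `pen` and
#'   `litter` columns.
#' @param pedigree A pedigree covering all phenotyped animals.
#' @param id,pen,litter Column names in `data`.
#' @param A Optional precomputed relationship matrix (otherwise built from
#'   `pedigree`).
#' @param ... Passed to [reml_fit()] (`init`, `control`, `social`,
#'   `litter`, `pen`, `blup`).
#' @return An object of class `sge_reml`.
#' @examples
#' \donttest{
#' study <- simulate_sge_study(sim_config(
#'   n_founders = 40, dams_per_sire = 3, litter_size = 8,
#'   n_pens = 30, pen_size = 8, seed = 42))
#' fit <- sge_reml(y ~ batch, data = study$phenotypes,
#'                 pedigree = study$pedigree)
#' summary(fit)
#' }
#' @export
sge_reml <- function(formula, data, pedigree, id = "animal", pen = "pen",
                     litter = "litter", A = NULL, ...) {
  ped <- if (inherits(pedigree, "sge_pedigree")) pedigree else
    sort_pedigree(pedigree)
  mf <- stats::model.frame(formula, data)
  resp <- as.character(attr(stats::terms(formula), "variables"))[2L]
  design <- build_design(data, ped, response = resp, id = id, pen = pen,
                         litter = litter, fixed = NULL)
  X <- stats::model.matrix(formula, data)
  attr(X, "assign") <- NULL
  attr(X, "contrasts") <- NULL
  design$X <- X
  design$y <- stats::model.response(mf)
  if (is.null(A)) A <- relationship_matrix(ped)
  fit <- reml_fit(design, A, ...)
  fit$call <- match.call()
  fit$formula <- formula
  fit$pedigree <- ped
  fit
}
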