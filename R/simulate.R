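# Per-purpose RNG substreams: adding animals to one stage must not perturb
# draws in another, and the top-level seed fully determines all output.
.sub_seed <- function(seed, purpose) {
  offs <- c(pedigree = 11L, effects = 23L, phenotypes = 37L,
            visits = 53L, omics = 71L, pens = 89L)
  as.integer((as.numeric(seed) * 48271 + offs[[purpose]]) %% 2147483629)
}

.set_seed <- function(seed) {
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
}

#' Configuration for the synthetic study generator
#'
#' Defaults describe the simulated study design used throughout the test
#' suite: 50 sires each mated to 3 dams (200 unrelated founders), one
#' offspring generation of 150 litters of 10 (1500 phenotyped animals)
#' housed in 150 pens of 10, with variance components set to the reference
#' estimates for residual feed intake (direct genetic 2594.808, social
#' genetic 1007.688, direct-social covariance 206.75063, litter 322.848,
#' pen 40354.019, residual 23234.581; trait units g/day squared), three
#' contemporary-group (year-month) levels and an 84-day test.
#'
#' @param n_founders Number of unrelated founders; must equal
#'   `n_sires * (1 + dams_per_sire)` for the nested mating design.
#' @param n_generations Number of offspring generations (0 = founders only).
#' @param dams_per_sire Dams mated to each sire.
#' @param litter_size Offspring per mating.
#' @param n_pens,pen_size Pen structure for the phenotyped generation.
#' @param sigma2_ad,sigma2_as,sigma_ads 2x2 genetic (co)variance of the
#'   direct and social breeding values; must be positive semi-definite.
#' @param sigma2_l,sigma2_g,sigma2_e Litter, pen and residual variances.
#' @param fixed_levels Numeric means of the contemporary-group levels.
#' @param test_days Length of the recording period in days.
#' @param start_date First test day (UTC date).
#' @param seed Integer seed; fully determines all generator output.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 200, n_generations = 1,
                       dams_per_sire = 3, litter_size = 10,
                       n_pens = 150, pen_size = 10,
                       sigma2_ad = 2594.808, sigma2_as = 1007.688,
                       sigma_ads = 206.75063,
                       sigma2_l = 322.848, sigma2_g = 40354.019,
                       sigma2_e = 23234.581,
                       fixed_levels = c(-150, 0, 150),
                       test_days = 84,
                       start_date = "2023-01-01",
                       seed = 1) {
  cfg <- list(n_founders = as.integer(n_founders),
              n_generations = as.integer(n_generations),
              dams_per_sire = as.integer(dams_per_sire),
              litter_size = as.integer(litter_size),
              n_pens = as.integer(n_pens), pen_size = as.integer(pen_size),
              sigma2_ad = sigma2_ad, sigma2_as = sigma2_as,
              sigma_ads = sigma_ads, sigma2_l = sigma2_l,
              sigma2_g = sigma2_g, sigma2_e = sigma2_e,
              fixed_levels = fixed_levels, test_days = as.integer(test_days),
              start_date = start_date, seed = as.integer(seed))
  if (cfg$n_founders < 1L) stop("need at least one founder")
  if (cfg$litter_size < 1L) stop("litter_size must be at least 1")
  if (cfg$dams_per_sire < 1L) stop("dams_per_sire must be at least 1")
  if (cfg$pen_size < 2L) stop("pen_size must be at least 2")
  if (cfg$n_founders %% (1L + cfg$dams_per_sire) != 0L)
    stop("n_founders must be a multiple of 1 + dams_per_sire")
  vars <- c(cfg$sigma2_ad, cfg$sigma2_as, cfg$sigma2_l, cfg$sigma2_g,
            cfg$sigma2_e)
  if (any(vars < 0)) stop("variances must be non-negative")
  if (cfg$sigma_ads^2 > cfg$sigma2_ad * cfg$sigma2_as + 1e-12)
    stop("genetic covariance exceeds its Cauchy-Schwarz bound (g0 not PSD)")
  if (!length(cfg$fixed_levels)) stop("need at least one fixed level")
  class(cfg) <- "sim_config"
  cfg
}

.g0 <- function(config) {
  matrix(c(config$sigma2_ad, config$sigma_ads,
           config$sigma_ads, config$sigma2_as), 2, 2)
}

#' Simulate a pedigree under a nested mating design
#'
#' Founders are unrelated and non-inbred; generation 0 comprises
#' `n_sires = n_founders / (1 + dams_per_sire)` sires and
#' `n_sires * dams_per_sire` dams. Each subsequent generation mates every
#' sire to `dams_per_sire` dams drawn from the previous generation, each
#' mating producing one litter of `litter_size` offspring with sexes
#' balanced within litter. Litter labels record the dam mating.
#'
#' @param config A [sim_config()].
#' @return A sorted `sge_pedigree` data frame with columns `animal, sire,
#'   dam, sex, generation, litter`.
#' @export
simulate_pedigree <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  .set_seed(.sub_seed(config$seed, "pedigree"))
  n_sires <- config$n_founders %/% (1L + config$dams_per_sire)
  n_dams <- n_sires * config$dams_per_sire
  id <- function(prefix, g, k) sprintf("%s%d_%04d", prefix, g, k)
  ped <- data.frame(animal = id("A", 0L, seq_len(config$n_founders)),
                    sire = NA_character_, dam = NA_character_,
                    sex = rep(c("M", "F"),
                              c(n_sires, config$n_founders - n_sires)),
                    generation = 0L, litter = NA_character_,
                    stringsAsFactors = FALSE)
  prev <- ped
  if (config$n_generations > 0L) {
    for (g in seq_len(config$n_generations)) {
      males <- prev$animal[prev$sex == "M"]
      females <- prev$animal[prev$sex == "F"]
      if (length(males) < n_sires || length(females) < n_dams)
        stop("not enough candidates of each sex in generation ", g - 1L)
      sires <- if (length(males) == n_sires) males else
        sample(males, n_sires)
      dams <- if (length(females) == n_dams) females else
        sample(females, n_dams)
      sire_of_mating <- rep(sires, each = config$dams_per_sire)
      n_mat <- length(dams)
      off <- data.frame(
        animal = id("A", g, seq_len(n_mat * config$litter_size)),
        sire = rep(sire_of_mating, each = config$litter_size),
        dam = rep(dams, each = config$litter_size),
        sex = rep_len(c("M", "F"), n_mat * config$litter_size),
        generation = g,
        litter = rep(sprintf("L%d_%03d", g, seq_len(n_mat)),
                     each = config$litter_size),
        stringsAsFactors = FALSE)
      ped <- rbind(ped, off)
      prev <- off
    }
  }
  rownames(ped) <- NULL
  class(ped) <- c("sge_pedigree", "data.frame")
  ped
}

# Memoised pairwise kinship; scales to deep/large pedigrees without the
# dense A matrix. f(i,i) = 0.5 * (1 + F_i).
.kinship_fun <- function(ped) {
  pp <- .check_sorted(ped)
  si <- pp$sire
  di <- pp$dam
  memo <- new.env(hash = TRUE, parent = emptyenv())
  f <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    if (i > j) { tmp <- i; i <- j; j <- tmp }
    key <- paste0(i, ":", j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    val <- if (i == j) {
      0.5 * (1 + f(si[i], di[i]))
    } else {
      # recurse on the younger animal (j > i implies j is not i's ancestor)
      0.5 * (f(i, si[j]) + f(i, di[j]))
    }
    memo[[key]] <- val
    val
  }
  list(f = f, sire = si, dam = di, ped = pp$ped)
}

#' Simulate true direct and social breeding values
#'
#' Samples `(a_d, a_s)` jointly distributed as `N(0, G0 kron A)` by
#' sequential recursion down the sorted pedigree: founders are drawn from
#' `N(0, G0)`; an offspring's mean is half the sum of its parents' values
#' and its Mendelian-segregation draw has covariance `m * G0` with
#' `m = 1` (no parents known), `m = 0.75 - 0.25 * F_p` (one parent) or
#' `m = 0.5 - 0.25 * (F_s + F_d)` (both parents), the standard scaling that
#' makes the recursion exact for the full covariance.
#'
#' @param ped A sorted pedigree ([sort_pedigree()] / [simulate_pedigree()]).
#' @param g0 2x2 genetic covariance matrix (or a [sim_config()], whose
#'   genetic block is used); must be positive semi-definite.
#' @param seed Integer seed.
#' @return Data frame `animal, a_d, a_s` in pedigree order.
#' @export
simulate_true_effects <- function(ped, g0, seed = 1) {
  if (inherits(g0, "sim_config")) g0 <- .g0(g0)
  g0 <- as.matrix(g0)
  if (!isTRUE(all.equal(g0, t(g0))) ||
      any(eigen(g0, symmetric = TRUE, only.values = TRUE)$values < -1e-8))
    stop("g0 must be symmetric positive semi-definite")
  kf <- .kinship_fun(ped)
  si <- kf$sire
  di <- kf$dam
  n <- length(si)
  ev <- eigen(g0, symmetric = TRUE)
  L <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), 2) %*% t(ev$vectors)
  .set_seed(.sub_seed(seed, "effects"))
  z <- matrix(stats::rnorm(2L * n), nrow = 2L)
  draws <- L %*% z  # 2 x n
  a <- matrix(0, n, 2L)
  founder <- is.na(si) & is.na(di)
  a[founder, ] <- t(draws[, founder, drop = FALSE])
  Fcoef <- numeric(n)  # founders 0
  for (i in which(!founder)) {
    s <- si[i]
    d <- di[i]
    Fcoef[i] <- if (!is.na(s) && !is.na(d)) 0.5 * kf$f(s, d) else 0
    if (!is.na(s) && !is.na(d)) {
      m <- 0.5 - 0.25 * (Fcoef[s] + Fcoef[d])
      mu <- 0.5 * (a[s, ] + a[d, ])
    } else {
      p <- if (!is.na(s)) s else d
      m <- 0.75 - 0.25 * Fcoef[p]
      mu <- 0.5 * a[p, ]
    }
    a[i, ] <- mu + sqrt(m) * draws[, i]
  }
  data.frame(animal = kf$ped$animal, a_d = a[, 1L], a_s = a[, 2L],
             stringsAsFactors = FALSE)
}

.as_map <- function(x, value_col, ids = NULL) {
  if (is.data.frame(x)) {
    out <- stats::setNames(as.character(x[[value_col]]),
                           as.character(x$animal))
  } else out <- stats::setNames(as.character(x), names(x))
  out
}

#' Simulate phenotypes under the direct-social animal model
#'
#' For each animal `i` with a pen and a litter,
#' `y_i = b[batch(i)] + a_d[i] + sum_(j in pen(i), j != i) a_s[j]
#'        + l[litter(i)] + g[pen(i)] + e_i`,
#' with litter, pen and residual effects independent mean-zero normals at
#' the configured variances. Contemporary-group (batch) levels are assigned
#' to pens round-robin over `config$fixed_levels`.
#'
#' @param ped Pedigree containing every phenotyped animal.
#' @param pen_map Named character vector or data frame (`animal`, `pen`)
#'   assigning each phenotyped animal to one pen.
#' @param litter_map Same shape, assigning each phenotyped animal a litter.
#' @param effects Output of [simulate_true_effects()] for `ped`.
#' @param config A [sim_config()] (variances, fixed levels, seed).
#' @return Data frame `animal, pen, litter, batch, y` (one row per animal
#'   in `pen_map`).
#' @export
simulate_phenotypes <- function(ped, pen_map, litter_map, effects, config) {
  stopifnot(inherits(config, "sim_config"))
  pen <- .as_map(pen_map, "pen")
  lit <- .as_map(litter_map, "litter")
  ids <- names(pen)
  if (anyNA(pen) || is.null(ids)) stop("every animal needs a pen")
  if (!all(ids %in% names(lit)) || anyNA(lit[ids]))
    stop("every phenotyped animal needs a litter")
  if (!all(ids %in% ped$animal)) stop("phenotyped animal absent from pedigree")
  eff <- effects[match(ids, effects$animal), , drop = FALSE]
  if (anyNA(eff$a_d)) stop("effects missing for some phenotyped animals")
  pens <- unique(pen[ids])
  lits <- unique(lit[ids])
  batch_of_pen <- stats::setNames(
    rep_len(seq_along(config$fixed_levels), length(pens)), pens)
  .set_seed(.sub_seed(config$seed, "phenotypes"))
  l_eff <- stats::setNames(stats::rnorm(length(lits), 0,
                                        sqrt(config$sigma2_l)), lits)
  g_eff <- stats::setNames(stats::rnorm(length(pens), 0,
                                        sqrt(config$sigma2_g)), pens)
  e <- stats::rnorm(length(ids), 0, sqrt(config$sigma2_e))
  # pen-mate social sums: total pen a_s minus own
  pen_tot <- tapply(eff$a_s, pen[ids], sum)
  social <- as.numeric(pen_tot[pen[ids]]) - eff$a_s
  b <- config$fixed_levels[batch_of_pen[pen[ids]]]
  y <- b + eff$a_d + social + l_eff[lit[ids]] + g_eff[pen[ids]] + e
  data.frame(animal = ids, pen = unname(pen[ids]), litter = unname(lit[ids]),
             batch = paste0("B", batch_of_pen[pen[ids]]),
             y = as.numeric(y), stringsAsFactors = FALSE, row.names = NULL)
}

#' Simulate a complete study
#'
#' Convenience wrapper: pedigree, true breeding values, random assignment
#' of the final generation to pens, and phenotypes. The final generation
#' size must equal `n_pens * pen_size`.
#'
#' @param config A [sim_config()].
#' @return List with elements `config`, `pedigree`, `effects`,
#'   `phenotypes`, `pen_map`, `litter_map`.
#' @export
simulate_sge_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  ped <- simulate_pedigree(config)
  eff <- simulate_true_effects(ped, .g0(config), seed = config$seed)
  last <- ped[ped$generation == max(ped$generation), , drop = FALSE]
  n_phen <- config$n_pens * config$pen_size
  if (nrow(last) != n_phen)
    stop(sprintf("final generation has %d animals but pens need %d",
                 nrow(last), n_phen))
  .set_seed(.sub_seed(config$seed, "pens"))
  ord <- sample(nrow(last))
  pen_map <- stats::setNames(
    rep(sprintf("P%03d", seq_len(config$n_pens)), each = config$pen_size),
    last$animal[ord])
  litter_map <- stats::setNames(last$litter, last$animal)
  phen <- simulate_phenotypes(ped, pen_map, litter_map, eff, config)
  list(config = config, pedigree = ped, effects = eff, phenotypes = phen,
       pen_map = pen_map, litter_map = litter_map)
}
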