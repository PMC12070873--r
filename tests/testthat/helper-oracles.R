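# Independent brute-force oracles shared across test files. Each oracle is
# deliberately written from the definition, not from the package's code
# path.

# Additive relationship by gene dropping: founder alleles get unique
# labels, offspring inherit one random allele per parent, and A_ij is
# estimated as twice the probability that randomly drawn alleles of i and
# j are identical by descent. Returns the estimate and its binomial MC SD.
gene_drop_A <- function(ped, R = 1e5) {
  ped <- sgeRFI::sort_pedigree(ped)
  ids <- ped$animal
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  n <- length(ids)
  L1 <- matrix(0L, R, n)
  L2 <- matrix(0L, R, n)
  lab <- 0L
  for (i in seq_len(n)) {
    if (is.na(si[i])) L1[, i] <- (lab <- lab + 1L) else {
      pick <- stats::runif(R) < 0.5
      L1[, i] <- ifelse(pick, L1[, si[i]], L2[, si[i]])
    }
    if (is.na(di[i])) L2[, i] <- (lab <- lab + 1L) else {
      pick <- stats::runif(R) < 0.5
      L2[, i] <- ifelse(pick, L1[, di[i]], L2[, di[i]])
    }
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  SD <- A
  for (i in seq_len(n)) {
    for (j in i:n) {
      ai <- ifelse(stats::runif(R) < 0.5, L1[, i], L2[, i])
      bj <- ifelse(stats::runif(R) < 0.5, L1[, j], L2[, j])
      f <- mean(ai == bj)
      A[i, j] <- A[j, i] <- 2 * f
      SD[i, j] <- SD[j, i] <- 2 * sqrt(f * (1 - f) / R)
    }
  }
  list(A = A, sd = SD)
}

# Displacement success by O(V^2) all-pairs enumeration over (exit, entry)
# event pairs within a pen.
ds_brute_force <- function(visits, gap_s = 2) {
  animals <- sort(unique(visits$animal_id))
  S <- setNames(numeric(length(animals)), animals)
  B <- S
  en <- as.numeric(visits$entry_ts)
  ex <- as.numeric(visits$exit_ts)
  nv <- nrow(visits)
  for (a in seq_len(nv)) {
    for (b in seq_len(nv)) {
      if (visits$pen_id[a] != visits$pen_id[b]) next
      if (visits$animal_id[a] == visits$animal_id[b]) next
      gap <- en[b] - ex[a]
      if (gap >= 0 && gap <= gap_s) {
        S[visits$animal_id[b]] <- S[visits$animal_id[b]] + 1
        B[visits$animal_id[a]] <- B[visits$animal_id[a]] + 1
      }
    }
  }
  tot <- S + B
  data.frame(animal_id = animals, succeeded = as.numeric(S),
             was_succeeded = as.numeric(B),
             DS = ifelse(tot > 0, 100 * S / tot, NA_real_),
             stringsAsFactors = FALSE)
}

# Benjamini-Hochberg step-up from the definition.
bh_brute_force <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (r in seq_len(m)) {
    i <- o[r]
    q[i] <- min(vapply(r:m, function(j) p[o[j]] * m / j, numeric(1)), 1)
  }
  q
}

# Restricted log-likelihood evaluated through base determinant()/solve(),
# never through the package's Cholesky path.
reml_ll_dense <- function(components, design, A) {
  sigma <- components
  Zstar <- cbind(design$Zd, design$Zs)
  G0 <- matrix(c(sigma[["sigma2_ad"]], sigma[["sigma_ads"]],
                 sigma[["sigma_ads"]], sigma[["sigma2_as"]]), 2, 2)
  V <- Zstar %*% kronecker(G0, A) %*% t(Zstar) +
    sigma[["sigma2_l"]] * tcrossprod(design$W) +
    sigma[["sigma2_g"]] * tcrossprod(design$V) +
    diag(sigma[["sigma2_e"]], nrow(design$X))
  X <- design$X
  y <- design$y
  n <- length(y)
  p <- ncol(X)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtViX) %*% t(X) %*% Vi
  -0.5 * (as.numeric(determinant(V)$modulus) +
            as.numeric(determinant(XtViX)$modulus) +
            drop(t(y) %*% P %*% y) + (n - p) * log(2 * pi))
}

# A small simulated dataset for model tests: returns design + A + truth.
tiny_study <- function(seed, n_founders = 24, dams_per_sire = 2,
                       litter_size = 6, n_pens = 12, pen_size = 8, ...) {
  cfg <- sgeRFI::sim_config(n_founders = n_founders,
                            dams_per_sire = dams_per_sire,
                            litter_size = litter_size, n_pens = n_pens,
                            pen_size = pen_size, seed = seed, ...)
  st <- sgeRFI::simulate_sge_study(cfg)
  des <- sgeRFI::build_design(st$phenotypes, st$pedigree)
  A <- sgeRFI::relationship_matrix(st$pedigree)
  list(study = st, design = des, A = A, config = cfg)
}

table1_components <- function() {
  path <- system.file("extdata", "study_variance_components.tsv",
                      package = "sgeRFI")
  tab <- read.delim(path)
  setNames(tab$estimate, tab$component)
}
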