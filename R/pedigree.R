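#' Sort and validate a pedigree
#'
#' Normalises a raw pedigree (animal/sire/dam records) into the form required
#' by [relationship_matrix()]: unique ids, unknown parents coded `NA`, and a
#' topological order in which every parent precedes its offspring.
#'
#' Unknown parents may be supplied as `NA`, the empty string, or `"0"`; all
#' are normalised to `NA` and treated as unrelated, non-inbred founders.
#'
#' @param ped A data frame with columns `animal`, `sire`, `dam` (coerced to
#'   character). Extra columns are carried along.
#' @return A data frame of class `sge_pedigree`, topologically sorted.
#' @examples
#' ped <- data.frame(animal = c("o1", "s", "d"),
#'                   sire   = c("s", NA, NA),
#'                   dam    = c("d", NA, NA))
#' sort_pedigree(ped)
#' @export
sort_pedigree <- function(ped) {
  ped <- as.data.frame(ped)
  need <- c("animal", "sire", "dam")
  if (!all(need %in% names(ped)))
    stop("pedigree must have columns 'animal', 'sire', 'dam'")
  for (col in need) {
    v <- as.character(ped[[col]])
    v[!is.na(v) & (v == "" | v == "0")] <- NA_character_
    ped[[col]] <- v
  }
  if (anyNA(ped$animal)) stop("missing animal id in pedigree")
  if (anyDuplicated(ped$animal))
    stop("duplicate animal id(s): ",
         paste(unique(ped$animal[duplicated(ped$animal)]), collapse = ", "))
  ids <- ped$animal
  # parents that never appear as animals become implicit founders
  ghosts <- setdiff(stats::na.omit(c(ped$sire, ped$dam)), ids)
  if (length(ghosts)) {
    extra <- ped[rep.int(NA_integer_, length(ghosts)), , drop = FALSE]
    extra$animal <- ghosts
    extra$sire <- NA_character_
    extra$dam <- NA_character_
    ped <- rbind(extra, ped)
    ids <- ped$animal
  }
  n <- nrow(ped)
  sire_i <- match(ped$sire, ids)
  dam_i <- match(ped$dam, ids)
  # Kahn's algorithm on the parent -> offspring DAG
  indeg <- (!is.na(sire_i)) + (!is.na(dam_i))
  kids <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(sire_i[i], dam_i[i]))
      if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
  }
  order <- integer(0)
  ready <- which(indeg == 0L)
  while (length(ready)) {
    i <- ready[1L]
    ready <- ready[-1L]
    order <- c(order, i)
    for (k in kids[[i]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) ready <- c(ready, k)
    }
  }
  if (length(order) < n) {
    cyc <- setdiff(seq_len(n), order)
    stop("pedigree contains a cycle involving: ",
         paste(ids[cyc], collapse = ", "))
  }
  out <- ped[order, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("sge_pedigree", "data.frame")
  out
}

.check_sorted <- function(ped) {
  if (!inherits(ped, "sge_pedigree")) ped <- sort_pedigree(ped)
  ids <- ped$animal
  si <- match(ped$sire, ids)
  di <- match(ped$dam, ids)
  if (any(si >= seq_along(ids), na.rm = TRUE) ||
      any(di >= seq_along(ids), na.rm = TRUE))
    stop("pedigree is not sorted: a parent follows its offspring")
  list(ped = ped, sire = si, dam = di)
}

#' Additive genetic relationship matrix
#'
#' Builds the numerator relationship matrix A from a sorted pedigree by the
#' tabular method: for animal `i` with parents `s` and `d`,
#' `A[j, i] = 0.5 * (A[j, s] + A[j, d])` for earlier `j` (a missing parent
#' contributes 0) and `A[i, i] = 1 + 0.5 * A[s, d]`.
#'
#' Unknown parents are treated as unrelated non-inbred founders, so the
#' diagonal equals `1 + F` with `F` the inbreeding coefficient and founders
#' have diagonal exactly 1. The result is symmetric positive semi-definite.
#'
#' @param ped A pedigree, sorted with [sort_pedigree()] (unsorted input is
#'   sorted on the fly; input where a parent follows its offspring after an
#'   explicit `sge_pedigree` claim is an error).
#' @return A dense symmetric matrix with dimnames equal to the animal ids,
#'   in pedigree order.
#' @seealso [inbreeding()]
#' @examples
#' ped <- sort_pedigree(data.frame(animal = c("s", "d", "o"),
#'                                 sire = c(NA, NA, "s"),
#'                                 dam  = c(NA, NA, "d")))
#' relationship_matrix(ped)
#' @export
relationship_matrix <- function(ped) {
  pp <- .check_sorted(ped)
  ids <- pp$ped$animal
  si <- pp$sire
  di <- pp$dam
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    s <- si[i]
    d <- di[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      row <- numeric(i - 1L)
      if (!is.na(s)) row <- row + A[j, s]
      if (!is.na(d)) row <- row + A[j, d]
      row <- 0.5 * row
      A[j, i] <- row
      A[i, j] <- row
    }
    A[i, i] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Inbreeding coefficients
#'
#' `F = diag(A) - 1` from the tabular relationship matrix.
#'
#' @inheritParams relationship_matrix
#' @return Named numeric vector of inbreeding coefficients in pedigree order.
#' @export
inbreeding <- function(ped) {
  diag(relationship_matrix(ped)) - 1
}

#' Read or write a pedigree CSV
#'
#' The on-disk dialect is a plain CSV with columns `animal,sire,dam`; an
#' empty field or `0` means unknown parent.
#'
#' @param file Path to a CSV file.
#' @param ped A pedigree data frame.
#' @return `read_pedigree()` returns a sorted `sge_pedigree`;
#'   `write_pedigree()` is called for its side effect and returns `file`
#'   invisibly.
#' @export
read_pedigree <- function(file) {
  raw <- utils::read.csv(file, colClasses = "character")
  sort_pedigree(raw)
}

#' @rdname read_pedigree
#' @export
write_pedigree <- function(ped, file) {
  out <- as.data.frame(ped)[, c("animal", "sire", "dam")]
  out$sire[is.na(out$sire)] <- ""
  out$dam[is.na(out$dam)] <- ""
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}
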