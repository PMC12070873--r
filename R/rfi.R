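#' Residual feed intake coefficients
#'
#' The fixed literature coefficients of the residual feed intake regression
#' used throughout: expected intake is `1.41 * ADG + 2.83 * BF + 110.9 * AMW`
#' and RFI is the observed average daily feed intake minus that expectation.
#'
#' @param c_adg Grams of feed per gram of average daily gain (default 1.41).
#' @param c_bf Coefficient on backfat depth in mm (default 2.83).
#' @param c_amw Coefficient on average metabolic body weight (default 110.9).
#' @return A named list of class `rfi_coefficients`.
#' @export
rfi_coefficients <- function(c_adg = 1.41, c_bf = 2.83, c_amw = 110.9) {
  co <- list(c_adg = c_adg, c_bf = c_bf, c_amw = c_amw)
  if (!all(vapply(co, function(x) is.numeric(x) && length(x) == 1L &&
                    is.finite(x), logical(1))))
    stop("RFI coefficients must be finite scalars")
  class(co) <- "rfi_coefficients"
  co
}

#' Average metabolic body weight
#'
#' Interval average of the metabolic weight `W^0.6` between the on-test and
#' off-test weights:
#' `AMW = (W2^1.6 - W1^1.6) / (1.6 * (W2 - W1))`,
#' with the analytic limit `W1^0.6` when `W1 == W2` (the integrand evaluated
#' at the common weight). Vectorised over both arguments.
#'
#' @param w1,w2 Initial and final body weight in kg, both > 0.
#' @param tol Width below which `|w2 - w1|` is treated as zero and the limit
#'   is returned; default `1e-9` kg.
#' @return AMW in kg^0.6 units.
#' @examples
#' compute_amw(33.6, 111)
#' compute_amw(50, 50)  # = 50^0.6
#' @export
compute_amw <- function(w1, w2, tol = 1e-9) {
  if (any(!is.finite(w1)) || any(!is.finite(w2)) ||
      any(w1 <= 0) || any(w2 <= 0))
    stop("weights must be finite and positive")
  degenerate <- abs(w2 - w1) < tol
  out <- ifelse(degenerate,
                w1^0.6,
                (w2^1.6 - w1^1.6) / (1.6 * (w2 - w1)))
  out
}

#' Residual feed intake
#'
#' `RFI = ADFI - c_adg * ADG - c_bf * BF - c_amw * AMW`. The default unit
#' convention is grams/day for ADFI and ADG (matching how the trait is
#' reported), backfat in mm, and AMW computed from kg body weights; the
#' coefficients are configuration, not re-estimated from data.
#'
#' @param adfi Average daily feed intake, g/day.
#' @param adg Average daily gain, g/day.
#' @param bf Backfat depth, mm.
#' @param amw Average metabolic body weight from [compute_amw()].
#' @param coeffs An [rfi_coefficients()] object.
#' @return RFI in g/day (vectorised).
#' @examples
#' compute_rfi(2000, 900, 10, 12)  # -628.1
#' @export
compute_rfi <- function(adfi, adg, bf, amw, coeffs = rfi_coefficients()) {
  stopifnot(inherits(coeffs, "rfi_coefficients"))
  vals <- c(adfi, adg, bf, amw)
  if (any(!is.finite(vals))) stop("RFI inputs must be finite")
  adfi - coeffs$c_adg * adg - coeffs$c_bf * bf - coeffs$c_amw * amw
}

#' Add RFI to a feeding-trait table
#'
#' Convenience wrapper joining [compute_amw()] and [compute_rfi()] onto the
#' per-animal trait table produced by [derive_traits()].
#'
#' @param traits Data frame with columns `W1`, `W2`, `ADFI`, `ADG`, `bf_mm`.
#' @param coeffs An [rfi_coefficients()] object.
#' @return `traits` with columns `AMW` and `RFI` appended.
#' @export
add_rfi <- function(traits, coeffs = rfi_coefficients()) {
  need <- c("W1", "W2", "ADFI", "ADG", "bf_mm")
  if (!all(need %in% names(traits)))
    stop("traits table must have columns: ", paste(need, collapse = ", "))
  traits$AMW <- compute_amw(traits$W1, traits$W2)
  traits$RFI <- compute_rfi(traits$ADFI, traits$ADG, traits$bf_mm,
                            traits$AMW, coeffs)
  traits
}
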