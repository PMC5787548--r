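# Standardized value transforms: head-size (eTIV) scaling with geometric
# exponents, multiplicative scanner-sequence contrast normalization, and the
# interhemispheric asymmetry index.

#' Scale a value to a reference intracranial volume
#'
#' Computes `value * (etiv_ref / etiv_subject)^exponent`, i.e. the value the
#' subject would show if their head had the reference intracranial volume,
#' under purely geometric scaling. The reference is conventionally the mean
#' eTIV of the full control dataset, frozen when the normative database is
#' built.
#'
#' @param value Measured value(s), native units.
#' @param etiv_subject Subject eTIV (mm^3), positive.
#' @param etiv_ref Reference eTIV (mm^3), positive.
#' @param exponent Geometric exponent from [scaling_exponent()].
#' @return Normalized value(s).
#' @export
#' @examples
#' normalize_etiv(100, 1.5e6, 1.5e6, 1)     # identity at the reference
#' normalize_etiv(100, 2 * 1.5e6, 1.5e6, 1) # a doubled head halves volume
normalize_etiv <- function(value, etiv_subject, etiv_ref, exponent) {
  if (any(!is.finite(etiv_subject) | etiv_subject <= 0) ||
      any(!is.finite(etiv_ref) | etiv_ref <= 0)) {
    abort("eTIV values must be finite and positive")
  }
  value * (etiv_ref / etiv_subject)^exponent
}

#' Multiplicative scanner-sequence factors for contrast normalization
#'
#' The gray-white contrast depends strongly on scanner and sequence, so each
#' scanner-sequence group of healthy controls is rescaled multiplicatively to
#' the grand control mean. This returns the per-group factors
#' `grand mean / group mean` estimated from control values.
#'
#' @param values Control values.
#' @param group Scanner-sequence group label per value.
#' @return Tibble with columns `group`, `factor`, `n`.
#' @export
contrast_factors <- function(values, group) {
  ok <- is.finite(values)
  values <- values[ok]
  group <- group[ok]
  if (length(values) == 0) abort("No finite values to normalize")
  grand <- mean(values)
  out <- tibble::tibble(group = group, value = values) |>
    dplyr::summarise(mean = mean(.data$value), n = dplyr::n(),
                     .by = "group")
  if (any(out$mean == 0)) {
    abort(paste0("Contrast group(s) with zero mean: ",
                 paste(out$group[out$mean == 0], collapse = ", ")))
  }
  out$factor <- grand / out$mean
  dplyr::select(out, "group", "factor", "n")
}

#' Normalize contrast values to a common group mean
#'
#' Rescales each scanner-sequence group so that the healthy-control mean of
#' every group equals the grand control mean. When `reference` factors (from
#' [contrast_factors()] on the control set) are supplied, patient values are
#' rescaled by their own group's control-derived factor; a patient group
#' absent from the control set is an error (unmatchable combination).
#'
#' @param values Values to normalize.
#' @param group Scanner-sequence label per value.
#' @param reference Optional factor table from [contrast_factors()]; if
#'   `NULL`, factors are estimated from `values` themselves.
#' @return Normalized values, same length as `values`.
#' @export
#' @examples
#' # two control groups with means 10 and 20 are both rescaled to mean 15
#' normalize_contrast(c(9, 11, 19, 21), c("a", "a", "b", "b"))
normalize_contrast <- function(values, group, reference = NULL) {
  fac <- reference %||% contrast_factors(values, group)
  missing_groups <- setdiff(unique(group), fac$group)
  if (length(missing_groups) > 0) {
    abort(paste0("Scanner-sequence combination(s) absent from the control ",
                 "set: ", paste(missing_groups, collapse = ", ")))
  }
  values * fac$factor[match(group, fac$group)]
}

#' Interhemispheric asymmetry index
#'
#' `AI = (right - left) / (right + left)`: zero for complete symmetry, +1
#' for extremely right-dominated and -1 for extremely left-dominated
#' structures. Computed from raw (not eTIV-normalized) values; for pairs
#' sharing a scaling exponent the eTIV factors cancel exactly. A pair whose
#' sum is zero yields `NA` (excluded downstream).
#'
#' @param right,left Paired values.
#' @return Asymmetry index in `[-1, 1]`, `NA` where `right + left == 0`.
#' @export
#' @examples
#' asymmetry_index(1, 1) # 0
#' asymmetry_index(1, 0) # +1
#' asymmetry_index(1, 3) # -0.5
asymmetry_index <- function(right, left) {
  s <- right + left
  out <- (right - left) / s
  out[!is.na(s) & s == 0] <- NA_real_
  out
}
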