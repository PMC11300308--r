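#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used when reporting percentages in
#' summary tables. Base R's `round()` rounds half to even, which disagrees
#' with hand-tabulated percentages at exact .5 boundaries.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Missing-aware logical OR
#'
#' Elementwise OR across several logical vectors where `NA` means "not
#' measured": any `TRUE` wins; all-`NA` stays `NA`; otherwise `FALSE`.
#' This is the semantics used to combine component lab thresholds into a
#' single criterion: an unmeasured lab can never satisfy a criterion, and a
#' criterion is only fully unknown when every component is unmeasured.
#'
#' @param ... logical vectors of equal length (length-1 vectors recycled).
#' @return logical vector.
#' @export
or_na <- function(...) {
  args <- list(...)
  m <- do.call(cbind, args)
  any_true <- apply(m, 1L, function(r) any(r %in% TRUE))
  all_na <- apply(m, 1L, function(r) all(is.na(r)))
  out <- rep(FALSE, nrow(m))
  out[any_true] <- TRUE
  out[!any_true & all_na] <- NA
  out
}

# TRUE where x is TRUE, FALSE where NA or FALSE: NA criteria count as unmet
# when matching stage rule combinations.
isTRUE_vec <- function(x) !is.na(x) & x

`%||%` <- function(a, b) if (is.null(a)) b else a
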