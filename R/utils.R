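# internal helpers shared across modules

#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero, the
#' convention used in agronomic report tables (base [round()] rounds ties to
#' even).
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return numeric vector of the same length as `x`.
#' @examples
#' round_half_away(0.125, 2)  # 0.13, where round() gives 0.12
#' @export
round_half_away <- function(x, digits = 0) {
  p <- 10^digits
  # nudge by an ulp-scale epsilon so values like 14.385 stored as 14.38499...
  # from decimal-binary conversion still round as printed
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# significance stars at the 0.05 / 0.01 convention used in trial reports
sig_stars <- function(p) {
  ifelse(is.na(p), NA_character_,
         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}
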