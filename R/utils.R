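#' @importFrom rlang %||% .data
#' @importFrom stats quantile rlnorm rpois runif dnorm
NULL

# Multi-code claim fields are serialized as ";"-separated strings so the
# claims table round-trips through plain CSV.
split_codes <- function(x) {
  x <- ifelse(is.na(x), "", x)
  strsplit(x, ";", fixed = TRUE)
}

join_codes <- function(codes) {
  vapply(codes, function(z) paste(z[nzchar(z)], collapse = ";"), character(1))
}

has_any_code <- function(field, codeset) {
  vapply(split_codes(field), function(z) any(z %in% codeset), logical(1))
}

#' Round a vector to integers while preserving its sum
#'
#' Largest-remainder (Hamilton) rounding: each component is floored and the
#' leftover units are given to the components with the largest fractional
#' parts, ties broken by position.  Used for bed allocation so that
#' emergent + elective + available always equals the total bed count
#' exactly.
#'
#' @param x Non-negative numeric vector.
#' @param total Integer the rounded vector must sum to; defaults to
#'   `round(sum(x))`.
#' @return Integer vector of `length(x)` summing exactly to `total`.
#' @examples
#' round_preserve_sum(c(56.0, 24.0, 20.0))
#' round_preserve_sum(c(1.4, 1.4, 1.2), total = 4)
#' @export
round_preserve_sum <- function(x, total = round(sum(x))) {
  if (any(x < -1e-8)) stop("round_preserve_sum() requires non-negative input")
  x <- pmax(x, 0)
  fl <- floor(x + 1e-9)
  rem <- as.integer(round(total)) - as.integer(sum(fl))
  if (rem < 0L || rem > length(x)) {
    stop("total is inconsistent with sum(x); cannot apportion remainder")
  }
  if (rem > 0L) {
    frac <- x - fl
    idx <- order(frac, decreasing = TRUE)[seq_len(rem)]
    fl[idx] <- fl[idx] + 1
  }
  as.integer(fl)
}

# Quartiles by linear interpolation between order statistics
# (stats::quantile type 7), the convention used for all IQR reporting.
quartiles <- function(x) {
  stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE,
                  na.rm = TRUE)
}

mdc_code_universe <- function() sprintf("%02d", 1:25)

check_probability <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1) {
    stop(sprintf("`%s` must be a single probability in [0, 1]", name),
         call. = FALSE)
  }
  invisible(x)
}

as_date_scalar <- function(x) as.Date(x, origin = "1970-01-01")
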