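#' Round half away from zero
#'
#' Printed tables in aphid host-transfer studies use commercial (half-up)
#' rounding, not the IEEE round-half-even of [base::round()]. Survival
#' percentages and R0/T are shown to 1 decimal, rm to 2, survey
#' percentages to 0.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector rounded half away from zero.
#' @examples
#' round_half_up(0.345, 2) # 0.35, where round() gives 0.34
#' round_half_up(76.47)    # 76
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# format mean +/- sd at a fixed number of decimals, "-" when undefined
fmt_mean_sd <- function(mean, sd, digits) {
  ifelse(
    is.na(mean),
    "-",
    sprintf(
      paste0("%.", digits, "f ± %.", digits, "f"),
      round_half_up(mean, digits), round_half_up(sd, digits)
    )
  )
}
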