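#' Round half away from zero
#'
#' The rounding convention of the published surveillance tables. Base
#' `round()` rounds half to even (`round(0.5)` is 0); the tables round half
#' up.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return `x` rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

fmt_num <- function(x, digits) {
  sprintf(paste0("%.", digits, "f"), round_half_up(x, digits))
}

split_codes <- function(codes) {
  out <- strsplit(ifelse(is.na(codes), "", codes), ";", fixed = TRUE)
  lapply(out, function(x) x[nzchar(x)])
}

join_codes <- function(code_list) {
  vapply(code_list, function(x) paste(sort(unique(x)), collapse = ";"), character(1))
}

check_prob <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    abort(sprintf("`%s` must be a probability in [0, 1]", field),
          class = "neosurv_config_error")
  }
  invisible(x)
}

check_count <- function(x, field, positive = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) && x == trunc(x) &&
    (x > 0 || (!positive && x >= 0))
  if (!ok) {
    abort(sprintf("`%s` must be a %s integer", field,
                  if (positive) "positive" else "non-negative"),
          class = "neosurv_config_error")
  }
  invisible(x)
}

# Columns of the episode CSV dialect, in order.
episode_cols <- c("infant_id", "unit_id", "year", "admission_date",
                  "discharge_date", "gestational_weeks", "codes")

ga_stratum <- function(gestational_weeks) {
  dplyr::case_when(
    is.na(gestational_weeks) ~ NA_character_,
    gestational_weeks >= 37 ~ "term",
    TRUE ~ "preterm"
  )
}
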