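#' Round half away from zero at a fixed number of decimals
#'
#' Published pharmacovigilance tables conventionally round halves up
#' (0.345 -> 0.35 at 2 decimals), whereas [base::round()] rounds halves to
#' even. This helper matches the tabular convention.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(0.345, 2) # 0.35
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

# Trim, upper-case, collapse internal whitespace.
norm_string <- function(x) {
  x <- toupper(trimws(as.character(x)))
  gsub("[[:space:]]+", " ", x)
}

# "YYYYQn" tag from an 8- or 6-digit date string; NA if precision < month.
quarter_tag <- function(text) {
  text <- as.character(text)
  ok <- !is.na(text) & grepl("^[0-9]{6}", text)
  out <- rep(NA_character_, length(text))
  yy <- substr(text[ok], 1, 4)
  mm <- as.integer(substr(text[ok], 5, 6))
  valid <- !is.na(mm) & mm >= 1 & mm <= 12
  out[ok][valid] <- paste0(yy[valid], "Q", (mm[valid] - 1) %/% 3 + 1)
  out
}

# First day of a "YYYYQn" quarter as Date.
quarter_start <- function(q) {
  y <- as.integer(substr(q, 1, 4))
  n <- as.integer(substr(q, 6, 6))
  as.Date(sprintf("%04d-%02d-01", y, (n - 1) * 3 + 1))
}

# Number of days in a "YYYYQn" quarter (vectorized).
quarter_days <- function(q) {
  s <- quarter_start(q)
  y <- as.integer(substr(q, 1, 4))
  n <- as.integer(substr(q, 6, 6))
  nxt <- ifelse(n == 4L, sprintf("%04dQ1", y + 1L),
                sprintf("%04dQ%d", y, n + 1L))
  as.integer(quarter_start(nxt) - s)
}

# Date -> FAERS 8-digit string.
date8 <- function(d) format(d, "%Y%m%d")

stop_faersdpa <- function(...) stop(..., call. = FALSE)
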