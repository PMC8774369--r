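# Codec for the MNCD notation string:
#   M<m>N<n>C<c>D<d> (<mmmm>/<nnnn>/<c>/<d>)-<years>
# Canonical output is pure ASCII. The parser additionally accepts the
# typographic dialect seen in print: underscored subscripts ("M_2_N_3_...")
# and an en/em dash before the time suffix. Parsers are liberal, formatters
# conservative.

format_years_suffix <- function(x) {
  stopifnot(is.numeric(x), length(x) == 1L, !is.na(x), x >= 0)
  if (x == round(x)) return(format(as.integer(round(x))))
  s <- sprintf("%.2f", x)
  s <- sub("0+$", "", s)
  sub("\\.$", "", s)
}

#' Format an MNCD record as its notation string
#'
#' Serializes a record to the canonical ASCII dialect, e.g.
#' `"M2N3C2D2 (1010/1110/2/2)-20"`. The M and N subscripts are always
#' computed from the flags, never taken from stored values. Integer years
#' print without a decimal point; fractional years print with up to two
#' decimals and no trailing zeros (six months from onset is `-0.5`).
#'
#' @param record an [mncd_record()].
#' @param include_time `TRUE` to append the `-<years>` suffix (an error if
#'   `years_from_onset` is missing), `FALSE` to omit it, or `NULL` (default)
#'   to append it exactly when `years_from_onset` is present.
#' @return A single character string.
#' @examples
#' r <- mncd_record(c(0, 0, 0, 1), rep(0, 4), 0, 0, years_from_onset = 2)
#' format_notation(r)  # "M1N0C0D0 (0001/0000/0/0)-2"
#' @export
format_notation <- function(record, include_time = NULL) {
  stopifnot(inherits(record, "mncd_record"))
  if (is.null(include_time)) include_time <- !is.na(record$years_from_onset)
  if (include_time && is.na(record$years_from_onset)) {
    stop("cannot include time suffix: `years_from_onset` is missing",
         call. = FALSE)
  }
  body <- sprintf("M%dN%dC%dD%d (%s/%s/%d/%d)",
                  motor_score(record), nonmotor_score(record),
                  record$cognition, record$dependency,
                  paste(record$motor, collapse = ""),
                  paste(record$nonmotor, collapse = ""),
                  record$cognition, record$dependency)
  if (include_time) {
    paste0(body, "-", format_years_suffix(record$years_from_onset))
  } else {
    body
  }
}

notation_error <- function(class, msg) {
  stop(errorCondition(msg, class = c(class, "mncd_notation_error")))
}

# Subscripts may be wrapped in underscores (M_2_), dashes before the time
# suffix may be ASCII "-", en dash or em dash; internal whitespace is free.
NOTATION_REGEX <- paste0(
  "^\\s*",
  "M\\s*_?\\s*([0-4])\\s*_?\\s*",
  "N\\s*_?\\s*([0-4])\\s*_?\\s*",
  "C\\s*_?\\s*([0-2])\\s*_?\\s*",
  "D\\s*_?\\s*([0-2])\\s*_?\\s*",
  "\\(\\s*([01]{4})\\s*/\\s*([01]{4})\\s*/\\s*([0-2])\\s*/\\s*([0-2])\\s*\\)",
  "\\s*(?:[-–—]\\s*([0-9]+(?:\\.[0-9]+)?))?\\s*\\.?\\s*$"
)

digits_of <- function(block) as.integer(strsplit(block, "", fixed = TRUE)[[1]])

#' Parse an MNCD notation string
#'
#' Accepts both the canonical ASCII dialect and the typographic dialect
#' (underscored subscripts such as `"M_3_N_1_C_1_D_1_"`, en/em dash before
#' the time suffix, flexible whitespace). The subscripts are redundant with
#' the parenthesized flag blocks; the parser enforces consistency and
#' reports the offending axis when they disagree.
#'
#' @param text a single notation string.
#' @return An [mncd_record()]; `years_from_onset` is `NA` when the time
#'   suffix is absent.
#' @examples
#' parse_notation("M3N1C1D1 (1110/1000/1/1)-6")
#' parse_notation("M_1_N_0_C_0_D_0_ (0001/0000/0/0)–2")  # en dash
#' @export
parse_notation <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  m <- regmatches(text, regexec(NOTATION_REGEX, text, perl = TRUE))[[1]]
  if (length(m) == 0L) {
    notation_error("mncd_syntax_error",
                   sprintf("not a valid MNCD notation string: %s",
                           deparse(text)))
  }
  sub_m <- as.integer(m[2]); sub_n <- as.integer(m[3])
  sub_c <- as.integer(m[4]); sub_d <- as.integer(m[5])
  motor <- digits_of(m[6]); nonmotor <- digits_of(m[7])
  par_c <- as.integer(m[8]); par_d <- as.integer(m[9])
  if (sub_m != sum(motor)) {
    notation_error("mncd_consistency_error", sprintf(
      "axis M: subscript %d does not match sub-axis sum %d of block %s",
      sub_m, sum(motor), m[6]))
  }
  if (sub_n != sum(nonmotor)) {
    notation_error("mncd_consistency_error", sprintf(
      "axis N: subscript %d does not match sub-axis sum %d of block %s",
      sub_n, sum(nonmotor), m[7]))
  }
  if (sub_c != par_c) {
    notation_error("mncd_consistency_error", sprintf(
      "axis C: subscript %d disagrees with parenthesized value %d",
      sub_c, par_c))
  }
  if (sub_d != par_d) {
    notation_error("mncd_consistency_error", sprintf(
      "axis D: subscript %d disagrees with parenthesized value %d",
      sub_d, par_d))
  }
  years <- if (is.na(m[10]) || m[10] == "") NA_real_ else as.numeric(m[10])
  mncd_record(motor, nonmotor, sub_c, sub_d, years_from_onset = years)
}
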