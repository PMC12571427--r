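#' Normalize an ICD diagnosis code
#'
#' Strips whitespace and dots and upper-cases the remainder, so codes can be
#' compared against dotless pattern strings (e.g. `"E11.9"` becomes
#' `"E119"`, `"250.00"` becomes `"25000"`).
#'
#' @param raw Character vector of raw code strings.
#' @return Character vector of normalized codes matching `[A-Z0-9]+`.
#' @examples
#' normalize_code(c("E11.9", " e10.65 ", "250.00"))
#' @export
normalize_code <- function(raw) {
  if (!is.character(raw)) stop("codes must be character")
  out <- toupper(gsub("[[:space:].]", "", raw))
  bad <- !nzchar(out) | !grepl("^[A-Z0-9]+$", out)
  if (any(bad)) {
    stop("invalid diagnosis code(s) after normalization: ",
         paste(utils::head(sQuote(raw[bad]), 5L), collapse = ", "))
  }
  out
}

## Translate a rule-sheet code pattern into an anchored regex.
## Grammar: literal characters plus "x" wildcards; a trailing "x" is an open
## extension (matches zero or more trailing characters), an interior "x"
## matches exactly one character.  Dots and whitespace are presentational.
pattern_regex <- function(pattern) {
  if (!is.character(pattern) || length(pattern) != 1L || is.na(pattern)) {
    stop("pattern must be a single string")
  }
  p <- gsub("[[:space:].]", "", pattern)
  if (!nzchar(p)) stop("empty code pattern: ", sQuote(pattern))
  chars <- strsplit(p, "", fixed = TRUE)[[1]]
  lit <- chars != "x"
  chars[lit] <- toupper(chars[lit])
  if (!all(grepl("^[A-Z0-9x]$", chars))) {
    stop("invalid code pattern: ", sQuote(pattern))
  }
  n <- length(chars)
  piece <- ifelse(chars == "x", "[A-Z0-9]", chars)
  if (chars[n] == "x") piece[n] <- "[A-Z0-9]*"
  paste0("^", paste(piece, collapse = ""), "$")
}

#' Match normalized codes against a code pattern
#'
#' Patterns follow the two styles used in published phenotype definitions:
#' a trailing `.x` denotes an open extension (`"E11.x"` matches `E11`,
#' `E119`, `E1165`, ...), while an interior `x` before further literal
#' characters is a fixed-length single-character wildcard (`"250.x0"`
#' matches exactly `250` + any character + `0`, e.g. `25010` but not
#' `25011`).
#'
#' @param code Character vector of normalized codes (see [normalize_code()]).
#' @param pattern A single pattern string such as `"E11.x"` or `"250.x0"`.
#' @return Logical vector, one element per code.
#' @examples
#' code_matches(c("E119", "E139"), "E11.x")
#' code_matches(c("25010", "25011"), "250.x0")
#' @export
code_matches <- function(code, pattern) {
  grepl(pattern_regex(pattern), code)
}

## Vectorized membership in a set of patterns.
code_matches_any <- function(code, patterns) {
  hit <- rep(FALSE, length(code))
  for (p in patterns) hit <- hit | code_matches(code, p)
  hit
}
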