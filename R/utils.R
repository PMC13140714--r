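#' @keywords internal
"_PACKAGE"

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x == floor(x)

is_fraction <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) &&
  x >= 0 && x <= 1

#' Inverse logit on the log2 scale
#'
#' Maps an M-value back to the beta (methylation fraction) scale:
#' `beta = 2^M / (1 + 2^M)`.
#'
#' @param m Numeric vector of M-values.
#' @return Numeric vector of beta values in (0, 1).
#' @export
m_to_beta <- function(m) {
  # computed via plogis on the natural scale for numerical stability at |m| >> 0
  stats::plogis(m * log(2))
}

#' Split a semicolon-delimited manifest field
#'
#' Illumina-style manifests pack multi-valued fields (gene symbols, RefSeq ids,
#' gene-structure groups) as `"A;B;C"`. Empty strings and NA yield
#' `character(0)`.
#'
#' @param x Character vector.
#' @return List of character vectors, one per element of `x`.
#' @export
split_semicolon <- function(x) {
  x[is.na(x)] <- ""
  out <- strsplit(x, ";", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

join_semicolon <- function(x) vapply(x, paste, "", collapse = ";")
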