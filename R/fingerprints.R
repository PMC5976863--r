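#' Binary fingerprint
#'
#' A fingerprint is a set of set-bit indices over a declared bit-space of
#' `size` positions (0-based indices, `0 <= index < size`). The textual
#' literal form used in TSV inputs is `size:idx,idx,...`, e.g. `16:0,3,9`;
#' an empty bit set is written `size:`.
#'
#' @param bits integer vector of set-bit indices (duplicates collapsed).
#' @param size bit-space size, a positive integer.
#' @return object of class `fzhy_fp` (list with `size` and sorted `bits`).
#' @export
fingerprint <- function(bits, size) {
  size <- as.integer(size)
  if (length(size) != 1 || is.na(size) || size <= 0) {
    stop("fingerprint size must be a single positive integer", call. = FALSE)
  }
  bits <- sort(unique(as.integer(bits)))
  if (length(bits) && (min(bits) < 0 || max(bits) >= size)) {
    stop("fingerprint bit indices must lie in [0, size)", call. = FALSE)
  }
  structure(list(size = size, bits = bits), class = "fzhy_fp")
}

#' @export
format.fzhy_fp <- function(x, ...) {
  paste0(x$size, ":", paste(x$bits, collapse = ","))
}

#' @export
print.fzhy_fp <- function(x, ...) {
  cat("<fingerprint ", length(x$bits), "/", x$size, " bits set>\n", sep = "")
  invisible(x)
}

#' Parse a fingerprint literal
#'
#' @param x character vector of literals `size:idx,idx,...`.
#' @return a `fzhy_fp` for length-1 input, else a list of them.
#' @export
parse_fingerprint <- function(x) {
  one <- function(s) {
    s <- trimws(s)
    if (!grepl("^[0-9]+:", s)) {
      stop("not a fingerprint literal: '", s, "'", call. = FALSE)
    }
    parts <- strsplit(s, ":", fixed = TRUE)[[1]]
    size <- as.integer(parts[1])
    bits <- if (length(parts) < 2 || !nzchar(parts[2])) integer(0) else
      as.integer(strsplit(parts[2], ",", fixed = TRUE)[[1]])
    fingerprint(bits, size)
  }
  if (length(x) == 1) one(x) else lapply(x, one)
}

#' Tanimoto similarity of two binary fingerprints
#'
#' `|A intersect B| / |A union B|`. Both fingerprints must declare the same
#' bit-space size. By convention `tanimoto(empty, empty) = 1` (two compounds
#' with no features are indistinguishable) and empty-vs-nonempty is 0.
#'
#' @param a,b `fzhy_fp` fingerprints over the same bit space.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fzhy_fp"), inherits(b, "fzhy_fp"))
  if (a$size != b$size) {
    stop("fingerprints have mismatched bit-space sizes (", a$size, " vs ",
         b$size, ")", call. = FALSE)
  }
  if (length(a$bits) == 0 && length(b$bits) == 0) return(1.0)
  ni <- length(intersect(a$bits, b$bits))
  nu <- length(a$bits) + length(b$bits) - ni
  ni / nu
}
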