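#' Normalize a compound name
#'
#' Trims leading/trailing whitespace, collapses internal runs of whitespace to
#' a single space, and case-folds. This is the only string normalization ever
#' applied to component names; merging of true synonyms (different words for
#' the same chemical entity) is done exclusively through an explicit synonym
#' map, never by fuzzy matching.
#'
#' @param x character vector of names.
#' @return character vector of normalized names.
#' @export
normalize_name <- function(x) {
  x <- gsub("\\s+", " ", trimws(as.character(x)))
  tolower(x)
}

#' Read a herb-component table
#'
#' Reads a UTF-8 TSV with columns `herb` and `component`, one row per
#' (herb, component) pair as printed in a component catalog. Names are
#' whitespace-trimmed but case is preserved; normalization happens later in
#' [build_catalog()].
#'
#' @param path path to the TSV file.
#' @return data.frame with columns `herb` and `component`. An empty file with
#'   a header yields a zero-row data.frame.
#' @export
load_component_table <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8", comment.char = "")
  for (col in c("herb", "component")) {
    if (!col %in% names(df)) {
      stop("component table '", path, "' lacks required column '", col, "'",
           call. = FALSE)
    }
  }
  extra <- intersect(c("smiles", "fingerprint"), names(df))
  df <- df[, c("herb", "component", extra), drop = FALSE]
  df$herb <- gsub("\\s+", " ", trimws(df$herb))
  df$component <- gsub("\\s+", " ", trimws(df$component))
  if (nrow(df) > 0 && any(!nzchar(df$herb) | !nzchar(df$component))) {
    bad <- which(!nzchar(df$herb) | !nzchar(df$component))
    stop("component table '", path, "' has empty herb/component at row(s) ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a synonym map
#'
#' Two-column TSV `alias<TAB>canonical`. Both sides are normalized with
#' [normalize_name()]. Canonical names must be fixed points: a canonical name
#' may not itself be an alias for something else.
#'
#' @param path path to the TSV (with header `alias<TAB>canonical`).
#' @return named character vector mapping normalized alias to normalized
#'   canonical name.
#' @export
load_synonym_map <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (col in c("alias", "canonical")) {
    if (!col %in% names(df)) {
      stop("synonym map '", path, "' lacks required column '", col, "'",
           call. = FALSE)
    }
  }
  synonym_map(stats::setNames(normalize_name(df$canonical),
                              normalize_name(df$alias)))
}

#' Construct and validate a synonym map
#'
#' @param entries named character vector, alias -> canonical (both will be
#'   normalized). May be empty.
#' @return validated named character vector.
#' @export
synonym_map <- function(entries = character(0)) {
  if (length(entries) == 0) return(stats::setNames(character(0), character(0)))
  map <- stats::setNames(normalize_name(entries), normalize_name(names(entries)))
  if (anyDuplicated(names(map))) {
    stop("synonym map has duplicate aliases: ",
         paste(unique(names(map)[duplicated(names(map))]), collapse = ", "),
         call. = FALSE)
  }
  # canonical names are fixed points: following the map from any canonical
  # value must not lead elsewhere (no chains, hence no cycles)
  chained <- map[map] # NA where a canonical is not itself an alias
  bad <- !is.na(chained) & chained != map
  if (any(bad)) {
    stop("synonym map canonical name(s) are not fixed points: ",
         paste(unique(map[bad]), collapse = ", "), call. = FALSE)
  }
  map
}

apply_synonyms <- function(names, map) {
  key <- normalize_name(names)
  hit <- match(key, names(map))
  ifelse(is.na(hit), key, unname(map[hit]))
}

#' Build a deduplicated compound catalog
#'
#' Collapses the herb-component rows to one entry per canonical compound name.
#' Names are normalized, optionally redirected through a synonym map, and rows
#' mapping to the same canonical name are merged; `herbs` collects the union
#' of source herbs.
#'
#' @param components data.frame from [load_component_table()]; may optionally
#'   carry `smiles` and/or `fingerprint` columns which are propagated (first
#'   non-empty value per compound).
#' @param synonyms synonym map from [synonym_map()] / [load_synonym_map()];
#'   default empty (no merging beyond exact normalized-name identity).
#' @return data.frame with columns `canonical_name`, `smiles`, `fingerprint`,
#'   `herbs` (list column of character vectors) and `n_herbs`, ordered
#'   lexicographically (byte order, locale-independent) by `canonical_name`.
#' @export
build_catalog <- function(components, synonyms = synonym_map()) {
  if (nrow(components) == 0) {
    return(data.frame(canonical_name = character(0), smiles = character(0),
                      fingerprint = character(0),
                      herbs = I(list()), n_herbs = integer(0)))
  }
  canon <- apply_synonyms(components$component, synonyms)
  smiles <- if ("smiles" %in% names(components)) components$smiles else
    rep(NA_character_, nrow(components))
  fp <- if ("fingerprint" %in% names(components)) components$fingerprint else
    rep(NA_character_, nrow(components))
  first_value <- function(x) {
    x <- x[!is.na(x) & nzchar(x)]
    if (length(x)) x[[1]] else NA_character_
  }
  idx <- split(seq_along(canon), canon)
  nm <- sort(names(idx), method = "radix")
  herbs <- lapply(nm, function(k) {
    sort(unique(components$herb[idx[[k]]]), method = "radix")
  })
  out <- data.frame(
    canonical_name = nm,
    smiles = vapply(nm, function(k) first_value(smiles[idx[[k]]]), character(1)),
    fingerprint = vapply(nm, function(k) first_value(fp[idx[[k]]]), character(1)),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$herbs <- I(herbs)
  out$n_herbs <- lengths(herbs)
  out
}

#' Compounds shared by several herbs
#'
#' Subset of the catalog whose compounds occur in two or more herbs, ordered
#' by the number of source herbs (descending), ties broken by name.
#'
#' @param catalog catalog from [build_catalog()].
#' @return data.frame with the same columns as `catalog`.
#' @export
shared_components <- function(catalog) {
  out <- catalog[catalog$n_herbs >= 2, , drop = FALSE]
  out <- out[order(-out$n_herbs, out$canonical_name, method = "radix"), ,
             drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Write a catalog TSV
#'
#' `canonical_name<TAB>smiles<TAB>herbs` with herbs semicolon-joined.
#'
#' @param catalog catalog data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  df <- data.frame(
    canonical_name = catalog$canonical_name,
    smiles = ifelse(is.na(catalog$smiles), "", catalog$smiles),
    herbs = vapply(catalog$herbs, paste, character(1), collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Packaged six-herb component fixture
#'
#' Copies (or points at) the packaged herb-component table of the six-herb
#' FZHY formula -- 46 printed rows across *S. miltiorrhiza*, *C. sinensis*,
#' *S. chinensis*, *G. pentaphyllum*, *S. Persicae* and *P. Pini* -- together
#' with the one-entry synonym map (danshensu and tanshinol name the same
#' compound).
#'
#' @param dir if non-NULL, the two TSVs are copied there; otherwise the
#'   installed paths are returned.
#' @return named character vector with elements `components` and `synonyms`.
#' @export
table1_fixture <- function(dir = NULL) {
  src <- c(
    components = system.file("extdata", "fzhy_components.tsv",
                             package = "fzhynet", mustWork = TRUE),
    synonyms = system.file("extdata", "fzhy_synonyms.tsv",
                           package = "fzhynet", mustWork = TRUE)
  )
  if (is.null(dir)) return(src)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dst <- file.path(dir, basename(src))
  names(dst) <- names(src)
  file.copy(src, dst, overwrite = TRUE)
  dst
}
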