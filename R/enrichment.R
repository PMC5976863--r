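#' Read annotation collections in GMT format
#'
#' Each line is `term_id<TAB>term_name|namespace<TAB>member1<TAB>member2...`.
#' `namespace` is one of `pathway`, `biological_process`,
#' `cellular_component`, `molecular_function`, `disease`; a missing
#' `|namespace` suffix defaults to `pathway`.
#'
#' @param path path to the GMT file.
#' @return data.frame `term_id`, `term_name`, `namespace`, `members` (list
#'   column of character vectors).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3
  if (any(short)) {
    stop("GMT line(s) with fewer than 3 fields: ",
         paste(which(short), collapse = ", "), call. = FALSE)
  }
  desc <- vapply(parts, `[[`, character(1), 2)
  has_ns <- grepl("|", desc, fixed = TRUE)
  term_name <- ifelse(has_ns, sub("\\|[^|]*$", "", desc), desc)
  namespace <- ifelse(has_ns, sub("^.*\\|", "", desc), "pathway")
  out <- data.frame(term_id = vapply(parts, `[[`, character(1), 1),
                    term_name = term_name, namespace = namespace,
                    stringsAsFactors = FALSE)
  out$members <- I(lapply(parts, function(p) unique(p[-(1:2)])))
  out
}

#' Write annotation collections in GMT format
#'
#' @param collections data.frame as returned by [read_gmt()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collections, path) {
  lines <- vapply(seq_len(nrow(collections)), function(i) {
    paste(c(collections$term_id[i],
            paste0(collections$term_name[i], "|", collections$namespace[i]),
            collections$members[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Exact hypergeometric upper-tail probability
#'
#' `P(X >= k)` where `X ~ Hypergeometric(N, K, n)`: the probability of seeing
#' at least `k` annotated proteins in a query of size `n` drawn without
#' replacement from a background of `N` proteins of which `K` carry the
#' annotation. This is the standard over-representation statistic.
#'
#' @param k observed overlap.
#' @param K term size (annotated proteins in the background).
#' @param n query size.
#' @param N background size.
#' @return exact p-value.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (k < 0 || K < 0 || n < 0 || N < 0 || k > min(K, n) || K > N || n > N) {
    stop("invalid hypergeometric counts: need 0 <= k <= min(K, n), ",
         "K <= N, n <= N (got k=", k, ", K=", K, ", n=", n, ", N=", N, ")",
         call. = FALSE)
  }
  if (k == 0) return(1.0)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment; a thin, named wrapper over
#' `stats::p.adjust(..., method = "BH")` so callers and reports are explicit
#' about the procedure.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return q-values in the same order.
#' @export
bh_adjust <- function(p) {
  stopifnot(all(p >= 0 & p <= 1, na.rm = TRUE))
  stats::p.adjust(p, method = "BH")
}

#' Over-representation analysis of a protein set
#'
#' One hypergeometric upper-tail test per annotation term with nonzero
#' overlap, BH adjustment within each namespace separately. Following common
#' practice in service-style enrichment reports, the significance flag uses
#' the raw p-value (`p < alpha`) by default, with the BH q-value reported
#' alongside; set `use_fdr = TRUE` to flag on `q < alpha` instead.
#'
#' @param query character vector of protein identifiers (nonempty, must be
#'   contained in the background).
#' @param collections annotation data.frame from [read_gmt()].
#' @param background background universe; default is the union of all
#'   annotation members.
#' @param alpha significance level, default 0.05.
#' @param use_fdr flag significance on the adjusted q instead of raw p.
#' @return data.frame `namespace`, `term_id`, `term_name`, `k`, `K`, `n`,
#'   `N`, `p`, `q`, `significant`, `overlap` (list column), sorted by
#'   namespace then p.
#' @export
enrich <- function(query, collections, background = NULL, alpha = 0.05,
                   use_fdr = FALSE) {
  query <- unique(as.character(query))
  if (length(query) == 0) stop("query protein set is empty", call. = FALSE)
  if (is.null(background)) {
    background <- unique(unlist(collections$members))
  } else {
    background <- unique(as.character(background))
    stray <- setdiff(unique(unlist(collections$members)), background)
    if (length(stray)) {
      stop("annotation member(s) outside the declared background: ",
           paste(utils::head(sort(stray), 10), collapse = ", "),
           call. = FALSE)
    }
  }
  off <- setdiff(query, background)
  if (length(off)) {
    stop("query protein(s) not in the background universe: ",
         paste(sort(off), collapse = ", "), call. = FALSE)
  }
  N <- length(background)
  n <- length(query)
  overlap <- lapply(collections$members, intersect, x = query)
  k <- lengths(overlap)
  keep <- k >= 1
  out <- data.frame(namespace = collections$namespace[keep],
                    term_id = collections$term_id[keep],
                    term_name = collections$term_name[keep],
                    k = k[keep], K = lengths(collections$members)[keep],
                    n = n, N = N, stringsAsFactors = FALSE)
  out$p <- vapply(seq_len(nrow(out)), function(i) {
    hypergeom_upper_tail(out$k[i], out$K[i], n, N)
  }, numeric(1))
  out$q <- NA_real_
  for (ns in unique(out$namespace)) {
    sel <- out$namespace == ns
    out$q[sel] <- bh_adjust(out$p[sel])
  }
  out$significant <- if (use_fdr) out$q < alpha else out$p < alpha
  out$overlap <- I(overlap[keep])
  ord <- order(out$namespace, out$p, out$term_id, method = "radix")
  out <- out[ord, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Bipartite term-protein annotation network
#'
#' Connects each significant term to the query proteins it annotates; terms
#' are ranked by overlap count (descending), the working rule being that an
#' annotation hit by more of the prioritized proteins matters more. With
#' `namespace = "disease"` this yields the target-disease network analogue.
#'
#' @param results data.frame from [enrich()] (typically filtered to
#'   `significant`).
#' @param namespace optional single namespace to restrict to.
#' @return igraph with vertex attributes `node_type` in
#'   `{"term", "protein"}` and, on term nodes, `rank` and `overlap_count`.
#' @export
annotation_network <- function(results, namespace = NULL) {
  if (!is.null(namespace)) {
    results <- results[results$namespace == namespace, , drop = FALSE]
  }
  if (nrow(results) == 0) return(igraph::make_empty_graph(0, directed = FALSE))
  ord <- order(-results$k, results$term_id, method = "radix")
  results <- results[ord, , drop = FALSE]
  edges <- do.call(rbind, lapply(seq_len(nrow(results)), function(i) {
    data.frame(from = results$term_id[i], to = results$overlap[[i]],
               stringsAsFactors = FALSE)
  }))
  proteins <- sort(unique(edges$to), method = "radix")
  verts <- data.frame(
    name = c(results$term_id, proteins),
    node_type = c(rep("term", nrow(results)), rep("protein", length(proteins))),
    rank = c(seq_len(nrow(results)), rep(NA_integer_, length(proteins))),
    overlap_count = c(results$k, rep(NA_integer_, length(proteins))),
    stringsAsFactors = FALSE
  )
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Write an enrichment result TSV
#'
#' @param results data.frame from [enrich()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_enrichment <- function(results, path) {
  df <- results[, c("namespace", "term_id", "term_name", "k", "K", "n", "N",
                    "p", "q", "significant")]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
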