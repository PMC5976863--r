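#' Read a reference drug library
#'
#' TSV with columns `drug_id`, `fingerprint` (a fingerprint literal,
#' see [parse_fingerprint()]) and `targets` (semicolon-joined protein
#' identifiers; may be empty, in which case the drug contributes nothing to
#' similarity mapping).
#'
#' @param path path to the TSV.
#' @return data.frame with `drug_id`, `fingerprint` (list column of
#'   `fzhy_fp`) and `targets` (list column of character vectors).
#' @export
load_reference_library <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (col in c("drug_id", "fingerprint", "targets")) {
    if (!col %in% names(df)) {
      stop("reference library '", path, "' lacks required column '", col, "'",
           call. = FALSE)
    }
  }
  out <- data.frame(drug_id = as.character(df$drug_id),
                    stringsAsFactors = FALSE)
  out$fingerprint <- I(lapply(df$fingerprint, parse_fingerprint))
  out$targets <- I(lapply(df$targets, function(t) {
    if (is.na(t) || !nzchar(t)) character(0) else
      strsplit(t, ";", fixed = TRUE)[[1]]
  }))
  out
}

#' Targets by fingerprint similarity against a drug library
#'
#' A compound inherits the annotated targets of every library drug whose
#' Tanimoto similarity to the compound's fingerprint reaches the cutoff
#' (inclusive, default 0.95 -- a deliberately stringent "near-duplicate"
#' screen).
#'
#' @param fp compound fingerprint (`fzhy_fp`), or NULL if the compound has no
#'   structure (skipped with a warning, empty result).
#' @param library reference library from [load_reference_library()].
#' @param cutoff similarity cutoff in `(0, 1]`.
#' @param compound compound name, used only in the missing-fingerprint
#'   warning.
#' @return sorted character vector of target protein identifiers.
#' @export
similarity_targets <- function(fp, library, cutoff = 0.95,
                               compound = "<compound>") {
  stopifnot(is.numeric(cutoff), length(cutoff) == 1, cutoff > 0, cutoff <= 1)
  if (is.null(fp)) {
    warning("compound '", compound,
            "' has no fingerprint; skipped in similarity mapping",
            call. = FALSE)
    return(character(0))
  }
  sims <- vapply(library$fingerprint, tanimoto, numeric(1), b = fp)
  hits <- unlist(library$targets[sims >= cutoff])
  if (is.null(hits)) return(character(0))
  sort(unique(hits), method = "radix")
}

#' Similarity-branch compound-target edges for a whole catalog
#'
#' @param catalog catalog with a `fingerprint` column of literals (NA allowed).
#' @param library reference library.
#' @param cutoff similarity cutoff, default 0.95.
#' @return data.frame of edges `compound`, `protein`.
#' @export
similarity_edges <- function(catalog, library, cutoff = 0.95) {
  rows <- lapply(seq_len(nrow(catalog)), function(i) {
    lit <- catalog$fingerprint[[i]]
    fp <- if (is.na(lit) || !nzchar(lit)) NULL else parse_fingerprint(lit)
    tg <- similarity_targets(fp, library, cutoff,
                             compound = catalog$canonical_name[[i]])
    if (length(tg) == 0) return(NULL)
    data.frame(compound = catalog$canonical_name[[i]], protein = tg,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(compound = character(0), protein = character(0))
  }
  row.names(out) <- NULL
  out
}

#' Docking hits against per-protein co-crystal controls
#'
#' A (compound, protein) docking score counts as a hit when it is strictly
#' greater than that protein's positive-control score (the co-crystallized
#' ligand's score). Every scored protein must have a control record.
#'
#' @param records data.frame with `compound`, `protein`, `score`.
#' @param controls data.frame with `protein`, `control_score` (one row per
#'   protein).
#' @return data.frame of hits `compound`, `protein`, `score`, `control_score`.
#' @export
docking_targets <- function(records, controls) {
  if (anyDuplicated(controls$protein)) {
    stop("multiple control scores for protein(s): ",
         paste(unique(controls$protein[duplicated(controls$protein)]),
               collapse = ", "), call. = FALSE)
  }
  if (nrow(records) == 0) {
    return(data.frame(compound = character(0), protein = character(0),
                      score = numeric(0), control_score = numeric(0)))
  }
  if (any(!is.finite(records$score)) || any(!is.finite(controls$control_score))) {
    stop("docking scores must be finite", call. = FALSE)
  }
  ctl <- controls$control_score[match(records$protein, controls$protein)]
  if (anyNA(ctl)) {
    missing <- sort(unique(records$protein[is.na(ctl)]))
    stop("no control score for scored protein(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  hit <- records$score > ctl
  out <- data.frame(compound = records$compound[hit],
                    protein = records$protein[hit],
                    score = records$score[hit],
                    control_score = ctl[hit],
                    stringsAsFactors = FALSE)
  row.names(out) <- NULL
  out
}

#' Merge similarity and docking target sets with provenance
#'
#' @param sim character vector of similarity-derived protein identifiers.
#' @param dock character vector of docking-derived protein identifiers.
#' @return data.frame `protein`, `provenance` (one of "similarity",
#'   "docking", "both"), sorted by protein.
#' @export
merge_target_sets <- function(sim, dock) {
  sim <- unique(as.character(sim)); dock <- unique(as.character(dock))
  all <- sort(union(sim, dock), method = "radix")
  prov <- ifelse(all %in% sim & all %in% dock, "both",
                 ifelse(all %in% sim, "similarity", "docking"))
  data.frame(protein = all, provenance = prov, stringsAsFactors = FALSE)
}

#' Build the compound-target protein interaction (CTPI) network
#'
#' Bipartite undirected graph of compounds and predicted targets. Edges are
#' deduplicated per (compound, target) pair; the network retains exactly the
#' nodes incident to at least one edge. Both edge endpoints must be known,
#' i.e. listed in the compound catalog and the merged target table.
#'
#' @param compounds catalog data.frame (`canonical_name` column used).
#' @param targets merged target data.frame from [merge_target_sets()].
#' @param edges data.frame with `compound`, `protein`.
#' @return igraph object with vertex attribute `node_type` in
#'   `{"compound", "target"}`.
#' @export
build_ctpi <- function(compounds, targets, edges) {
  if (nrow(edges) == 0) {
    g <- igraph::make_empty_graph(0, directed = FALSE)
    return(g)
  }
  bad_c <- setdiff(edges$compound, compounds$canonical_name)
  bad_t <- setdiff(edges$protein, targets$protein)
  if (length(bad_c) || length(bad_t)) {
    stop("CTPI edge endpoint(s) not in their catalogs: ",
         paste(c(bad_c, bad_t), collapse = ", "), call. = FALSE)
  }
  el <- unique(data.frame(compound = edges$compound, protein = edges$protein,
                          stringsAsFactors = FALSE))
  verts <- data.frame(
    name = c(sort(unique(el$compound), method = "radix"),
             sort(unique(el$protein), method = "radix")),
    stringsAsFactors = FALSE
  )
  verts$node_type <- c(rep("compound", length(unique(el$compound))),
                       rep("target", length(unique(el$protein))))
  igraph::graph_from_data_frame(el, directed = FALSE, vertices = verts)
}

#' Export a network as SIF
#'
#' One line per edge: `source<TAB>relation<TAB>target`. For bipartite
#' compound-target networks the relation is `targets`; edges of mixed
#' networks use their `relation` edge attribute when present.
#'
#' @param g igraph object.
#' @param path output path.
#' @param relation default relation label for edges without a `relation`
#'   attribute.
#' @return `path`, invisibly.
#' @export
write_sif <- function(g, path, relation = "targets") {
  el <- igraph::as_edgelist(g)
  rel <- if ("relation" %in% igraph::edge_attr_names(g)) {
    igraph::E(g)$relation
  } else {
    rep(relation, nrow(el))
  }
  lines <- if (nrow(el)) paste(el[, 1], rel, el[, 2], sep = "\t") else character(0)
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Export a network as GraphML
#'
#' Thin wrapper over [igraph::write_graph()]; vertex attributes such as
#' `node_type` are carried into the GraphML so downstream viewers (e.g.
#' Cytoscape) can style node roles.
#'
#' @param g igraph object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}
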