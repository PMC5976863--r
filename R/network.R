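#' Read a STRING-style PPI edge table
#'
#' TSV with columns `protein1`, `protein2`, `combined_score` (integer
#' confidence in `[0, 1000]`; 900 corresponds to a 0.9 "highest confidence"
#' threshold in STRING's convention).
#'
#' @param path path to the TSV.
#' @return data.frame `protein_a`, `protein_b`, `combined_score`.
#' @export
load_ppi <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (col in c("protein1", "protein2", "combined_score")) {
    if (!col %in% names(df)) {
      stop("PPI table '", path, "' lacks required column '", col, "'",
           call. = FALSE)
    }
  }
  data.frame(protein_a = as.character(df$protein1),
             protein_b = as.character(df$protein2),
             combined_score = as.integer(df$combined_score),
             stringsAsFactors = FALSE)
}

#' Filter PPI edges at a confidence threshold
#'
#' Keeps undirected edges whose combined score is at least `min_score`
#' (inclusive; the default 900 is STRING's "highest confidence" 0.9).
#' Undirected duplicates -- (A,B) and (B,A), or repeated (A,B) -- are
#' collapsed to a single edge carrying the maximum score, keeping first
#' -appearance order.
#'
#' @param ppi data.frame `protein_a`, `protein_b`, `combined_score`.
#' @param min_score minimum combined score, integer in `[0, 1000]`.
#' @return filtered, deduplicated data.frame with endpoints sorted within
#'   each row (`protein_a <= protein_b`).
#' @export
filter_ppi <- function(ppi, min_score = 900) {
  stopifnot(min_score >= 0, min_score <= 1000)
  if (nrow(ppi) == 0) return(ppi)
  sc <- ppi$combined_score
  if (any(is.na(sc) | sc < 0 | sc > 1000)) {
    bad <- which(is.na(sc) | sc < 0 | sc > 1000)
    stop("combined_score outside [0, 1000] at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  }
  if (any(ppi$protein_a == ppi$protein_b)) {
    stop("self-interaction edge(s) are not allowed: ",
         paste(unique(ppi$protein_a[ppi$protein_a == ppi$protein_b]),
               collapse = ", "), call. = FALSE)
  }
  a <- pmin(ppi$protein_a, ppi$protein_b)
  b <- pmax(ppi$protein_a, ppi$protein_b)
  key <- paste(a, b, sep = "\r")
  best <- tapply(sc, key, max)
  first <- !duplicated(key)
  out <- data.frame(protein_a = a[first], protein_b = b[first],
                    combined_score = as.integer(best[key[first]]),
                    stringsAsFactors = FALSE)
  out <- out[out$combined_score >= min_score, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Build the compound-target-differential gene (CTPG) network
#'
#' Tripartite integration of the CTPI bipartite network with filtered PPI
#' edges and a differential-gene list. Node roles are disjoint: compounds and
#' targets keep their CTPI roles; a protein appearing both as a predicted
#' target and as a differential gene takes the role `target` (and is marked
#' with vertex attribute `is_de`); remaining differential genes become
#' `de_gene` nodes. Retained edges are all CTPI compound-target edges
#' (relation `targets`) plus every PPI edge whose two endpoints both lie in
#' the target-or-DE protein set (relation `interacts`); PPI edges among DE
#' proteins are kept. The network contains exactly the endpoints of retained
#' edges.
#'
#' @param ctpi bipartite igraph from [build_ctpi()].
#' @param ppi filtered PPI data.frame from [filter_ppi()].
#' @param de_genes character vector of significant differential gene symbols
#'   (gene-to-protein mapping is identity on symbols).
#' @return igraph with vertex attributes `node_type` in
#'   `{"compound", "target", "de_gene"}` and `is_de`, and edge attribute
#'   `relation` in `{"targets", "interacts"}`.
#' @export
build_ctpg <- function(ctpi, ppi, de_genes) {
  de_genes <- unique(as.character(de_genes))
  if (igraph::vcount(ctpi) > 0) {
    cn <- igraph::V(ctpi)$name[igraph::V(ctpi)$node_type == "compound"]
    tn <- igraph::V(ctpi)$name[igraph::V(ctpi)$node_type == "target"]
    ctpi_el <- igraph::as_edgelist(ctpi)
  } else {
    cn <- character(0); tn <- character(0)
    ctpi_el <- matrix(character(0), ncol = 2)
  }
  dn <- setdiff(de_genes, tn)
  protein_set <- union(tn, dn)
  keep <- ppi$protein_a %in% protein_set & ppi$protein_b %in% protein_set
  ppi_el <- ppi[keep, c("protein_a", "protein_b"), drop = FALSE]
  edges <- rbind(
    data.frame(from = ctpi_el[, 1], to = ctpi_el[, 2],
               relation = rep("targets", nrow(ctpi_el)),
               stringsAsFactors = FALSE),
    data.frame(from = ppi_el$protein_a, to = ppi_el$protein_b,
               relation = rep("interacts", nrow(ppi_el)),
               stringsAsFactors = FALSE)
  )
  nodes <- unique(c(edges$from, edges$to))
  if (length(nodes) == 0) return(igraph::make_empty_graph(0, directed = FALSE))
  role <- ifelse(nodes %in% cn, "compound",
                 ifelse(nodes %in% tn, "target", "de_gene"))
  verts <- data.frame(name = nodes, node_type = role,
                      is_de = nodes %in% de_genes,
                      stringsAsFactors = FALSE)
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = verts)
}

#' Prioritize targets bridging compounds and differential genes
#'
#' The tripartite filtering rule: a target protein is prioritized exactly
#' when, in the CTPG, it is adjacent to at least one compound (it is an
#' actual predicted target of the formula) and to at least one
#' differential-gene protein (it plugs into the transcriptional program of
#' the condition). Compounds linked to at least one prioritized target are
#' the retained compound set.
#'
#' @param g CTPG igraph from [build_ctpg()].
#' @param self_de_counts if TRUE, a target that is itself a differential gene
#'   counts as its own DE evidence (it then qualifies even without a DE
#'   neighbor, and its `de_neighbor_count` includes itself). Default FALSE: a
#'   bridge requires a distinct DE neighbor.
#' @return data.frame `protein`, `de_neighbor_count`, `compounds` (list
#'   column), sorted by `de_neighbor_count` descending then protein name.
#'   The union of `compounds` is the retained compound set.
#' @export
prioritize_targets <- function(g, self_de_counts = FALSE) {
  empty <- data.frame(protein = character(0),
                      de_neighbor_count = integer(0),
                      stringsAsFactors = FALSE)
  empty$compounds <- I(list())
  if (igraph::vcount(g) == 0) return(empty)
  type <- igraph::V(g)$node_type
  is_de <- if ("is_de" %in% igraph::vertex_attr_names(g)) {
    igraph::V(g)$is_de
  } else {
    type == "de_gene"
  }
  targets <- which(type == "target")
  if (length(targets) == 0) return(empty)
  rows <- lapply(targets, function(v) {
    nb <- igraph::neighbors(g, v)
    nb_type <- type[as.integer(nb)]
    comp <- sort(unique(igraph::V(g)$name[as.integer(nb)[nb_type == "compound"]]),
                 method = "radix")
    # a DE neighbor is any adjacent protein flagged differential, whatever
    # its role (covers target-role proteins that are themselves DE)
    n_de <- sum(nb_type != "compound" & is_de[as.integer(nb)])
    if (self_de_counts && is_de[v]) n_de <- n_de + 1L
    if (length(comp) == 0 || n_de == 0) return(NULL)
    list(protein = igraph::V(g)$name[v], de_neighbor_count = as.integer(n_de),
         compounds = comp)
  })
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0) return(empty)
  out <- data.frame(
    protein = vapply(rows, `[[`, character(1), "protein"),
    de_neighbor_count = vapply(rows, `[[`, integer(1), "de_neighbor_count"),
    stringsAsFactors = FALSE
  )
  out$compounds <- I(lapply(rows, `[[`, "compounds"))
  ord <- order(-out$de_neighbor_count, out$protein, method = "radix")
  out <- out[ord, , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Retained compounds of a prioritization result
#'
#' @param prioritized data.frame from [prioritize_targets()].
#' @return sorted character vector of compound names linked to at least one
#'   prioritized target.
#' @export
retained_compounds <- function(prioritized) {
  comp <- unlist(prioritized$compounds)
  if (is.null(comp)) return(character(0))
  sort(unique(comp), method = "radix")
}

#' Summarize a CTPG (or CTPI) network
#'
#' @param g igraph with a `node_type` vertex attribute (absent for the empty
#'   graph).
#' @return list with `n_compounds`, `n_targets`, `n_de`, `n_nodes`,
#'   `n_edges` and `degree` (named integer vector, node -> degree).
#' @export
network_summary <- function(g) {
  if (igraph::vcount(g) == 0) {
    return(list(n_compounds = 0L, n_targets = 0L, n_de = 0L,
                n_nodes = 0L, n_edges = 0L,
                degree = stats::setNames(integer(0), character(0))))
  }
  type <- igraph::V(g)$node_type
  list(
    n_compounds = sum(type == "compound"),
    n_targets = sum(type == "target"),
    n_de = sum(type == "de_gene"),
    n_nodes = igraph::vcount(g),
    n_edges = igraph::ecount(g),
    degree = igraph::degree(g)
  )
}

#' Write a prioritization report TSV
#'
#' Columns `protein<TAB>de_neighbor_count<TAB>compounds` (semicolon-joined).
#'
#' @param prioritized data.frame from [prioritize_targets()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_prioritized <- function(prioritized, path) {
  df <- data.frame(
    protein = prioritized$protein,
    de_neighbor_count = prioritized$de_neighbor_count,
    compounds = vapply(prioritized$compounds, paste, character(1),
                       collapse = ";"),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
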