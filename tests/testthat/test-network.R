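toy_ctpg <- function(min_score = 900) {
  compounds <- data.frame(canonical_name = c("c1", "c2"))
  targets <- data.frame(protein = c("t1", "t2"), provenance = "similarity")
  ctpi <- build_ctpi(compounds, targets,
                     data.frame(compound = c("c1", "c2"),
                                protein = c("t1", "t2")))
  ppi <- data.frame(protein_a = c("t1", "t2"), protein_b = c("d1", "d2"),
                    combined_score = c(950L, 850L))
  build_ctpg(ctpi, filter_ppi(ppi, min_score), de_genes = c("d1", "d2"))
}

test_that("PPI filtering keeps scores at or above the threshold and dedupes", {
  ppi <- data.frame(protein_a = c("A", "B", "C"),
                    protein_b = c("B", "C", "D"),
                    combined_score = c(899L, 900L, 950L))
  expect_equal(nrow(filter_ppi(ppi, 900)), 2)
  expect_equal(nrow(filter_ppi(ppi, 0)), 3)

  dup <- data.frame(protein_a = c("A", "B"), protein_b = c("B", "A"),
                    combined_score = c(910L, 905L))
  out <- filter_ppi(dup, 900)
  expect_equal(nrow(out), 1)
  expect_equal(out$combined_score, 910L)
  expect_true(out$protein_a <= out$protein_b)

  expect_error(filter_ppi(data.frame(protein_a = "A", protein_b = "B",
                                     combined_score = 1500L), 900),
               "\\[0, 1000\\]")
  expect_error(filter_ppi(data.frame(protein_a = "A", protein_b = "A",
                                     combined_score = 950L), 900),
               "self-interaction")
})

test_that("the toy CTPG integrates CTPI with high-confidence PPI only", {
  g <- toy_ctpg()
  expect_setequal(igraph::V(g)$name, c("c1", "c2", "t1", "t2", "d1"))
  expect_equal(igraph::ecount(g), 3)
  type <- stats::setNames(igraph::V(g)$node_type, igraph::V(g)$name)
  expect_equal(unname(type[c("c1", "t1", "d1")]),
               c("compound", "target", "de_gene"))
  expect_equal(sum(igraph::E(g)$relation == "targets"), 2)
  expect_equal(sum(igraph::E(g)$relation == "interacts"), 1)
})

test_that("degenerate CTPG inputs reduce to the expected graphs", {
  compounds <- data.frame(canonical_name = c("c1", "c2"))
  targets <- data.frame(protein = c("t1", "t2"), provenance = "docking")
  ctpi <- build_ctpi(compounds, targets,
                     data.frame(compound = c("c1", "c2"),
                                protein = c("t1", "t2")))
  ppi <- data.frame(protein_a = "t1", protein_b = "t2",
                    combined_score = 990L)
  # no DE genes: CTPI plus target-target PPI edges
  g0 <- build_ctpg(ctpi, ppi, de_genes = character(0))
  expect_equal(igraph::ecount(g0), 3)
  expect_equal(sum(igraph::V(g0)$node_type == "de_gene"), 0)
  # empty CTPI: PPI among DE proteins only, no compounds
  g1 <- build_ctpg(build_ctpi(compounds, targets,
                              data.frame(compound = character(0),
                                         protein = character(0))),
                   data.frame(protein_a = c("d1", "d1"),
                              protein_b = c("d2", "x9"),
                              combined_score = c(950L, 920L)),
                   de_genes = c("d1", "d2"))
  expect_setequal(igraph::V(g1)$name, c("d1", "d2"))
  expect_equal(igraph::ecount(g1), 1)
})

test_that("prioritization finds bridging targets and their compounds", {
  pt <- prioritize_targets(toy_ctpg())
  expect_equal(pt$protein, "t1")
  expect_equal(pt$de_neighbor_count, 1L)
  expect_equal(pt$compounds[[1]], "c1")
  expect_equal(retained_compounds(pt), "c1")
  # drop the DE bridge entirely: nothing is prioritized
  pt_none <- prioritize_targets(toy_ctpg(min_score = 990))
  expect_equal(nrow(pt_none), 0)
  expect_length(retained_compounds(pt_none), 0)
})

test_that("prioritization matches the exhaustive path-check oracle on small graphs", {
  set.seed(77)
  for (i in 1:150) {
    case <- rand_tripartite(12)
    nodes <- case$nodes[[1]]; edges <- case$edges[[1]]
    g <- ctpg_from_parts(nodes, edges)
    got <- sort(prioritize_targets(g)$protein)
    expect_equal(got, bf_prioritize(nodes, edges),
                 info = paste("case", i))
  }
})

test_that("prioritized sets shrink with stricter PPI scores and grow with DE genes", {
  set.seed(42)
  compounds <- data.frame(canonical_name = sprintf("c%d", 1:5))
  targets <- data.frame(protein = sprintf("t%d", 1:6),
                        provenance = "similarity")
  ctpi <- build_ctpi(compounds, targets,
                     data.frame(compound = sample(compounds$canonical_name,
                                                  10, replace = TRUE),
                                protein = sample(targets$protein, 10,
                                                 replace = TRUE)))
  ppi <- data.frame(protein_a = sample(c(sprintf("t%d", 1:6),
                                         sprintf("d%d", 1:4)), 25,
                                       replace = TRUE),
                    protein_b = sample(sprintf("d%d", 1:4), 25,
                                       replace = TRUE),
                    combined_score = sample(600:1000, 25, replace = TRUE))
  ppi <- ppi[ppi$protein_a != ppi$protein_b, ]
  de <- sprintf("d%d", 1:4)
  prev <- NULL
  for (ms in c(600, 800, 900, 990)) {
    cur <- prioritize_targets(build_ctpg(ctpi, filter_ppi(ppi, ms), de))$protein
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
  # growing the DE list never removes a prioritized target
  base <- prioritize_targets(build_ctpg(ctpi, filter_ppi(ppi, 900),
                                        de[1:2]))$protein
  grown <- prioritize_targets(build_ctpg(ctpi, filter_ppi(ppi, 900), de))$protein
  expect_true(all(base %in% grown))
})

test_that("targets that are themselves differential count per the self-DE rule", {
  compounds <- data.frame(canonical_name = "c1")
  targets <- data.frame(protein = "t1", provenance = "docking")
  ctpi <- build_ctpi(compounds, targets,
                     data.frame(compound = "c1", protein = "t1"))
  ppi <- data.frame(protein_a = character(0), protein_b = character(0),
                    combined_score = integer(0))
  # t1 is itself DE but has no DE neighbor: excluded by default...
  g <- build_ctpg(ctpi, ppi, de_genes = "t1")
  expect_equal(nrow(prioritize_targets(g)), 0)
  # ...included when a protein's own DE status is accepted as evidence
  pt <- prioritize_targets(g, self_de_counts = TRUE)
  expect_equal(pt$protein, "t1")
  expect_equal(pt$de_neighbor_count, 1L)
})

test_that("network summaries are internally consistent", {
  g <- toy_ctpg()
  s <- network_summary(g)
  expect_equal(s$n_nodes, s$n_compounds + s$n_targets + s$n_de)
  expect_equal(s$n_nodes, 5L)
  expect_equal(s$n_edges, 3L)
  expect_equal(sum(s$degree), 2L * s$n_edges)
  empty <- network_summary(igraph::make_empty_graph(0, directed = FALSE))
  expect_equal(empty$n_nodes, 0L)
  expect_equal(empty$n_edges, 0L)
})
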