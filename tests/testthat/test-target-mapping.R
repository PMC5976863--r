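test_that("tanimoto matches set arithmetic and its conventions", {
  a <- fingerprint(c(1, 2, 3), 16)
  b <- fingerprint(c(2, 3, 4), 16)
  expect_equal(tanimoto(a, b), 0.5)
  expect_equal(tanimoto(a, a), 1.0)
  expect_equal(tanimoto(a, fingerprint(c(8, 9), 16)), 0.0)
  expect_equal(tanimoto(fingerprint(integer(0), 16),
                        fingerprint(integer(0), 16)), 1.0)
  expect_equal(tanimoto(fingerprint(integer(0), 16), a), 0.0)
  expect_error(tanimoto(a, fingerprint(1, 32)), "mismatched")

  set.seed(11)
  for (i in 1:50) {
    x <- rand_fp(); y <- rand_fp()
    expect_equal(tanimoto(x, y), tanimoto(y, x))
    expect_equal(tanimoto(x, y),
                 length(intersect(x$bits, y$bits)) /
                   length(union(x$bits, y$bits)))
  }
})

test_that("fingerprint literals parse and format round-trip", {
  fp <- parse_fingerprint("16:0,3,9")
  expect_equal(fp$bits, c(0L, 3L, 9L))
  expect_equal(format(fp), "16:0,3,9")
  expect_equal(parse_fingerprint("8:")$bits, integer(0))
  expect_error(parse_fingerprint("0,3,9"), "literal")
  expect_error(fingerprint(16, 16), "\\[0, size\\)")
})

test_that("similarity mapping applies the inclusive cutoff to library drugs", {
  fp <- fingerprint(0:19, 64)
  lib <- data.frame(drug_id = c("D1", "D2", "D3"))
  # D1 shares 24/25 bits (0.96), D2 18/20 via 2 substitutions (0.818), D3 exact
  lib$fingerprint <- I(list(fingerprint(c(0:19, 20:24), 64),  # 20/25 = 0.8
                            fingerprint(c(0:17, 30, 31), 64), # 18/22 = 0.818
                            fingerprint(0:19, 64)))
  lib$targets <- I(list(c("A", "B"), "C", "PPARG"))
  expect_equal(similarity_targets(fp, lib, cutoff = 0.95), "PPARG")
  expect_equal(similarity_targets(fp, lib, cutoff = 0.8),
               c("A", "B", "C", "PPARG"))
  expect_equal(similarity_targets(fp, lib, cutoff = 1.0), "PPARG")
  # a cutoff met exactly is a hit (inclusive rule)
  expect_equal(similarity_targets(fp, lib, cutoff = 0.818181818181818,
                                  compound = "x")[1], "C")
  expect_warning(out <- similarity_targets(NULL, lib, compound = "noodle"),
                 "noodle")
  expect_length(out, 0)
})

test_that("planted two-drug example picks only the drug above the cutoff", {
  fp <- fingerprint(0:24, 128)
  lib <- data.frame(drug_id = c("D1", "D2"))
  lib$fingerprint <- I(list(fingerprint(0:23, 128),   # 24/25 = 0.96
                            fingerprint(c(0:21, 40), 128)))  # 22/26 = 0.846
  lib$targets <- I(list(c("A", "B"), "C"))
  expect_equal(similarity_targets(fp, lib, cutoff = 0.95), c("A", "B"))
})

test_that("raising the similarity cutoff never enlarges the target set", {
  set.seed(5)
  for (i in 1:30) {
    fp <- rand_fp(64, 16)
    lib <- data.frame(drug_id = sprintf("D%d", 1:8))
    lib$fingerprint <- I(replicate(8, rand_fp(64, 16), simplify = FALSE))
    lib$targets <- I(replicate(8, sample(LETTERS, 3), simplify = FALSE))
    cuts <- sort(runif(3))
    sets <- lapply(cuts, function(ct) similarity_targets(fp, lib, cutoff = ct))
    expect_true(all(sets[[2]] %in% sets[[1]]))
    expect_true(all(sets[[3]] %in% sets[[2]]))
  }
})

test_that("docking hits require strictly beating the co-crystal control", {
  controls <- data.frame(protein = c("A", "B", "C"),
                         control_score = c(60, 70, 80))
  records <- data.frame(
    compound = c("c1", "c1", "c2", "c2", "c3"),
    protein = c("A", "B", "A", "C", "B"),
    score = c(62, 70, 59.9, 85, 71)
  )
  hits <- docking_targets(records, controls)
  # 62 > 60 hit; 70 == 70 not a hit; 59.9 < 60 no; 85 > 80 hit; 71 > 70 hit
  expect_equal(nrow(hits), 3)
  expect_setequal(paste(hits$compound, hits$protein),
                  c("c1 A", "c2 C", "c3 B"))
  expect_error(
    docking_targets(data.frame(compound = "c", protein = "ZZZ", score = 1),
                    controls),
    "ZZZ")
  expect_error(docking_targets(records,
                               rbind(controls,
                                     data.frame(protein = "A",
                                                control_score = 50))),
               "multiple control")
  # raising a control score never creates new hits
  bumped <- controls
  bumped$control_score <- bumped$control_score + 10
  expect_true(all(paste(docking_targets(records, bumped)$compound,
                        docking_targets(records, bumped)$protein) %in%
                    paste(hits$compound, hits$protein)))
})

test_that("merged target sets carry provenance and union arithmetic", {
  dual <- c("PPARG", "STAT3", "PGFRB", "KS6B1", "MK08")
  sim <- c(sprintf("SIM%02d", 1:40), dual)
  dock <- c(sprintf("DOCK%02d", 1:34), dual)
  merged <- merge_target_sets(sim, dock)
  expect_equal(nrow(merged), 79)
  expect_setequal(merged$protein[merged$provenance == "both"], dual)
  expect_equal(nrow(merged),
               length(sim) + length(dock) - length(intersect(sim, dock)))

  disjoint <- merge_target_sets(c("a", "b"), c("c", "d", "e"))
  expect_equal(nrow(disjoint), 5)
  expect_false(any(disjoint$provenance == "both"))

  same <- merge_target_sets(c("x", "y"), c("y", "x"))
  expect_equal(nrow(same), 2)
  expect_true(all(same$provenance == "both"))
})

test_that("CTPI networks are bipartite and keep only covered nodes", {
  compounds <- data.frame(canonical_name = c("c1", "c2", "c3"))
  targets <- data.frame(protein = c("T1", "T2"), provenance = "similarity")
  edges <- data.frame(compound = c("c1", "c2", "c1"),
                      protein = c("T1", "T1", "T1"))
  g <- build_ctpi(compounds, targets, edges)
  expect_equal(igraph::vcount(g), 3)   # c3 and T2 uncovered, duplicate edge gone
  expect_equal(igraph::ecount(g), 2)
  expect_true(igraph::bipartite_mapping(g)$res)
  expect_equal(igraph::vcount(build_ctpi(compounds, targets, edges[0, ])), 0)
  expect_error(build_ctpi(compounds, targets,
                          data.frame(compound = "ghost", protein = "T1")),
               "ghost")
})

test_that("SIF and GraphML exports carry edges and node roles", {
  compounds <- data.frame(canonical_name = c("c1", "c2"))
  targets <- data.frame(protein = "T1", provenance = "docking")
  g <- build_ctpi(compounds, targets,
                  data.frame(compound = c("c1", "c2"), protein = "T1"))
  sif <- withr::local_tempfile(fileext = ".sif")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_sif(g, sif)
  lines <- readLines(sif)
  expect_length(lines, 2)
  expect_true(all(grepl("\ttargets\t", lines)))
  write_graphml(g, gml)
  back <- igraph::read_graph(gml, format = "graphml")
  expect_equal(sort(igraph::V(back)$node_type), c("compound", "compound",
                                                  "target"))
})
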