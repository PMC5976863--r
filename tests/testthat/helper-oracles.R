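# Independent brute-force oracles used to validate the package's statistics
# and graph rules. These deliberately share no code with the implementation.

# hypergeometric upper tail by direct enumeration of point masses
bf_hyper_upper <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# Benjamini-Hochberg step-up: q_i = min_{j: p_(j) >= p_(i)} min(1, m p_(j) / j)
bf_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, m * p[ord] / seq_len(m))
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# exhaustive path check of the prioritization rule on a small node/edge list:
# a target t is prioritized iff some compound c and some DE node d satisfy
# edges c-t and t-d
bf_prioritize <- function(nodes, edges) {
  adjacent <- function(x, y) {
    any((edges$from == x & edges$to == y) | (edges$from == y & edges$to == x))
  }
  targets <- nodes$name[nodes$role == "target"]
  compounds <- nodes$name[nodes$role == "compound"]
  des <- nodes$name[nodes$role == "de_gene"]
  keep <- vapply(targets, function(t) {
    any(vapply(compounds, adjacent, logical(1), y = t)) &&
      any(vapply(des, adjacent, logical(1), y = t))
  }, logical(1))
  sort(targets[keep])
}

# random small tripartite universe with only legal edge kinds
# (compound-target, target-target, target-de, de-de)
rand_tripartite <- function(n_max = 12) {
  n <- sample(3:n_max, 1)
  roles <- sample(c("compound", "target", "de_gene"), n, replace = TRUE)
  # ensure at least one of each role so the rule can fire
  roles[sample(n, 3)] <- c("compound", "target", "de_gene")
  nodes <- data.frame(name = sprintf("n%02d", seq_len(n)), role = roles,
                      stringsAsFactors = FALSE)
  pairs <- t(combn(nodes$name, 2))
  role_of <- stats::setNames(nodes$role, nodes$name)
  legal <- apply(pairs, 1, function(p) {
    r <- sort(role_of[p])
    paste(r, collapse = "+") %in% c("compound+target", "target+target",
                                    "de_gene+target", "de_gene+de_gene")
  })
  pairs <- pairs[legal, , drop = FALSE]
  take <- runif(nrow(pairs)) < 0.4
  data.frame(nodes = I(list(nodes)),
             edges = I(list(data.frame(from = pairs[take, 1],
                                       to = pairs[take, 2],
                                       stringsAsFactors = FALSE))))
}

# assemble a CTPG igraph directly from a role-labelled node/edge list by
# routing the pieces through build_ctpi / filter_ppi / build_ctpg
ctpg_from_parts <- function(nodes, edges) {
  role_of <- stats::setNames(nodes$role, nodes$name)
  is_ct <- role_of[edges$from] == "compound" | role_of[edges$to] == "compound"
  ct <- edges[is_ct, , drop = FALSE]
  comp_first <- role_of[ct$from] == "compound"
  ctpi_edges <- data.frame(
    compound = ifelse(comp_first, ct$from, ct$to),
    protein = ifelse(comp_first, ct$to, ct$from),
    stringsAsFactors = FALSE
  )
  compounds <- data.frame(canonical_name = nodes$name[nodes$role == "compound"],
                          stringsAsFactors = FALSE)
  targets <- data.frame(protein = nodes$name[nodes$role == "target"],
                        provenance = "similarity", stringsAsFactors = FALSE)
  ctpi <- build_ctpi(compounds, targets, ctpi_edges)
  pp <- edges[!is_ct, , drop = FALSE]
  ppi <- data.frame(protein_a = pp$from, protein_b = pp$to,
                    combined_score = rep(950L, nrow(pp)),
                    stringsAsFactors = FALSE)
  build_ctpg(ctpi, ppi, de_genes = nodes$name[nodes$role == "de_gene"])
}

# random binary fingerprint
rand_fp <- function(size = 64, nbits = 12) {
  fingerprint(sample.int(size, nbits) - 1L, size)
}
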