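write_expr_fixture <- function(m, labels, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  mp <- file.path(dir, "expr.tsv")
  lp <- file.path(dir, "labels.tsv")
  utils::write.table(data.frame(gene = rownames(m), m, check.names = FALSE),
                     mp, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = names(labels),
                                condition = unname(labels)),
                     lp, sep = "\t", quote = FALSE, row.names = FALSE)
  c(matrix = mp, labels = lp)
}

sim_expr <- function(n_genes = 100, n = 3, seed = 1) {
  set.seed(seed)
  samples <- c(paste0("Q", 1:n), paste0("A", 1:n))
  m <- matrix(rnorm(n_genes * 2 * n, 8, 0.5), n_genes,
              dimnames = list(sprintf("g%03d", 1:n_genes), samples))
  labels <- stats::setNames(rep(c("quiescent", "activated"), each = n),
                            samples)
  list(m = m, labels = labels)
}

test_that("expression matrices load, validate, and report error locations", {
  e <- sim_expr()
  f <- write_expr_fixture(e$m, e$labels)
  expr <- load_expression(f["matrix"], f["labels"])
  expect_equal(dim(expr$values), c(100, 6))
  expect_equal(unname(expr$labels["A2"]), "activated")

  # unlabeled sample
  f2 <- write_expr_fixture(e$m, e$labels[-1])
  expect_error(load_expression(f2["matrix"], f2["labels"]), "Q1")

  # duplicated gene row
  m_dup <- rbind(e$m, e$m[1, , drop = FALSE])
  f3 <- write_expr_fixture(m_dup, e$labels)
  expect_error(load_expression(f3["matrix"], f3["labels"]), "g001")

  # non-numeric cell named by gene and sample
  m_chr <- e$m
  m_bad <- apply(m_chr, 2, as.character)
  rownames(m_bad) <- rownames(m_chr)
  m_bad[5, 2] <- "oops"
  f4 <- write_expr_fixture(m_bad, e$labels)
  expect_error(load_expression(f4["matrix"], f4["labels"]), "g005.*Q2")

  # log2 transform on load
  expr_l <- load_expression(f["matrix"], f["labels"], log2 = TRUE)
  expect_equal(expr_l$values, log2(expr$values + 1))
})

test_that("planted differential genes are recovered with near-zero false positives", {
  set.seed(2024)
  n <- 5
  samples <- c(paste0("Q", 1:n), paste0("A", 1:n))
  genes <- sprintf("g%04d", 1:1000)
  m <- matrix(rnorm(1000 * 2 * n, 8, 0.5), 1000,
              dimnames = list(genes, samples))
  planted <- genes[1:20]
  m[planted, (n + 1):(2 * n)] <- m[planted, (n + 1):(2 * n)] + 3
  labels <- stats::setNames(rep(c("quiescent", "activated"), each = n), samples)
  # the pooled test is exact under this equal-variance simulation and
  # recovers every planted gene; Welch occasionally loses one to its random
  # degrees of freedom at n = 5, so it is held to near-complete recall
  pooled <- differential_genes(list(values = m, labels = labels),
                               var_equal = TRUE)
  expect_true(all(pooled$significant[pooled$gene %in% planted]))
  expect_lte(sum(pooled$significant & !pooled$gene %in% planted), 2)
  welch <- differential_genes(list(values = m, labels = labels))
  expect_gte(mean(welch$significant[welch$gene %in% planted]), 0.9)
  expect_lte(sum(welch$significant & !welch$gene %in% planted), 2)
  expect_true(all(welch$log2fc[welch$gene %in% planted] > 2))
})

test_that("zero-variance genes are reported untested, small groups are rejected", {
  e <- sim_expr(n_genes = 10, n = 3)
  e$m[1, ] <- 5 # constant in both groups
  de <- differential_genes(list(values = e$m, labels = e$labels))
  expect_false(de$tested[1])
  expect_true(is.na(de$p[1]) && is.na(de$q[1]))
  expect_false(de$significant[1])
  expect_true(all(de$tested[-1]))

  one <- e$labels
  one[c("Q2", "Q3")] <- "activated"
  expect_error(differential_genes(list(values = e$m, labels = one)),
               "at least 2 samples")
})

test_that("p-values agree with stats::t.test in both variance modes", {
  e <- sim_expr(n_genes = 40, n = 4, seed = 9)
  expr <- list(values = e$m, labels = e$labels)
  for (ve in c(FALSE, TRUE)) {
    de <- differential_genes(expr, var_equal = ve)
    ref <- vapply(seq_len(nrow(e$m)), function(i) {
      stats::t.test(e$m[i, e$labels == "activated"],
                    e$m[i, e$labels == "quiescent"],
                    var.equal = ve)$p.value
    }, numeric(1))
    expect_equal(de$p, ref, tolerance = 1e-12)
  }
})

test_that("swapping condition labels negates fold changes and keeps p-values", {
  e <- sim_expr(n_genes = 50, n = 4, seed = 3)
  expr <- list(values = e$m, labels = e$labels)
  fwd <- differential_genes(expr)
  rev <- differential_genes(expr, conditions = c("activated", "quiescent"))
  expect_equal(rev$log2fc, -fwd$log2fc)
  expect_equal(rev$p, fwd$p)
  expect_equal(rev$significant, fwd$significant)
})

test_that("BH adjustment in the DE table equals the brute-force step-up", {
  e <- sim_expr(n_genes = 200, n = 3, seed = 4)
  de <- differential_genes(list(values = e$m, labels = e$labels))
  expect_equal(de$q, bf_bh(de$p))
  expect_true(all(de$q >= de$p))
})
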