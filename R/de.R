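#' Load a two-condition expression matrix
#'
#' The matrix TSV has a first column `gene` and one column per sample; the
#' labels TSV maps `sample<TAB>condition` with conditions `quiescent` and
#' `activated` (any two labels are accepted; these are the defaults used by
#' [differential_genes()]). Values are expected on the log2 scale; set
#' `log2 = TRUE` to apply `log2(x + 1)` to a raw-scale matrix on load.
#'
#' @param matrix_path path to the expression TSV.
#' @param labels_path path to the sample-label TSV.
#' @param log2 apply `log2(x + 1)` on load.
#' @return list of class `fzhy_expr` with `values` (numeric gene x sample
#'   matrix) and `labels` (named character vector, sample -> condition).
#' @export
load_expression <- function(matrix_path, labels_path, log2 = FALSE) {
  df <- utils::read.delim(matrix_path, sep = "\t", header = TRUE, quote = "",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  if (!"gene" %in% names(df) || names(df)[1] != "gene") {
    stop("expression matrix '", matrix_path,
         "' must have 'gene' as its first column", call. = FALSE)
  }
  genes <- as.character(df$gene)
  if (anyDuplicated(genes)) {
    stop("duplicated gene identifier(s) in '", matrix_path, "': ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "),
         call. = FALSE)
  }
  vals <- df[, -1, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop("non-numeric or missing value in '", matrix_path, "' at gene '",
           genes[bad], "', sample '", names(vals)[j], "'", call. = FALSE)
    }
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- genes
  lab <- utils::read.delim(labels_path, sep = "\t", header = TRUE, quote = "",
                           stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (col in c("sample", "condition")) {
    if (!col %in% names(lab)) {
      stop("label file '", labels_path, "' lacks required column '", col, "'",
           call. = FALSE)
    }
  }
  labels <- stats::setNames(as.character(lab$condition),
                            as.character(lab$sample))
  unlabeled <- setdiff(colnames(m), names(labels))
  if (length(unlabeled)) {
    stop("sample(s) without a condition label: ",
         paste(unlabeled, collapse = ", "), call. = FALSE)
  }
  labels <- labels[colnames(m)]
  if (log2) m <- log2(m + 1)
  structure(list(values = m, labels = labels), class = "fzhy_expr")
}

row_var <- function(x) {
  n <- ncol(x)
  if (n < 2) return(rep(NA_real_, nrow(x)))
  mu <- rowMeans(x)
  rowSums((x - mu)^2) / (n - 1)
}

#' Two-group differential expression
#'
#' Per-gene two-sample t-test on log2 values (Welch by default, pooled
#' variance with `var_equal = TRUE`), Benjamini-Hochberg adjustment across
#' all tested genes, and a fold-change floor. A gene is flagged significant
#' when `q < alpha` and `|log2fc| >= min_abs_log2fc`. Genes with zero
#' variance in both groups cannot be tested and are reported with
#' `tested = FALSE` and `NA` p/q.
#'
#' @param expr `fzhy_expr` from [load_expression()], or a list with `values`
#'   and `labels` of the same shape.
#' @param alpha significance level on the adjusted p-value, default 0.05.
#' @param min_abs_log2fc minimum absolute log2 fold change, default 1.
#' @param conditions length-2 character: reference condition first, treatment
#'   second; `log2fc` is treatment minus reference. Default
#'   `c("quiescent", "activated")`.
#' @param var_equal use the pooled-variance (Student) t statistic instead of
#'   Welch. The pooled test is exact when the two groups share a variance;
#'   Welch is robust to unequal variances but slightly conservative at very
#'   small group sizes.
#' @return data.frame `gene`, `log2fc`, `p`, `q`, `significant`, `tested`,
#'   in input gene order.
#' @export
differential_genes <- function(expr, alpha = 0.05, min_abs_log2fc = 1.0,
                               conditions = c("quiescent", "activated"),
                               var_equal = FALSE) {
  m <- expr$values
  labels <- expr$labels[colnames(m)]
  g1 <- m[, labels == conditions[1], drop = FALSE]
  g2 <- m[, labels == conditions[2], drop = FALSE]
  n1 <- ncol(g1); n2 <- ncol(g2)
  if (n1 < 2 || n2 < 2) {
    stop("each condition needs at least 2 samples (", conditions[1], ": ", n1,
         ", ", conditions[2], ": ", n2, ")", call. = FALSE)
  }
  m1 <- rowMeans(g1); m2 <- rowMeans(g2)
  v1 <- row_var(g1); v2 <- row_var(g2)
  log2fc <- m2 - m1
  tested <- !(v1 == 0 & v2 == 0)
  p <- rep(NA_real_, nrow(m))
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
    tt <- log2fc / se
    p[tested] <- 2 * stats::pt(-abs(tt[tested]), df)
  } else {
    se2 <- v1 / n1 + v2 / n2
    tt <- log2fc / sqrt(se2)
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
    p[tested] <- 2 * stats::pt(-abs(tt[tested]), df[tested])
  }
  q <- rep(NA_real_, nrow(m))
  q[tested] <- stats::p.adjust(p[tested], method = "BH")
  sig <- tested & !is.na(q) & q < alpha & abs(log2fc) >= min_abs_log2fc
  data.frame(gene = rownames(m), log2fc = log2fc, p = p, q = q,
             significant = sig, tested = tested,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a differential-expression result table
#'
#' @param de data.frame from [differential_genes()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}
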