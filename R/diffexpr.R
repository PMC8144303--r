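# Per-gene two-group differential expression on the log2 matrix, BH FDR,
# top-DEG selection and PCA summaries.

#' Two-group differential expression test
#'
#' Pooled-variance two-sample t-test per gene on log2 expression:
#' `log2FC = mean(group A) - mean(group B)`, t with `df = nA + nB - 2`,
#' two-sided p, and BH-adjusted q. Genes with `p < alpha` form the DEG set.
#' When both groups have zero within-group variance the pooled SD is floored
#' at `var_floor` and the gene is flagged `degenerate` (reachable with n = 3
#' pooled lanes per group).
#'
#' @param matrix Log2-scale `count_matrix`.
#' @param design A `design_table`; groups are its `group` column
#'   (`<APP>.<Arg1>`).
#' @param contrast Character vector `c(numerator_group, denominator_group)`.
#' @param alpha Unadjusted p-value DEG threshold (default 0.05).
#' @param var_floor Lower bound on the pooled SD (default 1e-8).
#' @return A `de_result` data.frame: `gene`, `log2fc`, `t`, `df`, `p`, `q`,
#'   `deg`, `degenerate`, with the contrast as an attribute.
#' @export
de_test <- function(matrix, design, contrast, alpha = 0.05, var_floor = 1e-8) {
  if (!identical(cm_scale(matrix), "log2"))
    stop("de_test expects a log2-scale matrix")
  stopifnot(length(contrast) == 2L)
  grp <- stats::setNames(design$group, design$sample_id)[colnames(matrix)]
  a <- colnames(matrix)[!is.na(grp) & grp == contrast[1L]]
  b <- colnames(matrix)[!is.na(grp) & grp == contrast[2L]]
  if (length(a) == 0L || length(b) == 0L)
    stop("empty contrast group: ",
         contrast[c(length(a) == 0L, length(b) == 0L)][1L])
  if (length(a) < 2L || length(b) < 2L)
    stop("both contrast groups need >= 2 samples")
  xa <- matrix[, a, drop = FALSE]
  xb <- matrix[, b, drop = FALSE]
  na <- length(a); nb <- length(b)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- apply(xa, 1L, stats::var)
  vb <- apply(xb, 1L, stats::var)
  df <- na + nb - 2L
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / df)
  degen <- sp < var_floor
  sp[degen] <- var_floor
  tstat <- (ma - mb) / (sp * sqrt(1 / na + 1 / nb))
  p <- 2 * stats::pt(abs(tstat), df = df, lower.tail = FALSE)
  res <- data.frame(gene = rownames(matrix), log2fc = ma - mb, t = tstat,
                    df = df, p = p, q = bh_fdr(p), deg = p < alpha,
                    degenerate = degen, row.names = NULL,
                    stringsAsFactors = FALSE)
  attr(res, "contrast") <- contrast
  attr(res, "alpha") <- alpha
  class(res) <- c("de_result", "data.frame")
  res
}

#' Benjamini-Hochberg adjusted p-values
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @return Adjusted q-values (same order as input).
#' @export
bh_fdr <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Top differentially expressed genes
#'
#' Ranks the DEG set (`p < alpha`) by absolute log2 fold change (descending)
#' or by p-value (ascending); ties break by gene name.
#'
#' @param de A `de_result`.
#' @param n Number of genes requested; if it exceeds the DEG count, all DEGs
#'   are returned with a `truncated` attribute and a warning.
#' @param by `"abs_log2fc"` or `"p"`.
#' @return Character vector of gene names.
#' @export
top_degs <- function(de, n, by = c("abs_log2fc", "p")) {
  by <- match.arg(by)
  degs <- de[de$deg, , drop = FALSE]
  key <- if (by == "abs_log2fc") -abs(degs$log2fc) else degs$p
  degs <- degs[order(key, degs$gene), , drop = FALSE]
  truncated <- n > nrow(degs)
  if (truncated)
    warning("requested ", n, " genes but only ", nrow(degs), " DEGs")
  out <- utils::head(degs$gene, n)
  attr(out, "truncated") <- truncated
  out
}

#' Principal component analysis of a log2 matrix
#'
#' Samples are observations; genes are centered (per-gene mean zero across
#' samples) and by default not scaled. Variance fractions cover all
#' components and sum to one.
#'
#' @param matrix Log2-scale `count_matrix`.
#' @param genes Optional gene subset.
#' @param n_components Components to keep in `scores`/`loadings` (default
#'   all).
#' @param scale. Scale genes to unit variance before the decomposition.
#' @return A `pca_result`: `scores` (samples x components), `loadings`
#'   (genes x components), `var_frac` (all components).
#' @export
pca_panel <- function(matrix, genes = NULL, n_components = NULL,
                      scale. = FALSE) {
  x <- unclass(matrix)
  if (!is.null(genes)) {
    miss <- setdiff(genes, rownames(x))
    if (length(miss))
      stop("genes absent from matrix: ", paste(miss, collapse = ", "))
    x <- x[genes, , drop = FALSE]
  }
  if (ncol(x) < 2L) stop("PCA needs >= 2 samples")
  if (all(apply(x, 1L, stats::var) == 0))
    stop("constant matrix: zero total variance")
  if (scale.) x <- x[apply(x, 1L, stats::var) > 0, , drop = FALSE]
  pr <- stats::prcomp(t(x), center = TRUE, scale. = scale.)
  var_all <- pr$sdev^2
  var_frac <- var_all / sum(var_all)
  k <- if (is.null(n_components)) length(var_frac) else
    min(n_components, length(var_frac))
  structure(list(scores = pr$x[, seq_len(k), drop = FALSE],
                 loadings = pr$rotation[, seq_len(k), drop = FALSE],
                 var_frac = var_frac),
            class = "pca_result")
}
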