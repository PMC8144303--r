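# The three scoring engines: first-principal-component pathway scores,
# directed/undirected global significance scores against a design covariate,
# and cell-type profiling by marker averaging with a random-gene-set QC null.

#' First-principal-component pathway score
#'
#' Restricts the log2 matrix to the set's measured genes, centers each gene
#' across samples, and scores each sample by its projection on the first
#' right singular vector. The sign is oriented so that higher expression of
#' the set gives a higher score: the score is flipped so that the majority of
#' gene loadings are positive; on an exact tie, so that the score correlates
#' positively with the per-sample mean expression of the set. Scores have
#' mean zero across samples.
#'
#' @param matrix Log2-scale `count_matrix` with >= 3 samples.
#' @param set A `gene_set` (or character vector of genes).
#' @param min_genes Minimum measured genes required; sets below it are
#'   skipped (return `NULL` with a message attribute via `skipped_set()`).
#'   Default 2 for a single set; pipeline-level scoring uses 5.
#' @return A `pathway_score` list: `scores` (named per-sample, mean 0),
#'   `orientation` (+1/-1 applied), `pc1_var_frac`, `genes` (measured
#'   members), `loadings`.
#' @export
pathway_score <- function(matrix, set, min_genes = 2L) {
  genes <- if (inherits(set, "gene_set")) set$genes else as.character(set)
  nm <- if (inherits(set, "gene_set")) set$name else "set"
  measured <- intersect(genes, rownames(matrix))
  if (length(measured) < min_genes)
    return(structure(list(name = nm, n_measured = length(measured),
                          reason = "fewer measured genes than min_genes"),
                     class = "skipped_set"))
  if (ncol(matrix) < 3L) stop("pathway scoring needs >= 3 samples")
  x <- unclass(matrix)[measured, , drop = FALSE]
  xc <- x - rowMeans(x)
  if (all(xc == 0)) stop("zero variance in gene set '", nm, "'")
  sv <- svd(xc)
  u1 <- sv$u[, 1L]
  scores <- as.vector(t(xc) %*% u1)
  orient <- sign(sum(u1))
  if (orient == 0) {
    set_mean <- colMeans(x)
    orient <- sign(stats::cor(scores, set_mean))
    if (is.na(orient) || orient == 0) orient <- 1
  }
  scores <- scores * orient
  structure(list(name = nm,
                 scores = stats::setNames(scores, colnames(x)),
                 orientation = orient,
                 pc1_var_frac = sv$d[1L]^2 / sum(sv$d^2),
                 genes = measured,
                 loadings = stats::setNames(u1 * orient, measured)),
            class = "pathway_score")
}

#' Pathway scores for a collection of gene sets
#'
#' @param matrix Log2-scale `count_matrix`.
#' @param sets Named list of `gene_set` objects.
#' @param min_genes Minimum measured genes per scored set (default 5,
#'   mirroring the rule that dropped sparse pathways from scoring).
#' @return A `score_table`: matrix of scores (sets x samples) with
#'   attributes `orientation`, `pc1_var_frac` and `skipped` (names of sets
#'   below `min_genes`).
#' @export
pathway_scores <- function(matrix, sets, min_genes = 5L) {
  res <- lapply(sets, pathway_score, matrix = matrix, min_genes = min_genes)
  skipped <- names(res)[vapply(res, inherits, TRUE, "skipped_set")]
  res <- res[setdiff(names(res), skipped)]
  if (length(res) == 0L) stop("no scorable gene sets")
  tab <- do.call(rbind, lapply(res, `[[`, "scores"))
  rownames(tab) <- names(res)
  structure(tab,
            orientation = vapply(res, `[[`, 0, "orientation"),
            pc1_var_frac = vapply(res, `[[`, 0, "pc1_var_frac"),
            skipped = skipped,
            class = c("score_table", "matrix", "array"))
}

#' Per-gene t-statistics against a design covariate
#'
#' Default engine fits the additive two-factor linear model
#' `log2 expression ~ APP + Arg1` over all samples and reports the
#' t-statistic of the requested covariate's coefficient (df = n - 3). The
#' `"univariate"` engine uses a pooled two-group t-test on that covariate
#' alone.
#'
#' @param matrix Log2-scale `count_matrix`.
#' @param design A `design_table`.
#' @param covariate `"APP"` or `"Arg1"`.
#' @param engine `"two_factor"` (default) or `"univariate"`.
#' @return Named numeric vector of t-statistics with attribute `df`.
#' @export
covariate_t <- function(matrix, design, covariate = c("APP", "Arg1"),
                        engine = c("two_factor", "univariate")) {
  covariate <- match.arg(covariate)
  engine <- match.arg(engine)
  d <- design[match(colnames(matrix), design$sample_id), ]
  if (anyNA(d$sample_id)) stop("design table does not cover all samples")
  if (nlevels(droplevels(d$APP)) < 2L || nlevels(droplevels(d$Arg1)) < 2L)
    stop("both covariates need both levels present")
  y <- t(unclass(matrix))                       # samples x genes
  if (engine == "univariate") {
    lev <- levels(d[[covariate]])
    hi <- d[[covariate]] == lev[2L]
    n1 <- sum(hi); n0 <- sum(!hi)
    m1 <- colMeans(y[hi, , drop = FALSE]); m0 <- colMeans(y[!hi, , drop = FALSE])
    v1 <- apply(y[hi, , drop = FALSE], 2L, stats::var)
    v0 <- apply(y[!hi, , drop = FALSE], 2L, stats::var)
    df <- n1 + n0 - 2L
    sp <- sqrt(((n1 - 1) * v1 + (n0 - 1) * v0) / df)
    t <- (m1 - m0) / (sp * sqrt(1 / n1 + 1 / n0))
    return(structure(stats::setNames(t, rownames(matrix)), df = df))
  }
  X <- stats::model.matrix(~ APP + Arg1, data = d)
  qx <- qr(X)
  if (qx$rank < ncol(X))
    stop("confounded design: APP and Arg1 are aliased")
  B <- qr.coef(qx, y)                           # 3 x genes
  res <- y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  coef_name <- paste0(covariate, levels(d[[covariate]])[2L])
  j <- match(coef_name, colnames(X))
  se <- sqrt(sigma2 * xtx_inv[j, j])
  structure(stats::setNames(B[j, ] / se, rownames(matrix)), df = df)
}

#' Directed global significance score
#'
#' For a gene set with per-gene t-statistics, let `m` be the mean of
#' `sign(t) * t^2` over the set's measured genes; the directed score is
#' `sign(m) * sqrt(|m|)`. Positive scores indicate overall up-regulation.
#'
#' @param gene_t Named numeric vector of t-statistics.
#' @param set A `gene_set` or character vector.
#' @return Signed score (scalar).
#' @export
directed_gss <- function(gene_t, set) {
  t_set <- gss_set_t(gene_t, set)
  m <- mean(sign(t_set) * t_set^2)
  sign(m) * sqrt(abs(m))
}

#' Undirected global significance score
#'
#' `sqrt(mean(t^2))` over the set's measured genes: magnitude of
#' differential expression regardless of direction. Always at least
#' `|directed_gss|`.
#'
#' @inheritParams directed_gss
#' @return Non-negative score (scalar).
#' @export
undirected_gss <- function(gene_t, set) {
  t_set <- gss_set_t(gene_t, set)
  sqrt(mean(t_set^2))
}

gss_set_t <- function(gene_t, set) {
  genes <- if (inherits(set, "gene_set")) set$genes else as.character(set)
  t_set <- gene_t[intersect(genes, names(gene_t))]
  if (length(t_set) == 0L) stop("no measured genes in set")
  t_set
}

#' Global significance score table per covariate
#'
#' Computes directed and undirected scores for every gene set against each
#' design covariate, flagging sets whose absolute directed score reaches the
#' cutoff as up- (positive) or down- (negative) regulated.
#'
#' @param matrix Log2-scale `count_matrix`.
#' @param design A `design_table`.
#' @param sets Named list of `gene_set` objects.
#' @param covariates Covariates to score against (default both).
#' @param cutoff Absolute directed-score significance cutoff (default 1.3).
#' @param min_genes Minimum measured genes per scored set (default 5).
#' @param engine Passed to [covariate_t()].
#' @return A `gss_result` data.frame: `pathway`, `covariate`, `n_genes`,
#'   `directed_gss`, `undirected_gss`, `flag` (`"up"`, `"down"`, `"ns"`).
#' @export
gss_table <- function(matrix, design, sets, covariates = c("APP", "Arg1"),
                      cutoff = 1.3, min_genes = 5L,
                      engine = c("two_factor", "univariate")) {
  engine <- match.arg(engine)
  rows <- list()
  for (cov in covariates) {
    gt <- covariate_t(matrix, design, cov, engine = engine)
    for (nm in names(sets)) {
      measured <- intersect(sets[[nm]]$genes, names(gt))
      if (length(measured) < min_genes) next
      d <- directed_gss(gt, measured)
      u <- undirected_gss(gt, measured)
      rows[[length(rows) + 1L]] <- data.frame(
        pathway = nm, covariate = cov, n_genes = length(measured),
        directed_gss = d, undirected_gss = u,
        flag = if (abs(d) >= cutoff) (if (d > 0) "up" else "down") else "ns",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  attr(res, "cutoff") <- cutoff
  class(res) <- c("gss_result", "data.frame")
  res
}

#' Cell-type score by marker averaging
#'
#' Per-sample score = arithmetic mean of the measured marker genes' log2
#' values, a relative (not absolute) cell abundance proxy.
#'
#' @param matrix Log2-scale `count_matrix`.
#' @param markers A `gene_set` of marker genes (or character vector).
#' @return Named numeric vector of per-sample scores with attribute
#'   `markers_used`.
#' @export
celltype_score <- function(matrix, markers) {
  genes <- if (inherits(markers, "gene_set")) markers$genes else
    as.character(markers)
  measured <- intersect(genes, rownames(matrix))
  if (length(measured) == 0L) stop("no measured marker genes")
  s <- colMeans(unclass(matrix)[measured, , drop = FALSE])
  attr(s, "markers_used") <- measured
  s
}

#' Marker co-correlation QC against random gene sets
#'
#' Validates a marker set by the mean pairwise Pearson correlation of its
#' members across samples, compared with `n_random` same-size gene sets
#' drawn without replacement from the non-marker measured genes. The
#' permutation p-value uses the add-one estimator
#' `(1 + #(null >= observed)) / (1 + n_random)`, so it is never zero. The
#' mean pairwise regression slope is reported descriptively.
#'
#' @param matrix Log2-scale `count_matrix`.
#' @param markers Marker `gene_set` or character vector.
#' @param n_random Number of random sets (>= 99; default 999).
#' @param seed RNG seed for the draws.
#' @return List: `qc_p`, `mean_marker_corr`, `mean_marker_slope`,
#'   `null_corr` (the permutation statistics), `flag` (`TRUE` when QC was
#'   undefined: fewer than 2 measured markers, `qc_p` set to 1).
#' @export
celltype_qc <- function(matrix, markers, n_random = 999L, seed = 1L) {
  genes <- if (inherits(markers, "gene_set")) markers$genes else
    as.character(markers)
  measured <- intersect(genes, rownames(matrix))
  if (length(measured) < 2L)
    return(list(qc_p = 1, mean_marker_corr = NA_real_,
                mean_marker_slope = NA_real_, null_corr = numeric(),
                flag = TRUE))
  if (n_random < 99L) stop("n_random must be >= 99")
  x <- unclass(matrix)
  pool <- setdiff(rownames(x), measured)
  if (length(pool) < length(measured))
    stop("non-marker gene pool smaller than the marker set")
  mean_pair_corr <- function(g) {
    cm <- stats::cor(t(x[g, , drop = FALSE]))
    mean(cm[upper.tri(cm)])
  }
  obs <- mean_pair_corr(measured)
  set.seed(seed)
  null <- vapply(seq_len(n_random), function(i)
    mean_pair_corr(sample(pool, length(measured))), 0)
  sub <- x[measured, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  cm <- stats::cor(t(sub))
  slope <- outer(sds, sds, `/`) * cm          # slope of row i on row j
  list(qc_p = (1 + sum(null >= obs)) / (1 + n_random),
       mean_marker_corr = obs,
       mean_marker_slope = mean(slope[upper.tri(slope) | lower.tri(slope)]),
       null_corr = null,
       flag = FALSE)
}

#' Cell-type profile across all annotated cell types
#'
#' @param matrix Log2-scale `count_matrix`.
#' @param marker_sets Named list of marker `gene_set`s (e.g. from
#'   [celltype_gene_sets()]).
#' @param n_random,seed Passed to [celltype_qc()].
#' @return List with `scores` (cell types x samples matrix) and `qc`
#'   (data.frame: cell type, n markers, mean correlation, qc p, flag).
#' @export
celltype_profile <- function(matrix, marker_sets, n_random = 999L, seed = 1L) {
  scores <- do.call(rbind, lapply(marker_sets, function(s)
    celltype_score(matrix, s)))
  rownames(scores) <- names(marker_sets)
  qc <- do.call(rbind, lapply(names(marker_sets), function(nm) {
    q <- celltype_qc(matrix, marker_sets[[nm]], n_random = n_random,
                     seed = seed)
    data.frame(celltype = nm,
               n_markers = length(intersect(marker_sets[[nm]]$genes,
                                            rownames(matrix))),
               mean_marker_corr = q$mean_marker_corr,
               qc_p = q$qc_p, flag = q$flag, stringsAsFactors = FALSE)
  }))
  list(scores = scores, qc = qc)
}
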