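# Lane-level system QC, limit-of-detection QC, background thresholding from
# negative controls, geNorm housekeeping selection and normalization to a
# log2 expression matrix.

#' QC thresholds for lane-level system QC
#'
#' Defaults follow standard nCounter practice: imaging passes when more than
#' 75 percent of attempted fields of view were counted; binding density must
#' lie within 0.10-2.25 spots/um^2 (inclusive); positive-control linearity
#' requires R^2 > 0.95 on the log2-log2 titration fit; the limit-of-detection
#' rule requires the 0.5 fM positive probe to exceed the negative-control
#' mean by `lod_sd_mult` standard deviations.
#'
#' @param fov_min Minimum percent fields of view counted (strict `>`).
#' @param bd_min,bd_max Binding density bounds in spots/um^2 (inclusive).
#' @param poslin_r2_min Minimum positive-control linearity R^2 (strict `>`).
#' @param lod_sd_mult SD multiplier for the LOD rule.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(fov_min = 75, bd_min = 0.1, bd_max = 2.25,
                          poslin_r2_min = 0.95, lod_sd_mult = 2) {
  stopifnot(bd_min < bd_max, poslin_r2_min > 0, poslin_r2_min <= 1)
  structure(list(fov_min = fov_min, bd_min = bd_min, bd_max = bd_max,
                 poslin_r2_min = poslin_r2_min, lod_sd_mult = lod_sd_mult),
            class = "qc_thresholds")
}

#' Positive-control linearity R^2
#'
#' R^2 of the simple linear regression of log2 counts on
#' `log2(concentration)` across the positive-control titration; a +0.5
#' offset is applied to the counts only when zeros are present, so an exact
#' power-law titration scores exactly 1. Constant counts give R^2 = 0 by
#' convention (zero explained variance).
#'
#' @param counts Numeric vector of positive-control counts, named by (or
#'   accompanied by) their fM concentrations.
#' @param concentrations Concentrations in fM; defaults to
#'   `as.numeric(names(counts))`.
#' @return R^2 in \[0, 1\].
#' @export
pos_control_r2 <- function(counts, concentrations = as.numeric(names(counts))) {
  if (any(is.na(concentrations)))
    stop("positive-control concentrations are missing")
  if (length(unique(concentrations)) < 3L)
    stop("need >= 3 distinct positive-control concentrations")
  if (any(counts < 0)) stop("counts must be non-negative")
  y <- log2(counts + if (any(counts == 0)) 0.5 else 0)
  x <- log2(concentrations)
  if (stats::sd(y) == 0) return(0)
  stats::cor(x, y)^2
}

#' Lane-level system and LOD QC
#'
#' Applies the four per-lane QC rules: imaging (percent fields of view
#' counted), binding density, positive-control linearity, and the
#' limit-of-detection rule (count of the 0.5 fM positive probe must exceed
#' `mean(neg) + lod_sd_mult * sd(neg)` computed within the lane).
#'
#' @param lanes List of `sample_lane` objects.
#' @param ann A `probe_annotation` identifying positive/negative probes and
#'   positive concentrations.
#' @param thresholds A [qc_thresholds()] object.
#' @param lod_conc Concentration (fM) of the LOD probe (default 0.5).
#' @return A `qc_report` data.frame: one row per lane with the measured
#'   values, the four pass flags and `overall_pass` (their conjunction).
#' @export
lane_qc <- function(lanes, ann, thresholds = qc_thresholds(), lod_conc = 0.5) {
  pos <- ann[ann$code_class == "Positive", ]
  neg <- ann[ann$code_class == "Negative", ]
  if (nrow(pos) == 0L || nrow(neg) == 0L)
    stop("annotation must contain positive and negative control probes")
  lod_probe <- pos$gene_id[which(pos$concentration == lod_conc)]
  if (length(lod_probe) != 1L)
    stop("annotation must contain exactly one positive probe at ",
         lod_conc, " fM")
  rows <- lapply(lanes, function(ln) {
    pc <- ln$counts[pos$gene_id]
    nc <- ln$counts[neg$gene_id]
    r2 <- pos_control_r2(pc, pos$concentration)
    lod_cut <- mean(nc) + thresholds$lod_sd_mult * stats::sd(nc)
    data.frame(sample_id = ln$sample_id,
               fov_counted_pct = ln$fov_counted_pct,
               binding_density = ln$binding_density,
               poslin_r2 = r2,
               lod_count = unname(pc[lod_probe]),
               lod_cutoff = lod_cut,
               fov_pass = ln$fov_counted_pct > thresholds$fov_min,
               bd_pass = ln$binding_density >= thresholds$bd_min &
                 ln$binding_density <= thresholds$bd_max,
               poslin_pass = r2 > thresholds$poslin_r2_min,
               lod_pass = unname(pc[lod_probe]) > lod_cut,
               stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  rep$overall_pass <- rep$fov_pass & rep$bd_pass & rep$poslin_pass & rep$lod_pass
  class(rep) <- c("qc_report", "data.frame")
  rep
}

#' Background threshold from pooled negative controls
#'
#' Threshold = arithmetic mean + `sd_mult` sample standard deviations of all
#' negative-control observations pooled across probes and lanes.
#'
#' @param neg_counts Numeric vector of negative-control counts (all negative
#'   probes x all lanes), length >= 2.
#' @param sd_mult SD multiplier (default 2).
#' @return The threshold, in counts.
#' @export
background_threshold <- function(neg_counts, sd_mult = 2) {
  if (length(neg_counts) < 2L)
    stop("need >= 2 negative-control observations")
  mean(neg_counts) + sd_mult * stats::sd(neg_counts)
}

#' Negative-control counts of a lane set, pooled
#'
#' @param matrix Raw `count_matrix` including controls.
#' @param ann A `probe_annotation`.
#' @return Numeric vector of all negative-control observations.
#' @export
negative_counts <- function(matrix, ann) {
  neg <- intersect(ann$gene_id[ann$code_class == "Negative"], rownames(matrix))
  if (length(neg) == 0L) stop("no negative-control probes in matrix")
  as.vector(matrix[neg, , drop = FALSE])
}

#' Background filtering by observation frequency
#'
#' A gene is removed when its count falls below the background threshold in
#' strictly more than `obs_freq` of the samples ("more than 50 percent" at
#' the default). Control probes are never filtered; the kept/removed
#' partition covers Endogenous and Housekeeping probes.
#'
#' @param matrix Raw `count_matrix`.
#' @param ann A `probe_annotation`.
#' @param threshold Background threshold in counts (e.g. from
#'   [background_threshold()]).
#' @param obs_freq Fraction of samples that must fall below threshold before
#'   a gene is removed (strict inequality; default 0.5).
#' @return A `background_filter` list: `threshold`, `obs_freq`, `kept`,
#'   `removed`.
#' @export
filter_background <- function(matrix, ann, threshold, obs_freq = 0.5) {
  if (!identical(cm_scale(matrix), "raw"))
    stop("background filtering applies to raw counts")
  target <- intersect(ann$gene_id[ann$code_class %in%
                                    c("Endogenous", "Housekeeping")],
                      rownames(matrix))
  below <- rowMeans(matrix[target, , drop = FALSE] < threshold)
  removed <- target[below > obs_freq]
  structure(list(threshold = threshold, obs_freq = obs_freq,
                 kept = setdiff(target, removed), removed = removed),
            class = "background_filter")
}

#' geNorm housekeeping-gene selection
#'
#' Ranks housekeeping candidates by the geNorm stability measure: for genes
#' j and k, V_jk is the standard deviation over samples of the pairwise
#' log2 expression ratio, and M_j is the mean of V_jk over all other
#' candidates. The least stable gene (largest M) is removed and M recomputed
#' until `n_select` candidates remain. Ties break by gene name
#' (lexicographically later name removed first among ties is avoided by
#' removing the lexicographically first of the tied maxima).
#'
#' @param hk_matrix Raw `count_matrix` (or plain matrix) restricted to the
#'   housekeeping candidates; all counts must be positive unless
#'   `offset > 0`.
#' @param n_select Number of housekeepers to retain.
#' @param offset Added to counts before logs when zeros are present
#'   (default 0.5; set to 0 to forbid zeros).
#' @return A `genorm_result`: `stability` (final M per selected gene),
#'   `selected` (gene names, most stable first), `removal_order`, and
#'   `m_history` (M values at each elimination round).
#' @export
genorm_select <- function(hk_matrix, n_select, offset = 0.5) {
  x <- unclass(hk_matrix)
  if (nrow(x) < n_select) stop("fewer candidates than n_select")
  if (any(x <= 0)) {
    if (offset <= 0) stop("zero counts present and offset disabled")
    x <- x + offset
  }
  lx <- log2(x)
  genorm_m <- function(lmat) {
    g <- nrow(lmat)
    m <- numeric(g)
    for (j in seq_len(g)) {
      v <- vapply(seq_len(g)[-j],
                  function(k) stats::sd(lmat[j, ] - lmat[k, ]), 0)
      m[j] <- mean(v)
    }
    stats::setNames(m, rownames(lmat))
  }
  removal <- character()
  history <- list()
  cur <- lx
  while (nrow(cur) > n_select) {
    m <- genorm_m(cur)
    history[[length(history) + 1L]] <- m
    worst <- names(m)[m == max(m)]
    worst <- sort(worst)[1L]              # tie-break: lexicographic
    removal <- c(removal, worst)
    cur <- cur[setdiff(rownames(cur), worst), , drop = FALSE]
  }
  m_final <- genorm_m(cur)
  structure(list(stability = m_final,
                 selected = names(sort(m_final)),
                 removal_order = removal,
                 m_history = history),
            class = "genorm_result")
}

#' Normalize lanes to a log2 expression matrix
#'
#' Optional positive-control scaling first: lane factor
#' `p_i = mean_i(sum of positive counts) / (sum of positive counts in lane i)`.
#' Then housekeeping scaling: with `g_i` the geometric mean of the selected
#' housekeeping genes in lane i (after positive scaling),
#' `h_i = mean_i(g_i) / g_i`. Normalized value = `raw * p_i * h_i`, returned
#' as `log2(normalized + offset)`. Positive and negative control probes are
#' excluded from the returned matrix.
#'
#' @param matrix Raw `count_matrix` including controls and housekeepers.
#' @param ann A `probe_annotation`.
#' @param genorm A `genorm_result` (its `selected` genes are used), or a
#'   character vector of housekeeping genes.
#' @param pos_norm Apply positive-control scaling first (default TRUE).
#' @param offset Added before the log2 (default 0.5); with `offset = 0`, a
#'   zero housekeeping count is an error.
#' @param keep Probe classes retained in the output (default Endogenous and
#'   Housekeeping).
#' @return A log2-scale `count_matrix` with attributes `pos_factors` and
#'   `hk_factors` (the per-lane scaling factors).
#' @export
normalize_lanes <- function(matrix, ann, genorm, pos_norm = TRUE,
                            offset = 0.5,
                            keep = c("Endogenous", "Housekeeping")) {
  if (!identical(cm_scale(matrix), "raw"))
    stop("normalization starts from raw counts")
  hk <- if (inherits(genorm, "genorm_result")) genorm$selected else genorm
  miss <- setdiff(hk, rownames(matrix))
  if (length(miss))
    stop("housekeeping genes missing from matrix: ", paste(miss, collapse = ", "))
  x <- unclass(matrix) * 1.0

  p <- rep(1, ncol(x))
  if (pos_norm) {
    posg <- intersect(ann$gene_id[ann$code_class == "Positive"], rownames(x))
    if (length(posg) == 0L) stop("pos_norm requested but no positive probes")
    pos_sum <- colSums(x[posg, , drop = FALSE])
    if (any(pos_sum == 0)) stop("lane with zero total positive counts")
    p <- mean(pos_sum) / pos_sum
    x <- sweep(x, 2L, p, `*`)
  }

  hk_x <- x[hk, , drop = FALSE]
  if (any(hk_x == 0)) {
    if (offset <= 0)
      stop("housekeeping gene with zero count and offset disabled")
    hk_x <- hk_x + offset
  }
  g <- exp(colMeans(log(hk_x)))
  h <- mean(g) / g
  x <- sweep(x, 2L, h, `*`)

  keep_genes <- intersect(rownames(x), ann$gene_id[ann$code_class %in% keep])
  out <- count_matrix(log2(x[keep_genes, , drop = FALSE] + offset),
                      scale = "log2")
  attr(out, "pos_factors") <- stats::setNames(p, colnames(x))
  attr(out, "hk_factors") <- stats::setNames(h, colnames(x))
  out
}
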