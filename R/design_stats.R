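# 2x2 factorial ANOVA with interaction and Fisher's (protected) least
# significant difference pairwise comparisons, applied to per-sample scores.

#' Two-way 2x2 factorial ANOVA
#'
#' Fits `score ~ APP * Arg1`. On a balanced layout sequential (type I) sums
#' of squares are used (identical to type III under balance); unbalanced
#' input falls back to type III sums of squares (sum-to-zero contrasts) with
#' a warning. F statistics test each effect against the residual mean
#' square with df = n - 4.
#'
#' @param values Named numeric vector of per-sample scores (names are sample
#'   ids) or unnamed vector aligned with `design`.
#' @param design A `design_table`.
#' @return An `anova_2x2` list: `F_A`, `F_B`, `F_AB`, `p_A`, `p_B`, `p_AB`,
#'   `df` (effect and residual), `mse`, `ss` (all components incl. total),
#'   `cell_means`, `group_n`, `omnibus_p` (overall model F test), and the
#'   data used.
#' @export
anova_2x2 <- function(values, design) {
  d <- align_scores(values, design)
  tab <- table(d$APP, d$Arg1)
  if (any(tab == 0L)) stop("empty cell in the 2x2 design")
  n <- nrow(d)
  if (n - 4L <= 0L) stop("no residual degrees of freedom (n <= 4)")
  balanced <- length(unique(as.vector(tab))) == 1L
  if (balanced) {
    fit <- stats::aov(y ~ APP * Arg1, data = d)
    sm <- summary(fit)[[1L]]
    ss <- sm[["Sum Sq"]]
    eff <- rownames(sm)
    get <- function(nm, col) sm[[col]][trimws(eff) == nm]
    F_A <- get("APP", "F value"); F_B <- get("Arg1", "F value")
    F_AB <- get("APP:Arg1", "F value")
    p_A <- get("APP", "Pr(>F)"); p_B <- get("Arg1", "Pr(>F)")
    p_AB <- get("APP:Arg1", "Pr(>F)")
    mse <- get("Residuals", "Mean Sq")
    ss_out <- c(A = get("APP", "Sum Sq"), B = get("Arg1", "Sum Sq"),
                AB = get("APP:Arg1", "Sum Sq"),
                residual = get("Residuals", "Sum Sq"))
  } else {
    warning("unbalanced 2x2 design: using type III sums of squares")
    op <- options(contrasts = c("contr.sum", "contr.poly"))
    on.exit(options(op))
    fit <- stats::lm(y ~ APP * Arg1, data = d)
    dr <- stats::drop1(fit, scope = ~ APP + Arg1 + APP:Arg1, test = "F")
    mse <- sum(stats::residuals(fit)^2) / fit$df.residual
    F_A <- dr["APP", "F value"]; F_B <- dr["Arg1", "F value"]
    F_AB <- dr["APP:Arg1", "F value"]
    p_A <- dr["APP", "Pr(>F)"]; p_B <- dr["Arg1", "Pr(>F)"]
    p_AB <- dr["APP:Arg1", "Pr(>F)"]
    ss_out <- c(A = dr["APP", "Sum of Sq"], B = dr["Arg1", "Sum of Sq"],
                AB = dr["APP:Arg1", "Sum of Sq"],
                residual = sum(stats::residuals(fit)^2))
  }
  ss_total <- sum((d$y - mean(d$y))^2)
  # omnibus: overall model F (all three effects jointly)
  ss_model <- ss_total - ss_out[["residual"]]
  F_omni <- (ss_model / 3) / mse
  omnibus_p <- stats::pf(F_omni, 3, n - 4L, lower.tail = FALSE)
  cell_means <- tapply(d$y, d$group, mean)
  structure(list(F_A = F_A, F_B = F_B, F_AB = F_AB,
                 p_A = p_A, p_B = p_B, p_AB = p_AB,
                 df = c(effect = 1L, residual = n - 4L),
                 mse = mse,
                 ss = c(ss_out, total = ss_total),
                 cell_means = cell_means,
                 group_n = table(d$group),
                 omnibus_p = omnibus_p,
                 balanced = balanced,
                 data = d),
            class = "anova_2x2")
}

align_scores <- function(values, design) {
  d <- as.data.frame(design)
  if (!is.null(names(values))) {
    idx <- match(d$sample_id, names(values))
    if (anyNA(idx)) stop("scores missing for samples: ",
                         paste(d$sample_id[is.na(idx)], collapse = ", "))
    d$y <- as.numeric(values[idx])
  } else {
    stopifnot(length(values) == nrow(d))
    d$y <- as.numeric(values)
  }
  d
}

#' Fisher's PLSD pairwise comparisons
#'
#' For each requested group pair, `t = (mean1 - mean2) /
#' sqrt(mse * (1/n1 + 1/n2))` with the ANOVA residual mean square and
#' df = n - 4; two-sided p. Comparisons are reported regardless of the
#' omnibus test (the protected-LSD convention is surfaced as a flag:
#' `protected` is `FALSE` when the omnibus model p >= 0.05).
#'
#' @param values,design As in [anova_2x2()]; ignored when `anova` is given.
#' @param comparisons List of 2-element character vectors of group labels
#'   (`<APP>.<Arg1>`).
#' @param anova Optional precomputed [anova_2x2()] result on the same data.
#' @return A data.frame: `group1`, `group2`, `mean_diff`, `t`, `df`, `p`,
#'   `protected`.
#' @export
plsd_pairwise <- function(values = NULL, design = NULL, comparisons,
                          anova = NULL) {
  if (is.null(anova)) anova <- anova_2x2(values, design)
  d <- anova$data
  groups <- names(anova$cell_means)
  rows <- lapply(comparisons, function(cmp) {
    stopifnot(length(cmp) == 2L)
    unknown <- setdiff(cmp, groups)
    if (length(unknown))
      stop("unknown group(s): ", paste(unknown, collapse = ", "))
    n1 <- sum(d$group == cmp[1L]); n2 <- sum(d$group == cmp[2L])
    diff <- anova$cell_means[[cmp[1L]]] - anova$cell_means[[cmp[2L]]]
    t <- diff / sqrt(anova$mse * (1 / n1 + 1 / n2))
    data.frame(group1 = cmp[1L], group2 = cmp[2L], mean_diff = diff,
               t = t, df = anova$df[["residual"]],
               p = 2 * stats::pt(abs(t), anova$df[["residual"]],
                                 lower.tail = FALSE),
               protected = anova$omnibus_p < 0.05,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Score-table ANOVA across rows
#'
#' Runs [anova_2x2()] and the two focused PLSD comparisons on every row of a
#' score table (pathways, cell types or signatures by samples).
#'
#' @param score_table Numeric matrix, scores in rows, samples in columns.
#' @param design A `design_table`.
#' @param comparisons List of group pairs for [plsd_pairwise()]; default the
#'   two focused comparisons (APP effect in Arg1-sufficient mice; Arg1
#'   effect in APP mice).
#' @return Data frame with one row per (score row, comparison) carrying the
#'   ANOVA effect p-values and the pairwise PLSD results.
#' @export
score_anova <- function(score_table, design,
                        comparisons = list(
                          c("APP.Arg1_suff", "nTg.Arg1_suff"),
                          c("APP.Arg1_insuff", "APP.Arg1_suff"))) {
  rows <- lapply(rownames(score_table), function(nm) {
    an <- anova_2x2(score_table[nm, ], design)
    pw <- plsd_pairwise(comparisons = comparisons, anova = an)
    cbind(score = nm, p_APP = an$p_A, p_Arg1 = an$p_B, p_int = an$p_AB, pw,
          stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
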