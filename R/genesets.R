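# Curation and scoring of the seven amyloid-associated glial transcriptomic
# signatures, their overlap decomposition, and the composite signature score.

#' The shipped glial signature bundle
#'
#' Seven amyloid-associated glial transcriptomic signatures restricted to the
#' panel: plaque-induced genes (PIGs, 17), plaque-correlated oligodendrocyte
#' genes (OLIGs, 30), disease-associated microglia (DAM, 15), homeostatic
#' microglia (HM, 9), microglial neurodegenerative phenotype (MGnD, 20),
#' tolerogenic microglia (M0, 25) and disease-associated astrocytes (DAA, 15).
#'
#' The 17 PIGs members are the published panel-overlap list. The other six
#' lists are synthetic stand-ins of the published sizes, assembled from
#' characteristic literature genes; rebuild them from the original studies'
#' ranked supplementary tables with [curate_signature()] when those are
#' available.
#'
#' @return Named list of seven `gene_set` objects.
#' @export
default_signatures <- function() {
  defs <- list(
    PIGs = list(
      genes = c("Apoe", "Trem2", "C4a", "Cd9", "Grn", "Gusb", "Npc2",
                "C1qa", "C1qb", "C1qc", "Csf1r", "Cx3cr1", "Hexb", "Fcrls",
                "Clu", "Gfap", "Man2b1"),
      theme = "plaque-induced genes",
      provenance = "published 17-gene panel overlap"),
    OLIGs = list(
      genes = c("Mog", "Mag", "Mbp", "Plp1", "Mobp", "Cnp", "Mal", "Opalin",
                "Cldn11", "Sox10", "Olig1", "Olig2", "Gal3st1", "Ugt8a",
                "Fa2h", "Pllp", "Plxnb3", "Aspa", "Trf", "Car2", "Qdpr",
                "Gjb1", "Gjc2", "Ermn", "Sirt2", "Tppp", "Tppp3", "Plekhb1",
                "Gpr37", "Cryab"),
      theme = "plaque-correlated oligodendrocyte genes",
      provenance = "synthetic stand-in, published size 30"),
    DAM = list(
      genes = c("Apoe", "Trem2", "Cd9", "Gusb", "Cst7", "Lpl", "Itgax",
                "Clec7a", "Axl", "Ctsb", "Ctsd", "Ctsl", "Tyrobp", "Timp2",
                "Cd63"),
      theme = "disease-associated microglia",
      provenance = "synthetic stand-in, published size 15"),
    HM = list(
      genes = c("Cx3cr1", "Hexb", "Fcrls", "Csf1r", "P2ry12", "Tmem119",
                "Olfml3", "Siglech", "Sall1"),
      theme = "homeostatic microglia",
      provenance = "synthetic stand-in, published size 9"),
    MGnD = list(
      genes = c("Apoe", "C4a", "Grn", "Npc2", "Axl", "Clec7a", "Itgax",
                "Lgals3", "Cybb", "Spp1", "Gpnmb", "Fabp5", "Lyz2", "Msr1",
                "Ccl2", "Csf1", "Cd74", "B2m", "Cd52", "Lag3"),
      theme = "microglial neurodegenerative phenotype",
      provenance = "synthetic stand-in, published size 20"),
    M0 = list(
      genes = c("C1qa", "C1qb", "C1qc", "Gpr34", "Selplg", "Mafb", "Mef2a",
                "Jun", "Junb", "Fos", "Egr1", "Klf2", "Klf4", "Tgfbr1",
                "Tgfb1", "Sparc", "P2ry13", "Entpd1", "Adgrg1", "Ltc4s",
                "Fcgr1", "Marcks", "Rhob", "Cd164", "Serinc3"),
      theme = "tolerogenic microglia",
      provenance = "synthetic stand-in, published size 25"),
    DAA = list(
      genes = c("Clu", "Gfap", "Aqp4", "Vim", "Serpina3n", "Cstb", "Osmr",
                "Gsn", "Mt1", "Mt2", "Id3", "Fxyd1", "Ckb", "Prdx6",
                "Sparcl1"),
      theme = "disease-associated astrocytes",
      provenance = "synthetic stand-in, published size 15"))
  out <- lapply(names(defs), function(nm)
    gene_set(nm, defs[[nm]]$genes, theme = defs[[nm]]$theme,
             provenance = defs[[nm]]$provenance))
  stats::setNames(out, names(defs))
}

#' Construct a ranked reference list for signature curation
#'
#' A reference list is the ranked gene table of a published signature:
#' genes with an ordering statistic, either `-log10(p)` or `log2` fold
#' change, and a regulation direction.
#'
#' @param gene Character vector of gene symbols (rank order of the source).
#' @param stat Numeric statistic per gene.
#' @param stat_kind `"neglog10_p"` or `"log2_fc"`.
#' @param direction `"up"` or `"down"` (regulation direction of the list).
#' @return A `ranked_reference` data.frame.
#' @export
ranked_reference <- function(gene, stat,
                             stat_kind = c("neglog10_p", "log2_fc"),
                             direction = c("up", "down")) {
  stat_kind <- match.arg(stat_kind)
  direction <- match.arg(direction)
  stopifnot(length(gene) == length(stat))
  structure(data.frame(gene = as.character(gene), stat = as.numeric(stat),
                       stringsAsFactors = FALSE),
            stat_kind = stat_kind, direction = direction,
            class = c("ranked_reference", "data.frame"))
}

#' Curate a panel signature from a ranked reference list
#'
#' Applies the published curation rule: keep reference genes passing the
#' statistic cutoff in the stated direction, then intersect with the panel's
#' measured genes, preserving reference order. For `-log10(p)` statistics the
#' cutoff is always a lower bound; for `log2` fold change it is a lower bound
#' for up-regulated lists and an upper bound for down-regulated lists.
#'
#' @param ref A `ranked_reference`.
#' @param cutoff Statistic threshold, on the scale of `ref`'s `stat_kind`.
#' @param panel_genes Character vector of panel gene identifiers.
#' @param stat_kind Expected statistic kind; must match `ref` (guards against
#'   applying a p-value cutoff to a fold-change list).
#' @param name Name for the curated set.
#' @return A `gene_set` (possibly empty `genes`, with a warning).
#' @export
curate_signature <- function(ref, cutoff, panel_genes,
                             stat_kind = attr(ref, "stat_kind"),
                             name = "curated") {
  if (!identical(stat_kind, attr(ref, "stat_kind")))
    stop("stat_kind mismatch: reference is ", attr(ref, "stat_kind"),
         ", cutoff given for ", stat_kind)
  if (length(panel_genes) == 0L) stop("panel_genes must be non-empty")
  keep <- if (identical(attr(ref, "stat_kind"), "log2_fc") &&
              identical(attr(ref, "direction"), "down")) {
    ref$stat <= cutoff
  } else {
    ref$stat >= cutoff
  }
  genes <- ref$gene[keep]
  genes <- genes[genes %in% panel_genes]
  if (length(genes) == 0L) {
    warning("curated signature '", name, "' has no panel genes")
    out <- structure(list(name = name, genes = character(),
                          theme = "", provenance = "curated"),
                     class = "gene_set")
    return(out)
  }
  gene_set(name, genes, provenance = sprintf(
    "curated: %s %s %.4g, %d/%d reference genes on panel",
    attr(ref, "stat_kind"),
    if (identical(attr(ref, "direction"), "down") &&
        identical(attr(ref, "stat_kind"), "log2_fc")) "<=" else ">=",
    cutoff, length(genes), nrow(ref)))
}

#' Overlap decomposition of a signature against named set groups
#'
#' Classifies every gene of `base` into the first group (in the given order)
#' that contains it; unclassified genes fall into `"others"`. Percentages are
#' rounded to integers with largest-remainder reconciliation so they total
#' 100.
#'
#' @param base A `gene_set` to decompose.
#' @param partitions Named list of `gene_set` objects or character vectors;
#'   order defines assignment precedence.
#' @return A data.frame with columns `group`, `n`, `percent`, `genes`
#'   (comma-separated members).
#' @export
signature_overlap <- function(base, partitions) {
  genes <- if (inherits(base, "gene_set")) base$genes else as.character(base)
  if (length(genes) == 0L) stop("empty base gene set")
  part_genes <- lapply(partitions, function(p)
    if (inherits(p, "gene_set")) p$genes else as.character(p))
  assigned <- rep(NA_character_, length(genes))
  for (nm in names(part_genes)) {
    hit <- is.na(assigned) & genes %in% part_genes[[nm]]
    assigned[hit] <- nm
  }
  assigned[is.na(assigned)] <- "others"
  groups <- c(names(part_genes), "others")
  n <- vapply(groups, function(g) sum(assigned == g), 0L)
  pct <- largest_remainder_percent(n)
  data.frame(group = groups, n = n,
             percent = pct,
             genes = vapply(groups, function(g)
               paste(genes[assigned == g], collapse = ","), ""),
             row.names = NULL, stringsAsFactors = FALSE)
}

# integer percentages summing to 100 (largest remainder method)
largest_remainder_percent <- function(n) {
  if (sum(n) == 0L) return(rep(0, length(n)))
  exact <- 100 * n / sum(n)
  fl <- floor(exact)
  rem <- 100L - sum(fl)
  order_rem <- order(exact - fl, decreasing = TRUE)
  add <- integer(length(n))
  if (rem > 0L) add[order_rem[seq_len(rem)]] <- 1L
  as.integer(fl + add)
}

#' Composite amyloid-associated glial signature score
#'
#' The per-sample composite is the unweighted arithmetic mean of the seven
#' glial signatures' pathway scores.
#'
#' @param signature_scores Numeric matrix, signatures in rows (rownames must
#'   cover the seven default signature names), samples in columns; or any
#'   named list of equal-length per-sample score vectors.
#' @param required Signature names that must all be present.
#' @return Named numeric vector: composite score per sample.
#' @export
composite_signature_score <- function(signature_scores,
                                      required = names(default_signatures())) {
  if (is.list(signature_scores) && !is.data.frame(signature_scores))
    signature_scores <- do.call(rbind, signature_scores)
  miss <- setdiff(required, rownames(signature_scores))
  if (length(miss))
    stop("missing signature score(s): ", paste(miss, collapse = ", "))
  colMeans(signature_scores[required, , drop = FALSE])
}
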