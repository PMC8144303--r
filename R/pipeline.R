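# End-to-end pipeline driver: simulate or read lanes, QC, normalize, then
# differential expression, pathway scores, gene-set GSS, cell-type
# profiling, glial signature scoring and the factorial ANOVA, with stage
# TSV outputs and a JSON run manifest.

#' Run the full panel analysis pipeline
#'
#' Executes the stages in dependency order and writes one TSV per stage
#' plus a `manifest.json` recording package version, seed, parameters and
#' input digests. Re-running with identical inputs and seed reproduces
#' identical outputs.
#'
#' @param out_dir Output directory (created if missing).
#' @param rcc_dir Directory of RCC lane files; when `NULL`, lanes are
#'   simulated from `config`.
#' @param design_path TSV design table; required with `rcc_dir`.
#' @param config A [sim_config()] used when simulating.
#' @param ann A `probe_annotation` (default [default_panel()]).
#' @param thresholds A [qc_thresholds()].
#' @param n_hk Number of housekeepers selected by geNorm (default 6).
#' @param contrasts Named list of group contrasts for differential
#'   expression; defaults to the two focused comparisons.
#' @param gss_cutoff Directed-GSS significance cutoff (default 1.3).
#' @param n_random Random sets for the cell-type QC null (default 999).
#' @param strict_qc Abort when a lane fails system QC (default FALSE:
#'   warn only).
#' @param seed Seed for stages with randomness (cell-type QC; simulation
#'   uses `config$seed`).
#' @return Invisibly, a list with all stage results and `out_dir`.
#' @export
run_pipeline <- function(out_dir,
                         rcc_dir = NULL, design_path = NULL,
                         config = sim_config(),
                         ann = NULL,
                         thresholds = qc_thresholds(),
                         n_hk = 6L,
                         contrasts = list(
                           APP_effect = c("APP.Arg1_suff", "nTg.Arg1_suff"),
                           Arg1_effect = c("APP.Arg1_insuff", "APP.Arg1_suff")),
                         gss_cutoff = 1.3,
                         n_random = 999L,
                         strict_qc = FALSE,
                         seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    message("[", name, "] ", appendLF = FALSE)
    t0 <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
    message(sprintf("done (%.2fs)", as.numeric(Sys.time() - t0, units = "secs")))
    out
  }

  input_digests <- character()
  if (is.null(rcc_dir)) {
    sim <- stage("simulate", simulate_panel(config, ann = ann))
    lanes <- sim$lanes; design <- sim$design; ann <- sim$ann
    write_design(design, file.path(out_dir, "design.tsv"))
    truth_df <- data.frame(gene = rownames(sim$truth$log2fc),
                           sim$truth$log2fc, row.names = NULL)
    utils::write.table(truth_df, file.path(out_dir, "truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    if (is.null(design_path)) stop("design_path is required with rcc_dir")
    if (!file.exists(design_path))
      stop("design file not found: ", design_path)
    files <- sort(list.files(rcc_dir, pattern = "\\.[Rr][Cc][Cc]$",
                             full.names = TRUE))
    if (!length(files)) stop("no RCC files in ", rcc_dir)
    lanes <- stage("read", lapply(files, read_rcc))
    design <- read_design(design_path)
    if (is.null(ann)) ann <- default_panel()
    input_digests <- tools::md5sum(c(files, design_path))
  }

  raw <- stage("assemble", assemble_matrix(lanes))
  validate_design(raw, design)

  qc <- stage("qc", lane_qc(lanes, ann, thresholds))
  utils::write.table(qc, file.path(out_dir, "qc_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!all(qc$overall_pass)) {
    msg <- paste("lanes failing system QC:",
                 paste(qc$sample_id[!qc$overall_pass], collapse = ", "))
    if (strict_qc) stop(msg) else warning(msg)
  }

  norm <- stage("normalize", {
    thr <- background_threshold(negative_counts(raw, ann))
    bf <- filter_background(raw, ann, thr)
    hk <- intersect(ann$gene_id[ann$code_class == "Housekeeping"],
                    rownames(raw))
    gn <- genorm_select(raw[hk, , drop = FALSE], n_select = n_hk)
    mat <- normalize_lanes(raw, ann, gn)
    mat <- count_matrix(unclass(mat)[intersect(rownames(mat), bf$kept), ,
                                     drop = FALSE], scale = "log2")
    list(matrix = mat, genorm = gn, filter = bf, threshold = thr)
  })
  write_count_matrix(norm$matrix, file.path(out_dir, "normalized_log2.tsv"))
  utils::write.table(
    data.frame(gene = names(norm$genorm$stability),
               stability_m = norm$genorm$stability, row.names = NULL),
    file.path(out_dir, "genorm.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)

  endo_genes <- intersect(rownames(norm$matrix),
                          ann$gene_id[ann$code_class == "Endogenous"])
  expr <- count_matrix(unclass(norm$matrix)[endo_genes, , drop = FALSE],
                       scale = "log2")

  de <- stage("de", lapply(contrasts, function(ct)
    de_test(expr, design, ct)))
  for (nm in names(de))
    utils::write.table(de[[nm]], file.path(out_dir, paste0("de_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  sets <- pathway_gene_sets(ann)
  psa <- stage("score-pathways", pathway_scores(expr, sets))
  utils::write.table(data.frame(pathway = rownames(psa),
                                unclass(psa), row.names = NULL,
                                check.names = FALSE),
                     file.path(out_dir, "pathway_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  gsa <- stage("gsa", gss_table(expr, design, sets, cutoff = gss_cutoff))
  utils::write.table(gsa, file.path(out_dir, "gss.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  ct_prof <- stage("celltype", celltype_profile(expr, celltype_gene_sets(ann),
                                                n_random = n_random,
                                                seed = seed))
  utils::write.table(ct_prof$qc, file.path(out_dir, "celltype_qc.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(celltype = rownames(ct_prof$scores),
                                ct_prof$scores, row.names = NULL,
                                check.names = FALSE),
                     file.path(out_dir, "celltype_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  sig <- stage("signatures", {
    sig_scores <- pathway_scores(expr, default_signatures(), min_genes = 2L)
    comp <- composite_signature_score(unclass(sig_scores))
    list(scores = sig_scores, composite = comp)
  })
  utils::write.table(data.frame(signature = c(rownames(sig$scores),
                                              "composite"),
                                rbind(unclass(sig$scores), sig$composite),
                                row.names = NULL, check.names = FALSE),
                     file.path(out_dir, "signature_scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  anova <- stage("anova", {
    tabs <- rbind(unclass(psa), unclass(sig$scores), ct_prof$scores)
    score_anova(tabs, design)
  })
  utils::write.table(anova, file.path(out_dir, "anova.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  manifest <- list(
    tool = "gliapanel",
    version = as.character(utils::packageVersion("gliapanel")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    simulated = is.null(rcc_dir),
    sim_seed = if (is.null(rcc_dir)) config$seed else NULL,
    input_digests = as.list(input_digests),
    parameters = list(n_hk = n_hk, gss_cutoff = gss_cutoff,
                      n_random = n_random,
                      thresholds = unclass(thresholds)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  invisible(list(out_dir = out_dir, qc = qc, norm = norm, de = de,
                 pathway_scores = psa, gss = gsa, celltype = ct_prof,
                 signatures = sig, anova = anova, design = design,
                 ann = ann, raw = raw, expr = expr))
}
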