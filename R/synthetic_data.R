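# Simulator for RCC-style lane data emulating a 770-gene neuropathology
# panel run: 12 lanes in four groups of three crossing an APP transgene
# factor with an Arg1 haploinsufficiency factor, negative-binomial
# endogenous counts with lane-level scale noise, Poisson control probes on a
# six-point titration, and pathway-level spiked effects with ground truth.

#' Default spiked-effect template
#'
#' Qualitative mirror of the study's biology: the APP factor drives
#' inflammation / AD-risk / autophagy pathways (log2FC 0.5-1.0), the Arg1
#' factor drives myelination and lipid metabolism with smaller effects
#' (0.3-0.4). Purely for test realism, not a claim of quantitative fidelity.
#'
#' @return List of effect specifications (`set`, `factor`, `log2fc`).
#' @export
default_sim_effects <- function() {
  list(list(set = "Activated Microglia", factor = "APP", log2fc = 1.0),
       list(set = "AD Causal Risk Pathway", factor = "APP", log2fc = 1.0),
       list(set = "Autophagy", factor = "APP", log2fc = 0.5),
       list(set = "Myelination", factor = "Arg1", log2fc = 0.4),
       list(set = "Lipid Metabolism", factor = "Arg1", log2fc = 0.3))
}

#' Simulation configuration
#'
#' @param n_genes Endogenous panel size (default 770).
#' @param n_per_cell Lanes per factorial cell (default 3; 12 lanes total).
#' @param baseline_log2_mean_range Range of per-gene baseline log2 mean
#'   counts, drawn uniformly (default c(2, 11): counts ~4 to ~2000, leaving
#'   a realistic fraction of probes under the negative-control background).
#' @param dispersion Negative-binomial size parameter for biological counts
#'   (default 20).
#' @param lane_scale_sd SD (log2 units) of the per-lane global scale factor
#'   (default 0.15).
#' @param effects List of spiked effects (`set` = pathway name or gene
#'   vector, `factor` = `"APP"`/`"Arg1"`, `log2fc`); default
#'   [default_sim_effects()].
#' @param hk_stability_sd SD (log2 units) of per-lane housekeeping
#'   deviations (default 0.05); may be a vector over the housekeeping
#'   candidates to include unstable decoys.
#' @param hk_baseline_log2_range Baseline range for housekeepers (default
#'   c(9, 11): well-expressed).
#' @param neg_mean Poisson mean of negative-control probes (default 5;
#'   pooled mean + 2 SD then sits near the published background of 10).
#' @param pos_scale Positive-control counts per fM (default 200; the 0.5 fM
#'   LOD probe then averages 100 counts).
#' @param pos_titration Named fM concentrations of the positive titration.
#' @param seed Root RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_genes = 770L, n_per_cell = 3L,
                       baseline_log2_mean_range = c(2, 11),
                       dispersion = 20,
                       lane_scale_sd = 0.15,
                       effects = default_sim_effects(),
                       hk_stability_sd = 0.05,
                       hk_baseline_log2_range = c(9, 11),
                       neg_mean = 5,
                       pos_scale = 200,
                       pos_titration = panel_pos_titration,
                       seed = 1L) {
  stopifnot(n_genes > 0, n_per_cell > 0, dispersion > 0, neg_mean > 0,
            pos_scale > 0, all(pos_titration > 0))
  structure(list(n_genes = as.integer(n_genes),
                 n_per_cell = as.integer(n_per_cell),
                 baseline_log2_mean_range = baseline_log2_mean_range,
                 dispersion = dispersion, lane_scale_sd = lane_scale_sd,
                 effects = effects, hk_stability_sd = hk_stability_sd,
                 hk_baseline_log2_range = hk_baseline_log2_range,
                 neg_mean = neg_mean, pos_scale = pos_scale,
                 pos_titration = pos_titration, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate a full panel run
#'
#' Generates lanes under the 2x2 design. Per endogenous gene g and lane i
#' the mean is `2^(b_g + sum(effects) + s_i)` and the count is negative
#' binomial with size `dispersion`; housekeepers replace the effect term by
#' a small per-lane stability deviation; negative controls are Poisson at
#' `neg_mean * 2^s_i`; positive controls are Poisson at
#' `pos_scale * concentration * 2^s_i`. One root seed drives gene-level
#' draws and spawns one sub-seed per lane, so lanes are reproducible and
#' independent given the seed.
#'
#' @param config A [sim_config()].
#' @param ann Optional `probe_annotation`; default [default_panel()] with
#'   `config$n_genes` endogenous probes (its control and housekeeping
#'   layout must match the config's titration).
#' @return List: `lanes` (list of `sample_lane`), `design` (a
#'   `design_table`), `truth` (per-gene true log2FC per factor, per-lane
#'   scale factors, spiked membership), `ann`.
#' @export
simulate_panel <- function(config = sim_config(), ann = NULL) {
  if (is.null(ann)) ann <- default_panel(config$n_genes)
  endo <- ann$gene_id[ann$code_class == "Endogenous"]
  hk <- ann$gene_id[ann$code_class == "Housekeeping"]
  pos <- ann[ann$code_class == "Positive", ]
  neg <- ann$gene_id[ann$code_class == "Negative"]
  sets <- pathway_gene_sets(ann)

  groups <- expand.grid(APP = c("nTg", "APP"),
                        Arg1 = c("Arg1_suff", "Arg1_insuff"),
                        stringsAsFactors = FALSE)
  design <- design_table(data.frame(
    sample_id = sprintf("S%02d", seq_len(4L * config$n_per_cell)),
    APP = rep(groups$APP, each = config$n_per_cell),
    Arg1 = rep(groups$Arg1, each = config$n_per_cell),
    sex = rep_len(c("M", "F"), 4L * config$n_per_cell),
    pool_size = 2L, stringsAsFactors = FALSE))
  n_lanes <- nrow(design)

  # true per-gene effects
  fc <- matrix(0, length(endo), 2L, dimnames = list(endo, c("APP", "Arg1")))
  spiked <- list()
  for (ef in config$effects) {
    genes <- if (length(ef$set) == 1L && ef$set %in% names(sets))
      sets[[ef$set]]$genes else as.character(ef$set)
    unknown <- setdiff(genes, endo)
    if (length(unknown))
      stop("effect references unknown gene(s): ",
           paste(utils::head(unknown, 5L), collapse = ", "))
    fc[genes, ef$factor] <- fc[genes, ef$factor] + ef$log2fc
    spiked[[length(spiked) + 1L]] <- list(
      set = if (length(ef$set) == 1L) ef$set else "custom",
      factor = ef$factor, log2fc = ef$log2fc, genes = genes)
  }

  set.seed(config$seed)
  b <- stats::runif(length(endo), config$baseline_log2_mean_range[1L],
                    config$baseline_log2_mean_range[2L])
  b_hk <- stats::runif(length(hk), config$hk_baseline_log2_range[1L],
                       config$hk_baseline_log2_range[2L])
  hk_sd <- rep_len(config$hk_stability_sd, length(hk))
  s <- stats::rnorm(n_lanes, 0, config$lane_scale_sd)
  names(s) <- design$sample_id
  lane_seeds <- sample.int(.Machine$integer.max - 1L, n_lanes)

  x_app <- as.integer(design$APP == "APP")
  x_arg <- as.integer(design$Arg1 == "Arg1_insuff")

  lanes <- vector("list", n_lanes)
  for (i in seq_len(n_lanes)) {
    set.seed(lane_seeds[i])
    mu_endo <- 2^(b + fc[, "APP"] * x_app[i] + fc[, "Arg1"] * x_arg[i] + s[i])
    c_endo <- stats::rnbinom(length(endo), mu = mu_endo,
                             size = config$dispersion)
    dev <- stats::rnorm(length(hk), 0, hk_sd)
    c_hk <- stats::rnbinom(length(hk), mu = 2^(b_hk + dev + s[i]),
                           size = config$dispersion)
    c_pos <- stats::rpois(nrow(pos),
                          config$pos_scale * pos$concentration * 2^s[i])
    c_neg <- stats::rpois(length(neg), config$neg_mean * 2^s[i])
    counts <- stats::setNames(c(c_endo, c_hk, c_pos, c_neg),
                              c(endo, hk, pos$gene_id, neg))
    lanes[[i]] <- sample_lane(
      sample_id = design$sample_id[i],
      counts = counts[ann$gene_id],
      fov_counted_pct = sample(92:100, 1L),
      binding_density = round(stats::runif(1L, 0.5, 1.8), 2L),
      group_labels = c(APP = as.character(design$APP[i]),
                       Arg1 = as.character(design$Arg1[i]),
                       sex = design$sex[i]))
  }

  list(lanes = lanes, design = design,
       truth = list(log2fc = fc, lane_scale = s, spiked = spiked,
                    baseline_log2 = stats::setNames(b, endo),
                    hk_stability_sd = stats::setNames(hk_sd, hk)),
       ann = ann)
}

#' Write a lane as an RCC file
#'
#' Emits the bracketed-section RCC dialect read by [read_rcc()]; writing
#' then re-reading reproduces the lane exactly.
#'
#' @param lane A `sample_lane`.
#' @param path Output file path.
#' @param ann Optional `probe_annotation` supplying the CodeClass column;
#'   probes absent from it are written as Endogenous.
#' @return The path, invisibly.
#' @export
write_rcc <- function(lane, path, ann = NULL) {
  cls <- rep("Endogenous", length(lane$counts))
  if (!is.null(ann)) {
    idx <- match(names(lane$counts), ann$gene_id)
    cls[!is.na(idx)] <- ann$code_class[idx[!is.na(idx)]]
  }
  sa <- c(ID = lane$sample_id, lane$group_labels)
  lines <- c(
    "<Header>",
    "FileVersion,1.7",
    "SoftwareVersion,gliapanel-sim",
    "</Header>",
    "<Sample_Attributes>",
    paste(names(sa), sa, sep = ","),
    "</Sample_Attributes>",
    "<Lane_Attributes>",
    "ID,1",
    "FovCount,100",
    paste0("FovCounted,", format(lane$fov_counted_pct, digits = 10)),
    paste0("BindingDensity,", format(lane$binding_density, digits = 10)),
    "</Lane_Attributes>",
    "<Code_Summary>",
    "CodeClass,Name,Accession,Count",
    sprintf("%s,%s,NA,%d", cls, names(lane$counts), lane$counts),
    "</Code_Summary>")
  writeLines(lines, path)
  invisible(path)
}
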