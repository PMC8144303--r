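# Shared in-code fixtures: a tiny panel annotation, hand-written RCC text,
# and small log2 matrices with known structure.

# 4 endogenous genes, 2 housekeepers, full 6-point positive titration,
# 4 negative probes
tiny_annotation <- function() {
  probe_annotation(
    gene_id = c("GeneA", "GeneB", "GeneC", "GeneD", "Hk1", "Hk2",
                paste0("POS_", LETTERS[1:6]), paste0("NEG_", LETTERS[1:4])),
    code_class = c(rep("Endogenous", 4), rep("Housekeeping", 2),
                   rep("Positive", 6), rep("Negative", 4)),
    concentration = c(rep(NA, 6), 128, 32, 8, 2, 0.5, 0.125, rep(NA, 4)),
    pathways = c(list("PathX"), list("PathX"), list("PathY"), list("PathY"),
                 rep(list(character()), 12)),
    celltypes = c(list("ctA"), list("ctA"), list(character()),
                  list(character()), rep(list(character()), 12)))
}

# lane over the tiny annotation with controllable counts
tiny_lane <- function(id = "L1", endo = c(100, 200, 50, 10),
                      hk = c(500, 600),
                      pos = round(200 * c(128, 32, 8, 2, 0.5, 0.125)),
                      neg = c(4, 5, 6, 5),
                      fov = 96, bd = 1.1) {
  ann <- tiny_annotation()
  sample_lane(id,
              stats::setNames(c(endo, hk, pos, neg), ann$gene_id),
              fov_counted_pct = fov, binding_density = bd,
              group_labels = c(APP = "nTg", Arg1 = "Arg1_suff"))
}

minimal_rcc_text <- function(counts = c(A = 5, B = 0)) {
  c("<Header>", "FileVersion,1.7", "</Header>",
    "<Sample_Attributes>", "ID,S1", "APP,nTg", "</Sample_Attributes>",
    "<Lane_Attributes>", "ID,1", "FovCount,100", "FovCounted,96",
    "BindingDensity,1.05", "</Lane_Attributes>",
    "<Code_Summary>", "CodeClass,Name,Accession,Count",
    sprintf("Endogenous,%s,NA,%s", names(counts), counts),
    "</Code_Summary>")
}

# log2 count_matrix from a plain numeric matrix
log2_cm <- function(values, genes = NULL, samples = NULL) {
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(values)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(values)))
  dimnames(values) <- list(genes, samples)
  count_matrix(values, scale = "log2")
}

# balanced 2x2 design over n_per_cell samples per cell
tiny_design <- function(n_per_cell = 3) {
  design_table(data.frame(
    sample_id = sprintf("s%d", seq_len(4 * n_per_cell)),
    APP = rep(c("nTg", "APP"), each = 2 * n_per_cell),
    Arg1 = rep(rep(c("Arg1_suff", "Arg1_insuff"), each = n_per_cell), 2),
    stringsAsFactors = FALSE))
}

# normalized log2 matrix straight from a simulated panel
simulated_log2 <- function(seed = 1, effects = list(), n_hk = 6) {
  sim <- simulate_panel(sim_config(effects = effects, seed = seed))
  raw <- assemble_matrix(sim$lanes)
  hk <- sim$ann$gene_id[sim$ann$code_class == "Housekeeping"]
  gn <- genorm_select(unclass(raw)[hk, , drop = FALSE], n_hk)
  list(matrix = normalize_lanes(raw, sim$ann, gn), sim = sim)
}

# brute-force geNorm M values: direct enumeration of pairwise log-ratio SDs
genorm_m_bruteforce <- function(mat) {
  lx <- log2(mat)
  g <- nrow(lx)
  m <- numeric(g)
  for (j in seq_len(g)) {
    vs <- c()
    for (k in seq_len(g)) {
      if (k == j) next
      vs <- c(vs, stats::sd(lx[j, ] - lx[k, ]))
    }
    m[j] <- mean(vs)
  }
  stats::setNames(m, rownames(mat))
}
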