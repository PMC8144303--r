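# Shipped default panel annotation. The true instrument panel definition
# (RLF) is proprietary and not redistributable, so the default panel is a
# synthetic stand-in: every gene named in the study design (signature members,
# pathway members, markers, housekeepers) is present under its real mouse
# symbol, and filler probes named SynG#### pad the Endogenous list to the
# panel's nominal 770 genes. Pathway membership beyond the explicitly curated
# sets is a deterministic round-robin over the filler pathways.

panel_pos_titration <- c(POS_A = 128, POS_B = 32, POS_C = 8,
                         POS_D = 2, POS_E = 0.5, POS_F = 0.125)

panel_hk_genes <- c("Aars", "Ccdc127", "Cnot10", "Csnk2a2", "Lars", "Mto1",
                    "Supt7l", "Tada2b", "Tbp", "Xpnpep1")

# curated pathway membership (real symbols; AD Causal Risk is exactly the
# 15-gene GWAS-derived list, Autophagy includes Atg5 and Becn1)
panel_curated_pathways <- list(
  "AD Causal Risk Pathway" = c("Cntnap2", "Cd33", "Psen2", "Mapt", "Psmb9",
                               "App", "Psen1", "Apoe", "Trem2", "Adam10",
                               "Psmb8", "Spi1", "Sorl1", "Clu", "C4a"),
  "Autophagy" = c("Atg5", "Becn1", "Atg3", "Atg7", "Atg12", "Map1lc3b",
                  "Sqstm1", "Lamp1", "Lamp2", "Ulk1", "Wipi2", "Ctsd",
                  "Ctsb", "Gba"),
  "Activated Microglia" = c("Trem2", "Cd68", "Itgax", "Clec7a", "Axl", "Cst7",
                            "Lpl", "Tyrobp", "Cd74", "B2m", "Lgals3", "Cybb",
                            "Spp1", "Msr1", "Ccl2", "Csf1", "C3", "C4a",
                            "Stab1", "Irf8", "Fcgr1", "Lyz2", "Gpnmb",
                            "Fabp5"),
  "Microglial Function" = c("Cx3cr1", "Hexb", "Fcrls", "Csf1r", "P2ry12",
                            "Tmem119", "Olfml3", "Siglech", "Sall1", "Gpr34",
                            "Selplg", "C1qa", "C1qb", "C1qc", "Itgam"),
  "Cytokines" = c("Il6", "Ccl2", "Csf1", "Tgfb1", "Il4ra", "Osmr", "Tgfbr1",
                  "Tgfbr2", "Fas", "Stat1", "Rela", "Il4r"),
  "Angiogenesis" = c("Flt1", "Pecam1", "Cldn5", "Emcn", "Tek", "Epha3",
                     "Slc2a1", "Vim", "Sparc"),
  "Myelination" = c("Mog", "Mag", "Mbp", "Plp1", "Mobp", "Cnp", "Mal",
                    "Cldn11", "Sox10", "Olig1", "Olig2", "Fa2h", "Pllp",
                    "Plxnb3", "Ugt8a", "Gal3st1", "Opalin", "Aspa", "Ermn",
                    "Gjc2"),
  "Lipid Metabolism" = c("Lpl", "Apoe", "Gba", "Cers4", "Npc2", "Fabp5",
                         "Ltc4s", "Prdx6", "Sorl1", "Gusb", "Man2b1"),
  "Neuronal Cytoskeleton" = c("Mapt", "Map2", "Nefl", "Tubb3", "Tppp",
                              "Tppp3", "Sirt2", "Cryab", "Stx1b", "Gnao1"),
  "Disease Association" = c("Apoe", "Trem2", "Cd33", "App", "Psen1", "Psen2",
                            "Mapt", "Snca", "Park7", "Sod1", "Grn", "Gusb",
                            "Gfap", "Serpina3n"),
  # deliberately small: mirrors a sparse matrix-remodeling annotation that
  # falls under the minimum detected-gene rule for pathway scoring
  "Matrix Remodeling" = c("Mmp9", "Mmp12", "Timp1", "Timp2")
)

panel_filler_pathways <- c(
  "Transmitter Release", "Vesicle Trafficking", "Oxidative Stress",
  "Apoptosis", "Unfolded Protein Response", "Growth Factor Signaling",
  "Carbohydrate Metabolism", "Chromatin Modification",
  "Transcription and Splicing", "Axon and Dendrite Structure",
  "Tissue Integrity", "Trophic Factors", "Neuropeptides",
  "Epigenetic Regulation")

panel_celltype_markers <- list(
  "microglia" = c("Fcrls", "Itgam", "Trem2", "Irf8", "Cd68", "Hexb",
                  "Cx3cr1"),
  "oligodendrocytes" = c("Mog", "Pllp", "Plxnb3", "Gsn", "Fa2h", "Mag"),
  "astrocytes" = c("Gfap", "Aqp4", "Slc1a3", "Aldoc", "Gja1", "Slc1a2"),
  "endothelial cells" = c("Cldn5", "Pecam1", "Flt1", "Emcn", "Tek"),
  "neurons" = c("Rbfox3", "Snap25", "Syp", "Nefl", "Map2", "Tubb3"))

# additional real symbols mentioned across the study's DEG/network tables
panel_extra_genes <- c(
  "Arg1", "Mta2", "Hmox1", "Ncl", "Lpar1", "Ache", "Casp6", "Grin2d",
  "Nos1", "U2af2", "Creb1", "Bcl2", "Calb2", "Grin1", "Mapk8", "Sirt1",
  "Akt2", "Gabrb3", "Cd9", "Cd63", "Ctsl", "Timp2", "Cd52", "Lag3",
  "Mafb", "Mef2a", "Jun", "Junb", "Fos", "Egr1", "Klf2", "Klf4", "P2ry13",
  "Entpd1", "Adgrg1", "Marcks", "Rhob", "Cd164", "Serinc3", "Cstb", "Mt1",
  "Mt2", "Id3", "Fxyd1", "Ckb", "Sparcl1", "Trf", "Car2", "Qdpr", "Gjb1",
  "Plekhb1", "Gpr37", "Gsn", "Aqp4", "Vim", "Serpina3n")

#' The shipped default panel annotation
#'
#' A 770-gene mouse neuropathology-style panel: all endogenous genes used by
#' the default pathways, signatures and cell-type marker sets under their
#' real symbols, plus synthetic filler probes (`SynG0001`, ...) padding to
#' `n_genes`; 10 housekeeping candidates; a 6-point positive-control
#' titration (128 to 0.125 fM) and 8 negative controls. The filler content
#' is a synthetic stand-in for the proprietary panel definition, not a copy
#' of it.
#'
#' @param n_genes Number of Endogenous probes (default 770).
#' @return A `probe_annotation`.
#' @export
default_panel <- function(n_genes = 770L) {
  sig <- default_signatures()
  real <- unique(c(unlist(panel_curated_pathways, use.names = FALSE),
                   unlist(panel_celltype_markers, use.names = FALSE),
                   unlist(lapply(sig, `[[`, "genes"), use.names = FALSE),
                   panel_extra_genes))
  real <- setdiff(real, panel_hk_genes)
  if (n_genes < length(real))
    stop("n_genes smaller than the curated gene list (", length(real), ")")
  n_fill <- n_genes - length(real)
  fillers <- sprintf("SynG%04d", seq_len(n_fill))
  endo <- c(real, fillers)

  pw <- stats::setNames(rep(list(character()), length(endo)), endo)
  for (p in names(panel_curated_pathways))
    for (g in panel_curated_pathways[[p]])
      pw[[g]] <- c(pw[[g]], p)
  # round-robin filler pathways over filler genes (deterministic)
  fp <- rep(panel_filler_pathways, length.out = n_fill)
  for (i in seq_len(n_fill)) pw[[fillers[i]]] <- fp[i]
  # real genes without any curated pathway also rotate through fillers
  orphan <- endo[vapply(pw, length, 0L) == 0L]
  op <- rep(panel_filler_pathways, length.out = length(orphan))
  for (i in seq_along(orphan)) pw[[orphan[i]]] <- op[i]

  ct <- stats::setNames(rep(list(character()), length(endo)), endo)
  for (type in names(panel_celltype_markers))
    for (g in panel_celltype_markers[[type]])
      ct[[g]] <- c(ct[[g]], type)

  probe_annotation(
    gene_id = c(endo, panel_hk_genes, names(panel_pos_titration),
                sprintf("NEG_%s", LETTERS[1:8])),
    code_class = c(rep("Endogenous", length(endo)),
                   rep("Housekeeping", length(panel_hk_genes)),
                   rep("Positive", length(panel_pos_titration)),
                   rep("Negative", 8L)),
    concentration = c(rep(NA_real_, length(endo) + length(panel_hk_genes)),
                      unname(panel_pos_titration), rep(NA_real_, 8L)),
    pathways = c(unname(pw),
                 rep(list(character()),
                     length(panel_hk_genes) + length(panel_pos_titration) + 8L)),
    celltypes = c(unname(ct),
                  rep(list(character()),
                      length(panel_hk_genes) + length(panel_pos_titration) + 8L)))
}
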