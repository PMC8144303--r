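test_that("read_rcc parses counts, lane attributes and group labels", {
  path <- withr::local_tempfile(fileext = ".RCC")
  writeLines(minimal_rcc_text(c(A = 5, B = 0)), path)
  lane <- read_rcc(path)
  expect_s3_class(lane, "sample_lane")
  expect_identical(lane$counts, c(A = 5L, B = 0L))
  expect_equal(lane$fov_counted_pct, 96)
  expect_equal(lane$binding_density, 1.05)
  expect_identical(lane$group_labels[["APP"]], "nTg")
})

test_that("read_rcc rejects malformed files with named errors", {
  path <- withr::local_tempfile(fileext = ".RCC")
  txt <- minimal_rcc_text(c(A = "3.5"))
  writeLines(txt, path)
  expect_error(read_rcc(path), "non-integer count '3.5'")

  writeLines(txt[!grepl("Code_Summary|CodeClass|Endogenous", txt)], path)
  expect_error(read_rcc(path), "missing Code_Summary")
})

test_that("write_rcc then read_rcc is an identity, also for all-zero lanes", {
  ann <- tiny_annotation()
  lane <- tiny_lane()
  path <- withr::local_tempfile(fileext = ".RCC")
  write_rcc(lane, path, ann = ann)
  expect_equal(read_rcc(path), lane)

  zero <- tiny_lane(endo = c(0, 0, 0, 0), hk = c(0, 0),
                    pos = rep(0, 6), neg = rep(0, 4))
  write_rcc(zero, path, ann = ann)
  expect_equal(read_rcc(path), zero)
})

test_that("RCC round-trip holds for full simulated lanes and CRLF input", {
  sim <- simulate_panel(sim_config(n_genes = 250, seed = 11))
  path <- withr::local_tempfile(fileext = ".RCC")
  write_rcc(sim$lanes[[5]], path, ann = sim$ann)
  expect_equal(read_rcc(path), sim$lanes[[5]])

  # CRLF line endings are accepted
  crlf <- gsub("\n", "\r\n", paste0(paste(readLines(path), collapse = "\n"),
                                    "\n"))
  writeBin(charToRaw(crlf), path)
  expect_equal(read_rcc(path), sim$lanes[[5]])
})

test_that("probe annotation enforces uniqueness and control contracts", {
  expect_error(probe_annotation(c("A", "A"), c("Endogenous", "Endogenous")),
               "duplicate gene_id")
  expect_error(probe_annotation("P", "Positive", concentration = NA_real_),
               "strictly positive concentration")
  expect_error(probe_annotation("N", "Negative", concentration = 2),
               "must not carry")
})

test_that("probe annotation TSV round-trips; empty file gives empty panel", {
  ann <- tiny_annotation()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_probe_annotations(ann, path)
  back <- read_probe_annotations(path)
  expect_equal(back$gene_id, ann$gene_id)
  expect_equal(back$code_class, ann$code_class)
  expect_equal(back$concentration, ann$concentration)
  expect_equal(back$pathways, ann$pathways)
  expect_equal(back$celltypes, ann$celltypes)

  writeLines("gene_id\tcode_class\tconcentration\tpathways\tcelltypes", path)
  expect_equal(nrow(read_probe_annotations(path)), 0L)
})

test_that("shipped default panel has the published structure", {
  ann <- default_panel()
  expect_equal(sum(ann$code_class == "Endogenous"), 770L)
  expect_equal(sum(ann$code_class == "Positive"), 6L)
  expect_equal(sum(ann$code_class == "Negative"), 8L)
  sets <- pathway_gene_sets(ann)
  expect_setequal(sets[["AD Causal Risk Pathway"]]$genes,
                  c("Cntnap2", "Cd33", "Psen2", "Mapt", "Psmb9", "App",
                    "Psen1", "Apoe", "Trem2", "Adam10", "Psmb8", "Spi1",
                    "Sorl1", "Clu", "C4a"))
  expect_length(sets[["AD Causal Risk Pathway"]]$genes, 15L)
  expect_true(all(c("Atg5", "Becn1") %in% sets[["Autophagy"]]$genes))
  # signature members are all on the panel
  for (s in default_signatures())
    expect_true(all(s$genes %in% ann$gene_id))
})

test_that("assemble_matrix preserves every count and rejects mismatches", {
  one <- tiny_lane()
  m1 <- assemble_matrix(list(one))
  expect_equal(dim(m1), c(16L, 1L))
  expect_equal(unname(m1[, 1]), unname(as.numeric(one$counts)))

  sim <- simulate_panel(sim_config(n_genes = 250, seed = 2))
  m <- assemble_matrix(sim$lanes)
  expect_equal(ncol(m), 12L)
  expect_equal(unname(colSums(m)),
               unname(vapply(sim$lanes, function(l) sum(l$counts), 0)))

  other <- tiny_lane("L2")
  names(other$counts)[1] <- "Elsewhere"
  expect_error(assemble_matrix(list(one, other)),
               "probe universe mismatch.*Elsewhere")
})

test_that("gene sets round-trip through GMT", {
  sets <- default_signatures()
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(sets, path)
  back <- read_gmt(path)
  expect_identical(names(back), names(sets))
  for (nm in names(sets))
    expect_identical(back[[nm]]$genes, sets[[nm]]$genes)
})

test_that("count matrices round-trip through TSV with their scale tag", {
  m <- log2_cm(matrix(rnorm(12), 4, 3))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_matrix(m, path)
  back <- read_count_matrix(path)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-12)
  expect_identical(attr(back, "scale"), "log2")
})

test_that("design table validates levels and covers matrices", {
  d <- tiny_design()
  expect_s3_class(d, "design_table")
  expect_identical(d$group[1], "nTg.Arg1_suff")
  expect_error(design_table(data.frame(sample_id = "s", APP = "bad",
                                       Arg1 = "Arg1_suff")),
               "APP column")
  m <- log2_cm(matrix(0, 2, 2), samples = c("s1", "zz"))
  expect_error(validate_design(m, d), "missing from design.*zz")
})
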