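test_that("lane_qc applies the four system QC rules", {
  ann <- tiny_annotation()
  good <- tiny_lane("ok", neg = c(5, 5, 5, 5), fov = 100, bd = 1.0)
  rep <- lane_qc(list(good), ann)
  expect_true(rep$overall_pass)

  dense <- tiny_lane("dense", bd = 2.5)
  rep <- lane_qc(list(dense), ann)
  expect_false(rep$bd_pass)
  expect_false(rep$overall_pass)
  expect_true(rep$fov_pass && rep$poslin_pass)

  blurry <- tiny_lane("blurry", fov = 75)   # rule is strict >
  expect_false(lane_qc(list(blurry), ann)$fov_pass)
})

test_that("LOD rule compares the 0.5 fM probe to the lane's negatives", {
  ann <- tiny_annotation()
  # negatives all 4 (SD 0) and the 0.5 fM probe at 4: 4 > 4 is false
  flat <- tiny_lane("flat", pos = c(25600, 6400, 1600, 400, 4, 25),
                    neg = c(4, 4, 4, 4))
  rep <- lane_qc(list(flat), ann)
  expect_false(rep$lod_pass)
  expect_equal(rep$lod_cutoff, 4)

  ok <- tiny_lane("ok", neg = c(4, 4, 4, 4))  # 0.5 fM probe at 100
  expect_true(lane_qc(list(ok), ann)$lod_pass)
})

test_that("positive-control linearity R2 matches a least-squares oracle", {
  conc <- c(128, 32, 8, 2, 0.5, 0.125)
  # exact power law -> 1; constant -> 0
  expect_equal(pos_control_r2(stats::setNames(200 * conc, conc)), 1)
  expect_equal(pos_control_r2(stats::setNames(rep(7, 6), conc)), 0)

  counts <- stats::setNames(c(1200, 300, 80, 22, 6, 2), conc)
  fit <- lm(log2(counts) ~ log2(conc))   # no zeros: no offset
  expect_equal(pos_control_r2(counts), summary(fit)$r.squared,
               tolerance = 1e-10)
  expect_error(pos_control_r2(c(`1` = 5, `2` = 6)), ">= 3 distinct")
})

test_that("background threshold is mean + k sample SDs of pooled negatives", {
  expect_equal(background_threshold(rep(5, 8)), 5)
  expect_equal(background_threshold(c(2, 4, 6, 8)), 5 + 2 * sd(c(2, 4, 6, 8)))
  expect_equal(background_threshold(c(2, 4, 6, 8)), 10.16398, tolerance = 1e-5)
  expect_equal(background_threshold(c(0, 0)), 0)
  expect_error(background_threshold(3), ">= 2")
})

test_that("background filtering removes genes under threshold in a strict
           majority of samples and never touches controls", {
  ann <- tiny_annotation()
  vals <- rbind(GeneA = c(3, 3, 3, 12),    # 3/4 below -> removed
                GeneB = c(3, 3, 12, 12),   # 2/4 = 0.5, not > 0.5 -> kept
                GeneC = c(12, 12, 12, 12),
                GeneD = c(1, 1, 1, 1),
                Hk1 = c(50, 50, 50, 50), Hk2 = c(60, 60, 60, 60),
                matrix(5, 10, 4,
                       dimnames = list(ann$gene_id[7:16], NULL)))
  colnames(vals) <- paste0("s", 1:4)
  m <- count_matrix(vals, "raw")
  bf <- filter_background(m, ann, threshold = 10)
  expect_setequal(bf$removed, c("GeneA", "GeneD"))
  expect_setequal(bf$kept, c("GeneB", "GeneC", "Hk1", "Hk2"))
  expect_length(intersect(bf$kept, bf$removed), 0L)

  # threshold 0: every count >= 0, nothing below, all kept
  expect_length(filter_background(m, ann, threshold = 0)$removed, 0L)

  # monotone: raising the threshold never grows the kept set
  kept_sizes <- vapply(c(0, 2, 5, 11, 13, 51, 61),
                       function(thr) length(filter_background(m, ann, thr)$kept),
                       0L)
  expect_true(all(diff(kept_sizes) <= 0))
})

test_that("geNorm keeps exact scalar multiples and drops the noisy candidate", {
  set.seed(42)
  a <- c(100, 150, 80, 120, 90)
  mat <- rbind(A = a, B = 3 * a,
               C = round(runif(5, 50, 400)))
  colnames(mat) <- paste0("s", 1:5)
  gn <- genorm_select(mat, n_select = 2)
  expect_identical(gn$removal_order, "C")
  expect_setequal(gn$selected, c("A", "B"))
  expect_equal(gn$stability[["A"]], gn$stability[["B"]])
})

test_that("geNorm M values equal the brute-force pairwise enumeration", {
  set.seed(7)
  for (rep in 1:5) {
    mat <- matrix(rpois(6 * 5, lambda = 300), 6, 5,
                  dimnames = list(paste0("hk", 1:6), paste0("s", 1:5)))
    gn <- genorm_select(mat, n_select = 6)
    expect_identical(gn$removal_order, character(0))
    expect_setequal(gn$selected, rownames(mat))
    oracle <- genorm_m_bruteforce(mat)
    expect_equal(gn$stability[names(oracle)], oracle, tolerance = 1e-10)
    # permutation invariance in sample order
    perm <- mat[, sample(ncol(mat))]
    expect_equal(genorm_select(perm, 6)$stability[names(oracle)], oracle,
                 tolerance = 1e-10)
  }
  expect_error(genorm_select(matrix(1:4, 2, 2,
                                    dimnames = list(c("a", "b"), c("x", "y"))),
                             n_select = 3),
               "fewer candidates")
})

test_that("normalization equalizes identical and scalar-multiple lanes", {
  ann <- tiny_annotation()
  l1 <- tiny_lane("L1")
  l2 <- tiny_lane("L2")
  m <- assemble_matrix(list(l1, l2))
  out <- normalize_lanes(m, ann, c("Hk1", "Hk2"), pos_norm = FALSE)
  expect_equal(out[, "L1"], out[, "L2"])
  expect_equal(unname(attr(out, "hk_factors")), c(1, 1))

  l2x <- tiny_lane("L2", endo = 2 * c(100, 200, 50, 10), hk = 2 * c(500, 600),
                   pos = 2 * round(200 * c(128, 32, 8, 2, 0.5, 0.125)),
                   neg = 2 * c(4, 5, 6, 5))
  m2 <- assemble_matrix(list(l1, l2x))
  out2 <- normalize_lanes(m2, ann, c("Hk1", "Hk2"), pos_norm = FALSE)
  h <- attr(out2, "hk_factors")
  expect_equal(h[["L2"]], h[["L1"]] / 2)
  expect_equal(out2[, "L1"], out2[, "L2"])
  # controls are excluded from the returned matrix
  expect_setequal(rownames(out2),
                  c("GeneA", "GeneB", "GeneC", "GeneD", "Hk1", "Hk2"))
})

test_that("an all-ones matrix normalizes to log2(1.5) everywhere", {
  ann <- tiny_annotation()
  vals <- matrix(1L, 16, 3,
                 dimnames = list(ann$gene_id, paste0("s", 1:3)))
  m <- count_matrix(vals, "raw")
  out <- normalize_lanes(m, ann, c("Hk1", "Hk2"), pos_norm = FALSE)
  expect_true(all(abs(out - log2(1.5)) < 1e-12))
})

test_that("zero housekeeping counts error when the offset is disabled", {
  ann <- tiny_annotation()
  lane <- tiny_lane("L1", hk = c(0, 600))
  m <- assemble_matrix(list(lane, tiny_lane("L2")))
  expect_error(normalize_lanes(m, ann, c("Hk1", "Hk2"), pos_norm = FALSE,
                               offset = 0),
               "zero count and offset disabled")
  expect_silent(normalize_lanes(m, ann, c("Hk1", "Hk2"), pos_norm = FALSE))
})
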