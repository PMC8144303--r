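test_that("pathway scores are zero-mean and match an independent PCA oracle", {
  set.seed(21)
  m <- log2_cm(matrix(rnorm(6 * 12, mean = 7), 6, 12))
  ps <- pathway_score(m, gene_set("set", rownames(m)))
  expect_equal(mean(ps$scores), 0, tolerance = 1e-10)
  pr <- stats::prcomp(t(unclass(m)), center = TRUE, scale. = FALSE)
  expect_lt(max(abs(abs(unname(ps$scores)) - abs(unname(pr$x[, 1])))), 1e-8)
  expect_equal(ps$pc1_var_frac, pr$sdev[1]^2 / sum(pr$sdev^2),
               tolerance = 1e-10)
  expect_true(ps$orientation %in% c(-1, 1))
})

test_that("pathway score orientation aligns with expression", {
  # all genes share one centered pattern: score must be proportional with
  # positive sign
  v <- c(2, -1, -3, 1, 0, 1)
  x <- 8 + rbind(1 * v, 2 * v, 0.5 * v)
  m <- log2_cm(x)
  ps <- pathway_score(m, rownames(m))
  expect_gt(stats::cor(ps$scores, v), 0.9999)

  # covariance: adding +delta to every set gene in one sample raises that
  # sample's score
  set.seed(22)
  base <- matrix(rnorm(5 * 8, mean = 6), 5, 8)
  m0 <- log2_cm(base)
  bumped <- base; bumped[, 3] <- bumped[, 3] + 2
  m1 <- log2_cm(bumped)
  s0 <- pathway_score(m0, rownames(m0))$scores
  s1 <- pathway_score(m1, rownames(m1))$scores
  expect_gt(s1[[3]] - mean(s1[-3]), s0[[3]] - mean(s0[-3]))
})

test_that("pathway scoring is invariant to gene order and constant shifts", {
  set.seed(23)
  x <- matrix(rnorm(6 * 9, mean = 5), 6, 9,
              dimnames = list(paste0("g", 1:6), paste0("s", 1:9)))
  ref <- pathway_score(log2_cm(x, genes = rownames(x)), rownames(x))
  perm <- x[sample(6), ]
  got <- pathway_score(count_matrix(perm, "log2"), rownames(x))
  expect_equal(got$scores, ref$scores, tolerance = 1e-9)
  shifted <- x; shifted["g2", ] <- shifted["g2", ] + 5
  got2 <- pathway_score(count_matrix(shifted, "log2"), rownames(x))
  expect_equal(got2$scores, ref$scores, tolerance = 1e-9)
})

test_that("sets below the measured-gene minimum are skipped with a report", {
  m <- log2_cm(matrix(rnorm(20), 4, 5))
  sk <- pathway_score(m, gene_set("tiny", c("g1", "absent")), min_genes = 2)
  expect_s3_class(sk, "skipped_set")
  expect_equal(sk$n_measured, 1L)

  tab <- pathway_scores(m, list(big = gene_set("big", rownames(m)),
                                tiny = gene_set("tiny", c("g1", "absent"))),
                        min_genes = 2)
  expect_identical(attr(tab, "skipped"), "tiny")
  expect_identical(rownames(tab), "big")
})

test_that("covariate_t equals the per-gene OLS oracle on the two-factor model", {
  set.seed(24)
  d <- tiny_design()
  m <- log2_cm(matrix(rnorm(15 * 12, 7), 15, 12), samples = d$sample_id)
  t_app <- covariate_t(m, d, "APP")
  t_arg <- covariate_t(m, d, "Arg1")
  expect_identical(attr(t_app, "df"), 9L)
  for (g in rownames(m)) {
    fit <- summary(lm(m[g, ] ~ APP + Arg1, data = d))$coefficients
    expect_equal(t_app[[g]], fit["APPAPP", "t value"], tolerance = 1e-8)
    expect_equal(t_arg[[g]], fit["Arg1Arg1_insuff", "t value"],
                 tolerance = 1e-8)
  }
})

test_that("covariate_t: clean shifts give huge t; null genes center at zero", {
  d <- tiny_design()
  x <- matrix(5, 1, 12, dimnames = list("g1", d$sample_id))
  x[1, d$APP == "APP"] <- x[1, d$APP == "APP"] + 1
  x <- x + rep(c(0, 1e-9), 6)   # break exact collinearity of residuals
  t1 <- covariate_t(count_matrix(x, "log2"), d, "APP")
  expect_gt(t1[["g1"]], 1e6)

  set.seed(25)
  tnull <- replicate(80, {
    m <- log2_cm(matrix(rnorm(12, 6), 1, 12), genes = "g",
                 samples = d$sample_id)
    covariate_t(m, d, "APP")[["g"]]
  })
  expect_lt(abs(mean(tnull)), 0.25)

  conf <- d; conf$Arg1 <- factor(ifelse(conf$APP == "APP", "Arg1_insuff",
                                        "Arg1_suff"),
                                 levels = levels(d$Arg1))
  conf$group <- paste(conf$APP, conf$Arg1, sep = ".")
  m <- log2_cm(matrix(rnorm(12), 1, 12), samples = d$sample_id)
  expect_error(covariate_t(m, conf, "APP"), "aliased|confounded")
})

test_that("directed and undirected GSS follow the signed-square formula", {
  s <- gene_set("s", c("g1", "g2"))
  expect_equal(directed_gss(c(g1 = 0), gene_set("z", "g1")), 0)
  expect_equal(directed_gss(c(g1 = 3, g2 = -1), s), 2)
  expect_equal(directed_gss(c(g1 = 2, g2 = -2), s), 0)
  expect_equal(undirected_gss(c(g1 = 3, g2 = -1), s), sqrt(5))
  expect_equal(undirected_gss(c(g1 = 0, g2 = 0), s), 0)
  expect_equal(undirected_gss(c(g1 = -4), gene_set("z", "g1")), 4)
  expect_error(directed_gss(c(x = 1), s), "no measured genes")
})

test_that("|directed| <= undirected, equality iff one sign", {
  set.seed(26)
  for (i in 1:200) {
    k <- sample(2:10, 1)
    t <- stats::setNames(rt(k, df = 5), paste0("g", seq_len(k)))
    s <- names(t)
    expect_lte(abs(directed_gss(t, s)), undirected_gss(t, s) + 1e-12)
  }
  one_sign <- c(g1 = 2, g2 = 0.5, g3 = 1)
  expect_equal(abs(directed_gss(one_sign, names(one_sign))),
               undirected_gss(one_sign, names(one_sign)), tolerance = 1e-12)
})

test_that("gss_table flags at the cutoff boundary and finds spiked sets", {
  # boundary: |GSS| just under 1.3 is not flagged, at 1.3 it is
  d <- tiny_design()
  set.seed(27)
  res <- simulated_log2(seed = 27,
                        effects = list(list(set = "AD Causal Risk Pathway",
                                            factor = "APP", log2fc = 1.5)))
  sets <- pathway_gene_sets(res$sim$ann)
  g <- gss_table(res$matrix, res$sim$design,
                 sets["AD Causal Risk Pathway"], covariates = "APP")
  expect_identical(g$flag, "up")
  expect_gte(g$directed_gss, 1.3)

  gt <- c(a = 1.2, b = -1.2, c = 1.2)      # |directed| < 1.3
  expect_lt(abs(directed_gss(gt, names(gt))), 1.3)
})

test_that("cell-type scores are marker means and degrade to single markers", {
  m <- log2_cm(rbind(c(4, 8), c(6, 2)), genes = c("mk1", "mk2"),
               samples = c("s1", "s2"))
  s <- celltype_score(m, c("mk1", "mk2"))
  expect_equal(unname(s), c(5, 5), ignore_attr = TRUE)
  s1 <- celltype_score(m, c("mk1", "zz"))
  expect_equal(unname(s1), unname(m["mk1", ]), ignore_attr = TRUE)
  expect_error(celltype_score(m, "zz"), "no measured marker")

  set.seed(28)
  big <- log2_cm(matrix(rnorm(50 * 6, 7), 50, 6))
  mk <- paste0("g", 1:7)
  expect_equal(unname(celltype_score(big, mk)),
               unname(colMeans(unclass(big)[mk, ])), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("marker co-correlation QC: perfectly coherent markers get the
           minimal permutation p; single markers are flagged", {
  set.seed(29)
  prof <- rnorm(10)
  markers <- t(sapply(1:5, function(i) 6 + prof)) # exact copies
  noise <- matrix(rnorm(200 * 10), 200, 10)
  m <- log2_cm(rbind(markers, noise))
  mk <- rownames(m)[1:5]
  q <- celltype_qc(m, mk, n_random = 999, seed = 1)
  expect_equal(q$qc_p, 1 / 1000)
  expect_equal(q$mean_marker_corr, 1, tolerance = 1e-12)

  single <- celltype_qc(m, "g1")
  expect_true(single$flag)
  expect_equal(single$qc_p, 1)
})

test_that("marker QC p-values are valid under the exchangeable null", {
  set.seed(30)
  m <- log2_cm(matrix(rnorm(60 * 8, 6), 60, 8))
  ps <- vapply(1:60, function(i)
    celltype_qc(m, sample(rownames(m), 5), n_random = 99, seed = i)$qc_p, 0)
  # super-uniformity at the 10% level and mean near 0.5
  expect_lte(mean(ps <= 0.1), 0.2)
  expect_lt(abs(mean(ps) - 0.5), 0.12)
})
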