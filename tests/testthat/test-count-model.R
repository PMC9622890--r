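test_that("size factors follow the median-of-ratios closed forms", {
  # identical samples are symmetric
  counts <- tiny_counts(cbind(A = c(10, 20, 5), B = c(10, 20, 5)))
  expect_equal(size_factors(counts)$size_factor, c(1, 1))

  # sample B = 2x sample A: geometric-mean reference puts them at 1/sqrt(2), sqrt(2)
  counts <- tiny_counts(cbind(A = c(10, 20, 30, 40), B = c(20, 40, 60, 80)))
  expect_equal(size_factors(counts)$size_factor, c(1 / sqrt(2), sqrt(2)),
               tolerance = 1e-9)

  # all-zero features are excluded from the reference
  with_zero <- tiny_counts(rbind(cbind(A = c(10, 20, 30, 40), B = c(20, 40, 60, 80)),
                                 c(0, 0)))
  expect_equal(size_factors(with_zero)$size_factor,
               size_factors(counts)$size_factor)

  # scale equivariance: scaling one sample by c scales its factor relative
  # to the others by c (the geometric-mean reference absorbs c^(1/n))
  scaled <- tiny_counts(cbind(A = c(10, 20, 30, 40), B = 3 * c(20, 40, 60, 80)))
  sfs <- size_factors(scaled)$size_factor
  sf0 <- size_factors(counts)$size_factor
  expect_equal(sfs[2] / sfs[1], 3 * sf0[2] / sf0[1], tolerance = 1e-12)

  # no feature covered everywhere -> informative error
  disjoint <- tiny_counts(cbind(A = c(5, 0), B = c(0, 5)))
  expect_error(size_factors(disjoint), "nonzero")
})

test_that("dispersion estimation recovers constant, Poisson and NB regimes", {
  meta <- tibble::tibble(sample = c("a1", "a2", "a3", "b1", "b2", "b3"),
                         group = rep(c("a", "b"), each = 3))

  # constant counts within groups -> zero raw dispersion
  m <- cbind(a1 = c(10, 50), a2 = c(10, 50), a3 = c(10, 50),
             b1 = c(20, 80), b2 = c(20, 80), b3 = c(20, 80))
  d <- estimate_dispersion(tiny_counts(m), meta)
  expect_equal(d$dispersion_raw, c(0, 0))
  expect_equal(d$dispersion, c(0, 0))

  # Poisson counts: median estimate near zero; NB alpha = 0.1 recovered
  set.seed(41)
  mu <- exp(runif(2000, log(50), log(500)))
  pois <- sapply(1:6, function(j) rpois(2000, mu))
  colnames(pois) <- meta$sample
  dp <- estimate_dispersion(tiny_counts(pois), meta)
  expect_lte(median(dp$dispersion), 0.01)

  nb <- sapply(1:6, function(j) rnbinom(2000, mu = mu, size = 10))
  colnames(nb) <- meta$sample
  dn <- estimate_dispersion(tiny_counts(nb), meta)
  expect_gte(median(dn$dispersion), 0.05)
  expect_lte(median(dn$dispersion), 0.2)

  # no replicated group -> error
  expect_error(
    estimate_dispersion(tiny_counts(m[, c(1, 4)]),
                        meta[c(1, 4), ]),
    "replicates|2 samples")
})

test_that("the Wald test is antisymmetric and handles zeros", {
  set.seed(7)
  m <- sapply(1:6, function(j) rnbinom(300, mu = 100, size = 20))
  m[1, ] <- 0  # all-zero feature
  colnames(m) <- sprintf("s%d", 1:6)
  counts <- tiny_counts(m)
  meta <- tibble::tibble(sample = colnames(m),
                         group = rep(c("ctl", "trt"), each = 3))
  de_fwd <- nb_wald_test(counts, meta, control = "ctl", treatment = "trt")
  de_rev <- nb_wald_test(counts, meta, control = "trt", treatment = "ctl")
  expect_equal(de_fwd$table$log2fc, -de_rev$table$log2fc)

  # all-zero features: undefined p, excluded from the BH family
  expect_true(is.na(de_fwd$table$pvalue[1]))
  expect_true(is.na(de_fwd$table$padj[1]))
  expect_equal(de_fwd$table$padj[-1],
               bh_adjust(de_fwd$table$pvalue[-1]))
  expect_true(all(de_fwd$table$padj >= de_fwd$table$pvalue, na.rm = TRUE))
})

test_that("log2 fold changes are invariant to sample rescaling at fixed dispersions", {
  set.seed(11)
  m <- sapply(1:6, function(j) rnbinom(400, mu = 80, size = 10))
  colnames(m) <- sprintf("s%d", 1:6)
  meta <- tibble::tibble(sample = colnames(m),
                         group = rep(c("ctl", "trt"), each = 3))
  disp <- estimate_dispersion(tiny_counts(m), meta)
  de1 <- nb_wald_test(tiny_counts(m), meta, "ctl", "trt", dispersions = disp)
  m2 <- m
  m2[, 2] <- m[, 2] * 2L
  sf1 <- size_factors(tiny_counts(m))
  sf2 <- size_factors(tiny_counts(m2))
  # the geometric-mean reference absorbs 2^(1/n) of the scaling, so the
  # scaled sample's factor grows by 2^((n-1)/n) and the others shrink by
  # 2^(1/n); factors relative to an unscaled sample grow by exactly 2
  # (consistent with the (1/sqrt(2), sqrt(2)) closed form above)
  expect_equal(sf2$size_factor[2] / sf2$size_factor[1],
               2 * sf1$size_factor[2] / sf1$size_factor[1],
               tolerance = 1e-12)
  # normalized counts shift by the common 2^(1/n), which cancels in the
  # fold change up to the fixed pseudocount
  de2 <- nb_wald_test(tiny_counts(m2), meta, "ctl", "trt", dispersions = disp)
  expect_equal(de2$table$log2fc, de1$table$log2fc, tolerance = 2e-3)
})

test_that("the null type-I rate sits in the calibration band", {
  rates <- vapply(1:3, function(s) {
    cfg <- sim_config(n_genes = 2000, markers_per_type = 1, marker_fold = 1,
                      depletion_fraction = 0, up_fraction = 0, seed = s)
    dep <- simulate_depletion_experiment(config = cfg)
    de <- nb_wald_test(dep$counts, dep$meta, "control", "knockdown")
    mean(de$table$pvalue < 0.05, na.rm = TRUE)
  }, numeric(1))
  expect_gte(mean(rates), 0.025)
  expect_lte(mean(rates), 0.075)
})

test_that("BH adjustment reproduces the step-up rule and its invariances", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(c(0, 0.5))[1], 0)

  set.seed(2)
  p <- runif(100)
  padj <- bh_adjust(p)
  expect_true(all(padj >= p))
  expect_true(all(padj <= 1))
  # order invariance
  perm <- sample(100)
  expect_equal(bh_adjust(p[perm]), padj[perm])
  # monotone in p-rank
  ord <- order(p)
  expect_true(all(diff(padj[ord]) >= -1e-12))
  # NAs do not count toward m
  expect_equal(bh_adjust(c(0.01, NA))[1], 0.01)
  expect_error(bh_adjust(c(-0.1, 0.5)), "\\[0, 1\\]")
})

test_that("DE calls use strict thresholds on both axes", {
  tab <- tibble::tibble(feature_id = c("a", "b", "c", "d"),
                        base_mean = 100, se = 0.1, stat = 1, pvalue = 0.001,
                        log2fc = c(0.5, -1.2, 0.51, 0.6),
                        padj = c(0.005, 0.005, 0.01, 0.009))
  calls <- call_de(tab)
  # log2fc exactly 0.5 and padj exactly 0.01 sit on the boundary: excluded
  expect_false("a" %in% calls$feature_id)
  expect_false("c" %in% calls$feature_id)
  expect_equal(calls$direction[calls$feature_id == "b"], "down")
  expect_equal(calls$direction[calls$feature_id == "d"], "up")
})

test_that("the engine agrees with an established NB differential pipeline", {
  skip_if_not_installed("DESeq2")
  cfg <- sim_config(n_genes = 800, markers_per_type = 40, seed = 5)
  dep <- simulate_depletion_experiment(config = cfg)
  de <- nb_wald_test(dep$counts, dep$meta, "control", "knockdown")
  m <- as.matrix(dep$counts[-1])
  rownames(m) <- dep$counts$gene_id
  dds <- DESeq2::DESeqDataSetFromMatrix(
    m, S4Vectors::DataFrame(condition = factor(dep$meta$group,
                                               levels = c("control", "knockdown"))),
    ~condition)
  dds <- suppressMessages(DESeq2::DESeq(dds, quiet = TRUE))
  res <- DESeq2::results(dds)
  expect_gt(cor(de$table$log2fc, res$log2FoldChange, use = "complete.obs"),
            0.99)
  mine <- call_de(de)$feature_id
  theirs <- rownames(res)[!is.na(res$padj) & res$padj < 0.01 &
                            abs(res$log2FoldChange) > 0.5]
  jac <- length(intersect(mine, theirs)) / length(union(mine, theirs))
  expect_gt(jac, 0.9)
})
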