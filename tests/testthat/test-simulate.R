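test_that("configuration invariants are enforced", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(marker_fold = 0.5), "marker_fold")
  expect_error(sim_config(depletion_fraction = 1.2), "depletion_fraction")
  expect_error(sim_config(nb_dispersion = -0.1), "nb_dispersion")
  expect_error(
    simulate_celltype_counts(sim_config(n_genes = 100, markers_per_type = 40)),
    "exceeds")
})

test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(n_genes = 300, markers_per_type = 20, seed = 17,
                    chrom_length = 1e5, n_genome_genes = 5,
                    n_bound_fragments = 20)
  a <- simulate_celltype_counts(cfg)
  b <- simulate_celltype_counts(cfg)
  expect_identical(a, b)

  da <- simulate_depletion_experiment(a, cfg)
  db <- simulate_depletion_experiment(b, cfg)
  expect_identical(da, db)

  ga <- simulate_genome_with_motifs(cfg, n_planted_genes = 2)
  gb <- simulate_genome_with_motifs(cfg, n_planted_genes = 2)
  expect_identical(ga, gb)

  ma <- simulate_damid(ga$genome, ga$genes, cfg)
  mb <- simulate_damid(gb$genome, gb$genes, cfg)
  expect_identical(ma, mb)

  # a different seed changes the draws
  cfg2 <- sim_config(n_genes = 300, markers_per_type = 20, seed = 18)
  expect_false(identical(simulate_celltype_counts(cfg2)$counts, a$counts))
})

test_that("planted markers carry the configured fold in their own type", {
  # dispersion ~ 0 and deep libraries: empirical mean ratio approaches the fold
  cfg <- sim_config(n_genes = 400, markers_per_type = 30, marker_fold = 8,
                    nb_dispersion = 0, library_size_mean = 2e7, seed = 33)
  cc <- simulate_celltype_counts(cfg)
  m <- as.matrix(cc$counts[-1])
  rownames(m) <- cc$counts$gene_id
  types <- setNames(cc$meta$celltype, cc$meta$sample)[colnames(m)]
  norm <- sweep(m, 2, colSums(m) / mean(colSums(m)), "/")
  mk <- cc$truth$markers$EE
  ee_mean <- rowMeans(norm[mk, types == "EE"])
  other_mean <- rowMeans(norm[mk, types != "EE"])
  # each type boosts its own markers, so totals stay symmetric and the
  # planted fold survives normalization
  expect_lt(abs(mean(ee_mean) / mean(other_mean) / 8 - 1), 0.05)

  # truth is recorded even under the null fold
  cfg_null <- sim_config(n_genes = 200, markers_per_type = 10,
                         marker_fold = 1, seed = 3)
  cc0 <- simulate_celltype_counts(cfg_null)
  expect_length(cc0$truth$markers$EE, 10)
})

test_that("the depletion experiment plants the advertised fold changes", {
  cfg <- sim_config(n_genes = 1000, markers_per_type = 80, depletion_fold = 4,
                    seed = 19)
  dep <- simulate_depletion_experiment(config = cfg)
  expect_equal(dep$truth$true_log2fc_down, -2)
  expect_equal(length(dep$truth$planted_down),
               round(0.8 * length(dep$truth$markers$EE)))

  m <- as.matrix(dep$counts[-1])
  rownames(m) <- dep$counts$gene_id
  grp <- setNames(dep$meta$group, dep$meta$sample)[colnames(m)]
  # median-of-ratios normalization: totals are distorted by the depleted
  # high-abundance markers themselves, the per-gene median is not
  norm <- sweep(m, 2, size_factors(dep$counts)$size_factor, "/")
  lr <- log2((rowMeans(norm[dep$truth$planted_down, grp == "knockdown"]) + 0.5) /
               (rowMeans(norm[dep$truth$planted_down, grp == "control"]) + 0.5))
  expect_lt(abs(mean(lr) + 2), 0.3)

  # depletion_fraction 0 leaves the groups exchangeable draws
  cfg0 <- sim_config(n_genes = 500, markers_per_type = 20,
                     depletion_fraction = 0, up_fraction = 0, seed = 5)
  dep0 <- simulate_depletion_experiment(config = cfg0)
  expect_length(dep0$truth$planted_down, 0)
  de0 <- nb_wald_test(dep0$counts, dep0$meta, "control", "knockdown")
  expect_lte(sum(de0$table$padj < 0.01, na.rm = TRUE), 5)
})

test_that("the toy genome honours plant requests and window guarantees", {
  cfg <- sim_config(seed = 29, chrom_length = 2e5, n_genome_genes = 6)
  # zero plants: truth windows contain no exact consensus hit
  gen0 <- simulate_genome_with_motifs(cfg, n_planted_genes = 0)
  expect_equal(nrow(gen0$truth$planted_motifs), 0L)

  gen <- simulate_genome_with_motifs(cfg, n_planted_genes = 4)
  pm <- gen$truth$planted_motifs
  expect_equal(nrow(pm), 4L)
  # every planted gene window contains exactly one exact hit (the plant)
  for (i in seq_len(nrow(pm))) {
    g <- gen$genes[gen$genes$gene_id == pm$gene_id[i], ]
    win <- extract_enhancer(gen$genome, g, -2500, 2500)
    expect_equal(nrow(scan_motif(win, "T-A/T-A-G-A/C/G-C-G/A/T")), 1L)
  }
  # plants land on both genome strands
  expect_setequal(unique(pm$strand), c("+", "-"))

  expect_error(
    simulate_genome_with_motifs(cfg, plant_positions = c(-5000L),
                                scan_window = 2500),
    "window too small")
})

test_that("DamID simulation matches the 2v3 design and planted enrichment", {
  cfg <- sim_config(seed = 41, chrom_length = 3e5, n_genome_genes = 8,
                    n_bound_fragments = 60, nb_dispersion = 0,
                    fragment_mean = 400)
  gen <- simulate_genome_with_motifs(cfg, n_planted_genes = 2)
  dam <- simulate_damid(gen$genome, gen$genes, cfg)

  expect_equal(sum(dam$meta$condition == "fusion"), 2L)
  expect_equal(sum(dam$meta$condition == "dam_only"), 3L)
  expect_length(dam$truth$bound_fragments, 60)

  m <- as.matrix(dam$counts[-1])
  rownames(m) <- dam$counts$fragment_id
  bnd <- dam$truth$bound_fragments
  fus <- dam$meta$sample[dam$meta$condition == "fusion"]
  ctl <- dam$meta$sample[dam$meta$condition == "dam_only"]
  # normalize by the depth of unbound fragments so the planted factor is not
  # diluted by the bound share of the library
  depth <- colSums(m[setdiff(rownames(m), bnd), ])
  norm_raw <- sweep(m, 2, depth / mean(depth), "/")
  ratio_raw <- mean(rowMeans(norm_raw[bnd, fus])) /
    mean(rowMeans(norm_raw[bnd, ctl]))
  expect_lt(abs(ratio_raw / cfg$damid_enrichment - 1), 0.1)

  # enrichment factor 1 -> conditions exchangeable
  cfg1 <- sim_config(seed = 41, chrom_length = 2e5, n_genome_genes = 5,
                     n_bound_fragments = 30, damid_enrichment = 1)
  dam1 <- simulate_damid(gen$genome, gen$genes, cfg1)
  b1 <- call_binding(dam1$counts, dam1$meta)
  expect_lte(length(b1$significant), 3)

  expect_error(
    simulate_damid(gen$genome, gen$genes,
                   sim_config(n_bound_fragments = 1e6)),
    "more bound fragments")
})
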