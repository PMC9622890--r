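test_that("the GATC fragment map tiles chromosomes exactly", {
  # two sites -> three fragments, boundaries at the occurrence starts
  map <- gatc_fragment_map(c(chr1 = "AAAGATCAAAAAGATCAAA"))
  expect_equal(map$start, c(0L, 3L, 12L))
  expect_equal(map$end, c(3L, 12L, 19L))

  # no site -> single fragment [0, L)
  map1 <- gatc_fragment_map(c(chr1 = "AAAAAA"))
  expect_equal(nrow(map1), 1L)
  expect_equal(c(map1$start, map1$end), c(0L, 6L))

  # site at position 0 -> no empty leading fragment
  map0 <- gatc_fragment_map(c(chr1 = "GATCAAAA"))
  expect_equal(map0$start, 0L)
  expect_equal(map0$end, 8L)

  # case-insensitive; tiling invariant on a random sequence
  set.seed(31)
  s <- random_dna(5000)
  map_r <- gatc_fragment_map(c(chrA = tolower(s), chrB = s))
  for (ch in c("chrA", "chrB")) {
    frs <- map_r[map_r$chrom == ch, ]
    expect_equal(sum(frs$end - frs$start), 5000L)
    expect_equal(frs$start[-1], frs$end[-nrow(frs)])
    expect_true(all(diff(frs$start) > 0))
  }
  expect_error(gatc_fragment_map(c(chr1 = "")), "empty")
})

test_that("intervals are credited to the fragment holding their 5' start", {
  map <- gatc_fragment_map(c(chr1 = "AAAGATCAAAAAGATCAAA"))
  iv <- tibble::tibble(chrom = "chr1",
                       start = c(4L, 10L, 0L),
                       end = c(6L, 14L, 2L),
                       sample = c("s1", "s1", "s2"))
  fc <- count_fragments(iv, map)
  m <- as.matrix(fc[-1])
  rownames(m) <- fc$fragment_id
  # fully inside [3,12) and straddling into [12,19): both count to [3,12)
  expect_equal(unname(m["chr1:3-12", "s1"]), 2L)
  expect_equal(unname(m["chr1:12-19", "s1"]), 0L)
  expect_equal(unname(m["chr1:0-3", "s2"]), 1L)

  # empty input -> all-zero counts over the map
  fc0 <- count_fragments(iv[0, ], map)
  expect_equal(nrow(fc0), nrow(map))
  expect_true(all(as.matrix(fc0[-1]) == 0))

  # off-map chromosome -> unassigned row, with a message
  expect_message(
    fc_un <- count_fragments(dplyr::mutate(iv, chrom = "chrX"), map),
    "unassigned")
  expect_true("unassigned" %in% fc_un$fragment_id)
})

test_that("replicate correlations separate conditions on simulated DamID", {
  cfg <- sim_config(n_genes = 200, chrom_length = 2e5, n_genome_genes = 8,
                    n_bound_fragments = 40, seed = 8)
  gen <- simulate_genome_with_motifs(cfg, n_planted_genes = 2)
  dam <- simulate_damid(gen$genome, gen$genes, cfg)
  r <- replicate_correlation(dam$counts)
  expect_equal(diag(r), rep(1, 5), ignore_attr = TRUE)
  expect_equal(r, t(r))

  fus <- dam$meta$sample[dam$meta$condition == "fusion"]
  ctl <- dam$meta$sample[dam$meta$condition == "dam_only"]
  within <- c(r[fus[1], fus[2]], r[ctl[1], ctl[2]], r[ctl[1], ctl[3]],
              r[ctl[2], ctl[3]])
  between <- as.vector(r[fus, ctl])
  expect_gt(min(within), max(between))

  # duplicated sample -> r = 1; reversal of an asymmetric profile -> r < 1
  prof <- dam$counts[, 1:2]
  prof$dup <- prof[[2]]
  prof$rev <- rev(prof[[2]])
  r2 <- replicate_correlation(prof)
  expect_equal(unname(r2[1, "dup"]), 1)
  expect_lt(r2[1, "rev"], 1)
})

test_that("binding calls recover planted fragments and respect strictness", {
  cfg <- sim_config(n_genes = 200, chrom_length = 3e5, n_genome_genes = 10,
                    n_bound_fragments = 50, seed = 12)
  gen <- simulate_genome_with_motifs(cfg, n_planted_genes = 2)
  dam <- simulate_damid(gen$genome, gen$genes, cfg)
  b <- call_binding(dam$counts, dam$meta)
  truth <- dam$truth$bound_fragments
  expect_gte(mean(truth %in% b$significant), 0.9)
  expect_gte(mean(b$significant %in% truth), 0.9)

  # fusion identical to control -> empty significant set
  flat <- dam$counts
  flat$fusion_1 <- flat$dam_only_1
  flat$fusion_2 <- flat$dam_only_2
  b0 <- call_binding(flat, dam$meta)
  expect_length(b0$significant, 0)

  # enrichment is one-sided: log2fc exactly at the floor is excluded
  tab <- b$table
  at_floor <- tab$fragment_id[!is.na(tab$padj) & tab$padj < 0.01 &
                                abs(tab$log2fc - 1) < 1e-12]
  expect_false(any(at_floor %in% b$significant))
  expect_true(all(tab$log2fc[tab$significant] > 1))
  expect_true(all(tab$padj[tab$significant] < 0.01))
})

test_that("peak merging follows the gap rule", {
  s <- paste0("AA", strrep("GATCAAAA", 5))  # five ~8 bp fragments
  map <- gatc_fragment_map(c(chr1 = s))
  ids <- map$fragment_id

  # adjacent significant fragments merge into one peak
  pk <- merge_peaks(ids[2:3], map)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$start, map$start[2])
  expect_equal(pk$end, map$end[3])
  expect_equal(pk$n_fragments, 2L)

  # fragments separated by one non-significant fragment: two peaks at gap 0,
  # one peak at gap 1
  expect_equal(nrow(merge_peaks(ids[c(2, 4)], map, max_gap_fragments = 0)), 2L)
  expect_equal(nrow(merge_peaks(ids[c(2, 4)], map, max_gap_fragments = 1)), 1L)

  expect_equal(nrow(merge_peaks(character(0), map)), 0L)
  expect_error(merge_peaks("chrZ:0-1", map), "present in the map")
})

test_that("peak-gene assignment is strand-aware with a 2 kb upstream window", {
  genes <- tibble::tibble(gene_id = c("gplus", "gminus"),
                          chrom = "chr1",
                          start = c(10000L, 40000L),
                          end = c(12000L, 42000L),
                          strand = c("+", "-"),
                          tss = c(10000L, 41999L))
  peak_at <- function(start, end) {
    tibble::tibble(peak_id = "p", chrom = "chr1", start = start, end = end,
                   n_fragments = 1L, fragment_ids = list("f"),
                   log2fc = 2, min_padj = 1e-4)
  }
  get_genes <- function(p) attr(annotate_peaks(p, genes), "genes")

  # inside the gene body
  expect_equal(get_genes(peak_at(10500L, 10600L)), "gplus")
  # 1,500 bp upstream of the plus-strand TSS: assigned; 2,500 bp: not
  expect_equal(get_genes(peak_at(8400L, 8500L)), "gplus")
  expect_equal(get_genes(peak_at(7400L, 7500L)), character(0))
  # upstream of a minus-strand gene is rightward
  expect_equal(get_genes(peak_at(43400L, 43500L)), "gminus")
  expect_equal(get_genes(peak_at(44400L, 44500L)), character(0))

  # two overlapping genes both assigned; distinct count deduplicates
  genes2 <- dplyr::mutate(genes, start = 10000L, end = 12000L,
                          strand = "+", tss = 10000L)
  ann <- annotate_peaks(peak_at(10500L, 10600L), genes2)
  expect_equal(ann$gene_ids[[1]], c("gminus", "gplus"))
  expect_equal(length(attr(ann, "genes")), 2L)
})
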