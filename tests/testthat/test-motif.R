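CONSENSUS <- "T-A/T-A-G-A/C/G-C-G/A/T"

test_that("consensus parsing produces the right IUPAC code", {
  m <- parse_consensus(CONSENSUS)
  expect_s3_class(m, "consensus_motif")
  expect_length(m, 7)
  expect_equal(attr(m, "iupac"), "TWAGVCD")

  expect_equal(unclass(parse_consensus("A"))[[1]], "A")
  expect_equal(attr(parse_consensus("A/C/G/T"), "iupac"), "N")
  # bare IUPAC strings round-trip
  expect_equal(attr(parse_consensus("TWAGVCD"), "iupac"), "TWAGVCD")
  expect_error(parse_consensus("T-A/X"), "invalid")
})

test_that("the scanner matches the printed 7-mers as documented", {
  m <- parse_consensus(CONSENSUS)

  # TTAGCCG satisfies every position at 0 mismatches
  h <- scan_motif("TTAGCCG", m)
  expect_equal(nrow(h[h$strand == "+", ]), 1L)
  expect_equal(h$mismatches[h$strand == "+"], 0L)

  # TAAGCTG fails position 6 (T where C is required): no exact hit,
  # one 1-mismatch hit localized to position 6
  expect_equal(nrow(dplyr::filter(scan_motif("TAAGCTG", m), strand == "+")), 0L)
  h1 <- dplyr::filter(scan_motif("TAAGCTG", m, max_mismatch = 1),
                      strand == "+")
  expect_equal(h1$mismatches, 1L)
  expect_equal(h1$mismatch_positions[[1]], 6L)

  # empty and too-short sequences give no hits
  expect_equal(nrow(scan_motif("", m)), 0L)
  expect_equal(nrow(scan_motif("TTAGC", m)), 0L)

  # a sequence containing only the reverse complement of a consensus word
  # yields exactly one minus-strand hit
  word <- "TAAGACG"
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(word)))
  seq <- paste0("AAAAA", rc, "AAAAA")
  h <- scan_motif(seq, m)
  expect_equal(nrow(h), 1L)
  expect_equal(h$strand, "-")
  expect_equal(h$start, 5L)
  expect_equal(h$matched_seq, word)

  # N never matches; case is ignored
  expect_equal(nrow(scan_motif("TTAGCNG", m)), 0L)
  expect_equal(scan_motif("ttagccg", m)$mismatches, scan_motif("TTAGCCG", m)$mismatches)
})

test_that("the scanner equals the per-window brute-force oracle", {
  m <- parse_consensus(CONSENSUS)
  sets <- unclass(m)
  set.seed(77)
  for (i in 1:150) {
    L <- sample(10:200, 1)
    s <- random_dna(L)
    for (mm in 0:2) {
      mine <- scan_motif(s, m, max_mismatch = mm)
      ref <- oracle_scan(s, sets, mm)
      mine <- mine[order(mine$start, mine$strand), ]
      ref <- ref[order(ref$start, ref$strand), ]
      expect_equal(mine$start, ref$start)
      expect_equal(mine$strand, ref$strand)
      expect_equal(mine$mismatches, ref$mismatches)
    }
  }
})

test_that("TSS-relative coordinates follow the signed no-zero convention", {
  hit <- function(s) tibble::tibble(start = s, end = s + 7L, strand = "+")

  # hit starting at the TSS base of a plus-strand gene -> (+1, +7)
  h <- tss_relative(hit(1000L), tss = 1000L, gene_strand = "+")
  expect_equal(c(h$rel_start, h$rel_end), c(1L, 7L))

  # hit ending 1 bp before the TSS -> (-7, -1)
  h <- tss_relative(hit(993L), tss = 1000L, gene_strand = "+")
  expect_equal(c(h$rel_start, h$rel_end), c(-7L, -1L))

  # the reported enhancer-motif intervals all have length 7
  for (iv in list(c(-1595L, -1589L), c(-1471L, -1465L), c(1734L, 1740L))) {
    expect_equal(abs(iv[1] - iv[2]) + 1L, 7L)
  }

  # minus-strand gene: downstream runs leftward
  h <- tss_relative(tibble::tibble(start = 994L, end = 1001L, strand = "+"),
                    tss = 1000L, gene_strand = "-")
  expect_equal(c(h$rel_start, h$rel_end), c(1L, 7L))
})

test_that("enhancer extraction spans and orients windows correctly", {
  set.seed(55)
  s <- random_dna(10000)
  genome <- c(chr1 = s)
  gplus <- list(chrom = "chr1", tss = 5000L, strand = "+")
  gminus <- list(chrom = "chr1", tss = 5000L, strand = "-")

  # the two enhancer windows span 516 and 755 bp
  expect_equal(nchar(extract_enhancer(genome, gplus, 1703, 2218)), 516L)
  expect_equal(nchar(extract_enhancer(genome, gplus, -2064, -1310)), 755L)
  # (+1, +1) is the TSS base itself
  expect_equal(extract_enhancer(genome, gplus, 1, 1),
               substring(s, 5001, 5001), ignore_attr = TRUE)
  # minus-strand windows come back reverse-complemented
  w <- extract_enhancer(genome, gminus, 1, 5)
  expect_equal(w, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(substring(s, 4997, 5001)))), ignore_attr = TRUE)
  # windows crossing the TSS skip position zero
  expect_equal(nchar(extract_enhancer(genome, gplus, -469, 634)), 1103L)

  expect_error(extract_enhancer(genome, gplus, 4500, 5200), "overflows")
})

test_that("extract-then-scan recovers planted fixtures on both strands", {
  cfg <- sim_config(n_genes = 100, seed = 21)
  gen <- simulate_genome_with_motifs(cfg)
  pm <- gen$truth$planted_motifs
  for (i in seq_len(nrow(pm))) {
    g <- gen$genes[gen$genes$gene_id == pm$gene_id[i], ]
    win <- extract_enhancer(gen$genome, g, -2500, 2500)
    h <- scan_motif(win, CONSENSUS, seq_id = g$gene_id)
    expect_equal(nrow(h), 1L)
    iv <- attr(win, "interval")
    abs_start <- if (g$strand == "+") iv["start"] + h$start else iv["end"] - h$end
    h2 <- tss_relative(tibble::tibble(start = as.integer(abs_start),
                                      end = as.integer(abs_start) + 7L,
                                      strand = h$strand),
                       g$tss, g$strand)
    expect_equal(h2$rel_start, pm$rel_start[i])
    expect_equal(h2$rel_end, pm$rel_end[i])
  }
})
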