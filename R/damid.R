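# DamID analysis at GATC-fragment resolution. All coordinates are 0-based
# half-open internally and in BED-style outputs.

# Accept a DNAStringSet, a named character vector, or a FASTA path.
as_dna <- function(genome) {
  if (inherits(genome, "DNAStringSet")) return(genome)
  if (is.character(genome) && length(genome) == 1 && file.exists(genome) &&
      is.null(names(genome))) {
    return(Biostrings::readDNAStringSet(genome))
  }
  if (is.character(genome)) {
    if (is.null(names(genome))) abort("genome sequences must be named")
    return(Biostrings::DNAStringSet(toupper(genome)))
  }
  abort("genome must be a DNAStringSet, named character vector, or FASTA path")
}

#' GATC restriction-fragment map
#'
#' Tiles each chromosome into the fragments produced by DpnII digestion:
#' internal boundaries sit at every occurrence start of `GATC`
#' (case-insensitive; the site is its own reverse complement, so scanning one
#' strand suffices) and the chromosome ends close the terminal fragments.
#' Fragment `k` spans `[site_k, site_{k+1})`; a site at position 0 produces no
#' empty leading fragment.
#'
#' @param genome A `DNAStringSet`, a named character vector of chromosome
#'   sequences, or a FASTA path.
#' @return A tibble with columns `fragment_id`, `chrom`, `start`, `end`
#'   (0-based half-open), tiling every chromosome exactly.
#' @examples
#' gatc_fragment_map(c(chr1 = "AAAGATCAAAAAGATCAAA"))  # [0,3) [3,12) [12,19)
#' @export
gatc_fragment_map <- function(genome) {
  dna <- as_dna(genome)
  if (length(dna) == 0 || any(Biostrings::width(dna) == 0)) {
    abort("empty sequence in genome")
  }
  per_chrom <- purrr::imap(as.list(dna), function(seq, chrom) {
    L <- length(seq)
    sites <- Biostrings::start(Biostrings::matchPattern("GATC", seq))
    bounds <- unique(c(0L, sites - 1L, L))  # to 0-based starts
    bounds <- sort(bounds[bounds < L])
    tibble::tibble(chrom = chrom, start = bounds,
                   end = c(bounds[-1], L))
  })
  out <- dplyr::bind_rows(per_chrom)
  out$fragment_id <- sprintf("%s:%d-%d", out$chrom, out$start, out$end)
  dplyr::select(out, "fragment_id", "chrom", "start", "end")
}

#' Assign intervals to GATC fragments and count
#'
#' Each interval is credited to the fragment containing its 5' start
#' coordinate — DamID fragments begin at GATC cuts, so the 5' end carries the
#' signal — regardless of where it ends. Intervals on chromosomes absent from
#' the map are tallied under the `"unassigned"` id and reported with a
#' message.
#'
#' @param intervals A tibble of aligned intervals with columns `chrom`,
#'   `start`, `end` (0-based half-open) and `sample`.
#' @param map A fragment map from [gatc_fragment_map()].
#' @return A tibble with `fragment_id` (every map fragment, plus
#'   `"unassigned"` if needed) and one count column per sample.
#' @export
count_fragments <- function(intervals, map) {
  stopifnot(all(c("chrom", "start", "end", "sample") %in% names(intervals)))
  samples <- unique(intervals$sample)
  if (nrow(intervals) == 0) samples <- character(0)

  frag_of <- rep(NA_character_, nrow(intervals))
  for (ch in unique(intervals$chrom)) {
    rows <- which(intervals$chrom == ch)
    frs <- map[map$chrom == ch, , drop = FALSE]
    if (nrow(frs) == 0) next
    pos <- intervals$start[rows]
    idx <- findInterval(pos, frs$start)
    ok <- idx >= 1 & pos < max(frs$end)
    frag_of[rows[ok]] <- frs$fragment_id[idx[ok]]
  }
  n_un <- sum(is.na(frag_of))
  if (n_un > 0) {
    inform(sprintf("%d interval(s) outside the fragment map counted as unassigned", n_un))
    frag_of[is.na(frag_of)] <- "unassigned"
  }

  ids <- map$fragment_id
  if (n_un > 0) ids <- c(ids, "unassigned")
  counts <- matrix(0L, length(ids), max(1L, length(samples)),
                   dimnames = list(ids, if (length(samples)) samples else "sample"))
  if (nrow(intervals) > 0) {
    tab <- table(factor(frag_of, levels = ids),
                 factor(intervals$sample, levels = samples))
    counts <- matrix(as.integer(tab), nrow = length(ids),
                     dimnames = list(ids, samples))
  }
  matrix_to_tibble(counts, id_col = "fragment_id")
}

#' Replicate correlation of fragment profiles
#'
#' Pearson correlation between samples of `log2(normalized count + 1)` across
#' fragments, the usual DamID replicate-consistency check: within-condition
#' pairs should correlate more strongly than fusion-vs-control pairs. Samples
#' with zero variance yield `NA` correlations for their pairs.
#'
#' @param counts Fragment counts (first column `fragment_id`, then samples).
#' @return A symmetric sample-by-sample correlation matrix with unit diagonal.
#' @export
replicate_correlation <- function(counts) {
  m <- as_count_matrix(counts)
  if (ncol(m) < 2) abort("need at least two samples")
  sfv <- .size_factors(m)
  lg <- log2(normalize_counts(m, sfv) + 1)
  sds <- apply(lg, 2, stats::sd)
  r <- suppressWarnings(cor(lg))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- 1
  r
}

#' Call TF-bound fragments from fusion-vs-control counts
#'
#' Runs the negative-binomial Wald engine on fragment counts with the
#' Dam-fusion condition as treatment and Dam-only as control, then applies the
#' one-sided enrichment filter: a fragment is bound when `log2fc` strictly
#' exceeds `min_log2fc` and `padj` is strictly below `padj_max`. Depleted
#' fragments (the mirror-image filter) are reported separately and never enter
#' peaks.
#'
#' @inheritParams nb_wald_test
#' @param counts Fragment counts (first column `fragment_id`, then samples).
#' @param meta Sample metadata with columns `sample` and `condition`
#'   (`"fusion"` or `"dam_only"` by default).
#' @param fusion,dam_only Condition labels.
#' @param min_log2fc Enrichment floor (default 1, strict).
#' @param padj_max FDR ceiling (default 0.01, strict).
#' @return A `damid_binding` object; [tidy()] gives the per-fragment test
#'   table with a logical `significant` column, `$significant` the bound
#'   fragment ids, `$depleted` the significantly depleted ids.
#' @export
call_binding <- function(counts, meta, fusion = "fusion",
                         dam_only = "dam_only", group_col = "condition",
                         min_log2fc = 1, padj_max = 0.01) {
  de <- nb_wald_test(counts, meta, control = dam_only, treatment = fusion,
                     group_col = group_col)
  tab <- de$table |>
    dplyr::rename(fragment_id = "feature_id") |>
    dplyr::mutate(
      significant = !is.na(.data$padj) & .data$log2fc > min_log2fc &
        .data$padj < padj_max,
      depleted = !is.na(.data$padj) & .data$log2fc < -min_log2fc &
        .data$padj < padj_max)
  structure(list(table = tab,
                 significant = tab$fragment_id[tab$significant],
                 depleted = tab$fragment_id[tab$depleted],
                 min_log2fc = min_log2fc,
                 padj_max = padj_max,
                 de = de),
            class = "damid_binding")
}

#' @export
tidy.damid_binding <- function(x, ...) x$table

#' @export
glance.damid_binding <- function(x, ...) {
  tibble::tibble(n_fragments = nrow(x$table),
                 n_significant = length(x$significant),
                 n_depleted = length(x$depleted),
                 min_log2fc = x$min_log2fc,
                 padj_max = x$padj_max)
}

#' @export
print.damid_binding <- function(x, ...) {
  cat(sprintf("<damid_binding> %d fragments, %d enriched (log2fc > %g, padj < %g), %d depleted\n",
              nrow(x$table), length(x$significant), x$min_log2fc,
              x$padj_max, length(x$depleted)))
  invisible(x)
}

#' Merge significant fragments into peaks
#'
#' Maximal runs of significant fragments — allowing up to `max_gap_fragments`
#' non-significant fragments between consecutive members — become one peak.
#' Peak `log2fc` is the count-weighted (base-mean-weighted) mean over member
#' fragments; `min_padj` the smallest member padj.
#'
#' @param binding A `damid_binding` from [call_binding()], or a character
#'   vector of significant fragment ids.
#' @param map The fragment map the ids come from.
#' @param max_gap_fragments Tolerated gap, in fragments (default 0).
#' @return A tibble of peaks: `peak_id`, `chrom`, `start`, `end`,
#'   `n_fragments`, `fragment_ids` (list-column), `log2fc`, `min_padj`.
#' @export
merge_peaks <- function(binding, map, max_gap_fragments = 0) {
  if (inherits(binding, "damid_binding")) {
    sig <- binding$significant
    stats <- binding$table
  } else {
    sig <- binding
    stats <- NULL
  }
  empty <- tibble::tibble(peak_id = character(), chrom = character(),
                          start = integer(), end = integer(),
                          n_fragments = integer(),
                          fragment_ids = list(),
                          log2fc = numeric(), min_padj = numeric())
  if (length(sig) == 0) return(empty)
  if (!all(sig %in% map$fragment_id)) {
    abort("significant fragments must all be present in the map")
  }

  peaks <- list()
  for (ch in unique(map$chrom)) {
    frs <- map[map$chrom == ch, , drop = FALSE]
    is_sig <- frs$fragment_id %in% sig
    if (!any(is_sig)) next
    sig_pos <- which(is_sig)
    brk <- c(TRUE, diff(sig_pos) > max_gap_fragments + 1)
    run <- cumsum(brk)
    for (r in unique(run)) {
      members <- frs[sig_pos[run == r], , drop = FALSE]
      peaks[[length(peaks) + 1]] <- tibble::tibble(
        chrom = ch,
        start = min(members$start),
        end = max(members$end),
        n_fragments = nrow(members),
        fragment_ids = list(members$fragment_id))
    }
  }
  out <- dplyr::bind_rows(peaks) |>
    dplyr::arrange(.data$chrom, .data$start)
  out$peak_id <- sprintf("peak_%d", seq_len(nrow(out)))

  if (!is.null(stats)) {
    agg <- purrr::map(out$fragment_ids, function(ids) {
      s <- stats[match(ids, stats$fragment_id), , drop = FALSE]
      w <- pmax(s$base_mean, .Machine$double.eps)
      tibble::tibble(log2fc = sum(w * s$log2fc) / sum(w),
                     min_padj = min(s$padj, na.rm = TRUE))
    })
    out <- dplyr::bind_cols(out, dplyr::bind_rows(agg))
  } else {
    out$log2fc <- NA_real_
    out$min_padj <- NA_real_
  }
  dplyr::select(out, "peak_id", "chrom", "start", "end", "n_fragments",
                "fragment_ids", "log2fc", "min_padj")
}

#' Assign genes to peaks
#'
#' A gene is assigned to a peak when the peak overlaps the gene span extended
#' by `upstream_bp` on the 5' side of the TSS, strand-aware (upstream is
#' leftward of a plus-strand gene, rightward of a minus-strand gene). A peak
#' may hit several genes and a gene several peaks.
#'
#' @param peaks Peak tibble from [merge_peaks()].
#' @param genes Gene annotation tibble with columns `gene_id`, `chrom`,
#'   `start`, `end` (0-based half-open span), `strand` (`"+"`/`"-"`).
#' @param upstream_bp Upstream extension in bp (default 2000).
#' @return The peak tibble with a `gene_ids` list-column and `n_genes`;
#'   the distinct bound-gene ids are in `attr(, "genes")`.
#' @export
annotate_peaks <- function(peaks, genes, upstream_bp = 2000) {
  stopifnot(all(c("gene_id", "chrom", "start", "end", "strand") %in% names(genes)))
  ext_start <- ifelse(genes$strand == "+",
                      pmax(0L, genes$start - upstream_bp), genes$start)
  ext_end <- ifelse(genes$strand == "+",
                    genes$end, genes$end + upstream_bp)
  if (nrow(peaks) == 0) {
    out <- dplyr::mutate(peaks, gene_ids = list(), n_genes = integer())
    attr(out, "genes") <- character(0)
    return(out)
  }
  off_chrom <- setdiff(peaks$chrom, genes$chrom)
  if (length(off_chrom) > 0) {
    inform(sprintf("peaks on unannotated chromosome(s): %s",
                   paste(off_chrom, collapse = ", ")))
  }
  gr_genes <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(ext_start + 1L, ext_end))
  gr_peaks <- GenomicRanges::GRanges(
    peaks$chrom, IRanges::IRanges(peaks$start + 1L, peaks$end))
  hits <- GenomicRanges::findOverlaps(gr_peaks, gr_genes)
  gene_ids <- vector("list", nrow(peaks))
  for (i in seq_len(nrow(peaks))) gene_ids[[i]] <- character(0)
  if (length(hits) > 0) {
    by_peak <- split(genes$gene_id[S4Vectors::subjectHits(hits)],
                     S4Vectors::queryHits(hits))
    for (q in names(by_peak)) {
      gene_ids[[as.integer(q)]] <- sort(unique(by_peak[[q]]))
    }
  }
  out <- peaks
  out$gene_ids <- gene_ids
  out$n_genes <- lengths(gene_ids)
  attr(out, "genes") <- sort(unique(unlist(gene_ids)))
  out
}
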