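# Degenerate consensus-motif scanning with TSS-relative coordinate reporting.

IUPAC_FROM_SET <- c(A = "A", C = "C", G = "G", T = "T",
                    AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K",
                    ACG = "V", ACT = "H", AGT = "D", CGT = "B", ACGT = "N")

#' Parse a dash/slash consensus motif
#'
#' Consensus strings written position-by-position, dashes between positions
#' and slashes between alternative bases within a position — e.g. the
#' 7-position homeodomain consensus `"T-A/T-A-G-A/C/G-C-G/A/T"` — become an
#' ordered list of allowed-base sets. A bare IUPAC string (no dashes) is also
#' accepted.
#'
#' @param spec Consensus text.
#' @return A `consensus_motif`: list of character vectors of allowed bases,
#'   with the equivalent IUPAC string in `attr(, "iupac")`.
#' @examples
#' parse_consensus("T-A/T-A-G-A/C/G-C-G/A/T")  # IUPAC TWAGVCD
#' @export
parse_consensus <- function(spec) {
  stopifnot(is.character(spec), length(spec) == 1, nzchar(spec))
  iupac_sets <- list(A = "A", C = "C", G = "G", T = "T",
                     M = c("A", "C"), R = c("A", "G"), W = c("A", "T"),
                     S = c("C", "G"), Y = c("C", "T"), K = c("G", "T"),
                     V = c("A", "C", "G"), H = c("A", "C", "T"),
                     D = c("A", "G", "T"), B = c("C", "G", "T"),
                     N = c("A", "C", "G", "T"))
  if (!grepl("-", spec, fixed = TRUE) && !grepl("/", spec, fixed = TRUE)) {
    chars <- strsplit(toupper(spec), "")[[1]]
    bad <- setdiff(chars, names(iupac_sets))
    if (length(bad) > 0) abort(sprintf("invalid IUPAC code: %s", bad[1]))
    sets <- iupac_sets[chars]
  } else {
    tokens <- strsplit(spec, "-", fixed = TRUE)[[1]]
    sets <- lapply(tokens, function(tok) {
      bases <- toupper(strsplit(tok, "/", fixed = TRUE)[[1]])
      bad <- setdiff(bases, c("A", "C", "G", "T"))
      if (length(bad) > 0 || length(bases) == 0) {
        abort(sprintf("invalid base in consensus token '%s'", tok))
      }
      sort(unique(bases))
    })
  }
  names(sets) <- NULL
  iupac <- paste(vapply(sets, function(s)
    IUPAC_FROM_SET[[paste(sort(s), collapse = "")]], character(1)),
    collapse = "")
  structure(sets, class = "consensus_motif", iupac = iupac)
}

#' @export
print.consensus_motif <- function(x, ...) {
  cat(sprintf("<consensus_motif> length %d, IUPAC %s\n",
              length(x), attr(x, "iupac")))
  invisible(x)
}

# Mismatch counts of every window of length m against the position sets.
# seq_chars: uppercase character vector; N (or any non-ACGT) matches nothing.
.window_mismatches <- function(seq_chars, motif) {
  m <- length(motif)
  L <- length(seq_chars)
  n_win <- L - m + 1
  if (n_win < 1) return(integer(0))
  mis <- integer(n_win)
  for (k in seq_len(m)) {
    ok <- seq_chars[k:(k + n_win - 1)] %in% motif[[k]]
    mis <- mis + !ok
  }
  mis
}

# 1-based motif positions violated by the window starting at `at` (1-based).
.mismatch_positions <- function(seq_chars, motif, at) {
  which(!vapply(seq_along(motif), function(k)
    seq_chars[at + k - 1] %in% motif[[k]], logical(1)))
}

#' Scan a sequence for consensus motif hits
#'
#' Every window of motif length, on one or both strands, with at most
#' `max_mismatch` positions violating the consensus is reported. Minus-strand
#' hits are found by scanning the reverse complement and are reported in
#' plus-strand coordinates with `strand = "-"`; their `matched_seq` is given
#' in motif (minus-strand) orientation. `N` (and any other ambiguity code) in
#' the subject matches no motif position. Overlapping hits are all reported;
#' case is ignored.
#'
#' @param sequence A single sequence: character scalar or `DNAString`.
#' @param motif A `consensus_motif` from [parse_consensus()] (or a string,
#'   parsed on the fly).
#' @param max_mismatch Maximum tolerated mismatches (default 0).
#' @param strands `"both"` (default), `"+"` or `"-"`.
#' @param seq_id Sequence id recorded in the output.
#' @return A tibble of hits: `seq_id`, `start`, `end` (0-based half-open,
#'   plus strand), `strand`, `mismatches`, `mismatch_positions` (list-column
#'   of violated 1-based motif positions) and `matched_seq`.
#' @export
scan_motif <- function(sequence, motif, max_mismatch = 0,
                       strands = c("both", "+", "-"), seq_id = "seq") {
  strands <- match.arg(strands)
  if (!inherits(motif, "consensus_motif")) motif <- parse_consensus(motif)
  seq_str <- toupper(as.character(sequence))
  m <- length(motif)
  empty <- tibble::tibble(seq_id = character(), start = integer(),
                          end = integer(), strand = character(),
                          mismatches = integer(), mismatch_positions = list(),
                          matched_seq = character())
  if (nchar(seq_str) < m) return(empty)
  chars <- strsplit(seq_str, "")[[1]]
  L <- length(chars)

  hits <- list()
  if (strands %in% c("both", "+")) {
    mis <- .window_mismatches(chars, motif)
    idx <- which(mis <= max_mismatch)
    if (length(idx) > 0) {
      hits[[length(hits) + 1]] <- tibble::tibble(
        seq_id = seq_id,
        start = idx - 1L, end = idx - 1L + m,
        strand = "+", mismatches = mis[idx],
        mismatch_positions = lapply(idx, function(i)
          .mismatch_positions(chars, motif, i)),
        matched_seq = substring(seq_str, idx, idx + m - 1L))
    }
  }
  if (strands %in% c("both", "-")) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq_str)))
    rc_chars <- strsplit(rc, "")[[1]]
    mis <- .window_mismatches(rc_chars, motif)
    idx <- which(mis <= max_mismatch)
    if (length(idx) > 0) {
      # window [i, i+m) on the revcomp maps to plus coords [L-i-m+1, L-i+1)
      # for 1-based i; in 0-based terms start = L - (i-1) - m.
      hits[[length(hits) + 1]] <- tibble::tibble(
        seq_id = seq_id,
        start = L - (idx - 1L) - m, end = L - (idx - 1L),
        strand = "-", mismatches = mis[idx],
        mismatch_positions = lapply(idx, function(i)
          .mismatch_positions(rc_chars, motif, i)),
        matched_seq = substring(rc, idx, idx + m - 1L))
    }
  }
  if (length(hits) == 0) return(empty)
  dplyr::bind_rows(hits) |>
    dplyr::arrange(.data$start, .data$strand)
}

# Map an absolute 0-based position to the signed 1-based TSS-relative
# convention: +1 is the TSS base, -1 the first upstream base, no zero;
# positive is downstream along the gene's orientation.
.abs_to_rel <- function(pos, tss, gene_strand) {
  if (gene_strand == "+") {
    ifelse(pos >= tss, pos - tss + 1L, pos - tss)
  } else {
    ifelse(pos <= tss, tss - pos + 1L, tss - pos)
  }
}

.rel_to_abs <- function(rel, tss, gene_strand) {
  if (any(rel == 0)) abort("TSS-relative coordinates have no position 0")
  if (gene_strand == "+") {
    ifelse(rel > 0, tss + rel - 1L, tss + rel)
  } else {
    ifelse(rel > 0, tss - rel + 1L, tss - rel)
  }
}

#' TSS-relative coordinates of motif hits
#'
#' Converts absolute hit intervals to the signed convention used for
#' enhancer and motif positions: `+1` is the TSS base, `-1` the first base
#' upstream, there is no position 0, and positive runs downstream along the
#' gene's orientation. Intervals are reported `(rel_start, rel_end)` with
#' `rel_start` the 5'-most and `rel_end` the 3'-most base in gene
#' orientation.
#'
#' @param hits A hit tibble from [scan_motif()] (needs `start`, `end`).
#' @param tss Absolute 0-based position of the gene's TSS base.
#' @param gene_strand `"+"` or `"-"`.
#' @return `hits` with added integer columns `rel_start`, `rel_end`.
#' @export
tss_relative <- function(hits, tss, gene_strand = "+") {
  stopifnot(gene_strand %in% c("+", "-"))
  first <- .abs_to_rel(hits$start, tss, gene_strand)          # leftmost base
  last <- .abs_to_rel(hits$end - 1L, tss, gene_strand)        # rightmost base
  if (gene_strand == "+") {
    hits$rel_start <- as.integer(first)
    hits$rel_end <- as.integer(last)
  } else {
    hits$rel_start <- as.integer(last)
    hits$rel_end <- as.integer(first)
  }
  hits
}

#' Extract an enhancer window in TSS-relative coordinates
#'
#' Returns the sequence of the window `[rel_start, rel_end]` (signed 1-based,
#' no zero, gene orientation) around a gene's TSS, in gene orientation —
#' i.e. reverse-complemented for minus-strand genes. The window length is the
#' number of covered positions: `rel_end - rel_start + 1` when both ends share
#' a sign, one less when the window crosses the TSS (no position 0).
#'
#' @param genome A `DNAStringSet`, named character vector, or FASTA path.
#' @param gene A one-row data frame (or list) with `chrom`, `tss` (absolute
#'   0-based TSS position) and `strand`.
#' @param rel_start,rel_end Signed TSS-relative window bounds, `rel_start <=
#'   rel_end` in gene orientation.
#' @return The window sequence as a character scalar, with the absolute
#'   0-based half-open interval in `attr(, "interval")`.
#' @export
extract_enhancer <- function(genome, gene, rel_start, rel_end) {
  dna <- as_dna(genome)
  if (rel_start > rel_end) abort("rel_start must not exceed rel_end")
  chrom <- as.character(gene$chrom)
  strand <- as.character(gene$strand)
  tss <- as.integer(gene$tss)
  if (!chrom %in% names(dna)) abort(sprintf("chromosome '%s' not in genome", chrom))
  ends <- .rel_to_abs(c(rel_start, rel_end), tss, strand)
  a0 <- min(ends)
  a1 <- max(ends) + 1L  # half-open
  L <- Biostrings::width(dna)[match(chrom, names(dna))]
  if (a0 < 0 || a1 > L) {
    abort(sprintf("window [%d, %d) overflows chromosome %s of length %d",
                  a0, a1, chrom, L))
  }
  s <- as.character(Biostrings::subseq(dna[[chrom]], start = a0 + 1L, end = a1))
  if (strand == "-") {
    s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  structure(s, interval = c(start = a0, end = a1))
}
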