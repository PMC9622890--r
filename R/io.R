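# Format readers and writers. Coordinate conventions: everything internal is
# 0-based half-open; BED and bedGraph share that convention natively; GFF3 is
# 1-based inclusive and converted on ingest/egress. Files written here carry
# a '#'-prefixed header line stating the convention where coordinates appear.

#' Read and write FASTA
#'
#' Thin wrappers over the Biostrings readers/writers; sequences are returned
#' as (and accepted from) named character vectors, 60-column wrapped on
#' output.
#'
#' @param path File path.
#' @param sequences Named character vector of sequences.
#' @return `read_fasta()`: a named character vector.
#' @export
read_fasta <- function(path) {
  dna <- Biostrings::readDNAStringSet(path)
  setNames(as.character(dna), names(dna))
}

#' @rdname read_fasta
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path,
                              width = 60L)
  invisible(path)
}

#' Read and write gene annotation
#'
#' `read_gff3()` ingests gene records from a GFF3 file (1-based inclusive)
#' and converts them to the internal 0-based half-open convention, deriving
#' the TSS from the strand (`start` for `+`, `end` for `-`). `write_gff3()`
#' is its inverse. `read_gene_tsv()`/`write_gene_tsv()` handle the simplified
#' gene table (`gene_id`, `chrom`, `tss`, `strand`, `length`, plus the span),
#' 0-based, with the convention stated in a comment header.
#'
#' @param path File path.
#' @param genes A gene tibble with columns `gene_id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand`, `tss` (0-based TSS position).
#' @return Readers return the gene tibble described above.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) abort("no records in GFF3 file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9)
  if (length(bad) > 0) {
    abort(sprintf("malformed GFF3 record at line %d", bad[1]))
  }
  rec <- purrr::map(fields, function(f) {
    tibble::tibble(chrom = f[1], type = f[3],
                   start1 = as.integer(f[4]), end1 = as.integer(f[5]),
                   strand = f[7], attr = f[9])
  })
  tab <- dplyr::bind_rows(rec) |>
    dplyr::filter(.data$type == "gene")
  id <- stringr::str_match(tab$attr, "ID=([^;]+)")[, 2]
  tibble::tibble(gene_id = id,
                 chrom = tab$chrom,
                 start = tab$start1 - 1L,
                 end = tab$end1,
                 strand = tab$strand,
                 tss = ifelse(tab$strand == "+", tab$start1 - 1L,
                              tab$end1 - 1L),
                 length = tab$end1 - tab$start1 + 1L)
}

#' @rdname read_gff3
#' @export
write_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tdamtargets\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, genes$start + 1L, genes$end, genes$strand,
                     genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname read_gff3
#' @export
read_gene_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(
                    gene_id = "c", chrom = "c", start = "i", end = "i",
                    strand = "c", tss = "i", length = "i"))
}

#' @rdname read_gff3
#' @export
write_gene_tsv <- function(genes, path) {
  con <- file(path, "w")
  writeLines("# coordinates 0-based half-open; tss = 0-based TSS position", con)
  close(con)
  readr::write_tsv(genes, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read and write BED intervals
#'
#' Three- to six-column BED, 0-based half-open, tab-separated, no header.
#'
#' @param path File path.
#' @param intervals Tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`.
#' @return `read_bed()`: a tibble with the columns present in the file.
#' @export
read_bed <- function(path) {
  cols <- c("chrom", "start", "end", "name", "score", "strand")
  tab <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE)
  if (ncol(tab) < 3) abort("BED needs at least 3 columns")
  names(tab) <- cols[seq_len(min(ncol(tab), 6))]
  tab$start <- as.integer(tab$start)
  tab$end <- as.integer(tab$end)
  tab
}

#' @rdname read_bed
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(intervals))
  readr::write_tsv(intervals[cols], path, col_names = FALSE)
  invisible(path)
}

#' Read and write counts tables
#'
#' Counts TSVs have the feature id in the first column and one integer column
#' per sample. `write_table()` is the shared table writer: numeric columns
#' are rounded to `digits` significant digits unless `digits = NA` (full
#' precision).
#'
#' @param path File path.
#' @param counts,x A tibble.
#' @param digits Significant digits for numeric columns (`NA` = full).
#' @return `read_counts_tsv()`: a tibble.
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' @rdname read_counts_tsv
#' @export
write_table <- function(x, path, digits = 6) {
  if (!is.na(digits)) {
    x <- dplyr::mutate(x, dplyr::across(
      dplyr::where(is.double), ~ signif(.x, digits)))
  }
  x <- dplyr::mutate(x, dplyr::across(
    dplyr::where(is.list), ~ vapply(.x, paste, character(1), collapse = ",")))
  readr::write_tsv(x, path)
  invisible(path)
}

#' Read and write GMT gene sets
#'
#' One set per line: name, description, then member genes, tab-separated.
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @return `read_gmt()`: a named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  if (length(bad) > 0) abort(sprintf("malformed GMT record at line %d", bad[1]))
  setNames(lapply(fields, function(f) f[-(1:2)]),
           vapply(fields, `[[`, character(1), 1))
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a bedGraph track
#'
#' Four columns (`chrom`, `start`, `end`, `value`), 0-based half-open.
#'
#' @param intervals Tibble with `chrom`, `start`, `end`.
#' @param values Numeric signal per interval.
#' @param path File path.
#' @export
write_bedgraph <- function(intervals, values, path) {
  stopifnot(nrow(intervals) == length(values))
  readr::write_tsv(tibble::tibble(chrom = intervals$chrom,
                                  start = intervals$start,
                                  end = intervals$end,
                                  value = signif(values, 6)),
                   path, col_names = FALSE)
  invisible(path)
}
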