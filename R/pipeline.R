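# The umbrella pipeline: joint synthetic inputs, stage execution in
# dependency order, per-stage manifests, deterministic output tables.

#' Jointly simulate expression, genome and DamID data with linked truth
#'
#' Runs the four generators under one configuration and links their gene
#' namespaces: the toy genome's annotated genes are renamed to genes of the
#' expression simulation — some planted-down, some planted-up, the rest
#' unaffected, all drawn from the well-expressed stratum (baseline above
#' `min_baseline_rpkm`) so that binding and expression evidence can be
#' intersected meaningfully. Every annotated gene receives at least one
#' planted bound fragment near its TSS (given enough plants), so the truth
#' target set is `mapped planted-DE genes` exactly.
#'
#' @param config A [sim_config()].
#' @param n_down_genes,n_up_genes How many toy-genome genes map to
#'   planted-down / planted-up expression genes; by default half and a tenth
#'   of the genome's genes (10 and 2 of the default 20).
#' @param min_baseline_rpkm Expression floor for mapped genes (default 20).
#' @return A list: `celltype`, `depletion`, `genome`, `damid` (the four
#'   generator outputs, genome genes renamed), `genes` (renamed annotation)
#'   and `truth` (mapped down/up/null gene ids and the expected target set).
#' @export
simulate_joint <- function(config = sim_config(), n_down_genes = NULL,
                           n_up_genes = NULL, min_baseline_rpkm = 20) {
  cfg <- config
  cc <- simulate_celltype_counts(cfg)
  dep <- simulate_depletion_experiment(cc, cfg)
  gen <- simulate_genome_with_motifs(cfg)

  set.seed(cfg$seed + 4000L)
  n_gg <- nrow(gen$genes)
  n_down_genes <- n_down_genes %||% max(1L, round(0.5 * n_gg))
  n_up_genes <- n_up_genes %||% max(1L, round(0.1 * n_gg))
  if (n_down_genes + n_up_genes > n_gg) {
    abort("more mapped DE genes requested than toy-genome genes")
  }
  expressed <- names(cc$truth$baseline_rpkm)[
    cc$truth$baseline_rpkm >= min_baseline_rpkm]
  down_pool <- intersect(dep$truth$planted_down, expressed)
  up_pool <- intersect(dep$truth$planted_up, expressed)
  null_pool <- setdiff(expressed,
                       c(unlist(dep$truth$markers), dep$truth$planted_up))
  n_null <- n_gg - n_down_genes - n_up_genes
  if (length(down_pool) < n_down_genes || length(up_pool) < n_up_genes ||
      length(null_pool) < n_null) {
    abort("not enough well-expressed genes to map onto the toy genome")
  }
  mapped <- sample(c(sample(down_pool, n_down_genes),
                     sample(up_pool, n_up_genes),
                     sample(null_pool, n_null)))

  rename <- setNames(mapped, gen$genes$gene_id)
  genes <- gen$genes
  genes$gene_id <- unname(rename[genes$gene_id])
  gen$genes <- genes
  gen$truth$planted_motifs$gene_id <-
    unname(rename[gen$truth$planted_motifs$gene_id])

  dam <- simulate_damid(gen$genome, genes, cfg)

  truth <- list(
    mapped_down = intersect(mapped, dep$truth$planted_down),
    mapped_up = intersect(mapped, dep$truth$planted_up),
    mapped_null = setdiff(mapped, c(dep$truth$planted_down,
                                    dep$truth$planted_up)),
    bound_genes = dam$truth$bound_genes,
    expected_targets = sort(intersect(
      dam$truth$bound_genes,
      c(dep$truth$planted_down, dep$truth$planted_up))))

  list(celltype = cc, depletion = dep, genome = gen, damid = dam,
       genes = genes, truth = truth)
}

#' Pipeline configuration
#'
#' All stage parameters with their conventional defaults: the 3.5-RPKM
#' signature floor and top-250 rule; DE thresholds padj < 0.01 and
#' |log2FC| > 0.5; DamID thresholds log2FC > 1 and padj < 0.01 with a 2 kb
#' upstream gene-assignment window; 1000 permutations for GSEA; exact-match
#' motif scanning of the 7-position consensus. Unknown keys are rejected.
#'
#' @param ... Overrides of the defaults listed above.
#' @param sim A [sim_config()] for the synthetic inputs.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(..., sim = sim_config()) {
  defaults <- list(min_rpkm = 3.5, top_n = 250,
                   de_padj = 0.01, de_lfc = 0.5,
                   damid_lfc = 1, damid_padj = 0.01,
                   upstream_bp = 2000, max_gap_fragments = 0,
                   n_perm = 1000, gsea_mode = "auto",
                   consensus = "T-A/T-A-G-A/C/G-C-G/A/T",
                   max_mismatch = 0, motif_window = c(-2500, 2500),
                   digits = 6)
  over <- list(...)
  unknown <- setdiff(names(over), names(defaults))
  if (length(unknown) > 0) {
    abort(sprintf("unknown pipeline parameter(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, over)
  cfg$sim <- sim
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML
#'
#' Top-level keys are pipeline parameters; the optional `sim` block holds
#' [sim_config()] fields.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim %||% list()
  y$sim <- NULL
  do.call(pipeline_config, c(y, list(sim = do.call(sim_config, sim_args))))
}

.manifest <- function(stage, params, inputs, out_dir) {
  hashes <- if (length(inputs) > 0) {
    as.list(tools::md5sum(inputs))
  } else {
    list()
  }
  man <- list(stage = stage,
              parameters = params,
              input_hashes = hashes,
              version = as.character(utils::packageVersion("damtargets")),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(man, file.path(out_dir, sprintf("manifest_%s.json", stage)),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}

#' Run the full analysis pipeline on synthetic inputs
#'
#' Generates the joint synthetic data set, then executes the stages in
#' dependency order — signature scoring, depletion differential expression,
#' signature GSEA, DamID fragment analysis with peak calling and annotation,
#' target integration, and motif scanning of the planted enhancer windows —
#' writing each stage's tables (and a parameter/input-hash manifest) under
#' `out_dir`. Reruns with the same configuration and seed produce
#' byte-identical tables.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory stage results and the
#'   summary written to `summary.json`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(stage, msg) {
    if (!quiet) message(sprintf("[%s] %s", stage, msg))
  }
  dg <- config$digits
  sub <- function(d) {
    p <- file.path(out_dir, d)
    dir.create(p, showWarnings = FALSE)
    p
  }

  # inputs ----
  say("simulate", "generating joint synthetic inputs")
  joint <- simulate_joint(config$sim)
  ind <- sub("inputs")
  write_table(joint$celltype$counts, file.path(ind, "celltype_counts.tsv"), NA)
  write_table(joint$celltype$meta, file.path(ind, "celltype_meta.tsv"), NA)
  write_table(joint$depletion$counts, file.path(ind, "depletion_counts.tsv"), NA)
  write_table(joint$depletion$meta, file.path(ind, "depletion_meta.tsv"), NA)
  write_table(joint$celltype$lengths, file.path(ind, "gene_lengths.tsv"), NA)
  write_fasta(joint$genome$genome, file.path(ind, "genome.fa"))
  write_gff3(joint$genes, file.path(ind, "genes.gff3"))
  write_gene_tsv(joint$genes, file.path(ind, "genes.tsv"))
  write_table(joint$damid$counts, file.path(ind, "damid_counts.tsv"), NA)
  write_table(joint$damid$meta, file.path(ind, "damid_meta.tsv"), NA)
  jsonlite::write_json(
    list(markers = joint$celltype$truth$markers,
         planted_down = joint$depletion$truth$planted_down,
         planted_up = joint$depletion$truth$planted_up,
         bound_fragments = joint$damid$truth$bound_fragments,
         planted_motifs = joint$genome$truth$planted_motifs,
         expected_targets = joint$truth$expected_targets),
    file.path(ind, "truth.json"), auto_unbox = TRUE, pretty = TRUE, digits = NA)
  input_files <- list.files(ind, full.names = TRUE)
  .manifest("simulate", unclass(config$sim), input_files, out_dir)

  # signature ----
  say("signature", "scoring cell-type signatures")
  sd <- sub("signature")
  rp <- rpkm(joint$celltype$counts, joint$celltype$meta,
             joint$celltype$lengths)
  sigs <- score_signatures(rp, min_rpkm = config$min_rpkm,
                           top_n = config$top_n)
  write_table(rp, file.path(sd, "rpkm.tsv"), dg)
  write_table(sigs, file.path(sd, "signatures.tsv"), dg)
  write_gmt(signature_sets(sigs), file.path(sd, "signatures.gmt"))
  .manifest("signature",
            list(min_rpkm = config$min_rpkm, top_n = config$top_n),
            input_files, out_dir)

  # de ----
  say("de", "testing depletion differential expression")
  dd <- sub("de")
  de <- nb_wald_test(joint$depletion$counts, joint$depletion$meta,
                     control = "control", treatment = "knockdown")
  de_calls <- call_de(de, config$de_padj, config$de_lfc)
  write_table(tidy(de), file.path(dd, "de_table.tsv"), dg)
  write_table(de_calls, file.path(dd, "de_calls.tsv"), dg)
  .manifest("de", list(padj = config$de_padj, lfc = config$de_lfc),
            input_files, out_dir)

  # gsea ----
  say("gsea", "running signature GSEA")
  gd <- sub("gsea")
  focal <- config$sim$celltypes[1]
  gres <- permutation_nes(joint$depletion$counts, joint$depletion$meta,
                          signature_sets(sigs),
                          control = "control", treatment = "knockdown",
                          n_perm = config$n_perm, mode = config$gsea_mode,
                          seed = config$sim$seed + 5000L)
  write_table(tidy(gres), file.path(gd, "gsea_results.tsv"), dg)
  for (nm in names(gres$running)) {
    write_table(gres$running[[nm]],
                file.path(gd, sprintf("running_sum_%s.tsv", nm)), dg)
  }
  .manifest("gsea", list(n_perm = config$n_perm, mode = config$gsea_mode),
            input_files, out_dir)

  # damid ----
  say("damid", "calling DamID binding and peaks")
  md <- sub("damid")
  binding <- call_binding(joint$damid$counts, joint$damid$meta,
                          min_log2fc = config$damid_lfc,
                          padj_max = config$damid_padj)
  peaks <- merge_peaks(binding, joint$damid$map,
                       max_gap_fragments = config$max_gap_fragments)
  peaks <- annotate_peaks(peaks, joint$genes,
                          upstream_bp = config$upstream_bp)
  corr <- replicate_correlation(joint$damid$counts)
  write_table(joint$damid$map |>
                dplyr::select("chrom", "start", "end",
                              name = "fragment_id"),
              file.path(md, "fragment_map.bed"), NA)
  write_table(tidy(binding), file.path(md, "fragment_results.tsv"), dg)
  write_table(peaks, file.path(md, "peaks.tsv"), dg)
  write_bed(dplyr::select(peaks, "chrom", "start", "end", name = "peak_id"),
            file.path(md, "peaks.bed"))
  write_table(matrix_to_tibble(corr, id_col = "sample"),
              file.path(md, "correlation.tsv"), dg)
  cm <- as_count_matrix(joint$damid$counts)
  norm <- normalize_counts(cm, .size_factors(cm))
  for (s in colnames(norm)) {
    write_bedgraph(joint$damid$map, norm[, s],
                   file.path(md, sprintf("signal_%s.bedGraph", s)))
  }
  .manifest("damid",
            list(min_log2fc = config$damid_lfc, padj_max = config$damid_padj,
                 max_gap_fragments = config$max_gap_fragments,
                 upstream_bp = config$upstream_bp),
            input_files, out_dir)

  # integrate ----
  say("integrate", "intersecting binding with expression")
  it <- sub("integrate")
  targets <- call_targets(peaks, de, padj_max = config$de_padj,
                          min_abs_log2fc = config$de_lfc)
  ranked <- rank_genes(de)
  focal_sig <- sigs$gene_id[sigs$celltype == focal]
  overlap <- signature_overlap(targets, focal_sig, ranked,
                               n_perm = config$n_perm,
                               seed = config$sim$seed + 6000L)
  write_table(tidy(targets), file.path(it, "targets.tsv"), dg)
  summary_counts <- glance(targets)
  jsonlite::write_json(
    c(as.list(summary_counts),
      list(signature_overlap = overlap$overlap,
           signature_down_fraction = overlap$down_fraction)),
    file.path(it, "summary.json"), auto_unbox = TRUE, pretty = TRUE,
    digits = NA)
  .manifest("integrate",
            list(padj = config$de_padj, lfc = config$de_lfc),
            input_files, out_dir)

  # motif ----
  say("motif", "scanning enhancer windows for the consensus")
  od <- sub("motif")
  hits <- purrr::map_dfr(seq_len(nrow(joint$genes)), function(i) {
    g <- joint$genes[i, ]
    win <- extract_enhancer(joint$genome$genome, g,
                            config$motif_window[1], config$motif_window[2])
    h <- scan_motif(win, config$consensus,
                    max_mismatch = config$max_mismatch, seq_id = g$gene_id)
    if (nrow(h) == 0) return(h)
    # hit coordinates within the window -> absolute and TSS-relative
    iv <- attr(win, "interval")
    if (g$strand == "+") {
      abs_start <- iv["start"] + h$start
    } else {
      abs_start <- iv["end"] - h$end
      h$strand <- ifelse(h$strand == "+", "-", "+")  # back to genome strand
    }
    h$start <- as.integer(abs_start)
    h$end <- h$start + nchar(h$matched_seq)
    tss_relative(h, g$tss, g$strand)
  })
  write_table(hits, file.path(od, "motif_hits.tsv"), dg)
  if (nrow(hits) > 0) {
    write_bed(tibble::tibble(chrom = "chr1", start = hits$start,
                             end = hits$end, name = hits$seq_id,
                             score = hits$mismatches, strand = hits$strand),
              file.path(od, "motif_hits.bed"))
  }
  .manifest("motif",
            list(consensus = config$consensus,
                 max_mismatch = config$max_mismatch,
                 window = config$motif_window),
            input_files, out_dir)

  summary <- list(
    n_signature_genes = nrow(sigs),
    n_de_up = sum(de_calls$direction == "up"),
    n_de_down = sum(de_calls$direction == "down"),
    gsea = as.list(tidy(gres)[tidy(gres)$set == focal,
                              c("es", "nes", "pvalue")]),
    n_significant_fragments = length(binding$significant),
    n_peaks = nrow(peaks),
    n_bound_genes = length(attr(peaks, "genes")),
    n_targets = summary_counts$n_targets,
    n_down_targets = summary_counts$n_down,
    signature_overlap = overlap$overlap,
    n_motif_hits = nrow(hits))
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("done", sprintf("outputs in %s", out_dir))
  invisible(list(joint = joint, rpkm = rp, signatures = sigs, de = de,
                 gsea = gres, binding = binding, peaks = peaks,
                 targets = targets, overlap = overlap, motif_hits = hits,
                 summary = summary))
}
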