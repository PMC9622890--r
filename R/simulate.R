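# Seeded synthetic-data generators emulating the study design: three
# cell-type bulk transcriptomes with planted markers, a control-vs-knockdown
# depletion experiment in the EE type, a toy genome with planted consensus
# motifs near annotated TSSs, and a fusion-vs-Dam-only DamID experiment with
# planted bound fragments. Every generator records ground truth sufficient to
# score downstream callers, and a fixed seed gives byte-identical reruns.

#' Simulation configuration
#'
#' Collects the knobs of all four generators with the study-design defaults:
#' three cell types ("EE", "progenitor", "EC") with three replicates each,
#' 200 planted markers per type at 8-fold enrichment; a 3-vs-3
#' control/knockdown experiment in which 80% of the EE markers are depleted
#' 4-fold and a 5% minority of non-marker genes rises 4-fold; a 1 Mb
#' single-chromosome toy genome; a 2-fusion-vs-3-control DamID design with
#' 100 bound fragments at 8-fold enrichment.
#'
#' Baseline expression is log-normal on an RPKM-like scale
#' (`meanlog = 4`, `sdlog = 1.5`, spanning the 3.5-RPKM signature filter) and
#' converted to expected counts through gene length and library size; counts
#' are negative-binomial with variance `mu + alpha * mu^2`.
#'
#' @param n_genes Number of genes.
#' @param celltypes Cell-type labels; the first is the focal (EE-like) type.
#' @param replicates_per_group Replicates per cell type and per
#'   control/knockdown group.
#' @param markers_per_type Planted markers per cell type.
#' @param marker_fold Expression fold of a marker in its own type (> 1, or 1
#'   for a null simulation).
#' @param depletion_fraction Fraction of focal-type markers down-regulated in
#'   the knockdown.
#' @param depletion_fold Fold reduction of depleted genes (true log2FC is
#'   `-log2(depletion_fold)`).
#' @param up_fraction,up_fold Minority of non-marker genes up-regulated in
#'   the knockdown, and their fold.
#' @param nb_dispersion NB dispersion `alpha` (0 gives Poisson counts).
#' @param library_size_mean Expected per-sample sequencing depth.
#' @param chrom_length Toy chromosome length in bp.
#' @param n_genome_genes Genes annotated on the toy genome.
#' @param n_bound_fragments Planted TF-bound GATC fragments.
#' @param damid_enrichment Fusion-over-control fold of bound fragments.
#' @param fusion_reps,control_reps DamID replicate structure (2 vs 3 by
#'   default, the study design).
#' @param fragment_mean Mean baseline count per fragment.
#' @param seed Integer seed; all generators derive their streams from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 5000,
                       celltypes = c("EE", "progenitor", "EC"),
                       replicates_per_group = 3,
                       markers_per_type = 200,
                       marker_fold = 8,
                       depletion_fraction = 0.8,
                       depletion_fold = 4,
                       up_fraction = 0.05,
                       up_fold = 4,
                       nb_dispersion = 0.05,
                       library_size_mean = 5e6,
                       chrom_length = 1e6,
                       n_genome_genes = 20,
                       n_bound_fragments = 100,
                       damid_enrichment = 8,
                       fusion_reps = 2,
                       control_reps = 3,
                       fragment_mean = 50,
                       seed = 1) {
  cfg <- list(
    n_genes = check_positive_int(n_genes, "n_genes"),
    celltypes = as.character(celltypes),
    replicates_per_group = check_positive_int(replicates_per_group,
                                              "replicates_per_group"),
    markers_per_type = check_positive_int(markers_per_type, "markers_per_type"),
    marker_fold = marker_fold,
    depletion_fraction = check_fraction(depletion_fraction, "depletion_fraction"),
    depletion_fold = depletion_fold,
    up_fraction = check_fraction(up_fraction, "up_fraction"),
    up_fold = up_fold,
    nb_dispersion = nb_dispersion,
    library_size_mean = library_size_mean,
    chrom_length = check_positive_int(chrom_length, "chrom_length"),
    n_genome_genes = check_positive_int(n_genome_genes, "n_genome_genes"),
    n_bound_fragments = check_positive_int(n_bound_fragments,
                                           "n_bound_fragments"),
    damid_enrichment = damid_enrichment,
    fusion_reps = check_positive_int(fusion_reps, "fusion_reps"),
    control_reps = check_positive_int(control_reps, "control_reps"),
    fragment_mean = fragment_mean,
    seed = check_positive_int(seed, "seed", min = 0))
  if (length(cfg$celltypes) < 2) abort("need at least two cell types")
  for (f in c("marker_fold", "depletion_fold", "up_fold", "damid_enrichment")) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] < 1) {
      abort(sprintf("`%s` must be >= 1", f))
    }
  }
  if (cfg$nb_dispersion < 0) abort("`nb_dispersion` must be >= 0")
  if (cfg$library_size_mean <= 0 || cfg$fragment_mean <= 0) {
    abort("library_size_mean and fragment_mean must be positive")
  }
  structure(cfg, class = "sim_config")
}

# NB draw that degrades gracefully to Poisson at alpha = 0.
rnb <- function(n, mu, alpha) {
  if (alpha <= 0) stats::rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / alpha)
}

# Shared gene-level baseline: ids, lengths (log-uniform 500-10,000 bp),
# RPKM-scale abundances, and disjoint planted marker sets per cell type.
.gene_baseline <- function(cfg) {
  n <- cfg$n_genes
  if (cfg$markers_per_type * length(cfg$celltypes) > n) {
    abort("markers_per_type x n_celltypes exceeds n_genes")
  }
  ids <- sprintf("g%05d", seq_len(n))
  lengths <- round(exp(runif(n, log(500), log(10000))))
  rpkm0 <- rlnorm(n, meanlog = 4, sdlog = 1.5)
  pool <- sample(ids, cfg$markers_per_type * length(cfg$celltypes))
  markers <- split(pool, rep(cfg$celltypes, each = cfg$markers_per_type))
  list(ids = ids, lengths = setNames(lengths, ids),
       rpkm0 = setNames(rpkm0, ids), markers = markers[cfg$celltypes])
}

# Expected count for a gene at rpkm-scale abundance x, given length and depth.
.expected_counts <- function(rpkm, lengths, lib_size) {
  rpkm * lengths * lib_size / 1e9
}

#' Simulate three cell-type transcriptomes with planted markers
#'
#' Gene baselines are drawn log-normally on an RPKM-like scale; each cell
#' type's samples draw negative-binomial counts around cell-type-specific
#' means, where a planted marker of type `t` has its mean multiplied by
#' `marker_fold` in type `t` only. Gene lengths are attached for RPKM
#' computation. `marker_fold = 1` gives the null: truth still records the
#' marker sets but no gene is enriched beyond noise.
#'
#' @param config A [sim_config()].
#' @return A list: `counts` (tibble, `gene_id` + one column per sample),
#'   `meta` (`sample`, `celltype`, `replicate`), `lengths` (tibble
#'   `gene_id`, `length`), and `truth` (planted marker sets, baseline
#'   abundances, config echo).
#' @export
simulate_celltype_counts <- function(config = sim_config()) {
  cfg <- config
  set.seed(cfg$seed)
  base <- .gene_baseline(cfg)

  samples <- as.vector(t(outer(cfg$celltypes,
                               seq_len(cfg$replicates_per_group),
                               function(ct, r) paste0(ct, "_", r))))
  types <- rep(cfg$celltypes, each = cfg$replicates_per_group)
  lib <- cfg$library_size_mean * rlnorm(length(samples), 0, 0.1)

  counts <- matrix(0L, cfg$n_genes, length(samples),
                   dimnames = list(base$ids, samples))
  for (j in seq_along(samples)) {
    fold <- rep(1, cfg$n_genes)
    mk <- base$markers[[types[j]]]
    fold[match(mk, base$ids)] <- cfg$marker_fold
    mu <- .expected_counts(base$rpkm0 * fold, base$lengths, lib[j])
    counts[, j] <- rnb(cfg$n_genes, mu, cfg$nb_dispersion)
  }

  list(counts = matrix_to_tibble(counts, id_col = "gene_id"),
       meta = tibble::tibble(sample = samples, celltype = types,
                             replicate = rep(seq_len(cfg$replicates_per_group),
                                             times = length(cfg$celltypes))),
       lengths = tibble::tibble(gene_id = base$ids,
                                length = unname(base$lengths)),
       truth = list(markers = base$markers,
                    baseline_rpkm = base$rpkm0,
                    gene_lengths = base$lengths,
                    config = cfg))
}

#' Simulate the control-vs-knockdown depletion experiment
#'
#' Draws two groups of focal-type (EE-like) samples. In the knockdown group a
#' `depletion_fraction` of the focal type's planted markers have their means
#' divided by `depletion_fold`, and an `up_fraction` of non-marker genes have
#' theirs multiplied by `up_fold` — emulating a knockdown that collapses the
#' cell type's identity program while a minority of genes responds in the
#' opposite direction. True log2 fold changes are recorded in the truth.
#'
#' @param base Output of [simulate_celltype_counts()] supplying the gene
#'   baseline and marker truth; generated internally (same config) if `NULL`.
#' @param config A [sim_config()].
#' @return A list: `counts`, `meta` (`sample`, `group`, `replicate`),
#'   `lengths` and `truth` (`planted_down`, `planted_up` with true log2FCs,
#'   marker sets, config echo).
#' @export
simulate_depletion_experiment <- function(base = NULL, config = sim_config()) {
  cfg <- config
  if (is.null(base)) base <- simulate_celltype_counts(cfg)
  set.seed(cfg$seed + 1000L)

  focal <- cfg$celltypes[1]
  ids <- base$truth$config$n_genes
  gene_ids <- base$lengths$gene_id
  rpkm0 <- base$truth$baseline_rpkm
  lengths <- base$truth$gene_lengths
  markers <- base$truth$markers[[focal]]

  # Focal-type baseline: markers of the focal type are high in these cells.
  fold_base <- rep(1, length(gene_ids))
  fold_base[match(markers, gene_ids)] <- cfg$marker_fold

  n_down <- round(cfg$depletion_fraction * length(markers))
  planted_down <- if (n_down > 0) sample(markers, n_down) else character(0)
  non_marker <- setdiff(gene_ids, unlist(base$truth$markers))
  n_up <- round(cfg$up_fraction * length(non_marker))
  planted_up <- if (n_up > 0) sample(non_marker, n_up) else character(0)

  fold_kd <- fold_base
  fold_kd[match(planted_down, gene_ids)] <-
    fold_kd[match(planted_down, gene_ids)] / cfg$depletion_fold
  fold_kd[match(planted_up, gene_ids)] <-
    fold_kd[match(planted_up, gene_ids)] * cfg$up_fold

  groups <- c("control", "knockdown")
  samples <- as.vector(t(outer(groups, seq_len(cfg$replicates_per_group),
                               paste, sep = "_")))
  grp <- rep(groups, each = cfg$replicates_per_group)
  lib <- cfg$library_size_mean * rlnorm(length(samples), 0, 0.1)

  counts <- matrix(0L, length(gene_ids), length(samples),
                   dimnames = list(gene_ids, samples))
  for (j in seq_along(samples)) {
    fold <- if (grp[j] == "control") fold_base else fold_kd
    mu <- .expected_counts(rpkm0 * fold, lengths, lib[j])
    counts[, j] <- rnb(length(gene_ids), mu, cfg$nb_dispersion)
  }

  list(counts = matrix_to_tibble(counts, id_col = "gene_id"),
       meta = tibble::tibble(sample = samples, group = grp,
                             replicate = rep(seq_len(cfg$replicates_per_group),
                                             times = 2)),
       lengths = base$lengths,
       truth = list(planted_down = sort(planted_down),
                    planted_up = sort(planted_up),
                    true_log2fc_down = -log2(cfg$depletion_fold),
                    true_log2fc_up = log2(cfg$up_fold),
                    markers = base$truth$markers,
                    config = cfg))
}

# A random consensus word: one allowed base per position.
.consensus_word <- function(motif) {
  paste(vapply(motif, function(s) sample(s, 1), character(1)), collapse = "")
}

.revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

#' Simulate a toy genome with planted consensus motifs
#'
#' A random-base chromosome (GATC sites occur naturally, about every 256 bp)
#' with `n_genome_genes` genes annotated with TSS and strand, and exact
#' consensus-matching 7-mers planted at recorded TSS-relative positions on
#' both strands. Background within each planted gene's scan window is cleared
#' of accidental 0-mismatch consensus matches by rejection sampling, so the
#' planted hits are the only exact hits in those windows.
#'
#' @param config A [sim_config()].
#' @param consensus Consensus to plant (default the 7-position homeodomain
#'   motif `"T-A/T-A-G-A/C/G-C-G/A/T"`).
#' @param plant_positions TSS-relative start positions of the plants, cycled
#'   with alternating genome strand over the planted genes. The defaults
#'   reuse the enhancer-motif offsets reported for the NPF and CCHa1 loci
#'   (-1595, -1471, +1734).
#' @param n_planted_genes How many genes receive one plant each (default 6).
#' @param scan_window Half-width in bp of the TSS-centered window kept free
#'   of accidental exact matches (default 2500).
#' @return A list: `genome` (named character), `genes` (tibble `gene_id`,
#'   `chrom`, `start`, `end`, `strand`, `tss`, `length`; 0-based half-open,
#'   `tss` the 0-based TSS base), and `truth$planted_motifs` (tibble
#'   `gene_id`, `rel_start`, `rel_end`, `strand`, `word`, `abs_start`).
#' @export
simulate_genome_with_motifs <- function(config = sim_config(),
                                        consensus = "T-A/T-A-G-A/C/G-C-G/A/T",
                                        plant_positions = c(-1595L, -1471L, 1734L),
                                        n_planted_genes = 6,
                                        scan_window = 2500) {
  cfg <- config
  set.seed(cfg$seed + 2000L)
  motif <- parse_consensus(consensus)
  m <- length(motif)
  L <- cfg$chrom_length
  n_genes <- cfg$n_genome_genes
  n_planted_genes <- min(n_planted_genes, n_genes)
  if (scan_window < max(abs(plant_positions)) + m) {
    abort("scan window too small for the requested plant positions")
  }

  chars <- sample(c("A", "C", "G", "T"), L, replace = TRUE)

  # Genes on an even grid with jitter; strands alternate. Keep a margin so
  # TSS-relative windows stay on-chromosome.
  margin <- scan_window + 1000L
  grid <- round(seq(margin, L - margin, length.out = n_genes))
  tss <- as.integer(grid + sample(-200:200, n_genes, replace = TRUE))
  strand <- rep(c("+", "-"), length.out = n_genes)
  glen <- as.integer(round(runif(n_genes, 2000, 8000)))
  start <- ifelse(strand == "+", tss, pmax(0L, tss - glen + 1L))
  end <- ifelse(strand == "+", pmin(L, tss + glen), tss + 1L)
  genes <- tibble::tibble(gene_id = sprintf("gene%03d", seq_len(n_genes)),
                          chrom = "chr1",
                          start = as.integer(start), end = as.integer(end),
                          strand = strand, tss = tss, length = glen)

  planted_rows <- seq_len(n_planted_genes)
  plants <- tibble::tibble(
    gene_id = genes$gene_id[planted_rows],
    rel_start = rep(as.integer(plant_positions),
                    length.out = n_planted_genes),
    strand = rep(c("+", "-"), length.out = n_planted_genes))
  plants$rel_end <- plants$rel_start + m - 1L +
    ifelse(plants$rel_start < 0 & plants$rel_start + m - 1L >= 0, 1L, 0L)

  # Absolute plus-strand 0-based start of each plant, along gene orientation.
  plants$abs_start <- vapply(seq_len(nrow(plants)), function(i) {
    g <- genes[planted_rows[i], ]
    pos <- .rel_to_abs(c(plants$rel_start[i], plants$rel_end[i]),
                       g$tss, g$strand)
    as.integer(min(pos))
  }, integer(1))

  win_of <- function(g) {
    lo <- max(0L, g$tss - as.integer(scan_window))
    hi <- min(L, g$tss + as.integer(scan_window) + 1L)
    c(lo, hi)
  }

  # Rejection-sample the background of each planted gene's window until no
  # exact consensus match remains (the plants are written afterwards and
  # rechecked, so boundary effects cannot reintroduce hits).
  write_plants <- function(chars) {
    for (i in seq_len(nrow(plants))) {
      word <- plants$word[i]
      if (plants$strand[i] == "-") word <- .revcomp_chr(word)
      a <- plants$abs_start[i]
      chars[(a + 1):(a + m)] <- strsplit(word, "")[[1]]
    }
    chars
  }
  plants$word <- vapply(seq_len(nrow(plants)), function(i)
    .consensus_word(motif), character(1))

  for (i in planted_rows) {
    g <- genes[i, ]
    w <- win_of(g)
    for (iter in 1:100) {
      seg <- paste(chars[(w[1] + 1):w[2]], collapse = "")
      hits <- scan_motif(seg, motif, max_mismatch = 0)
      if (nrow(hits) == 0) break
      bad <- unique(unlist(purrr::map2(hits$start, hits$end,
                                       function(s, e) (s + 1):e)))
      chars[w[1] + bad] <- sample(c("A", "C", "G", "T"), length(bad),
                                  replace = TRUE)
      if (iter == 100) abort("failed to clear accidental motif matches")
    }
  }
  chars <- write_plants(chars)
  # Verify: each planted window now contains exactly the planted hits.
  for (i in planted_rows) {
    g <- genes[i, ]
    w <- win_of(g)
    seg <- paste(chars[(w[1] + 1):w[2]], collapse = "")
    hits <- scan_motif(seg, motif, max_mismatch = 0)
    own <- plants$abs_start[plants$gene_id == g$gene_id] - w[1]
    extra <- setdiff(hits$start, own)
    for (iter in 1:100) {
      if (length(extra) == 0) break
      bad <- unique(unlist(lapply(extra, function(s) (s + 1):(s + m))))
      bad <- setdiff(bad, unlist(lapply(own, function(s) (s + 1):(s + m))))
      chars[w[1] + bad] <- sample(c("A", "C", "G", "T"), length(bad),
                                  replace = TRUE)
      seg <- paste(chars[(w[1] + 1):w[2]], collapse = "")
      hits <- scan_motif(seg, motif, max_mismatch = 0)
      extra <- setdiff(hits$start, own)
      if (iter == 100) abort("failed to clear accidental motif matches")
    }
  }

  genome <- setNames(paste(chars, collapse = ""), "chr1")
  list(genome = genome,
       genes = genes,
       truth = list(planted_motifs = dplyr::select(
         plants, "gene_id", "rel_start", "rel_end", "strand", "word",
         "abs_start"),
         consensus = attr(motif, "iupac"),
         config = cfg))
}

#' Simulate a DamID fragment-count experiment
#'
#' Builds the GATC fragment map of the toy genome, draws a shared
#' accessibility-like baseline per fragment, and simulates fusion
#' (`fusion_reps`) versus Dam-only (`control_reps`) samples. Planted bound
#' fragments — chosen preferentially among fragments near annotated TSSs —
#' have their fusion-condition means multiplied by `damid_enrichment`.
#' `damid_enrichment = 1` makes the two conditions exchangeable.
#'
#' @param genome,genes Output of [simulate_genome_with_motifs()] (or any
#'   genome + gene annotation of the same shape).
#' @param config A [sim_config()].
#' @param prefer_tss_bp Fragments whose start lies within this distance of an
#'   annotated TSS are preferred when planting bound fragments (default 1000).
#' @return A list: `counts` (tibble, `fragment_id` + samples), `meta`
#'   (`sample`, `condition`, `replicate`), `map` (the fragment map), and
#'   `truth` (`bound_fragments`, `enrichment`, `bound_genes`, config echo).
#' @export
simulate_damid <- function(genome, genes, config = sim_config(),
                           prefer_tss_bp = 1000) {
  cfg <- config
  set.seed(cfg$seed + 3000L)
  map <- gatc_fragment_map(genome)
  n_frag <- nrow(map)
  if (cfg$n_bound_fragments > n_frag) {
    abort("requested more bound fragments than fragments available")
  }

  near_tss <- purrr::map(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    which(map$chrom == g$chrom &
            map$start >= g$tss - prefer_tss_bp &
            map$start <= g$tss + prefer_tss_bp)
  })
  # One TSS-proximal fragment per gene first (so every annotated gene is
  # covered when enough plants are requested), then more TSS-proximal
  # fragments, then anywhere.
  per_gene <- unlist(purrr::map(near_tss, function(ix)
    if (length(ix) > 0) sample(ix, 1) else integer(0)))
  per_gene <- unique(per_gene)
  bound_idx <- head(per_gene, cfg$n_bound_fragments)
  candidates <- setdiff(unique(unlist(near_tss)), bound_idx)
  n_more <- cfg$n_bound_fragments - length(bound_idx)
  if (n_more > 0 && length(candidates) > 0) {
    bound_idx <- c(bound_idx, sample(candidates, min(n_more, length(candidates))))
  }
  n_more <- cfg$n_bound_fragments - length(bound_idx)
  if (n_more > 0) {
    rest <- setdiff(seq_len(n_frag), bound_idx)
    bound_idx <- c(bound_idx, sample(rest, n_more))
  }
  bound <- map$fragment_id[sort(bound_idx)]
  bound_genes <- sort(unique(genes$gene_id[
    vapply(near_tss, function(ix) any(ix %in% bound_idx), logical(1))]))

  baseline <- rlnorm(n_frag, meanlog = log(cfg$fragment_mean), sdlog = 0.7)
  conds <- c(rep("fusion", cfg$fusion_reps), rep("dam_only", cfg$control_reps))
  reps <- c(seq_len(cfg$fusion_reps), seq_len(cfg$control_reps))
  samples <- paste0(conds, "_", reps)
  depth <- rlnorm(length(samples), 0, 0.1)

  counts <- matrix(0L, n_frag, length(samples),
                   dimnames = list(map$fragment_id, samples))
  is_bound <- map$fragment_id %in% bound
  for (j in seq_along(samples)) {
    mu <- baseline * depth[j]
    if (conds[j] == "fusion") mu[is_bound] <- mu[is_bound] * cfg$damid_enrichment
    counts[, j] <- rnb(n_frag, mu, cfg$nb_dispersion)
  }

  list(counts = matrix_to_tibble(counts, id_col = "fragment_id"),
       meta = tibble::tibble(sample = samples, condition = conds,
                             replicate = reps),
       map = map,
       truth = list(bound_fragments = bound,
                    enrichment = cfg$damid_enrichment,
                    bound_genes = bound_genes,
                    config = cfg))
}
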