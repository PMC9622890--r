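#' Rank genes for enrichment analysis
#'
#' Orders genes best-to-worst by a signed differential-expression metric.
#' Genes with an undefined metric are dropped; ties are broken by gene id so
#' the order is deterministic.
#'
#' @param de A `de_result` from [nb_wald_test()] or its tidied table.
#' @param metric Ranking metric: the Wald statistic (`"stat"`, default), the
#'   log2 fold change (`"log2fc"`), or the signed `-log10` p-value
#'   (`"signed_logp"`).
#' @return A tibble with columns `gene_id` and `metric`, ordered by descending
#'   metric.
#' @export
rank_genes <- function(de, metric = c("stat", "log2fc", "signed_logp")) {
  metric <- match.arg(metric)
  tab <- if (inherits(de, "de_result")) de$table else tibble::as_tibble(de)
  if (nrow(tab) == 0) abort("empty differential-expression table")
  val <- switch(metric,
                stat = tab$stat,
                log2fc = tab$log2fc,
                signed_logp = sign(tab$log2fc) * -log10(pmax(tab$pvalue, 1e-300)))
  out <- tibble::tibble(gene_id = tab$feature_id, metric = val) |>
    dplyr::filter(is.finite(.data$metric)) |>
    dplyr::arrange(dplyr::desc(.data$metric), .data$gene_id)
  if (nrow(out) == 0) abort("no genes with a finite ranking metric")
  out
}

#' Weighted running-sum enrichment score
#'
#' The Kolmogorov-Smirnov-style GSEA statistic: walking down the ranked list,
#' the running sum increases by `|metric|^weight / N_R` at each gene-set hit
#' (`N_R` = the sum of those weights over hits) and decreases by
#' `1 / (n - n_hits)` at each miss. The enrichment score is the extremum of
#' largest absolute deviation from zero; the leading edge is the hits at or
#' before the extremum (at or after it, for a negative ES).
#'
#' If the set covers the whole list there are no misses; the ES is 1 by
#' convention and flagged degenerate.
#'
#' @param ranked Output of [rank_genes()]: `gene_id` and `metric`, descending.
#' @param geneset Character vector of gene ids; must intersect the list.
#' @param weight Exponent on `|metric|` for hit increments (default 1; 0 gives
#'   the unweighted KS statistic).
#' @return A list with `es`, `running` (tibble of `position`, `gene_id`,
#'   `hit`, `running_sum`), `leading_edge` (character vector) and `degenerate`.
#' @export
enrichment_score <- function(ranked, geneset, weight = 1) {
  hit <- ranked$gene_id %in% geneset
  n <- length(hit)
  nh <- sum(hit)
  if (nh == 0) abort("gene set is disjoint from the ranked list")
  degenerate <- nh == n
  if (degenerate) {
    running <- cumsum(rep(1 / n, n))
    es <- 1
    le <- ranked$gene_id
  } else {
    w <- abs(ranked$metric)^weight
    nr <- sum(w[hit])
    inc <- if (nr > 0) w / nr else rep(1 / nh, n)
    step <- ifelse(hit, inc, -1 / (n - nh))
    running <- cumsum(step)
    i_star <- which.max(abs(running))
    es <- running[i_star]
    le <- if (es >= 0) ranked$gene_id[hit & seq_len(n) <= i_star]
          else ranked$gene_id[hit & seq_len(n) >= i_star]
  }
  list(es = es,
       running = tibble::tibble(position = seq_len(n),
                                gene_id = ranked$gene_id,
                                hit = hit,
                                running_sum = running),
       leading_edge = le,
       degenerate = degenerate)
}

# All distinct relabelings assigning `n_t` of `n` samples to the treatment
# group, as a matrix of treatment-index columns.
.label_assignments <- function(n, n_t) {
  utils::combn(n, n_t)
}

# Null ES matrix by gene-set permutation against a fixed ranking.
.geneset_null <- function(ranked, sizes, n_perm, weight) {
  n <- nrow(ranked)
  perm_es <- matrix(NA_real_, n_perm, length(sizes))
  for (k in seq_len(n_perm)) {
    perm_es[k, ] <- vapply(sizes, function(sz) {
      fake <- ranked$gene_id[sample.int(n, sz)]
      enrichment_score(ranked, fake, weight)$es
    }, numeric(1))
  }
  perm_es
}

# NES, nominal p and pooled-NES FDR from observed scores and a permutation
# ES matrix (rows = permutations, cols = sets).
.assemble_gsea_result <- function(obs, perm_es, genesets, sizes, ranked,
                                  mode, switched, n_used) {
  norm_one <- function(es, null_es) {
    same <- null_es[sign(null_es) == sign(es) & null_es != 0]
    if (es == 0 || length(same) == 0) {
      return(list(nes = NA_real_, p = NA_real_))
    }
    list(nes = es / mean(abs(same)),
         p = (1 + sum(abs(same) >= abs(es))) / (1 + length(same)))
  }
  normed <- purrr::map(seq_along(obs), function(i)
    norm_one(obs[[i]]$es, perm_es[, i]))
  nes <- unname(vapply(normed, `[[`, numeric(1), "nes"))
  pvals <- unname(vapply(normed, `[[`, numeric(1), "p"))

  perm_nes <- perm_es
  for (i in seq_along(genesets)) {
    pos <- perm_es[, i] > 0
    neg <- perm_es[, i] < 0
    if (any(pos)) perm_nes[pos, i] <- perm_es[pos, i] / mean(perm_es[pos, i])
    if (any(neg)) perm_nes[neg, i] <- perm_es[neg, i] / mean(abs(perm_es[neg, i]))
  }
  pool <- as.vector(perm_nes)
  fdr <- vapply(nes, function(x) {
    if (is.na(x)) return(NA_real_)
    if (x >= 0) {
      num <- mean(pool[pool >= 0] >= x)
      den <- mean(nes[!is.na(nes) & nes >= 0] >= x)
    } else {
      num <- mean(pool[pool <= 0] <= x)
      den <- mean(nes[!is.na(nes) & nes <= 0] <= x)
    }
    if (is.nan(num) || is.nan(den) || den == 0) return(NA_real_)
    min(1, num / den)
  }, numeric(1))

  res <- tibble::tibble(set = names(genesets),
                        size = unname(as.integer(sizes)),
                        es = unname(vapply(obs, `[[`, numeric(1), "es")),
                        nes = nes,
                        pvalue = pvals,
                        fdr = fdr,
                        n_perm_used = as.integer(n_used),
                        mode = mode)
  structure(list(results = res,
                 running = setNames(purrr::map(obs, "running"), names(genesets)),
                 leading_edge = setNames(purrr::map(obs, "leading_edge"),
                                         names(genesets)),
                 ranked = ranked,
                 mode = mode,
                 auto_switched = switched,
                 n_perm_used = n_used),
            class = "gsea_result")
}

.as_geneset_list <- function(genesets) {
  if (!is.list(genesets)) genesets <- list(geneset = genesets)
  if (is.null(names(genesets)) || any(names(genesets) == "")) {
    names(genesets) <- paste0("set", seq_along(genesets))
  }
  genesets
}

#' Permutation-normalized enrichment analysis
#'
#' Computes per-set enrichment scores on the observed ranking and builds a
#' null distribution by permutation. In phenotype mode group labels are
#' permuted and the differential-expression ranking is recomputed for every
#' relabeling (dispersions held at their observed estimates); with few
#' replicates the distinct relabelings are enumerated exhaustively, the
#' observed labeling is excluded from the null, and the attainable p-value is
#' floored at one over the number of relabelings. In gene-set mode membership
#' is permuted against the fixed observed ranking. `mode = "auto"` selects
#' gene-set permutation whenever fewer than 100 distinct relabelings exist
#' (a 3-vs-3 design has only 20), since phenotype permutation cannot resolve
#' small p-values there; the switch is recorded in the result.
#'
#' NES is the ES divided by the mean absolute permuted ES of the same sign;
#' the nominal p-value is `(1 + n_extreme) / (1 + n_same_sign)` over
#' direction-consistent permutations. FDR across multiple sets uses the
#' standard pooled-NES procedure. Sets with no same-sign permutations get an
#' undefined NES, reported as `NA`.
#'
#' @inheritParams nb_wald_test
#' @param genesets A named list of gene-id vectors (or a single character
#'   vector, taken as one set).
#' @param n_perm Number of permutations (>= 10; default 1000).
#' @param mode `"auto"`, `"phenotype"` or `"geneset"`.
#' @param metric Ranking metric passed to [rank_genes()].
#' @param weight Hit-weight exponent passed to [enrichment_score()].
#' @param seed Integer seed for the permutation stream.
#' @return A `gsea_result`. [tidy()] returns one row per set (`set`, `size`,
#'   `es`, `nes`, `pvalue`, `fdr`, `n_perm_used`, `mode`); [autoplot()] draws
#'   the running-sum trace.
#' @export
permutation_nes <- function(counts, meta, genesets, control, treatment,
                            group_col = "group", n_perm = 1000,
                            mode = c("auto", "phenotype", "geneset"),
                            metric = "stat", weight = 1, seed = NULL) {
  mode <- match.arg(mode)
  if (n_perm < 10) abort("n_perm must be at least 10")
  genesets <- .as_geneset_list(genesets)
  if (!is.null(seed)) set.seed(seed)

  m <- as_count_matrix(counts)
  groups <- sample_groups(colnames(m), meta, group_col)
  keep <- groups %in% c(control, treatment)
  m <- m[, keep, drop = FALSE]
  groups <- groups[keep]
  sfv <- .size_factors(m)
  disp_tab <- .estimate_dispersion(m, groups, sfv)

  rank_for <- function(labels) {
    de <- nb_wald_test(matrix_to_tibble(m),
                       tibble::tibble(sample = colnames(m), group = labels),
                       control = control, treatment = treatment,
                       sf = tibble::tibble(sample = colnames(m),
                                           size_factor = unname(sfv)),
                       dispersions = disp_tab)
    rank_genes(de, metric)
  }
  ranked <- rank_for(unname(groups))

  n_t <- sum(groups == treatment)
  n_distinct <- choose(length(groups), n_t)
  switched <- FALSE
  if (mode == "auto") {
    mode <- if (n_distinct < 100) "geneset" else "phenotype"
    switched <- mode == "geneset"
  }

  obs <- lapply(genesets, function(gs) enrichment_score(ranked, gs, weight))
  sizes <- vapply(genesets, function(gs) sum(ranked$gene_id %in% gs), 1L)

  if (mode == "phenotype") {
    assign_all <- .label_assignments(length(groups), n_t)
    obs_idx <- unname(which(groups == treatment))
    is_obs <- apply(assign_all, 2, function(j) identical(sort(j), sort(obs_idx)))
    assign_all <- assign_all[, !is_obs, drop = FALSE]
    n_used <- ncol(assign_all)
    if (n_used > n_perm) {
      assign_all <- assign_all[, sample(n_used, n_perm), drop = FALSE]
      n_used <- n_perm
    }
    perm_es <- matrix(NA_real_, n_used, length(genesets))
    for (k in seq_len(n_used)) {
      lab <- rep(control, length(groups))
      lab[assign_all[, k]] <- treatment
      rk <- rank_for(lab)
      perm_es[k, ] <- vapply(genesets, function(gs)
        enrichment_score(rk, gs, weight)$es, numeric(1))
    }
  } else {
    n_used <- n_perm
    perm_es <- .geneset_null(ranked, sizes, n_perm, weight)
  }

  .assemble_gsea_result(obs, perm_es, genesets, sizes, ranked,
                        mode, switched, n_used)
}

#' Preranked enrichment analysis
#'
#' Gene-set-permutation GSEA against a ranking supplied directly, for when
#' the count data behind the ranking are not at hand (or the ranking comes
#' from elsewhere).
#'
#' @inheritParams permutation_nes
#' @param ranked A ranking from [rank_genes()].
#' @return A `gsea_result`, as for [permutation_nes()].
#' @export
gsea_preranked <- function(ranked, genesets, n_perm = 1000, weight = 1,
                           seed = NULL) {
  if (n_perm < 10) abort("n_perm must be at least 10")
  genesets <- .as_geneset_list(genesets)
  if (!is.null(seed)) set.seed(seed)
  obs <- lapply(genesets, function(gs) enrichment_score(ranked, gs, weight))
  sizes <- vapply(genesets, function(gs) sum(ranked$gene_id %in% gs), 1L)
  perm_es <- .geneset_null(ranked, sizes, n_perm, weight)
  .assemble_gsea_result(obs, perm_es, genesets, sizes, ranked,
                        mode = "geneset", switched = FALSE, n_used = n_perm)
}

#' @export
tidy.gsea_result <- function(x, ...) x$results

#' @export
glance.gsea_result <- function(x, ...) {
  tibble::tibble(n_sets = nrow(x$results),
                 mode = x$mode,
                 auto_switched = x$auto_switched,
                 n_perm_used = x$n_perm_used)
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea_result> %d set(s), %s permutation (%d used)\n",
              nrow(x$results), x$mode, x$n_perm_used))
  print(x$results)
  invisible(x)
}
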