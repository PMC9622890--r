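#' Median-of-ratios size factors
#'
#' Per-sample normalization factors computed by the median-of-ratios
#' convention: each sample's factor is the median, over features with nonzero
#' counts in every sample, of that sample's count divided by the feature's
#' geometric mean across samples. Factors are scale-equivariant: multiplying
#' one sample's counts by `c` multiplies its factor by `c`.
#'
#' @param counts A data frame whose first column holds feature ids and whose
#'   remaining columns hold non-negative integer counts, one column per sample.
#' @return A tibble with columns `sample` and `size_factor`.
#' @examples
#' counts <- tibble::tibble(gene = c("g1", "g2"), a = c(10L, 20L), b = c(20L, 40L))
#' size_factors(counts)
#' @export
size_factors <- function(counts) {
  m <- as_count_matrix(counts)
  tibble::tibble(sample = colnames(m),
                 size_factor = unname(.size_factors(m)))
}

.size_factors <- function(m) {
  keep <- rowSums(m == 0) == 0
  if (!any(keep)) {
    abort(paste0("no feature has nonzero counts in all samples; ",
                 "cannot form a median-of-ratios reference. ",
                 "Filter samples or pool features before normalizing."))
  }
  ref <- exp(rowMeans(log(m[keep, , drop = FALSE])))
  apply(m[keep, , drop = FALSE], 2, function(col) median(col / ref))
}

# Counts divided columnwise by size factors.
normalize_counts <- function(m, sf) {
  sweep(m, 2, sf, "/")
}

#' Moderated method-of-moments dispersion estimates
#'
#' Per-feature negative-binomial dispersion on normalized counts. The raw
#' estimate is method-of-moments, `alpha = max(0, (s2 - mu) / mu^2)`, with the
#' variance pooled within groups (df-weighted) so condition effects do not
#' inflate it. Raw estimates at replicate numbers this small are noisy, so each
#' is moderated by a 50/50 weighted average with the mean raw dispersion of
#' the 200 features nearest in mean expression — a crude but monotone
#' stand-in for trend shrinkage.
#'
#' @inheritParams size_factors
#' @param meta Sample metadata with columns `sample` and the grouping column.
#' @param group_col Name of the metadata column holding group labels.
#' @param sf Optional size-factor tibble from [size_factors()]; computed if
#'   missing.
#' @param n_neighbors Window size for the local-median moderation.
#' @return A tibble with columns `feature_id`, `base_mean`, `dispersion_raw`
#'   and `dispersion` (the moderated value used by [nb_wald_test()]).
#' @export
estimate_dispersion <- function(counts, meta, group_col = "group",
                                sf = NULL, n_neighbors = 200) {
  m <- as_count_matrix(counts)
  groups <- sample_groups(colnames(m), meta, group_col)
  sfv <- if (is.null(sf)) .size_factors(m) else {
    setNames(sf$size_factor, sf$sample)[colnames(m)]
  }
  .estimate_dispersion(m, groups, sfv, n_neighbors)
}

.estimate_dispersion <- function(m, groups, sfv, n_neighbors = 200) {
  norm <- normalize_counts(m, sfv)
  split_idx <- split(seq_along(groups), groups)
  rep_groups <- split_idx[vapply(split_idx, length, 1L) >= 2]
  if (length(rep_groups) == 0) {
    abort("dispersion estimation needs at least one group with >= 2 samples")
  }
  group_means <- vapply(split_idx, function(j) rowMeans(norm[, j, drop = FALSE]),
                        numeric(nrow(norm)))
  if (nrow(norm) == 1) group_means <- matrix(group_means, nrow = 1)
  mu_bar <- rowMeans(group_means)
  # Pooled within-group variance, weighted by degrees of freedom.
  ss <- 0
  df <- 0
  for (j in rep_groups) {
    gm <- rowMeans(norm[, j, drop = FALSE])
    ss <- ss + rowSums((norm[, j, drop = FALSE] - gm)^2)
    df <- df + length(j) - 1
  }
  s2 <- ss / df
  raw <- ifelse(mu_bar > 0, pmax(0, (s2 - mu_bar) / mu_bar^2), 0)

  moderated <- .moderate_dispersion(raw, mu_bar, n_neighbors)
  tibble::tibble(feature_id = rownames(m),
                 base_mean = unname(mu_bar),
                 dispersion_raw = unname(raw),
                 dispersion = unname(moderated))
}

# 50/50 average of each raw estimate with the mean raw dispersion of the
# n_neighbors features nearest in base_mean (by rank, window clipped at the
# edges). The plain local mean is used because the method-of-moments
# estimator is approximately unbiased in expectation while robust location
# estimates (median, trimmed mean) sit below it for its right-skewed
# distribution, which under-shrinks and inflates type-I error.
# Features with zero mean keep dispersion 0.
.moderate_dispersion <- function(raw, base_mean, n_neighbors = 200) {
  n <- length(raw)
  ok <- base_mean > 0
  out <- numeric(n)
  idx <- which(ok)
  if (length(idx) == 0) return(out)
  ord <- idx[order(base_mean[idx])]
  k <- min(n_neighbors, length(ord))
  half <- k %/% 2
  local_trend <- vapply(seq_along(ord), function(i) {
    lo <- max(1, min(i - half, length(ord) - k + 1))
    hi <- min(length(ord), lo + k - 1)
    mean(raw[ord[lo:hi]])
  }, numeric(1))
  out[ord] <- 0.5 * raw[ord] + 0.5 * local_trend
  out
}

#' Negative-binomial Wald test for a two-group comparison
#'
#' A transparent differential-count engine in the style of the standard
#' negative-binomial RNA-seq tools: median-of-ratios normalization, moderated
#' method-of-moments dispersion, a log2 fold change from group means of
#' normalized counts (pseudocount 0.5), a delta-method standard error under the
#' NB variance function `mu + alpha * mu^2`, a two-sided Wald z-test, and
#' Benjamini-Hochberg adjustment over the tested features. Features with zero
#' counts in both groups get undefined p-values and are excluded from the BH
#' family.
#'
#' @inheritParams estimate_dispersion
#' @param control,treatment Group labels; the fold change is
#'   treatment-over-control.
#' @param dispersions Optional dispersion tibble from [estimate_dispersion()];
#'   estimated if missing.
#' @return A `de_result` object. [tidy()] returns the per-feature table with
#'   columns `feature_id`, `base_mean`, `log2fc`, `se`, `stat`, `pvalue`,
#'   `padj`; [glance()] a one-row summary; [autoplot()] a volcano plot.
#' @examples
#' sim <- simulate_depletion_experiment(config = sim_config(n_genes = 300, seed = 1))
#' de <- nb_wald_test(sim$counts, sim$meta, control = "control", treatment = "knockdown")
#' glance(de)
#' @export
nb_wald_test <- function(counts, meta, control, treatment,
                         group_col = "group", sf = NULL, dispersions = NULL) {
  m <- as_count_matrix(counts)
  groups <- sample_groups(colnames(m), meta, group_col)
  if (!all(c(control, treatment) %in% groups)) {
    abort("both `control` and `treatment` labels must appear in the metadata")
  }
  keep <- groups %in% c(control, treatment)
  m <- m[, keep, drop = FALSE]
  groups <- groups[keep]
  if (length(unique(groups)) != 2) {
    abort("exactly two groups are required")
  }
  sfv <- if (is.null(sf)) .size_factors(m) else {
    setNames(sf$size_factor, sf$sample)[colnames(m)]
  }
  disp <- if (is.null(dispersions)) {
    .estimate_dispersion(m, groups, sfv)$dispersion
  } else {
    setNames(dispersions$dispersion, dispersions$feature_id)[rownames(m)]
  }

  norm <- normalize_counts(m, sfv)
  jc <- which(groups == control)
  jt <- which(groups == treatment)
  mu_c <- rowMeans(norm[, jc, drop = FALSE])
  mu_t <- rowMeans(norm[, jt, drop = FALSE])
  base_mean <- rowMeans(norm)

  pseudo <- 0.5
  log2fc <- log2((mu_t + pseudo) / (mu_c + pseudo))

  # Delta method: Var(mean of K_j / s_j) = (1/n^2) sum_j (mu/s_j + alpha mu^2),
  # then Var(log2(mean + pseudo)) = Var(mean) / ((mean + pseudo) ln 2)^2.
  var_of_log2_mean <- function(mu, j) {
    v <- vapply(seq_along(mu), function(i) {
      sum(mu[i] / sfv[j] + disp[i] * mu[i]^2) / length(j)^2
    }, numeric(1))
    v / ((mu + pseudo) * log(2))^2
  }
  se <- sqrt(var_of_log2_mean(mu_c, jc) + var_of_log2_mean(mu_t, jt))

  all_zero <- mu_c == 0 & mu_t == 0
  stat <- ifelse(se > 0, log2fc / se, 0)
  pvalue <- 2 * pnorm(-abs(stat))
  pvalue[all_zero] <- NA_real_
  stat[all_zero] <- NA_real_
  se[all_zero] <- NA_real_

  tab <- tibble::tibble(feature_id = rownames(m),
                        base_mean = unname(base_mean),
                        log2fc = unname(log2fc),
                        se = unname(se),
                        stat = unname(stat),
                        pvalue = unname(pvalue),
                        padj = unname(bh_adjust(pvalue)))
  structure(list(table = tab,
                 control = control,
                 treatment = treatment,
                 n_control = length(jc),
                 n_treatment = length(jt),
                 size_factors = sfv),
            class = "de_result")
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH over the defined p-values; undefined entries stay undefined and
#' do not count toward the family size `m`. Output is capped at 1 and monotone
#' non-decreasing in p-rank.
#'
#' @param p Numeric vector of p-values in `[0, 1]`, possibly with `NA`s.
#' @return Adjusted p-values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    abort("p-values must lie in [0, 1]")
  }
  out <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  out[ok] <- stats::p.adjust(p[ok], method = "BH")
  out
}

#' Call differentially expressed features
#'
#' Applies the strict significance-and-effect filter: a feature is called up
#' when `padj < padj_max` and `log2fc > min_abs_log2fc`, down with the negated
#' sign. Both inequalities are strict, so a feature sitting exactly on either
#' boundary is excluded.
#'
#' @param de A `de_result` from [nb_wald_test()], or its tidied table.
#' @param padj_max Adjusted-p ceiling (default 0.01).
#' @param min_abs_log2fc Absolute log2 fold-change floor (default 0.5).
#' @return A tibble with columns `feature_id`, `log2fc`, `padj` and
#'   `direction` (`"up"` or `"down"`), one row per called feature.
#' @export
call_de <- function(de, padj_max = 0.01, min_abs_log2fc = 0.5) {
  tab <- if (inherits(de, "de_result")) de$table else tibble::as_tibble(de)
  tab |>
    dplyr::filter(!is.na(.data$padj),
                  .data$padj < padj_max,
                  abs(.data$log2fc) > min_abs_log2fc) |>
    dplyr::mutate(direction = ifelse(.data$log2fc > 0, "up", "down")) |>
    dplyr::select("feature_id", "log2fc", "padj", "direction")
}

#' @export
tidy.de_result <- function(x, ...) x$table

#' @export
glance.de_result <- function(x, padj_max = 0.01, min_abs_log2fc = 0.5, ...) {
  calls <- call_de(x, padj_max, min_abs_log2fc)
  tibble::tibble(n_features = nrow(x$table),
                 n_tested = sum(!is.na(x$table$padj)),
                 n_up = sum(calls$direction == "up"),
                 n_down = sum(calls$direction == "down"),
                 control = x$control,
                 treatment = x$treatment)
}

#' @export
print.de_result <- function(x, ...) {
  cat(sprintf("<de_result> %s vs %s (%d + %d samples), %d features\n",
              x$treatment, x$control, x$n_treatment, x$n_control,
              nrow(x$table)))
  print(x$table, n = 6)
  invisible(x)
}
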