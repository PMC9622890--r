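# Independent oracles and small fixture builders used across the suite.

# Brute-force running-sum accumulation, written as a plain loop independent
# of the package's vectorized path. Returns the extremum and the full trace.
oracle_es <- function(ids, metric, geneset, weight = 1) {
  n <- length(ids)
  hit <- ids %in% geneset
  nh <- sum(hit)
  nr <- sum(abs(metric[hit])^weight)
  cur <- 0
  run <- numeric(n)
  for (i in seq_len(n)) {
    if (hit[i]) {
      cur <- cur + if (nr > 0) abs(metric[i])^weight / nr else 1 / nh
    } else {
      cur <- cur - 1 / (n - nh)
    }
    run[i] <- cur
  }
  list(es = run[which.max(abs(run))], running = run)
}

# Compare an ES against the oracle. When the positive and negative extremes
# of the trace tie in magnitude to float precision, the selected sign depends
# on 1-ulp accumulation differences; only the magnitude is comparable there.
expect_es_matches_oracle <- function(es, ref) {
  gap <- abs(max(ref$running)) - abs(min(ref$running))
  if (abs(gap) < 1e-9) {
    expect_equal(abs(es), abs(ref$es), tolerance = 1e-12)
  } else {
    expect_equal(es, ref$es, tolerance = 1e-12)
  }
}

# Per-window, per-strand explicit motif comparison.
oracle_scan <- function(sequence, sets, max_mismatch) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  s <- toupper(sequence)
  chars <- strsplit(s, "")[[1]]
  n <- length(chars)
  m <- length(sets)
  out <- list()
  if (n >= m) {
    for (st in 0:(n - m)) {
      win <- chars[(st + 1):(st + m)]
      mm_plus <- sum(vapply(seq_len(m), function(k)
        !win[k] %in% sets[[k]], logical(1)))
      if (mm_plus <= max_mismatch) {
        out[[length(out) + 1]] <- data.frame(start = st, strand = "+",
                                             mismatches = mm_plus)
      }
      rcw <- rev(unname(comp[win]))
      rcw[is.na(rcw)] <- "N"
      mm_minus <- sum(vapply(seq_len(m), function(k)
        !rcw[k] %in% sets[[k]], logical(1)))
      if (mm_minus <= max_mismatch) {
        out[[length(out) + 1]] <- data.frame(start = st, strand = "-",
                                             mismatches = mm_minus)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(start = integer(), strand = character(),
                      mismatches = integer()))
  }
  do.call(rbind, out)
}

# A tiny counts tibble from a matrix-like specification.
tiny_counts <- function(m, ids = sprintf("g%d", seq_len(nrow(m)))) {
  colnames(m) <- colnames(m) %||% sprintf("s%d", seq_len(ncol(m)))
  out <- tibble::as_tibble(as.data.frame(m))
  tibble::add_column(out, feature_id = ids, .before = 1)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
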