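# Fixture builders and independent brute-force oracles.  The oracles
# deliberately use naive explicit loops so they share no code path with
# the implementation they check.

with_seed <- function(seed, code) {
  set.seed(seed)
  force(code)
}

random_raw_matrix <- function(n, seed, id = "rnd") {
  with_seed(seed, {
    vals <- matrix(sample(-10:12, n * 20L, replace = TRUE), n, 20L)
    seq <- paste(sample(aa_order(), n, replace = TRUE), collapse = "")
    score_matrix(vals, protein_id = id, stage = "raw", sequence = seq)
  })
}

random_protein <- function(n, seed, id = "p") {
  with_seed(seed, {
    seq <- paste(sample(aa_order(), n, replace = TRUE), collapse = "")
    k <- sample(0:2, 1)
    iv <- NULL
    if (k > 0 && n >= 8) {
      starts <- sort(sample(seq_len(n - 3L), k))
      iv <- cbind(starts, pmin(starts + sample(2:6, k, replace = TRUE), n))
    }
    protein_record(id, seq, morf_intervals = iv)
  })
}

# Formula-literal masking: explicit window enumeration per position and
# column, truncated mean at termini.
oracle_mask <- function(values, window) {
  half <- (window - 1) / 2
  n <- nrow(values)
  out <- values * 0
  for (i in seq_len(n)) {
    for (j in seq_len(ncol(values))) {
      members <- max(1, i - half):min(n, i + half)
      out[i, j] <- values[i, j] - mean(values[members, j])
    }
  }
  out
}

# Zero-padded windowed box sum, padding made explicit.
oracle_smooth <- function(values, window) {
  half <- (window - 1) / 2
  n <- nrow(values)
  padded <- rbind(matrix(0, half, ncol(values)), values,
                  matrix(0, half, ncol(values)))
  out <- values * 0
  for (i in seq_len(n)) {
    for (j in seq_len(ncol(values))) {
      out[i, j] <- sum(padded[(i):(i + 2 * half), j])
    }
  }
  out
}

# Per-position concatenation of the outside window, zero rows beyond
# the termini.
oracle_window_features <- function(values, position, window) {
  half <- (window - 1) / 2
  n <- nrow(values)
  out <- c()
  for (k in (position - half):(position + half)) {
    row <- if (k >= 1 && k <= n) values[k, ] else rep(0, ncol(values))
    out <- c(out, row)
  }
  out
}

# Mann-Whitney pair counting: fraction of positive-negative pairs
# ordered correctly, ties counting one half.
oracle_auc <- function(scores, truth) {
  pos <- scores[truth == 1]
  neg <- scores[truth == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
  }
  total / (length(pos) * length(neg))
}

# Explicit per-residue tally.
oracle_confusion <- function(calls, truth) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(calls)) {
    if (calls[i] == 1 && truth[i] == 1) tp <- tp + 1L
    if (calls[i] == 0 && truth[i] == 0) tn <- tn + 1L
    if (calls[i] == 1 && truth[i] == 0) fp <- fp + 1L
    if (calls[i] == 0 && truth[i] == 1) fn <- fn + 1L
  }
  c(tp = tp, tn = tn, fp = fp, fn = fn)
}

# Letter tally of one region, via a per-residue distance scan.
oracle_region_tags <- function(protein, w) {
  lab <- morf_labels(protein)
  n <- protein$length
  tags <- character(n)
  for (i in seq_len(n)) {
    if (lab[i] == 1) {
      tags[i] <- "MoRF"
    } else {
      d <- Inf
      for (k in seq_len(nrow(protein$morf_intervals))) {
        s <- protein$morf_intervals[k, "start"]
        e <- protein$morf_intervals[k, "end"]
        d <- min(d, if (i < s) s - i else i - e)
      }
      tags[i] <- if (d <= w) "flank" else "nonMoRF"
    }
  }
  tags
}

oracle_composition <- function(records, w, region) {
  counts <- stats::setNames(rep(0, 20), aa_order())
  for (p in records) {
    tags <- oracle_region_tags(p, w)
    chars <- strsplit(p$sequence, "")[[1]]
    for (i in seq_along(chars)) {
      if (tags[i] == region && chars[i] != "X")
        counts[chars[i]] <- counts[chars[i]] + 1
    }
  }
  counts / sum(counts)
}

# Textbook Pearson r and its t-based two-sided p-value.
oracle_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}
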