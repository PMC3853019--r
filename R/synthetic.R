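# Seeded generator of synthetic proteins with planted MoRFs and
# PSSM-like raw score matrices.  The recoverable signal is conservation
# contrast: MoRF positions are "conserved" (one high-scoring column,
# low elsewhere) with much higher probability than background
# positions, mirroring the local-conservation excess of real MoRFs.
# It is a test harness, not an evolutionary simulator.

# Approximate background amino-acid frequencies of natural proteins
# (Robinson-Robinson style), in canonical column order.
BACKGROUND_FREQS <- c(
  A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019, Q = 0.043,
  E = 0.063, G = 0.074, H = 0.022, I = 0.051, L = 0.091, K = 0.057,
  M = 0.022, F = 0.039, P = 0.052, S = 0.071, T = 0.058, W = 0.013,
  Y = 0.032, V = 0.065)

#' Simulation configuration
#'
#' Defaults emulate desk-scale versions of a MoRF benchmark: chains of
#' 60-200 residues carrying one or two planted MoRFs of 5-25 residues
#' (the length class of short MoRFs), where a MoRF position is
#' conserved with probability 0.7 against a background of 0.15.  A
#' conserved position's score row has one high-scoring column (its own
#' residue, centred near +7) and low scores elsewhere (near -3); a
#' variable position's row is i.i.d. near -1 with spread 2.  All scores
#' are integers clipped to the PSI-BLAST-plausible range \[-10, 12\].
#'
#' @param n_proteins Number of proteins to generate.
#' @param length_range Min/max chain length.
#' @param morf_length_range Min/max MoRF length (default `c(5, 25)`).
#' @param morfs_per_protein Single count or min/max range (default 1-2).
#' @param min_separation Minimum gap between planted MoRFs.
#' @param p_conserved_in_morf,p_conserved_background Probability that a
#'   position inside / outside a MoRF is conserved.
#' @param conserved_high_mean,conserved_low_mean,variable_mean,variable_sd
#'   Score-generation parameters (see Details above).
#' @param baseline_sd Standard deviation of a per-protein integer
#'   offset added to every score, emulating between-protein variation
#'   in absolute conservation level (alignment depth, evolutionary
#'   rate).  Relative local conservation is invariant to it; absolute
#'   scores are not.
#' @param score_range Integer clip range for all scores.
#' @param flank_bias If `TRUE`, residue letters in the 5 positions
#'   flanking each MoRF are biased toward the disorder-promoting set
#'   A, G, E, S, T, emulating the composition contrast of real flanks.
#' @param seed Integer seed; the whole simulation is reproducible from
#'   it.
#'
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_proteins = 50L, length_range = c(60L, 200L),
                              morf_length_range = c(5L, 25L),
                              morfs_per_protein = c(1L, 2L),
                              min_separation = 10L,
                              p_conserved_in_morf = 0.7,
                              p_conserved_background = 0.15,
                              conserved_high_mean = 7,
                              conserved_low_mean = -3,
                              variable_mean = -1, variable_sd = 1,
                              baseline_sd = 2,
                              score_range = c(-10L, 12L),
                              flank_bias = FALSE, seed = 1L) {
  stopifnot(n_proteins >= 0, length(length_range) == 2L,
            length_range[1] <= length_range[2],
            length(morf_length_range) == 2L,
            morf_length_range[1] <= morf_length_range[2],
            morf_length_range[1] >= 1,
            p_conserved_in_morf >= 0, p_conserved_in_morf <= 1,
            p_conserved_background >= 0, p_conserved_background <= 1,
            min_separation >= 0, variable_sd >= 0, baseline_sd >= 0,
            score_range[1] < score_range[2])
  if (length(morfs_per_protein) == 1L)
    morfs_per_protein <- rep(morfs_per_protein, 2L)
  stopifnot(morfs_per_protein[1] <= morfs_per_protein[2],
            morfs_per_protein[1] >= 0)
  structure(list(n_proteins = as.integer(n_proteins),
                 length_range = as.integer(length_range),
                 morf_length_range = as.integer(morf_length_range),
                 morfs_per_protein = as.integer(morfs_per_protein),
                 min_separation = as.integer(min_separation),
                 p_conserved_in_morf = p_conserved_in_morf,
                 p_conserved_background = p_conserved_background,
                 conserved_high_mean = conserved_high_mean,
                 conserved_low_mean = conserved_low_mean,
                 variable_mean = variable_mean, variable_sd = variable_sd,
                 baseline_sd = baseline_sd,
                 score_range = as.integer(score_range),
                 flank_bias = isTRUE(flank_bias),
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Place `k` non-overlapping intervals of the given lengths in [1, n]
# with at least `sep` residues between consecutive intervals.  Uniform
# over feasible placements (stars-and-bars over the slack); errors when
# the intervals cannot fit.
place_intervals <- function(n, lengths, sep) {
  k <- length(lengths)
  if (k == 0L)
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  lengths <- lengths[sample.int(k)]
  slack <- n - sum(lengths) - (k - 1L) * sep
  if (slack < 0L)
    stop(sprintf("%d MoRF(s) totalling %d residues (+%d separation) cannot fit in a %d-residue protein; widen length_range",
                 k, sum(lengths), (k - 1L) * sep, n))
  bars <- sort(sample.int(slack + k, k))
  gaps <- c(bars, slack + k + 1L) - c(0L, bars) - 1L # k+1 gaps summing to slack
  iv <- matrix(0L, k, 2L, dimnames = list(NULL, c("start", "end")))
  pos <- 0L
  for (j in seq_len(k)) {
    pos <- pos + gaps[j] + if (j > 1L) sep else 0L
    iv[j, ] <- c(pos + 1L, pos + lengths[j])
    pos <- pos + lengths[j]
  }
  iv
}

# sample() treats a scalar first argument as 1:n; always draw from an
# explicit range instead.
sample_range <- function(range, size = 1L) {
  range[1] + sample.int(range[2] - range[1] + 1L, size, replace = TRUE) - 1L
}

simulate_one <- function(config, id) {
  n <- sample_range(config$length_range)
  k <- sample_range(config$morfs_per_protein)
  lengths <- sample_range(config$morf_length_range, k)
  iv <- place_intervals(n, lengths, config$min_separation)

  letters20 <- aa_order()
  seq_chars <- sample(letters20, n, replace = TRUE, prob = BACKGROUND_FREQS)
  in_morf <- logical(n)
  for (r in seq_len(nrow(iv))) in_morf[iv[r, 1]:iv[r, 2]] <- TRUE
  if (config$flank_bias) {
    flanky <- logical(n)
    for (r in seq_len(nrow(iv))) {
      flanky[max(1L, iv[r, 1] - 5L):min(n, iv[r, 2] + 5L)] <- TRUE
    }
    flanky <- flanky & !in_morf
    disorder_set <- c("A", "G", "E", "S", "T")
    pick <- flanky & stats::runif(n) < 0.5
    seq_chars[pick] <- sample(disorder_set, sum(pick), replace = TRUE)
  }

  p_cons <- ifelse(in_morf, config$p_conserved_in_morf,
                   config$p_conserved_background)
  conserved <- stats::runif(n) < p_cons
  baseline <- round(stats::rnorm(1L, 0, config$baseline_sd))
  values <- matrix(0L, n, 20L)
  for (i in seq_len(n)) {
    if (conserved[i]) {
      row <- stats::rnorm(20L, config$conserved_low_mean, 1)
      own <- match(seq_chars[i], letters20)
      row[own] <- stats::rnorm(1L, config$conserved_high_mean, 1)
    } else {
      row <- stats::rnorm(20L, config$variable_mean, config$variable_sd)
    }
    values[i, ] <- as.integer(pmin(pmax(round(row) + baseline,
                                        config$score_range[1]),
                                   config$score_range[2]))
  }
  protein_record(id, paste(seq_chars, collapse = ""), morf_intervals = iv,
                 matrix = score_matrix(values, protein_id = id, stage = "raw",
                                       sequence = paste(seq_chars, collapse = "")))
}

#' Simulate proteins with planted, locally conserved MoRFs
#'
#' Generates `config$n_proteins` protein records, each with sequence,
#' MoRF annotation intervals and an attached `stage = "raw"` score
#' matrix, fully reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @return List of [protein_record()] with matrices attached.
#' @export
simulate_proteins <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$n_proteins == 0L) return(list())
  with_seed(config$seed,
            lapply(seq_len(config$n_proteins), function(k)
              simulate_one(config, sprintf("synth%03d", k))))
}

#' Write a simulated fixture bundle to disk
#'
#' Emits `sequences.fasta`, `annotations.tsv` and one PSI-BLAST-format
#' PSSM file per protein under `dir/pssm/`, all readable by the package
#' I/O without special-casing.
#'
#' @param records Non-empty list of [protein_record()] with raw
#'   matrices.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(records, dir) {
  if (length(records) == 0L) stop("records must be non-empty")
  dir.create(file.path(dir, "pssm"), recursive = TRUE, showWarnings = FALSE)
  write_fasta(records, file.path(dir, "sequences.fasta"))
  write_annotations(records, file.path(dir, "annotations.tsv"))
  for (p in records) {
    if (is.null(p$matrix) || p$matrix$stage != "raw")
      stop(sprintf("protein '%s' has no raw matrix to write", p$id))
    write_psiblast_pssm(p$matrix, file.path(dir, "pssm", paste0(p$id, ".pssm")))
  }
  invisible(dir)
}

#' Read a fixture bundle back into protein records
#'
#' @param dir Directory written by [write_fixture_bundle()].
#' @return List of [protein_record()] with raw matrices and intervals.
#' @export
read_fixture_bundle <- function(dir) {
  proteins <- read_fasta(file.path(dir, "sequences.fasta"))
  proteins <- read_annotations(file.path(dir, "annotations.tsv"), proteins)
  lapply(proteins, function(p)
    set_matrix(p, read_psiblast_pssm(file.path(dir, "pssm",
                                               paste0(p$id, ".pssm")))))
}
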