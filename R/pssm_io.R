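# I/O for all on-disk artifacts: FASTA sequences, MoRF annotation TSVs,
# PSI-BLAST ASCII PSSM files, transformed-matrix TSVs and prediction TSVs.
# Coordinates on disk are 1-based inclusive (the biological convention);
# everything in memory is plain R 1-based indexing.

VALID_STAGES <- c("raw", "masked", "filtered", "smoothed", "scaled")
AA_ALPHABET <- paste0(paste(c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
                              "I", "L", "K", "M", "F", "P", "S", "T", "W",
                              "Y", "V"), collapse = ""), "X")

#' Protein record
#'
#' Bundles a protein identifier, its amino-acid sequence, optional MoRF
#' annotation intervals (1-based inclusive, canonicalized to sorted,
#' merged, non-overlapping form) and an optional score matrix.
#'
#' @param id Character identifier.
#' @param sequence Amino-acid sequence over the 20 standard letters plus
#'   `X` for unknown residues.
#' @param morf_intervals Two-column matrix or data frame of `start`,
#'   `end` residue intervals, 1-based inclusive; may be `NULL`.
#' @param matrix Optional [score_matrix()] whose row count equals the
#'   sequence length.
#'
#' @return An object of class `protein_record` with fields `id`,
#'   `sequence`, `length`, `morf_intervals` and `matrix`.
#' @export
protein_record <- function(id, sequence, morf_intervals = NULL, matrix = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- toupper(as.character(sequence))
  if (!nzchar(sequence)) stop("sequence must contain at least one residue")
  bad <- setdiff(strsplit(sequence, "")[[1]], strsplit(AA_ALPHABET, "")[[1]])
  if (length(bad))
    stop(sprintf("protein '%s': invalid residue letters: %s",
                 id, paste(unique(bad), collapse = ", ")))
  n <- nchar(sequence)
  iv <- canonicalize_intervals(morf_intervals, n, id)
  rec <- structure(list(id = id, sequence = sequence, length = n,
                        morf_intervals = iv, matrix = NULL),
                   class = "protein_record")
  if (!is.null(matrix)) rec <- set_matrix(rec, matrix)
  rec
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("<protein_record> %s: %d residues, %d MoRF interval(s)%s\n",
              x$id, x$length, nrow(x$morf_intervals),
              if (is.null(x$matrix)) "" else
                sprintf(", %s matrix attached", x$matrix$stage)))
  invisible(x)
}

# Sort and merge 1-based inclusive intervals; validate bounds.
canonicalize_intervals <- function(iv, n, id = "?") {
  if (is.null(iv) || NROW(iv) == 0L)
    return(matrix(integer(), ncol = 2L, dimnames = list(NULL, c("start", "end"))))
  iv <- as.matrix(iv)[, 1:2, drop = FALSE]
  storage.mode(iv) <- "integer"
  colnames(iv) <- c("start", "end")
  if (any(iv[, "start"] > iv[, "end"]))
    stop(sprintf("protein '%s': interval start > end", id))
  if (any(iv[, "start"] < 1L) || any(iv[, "end"] > n))
    stop(sprintf("protein '%s': interval outside [1, %d]", id, n))
  iv <- iv[order(iv[, "start"], iv[, "end"]), , drop = FALSE]
  merged <- iv[1, , drop = FALSE]
  for (k in seq_len(nrow(iv))[-1]) {
    last <- nrow(merged)
    if (iv[k, "start"] <= merged[last, "end"] + 1L)
      merged[last, "end"] <- max(merged[last, "end"], iv[k, "end"])
    else
      merged <- rbind(merged, iv[k, , drop = FALSE])
  }
  merged
}

#' Per-residue MoRF labels of a protein record
#'
#' @param record A [protein_record()].
#' @return Integer vector of length `record$length`; 1 inside an
#'   annotated MoRF interval, 0 elsewhere.
#' @export
morf_labels <- function(record) {
  stopifnot(inherits(record, "protein_record"))
  lab <- integer(record$length)
  iv <- record$morf_intervals
  for (k in seq_len(nrow(iv))) lab[iv[k, "start"]:iv[k, "end"]] <- 1L
  lab
}

set_matrix <- function(record, matrix) {
  stopifnot(inherits(record, "protein_record"), inherits(matrix, "score_matrix"))
  if (nrow(matrix$values) != record$length)
    stop(sprintf("protein '%s': matrix has %d rows but sequence has %d residues",
                 record$id, nrow(matrix$values), record$length))
  record$matrix <- matrix
  record
}

#' Per-residue score matrix
#'
#' An N x 20 matrix of conservation scores in canonical PSI-BLAST column
#' order, tagged with the transformation stage it has reached.
#' Stage invariants: `raw` values are integers as emitted by the
#' aligner; `filtered` values are non-negative; `scaled` values lie in
#' \[-1, 1\].  `smoothed` matrices carry no sign constraint because
#' smoothing may also be applied directly to a raw matrix (the
#' smoothing-only ablation encoder).
#'
#' @param values Numeric N x 20 matrix.
#' @param protein_id Identifier of the owning protein.
#' @param stage One of `"raw"`, `"masked"`, `"filtered"`, `"smoothed"`,
#'   `"scaled"`.
#' @param sequence Optional residue sequence of length N (kept so matrix
#'   TSVs can print a residue column).
#'
#' @return An object of class `score_matrix`.
#' @export
score_matrix <- function(values, protein_id = "protein", stage = "raw",
                         sequence = NULL) {
  stage <- match.arg(stage, VALID_STAGES)
  values <- as.matrix(values)
  if (ncol(values) != 20L)
    stop(sprintf("score matrix must have exactly 20 columns, got %d", ncol(values)))
  if (nrow(values) < 1L) stop("score matrix must have at least one row")
  if (anyNA(values)) stop("score matrix contains NA values")
  colnames(values) <- aa_order()
  rownames(values) <- NULL
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (nchar(sequence) != nrow(values))
      stop("sequence length does not match matrix row count")
  }
  check_stage_values(values, stage)
  structure(list(protein_id = protein_id, values = values, stage = stage,
                 sequence = sequence),
            class = "score_matrix")
}

check_stage_values <- function(values, stage) {
  if (stage == "raw" && any(values != round(values)))
    stop("stage=raw requires integer scores")
  if (stage == "filtered" && any(values < 0))
    stop("stage=filtered requires non-negative scores")
  if (stage == "scaled" && (any(values < -1) || any(values > 1)))
    stop("stage=scaled requires scores in [-1, 1]")
  invisible(TRUE)
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %s: %d x 20, stage=%s\n",
              x$protein_id, nrow(x$values), x$stage))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' @param path FASTA file path.
#' @param nonstandard What to do with letters outside the 20 standard
#'   amino acids plus X: `"error"` rejects the file, `"map-to-X"`
#'   replaces them with X.
#'
#' @return List of [protein_record()] (intervals empty), in file order.
#' @export
read_fasta <- function(path, nonstandard = c("error", "map-to-X")) {
  nonstandard <- match.arg(nonstandard)
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop(sprintf("FASTA file is empty: %s", path))
  ids <- sub("\\s.*$", "", names(seqs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop(sprintf("duplicate FASTA id(s): %s", paste(dup, collapse = ", ")))
  lapply(seq_along(seqs), function(k) {
    s <- toupper(as.character(seqs[[k]]))
    if (nonstandard == "map-to-X")
      s <- gsub(sprintf("[^%s]", AA_ALPHABET), "X", s)
    protein_record(ids[k], s)
  })
}

#' Write protein records to a FASTA file
#'
#' @param records List of [protein_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(vapply(records, `[[`, "", "sequence"))
  names(set) <- vapply(records, `[[`, "", "id")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Attach MoRF annotations from a TSV file
#'
#' The TSV must carry a header line with columns `protein_id`, `start`,
#' `end`; coordinates are 1-based inclusive.  Intervals for the same
#' protein are canonicalized (sorted, merged).
#'
#' @param path Annotation TSV path.
#' @param proteins List of [protein_record()] the annotations refer to.
#' @param unknown `"error"` fails on an annotation whose protein id is
#'   absent from `proteins`; `"warn"` skips it with a warning.
#'
#' @return `proteins` with `morf_intervals` attached.
#' @export
read_annotations <- function(path, proteins, unknown = c("error", "warn")) {
  unknown <- match.arg(unknown)
  if (!file.exists(path)) stop(sprintf("annotation file not found: %s", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "start", "end")
  if (!all(need %in% names(tab)))
    stop(sprintf("annotation TSV must have columns %s", paste(need, collapse = ", ")))
  ids <- vapply(proteins, `[[`, "", "id")
  missing_ids <- setdiff(unique(tab$protein_id), ids)
  if (length(missing_ids)) {
    msg <- sprintf("annotations reference unknown protein id(s): %s",
                   paste(missing_ids, collapse = ", "))
    if (unknown == "error") stop(msg) else warning(msg)
    tab <- tab[tab$protein_id %in% ids, , drop = FALSE]
  }
  lapply(proteins, function(p) {
    rows <- tab[tab$protein_id == p$id, , drop = FALSE]
    if (nrow(rows) == 0L) return(p)
    protein_record(p$id, p$sequence,
                   morf_intervals = cbind(rows$start, rows$end),
                   matrix = p$matrix)
  })
}

#' Write MoRF annotations to a TSV file
#'
#' @param records List of [protein_record()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(records, path) {
  rows <- do.call(rbind, lapply(records, function(p) {
    if (nrow(p$morf_intervals) == 0L) return(NULL)
    data.frame(protein_id = p$id,
               start = p$morf_intervals[, "start"],
               end = p$morf_intervals[, "end"])
  }))
  if (is.null(rows))
    rows <- data.frame(protein_id = character(), start = integer(),
                       end = integer())
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Parse a PSI-BLAST ASCII PSSM file
#'
#' Reads the matrix PSI-BLAST writes with `-out_ascii_pssm`: a header
#' line of 20 amino-acid letters followed by one row per residue holding
#' the position index, the query residue and 20 integer log-odds scores
#' (any trailing columns — the weighted-percentage block, information
#' content, relative weight — are ignored).  Columns are reordered to
#' canonical order if the header differs.
#'
#' @param path PSSM file path.
#' @param protein_id Identifier for the returned matrix; defaults to the
#'   file name without extension.
#'
#' @return A [score_matrix()] with `stage = "raw"` carrying the query
#'   sequence.
#' @export
read_psiblast_pssm <- function(path, protein_id = NULL) {
  if (!file.exists(path)) stop(sprintf("PSSM file not found: %s", path))
  protein_id <- protein_id %||% sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)

  header_at <- NA_integer_
  header_cols <- NULL
  for (k in seq_along(lines)) {
    toks <- strsplit(trimws(lines[k]), "\\s+")[[1]]
    if (length(toks) >= 20L && all(nchar(toks[1:20]) == 1L) &&
        setequal(toks[1:20], aa_order())) {
      header_at <- k
      header_cols <- toks[1:20]
      break
    }
  }
  if (is.na(header_at))
    stop(sprintf("%s: no PSSM header line of 20 amino-acid letters found", path))

  residues <- character()
  rows <- list()
  body <- if (header_at < length(lines)) (header_at + 1L):length(lines) else integer(0)
  for (k in body) {
    line <- lines[k]
    if (!grepl("^\\s*[0-9]+\\s+[A-Za-z]", line)) break
    toks <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(toks) < 22L)
      stop(sprintf("%s: malformed PSSM row %d: fewer than 20 score columns",
                   path, length(rows) + 1L))
    scores <- suppressWarnings(as.numeric(toks[3:22]))
    if (anyNA(scores))
      stop(sprintf("%s: non-numeric score in PSSM row %d", path, length(rows) + 1L))
    if (any(scores != round(scores)))
      stop(sprintf("%s: non-integer score in the log-odds block, row %d",
                   path, length(rows) + 1L))
    residues <- c(residues, toupper(toks[2]))
    rows[[length(rows) + 1L]] <- scores
  }
  if (length(rows) == 0L) stop(sprintf("%s: PSSM contains no residue rows", path))

  values <- do.call(rbind, rows)
  colnames(values) <- header_cols
  values <- values[, aa_order(), drop = FALSE]
  score_matrix(values, protein_id = protein_id, stage = "raw",
               sequence = paste(residues, collapse = ""))
}

#' Write a score matrix in PSI-BLAST ASCII PSSM layout
#'
#' Produces a file [read_psiblast_pssm()] can parse: the standard
#' preamble, a 20-letter header, and one row per residue with index,
#' residue letter and 20 integer scores (plus a zero-filled trailing
#' block mimicking the weighted-percentage columns).
#'
#' @param matrix A `stage = "raw"` [score_matrix()] carrying a sequence.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_psiblast_pssm <- function(matrix, path) {
  stopifnot(inherits(matrix, "score_matrix"))
  if (matrix$stage != "raw") stop("only stage=raw matrices are written as PSSM files")
  if (is.null(matrix$sequence)) stop("matrix must carry a sequence to write a PSSM file")
  res <- strsplit(matrix$sequence, "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("",
               "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts",
               paste0("           ",
                      paste(sprintf("%3s", c(aa_order(), aa_order())), collapse = " "))),
             con)
  for (i in seq_len(nrow(matrix$values))) {
    writeLines(sprintf("%5d %s  %s  %s  0.00 0.00", i, res[i],
                       paste(sprintf("%3d", as.integer(matrix$values[i, ])), collapse = " "),
                       paste(sprintf("%3d", integer(20)), collapse = " ")),
               con)
  }
  writeLines("", con)
  invisible(path)
}

#' Write / read a score matrix as TSV
#'
#' Lossless round-trip of values (full double precision), stage, protein
#' id, column order and (when present) the residue column.  The file
#' starts with two comment lines (`# protein_id:`, `# stage:`) followed
#' by a header row `pos res A R N ... V`.
#'
#' @param matrix A [score_matrix()].
#' @param path File path.
#' @return `write_matrix_tsv`: `path`, invisibly.  `read_matrix_tsv`:
#'   the [score_matrix()].
#' @export
write_matrix_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "score_matrix"))
  n <- nrow(matrix$values)
  res <- if (is.null(matrix$sequence)) rep("-", n) else
    strsplit(matrix$sequence, "")[[1]]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# protein_id: %s", matrix$protein_id),
               sprintf("# stage: %s", matrix$stage),
               paste(c("pos", "res", aa_order()), collapse = "\t")), con)
  body <- vapply(seq_len(n), function(i)
    paste(c(i, res[i], sprintf("%.17g", matrix$values[i, ])), collapse = "\t"),
    character(1))
  writeLines(body, con)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop(sprintf("matrix TSV not found: %s", path))
  head2 <- readLines(path, n = 2L)
  pid <- sub("^# protein_id:\\s*", "", head2[1])
  stage <- sub("^# stage:\\s*", "", head2[2])
  if (!stage %in% VALID_STAGES)
    stop(sprintf("%s: unknown stage tag '%s'", path, stage))
  tab <- utils::read.delim(path, skip = 2L, check.names = FALSE)
  values <- as.matrix(tab[, aa_order(), drop = FALSE])
  seq <- paste(tab$res, collapse = "")
  if (grepl("-", seq, fixed = TRUE)) seq <- NULL
  score_matrix(values, protein_id = pid, stage = stage, sequence = seq)
}

#' Write per-residue predictions to TSV
#'
#' @param predictions Data frame with columns `protein_id`, `position`,
#'   `residue`, `score`, `call` as returned by
#'   [predict.morf_model()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path) {
  utils::write.table(predictions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  if (!file.exists(path)) stop(sprintf("prediction TSV not found: %s", path))
  utils::read.delim(path, stringsAsFactors = FALSE)
}
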