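# Sliding-window feature encoding: each residue is represented by the
# concatenated rows of the (transformed) score matrix inside an outside
# window centred on it, with zero rows beyond the termini.

#' Outside sliding-window configuration
#'
#' @param outside_window Odd positive integer `2h + 1`, the number of
#'   matrix rows concatenated into one residue's feature vector
#'   (default 25, giving 25 x 20 = 500 dimensions).
#'
#' @return An object of class `window_config`.
#' @export
window_config <- function(outside_window = 25L) {
  structure(list(outside_window = check_odd_window(outside_window,
                                                   "outside_window")),
            class = "window_config")
}

# N x (2h+1)*20 matrix: row i = rows i-h .. i+h of `values`, zero-padded.
window_feature_matrix <- function(values, outside_window) {
  h <- (outside_window - 1L) %/% 2L
  n <- nrow(values)
  pad <- matrix(0, h, 20L)
  padded <- rbind(pad, values, pad)
  do.call(cbind, lapply(0:(2L * h), function(k)
    padded[seq_len(n) + k, , drop = FALSE]))
}

#' Feature vector of one residue
#'
#' Concatenates the `2h + 1` matrix rows centred at `position`, in
#' sequence order; positions beyond the sequence ends contribute
#' all-zero rows.
#'
#' @param matrix A `stage = "scaled"` [score_matrix()].
#' @param position Residue position, 1-based.
#' @param config A [window_config()].
#'
#' @return Numeric vector of length `(2h + 1) * 20`.
#' @export
window_features <- function(matrix, position, config = window_config()) {
  stopifnot(inherits(matrix, "score_matrix"), inherits(config, "window_config"))
  n <- nrow(matrix$values)
  if (position < 1L || position > n)
    stop(sprintf("position %d out of range [1, %d]", position, n))
  as.numeric(window_feature_matrix(matrix$values,
                                   config$outside_window)[position, ])
}

#' Build a labelled per-residue dataset
#'
#' One sample per residue across all proteins; label 1 iff the residue
#' lies inside an annotated MoRF interval.  With `balance = TRUE` all
#' positives are kept and negatives are down-sampled uniformly at
#' random (seeded) to `ratio` negatives per positive (default 1:1).
#' When fewer negatives exist than requested, all are kept with a
#' warning.
#'
#' @param proteins List of [protein_record()] each carrying a
#'   `stage = "scaled"` matrix of matching length.
#' @param config A [window_config()].
#' @param balance Down-sample negatives?
#' @param ratio Negatives per positive after balancing.
#' @param seed Integer seed for the negative sampling.
#'
#' @return An object of class `morf_dataset`: list with `x` (sample x
#'   feature matrix), `y` (integer 0/1 labels) and `provenance` (data
#'   frame of `protein_id`, `position`).
#' @export
build_dataset <- function(proteins, config = window_config(), balance = FALSE,
                          ratio = 1, seed = 1L) {
  stopifnot(inherits(config, "window_config"))
  parts <- lapply(proteins, function(p) {
    stopifnot(inherits(p, "protein_record"))
    if (is.null(p$matrix)) stop(sprintf("protein '%s' has no matrix", p$id))
    if (p$matrix$stage != "scaled")
      stop(sprintf("protein '%s': dataset requires a stage=scaled matrix, got %s",
                   p$id, p$matrix$stage))
    if (nrow(p$matrix$values) != p$length)
      stop(sprintf("protein '%s': matrix/sequence length mismatch", p$id))
    list(x = window_feature_matrix(p$matrix$values, config$outside_window),
         y = morf_labels(p),
         prov = data.frame(protein_id = p$id, position = seq_len(p$length)))
  })
  x <- do.call(rbind, lapply(parts, `[[`, "x"))
  y <- unlist(lapply(parts, `[[`, "y"), use.names = FALSE)
  prov <- do.call(rbind, lapply(parts, `[[`, "prov"))

  if (balance) {
    pos <- which(y == 1L)
    neg <- which(y == 0L)
    want <- floor(length(pos) * ratio)
    if (length(neg) <= want) {
      warning(sprintf("only %d negatives available for %d requested; keeping all",
                      length(neg), want))
      keep <- sort(c(pos, neg))
    } else {
      sampled <- with_seed(seed, sample(neg, want))
      keep <- sort(c(pos, sampled))
    }
    x <- x[keep, , drop = FALSE]
    y <- y[keep]
    prov <- prov[keep, , drop = FALSE]
    rownames(prov) <- NULL
  }
  structure(list(x = x, y = as.integer(y), provenance = prov,
                 window_config = config),
            class = "morf_dataset")
}

#' @export
print.morf_dataset <- function(x, ...) {
  cat(sprintf("<morf_dataset> %d samples (%d MoRF, %d non-MoRF), %d features\n",
              length(x$y), sum(x$y == 1L), sum(x$y == 0L), ncol(x$x)))
  invisible(x)
}
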