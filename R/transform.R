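# PSSM transformations: masking (local-mean subtraction), filtering
# (zeroing sub-average scores), smoothing (windowed row summation with
# zero padding), [-1, 1] scaling, the ablation encoders and the row-sum
# conservation profiles.

#' Transformation configuration
#'
#' Window sizes and scaling for the PSSM transformation chain.
#' Defaults are the final model's choices: masking window 25 residues,
#' smoothing window 13, and a scale divisor resolved from the training
#' set (`"auto"` = maximum absolute value over all training matrices at
#' the encoder's final pre-scaling stage).
#'
#' @param mask_window Odd positive integer, the masking window `2n + 1`.
#' @param smooth_window Odd positive integer, the smoothing window
#'   `2m + 1`.
#' @param scale_divisor Positive number, or `"auto"` to resolve from
#'   training data (see [resolve_scale_divisor()]).
#' @param encoder_mode One of `"raw"` (scaled standard PSSM),
#'   `"mask_only"` (mask + filter), `"smooth_only"` (smoothing applied
#'   directly to the raw matrix) or `"mfs"` (mask, filter, smooth — the
#'   full chain).
#'
#' @return An object of class `transform_config`.
#' @export
transform_config <- function(mask_window = 25L, smooth_window = 13L,
                             scale_divisor = "auto",
                             encoder_mode = c("mfs", "raw", "mask_only",
                                              "smooth_only")) {
  encoder_mode <- match.arg(encoder_mode)
  mask_window <- check_odd_window(mask_window, "mask_window")
  smooth_window <- check_odd_window(smooth_window, "smooth_window")
  if (is.numeric(scale_divisor)) {
    if (length(scale_divisor) != 1L || is.na(scale_divisor) || scale_divisor <= 0)
      stop("`scale_divisor` must be a single positive number or \"auto\"")
  } else if (!identical(scale_divisor, "auto")) {
    stop("`scale_divisor` must be a single positive number or \"auto\"")
  }
  structure(list(mask_window = mask_window, smooth_window = smooth_window,
                 scale_divisor = scale_divisor, encoder_mode = encoder_mode),
            class = "transform_config")
}

#' Mask a raw PSSM (relative local conservation)
#'
#' For each of the 20 columns independently, subtracts from every score
#' the mean of the scores in the window of `mask_window` positions
#' centred on it (the window includes the position itself).  At the
#' sequence termini the window is truncated to the positions that exist
#' and the mean divides by the actual count.
#'
#' @param matrix A `stage = "raw"` [score_matrix()].
#' @param mask_window Odd positive window size `2n + 1` (default 25).
#'
#' @return A `stage = "masked"` [score_matrix()].
#' @export
mask_pssm <- function(matrix, mask_window = 25L) {
  stopifnot(inherits(matrix, "score_matrix"))
  if (matrix$stage != "raw")
    stop(sprintf("mask_pssm expects a stage=raw matrix, got stage=%s", matrix$stage))
  mask_window <- check_odd_window(mask_window, "mask_window")
  half <- (mask_window - 1L) %/% 2L
  n <- nrow(matrix$values)
  cnt <- window_count(n, half)
  out <- matrix$values - vapply(seq_len(20L), function(j)
    window_sum(matrix$values[, j], half) / cnt, numeric(n))
  score_matrix(base::matrix(out, nrow = n), protein_id = matrix$protein_id,
               stage = "masked", sequence = matrix$sequence)
}

#' Filter a masked PSSM
#'
#' Keeps only above-local-average conservation: every masked score
#' `v` becomes `v` if `v > 0` and `0` otherwise.
#'
#' @param matrix A `stage = "masked"` [score_matrix()].
#' @return A `stage = "filtered"` [score_matrix()].
#' @export
filter_pssm <- function(matrix) {
  stopifnot(inherits(matrix, "score_matrix"))
  if (matrix$stage != "masked")
    stop(sprintf("filter_pssm expects a stage=masked matrix, got stage=%s",
                 matrix$stage))
  score_matrix(pmax(matrix$values, 0), protein_id = matrix$protein_id,
               stage = "filtered", sequence = matrix$sequence)
}

#' Smooth a PSSM by windowed row summation
#'
#' Conceptually appends `m = (smooth_window - 1) / 2` all-zero rows at
#' each end, then replaces row `i` by the element-wise SUM (not mean) of
#' rows `i - m` to `i + m`.  The output has exactly N rows.  Normally
#' applied to a filtered matrix (the full transformation chain); may
#' also be applied directly to a raw matrix for the smoothing-only
#' ablation encoder.
#'
#' @param matrix A `stage = "filtered"` or `stage = "raw"`
#'   [score_matrix()].
#' @param smooth_window Odd positive window size `2m + 1` (default 13).
#'
#' @return A `stage = "smoothed"` [score_matrix()].
#' @export
smooth_pssm <- function(matrix, smooth_window = 13L) {
  stopifnot(inherits(matrix, "score_matrix"))
  if (!matrix$stage %in% c("filtered", "raw"))
    stop(sprintf("smooth_pssm expects a stage=filtered or stage=raw matrix, got stage=%s",
                 matrix$stage))
  smooth_window <- check_odd_window(smooth_window, "smooth_window")
  half <- (smooth_window - 1L) %/% 2L
  n <- nrow(matrix$values)
  out <- vapply(seq_len(20L), function(j)
    window_sum(matrix$values[, j], half), numeric(n))
  score_matrix(base::matrix(out, nrow = n), protein_id = matrix$protein_id,
               stage = "smoothed", sequence = matrix$sequence)
}

#' Scale a matrix into \[-1, 1\]
#'
#' Divides every value by `scale_divisor` and clips the result to
#' \[-1, 1\].  The divisor is a single global constant learned from the
#' training set (see [resolve_scale_divisor()]) and reused verbatim at
#' prediction time, so train and test features live in the same space.
#'
#' @param matrix A [score_matrix()] at any stage but `scaled`.
#' @param scale_divisor Positive number.
#' @return A `stage = "scaled"` [score_matrix()].
#' @export
scale_pssm <- function(matrix, scale_divisor) {
  stopifnot(inherits(matrix, "score_matrix"))
  if (matrix$stage == "scaled") stop("matrix is already scaled")
  if (!is.numeric(scale_divisor) || length(scale_divisor) != 1L ||
      is.na(scale_divisor) || scale_divisor <= 0)
    stop("`scale_divisor` must be a single positive number")
  vals <- pmin(pmax(matrix$values / scale_divisor, -1), 1)
  score_matrix(vals, protein_id = matrix$protein_id, stage = "scaled",
               sequence = matrix$sequence)
}

# The pre-scaling transformation chain of an encoder mode.
encoder_prescale <- function(matrix, config) {
  switch(config$encoder_mode,
         raw = matrix,
         mask_only = filter_pssm(mask_pssm(matrix, config$mask_window)),
         smooth_only = smooth_pssm(matrix, config$smooth_window),
         mfs = smooth_pssm(filter_pssm(mask_pssm(matrix, config$mask_window)),
                           config$smooth_window))
}

#' Resolve an "auto" scale divisor from training matrices
#'
#' Applies the configured encoder's transformation chain to every raw
#' training matrix and returns the maximum absolute value observed —
#' the global ratio that maps the training feature space into
#' \[-1, 1\].  Falls back to 1 if all values are zero.
#'
#' @param matrices List of `stage = "raw"` [score_matrix()] objects.
#' @param config A [transform_config()].
#' @return A positive number.
#' @export
resolve_scale_divisor <- function(matrices, config) {
  stopifnot(inherits(config, "transform_config"))
  if (is.numeric(config$scale_divisor)) return(config$scale_divisor)
  mx <- max(vapply(matrices, function(m)
    max(abs(encoder_prescale(m, config)$values)), numeric(1)))
  if (mx == 0) 1 else mx
}

#' Apply a full encoder to a raw matrix
#'
#' Runs the transformation chain selected by `config$encoder_mode` and
#' scales the result into \[-1, 1\]:
#' `raw` = identity then scale; `mask_only` = mask, filter, scale;
#' `smooth_only` = smooth the raw matrix, scale; `mfs` = mask, filter,
#' smooth, scale.
#'
#' @param matrix A `stage = "raw"` [score_matrix()].
#' @param config A [transform_config()] whose `scale_divisor` is
#'   numeric (already resolved).
#'
#' @return A `stage = "scaled"` [score_matrix()].
#' @export
apply_encoder <- function(matrix, config) {
  stopifnot(inherits(matrix, "score_matrix"), inherits(config, "transform_config"))
  if (matrix$stage != "raw")
    stop(sprintf("apply_encoder expects a stage=raw matrix, got stage=%s",
                 matrix$stage))
  if (!is.numeric(config$scale_divisor))
    stop("scale_divisor is unresolved; call resolve_scale_divisor() on the training matrices first")
  scale_pssm(encoder_prescale(matrix, config), config$scale_divisor)
}

#' Per-residue conservation profile (row sums)
#'
#' Sums each residue's 20 column scores, giving one local-conservation
#' value per position.  Applied to raw, masked(+filtered) and smoothed
#' matrices this yields the three profiles whose MoRF/non-MoRF
#' distributions shift across the transformation chain.
#'
#' @param matrix A [score_matrix()].
#' @return An object of class `conservation_profile`: list with
#'   `protein_id`, `sums` (length-N numeric) and `stage`.
#' @export
conservation_profile <- function(matrix) {
  stopifnot(inherits(matrix, "score_matrix"))
  structure(list(protein_id = matrix$protein_id,
                 sums = rowSums(matrix$values),
                 stage = matrix$stage),
            class = "conservation_profile")
}
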