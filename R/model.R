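# RBF-kernel SVM classifier over windowed PSSM features: stratified
# k-fold grid search, training, persistence and per-residue prediction.
# The SVM itself comes from e1071 (libsvm); everything around it — the
# encoder, the featurization, the fold assignment and the decision-score
# orientation — is owned here so that a persisted model reproduces its
# predictions exactly.

default_cost_grid <- function() 2^seq(-5, 15, by = 2)
default_gamma_grid <- function() 2^seq(-15, 3, by = 2)

# Stratified fold ids: each class is split as evenly as possible.
stratified_folds <- function(y, folds, seed) {
  id <- integer(length(y))
  with_seed(seed, {
    for (cls in unique(y)) {
      idx <- which(y == cls)
      id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
  })
  id
}

svm_fit <- function(x, y, cost, gamma) {
  e1071::svm(x = x, y = factor(y, levels = c(0L, 1L)), scale = FALSE,
             type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma)
}

# Signed decision score oriented so that larger = more MoRF-like.
svm_scores <- function(fit, x) {
  dv <- attr(stats::predict(fit, x, decision.values = TRUE),
             "decision.values")
  s <- dv[, 1L]
  # libsvm labels the column "a/b" with positive values favouring a
  if (startsWith(colnames(dv)[1L], "0")) s <- -s
  unname(s)
}

#' Grid search for SVM hyperparameters
#'
#' Exhaustively evaluates every (cost, gamma) pair by stratified k-fold
#' cross-validation and returns the pair maximizing mean balanced
#' accuracy ((sensitivity + specificity) / 2) across folds.  Fold
#' assignment is seeded, so the search is reproducible.
#'
#' @param dataset A [build_dataset()] result with both classes present.
#' @param cost_grid,gamma_grid Numeric grids; defaults are the coarse
#'   powers-of-two grid of libsvm practice (cost 2^-5..2^15, gamma
#'   2^-15..2^3, steps of 2^2).
#' @param folds Number of cross-validation folds (default 5).
#' @param seed Integer seed for the fold assignment.
#'
#' @return List with `cost`, `gamma`, `accuracy` (the winning mean CV
#'   balanced accuracy) and `table` (a data frame of all grid points).
#' @export
grid_search <- function(dataset, cost_grid = default_cost_grid(),
                        gamma_grid = default_gamma_grid(), folds = 5L,
                        seed = 1L) {
  stopifnot(inherits(dataset, "morf_dataset"), folds >= 2L)
  y <- dataset$y
  if (length(unique(y)) < 2L)
    stop("grid search requires both classes in the dataset")
  fold_id <- stratified_folds(y, folds, seed)
  grid <- expand.grid(cost = cost_grid, gamma = gamma_grid,
                      KEEP.OUT.ATTRS = FALSE)
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(k) {
    accs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2L || !any(!tr)) return(NA_real_)
      fit <- svm_fit(dataset$x[tr, , drop = FALSE], y[tr],
                     grid$cost[k], grid$gamma[k])
      calls <- as.integer(svm_scores(fit, dataset$x[!tr, , drop = FALSE]) > 0)
      cm <- confusion_counts(calls, y[!tr])
      classification_metrics(cm)$balanced_accuracy
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(grid$accuracy)
  list(cost = grid$cost[best], gamma = grid$gamma[best],
       accuracy = grid$accuracy[best], table = grid)
}

#' Train the MoRF classifier
#'
#' Fits an RBF-kernel C-SVM on a labelled windowed-feature dataset and
#' packages it with the transformation and window configurations that
#' produced the features, so prediction on a new protein reapplies the
#' exact same encoding.
#'
#' @param dataset A [build_dataset()] result with both classes present.
#' @param cost,gamma SVM hyperparameters (see [grid_search()]).
#' @param transform_config The [transform_config()] used to encode the
#'   training matrices; its `scale_divisor` must be numeric (resolved).
#' @param threshold Decision threshold on the signed score for binary
#'   calls (default 0).
#' @param seed Seed recorded in the training metadata.
#'
#' @return An object of class `morf_model`.
#' @export
train_model <- function(dataset, cost, gamma, transform_config,
                        threshold = 0, seed = NA_integer_) {
  stopifnot(inherits(dataset, "morf_dataset"),
            inherits(transform_config, "transform_config"))
  if (length(dataset$y) == 0L) stop("dataset is empty")
  if (length(unique(dataset$y)) < 2L)
    stop("training requires both classes in the dataset")
  if (!is.numeric(transform_config$scale_divisor))
    stop("transform_config$scale_divisor must be resolved (numeric) before training")
  fit <- svm_fit(dataset$x, dataset$y, cost, gamma)
  structure(list(fit = fit, cost = cost, gamma = gamma,
                 threshold = threshold,
                 transform_config = transform_config,
                 window_config = dataset$window_config,
                 n_positive = sum(dataset$y == 1L),
                 n_negative = sum(dataset$y == 0L),
                 seed = seed),
            class = "morf_model")
}

#' @export
print.morf_model <- function(x, ...) {
  cat(sprintf(paste0("<morf_model> RBF SVM (cost=%g, gamma=%g), encoder=%s,",
                     " trained on %d MoRF / %d non-MoRF residues\n"),
              x$cost, x$gamma, x$transform_config$encoder_mode,
              x$n_positive, x$n_negative))
  invisible(x)
}

#' Predict MoRF residues of a protein
#'
#' Applies the model's stored encoder (with the training-time scale
#' divisor) and window featurization to the protein's raw score matrix,
#' then scores every residue with the SVM.  The binary call is
#' `score > threshold` with the model's stored threshold.
#'
#' @param object A [train_model()] result.
#' @param protein A [protein_record()] carrying a `stage = "raw"`
#'   matrix, or a bare `stage = "raw"` [score_matrix()].
#' @param ... Ignored.
#'
#' @return Data frame with one row per residue: `protein_id`,
#'   `position` (1-based), `residue`, `score` (signed decision value,
#'   larger = more MoRF-like) and `call` (0/1).
#' @export
predict.morf_model <- function(object, protein, ...) {
  if (inherits(protein, "protein_record")) {
    if (is.null(protein$matrix))
      stop(sprintf("protein '%s' has no matrix attached", protein$id))
    matrix <- protein$matrix
    residues <- strsplit(protein$sequence, "")[[1]]
  } else if (inherits(protein, "score_matrix")) {
    matrix <- protein
    residues <- if (is.null(matrix$sequence)) rep("-", nrow(matrix$values)) else
      strsplit(matrix$sequence, "")[[1]]
  } else stop("`protein` must be a protein_record or a score_matrix")
  if (matrix$stage != "raw")
    stop(sprintf("prediction requires a stage=raw matrix, got stage=%s",
                 matrix$stage))
  scaled <- apply_encoder(matrix, object$transform_config)
  feats <- window_feature_matrix(scaled$values,
                                 object$window_config$outside_window)
  score <- svm_scores(object$fit, feats)
  data.frame(protein_id = matrix$protein_id,
             position = seq_along(score),
             residue = residues,
             score = score,
             call = as.integer(score > object$threshold))
}

#' Save / load a trained model
#'
#' Plain RDS round-trip; a loaded model predicts identically to the
#' model that was saved.
#'
#' @param model A `morf_model`.
#' @param path File path.
#' @return `save_model`: `path`, invisibly.  `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "morf_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "morf_model"))
    stop(sprintf("%s does not contain a morf_model", path))
  model
}

#' End-to-end training pipeline
#'
#' Convenience wrapper over the full training chain: resolves the scale
#' divisor from the training matrices, encodes every protein, builds a
#' class-balanced windowed dataset and fits the SVM.
#'
#' @param proteins List of [protein_record()] each carrying a
#'   `stage = "raw"` matrix and MoRF annotations.
#' @param transform_config A [transform_config()]; an `"auto"` scale
#'   divisor is resolved here and stored resolved in the model.
#' @param window_config A [window_config()].
#' @param cost,gamma SVM hyperparameters.
#' @param balance,ratio,seed Passed to [build_dataset()].
#'
#' @return A `morf_model`.
#' @export
fit_morf_predictor <- function(proteins,
                               transform_config = morfscan::transform_config(),
                               window_config = morfscan::window_config(),
                               cost = 1, gamma = NULL,
                               balance = TRUE, ratio = 1, seed = 1L) {
  raw <- lapply(proteins, function(p) {
    if (is.null(p$matrix) || p$matrix$stage != "raw")
      stop(sprintf("protein '%s' must carry a stage=raw matrix", p$id))
    p$matrix
  })
  divisor <- resolve_scale_divisor(raw, transform_config)
  cfg <- transform_config
  cfg$scale_divisor <- divisor
  encoded <- lapply(proteins, function(p)
    set_matrix(p, apply_encoder(p$matrix, cfg)))
  dataset <- build_dataset(encoded, window_config, balance = balance,
                           ratio = ratio, seed = seed)
  if (is.null(gamma)) gamma <- 1 / ncol(dataset$x)
  train_model(dataset, cost = cost, gamma = gamma, transform_config = cfg,
              seed = seed)
}
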