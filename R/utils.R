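# Internal helpers shared across modules.

#' Canonical PSI-BLAST amino-acid column order
#'
#' The 20 standard amino acids in the order PSI-BLAST prints its matrix
#' header: A R N D C Q E G H I L K M F P S T W Y V.
#'
#' @return Character vector of length 20.
#' @export
aa_order <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Windowed sum of x over [i - half, i + half], positions outside the vector
# contributing zero.  O(n) via cumulative sums.
window_sum <- function(x, half) {
  n <- length(x)
  cs <- cumsum(x)
  hi <- pmin(seq_len(n) + half, n)
  lo <- pmax(seq_len(n) - half, 1L)
  cs[hi] - c(0, cs)[lo]
}

# Number of in-range positions in the window [i - half, i + half].
window_count <- function(n, half) {
  pmin(seq_len(n) + half, n) - pmax(seq_len(n) - half, 1L) + 1L
}

check_odd_window <- function(w, name) {
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 1 || w %% 2 != 1)
    stop(sprintf("`%s` must be an odd positive integer, got %s",
                 name, deparse(w)), call. = FALSE)
  as.integer(w)
}
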