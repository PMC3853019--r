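# Composition analysis of MoRFs, their flanking regions and general
# non-MoRF regions: per-residue region partition at a flank length W,
# pooled amino-acid and physicochemical-property compositions,
# composition-difference curves across W, and Pearson correlation of
# the difference with W.

REGION_TAGS <- c("MoRF", "flank", "nonMoRF")

#' Physicochemical property groups
#'
#' The ten properties used in the composition analysis (hydrophobic,
#' polar, small, proline, tiny, aliphatic, aromatic, positive, negative,
#' charged), with membership following Taylor's amino-acid
#' classification.  Groups overlap, so property fractions carry no
#' sum-to-one constraint.
#'
#' @return Named list of character vectors of amino-acid letters.
#' @export
property_groups <- function() {
  list(hydrophobic = c("A", "C", "F", "G", "H", "I", "K", "L", "M", "T",
                       "V", "W", "Y"),
       polar = c("C", "D", "E", "H", "K", "N", "Q", "R", "S", "T", "W", "Y"),
       small = c("A", "C", "D", "G", "N", "P", "S", "T", "V"),
       proline = "P",
       tiny = c("A", "C", "G", "S"),
       aliphatic = c("I", "L", "V"),
       aromatic = c("F", "H", "W", "Y"),
       positive = c("H", "K", "R"),
       negative = c("D", "E"),
       charged = c("D", "E", "H", "K", "R"))
}

#' Read property groups from a two-column TSV
#'
#' Expects columns `property` and `residues` (a string of amino-acid
#' letters), one row per property.
#'
#' @param path TSV path.
#' @return Named list of character vectors, as [property_groups()].
#' @export
read_property_groups <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("property", "residues") %in% names(tab)))
    stop("property TSV must have columns 'property' and 'residues'")
  groups <- lapply(tab$residues, function(s) strsplit(toupper(s), "")[[1]])
  names(groups) <- tab$property
  bad <- setdiff(unlist(groups), aa_order())
  if (length(bad))
    stop(sprintf("property groups contain non-standard letters: %s",
                 paste(unique(bad), collapse = ", ")))
  groups
}

#' Partition a protein into MoRF / flank / non-MoRF regions
#'
#' MoRF residues are exactly those inside annotated intervals.  Flank
#' residues lie within `w` positions of a MoRF boundary but outside
#' every MoRF (two MoRFs closer than `2w` share the intervening flank,
#' each residue tagged once).  Everything else is general non-MoRF.
#'
#' @param protein A [protein_record()].
#' @param w Flank length in residues (>= 0).
#'
#' @return Character vector of length `protein$length` with values
#'   `"MoRF"`, `"flank"`, `"nonMoRF"`.
#' @export
partition_regions <- function(protein, w) {
  stopifnot(inherits(protein, "protein_record"), w >= 0)
  labels <- morf_labels(protein)
  tags <- rep("nonMoRF", protein$length)
  tags[labels == 1L] <- "MoRF"
  iv <- protein$morf_intervals
  for (k in seq_len(nrow(iv))) {
    left <- max(1L, iv[k, "start"] - as.integer(w)):iv[k, "start"]
    right <- iv[k, "end"]:min(protein$length, iv[k, "end"] + as.integer(w))
    near <- c(left, right)
    tags[near[labels[near] == 0L]] <- "flank"
  }
  tags
}

# Pooled residue letters of one region across a list of proteins.
region_residues <- function(records, w, region) {
  region <- match.arg(region, REGION_TAGS)
  unlist(lapply(records, function(p) {
    tags <- partition_regions(p, w)
    strsplit(p$sequence, "")[[1]][tags == region]
  }), use.names = FALSE)
}

#' Amino-acid composition of a region
#'
#' Pools all residues carrying the region tag across all proteins and
#' returns the fraction of each of the 20 standard amino acids (X
#' residues are excluded from the denominator).  Fractions sum to 1
#' for a non-empty region.
#'
#' @param records List of [protein_record()].
#' @param w Flank length.
#' @param region One of `"MoRF"`, `"flank"`, `"nonMoRF"`.
#'
#' @return Named numeric vector of 20 fractions (all `NA` when the
#'   region is empty over the dataset).
#' @export
region_composition <- function(records, w, region) {
  res <- region_residues(records, w, region)
  res <- res[res != "X"]
  counts <- table(factor(res, levels = aa_order()))
  if (length(res) == 0L) {
    warning(sprintf("region '%s' is empty at W=%d", region, w))
    return(stats::setNames(rep(NA_real_, 20L), aa_order()))
  }
  stats::setNames(as.numeric(counts) / length(res), aa_order())
}

#' Physicochemical-property composition of a region
#'
#' For each property group, the fraction of the region's residues whose
#' amino acid belongs to the group.
#'
#' @inheritParams region_composition
#' @param groups Named list of amino-acid sets, default
#'   [property_groups()].
#'
#' @return Named numeric vector, one fraction in \[0, 1\] per property.
#' @export
property_composition <- function(records, w, region, groups = property_groups()) {
  res <- region_residues(records, w, region)
  res <- res[res != "X"]
  if (length(res) == 0L) {
    warning(sprintf("region '%s' is empty at W=%d", region, w))
    return(stats::setNames(rep(NA_real_, length(groups)), names(groups)))
  }
  vapply(groups, function(g) mean(res %in% g), numeric(1))
}

#' Composition-difference curves across flank lengths
#'
#' For every flank length in `w_range`, computes composition(region_a)
#' minus composition(region_b) per feature (amino acid or property),
#' e.g. flank-vs-general-non-MoRF enrichment as a function of flank
#' length.
#'
#' @param records List of [protein_record()].
#' @param region_a,region_b Region tags to difference (A minus B).
#' @param w_range Integer vector of flank lengths (default 1:30).
#' @param type `"aa"` for the 20 amino acids, `"property"` for the ten
#'   property groups.
#' @param groups Property groups when `type = "property"`.
#'
#' @return Data frame with columns `w`, `feature`, `difference`.
#' @export
difference_curve <- function(records, region_a = "flank",
                             region_b = "nonMoRF", w_range = 1:30,
                             type = c("aa", "property"),
                             groups = property_groups()) {
  type <- match.arg(type)
  stopifnot(length(w_range) >= 1L)
  comp <- function(region, w)
    if (type == "aa") region_composition(records, w, region)
    else property_composition(records, w, region, groups)
  do.call(rbind, lapply(w_range, function(w) {
    d <- comp(region_a, w) - comp(region_b, w)
    data.frame(w = w, feature = names(d), difference = as.numeric(d),
               row.names = NULL)
  }))
}

#' Pearson correlation of composition difference with flank length
#'
#' Standard Pearson product–moment correlation of the difference series
#' against W, with the two-sided t-distribution p-value.  A constant
#' series (zero variance) yields `NA` with a warning.
#'
#' @param w Flank lengths.
#' @param difference Composition differences, same length (>= 3).
#'
#' @return List with `r` and `p`.
#' @export
flank_correlation <- function(w, difference) {
  if (length(w) != length(difference)) stop("w and difference differ in length")
  if (length(w) < 3L) stop("at least 3 points are required")
  if (stats::sd(w) == 0 || stats::sd(difference) == 0) {
    warning("constant series: correlation undefined")
    return(list(r = NA_real_, p = NA_real_))
  }
  ct <- stats::cor.test(w, difference, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Correlation table over all features
#'
#' Convenience wrapper producing one Pearson `r` and p-value per
#' feature from a [difference_curve()] result.
#'
#' @param curve Data frame from [difference_curve()].
#' @return Data frame with columns `feature`, `r`, `p`.
#' @export
flank_correlation_table <- function(curve) {
  stopifnot(all(c("w", "feature", "difference") %in% names(curve)))
  feats <- unique(curve$feature)
  do.call(rbind, lapply(feats, function(f) {
    sub <- curve[curve$feature == f, ]
    fc <- suppressWarnings(flank_correlation(sub$w, sub$difference))
    data.frame(feature = f, r = fc$r, p = fc$p, row.names = NULL)
  }))
}
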