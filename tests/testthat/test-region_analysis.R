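# Region partition, amino-acid / property composition, difference
# curves and flank-length correlation.

test_that("partition splits MoRF, flank and general non-MoRF regions", {
  p <- protein_record("p1", strrep("A", 10), morf_intervals = cbind(4, 6))
  tags <- partition_regions(p, 2)
  expect_equal(which(tags == "MoRF"), 4:6)
  expect_equal(which(tags == "flank"), c(2, 3, 7, 8))
  expect_equal(which(tags == "nonMoRF"), c(1, 9, 10))

  # W = 0: no flank at all
  expect_false("flank" %in% partition_regions(p, 0))

  # two MoRFs closer than 2W share the intervening flank
  q <- protein_record("q", strrep("A", 12),
                      morf_intervals = rbind(c(2, 3), c(7, 8)))
  tags <- partition_regions(q, 3)
  expect_equal(which(tags == "MoRF"), c(2, 3, 7, 8))
  expect_equal(which(tags == "flank"), c(1, 4, 5, 6, 9, 10, 11))
  expect_equal(sum(tags == "flank") + sum(tags == "MoRF") +
                 sum(tags == "nonMoRF"), 12L)
})

test_that("partition matches the per-residue distance oracle", {
  for (seed in 1:30) {
    p <- random_protein(40, seed = 200 + seed)
    for (w in c(0, 2, 5)) {
      tags <- partition_regions(p, w)
      expect_equal(tags, oracle_region_tags(p, w),
                   label = sprintf("seed=%d w=%d", seed, w))
    }
  }
})

test_that("region composition pools residues across proteins", {
  a <- protein_record("a", "AAAA", morf_intervals = cbind(1, 4))
  comp <- region_composition(list(a), 5, "MoRF")
  expect_equal(unname(comp["A"]), 1)
  expect_equal(sum(comp), 1)

  # two proteins contributing "AC" and "CA" to the MoRF region
  b1 <- protein_record("b1", "GGACGG", morf_intervals = cbind(3, 4))
  b2 <- protein_record("b2", "GGCAGG", morf_intervals = cbind(3, 4))
  comp <- region_composition(list(b1, b2), 0, "MoRF")
  expect_equal(unname(comp["A"]), 0.5)
  expect_equal(unname(comp["C"]), 0.5)

  for (seed in 1:10) {
    recs <- lapply(1:4, function(k) random_protein(30, seed = 300 + 4 * seed + k,
                                                   id = paste0("r", k)))
    for (region in c("MoRF", "flank", "nonMoRF")) {
      got <- suppressWarnings(region_composition(recs, 3, region))
      want <- suppressWarnings(oracle_composition(recs, 3, region))
      if (all(is.na(got))) next
      expect_equal(unname(got), unname(want), tolerance = 1e-12,
                   label = sprintf("seed=%d region=%s", seed, region))
    }
  }

  # an empty region is explicit, not silently zero
  none <- protein_record("n", "AAAA")
  expect_warning(out <- region_composition(list(none), 2, "MoRF"), "empty")
  expect_true(all(is.na(out)))
})

test_that("region compositions reconstruct the whole-dataset composition", {
  recs <- lapply(1:5, function(k) random_protein(50, seed = 400 + k,
                                                 id = paste0("w", k)))
  w <- 4
  pooled <- rep(0, 20)
  total <- 0
  for (region in c("MoRF", "flank", "nonMoRF")) {
    n_region <- sum(vapply(recs, function(p)
      sum(partition_regions(p, w) == region), numeric(1)))
    if (n_region == 0) next
    pooled <- pooled + region_composition(recs, w, region) * n_region
    total <- total + n_region
  }
  whole <- table(factor(unlist(strsplit(vapply(recs, `[[`, "", "sequence"), "")),
                        levels = aa_order()))
  expect_equal(unname(pooled / total), as.numeric(whole) / sum(whole),
               tolerance = 1e-12)
})

test_that("property composition counts group membership", {
  d <- protein_record("d", "DDEE", morf_intervals = cbind(1, 4))
  pc <- property_composition(list(d), 0, "MoRF")
  expect_equal(unname(pc["negative"]), 1)
  expect_equal(unname(pc["charged"]), 1)
  expect_equal(unname(pc["aromatic"]), 0)

  g <- protein_record("g", "GGGG", morf_intervals = cbind(1, 4))
  expect_equal(unname(property_composition(list(g), 0, "MoRF")["aromatic"]), 0)

  # membership-counting oracle on a random region
  for (seed in 1:5) {
    recs <- lapply(1:3, function(k) random_protein(30, seed = 500 + 3 * seed + k,
                                                   id = paste0("m", k)))
    groups <- property_groups()
    got <- suppressWarnings(property_composition(recs, 2, "flank", groups))
    if (all(is.na(got))) next
    chars <- unlist(lapply(recs, function(p) {
      strsplit(p$sequence, "")[[1]][oracle_region_tags(p, 2) == "flank"]
    }))
    for (prop in names(groups)) {
      expect_equal(unname(got[prop]),
                   sum(chars %in% groups[[prop]]) / length(chars),
                   label = prop)
    }
  }
})

test_that("difference curves are antisymmetric recomputations per W", {
  recs <- lapply(1:4, function(k) random_protein(60, seed = 600 + k,
                                                 id = paste0("d", k)))
  w_range <- 1:5
  ab <- suppressWarnings(difference_curve(recs, "flank", "nonMoRF", w_range))
  ba <- suppressWarnings(difference_curve(recs, "nonMoRF", "flank", w_range))
  expect_equal(ab$difference, -ba$difference)

  # self-difference is identically zero
  aa <- suppressWarnings(difference_curve(recs, "MoRF", "MoRF", w_range))
  expect_true(all(aa$difference == 0))

  # entries equal independently recomputed composition differences
  for (w in w_range) {
    d <- suppressWarnings(region_composition(recs, w, "flank") -
                            region_composition(recs, w, "nonMoRF"))
    sub <- ab[ab$w == w, ]
    expect_equal(sub$difference, unname(d), tolerance = 1e-12)
  }
})

test_that("flank correlation reproduces the textbook Pearson formula", {
  expect_equal(flank_correlation(1:3, 1:3)$r, 1)
  expect_equal(flank_correlation(1:3, 3:1)$r, -1)

  with_seed(95, {
    w <- 1:20
    d <- 0.02 * w + rnorm(20, sd = 0.1)
  })
  got <- flank_correlation(w, d)
  want <- oracle_pearson(w, d)
  expect_equal(got$r, want$r, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
  expect_lte(abs(got$r), 1)

  # r is invariant under affine rescaling of W
  expect_equal(flank_correlation(2 * w + 5, d)$r, got$r)

  expect_warning(out <- flank_correlation(1:5, rep(0.3, 5)), "constant")
  expect_true(is.na(out$r))
  expect_error(flank_correlation(1:2, 1:2), "3 points")
})

test_that("the correlation table covers every feature in the curve", {
  recs <- lapply(1:4, function(k) random_protein(60, seed = 700 + k,
                                                 id = paste0("c", k)))
  curve <- suppressWarnings(difference_curve(recs, "flank", "nonMoRF", 1:6))
  tab <- flank_correlation_table(curve)
  expect_setequal(tab$feature, aa_order())
  one <- suppressWarnings(
    flank_correlation(curve$w[curve$feature == "L"],
                      curve$difference[curve$feature == "L"]))
  expect_equal(tab$r[tab$feature == "L"], one$r)
})

test_that("property groups load from TSV and reject bad letters", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("property\tresidues", "negative\tDE", "tiny\tACGS"), f)
  g <- read_property_groups(f)
  expect_equal(g$negative, c("D", "E"))
  expect_equal(g$tiny, c("A", "C", "G", "S"))
  writeLines(c("property\tresidues", "odd\tDZ"), f)
  expect_error(read_property_groups(f), "non-standard")
})
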