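# FASTA, annotation, PSI-BLAST PSSM and matrix-TSV I/O.

test_that("FASTA parsing handles minimal files, duplicates and round-trips", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MKV"), f)
  recs <- read_fasta(f)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$id, "p1")
  expect_equal(recs[[1]]$length, 3L)
  expect_equal(recs[[1]]$sequence, "MKV")

  writeLines(c(">p1", "MKV", ">p1", "AC"), f)
  expect_error(read_fasta(f), "duplicate")

  expect_error(read_fasta(file.path(tempdir(), "nope.fasta")), "not found")

  # write-then-read identity on a generated set, order preserved
  recs <- lapply(1:25, function(k) random_protein(20 + k, seed = k,
                                                  id = sprintf("q%02d", k)))
  f2 <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f2)
  back <- read_fasta(f2)
  expect_equal(vapply(back, `[[`, "", "id"), vapply(recs, `[[`, "", "id"))
  expect_equal(vapply(back, `[[`, "", "sequence"),
               vapply(recs, `[[`, "", "sequence"))
})

test_that("nonstandard residue letters are rejected or mapped to X", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">p1", "MKBZV"), f)
  expect_error(read_fasta(f, nonstandard = "error"), "invalid residue")
  recs <- read_fasta(f, nonstandard = "map-to-X")
  expect_equal(recs[[1]]$sequence, "MKXXV")
})

test_that("annotations attach, canonicalize and validate intervals", {
  p <- protein_record("p1", strrep("A", 10))
  f <- withr::local_tempfile(fileext = ".tsv")

  writeLines(c("protein_id\tstart\tend", "p1\t4\t6"), f)
  out <- read_annotations(f, list(p))
  expect_equal(out[[1]]$morf_intervals,
               matrix(c(4L, 6L), 1, dimnames = list(NULL, c("start", "end"))))
  expect_equal(sum(morf_labels(out[[1]])), 3L)

  writeLines(c("protein_id\tstart\tend", "p1\t8\t12"), f)
  expect_error(read_annotations(f, list(p)), "outside")

  writeLines(c("protein_id\tstart\tend", "p1\t6\t4"), f)
  expect_error(read_annotations(f, list(p)), "start > end")

  # overlapping rows merge into one interval
  writeLines(c("protein_id\tstart\tend", "p1\t2\t5", "p1\t4\t7"), f)
  out <- read_annotations(f, list(p))
  expect_equal(unname(out[[1]]$morf_intervals[1, ]), c(2L, 7L))

  writeLines(c("protein_id\tstart\tend", "ghost\t1\t2"), f)
  expect_error(read_annotations(f, list(p)), "unknown protein")
  expect_warning(out <- read_annotations(f, list(p), unknown = "warn"),
                 "unknown protein")
  expect_equal(nrow(out[[1]]$morf_intervals), 0L)
})

test_that("annotation write/read is an identity on generated records", {
  recs <- lapply(1:10, function(k) random_protein(40, seed = 100 + k,
                                                  id = sprintf("r%02d", k)))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_annotations(recs, f)
  back <- read_annotations(f, lapply(recs, function(p)
    protein_record(p$id, p$sequence)))
  for (k in seq_along(recs))
    expect_equal(back[[k]]$morf_intervals, recs[[k]]$morf_intervals)
})

test_that("PSI-BLAST ASCII PSSM fixtures parse literally", {
  f <- withr::local_tempfile(fileext = ".pssm")
  header <- paste0("           ", paste(sprintf("%3s", aa_order()), collapse = ""))
  row1 <- paste0("    1 M  ", paste(sprintf("%3d", 1:20), collapse = ""), "  0.51 0.20")
  row2 <- paste0("    2 K  ", paste(sprintf("%3d", rep(-2L, 20)), collapse = ""))
  row3 <- paste0("    3 V  ", paste(sprintf("%3d", 20:1), collapse = ""))
  writeLines(c("", "Last position-specific scoring matrix computed",
               header, row1, row2, row3, ""), f)
  m <- read_psiblast_pssm(f, protein_id = "fix")
  expect_equal(m$stage, "raw")
  expect_equal(m$sequence, "MKV")
  expect_equal(unname(m$values[1, ]), as.numeric(1:20))
  expect_equal(unname(m$values[2, ]), rep(-2, 20))
  expect_equal(unname(m$values[3, ]), as.numeric(20:1))
})

test_that("PSSM parsing reorders non-canonical header columns", {
  f <- withr::local_tempfile(fileext = ".pssm")
  perm <- rev(aa_order())
  header <- paste0("           ", paste(sprintf("%3s", perm), collapse = ""))
  row1 <- paste0("    1 A  ", paste(sprintf("%3d", 1:20), collapse = ""))
  writeLines(c(header, row1), f)
  m <- read_psiblast_pssm(f)
  # value under header letter V (first in the permuted file) is 1
  expect_equal(unname(m$values[1, "V"]), 1)
  expect_equal(unname(m$values[1, "A"]), 20)
})

test_that("malformed PSSM files are rejected, not truncated", {
  f <- withr::local_tempfile(fileext = ".pssm")
  header <- paste0("           ", paste(sprintf("%3s", aa_order()), collapse = ""))
  writeLines(c(header, paste0("    1 M  ", paste(sprintf("%3d", 1:19), collapse = ""))), f)
  expect_error(read_psiblast_pssm(f), "fewer than 20")

  writeLines(c(header,
               paste0("    1 M  ", paste(sprintf("%3s", c("0.5", 2:20)), collapse = " "))), f)
  expect_error(read_psiblast_pssm(f), "non-integer")

  writeLines(header, f)
  expect_error(read_psiblast_pssm(f), "no residue rows")
})

test_that("PSSM write/read round-trips simulated matrices exactly", {
  m <- random_raw_matrix(30, seed = 5, id = "rt")
  f <- withr::local_tempfile(fileext = ".pssm")
  write_psiblast_pssm(m, f)
  back <- read_psiblast_pssm(f, protein_id = "rt")
  expect_equal(back$values, m$values)
  expect_equal(back$sequence, m$sequence)
})

test_that("matrix TSVs round-trip values, stage and sequence losslessly", {
  for (seed in 1:20) {
    raw <- random_raw_matrix(5 + seed, seed = seed)
    m <- smooth_pssm(filter_pssm(mask_pssm(raw, 5)), 3)
    f <- withr::local_tempfile(fileext = ".tsv")
    write_matrix_tsv(m, f)
    back <- read_matrix_tsv(f)
    expect_identical(back$values, m$values)
    expect_equal(back$stage, m$stage)
    expect_equal(back$protein_id, m$protein_id)
    expect_equal(back$sequence, m$sequence)
  }
})

test_that("a filtered-stage TSV containing negatives violates its stage contract", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# protein_id: bad", "# stage: filtered",
               paste(c("pos", "res", aa_order()), collapse = "\t"),
               paste(c("1", "A", -1, rep(0, 19)), collapse = "\t")), f)
  expect_error(read_matrix_tsv(f), "non-negative")
})
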