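test_that("exact and partial 3' adapters are trimmed, absent adapters are not", {
  adapter <- "AGATCGGAAGAGC"
  full <- tibble::tibble(seq = paste0("ACGTACGT", adapter),
                         qual = strrep("I", 8 + nchar(adapter)))
  out <- trim_adapter(full, adapter)
  expect_equal(out$seq, "ACGTACGT")
  expect_equal(out$qual, strrep("I", 8))

  none <- tibble::tibble(seq = "ACGTACGTACGTACGT", qual = strrep("I", 16))
  expect_equal(trim_adapter(none, adapter)$seq, none$seq)

  # read ending in the first 5 adapter bases: brute-force confirms position
  prefix5 <- substr(adapter, 1, 5)
  read <- paste0("TTTTGGGGCCCC", prefix5)
  out5 <- trim_adapter(tibble::tibble(seq = read, qual = strrep("I", nchar(read))),
                       adapter)
  expect_equal(out5$seq, "TTTTGGGGCCCC")
})

test_that("error-free overlapping pairs reconstruct the fragment exactly", {
  frag <- withr::with_seed(5, random_dna(420))
  pairs <- fixture_pairs(frag, read_len = 300)
  m <- merge_pairs(pairs)
  expect_equal(m$status, "merged")
  expect_equal(m$overlap_len, 180L)
  expect_equal(m$mismatches, 0L)
  expect_equal(m$merged_seq, frag)
  expect_equal(nchar(m$merged_seq), 300 + 300 - m$overlap_len)
})

test_that("unrelated reads fail to merge", {
  withr::with_seed(9, {
    pairs <- tibble::tibble(
      id = "x", seq1 = random_dna(300), qual1 = strrep("I", 300),
      seq2 = random_dna(300), qual2 = strrep("I", 300)
    )
  })
  expect_equal(merge_pairs(pairs)$status, "no_overlap")
})

test_that("overlap errors resolve toward the higher-quality base", {
  frag <- withr::with_seed(7, random_dna(420))
  pairs <- fixture_pairs(frag, read_len = 300)
  # corrupt 2 bases of r2 inside the overlap, marked low-quality
  s2 <- strsplit(pairs$seq2, "")[[1]]
  q2 <- strsplit(pairs$qual2, "")[[1]]
  # r2 position i covers fragment position 420 - i + 1; the overlap spans
  # fragment positions 121..300, i.e. r2 positions 121..300
  pos <- c(150, 250)
  for (i in pos) {
    s2[i] <- setdiff(c("A", "C", "G", "T"), s2[i])[1]
    q2[i] <- "#"
  }
  pairs$seq2 <- paste(s2, collapse = "")
  pairs$qual2 <- paste(q2, collapse = "")
  m <- merge_pairs(pairs)
  expect_equal(m$status, "merged")
  expect_equal(m$overlap_len, 180L)
  expect_equal(m$mismatches, 2L)
  expect_equal(m$merged_seq, frag)
  # brute-force check that the chosen overlap minimises mismatch density
  s2rc <- strsplit(revcomp(pairs$seq2), "")[[1]]
  s1 <- strsplit(pairs$seq1, "")[[1]]
  dens <- vapply(10:250, function(o) {
    mean(s1[(300 - o + 1):300] != s2rc[1:o])
  }, numeric(1))
  expect_equal(180L, (10:250)[which.min(dens)])
})

test_that("merge reconstructs random fragments across lengths (property)", {
  withr::with_seed(21, {
    # 300 bp reads with a 250 bp overlap cap merge fragments of 350-550 bp
    lens <- sample(350:550, 30, replace = TRUE)
    frags <- vapply(lens, random_dna, character(1))
  })
  m <- merge_pairs(fixture_pairs(frags, read_len = 300))
  expect_true(all(m$status == "merged"))
  expect_equal(m$merged_seq, frags)
  expect_equal(nchar(m$merged_seq), 600L - m$overlap_len)
})

test_that("merging is symmetric under mate swap with re-complementation", {
  frag <- withr::with_seed(13, random_dna(450))
  p <- fixture_pairs(frag, read_len = 300)
  fwd <- merge_pairs(p)
  swapped <- tibble::tibble(id = p$id, seq1 = p$seq2, qual1 = p$qual2,
                            seq2 = p$seq1, qual2 = p$qual1)
  rev <- merge_pairs(swapped)
  expect_equal(rev$overlap_len, fwd$overlap_len)
  expect_equal(revcomp(rev$merged_seq), fwd$merged_seq)
})

test_that("preprocess_sample merges paired samples and passes single reads through", {
  dir <- withr::local_tempdir()
  frags <- withr::with_seed(3, vapply(rep(400, 100), random_dna, character(1)))
  pairs <- fixture_pairs(frags, read_len = 300)
  write_fastq(dplyr::transmute(pairs, id, seq = seq1, qual = qual1),
              file.path(dir, "r1.fastq"))
  write_fastq(dplyr::transmute(pairs, id, seq = seq2, qual = qual2),
              file.path(dir, "r2.fastq"))
  entry <- as_pan_design(tibble::tibble(
    sample_id = "s1", pan = "p", round = 0, replicate = "rep1",
    r1 = file.path(dir, "r1.fastq"), r2 = file.path(dir, "r2.fastq")
  ))[1, ]
  res <- preprocess_sample(entry)
  expect_equal(res$stats$reads_merged, 100)
  expect_equal(res$stats$merge_rate, 1)
  expect_setequal(res$reads$seq, frags)

  # disjoint pairs are dropped
  bad <- withr::with_seed(4, tibble::tibble(
    id = sprintf("bad%02d", 1:20),
    seq1 = vapply(rep(300, 20), random_dna, character(1)),
    qual1 = strrep("I", 300),
    seq2 = vapply(rep(300, 20), random_dna, character(1)),
    qual2 = strrep("I", 300)
  ))
  both <- dplyr::bind_rows(pairs, bad)
  write_fastq(dplyr::transmute(both, id, seq = seq1, qual = qual1),
              file.path(dir, "r1.fastq"))
  write_fastq(dplyr::transmute(both, id, seq = seq2, qual = qual2),
              file.path(dir, "r2.fastq"))
  res2 <- preprocess_sample(entry)
  expect_equal(res2$stats$reads_merged, 100)
  expect_equal(res2$stats$merge_rate, 100 / 120)

  # single-read mode: merge stage skipped
  write_fastq(dplyr::transmute(pairs[1:50, ], id, seq = seq1, qual = qual1),
              file.path(dir, "sr.fastq"))
  entry_sr <- as_pan_design(tibble::tibble(
    sample_id = "s2", pan = "p", round = 0, replicate = "rep1",
    r1 = file.path(dir, "sr.fastq")
  ))[1, ]
  res3 <- preprocess_sample(entry_sr)
  expect_equal(nrow(res3$reads), 50)
  expect_equal(res3$stats$mode, "single")
  expect_equal(res3$reads$seq, pairs$seq1[1:50])
})
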