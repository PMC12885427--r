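test_that("approximate_match finds exact and near-exact occurrences", {
  hit <- approximate_match("ACGT", "TTACGTTT", 0)
  expect_equal(hit, tibble::tibble(start = 3L, end = 6L, edits = 0L))
  hit1 <- approximate_match("ACGT", "TTAGGTTT", 1)
  expect_equal(hit1$edits, 1L)
  expect_equal(nrow(approximate_match("ACGT", "TTTTTTTT", 1)), 0)
})

test_that("approximate_match agrees with the quadratic DP oracle", {
  withr::with_seed(42, {
    for (i in 1:150) {
      m <- sample(3:30, 1)
      p <- random_dna(m)
      t <- random_dna(sample(m:200, 1))
      hit <- approximate_match(p, t, m + nchar(t))
      expect_equal(hit$edits, oracle_semiglobal_edits(p, t))
    }
  })
})

test_that("internal long-pattern matcher agrees with the DP on edit counts", {
  withr::with_seed(24, {
    for (i in 1:40) {
      m <- sample(c(40:70, 120:300), 1)
      p <- random_dna(m)
      t <- random_dna(m + sample(0:150, 1))
      my <- panvhh:::cpp_myers_batch(p, t)
      dp <- panvhh:::cpp_approx_match(p, t, 100000L)
      expect_equal(my[1, "edits"], c(edits = dp[3]))
    }
  })
})

test_that("V references are trimmed to just before the last cysteine", {
  out <- trim_to_cysteine(tibble::tibble(name = "V1", seq = "ATGTGTGCT"))
  expect_equal(out$cys_trim_nt, "ATG") # last Cys is codon 2
  out2 <- trim_to_cysteine(tibble::tibble(name = "V2", seq = "TGTAAA"))
  expect_equal(out2$cys_trim_nt, "") # Cys is the first codon
  expect_warning(
    out3 <- trim_to_cysteine(tibble::tibble(name = "V3", seq = "ATGAAA")),
    "cysteine"
  )
  expect_equal(nrow(out3), 0)
  # the codon following the trim point is always a cysteine codon
  refs <- fixture_vrefs(4)
  pr <- trim_to_cysteine(refs)
  nxt <- substr(pr$seq_nt, nchar(pr$cys_trim_nt) + 1, nchar(pr$cys_trim_nt) + 3)
  expect_true(all(nxt %in% c("TGT", "TGC")))
  expect_true(all(startsWith(pr$seq_nt, pr$cys_trim_nt)))
})

test_that("the V-gene survey ranks references by read support", {
  refs <- fixture_vrefs(4, seed = 77)
  pr <- trim_to_cysteine(refs)
  withr::with_seed(8, {
    reads1 <- tibble::tibble(
      id = sprintf("r%03d", 1:100),
      seq = vapply(1:100, function(i) fixture_clone(pr[1, ]), character(1))
    )
  })
  only <- survey_v_genes(reads1, refs, pan_params(survey_size = 100))
  expect_equal(only$name, refs$name[1])

  withr::with_seed(9, {
    mix <- tibble::tibble(
      id = sprintf("m%03d", 1:1000),
      seq = c(
        vapply(1:600, function(i) fixture_clone(pr[1, ]), character(1)),
        vapply(1:400, function(i) fixture_clone(pr[2, ]), character(1))
      )
    )
  })
  ranked <- survey_v_genes(mix, refs, pan_params(survey_size = 1000))
  expect_equal(ranked$name, refs$name[1:2])
  top1 <- survey_v_genes(mix, refs, pan_params(survey_size = 1000,
                                               num_v_genes = 1))
  expect_equal(top1$name, refs$name[1])
  # no read resembles any reference
  junk <- withr::with_seed(10, tibble::tibble(
    id = "j1", seq = random_dna(400)
  ))
  expect_error(survey_v_genes(junk, refs, pan_params()), "no V genes")
})

test_that("error-free reads are annotated with exact V gene and CDR3", {
  refs <- fixture_vrefs(3, seed = 55)
  pr <- trim_to_cysteine(refs)
  cdr3_nt <- withr::with_seed(12, {
    paste(sample(setdiff(panvhh:::CODONS, c("TAA", "TAG", "TGA")), 9,
                 replace = TRUE), collapse = "")
  })
  read_seq <- paste0(pr$cys_trim_nt[2], "TGT", cdr3_nt, FWR4_FIX, "GGTCAA")
  ann <- annotate_read(tibble::tibble(id = "r1", seq = read_seq), pr,
                       FWR4_FIX)
  expect_true(ann$productive)
  expect_equal(ann$v_gene, pr$name[2])
  expect_equal(ann$cdr3_nt, cdr3_nt)
  expect_equal(ann$cdr3_aa, translate_dna(cdr3_nt))
  expect_equal(ann$orientation, "+")

  # orientation invariance: the reverse-complemented read annotates the
  # same, with the strand flipped
  rc <- annotate_read(tibble::tibble(id = "r1rc", seq = revcomp(read_seq)),
                      pr, FWR4_FIX)
  expect_equal(rc$orientation, "-")
  expect_equal(rc[c("v_gene", "cdr3_nt", "cdr3_aa", "full_nt", "full_aa",
                    "productive")],
               ann[c("v_gene", "cdr3_nt", "cdr3_aa", "full_nt", "full_aa",
                     "productive")])
})

test_that("stop codons and frameshifts mark reads unproductive", {
  refs <- fixture_vrefs(2, seed = 66)
  pr <- trim_to_cysteine(refs)
  cdr3_nt <- "GCTAAAGATTGGTATGCTGCTGCTGCTTAT" # 10 codons, no stops
  good <- paste0(pr$cys_trim_nt[1], "TGT", cdr3_nt, FWR4_FIX, "GGTCAA")
  # in-frame TAA inside the CDR3
  bad_stop <- paste0(pr$cys_trim_nt[1], "TGT", substr(cdr3_nt, 1, 15), "TAA",
                     substr(cdr3_nt, 16, 30), FWR4_FIX, "GGTCAA")
  a1 <- annotate_read(tibble::tibble(id = "s", seq = bad_stop), pr, FWR4_FIX)
  expect_false(a1$productive)
  expect_equal(a1$fail_reason, "stop_codon")
  # 1-base deletion between the cysteine and FWR4 breaks the frame
  bad_del <- paste0(pr$cys_trim_nt[1], "TGT", substr(cdr3_nt, 2, 30),
                    FWR4_FIX, "GGTCAA")
  a2 <- annotate_read(tibble::tibble(id = "d", seq = bad_del), pr, FWR4_FIX)
  expect_false(a2$productive)
  expect_equal(a2$fail_reason, "frameshift")
  # control stays productive
  a0 <- annotate_read(tibble::tibble(id = "g", seq = good), pr, FWR4_FIX)
  expect_true(a0$productive)
})

test_that("productive annotations have in-frame CDR3s inside the full translation", {
  cfg <- sim_config(n_clones = 80, n_binders = 0, enrichment_factor = 1,
                    rounds = 0, depth_per_round = 500,
                    subst_error_rate = 0.01, n_v_genes = 3, seed = 31)
  sim <- simulate_campaign(cfg, single_read = TRUE)
  ann <- annotate_sample(sim$samples[[1]]$reads, sim$truth$v_refs,
                         sim$truth$fwr4_nt, pan_params(survey_size = 200))
  prod <- dplyr::filter(ann$annotations, productive)
  expect_gt(nrow(prod), 0)
  expect_true(all(nchar(prod$cdr3_nt) %% 3 == 0))
  expect_true(all(mapply(grepl, prod$cdr3_aa, prod$full_aa,
                         MoreArgs = list(fixed = TRUE))))
  expect_false(any(grepl("*", prod$full_aa, fixed = TRUE)))
})

test_that("random DNA annotates as unproductive no_v; mixtures score in between", {
  refs <- fixture_vrefs(3, seed = 91)
  withr::with_seed(14, {
    junk <- tibble::tibble(
      id = sprintf("j%03d", 1:60),
      seq = vapply(rep(380, 60), random_dna, character(1))
    )
  })
  pr <- trim_to_cysteine(refs)
  ann <- annotate_reads(junk, pr, FWR4_FIX)
  expect_true(all(!ann$productive))
  expect_true(all(ann$fail_reason == "no_v"))

  withr::with_seed(15, {
    valid <- tibble::tibble(
      id = sprintf("v%03d", 1:90),
      seq = vapply(1:90, function(i) fixture_clone(pr[1, ]), character(1))
    )
  })
  mixed <- dplyr::bind_rows(valid, junk[1:10, ])
  res <- annotate_sample(mixed, refs, FWR4_FIX,
                         pan_params(survey_size = 100))
  expect_equal(res$stats$productive_rate, 0.9)
  expect_equal(res$stats$n_no_v, 10L)
})
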