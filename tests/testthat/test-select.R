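mk_clusters <- function(n, priority = TRUE, reps_enriched = 1L,
                        cpm = NULL, prefix = "CL") {
  cpm <- cpm %||% seq(2000, 2000 + n - 1)
  tibble::tibble(
    cluster_id = seq_len(n),
    representative = sprintf("%s%04dW", prefix, seq_len(n)),
    rep_full_aa = sprintf("QV%s%04dW", prefix, seq_len(n)),
    n_members = 1L,
    final_cpm = cpm,
    round0_cpm = 1,
    max_logfc = if (priority) 5 else 2,
    n_replicates_enriched = reps_enriched,
    consistent_increase = FALSE,
    priority = priority
  )
}
mk_members <- function(clusters) {
  tibble::tibble(
    clone = clusters$representative,
    abundance = clusters$final_cpm,
    logfc = clusters$max_logfc,
    n_replicates_enriched = clusters$n_replicates_enriched,
    cluster_id = clusters$cluster_id,
    representative = clusters$representative
  )
}
mk_ct <- function(members) {
  tibble::tibble(clone = members$clone, sample_id = "s",
                 count = 10L, cpm = members$abundance,
                 full_aa = paste0("QV", members$clone))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("with more priority clusters than slots, the list is all priority tier", {
  cl <- mk_clusters(150)
  mem <- mk_members(cl)
  sel <- pick_top_n(cl, mem, mk_ct(mem))
  expect_equal(nrow(sel), 100)
  expect_true(all(sel$tier == "priority"))
  expect_equal(sel$rank, 1:100)
  # ordered by final CPM descending within the tier
  expect_equal(sel$clone,
               mem$clone[order(-mem$abundance)][1:100])
})

test_that("scarce clusters fill the list from within selected clusters", {
  cl <- mk_clusters(3)
  mem <- purrr::map(1:3, function(i) {
    tibble::tibble(
      clone = sprintf("C%dM%02dWXX", i, 1:14)[1:(if (i == 1) 14 else 13)],
      abundance = seq(1000, 100, length.out = if (i == 1) 14 else 13),
      logfc = 3, n_replicates_enriched = 1L,
      cluster_id = i, representative = sprintf("C%dM01WXX", i)
    )
  }) |> purrr::list_rbind()
  # 40 unique member clones in total across 3 clusters
  expect_equal(nrow(mem), 40)
  cl$representative <- sprintf("C%dM01WXX", 1:3)
  sel <- pick_top_n(cl, mem, mk_ct(mem))
  expect_equal(nrow(sel), 40) # exhaustion below top_n
  expect_equal(sum(sel$tier != "intra_cluster_fill"), 3)
  expect_equal(sum(sel$tier == "intra_cluster_fill"), 37)
  expect_equal(anyDuplicated(sel$clone), 0)
})

test_that("clusters enriched in more replicates outrank equal-abundance ones", {
  x <- mk_clusters(1, reps_enriched = 3L, cpm = 5000, prefix = "XA")
  y <- mk_clusters(1, reps_enriched = 1L, cpm = 5000, prefix = "YB")
  y$cluster_id <- 2L
  cl <- dplyr::bind_rows(y, x) # input order must not matter
  mem <- mk_members(cl)
  sel <- pick_top_n(cl, mem, mk_ct(mem))
  expect_equal(sel$cluster_id, c(1L, 2L)) # X (3/3) before Y (1/3)
  expect_lt(sel$rank[sel$clone == x$representative],
            sel$rank[sel$clone == y$representative])
})

test_that("selection output is deterministic", {
  cl <- mk_clusters(30, priority = FALSE)
  mem <- mk_members(cl)
  s1 <- pick_top_n(cl, mem, mk_ct(mem))
  s2 <- pick_top_n(cl, mem, mk_ct(mem))
  expect_identical(s1, s2)
  empty <- suppressWarnings(pick_top_n(cl[0, ], mem[0, ], mk_ct(mem)))
  expect_equal(nrow(empty), 0)
})

test_that("replicate concordance emits all pairs with correct correlations", {
  mk_tab <- function(cpms) {
    n <- length(cpms[[1]])
    purrr::imap(cpms, function(v, rep) {
      tibble::tibble(clone = sprintf("CL%04d", 1:n),
                     sample_id = paste0("panA_", rep, "_r1"),
                     count = 10L, cpm = v, full_aa = "X")
    }) |> purrr::list_rbind()
  }
  des3 <- as_pan_design(tidyr::expand_grid(
    replicate = c("rep1", "rep2", "rep3"), round = c(0, 1)
  ) |> dplyr::mutate(pan = "panA", antigen = "panA",
                     sample_id = paste0("panA_", replicate, "_r", round),
                     r1 = "x"))
  # identical replicates: perfect correlation on the diagonal
  v <- withr::with_seed(4, runif(200, 0, 5000))
  tab <- mk_tab(list(rep1 = v, rep2 = v, rep3 = v))
  tab <- dplyr::bind_rows(tab, dplyr::mutate(
    tab, sample_id = sub("_r1$", "_r0", sample_id)
  ))
  conc <- replicate_concordance(tab, des3)
  sc <- glance(conc)
  expect_equal(nrow(dplyr::distinct(sc, rep_i, rep_j)), 3) # 3 pairs
  expect_true(all(sc$r == 1))
  expect_true(all(conc$cpm_i == conc$cpm_j))

  # independent random count vectors decorrelate
  withr::with_seed(5, {
    tabr <- mk_tab(list(rep1 = runif(1000, 0, 5000),
                        rep2 = runif(1000, 0, 5000)))
  })
  des2 <- des3[des3$replicate != "rep3", ]
  class(des2) <- class(des3)
  tabr <- dplyr::bind_rows(tabr, dplyr::mutate(
    tabr, sample_id = sub("_r1$", "_r0", sample_id)
  ))
  scr <- glance(replicate_concordance(tabr, des2))
  expect_true(all(abs(scr$r) < 0.1))

  # a single replicate yields an empty result, not an error
  one <- des3[des3$replicate == "rep1", ]
  class(one) <- class(des3)
  expect_equal(nrow(replicate_concordance(tab[grepl("rep1", tab$sample_id), ],
                                          one)), 0)
})

test_that("pan comparison pools similar clones and classifies membership", {
  mk_enr <- function(pan, clones, cpm = 3000) {
    tibble::tibble(clone = clones, pan = pan, final_cpm = cpm,
                   round0_cpm = 10, logfc = 4, enriched = TRUE,
                   n_replicates = 1L, n_replicates_enriched = 1L,
                   per_replicate = list(tibble::tibble()))
  }
  # similar but not identical clones across pans become cross-reactive
  enr <- dplyr::bind_rows(mk_enr("A", "CARDYW"), mk_enr("B", "CARDYF"))
  ov <- compare_pans(enr)
  expect_equal(nrow(ov$clusters), 1)
  expect_true(ov$clusters$A & ov$clusters$B)
  expect_equal(ov$classes$membership, "A&B")

  # dissimilar sets stay private
  enr2 <- dplyr::bind_rows(mk_enr("A", "CAAAAAAW"), mk_enr("B", "WGGGGGGC"))
  ov2 <- compare_pans(enr2)
  expect_setequal(ov2$classes$membership, c("A", "B"))

  # three pans sharing one clone family
  enr3 <- dplyr::bind_rows(mk_enr("A", "CARDYWAA"), mk_enr("B", "CARDYWAA"),
                           mk_enr("C", "CARDYWAV"),
                           mk_enr("A", "CHHHHHHW"))
  ov3 <- compare_pans(enr3)
  expect_equal(ov3$classes$n_clusters[ov3$classes$membership == "A&B&C"], 1L)

  # subtraction: keep target-only clusters, drop shared; partition holds
  kept <- subtract_pans(ov3, "A", "B")
  expect_equal(kept$representative, "CHHHHHHW")
  with_a <- ov3$clusters[ov3$clusters$A, ]
  removed <- subtract_pans(ov3, "A", character(0))
  expect_equal(nrow(removed), nrow(with_a)) # no subtraction = all target
  expect_error(subtract_pans(ov3, "Z", "B"), "not present")
  # every pooled cluster sits in exactly one membership class
  expect_equal(sum(ov3$classes$n_clusters), nrow(ov3$clusters))
})
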