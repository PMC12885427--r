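test_that("global identity uses the shorter-sequence denominator", {
  expect_equal(global_identity("CAKDW", "CAKDW"), 1.0)
  expect_equal(global_identity("CAKDW", "CAKEW"), 0.8)
  expect_equal(global_identity("CAK", "CAKDW"), 1.0)
  withr::with_seed(3, {
    for (i in 1:40) {
      a <- random_aa(sample(5:20, 1))
      b <- random_aa(sample(5:20, 1))
      expect_equal(global_identity(a, b), oracle_identity(a, b))
    }
  })
})

test_that("greedy clustering joins by representative identity and abundance order", {
  one <- greedy_cluster(tibble::tibble(
    clone = c("CARDYW", "CARDYF"), abundance = c(5000, 100)
  ))
  expect_equal(dplyr::n_distinct(one$cluster_id), 1)
  expect_equal(unique(one$representative), "CARDYW") # identity 5/6 >= 0.8

  three <- greedy_cluster(tibble::tibble(
    clone = c("CARDYWAAA", "GGGGGGGGG", "WWWWWCCCC"),
    abundance = c(3, 2, 1)
  ))
  expect_equal(dplyr::n_distinct(three$cluster_id), 3)

  fam <- greedy_cluster(tibble::tibble(
    clone = c("CARDYW", "CARDYF", "CARDYY"), abundance = c(9, 5, 1)
  ))
  expect_equal(dplyr::n_distinct(fam$cluster_id), 1)

  # every member passes the identity threshold against its representative
  withr::with_seed(6, {
    clones <- tibble::tibble(
      clone = unique(vapply(rep(c(8, 12, 16), 40), random_aa, character(1))),
      abundance = NA_real_
    )
    clones$abundance <- runif(nrow(clones), 1, 1e4)
  })
  cl <- greedy_cluster(clones)
  ok <- mapply(function(a, b) oracle_identity(a, b) >= 0.8,
               cl$clone, cl$representative)
  expect_true(all(ok))
  lr <- pmin(nchar(cl$clone), nchar(cl$representative)) /
    pmax(nchar(cl$clone), nchar(cl$representative))
  expect_true(all(lr >= 0.8))
  # deterministic across reruns
  expect_identical(cl, greedy_cluster(clones))
})

test_that("cluster abundance filter keeps >= 100 CPM and drops below", {
  cl <- tibble::tibble(cluster_id = 1:3, final_cpm = c(99.9, 100, 2500))
  kept <- filter_clusters(cl)
  expect_equal(kept$cluster_id, c(2L, 3L))
  expect_equal(nrow(filter_clusters(cl[0, ])), 0)
})

test_that("BLOSUM62 affine scores match the Gotoh oracle and are symmetric", {
  expect_equal(unname(blosum_score_matrix(c("CAK", "CAKW"))[1, 1]), 18)
  sub <- blosum62()
  withr::with_seed(11, {
    seqs <- unique(vapply(sample(6:18, 24, TRUE), random_aa, character(1)))
  })
  S <- blosum_score_matrix(seqs)
  expect_equal(S, t(S))
  for (i in 1:6) {
    for (j in (i + 1):7) {
      expect_equal(S[i, j],
                   oracle_affine_score(seqs[i], seqs[j], sub))
    }
  }
  # diagonal equals the self-alignment (sum of diagonal substitutions)
  self <- vapply(seqs, function(s) {
    sum(diag(sub[strsplit(s, "")[[1]], strsplit(s, "")[[1]], drop = FALSE]))
  }, numeric(1))
  expect_equal(unname(diag(S)), unname(self))
})

test_that("MDS embedding is deterministic and separates similarity blocks", {
  # two labels with identical score rows embed at identical coordinates
  S <- matrix(c(10, 9, 2, 9, 10, 2, 2, 2, 10), 3, 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  S["a", "b"] <- S["b", "a"] <- 10
  S["a", "a"] <- S["b", "b"] <- 10
  emb <- mds_embed(S)
  expect_equal(emb$PC1[1], emb$PC1[2])
  expect_error(mds_embed(S, n_components = 3), "smaller")

  # label permutation permutes coordinates without changing them
  withr::with_seed(13, {
    seqs <- unique(vapply(rep(10, 12), random_aa, character(1)))
  })
  S2 <- blosum_score_matrix(seqs)
  e1 <- mds_embed(S2)
  perm <- withr::with_seed(14, sample(length(seqs)))
  e2 <- mds_embed(S2[perm, perm])
  j <- dplyr::inner_join(e1, e2, by = "label")
  expect_equal(j$PC1.x, j$PC1.y, tolerance = 1e-8)
  expect_equal(j$PC2.x, j$PC2.y, tolerance = 1e-8)

  # two well-separated sequence families split on the first axis
  withr::with_seed(15, {
    base1 <- random_aa(12); base2 <- random_aa(12)
    mut <- function(b) {
      ch <- strsplit(b, "")[[1]]
      i <- sample(12, 2)
      ch[i] <- sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], 2)
      paste(ch, collapse = "")
    }
    fam <- unique(c(vapply(1:5, function(i) mut(base1), character(1)),
                    vapply(1:5, function(i) mut(base2), character(1)),
                    base1, base2))
  })
  grp <- ifelse(vapply(fam, oracle_identity, numeric(1), b = base1) >
                  vapply(fam, oracle_identity, numeric(1), b = base2), 1, 2)
  e3 <- mds_embed(blosum_score_matrix(fam))
  # silhouette-like check on axis 1: within-group spread smaller than
  # between-group separation
  m1 <- mean(e3$PC1[grp == 1]); m2 <- mean(e3$PC1[grp == 2])
  expect_true(all(abs(e3$PC1[grp == 1] - m1) < abs(m1 - m2) / 2))
  expect_true(all(abs(e3$PC1[grp == 2] - m2) < abs(m1 - m2) / 2))
})

test_that("cladograms are valid Newick with the expected topology", {
  S <- matrix(c(20, 18, 2,
                18, 20, 3,
                2, 3, 20), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tree <- build_cladogram(S)
  expect_s3_class(tree, "phylo")
  nwk <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tree, nwk)
  back <- ape::read.tree(nwk)
  expect_setequal(back$tip.label, c("A", "B", "C"))
  # the close pair (A, B) forms a cherry
  pair_depth <- ape::cophenetic.phylo(back)
  expect_lt(pair_depth["A", "B"], pair_depth["A", "C"])
  expect_lt(pair_depth["A", "B"], pair_depth["B", "C"])

  # two labels: single merge, both branch lengths equal
  t2 <- build_cladogram(S[1:2, 1:2])
  expect_equal(length(t2$tip.label), 2)
  expect_equal(t2$edge.length[1], t2$edge.length[2])
  expect_error(build_cladogram(S[1, 1, drop = FALSE]), "at least 2")
})
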