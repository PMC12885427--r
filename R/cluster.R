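#' Global alignment identity of two residue strings
#'
#' Identity is the number of identically aligned positions under a global
#' alignment maximising matches (match 1, mismatch 0, gaps free), divided by
#' the length of the shorter sequence -- the convention of greedy-incremental
#' clustering tools.
#'
#' @param a,b residue strings.
#' @return Identity fraction in \[0, 1\].
#' @examples
#' global_identity("CAKDW", "CAKEW") # 0.8
#' global_identity("CAK", "CAKDW")   # 1.0 (shorter-length denominator)
#' @export
global_identity <- function(a, b) cpp_identity(a, b)

#' Greedy incremental clustering of CDR3s
#'
#' Clones are sorted by decreasing abundance (ties: longer sequence first,
#' then lexicographic) and scanned in order; each clone joins the first
#' existing cluster whose representative (founder, the cluster's most
#' abundant member) passes both `identity_thr` (see [global_identity()])
#' and the length-ratio threshold `min(len)/max(len) >= length_thr`, else it
#' founds a new cluster.
#'
#' @param clones tibble with columns `clone` (CDR3 aa, unique) and
#'   `abundance` (final-round CPM or similar).
#' @param identity_thr minimum identity to the representative.
#' @param length_thr minimum length ratio to the representative.
#' @return The input tibble (in scan order) with `cluster_id` (integer) and
#'   `representative` columns appended.
#' @export
greedy_cluster <- function(clones, identity_thr = 0.80, length_thr = 0.80) {
  if (anyDuplicated(clones$clone)) abort("clone keys must be unique")
  ord <- clones |>
    arrange(desc(.data$abundance), desc(nchar(.data$clone)), .data$clone)
  if (nrow(ord) == 0) {
    return(mutate(ord, cluster_id = integer(), representative = character()))
  }
  cl <- cpp_greedy_cluster(ord$clone, identity_thr, length_thr)
  reps <- ord$clone[!duplicated(cl)][order(unique(cl))]
  ord |>
    mutate(cluster_id = as.integer(cl), representative = reps[cl])
}

#' Remove clusters below a final-round abundance floor
#'
#' Clusters whose summed final-round CPM is below `min_cluster_cpm` are
#' discarded as likely false positives.
#'
#' @param clusters cluster-level tibble with a `final_cpm` column (summed
#'   member CPM at the final round).
#' @param min_cluster_cpm retention threshold (kept when `>=`).
#' @return The retained rows.
#' @export
filter_clusters <- function(clusters, min_cluster_cpm = 100) {
  filter(clusters, .data$final_cpm >= min_cluster_cpm)
}

#' Cluster the enriched clones of one pan
#'
#' Convenience wrapper: greedy-clusters a pan's enriched clones by
#' final-round CPM, aggregates member abundance and enrichment per cluster
#' (including per-round summed CPM, replicate support and the
#' consistent-increase flag used for candidate priority), and applies the
#' final-round CPM floor.
#'
#' @param enrichment a [call_enriched()] result, restricted to one pan.
#' @param clone_table the campaign clone table.
#' @param design the campaign `pan_design`.
#' @param params a [pan_params()] list.
#' @return A list with `members` (clone-level tibble with cluster
#'   assignment) and `clusters` (cluster-level tibble: `cluster_id`,
#'   `representative`, `rep_full_aa`, `n_members`, `final_cpm`,
#'   `round0_cpm`, `max_logfc`, `n_replicates_enriched`,
#'   `consistent_increase`, `priority`).
#' @export
cluster_enriched <- function(enrichment, clone_table, design,
                             params = pan_params()) {
  params <- as_pan_params(params)
  pan_name <- unique(enrichment$pan)
  if (length(pan_name) != 1) abort("`enrichment` must cover exactly one pan")
  enr <- filter(enrichment, .data$enriched)
  empty <- list(
    members = tibble(clone = character(), abundance = numeric(),
                     cluster_id = integer(), representative = character()),
    clusters = tibble(cluster_id = integer(), representative = character(),
                      rep_full_aa = character(), n_members = integer(),
                      final_cpm = numeric(), round0_cpm = numeric(),
                      max_logfc = numeric(), n_replicates_enriched = integer(),
                      consistent_increase = logical(), priority = logical())
  )
  if (nrow(enr) == 0) return(empty)
  members <- enr |>
    select("clone", abundance = "final_cpm", "logfc",
           "n_replicates_enriched") |>
    greedy_cluster(params$cluster_identity, params$cluster_length_ratio)
  # per-round cluster CPM (replicate-mean of per-sample sums)
  rounds_cpm <- clone_table |>
    inner_join(members |> select("clone", "cluster_id"), by = "clone") |>
    inner_join(
      design |> as_tibble() |>
        filter(.data$pan == pan_name) |>
        select("sample_id", "round"),
      by = "sample_id"
    ) |>
    group_by(.data$cluster_id, .data$round, .data$sample_id) |>
    summarise(cpm = sum(.data$cpm), .groups = "drop_last") |>
    summarise(cpm = mean(.data$cpm), .groups = "drop")
  final_round <- max(rounds_cpm$round)
  trend <- rounds_cpm |>
    group_by(.data$cluster_id) |>
    arrange(.data$round, .by_group = TRUE) |>
    summarise(
      final_cpm = .data$cpm[.data$round == final_round],
      round0_cpm = .data$cpm[.data$round == 0L],
      consistent_increase = all(diff(.data$cpm) >= 0) &
        dplyr::last(.data$cpm) > dplyr::first(.data$cpm)
    )
  rep_aa <- clone_table |>
    distinct(.data$clone, .data$full_aa)
  clusters <- members |>
    group_by(.data$cluster_id, .data$representative) |>
    summarise(
      n_members = n(),
      max_logfc = max(.data$logfc),
      n_replicates_enriched = max(.data$n_replicates_enriched),
      .groups = "drop"
    ) |>
    left_join(trend, by = "cluster_id") |>
    left_join(rep_aa, by = c(representative = "clone")) |>
    rename(rep_full_aa = "full_aa") |>
    mutate(priority = .data$max_logfc > params$priority_logfc |
             .data$final_cpm > params$priority_cpm |
             .data$consistent_increase) |>
    select("cluster_id", "representative", "rep_full_aa", "n_members",
           "final_cpm", "round0_cpm", "max_logfc", "n_replicates_enriched",
           "consistent_increase", "priority")
  clusters <- filter_clusters(clusters, params$min_cluster_cpm)
  members <- filter(members, .data$cluster_id %in% clusters$cluster_id)
  list(members = members, clusters = clusters)
}

#' All-vs-all BLOSUM62 global alignment scores
#'
#' Global (Needleman-Wunsch) affine-gap alignment score of every pair of
#' representative CDR3s, with gap opening -10, gap extension -1 and the
#' BLOSUM62 substitution matrix.
#'
#' @param representatives character vector of residue strings (unique).
#' @param gap_open,gap_extend gap penalties (negative; a gap of length L
#'   costs `gap_open + L * gap_extend`).
#' @return A symmetric numeric matrix with the sequences as dimnames.
#' @export
blosum_score_matrix <- function(representatives, gap_open = -10,
                                gap_extend = -1) {
  n <- length(representatives)
  if (n < 2) abort("need at least 2 representatives")
  if (anyDuplicated(representatives)) abort("representatives must be unique")
  set <- Biostrings::AAStringSet(representatives)
  S <- matrix(0, n, n, dimnames = list(representatives, representatives))
  for (i in seq_len(n)) {
    sc <- Biostrings::pairwiseAlignment(
      set[i:n], set[[i]], type = "global",
      substitutionMatrix = "BLOSUM62",
      gapOpening = -gap_open, gapExtension = -gap_extend,
      scoreOnly = TRUE
    )
    S[i, i:n] <- sc
    S[i:n, i] <- sc
  }
  S
}

#' MDS embedding of a similarity matrix
#'
#' Principal-component projection of the (column-centred) score-matrix rows
#' onto the leading axes; each cluster representative becomes a point whose
#' distances reflect alignment similarity. Axis signs follow a fixed
#' convention (the largest-magnitude loading on each axis is positive) so
#' embeddings are reproducible.
#'
#' @param score_matrix symmetric score matrix from [blosum_score_matrix()].
#' @param n_components number of axes (< number of labels).
#' @return A tibble with `label` and one `PCk` column per axis, with the
#'   proportion of variance per axis in attribute `"var_explained"`.
#' @export
mds_embed <- function(score_matrix, n_components = 2) {
  n <- nrow(score_matrix)
  if (n_components >= n) {
    abort("`n_components` must be smaller than the number of labels")
  }
  pc <- prcomp(score_matrix, center = TRUE, scale. = FALSE,
               rank. = n_components)
  flip <- vapply(seq_len(n_components), function(k) {
    v <- pc$rotation[, k]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  scores <- sweep(pc$x[, seq_len(n_components), drop = FALSE], 2, flip, `*`)
  out <- bind_cols(tibble(label = rownames(score_matrix)),
                   as_tibble(scores))
  attr(out, "var_explained") <-
    (pc$sdev^2 / sum(pc$sdev^2))[seq_len(n_components)]
  class(out) <- c("pan_mds", class(out))
  out
}

#' Average-linkage cladogram of representative CDR3s
#'
#' Hierarchical clustering (UPGMA/average linkage) on the distance
#' `d(i, j) = max(S) - S[i, j]` derived from the alignment score matrix,
#' optionally restricted to the most abundant representatives.
#'
#' @param score_matrix symmetric score matrix from [blosum_score_matrix()].
#' @param keep optional character vector of labels to retain (e.g. the most
#'   abundant representatives).
#' @return An [ape::as.phylo()] tree; write with [ape::write.tree()] for
#'   Newick output.
#' @export
build_cladogram <- function(score_matrix, keep = NULL) {
  if (!is.null(keep)) {
    keep <- intersect(rownames(score_matrix), keep)
    score_matrix <- score_matrix[keep, keep, drop = FALSE]
  }
  if (nrow(score_matrix) < 2) abort("need at least 2 labels for a cladogram")
  d <- max(score_matrix) - score_matrix
  hc <- hclust(as.dist(d), method = "average")
  ape::as.phylo(hc)
}
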