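#' Rank a top-N candidate list
#'
#' Builds the ranked candidate list from a pan's retained clusters in three
#' tiers. Tier "priority": one pick (the most abundant member clone) from
#' every priority cluster -- those with max logFC above `priority_logfc`, or
#' final-round CPM above `priority_cpm`, or consistently increasing
#' abundance across rounds. Tier "enriched_fill": one pick from every
#' remaining cluster. Within both tiers clusters are ordered by replicate
#' support (descending), then final CPM (descending), then representative
#' (lexicographic). Tier "intra_cluster_fill": further members of
#' already-selected clusters by member CPM, until `top_n` picks or
#' exhaustion.
#'
#' @param clusters cluster-level tibble from [cluster_enriched()].
#' @param members member-level tibble from [cluster_enriched()].
#' @param clone_table the campaign clone table (source of full-length
#'   sequences).
#' @param params a [pan_params()] list.
#' @return A tibble with columns `rank`, `clone`, `full_aa`, `cluster_id`,
#'   `tier`; at most `params$top_n` rows, clones unique.
#' @export
pick_top_n <- function(clusters, members, clone_table,
                       params = pan_params()) {
  params <- as_pan_params(params)
  empty <- tibble(rank = integer(), clone = character(),
                  full_aa = character(), cluster_id = integer(),
                  tier = character())
  if (nrow(clusters) == 0) {
    warn("no clusters to select from")
    return(empty)
  }
  ordered <- clusters |>
    arrange(desc(.data$n_replicates_enriched), desc(.data$final_cpm),
            .data$representative)
  top_member <- members |>
    group_by(.data$cluster_id) |>
    arrange(desc(.data$abundance), .data$clone, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    select("cluster_id", "clone")
  tier12 <- ordered |>
    left_join(top_member, by = "cluster_id") |>
    mutate(tier = if_else(.data$priority, "priority", "enriched_fill")) |>
    arrange(desc(.data$priority)) |>
    select("clone", "cluster_id", "tier")
  picks <- head(tier12, params$top_n)
  if (nrow(picks) < params$top_n) {
    fill <- members |>
      filter(.data$cluster_id %in% picks$cluster_id,
             !.data$clone %in% picks$clone) |>
      arrange(desc(.data$abundance), .data$clone) |>
      mutate(tier = "intra_cluster_fill") |>
      select("clone", "cluster_id", "tier")
    picks <- bind_rows(picks, head(fill, params$top_n - nrow(picks)))
  }
  full <- clone_table |> distinct(.data$clone, .data$full_aa)
  picks |>
    distinct(.data$clone, .keep_all = TRUE) |>
    left_join(full, by = "clone") |>
    mutate(rank = row_number()) |>
    select("rank", "clone", "full_aa", "cluster_id", "tier")
}

#' Replicate concordance of clone abundance
#'
#' For every pan with at least two replicates, emits the clone-level CPM of
#' each replicate pair at each round (the data behind all-vs-all replicate
#' scatterplots), for spotting abnormal replicates.
#'
#' @param clone_table a clone table.
#' @param design a `pan_design`.
#' @return A tibble of class `pan_concordance` with columns `pan`, `round`,
#'   `rep_i`, `rep_j`, `clone`, `cpm_i`, `cpm_j`; zero rows when no pan has
#'   two replicates. Use [glance()] for per-pair Pearson correlations of
#'   log1p(CPM).
#' @export
replicate_concordance <- function(clone_table, design) {
  empty <- tibble(pan = character(), round = integer(), rep_i = character(),
                  rep_j = character(), clone = character(),
                  cpm_i = numeric(), cpm_j = numeric())
  long <- clone_table |>
    inner_join(design |> as_tibble() |>
                 select("sample_id", "pan", "round", "replicate"),
               by = "sample_id")
  reps <- long |> distinct(.data$pan, .data$round, .data$replicate)
  combos <- reps |>
    inner_join(reps, by = c("pan", "round"),
               relationship = "many-to-many", suffix = c("_i", "_j")) |>
    filter(.data$replicate_i < .data$replicate_j) |>
    rename(rep_i = "replicate_i", rep_j = "replicate_j")
  out <- if (nrow(combos) == 0) empty else {
    combos |>
      pmap(function(pan, round, rep_i, rep_j) {
        wide <- long |>
          filter(.data$pan == !!pan, .data$round == !!round,
                 .data$replicate %in% c(rep_i, rep_j)) |>
          select("clone", "replicate", "cpm") |>
          pivot_wider(names_from = "replicate", values_from = "cpm",
                      values_fill = 0)
        vi <- wide[[rep_i]]
        vj <- wide[[rep_j]]
        tibble(pan = pan, round = round, rep_i = rep_i, rep_j = rep_j,
               clone = wide$clone, cpm_i = vi, cpm_j = vj)
      }) |>
      list_rbind()
  }
  class(out) <- c("pan_concordance", class(out))
  out
}

#' Pool and re-cluster enriched clones across pans
#'
#' All clones enriched in any pan are pooled and greedy-clustered at the
#' usual identity/length thresholds, so that similar-but-not-identical
#' clones selected in different pans fall in the same pooled cluster. Each
#' pooled cluster's membership is the set of pans contributing at least one
#' member; the distinct membership sets with their counts are the data of an
#' UpSet plot, and clusters spanning several pans are candidate
#' cross-reactive binders.
#'
#' @param enrichment a [call_enriched()] result covering >= 2 pans.
#' @param params a [pan_params()] list.
#' @return A list of class `pan_overlap` with `clusters` (tibble:
#'   `cluster_id`, `representative`, `membership` string, `n_pans`, one
#'   logical column per pan), `members` (clone-level assignments) and
#'   `classes` (tibble `membership`, `n_clusters`).
#' @export
compare_pans <- function(enrichment, params = pan_params()) {
  params <- as_pan_params(params)
  pans <- sort(unique(enrichment$pan))
  if (length(pans) < 2) abort("`enrichment` must cover at least 2 pans")
  enr <- filter(enrichment, .data$enriched)
  none <- setdiff(pans, unique(enr$pan))
  if (length(none)) {
    warn(sprintf("pan(s) with no enriched clones: %s",
                 paste(none, collapse = ", ")))
  }
  pooled <- enr |>
    group_by(.data$clone) |>
    summarise(abundance = max(.data$final_cpm),
              pans_of = list(sort(unique(.data$pan)))) |>
    greedy_cluster(params$cluster_identity, params$cluster_length_ratio)
  memb <- pooled |>
    select("cluster_id", "representative", "pans_of") |>
    unnest("pans_of") |>
    distinct(.data$cluster_id, .data$representative, pan = .data$pans_of) |>
    mutate(present = TRUE) |>
    pivot_wider(names_from = "pan", values_from = "present",
                values_fill = FALSE)
  for (p in setdiff(pans, names(memb))) memb[[p]] <- FALSE
  memb <- memb |>
    mutate(
      membership = pmap_chr_sets(dplyr::pick(dplyr::all_of(pans)), pans),
      n_pans = rowSums(dplyr::pick(dplyr::all_of(pans)))
    ) |>
    select("cluster_id", "representative", "membership", "n_pans",
           dplyr::all_of(pans)) |>
    arrange(.data$cluster_id)
  classes <- memb |>
    count(.data$membership, name = "n_clusters") |>
    arrange(desc(.data$n_clusters))
  out <- list(
    clusters = memb,
    members = pooled |> select("clone", "abundance", "cluster_id",
                               "representative"),
    pans = pans,
    classes = classes
  )
  class(out) <- "pan_overlap"
  out
}

pmap_chr_sets <- function(flags, pans) {
  apply(as.matrix(flags), 1, function(r) paste(pans[r], collapse = "&"))
}

#' @export
print.pan_overlap <- function(x, ...) {
  cat(sprintf("<pan_overlap> %d pooled clusters across %d pans\n",
              nrow(x$clusters), length(x$pans)))
  print(x$classes)
  invisible(x)
}

#' Cluster-by-pan membership matrix
#'
#' @param overlap a `pan_overlap` from [compare_pans()].
#' @return A tibble (clusters x pans, 0/1) suitable for UpSet-style plots.
#' @export
membership_matrix <- function(overlap) {
  overlap$clusters |>
    mutate(across(dplyr::all_of(overlap$pans), as.integer)) |>
    select("cluster_id", "representative", dplyr::all_of(overlap$pans))
}

#' Subtract pans from a target pan
#'
#' Retains pooled clusters whose membership includes `target_pan` and
#' excludes every pan in `subtract`: binders of X that are not binders of Y.
#'
#' @param overlap a `pan_overlap` from [compare_pans()].
#' @param target_pan pan whose binders are sought.
#' @param subtract character vector of pans to subtract.
#' @return The retained rows of `overlap$clusters`.
#' @export
subtract_pans <- function(overlap, target_pan, subtract) {
  if (!target_pan %in% overlap$pans) {
    abort(sprintf("target pan '%s' not present in the overlap", target_pan))
  }
  bad <- setdiff(subtract, overlap$pans)
  if (length(bad)) {
    abort(sprintf("subtract pan(s) not present: %s",
                  paste(bad, collapse = ", ")))
  }
  cl <- overlap$clusters
  keep <- cl[[target_pan]]
  for (p in subtract) keep <- keep & !cl[[p]]
  cl[keep, , drop = FALSE]
}
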