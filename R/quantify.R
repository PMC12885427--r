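#' Collapse productive annotations into CDR3-level clones
#'
#' Reads are counted per sample by CDR3 amino-acid sequence; within each
#' sample, clones seen exactly once are removed (count-1 CDR3s likely result
#' from sequencing errors). Clone keys are then unioned across samples
#' (absent = count 0) and CPM-normalised per sample over the retained
#' clones. Each clone carries the full amino-acid sequence of its most
#' abundant read as representative.
#'
#' @param annotations tibble of productive-capable annotations with columns
#'   `sample_id`, `cdr3_aa`, `full_aa`, `productive` (non-productive rows
#'   are dropped).
#' @return A clone table: tibble with one row per clone x sample and columns
#'   `clone` (CDR3 aa), `sample_id`, `count`, `cpm`, `full_aa`.
#' @export
collapse_clones <- function(annotations) {
  prod <- filter(annotations, .data$productive, nzchar(.data$cdr3_aa))
  if (nrow(prod) == 0) abort("no productive annotations in any sample")
  counts <- prod |>
    count(.data$sample_id, .data$cdr3_aa, name = "count") |>
    filter(.data$count > 1)
  if (nrow(counts) == 0) {
    abort("all clones are singletons; nothing retained after count-1 removal")
  }
  # representative full-length sequence: the most frequent full_aa of the
  # clone's reads across the campaign, ties to the first observed
  rep_full <- prod |>
    count(.data$cdr3_aa, .data$full_aa, name = "n_reads") |>
    group_by(.data$cdr3_aa) |>
    arrange(desc(.data$n_reads), .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    select(clone = "cdr3_aa", "full_aa")
  tab <- counts |>
    rename(clone = "cdr3_aa") |>
    complete(clone = unique(.data$clone),
             sample_id = unique(annotations$sample_id),
             fill = list(count = 0L)) |>
    cpm_normalize() |>
    left_join(rep_full, by = "clone") |>
    arrange(.data$clone, .data$sample_id)
  class(tab) <- c("clone_table", class(tab))
  tab
}

#' Counts-per-million normalisation
#'
#' Adds `cpm = 1e6 * count / sum(count)` within each sample, the denominator
#' running over the retained clones of that sample.
#'
#' @param counts tibble with columns `sample_id` and `count` (one row per
#'   clone x sample).
#' @return The input with a `cpm` column appended.
#' @examples
#' cpm_normalize(tibble::tibble(
#'   sample_id = "s1", clone = c("A", "C"), count = c(5L, 15L)
#' ))
#' @export
cpm_normalize <- function(counts) {
  totals <- counts |>
    group_by(.data$sample_id) |>
    summarise(total = sum(.data$count))
  zero <- totals$sample_id[totals$total == 0]
  if (length(zero)) {
    abort(sprintf("sample(s) with zero total count: %s",
                  paste(zero, collapse = ", ")))
  }
  counts |>
    left_join(totals, by = "sample_id") |>
    mutate(cpm = 1e6 * .data$count / .data$total) |>
    select(-"total")
}

#' Pseudocounted log2 fold change
#'
#' `log2((final_cpm + pseudocount) / (round0_cpm + pseudocount))`: the
#' pseudocount damps the influence of lowly abundant clones whose counts
#' are unreliable.
#'
#' @param final_cpm,round0_cpm CPM at the final round and at round zero
#'   (vectorised).
#' @param pseudocount CPM added to numerator and denominator.
#' @return log2 fold changes.
#' @examples
#' log_fold_change(990, 0) # log2(100)
#' @export
log_fold_change <- function(final_cpm, round0_cpm, pseudocount = 10) {
  log2((final_cpm + pseudocount) / (round0_cpm + pseudocount))
}

#' Call enriched clones per pan
#'
#' For every clone present (count > 1, i.e. retained) at the final round of
#' a pan, computes the pseudocounted log2 fold change of final-round CPM
#' over round-zero CPM; a clone is enriched when logFC >= `enrich_logfc`.
#' With replicates the fold change is computed per replicate (against that
#' replicate's round-zero sample when it exists, else the mean round-zero
#' CPM) and the headline value at the combined (mean, or max, per
#' `params$replicate_combine`) CPM level.
#'
#' @param clone_table a clone table from [collapse_clones()].
#' @param design a `pan_design`.
#' @param params a [pan_params()] list.
#' @return A tibble with one row per clone x pan: `clone`, `pan`,
#'   `final_cpm`, `round0_cpm`, `logfc`, `enriched`, `n_replicates`,
#'   `n_replicates_enriched` and a nested `per_replicate` tibble
#'   (`replicate`, `final_cpm`, `round0_cpm`, `logfc`, `enriched`).
#' @export
call_enriched <- function(clone_table, design, params = pan_params()) {
  params <- as_pan_params(params)
  fr <- final_rounds(design)
  long <- clone_table |>
    inner_join(
      design |> as_tibble() |>
        select("sample_id", "pan", "round", "replicate"),
      by = "sample_id"
    ) |>
    inner_join(fr, by = "pan")
  combine <- if (params$replicate_combine == "max") max else mean
  res <- long |>
    filter(.data$round %in% c(0L, .data$final_round)) |>
    mutate(stage = if_else(.data$round == 0L, "round0", "final")) |>
    group_by(.data$pan, .data$clone) |>
    nest(.key = "d") |>
    ungroup()
  per_rep <- map(res$d, function(d) {
    mean0 <- mean(d$cpm[d$stage == "round0"])
    reps <- d |>
      filter(.data$stage == "final") |>
      group_by(.data$replicate) |>
      summarise(final_cpm = mean(.data$cpm), final_count = max(.data$count))
    reps$round0_cpm <- vapply(reps$replicate, function(r) {
      z <- d$cpm[d$stage == "round0" & d$replicate == r]
      if (length(z)) mean(z) else mean0
    }, numeric(1))
    reps |>
      mutate(
        logfc = log_fold_change(.data$final_cpm, .data$round0_cpm,
                                params$pseudocount),
        enriched = .data$logfc >= params$enrich_logfc
      )
  })
  out <- tibble(
    clone = res$clone,
    pan = res$pan,
    final_cpm = map_dbl(per_rep, ~ combine(.x$final_cpm)),
    round0_cpm = map_dbl(res$d, ~ {
      z <- .x$cpm[.x$stage == "round0"]
      if (length(z)) combine(z) else 0
    }),
    n_replicates = map_int(per_rep, nrow),
    n_replicates_enriched = map_int(per_rep, ~ sum(.x$enriched)),
    present_final = map_lgl(per_rep, ~ any(.x$final_count > 1)),
    per_replicate = map(per_rep, ~ select(.x, -"final_count"))
  ) |>
    filter(.data$present_final) |>
    select(-"present_final") |>
    mutate(
      logfc = log_fold_change(.data$final_cpm, .data$round0_cpm,
                              params$pseudocount),
      enriched = .data$logfc >= params$enrich_logfc
    ) |>
    select("clone", "pan", "final_cpm", "round0_cpm", "logfc", "enriched",
           "n_replicates", "n_replicates_enriched", "per_replicate") |>
    arrange(.data$pan, desc(.data$logfc), .data$clone)
  class(out) <- c("pan_enrichment", class(out))
  out
}
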