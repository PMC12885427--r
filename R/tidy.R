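#' Tidy enrichment results
#'
#' @param x a `pan_enrichment` from [call_enriched()].
#' @param per_replicate unnest the per-replicate fold changes into long
#'   form.
#' @param ... ignored.
#' @return A flat tibble of enrichment calls.
#' @export
tidy.pan_enrichment <- function(x, per_replicate = FALSE, ...) {
  if (per_replicate) {
    x |>
      as_tibble() |>
      select("clone", "pan", "per_replicate") |>
      unnest("per_replicate")
  } else {
    x |>
      as_tibble() |>
      select(-"per_replicate")
  }
}

#' Summarise enrichment results
#'
#' @param x a `pan_enrichment`.
#' @param ... ignored.
#' @return One row per pan: clones evaluated, clones enriched, fraction.
#' @export
glance.pan_enrichment <- function(x, ...) {
  x |>
    as_tibble() |>
    group_by(.data$pan) |>
    summarise(n_clones = n(), n_enriched = sum(.data$enriched),
              prop_enriched = mean(.data$enriched))
}

#' Per-pair replicate concordance scores
#'
#' @param x a `pan_concordance` from [replicate_concordance()].
#' @param ... ignored.
#' @return One row per pan, round and replicate pair with the Pearson
#'   correlation of log1p(CPM).
#' @export
glance.pan_concordance <- function(x, ...) {
  if (nrow(x) == 0) {
    return(tibble(pan = character(), round = integer(), rep_i = character(),
                  rep_j = character(), n_clones = integer(), r = numeric()))
  }
  x |>
    as_tibble() |>
    group_by(.data$pan, .data$round, .data$rep_i, .data$rep_j) |>
    summarise(n_clones = n(),
              r = cor(log1p(.data$cpm_i), log1p(.data$cpm_j)),
              .groups = "drop")
}

#' Tidy a pan overlap
#'
#' @param x a `pan_overlap` from [compare_pans()].
#' @param ... ignored.
#' @return One row per pooled cluster with its membership class.
#' @export
tidy.pan_overlap <- function(x, ...) x$clusters

#' Summarise a pan overlap
#'
#' @param x a `pan_overlap`.
#' @param ... ignored.
#' @return The membership classes with cluster counts (UpSet data).
#' @export
glance.pan_overlap <- function(x, ...) x$classes

#' Tidy a campaign: the ranked candidate lists
#'
#' @param x a `pan_campaign` from [pan_run()].
#' @param ... ignored.
#' @return The per-pan top-N selections, bound with a `pan` column.
#' @export
tidy.pan_campaign <- function(x, ...) {
  imap(x$pans, ~ mutate(.x$selection, pan = .y, .before = 1)) |>
    list_rbind()
}

#' Summarise a campaign
#'
#' @param x a `pan_campaign`.
#' @param ... ignored.
#' @return A one-row tibble of campaign-level counts.
#' @export
glance.pan_campaign <- function(x, ...) {
  tibble(
    n_samples = nrow(x$design),
    n_pans = length(x$pans),
    n_clones = dplyr::n_distinct(x$clone_table$clone),
    n_enriched = sum(x$enrichment$enriched),
    n_clusters = sum(vapply(x$pans, function(p) nrow(p$clusters),
                            integer(1))),
    n_selected = sum(vapply(x$pans, function(p) nrow(p$selection),
                            integer(1)))
  )
}
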