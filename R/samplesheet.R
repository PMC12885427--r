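#' Parse a campaign samplesheet
#'
#' The samplesheet is a CSV with one row per sequenced sample and columns
#' `sample_id`, `pan`, `antigen`, `round`, `replicate`, `r1` and (optionally)
#' `r2`. Omitting `r2` for a row declares single-read mode for that sample
#' (pre-merged, Sanger or long reads). Round 0 is the pre-selection library
#' and must be present for every pan; the largest round index per pan is the
#' final round.
#'
#' @param path path to the samplesheet CSV.
#' @return A validated `pan_design` tibble, rows ordered by pan, round,
#'   replicate then sample id (so parsing is insensitive to row order).
#' @export
read_samplesheet <- function(path) {
  if (!file.exists(path)) abort(sprintf("samplesheet not found: %s", path))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = "c"))
  as_pan_design(df)
}

#' Validate a campaign design
#'
#' @param df data frame with the samplesheet columns (see
#'   [read_samplesheet()]); `r2` and `antigen` may be absent.
#' @return A `pan_design` tibble.
#' @export
as_pan_design <- function(df) {
  need <- c("sample_id", "pan", "round", "replicate", "r1")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    abort(sprintf("samplesheet is missing column(s): %s",
                  paste(miss, collapse = ", ")))
  }
  if (!"antigen" %in% names(df)) df$antigen <- df$pan
  if (!"r2" %in% names(df)) df$r2 <- NA_character_
  df <- as_tibble(df) |>
    mutate(
      sample_id = as.character(.data$sample_id),
      pan = as.character(.data$pan),
      antigen = as.character(.data$antigen),
      round = as.integer(.data$round),
      replicate = as.character(.data$replicate),
      r1 = as.character(.data$r1),
      r2 = dplyr::na_if(as.character(.data$r2), "")
    ) |>
    select("sample_id", "pan", "antigen", "round", "replicate", "r1", "r2")
  if (anyDuplicated(df$sample_id)) {
    abort(sprintf("duplicate sample_id(s): %s",
                  paste(unique(df$sample_id[duplicated(df$sample_id)]),
                        collapse = ", ")))
  }
  if (any(is.na(df$round) | df$round < 0)) {
    abort("`round` must be a non-negative integer for every sample")
  }
  bad <- is.na(df$r1) | df$r1 == ""
  if (any(bad)) {
    abort(sprintf("missing r1 path for sample(s): %s",
                  paste(df$sample_id[bad], collapse = ", ")))
  }
  no_zero <- df |>
    group_by(.data$pan) |>
    summarise(has0 = any(.data$round == 0)) |>
    filter(!.data$has0)
  if (nrow(no_zero) > 0) {
    abort(sprintf("pan(s) without a round-zero (library) sample: %s",
                  paste(no_zero$pan, collapse = ", ")))
  }
  df <- arrange(df, .data$pan, .data$round, .data$replicate, .data$sample_id)
  class(df) <- c("pan_design", class(df))
  df
}

#' Final round index per pan
#'
#' @param design a `pan_design`.
#' @return tibble with columns `pan`, `final_round`.
#' @export
final_rounds <- function(design) {
  design |>
    as_tibble() |>
    group_by(.data$pan) |>
    summarise(final_round = max(.data$round))
}

is_single_read <- function(entry) is.na(entry$r2) | entry$r2 == ""
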