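#' Read a FASTQ file into a tibble
#'
#' Phred+33 qualities are kept as the raw ASCII string alongside the
#' sequence; gzip-compressed files are handled transparently.
#'
#' @param path path to a FASTQ (optionally `.gz`) file.
#' @return A tibble with columns `id`, `seq`, `qual` (one row per read).
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' read_fastq(fq)
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTQ file not found: %s", path))
  tryCatch({
    x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                      with.qualities = TRUE)
    if (length(x) == 0) {
      return(tibble(id = character(), seq = character(), qual = character()))
    }
    q <- S4Vectors::mcols(x)$qualities
    if (any(Biostrings::width(q) != Biostrings::width(x))) {
      bad <- which(Biostrings::width(q) != Biostrings::width(x))[1]
      stop(sprintf(
        "quality length != sequence length at record %d (near line %d)",
        bad, (bad - 1) * 4 + 1
      ))
    }
    tibble(
      id = sub("\\s.*$", "", names(x)),
      seq = unname(toupper(as.character(x))),
      qual = unname(as.character(q))
    )
  }, error = function(e) {
    abort(sprintf("malformed FASTQ '%s': %s", path, conditionMessage(e)))
  })
}

#' Write reads to FASTQ
#'
#' @param reads tibble with columns `id`, `seq` and `qual`.
#' @param path output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual),
    compress = grepl("\\.gz$", path)
  )
  invisible(path)
}

#' Read a FASTA file into a tibble
#'
#' @param path path to a FASTA (optionally `.gz`) file.
#' @return A tibble with columns `name`, `seq`. Duplicate record names are an
#'   error.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTA file not found: %s", path))
  x <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(x))
  if (anyDuplicated(nm)) {
    abort(sprintf(
      "duplicate FASTA id(s) in '%s': %s", path,
      paste(unique(nm[duplicated(nm)]), collapse = ", ")
    ))
  }
  tibble(name = nm, seq = unname(toupper(as.character(x))))
}

#' Write sequences to FASTA
#'
#' @param records tibble with columns `name` and `seq`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (anyDuplicated(records$name)) abort("duplicate record names")
  x <- Biostrings::DNAStringSet(records$seq)
  names(x) <- records$name
  Biostrings::writeXStringSet(x, path, compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Write campaign result tables to a directory
#'
#' Exports the machine-readable artifacts of a campaign: the clone-level CPM
#' matrix, the cluster table, the ranked candidate list, MDS coordinates, the
#' cladogram in Newick format, enrichment calls, QC and (for multi-pan
#' campaigns) the cluster-by-pan membership matrix. Numeric columns are
#' written at full precision.
#'
#' @param campaign a `pan_campaign` object from [pan_run()].
#' @param out_dir output directory (created if absent).
#' @return Character vector of written paths, invisibly.
#' @export
write_results <- function(campaign, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) abort(sprintf("cannot create output directory '%s'", out_dir))
  }
  paths <- character()
  emit <- function(df, file) {
    p <- file.path(out_dir, file)
    readr::write_csv(df, p)
    paths <<- c(paths, p)
  }
  cpm_wide <- campaign$clone_table |>
    select("clone", "sample_id", "cpm") |>
    pivot_wider(names_from = "sample_id", values_from = "cpm", values_fill = 0)
  emit(cpm_wide, "clone_cpm.csv")
  count_wide <- campaign$clone_table |>
    select("clone", "sample_id", "count") |>
    pivot_wider(names_from = "sample_id", values_from = "count", values_fill = 0L)
  emit(count_wide, "clone_counts.csv")
  emit(
    campaign$enrichment |> select(-dplyr::any_of("per_replicate")),
    "enrichment.csv"
  )
  for (pan in names(campaign$pans)) {
    res <- campaign$pans[[pan]]
    tag <- gsub("[^A-Za-z0-9_.-]", "_", pan)
    cl <- res$clusters |>
      left_join(
        res$members |>
          group_by(.data$cluster_id) |>
          summarise(members = paste(.data$clone, collapse = ";")),
        by = "cluster_id"
      )
    emit(cl, sprintf("clusters_%s.csv", tag))
    emit(res$selection, sprintf("top_n_%s.csv", tag))
    if (!is.null(res$mds)) emit(res$mds, sprintf("mds_%s.csv", tag))
    if (!is.null(res$cladogram)) {
      p <- file.path(out_dir, sprintf("cladogram_%s.nwk", tag))
      ape::write.tree(res$cladogram, file = p)
      paths <- c(paths, p)
    }
  }
  if (!is.null(campaign$overlap)) {
    emit(membership_matrix(campaign$overlap), "pan_membership.csv")
  }
  if (!is.null(campaign$qc)) emit(campaign$qc, "qc_summary.csv")
  if (!is.null(campaign$concordance) && nrow(campaign$concordance) > 0) {
    emit(campaign$concordance, "replicate_concordance.csv")
  }
  invisible(paths)
}
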