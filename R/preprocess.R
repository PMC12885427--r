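#' Trim a 3' sequencing adapter
#'
#' Removes the best occurrence of `adapter` (the full adapter anywhere, or a
#' prefix of at least `min_match` bases running into the 3' end) whose
#' mismatch fraction is at most `error_rate`. Quality strings are trimmed in
#' lockstep. Reads without an acceptable occurrence are returned unchanged.
#'
#' @param reads tibble with columns `seq` and optionally `qual`.
#' @param adapter adapter nucleotide sequence.
#' @param min_match minimum adapter prefix length considered.
#' @param error_rate tolerated mismatch fraction.
#' @return The input tibble with `seq`/`qual` shortened where an adapter was
#'   found.
#' @examples
#' trim_adapter(tibble::tibble(seq = "ACGTACGTAGATCGGAAG"), "AGATCGGAAGAGC")
#' @export
trim_adapter <- function(reads, adapter, min_match = 3, error_rate = 0.1) {
  if (!nzchar(adapter)) abort("`adapter` must be non-empty")
  if (nrow(reads) == 0) return(reads)
  keep <- cpp_trim_adapter(reads$seq, toupper(adapter),
                           as.integer(min_match), error_rate)
  out <- reads
  out$seq <- substr(reads$seq, 1L, keep)
  if (!is.null(reads$qual)) out$qual <- substr(reads$qual, 1L, keep)
  out
}

#' Merge one read pair by overlap
#'
#' `r2` is reverse-complemented, candidate overlaps between `min_overlap`
#' and `max_overlap` bp are scored by mismatch density, and the pair is
#' merged at the lowest-density overlap (ties to the longer overlap) when
#' that density is at most `max_mismatch_density`. Disagreeing bases are
#' resolved toward the higher Phred score.
#'
#' @param r1,r2 single-row tibbles (or lists) with `seq` and `qual`; `r2` on
#'   the reverse strand as sequenced.
#' @param min_overlap,max_overlap overlap search range in bp.
#' @param max_mismatch_density maximum tolerated mismatch fraction.
#' @return A one-row tibble with `merged_seq`, `merged_qual`, `overlap_len`,
#'   `mismatches`, `status` (one of `"merged"`, `"no_overlap"`,
#'   `"too_short"`).
#' @export
merge_pair <- function(r1, r2, min_overlap = 10, max_overlap = 250,
                       max_mismatch_density = 0.25) {
  merge_pairs(
    tibble(id = "pair", seq1 = r1$seq[[1]], qual1 = r1$qual[[1]],
           seq2 = r2$seq[[1]], qual2 = r2$qual[[1]]),
    min_overlap, max_overlap, max_mismatch_density
  )
}

#' Merge many read pairs by overlap
#'
#' Vectorised form of [merge_pair()].
#'
#' @param pairs tibble with columns `id`, `seq1`, `qual1`, `seq2`, `qual2`.
#' @inheritParams merge_pair
#' @return A tibble with one row per pair: `id`, `merged_seq`, `merged_qual`,
#'   `overlap_len`, `mismatches`, `status`.
#' @export
merge_pairs <- function(pairs, min_overlap = 10, max_overlap = 250,
                        max_mismatch_density = 0.25) {
  if (nrow(pairs) == 0) {
    return(tibble(id = character(), merged_seq = character(),
                  merged_qual = character(), overlap_len = integer(),
                  mismatches = integer(), status = character()))
  }
  if (any(!nzchar(pairs$seq1)) || any(!nzchar(pairs$seq2))) {
    abort("empty read sequence in pair input")
  }
  res <- cpp_merge_pairs(pairs$seq1, pairs$qual1, pairs$seq2, pairs$qual2,
                         as.integer(min_overlap), as.integer(max_overlap),
                         max_mismatch_density)
  tibble(id = pairs$id, !!!res)
}

#' Preprocess one sample: trim then merge
#'
#' For a paired-end sample both mates are adapter-trimmed and merged;
#' only merged pairs are kept. For a single-read sample (no `r2` in the
#' design row) reads are trimmed and passed through, with the merge stage
#' skipped.
#'
#' @param entry one row of a `pan_design`.
#' @param params a [pan_params()] list.
#' @param adapter adapter sequence, or `NULL` to skip trimming.
#' @return A list with `reads` (tibble `id`, `seq`, `qual`) and `stats`
#'   (one-row tibble of stage counts).
#' @export
preprocess_sample <- function(entry, params = pan_params(), adapter = NULL) {
  params <- as_pan_params(params)
  single <- is_single_read(entry)
  r1 <- read_fastq(entry$r1)
  n_in <- nrow(r1)
  if (!is.null(adapter)) {
    r1 <- trim_adapter(r1, adapter, params$trim_min_match, params$trim_error_rate)
  }
  if (single) {
    reads <- filter(r1, nzchar(.data$seq))
    stats <- tibble(
      sample_id = entry$sample_id, reads_in = n_in,
      reads_trimmed = nrow(reads), reads_merged = nrow(reads),
      merge_rate = if (n_in > 0) nrow(reads) / n_in else 0,
      mode = "single"
    )
    return(list(reads = reads, stats = stats))
  }
  r2 <- read_fastq(entry$r2)
  if (nrow(r2) != n_in) {
    abort(sprintf("sample '%s': r1 has %d reads but r2 has %d",
                  entry$sample_id, n_in, nrow(r2)))
  }
  if (!is.null(adapter)) {
    r2 <- trim_adapter(r2, adapter, params$trim_min_match, params$trim_error_rate)
  }
  ok <- nzchar(r1$seq) & nzchar(r2$seq)
  pairs <- tibble(id = r1$id[ok], seq1 = r1$seq[ok], qual1 = r1$qual[ok],
                  seq2 = r2$seq[ok], qual2 = r2$qual[ok])
  merged <- merge_pairs(pairs, params$min_overlap, params$max_overlap,
                        params$max_mismatch_density)
  kept <- merged |>
    filter(.data$status == "merged") |>
    select("id", seq = "merged_seq", qual = "merged_qual")
  stats <- tibble(
    sample_id = entry$sample_id, reads_in = n_in,
    reads_trimmed = nrow(pairs), reads_merged = nrow(kept),
    merge_rate = if (nrow(pairs) > 0) nrow(kept) / nrow(pairs) else 0,
    mode = "paired"
  )
  list(reads = kept, stats = stats)
}
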