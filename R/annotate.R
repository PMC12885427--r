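#' Approximate (error-tolerant) pattern search
#'
#' Finds the occurrence of `pattern` in `text` with the fewest Levenshtein
#' edits, the pattern aligned globally and the text locally (semi-global).
#' Ties are broken by leftmost start, then shortest span. `N` bases never
#' match.
#'
#' @param pattern,text nucleotide (or residue) strings.
#' @param max_edits maximum number of edits tolerated.
#' @return A one-row tibble with 1-based inclusive `start`, `end` and
#'   `edits`, or a zero-row tibble if no occurrence is within `max_edits`.
#' @examples
#' approximate_match("ACGT", "TTACGTTT", 0) # start 3, end 6, 0 edits
#' @export
approximate_match <- function(pattern, text, max_edits) {
  if (!nzchar(pattern) || !nzchar(text)) {
    abort("`pattern` and `text` must be non-empty")
  }
  h <- cpp_approx_match(toupper(pattern), toupper(text),
                        as.integer(max_edits))
  if (length(h) == 0) {
    return(tibble(start = integer(), end = integer(), edits = integer()))
  }
  tibble(start = h[1] + 1L, end = h[2], edits = h[3])
}

#' Reverse-complement DNA strings
#'
#' @param seqs character vector of DNA sequences.
#' @return Character vector of reverse complements (`N`-preserving).
#' @export
revcomp <- function(seqs) cpp_revcomp(seqs)

#' Translate DNA to protein
#'
#' Translates in frame 0 with the standard genetic code, truncating any
#' trailing partial codon; codons containing `N` translate to `X`.
#'
#' @param nt character vector of nucleotide sequences.
#' @return Character vector of amino-acid sequences (`*` marks stops).
#' @export
translate_dna <- function(nt) {
  nt <- toupper(nt)
  keep <- nchar(nt) - nchar(nt) %% 3L
  trimmed <- substr(nt, 1L, keep)
  out <- character(length(nt))
  nz <- which(nchar(trimmed) > 0)
  if (length(nz)) {
    aa <- suppressWarnings(Biostrings::translate(
      Biostrings::DNAStringSet(trimmed[nz]), if.fuzzy.codon = "X",
      no.init.codon = TRUE
    ))
    out[nz] <- as.character(aa)
  }
  out
}

#' Trim V-gene references to just before the last conserved cysteine
#'
#' Each reference is read in frame from position 1 and truncated immediately
#' before its last in-frame cysteine codon (TGT/TGC), the conserved cysteine
#' that precedes CDR3. References with no in-frame cysteine are dropped with
#' a warning.
#'
#' @param refs tibble with columns `name`, `seq` (nucleotide, in frame).
#' @return A tibble with columns `name`, `seq_nt` (full), `cys_trim_nt`
#'   (truncated), `aa` (translation of the full sequence).
#' @examples
#' trim_to_cysteine(tibble::tibble(name = "V1", seq = "ATGTGTGCT"))
#' @export
trim_to_cysteine <- function(refs) {
  seqs <- toupper(refs$seq)
  aa <- translate_dna(seqs)
  last_cys <- vapply(aa, function(a) {
    pos <- gregexpr("C", a, fixed = TRUE)[[1]]
    if (pos[1] == -1) NA_integer_ else as.integer(max(pos))
  }, integer(1), USE.NAMES = FALSE)
  drop <- is.na(last_cys)
  if (any(drop)) {
    warn(sprintf("dropping V reference(s) without an in-frame cysteine: %s",
                 paste(refs$name[drop], collapse = ", ")))
  }
  tibble(
    name = refs$name[!drop],
    seq_nt = seqs[!drop],
    cys_trim_nt = substr(seqs[!drop], 1L, 3L * (last_cys[!drop] - 1L)),
    aa = aa[!drop]
  )
}

# minimum-edit hit of each prepared pattern against each read, both strands;
# returns per-read best (ref index, orientation, edits, end on the oriented
# strand) given per-ref edit budgets
best_v_hits <- function(seqs, patterns, budgets) {
  n <- length(seqs)
  k <- length(patterns)
  rc <- cpp_revcomp(seqs)
  best_e <- rep.int(.Machine$integer.max, n)
  best_ref <- rep.int(NA_integer_, n)
  best_or <- rep.int(NA_character_, n)
  best_end <- rep.int(NA_integer_, n)
  for (i in seq_len(k)) {
    for (orient in c("+", "-")) {
      m <- cpp_myers_batch(patterns[i], if (orient == "+") seqs else rc)
      ok <- m[, "edits"] <= budgets[i] & m[, "edits"] < best_e
      if (any(ok)) {
        best_e[ok] <- m[ok, "edits"]
        best_ref[ok] <- i
        best_or[ok] <- orient
        best_end[ok] <- m[ok, "end"]
      }
    }
  }
  list(ref = best_ref, orientation = best_or, edits = best_e, end = best_end)
}

#' Survey the most common V genes in a read sample
#'
#' Draws `survey_size` reads without replacement (seeded by `params$seed`),
#' assigns each to its best-matching V-gene reference within an edit budget
#' of `v_error_rate` times the reference length (both orientations), and
#' returns the `num_v_genes` most frequently hit references, trimmed to the
#' conserved cysteine, ranked by frequency (ties by reference order).
#'
#' @param reads tibble with a `seq` column.
#' @param refs tibble with columns `name`, `seq` (V-gene nucleotide
#'   references, in frame).
#' @param params a [pan_params()] list.
#' @return A ranked tibble as returned by [trim_to_cysteine()] with an extra
#'   `survey_hits` column.
#' @export
survey_v_genes <- function(reads, refs, params = pan_params()) {
  params <- as_pan_params(params)
  if (nrow(refs) == 0) abort("`refs` must be non-empty")
  n <- min(params$survey_size, nrow(reads))
  idx <- withr::with_seed(params$seed, sample.int(nrow(reads), n))
  seqs <- toupper(reads$seq[idx])
  budgets <- ceiling(params$v_error_rate * nchar(refs$seq))
  hits <- best_v_hits(seqs, toupper(refs$seq), budgets)
  if (all(is.na(hits$ref))) abort("no V genes detected")
  tallies <- tabulate(hits$ref, nbins = nrow(refs))
  ord <- order(-tallies, seq_along(tallies))
  keep <- ord[tallies[ord] > 0]
  keep <- head(keep, params$num_v_genes)
  shortlist <- trim_to_cysteine(refs[keep, , drop = FALSE] |>
                                  select("name", "seq"))
  shortlist$survey_hits <- tallies[keep][match(shortlist$name, refs$name[keep])]
  shortlist
}

#' Annotate reads with V gene and CDR3
#'
#' For each read: (1) the best approximate occurrence of each
#' cysteine-trimmed V gene is sought on both strands within an edit budget
#' of `anchor_error_rate` times the trimmed length, and the read is
#' reoriented to the V-gene strand; (2) the FWR4 anchor is matched
#' downstream of the cysteine codon that follows the V gene; (3) the CDR3 is
#' excised as the bases strictly between that cysteine codon and the FWR4
#' match start (IMGT-style: the conserved cysteine is not part of CDR3);
#' (4) the full sequence (V-gene start through FWR4 end) and the CDR3 are
#' translated; (5) a read is productive when its translation has no stop
#' codon, its CDR3 length is a multiple of 3 and the CDR3 translation is a
#' substring of the full translation (same reading frame).
#'
#' @param reads tibble with columns `id` and `seq`.
#' @param shortlist prepared V references ([survey_v_genes()] or
#'   [trim_to_cysteine()] output).
#' @param fwr4_nt FWR4 anchor nucleotide sequence.
#' @param params a [pan_params()] list.
#' @return A tibble with one row per read: `read_id`, `v_gene`,
#'   `orientation`, `cdr3_nt`, `cdr3_aa`, `full_nt`, `full_aa`,
#'   `productive`, `fail_reason` (`NA`, `"no_v"`, `"no_fwr4"`,
#'   `"stop_codon"` or `"frameshift"`).
#' @export
annotate_reads <- function(reads, shortlist, fwr4_nt,
                           params = pan_params()) {
  params <- as_pan_params(params)
  fwr4_nt <- toupper(fwr4_nt)
  if (!nzchar(fwr4_nt)) abort("`fwr4_nt` must be non-empty")
  usable <- nzchar(shortlist$cys_trim_nt)
  if (!all(usable)) {
    warn("ignoring V reference(s) whose cysteine-trimmed sequence is empty")
    shortlist <- shortlist[usable, , drop = FALSE]
  }
  if (nrow(shortlist) == 0) abort("no usable V references")
  if (nrow(reads) == 0) {
    return(tibble(
      read_id = character(), v_gene = character(), orientation = character(),
      cdr3_nt = character(), cdr3_aa = character(), full_nt = character(),
      full_aa = character(), productive = logical(),
      fail_reason = character()
    ))
  }
  # identical read sequences get identical annotations: work on uniques
  all_seqs <- toupper(reads$seq)
  seqs <- unique(all_seqs)
  ui <- match(all_seqs, seqs)
  n <- length(seqs)
  ua <- tibble(
    v_gene = rep(NA_character_, n), orientation = NA_character_,
    cdr3_nt = "", cdr3_aa = "", full_nt = "", full_aa = "",
    productive = FALSE, fail_reason = NA_character_
  )
  budgets <- ceiling(params$anchor_error_rate * nchar(shortlist$cys_trim_nt))
  hits <- best_v_hits(seqs, shortlist$cys_trim_nt, budgets)
  no_v <- is.na(hits$ref)
  ua$fail_reason[no_v] <- "no_v"
  idx <- which(!no_v)
  if (length(idx) > 0) {
    oriented <- seqs[idx]
    neg <- hits$orientation[idx] == "-"
    oriented[neg] <- cpp_revcomp(oriented[neg])
    vend <- hits$end[idx] # 0-based half-open end of the V match
    vstart <- integer(length(idx))
    for (r in unique(hits$ref[idx])) {
      sel <- hits$ref[idx] == r
      vstart[sel] <- cpp_myers_start_batch(shortlist$cys_trim_nt[r],
                                           oriented[sel], vend[sel])
    }
    ua$v_gene[idx] <- shortlist$name[hits$ref[idx]]
    ua$orientation[idx] <- hits$orientation[idx]
    # FWR4 search downstream of the cysteine codon that follows the V gene
    fbudget <- ceiling(params$anchor_error_rate * nchar(fwr4_nt))
    suffix <- substr(oriented, vend + 4L, nchar(oriented))
    fh <- cpp_anchor_batch(fwr4_nt, suffix, as.integer(fbudget))
    no_f <- fh[, "edits"] < 0
    ua$fail_reason[idx[no_f]] <- "no_fwr4"
    ok <- which(!no_f)
    if (length(ok) > 0) {
      io <- idx[ok]
      cdr3_nt <- substr(oriented[ok], vend[ok] + 4L,
                        vend[ok] + 3L + fh[ok, "start"])
      full_nt <- substr(oriented[ok], vstart[ok] + 1L,
                        vend[ok] + 3L + fh[ok, "end"])
      full_aa <- translate_dna(full_nt)
      cdr3_aa <- translate_dna(cdr3_nt)
      has_stop <- grepl("*", full_aa, fixed = TRUE)
      in_frame <- nchar(cdr3_nt) > 0 & nchar(cdr3_nt) %% 3L == 0L &
        !grepl("X", cdr3_aa, fixed = TRUE) &
        vapply(seq_along(ok),
               function(j) grepl(cdr3_aa[j], full_aa[j], fixed = TRUE),
               logical(1))
      ua$cdr3_nt[io] <- cdr3_nt
      ua$cdr3_aa[io] <- cdr3_aa
      ua$full_nt[io] <- full_nt
      ua$full_aa[io] <- full_aa
      ua$productive[io] <- !has_stop & in_frame
      ua$fail_reason[io] <- dplyr::case_when(
        !has_stop & in_frame ~ NA_character_,
        has_stop ~ "stop_codon",
        .default = "frameshift"
      )
    }
  }
  bind_cols(tibble(read_id = reads$id), ua[ui, ])
}

#' Annotate a single read
#'
#' @param read one-row tibble (or list) with `id` and `seq`.
#' @inheritParams annotate_reads
#' @return A one-row annotation tibble (see [annotate_reads()]).
#' @export
annotate_read <- function(read, shortlist, fwr4_nt, params = pan_params()) {
  annotate_reads(tibble(id = read$id[[1]], seq = read$seq[[1]]),
                 shortlist, fwr4_nt, params)
}

#' Survey and annotate one sample
#'
#' Runs [survey_v_genes()] on the sample's reads, annotates every read
#' against the surveyed shortlist, and summarises outcomes.
#'
#' @inheritParams annotate_reads
#' @param refs full V-gene reference tibble (`name`, `seq`).
#' @param csv_path optional path; when given, the per-read annotation table
#'   is also written as CSV.
#' @return A list with `annotations` (tibble), `shortlist` and `stats` (a
#'   one-row tibble with `reads`, `productive`, `productive_rate` and one
#'   `n_<fail_reason>` column per failure mode).
#' @export
annotate_sample <- function(reads, refs, fwr4_nt, params = pan_params(),
                            csv_path = NULL) {
  params <- as_pan_params(params)
  shortlist <- survey_v_genes(reads, refs, params)
  ann <- annotate_reads(reads, shortlist, fwr4_nt, params)
  fails <- table(factor(ann$fail_reason,
                        levels = c("no_v", "no_fwr4", "stop_codon",
                                   "frameshift")))
  stats <- tibble(
    reads = nrow(ann),
    productive = sum(ann$productive),
    productive_rate = if (nrow(ann) > 0) mean(ann$productive) else 0,
    n_no_v = as.integer(fails[["no_v"]]),
    n_no_fwr4 = as.integer(fails[["no_fwr4"]]),
    n_stop_codon = as.integer(fails[["stop_codon"]]),
    n_frameshift = as.integer(fails[["frameshift"]])
  )
  if (!is.null(csv_path)) {
    readr::write_csv(
      select(ann, "read_id", "v_gene", "cdr3_nt", "cdr3_aa", "full_aa",
             "productive"),
      csv_path
    )
  }
  list(annotations = ann, shortlist = shortlist, stats = stats)
}
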