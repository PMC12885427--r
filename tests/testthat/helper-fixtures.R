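# Shared fixture builders; everything is generated in code under fixed seeds.

# tiny prepared V-reference set (deterministic)
fixture_vrefs <- function(n = 3, seed = 101) {
  withr::with_seed(seed, synthetic_v_genes(n))
}

FWR4_FIX <- "TGGGGCCAAGGGACCCAGGTCACCGTCTCCTCA"

# one synthetic full-length nanobody read from a given prepared reference
fixture_clone <- function(prepped, cdr3_aa_len = 10, seed = NULL) {
  build <- function() {
    codons <- setdiff(panvhh:::CODONS, c("TAA", "TAG", "TGA"))
    cdr3 <- paste(sample(codons, cdr3_aa_len, replace = TRUE), collapse = "")
    paste0(prepped$cys_trim_nt[1], "TGT", cdr3, FWR4_FIX, "GGTCAACCGGTC")
  }
  if (is.null(seed)) build() else withr::with_seed(seed, build())
}

# turn simulator counts into a clone table keyed by CDR3 aa (counts-level
# shortcut past the read stage, for quantify/select-layer tests)
counts_to_clone_table <- function(truth, counts, pan = "panA") {
  df <- counts |>
    dplyr::inner_join(
      truth$clones |> dplyr::select(clone_id, cdr3_aa, full_aa),
      by = "clone_id"
    ) |>
    dplyr::mutate(sample_id = sprintf("%s_%s_r%d", pan, replicate, round)) |>
    dplyr::group_by(clone = cdr3_aa, sample_id) |>
    dplyr::summarise(count = sum(count), full_aa = full_aa[1],
                     .groups = "drop") |>
    dplyr::mutate(count = ifelse(count == 1L, 0L, count)) # singleton removal
  keep <- df |>
    dplyr::group_by(clone) |>
    dplyr::summarise(any_pos = any(count > 0)) |>
    dplyr::filter(any_pos)
  df <- df |>
    dplyr::filter(clone %in% keep$clone) |>
    tidyr::complete(clone, sample_id, fill = list(count = 0L)) |>
    dplyr::group_by(clone) |>
    dplyr::mutate(full_aa = full_aa[!is.na(full_aa)][1]) |>
    dplyr::ungroup()
  out <- cpm_normalize(df)
  class(out) <- c("clone_table", class(out))
  out
}

design_for_counts <- function(counts, pan = "panA") {
  d <- counts |>
    dplyr::distinct(replicate, round) |>
    dplyr::mutate(
      sample_id = sprintf("%s_%s_r%d", pan, replicate, round),
      pan = pan, antigen = pan,
      r1 = paste0("memory://", sample_id), r2 = NA_character_
    )
  as_pan_design(d)
}

# read pairs from known fragments with per-read substitution errors; error
# bases are written with low quality ('#', Q2) and correct bases with 'I'
# (Q40), so the higher-Phred base at an overlap disagreement is the true one
fixture_pairs <- function(fragments, read_len = 300, error_rate = 0) {
  n <- length(fragments)
  corrupt <- function(s) {
    if (error_rate == 0) return(list(seq = s, qual = strrep("I", nchar(s))))
    ch <- strsplit(s, "")[[1]]
    q <- rep("I", length(ch))
    hit <- which(stats::runif(length(ch)) < error_rate)
    for (i in hit) {
      ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
      q[i] <- "#"
    }
    list(seq = paste(ch, collapse = ""), qual = paste(q, collapse = ""))
  }
  r1 <- lapply(substr(fragments, 1, read_len), corrupt)
  r2p <- lapply(substr(fragments, nchar(fragments) - read_len + 1,
                       nchar(fragments)), corrupt)
  tibble::tibble(
    id = sprintf("frag%05d", seq_len(n)),
    seq1 = vapply(r1, `[[`, "", "seq"),
    qual1 = vapply(r1, `[[`, "", "qual"),
    seq2 = revcomp(vapply(r2p, `[[`, "", "seq")),
    qual2 = vapply(r2p, function(x) {
      paste(rev(strsplit(x$qual, "")[[1]]), collapse = "")
    }, "")
  )
}

# best achievable reconstruction of a fragment from an error-injected pair:
# unique regions come from the read covering them, overlap disagreements
# resolve to the higher-quality base (ties to read 1)
fixture_consensus <- function(fragment, pair, read_len = 300) {
  L <- nchar(fragment)
  ov <- 2 * read_len - L
  s1 <- strsplit(pair$seq1, "")[[1]]
  q1 <- strsplit(pair$qual1, "")[[1]]
  s2 <- rev(strsplit(chartr("ACGT", "TGCA", pair$seq2), "")[[1]])
  q2 <- rev(strsplit(pair$qual2, "")[[1]])
  out <- character(L)
  out[1:(L - read_len)] <- s1[1:(L - read_len)]
  out[(read_len + 1):L] <- s2[(ov + 1):read_len]
  for (k in (L - read_len + 1):read_len) {
    i2 <- k - (L - read_len)
    out[k] <- if (s1[k] == s2[i2]) s1[k] else
      if (q2[i2] > q1[k]) s2[i2] else s1[k]
  }
  paste(out, collapse = "")
}
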