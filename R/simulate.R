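# canonical VHH framework-4 anchor (WGQGTQVTVSS) used as the default 3'
# anchor for CDR3 excision and by the simulator
FWR4_DEFAULT <- "TGGGGCCAAGGGACCCAGGTCACCGTCTCCTCA"

CODONS <- {
  b <- c("A", "C", "G", "T")
  as.vector(outer(outer(b, b, paste0), b, paste0))
}
STOPS <- c("TAA", "TAG", "TGA")
CYS <- c("TGT", "TGC")

#' Simulation configuration
#'
#' Defines a synthetic panning campaign: a clone library drawn from a small
#' V-gene pool with variable CDR3s, designated binders that multiply their
#' frequency each round, multinomial sequencing depth, per-base substitution
#' errors and fragmentation into overlapping 2 x `read_length` read pairs.
#' The defaults describe a routine campaign: 1000 clones over 5 V genes,
#' 50 binders enriching 4-fold per round over 3 rounds, 100,000 reads per
#' round and a 0.5% per-base error rate on 300 bp reads.
#'
#' @param n_clones number of unique clones in the library.
#' @param n_binders number of designated binders.
#' @param enrichment_factor per-round frequency multiplier for binders
#'   (scalar or length `n_clones` vector of per-clone factors; 1 = neutral).
#' @param rounds number of selection rounds after round zero.
#' @param depth_per_round sequenced reads per round.
#' @param subst_error_rate per-base substitution error probability.
#' @param cdr3_len_range CDR3 length range in amino acids.
#' @param read_length read length in bp (clone lengths must stay between
#'   `read_length` and `2 * read_length` so pairs overlap).
#' @param n_v_genes size of the synthetic V-gene pool (ignored when
#'   `v_gene_pool` is given).
#' @param v_gene_pool optional tibble (`name`, `seq`) of V-gene references.
#' @param fwr4_nt FWR4 anchor used to build clones.
#' @param adapter adapter appended when a fragment is shorter than the read.
#' @param seed integer seed governing every random choice.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_clones = 1000, n_binders = 50,
                       enrichment_factor = 4, rounds = 3,
                       depth_per_round = 1e5, subst_error_rate = 0.005,
                       cdr3_len_range = c(8, 20), read_length = 300,
                       n_v_genes = 5, v_gene_pool = NULL,
                       fwr4_nt = FWR4_DEFAULT,
                       adapter = "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA",
                       seed = 1L) {
  if (n_binders > n_clones) abort("`n_binders` must be <= `n_clones`")
  if (depth_per_round <= 0) abort("`depth_per_round` must be > 0")
  if (any(enrichment_factor < 1)) {
    abort("`enrichment_factor` must be >= 1 (1 = null campaign)")
  }
  structure(
    list(n_clones = as.integer(n_clones), n_binders = as.integer(n_binders),
         enrichment_factor = enrichment_factor, rounds = as.integer(rounds),
         depth_per_round = as.integer(depth_per_round),
         subst_error_rate = subst_error_rate,
         cdr3_len_range = as.integer(cdr3_len_range),
         read_length = as.integer(read_length),
         n_v_genes = as.integer(n_v_genes), v_gene_pool = v_gene_pool,
         fwr4_nt = toupper(fwr4_nt), adapter = toupper(adapter),
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

random_codons <- function(n, exclude = STOPS) {
  pool <- setdiff(CODONS, exclude)
  paste(sample(pool, n, replace = TRUE), collapse = "")
}

#' Generate a synthetic V-gene reference pool
#'
#' Each reference is 96 random stop-free codons (the FR1-FR3 body), the
#' conserved cysteine codon, and a 4-codon tail free of further cysteines,
#' so the last in-frame cysteine is the conserved one. Uses the current RNG
#' state.
#'
#' @param n number of references.
#' @param body_codons codons before the conserved cysteine.
#' @return tibble (`name`, `seq`).
#' @export
synthetic_v_genes <- function(n, body_codons = 96) {
  tibble(
    name = sprintf("IGHV_sim%02d", seq_len(n)),
    seq = vapply(seq_len(n), function(i) {
      paste0(random_codons(body_codons, exclude = c(STOPS, CYS)), "TGT",
             random_codons(4, exclude = c(STOPS, CYS)))
    }, character(1))
  )
}

#' Simulate a clone library with known ground truth
#'
#' Builds `n_clones` unique clones, each the concatenation of a V gene
#' (truncated at the conserved cysteine), the cysteine codon, a random
#' in-frame stop-free CDR3, the FWR4 anchor and a short constant tail.
#' Initial library frequencies are log-normal (sigma = 1, the skewed clone
#' sizes typical of panning libraries), normalised to 1. The first
#' `n_binders` clones (after shuffling) are flagged binders.
#'
#' @param config a [sim_config()].
#' @return A list of class `sim_truth`: `clones` (tibble with `clone_id`,
#'   `v_gene`, `cdr3_nt`, `cdr3_aa`, `full_nt`, `full_aa`, `binder`,
#'   `factor`, `init_freq`), `v_refs`, `fwr4_nt`, `config`.
#' @export
simulate_library <- function(config) {
  set.seed(config$seed)
  v_refs <- config$v_gene_pool %||% synthetic_v_genes(config$n_v_genes)
  prepped <- trim_to_cysteine(v_refs)
  lens <- seq(config$cdr3_len_range[1], config$cdr3_len_range[2])
  tail_nt <- "GGTCAACCGGTC"
  n <- config$n_clones
  cdr3 <- character(0)
  while (length(cdr3) < n) {
    draw <- lens[sample.int(length(lens), n - length(cdr3), replace = TRUE)]
    more <- vapply(draw, function(L) random_codons(L), character(1))
    cdr3 <- unique(c(cdr3, more))
  }
  cdr3 <- cdr3[seq_len(n)]
  vi <- sample(nrow(prepped), n, replace = TRUE)
  full_nt <- paste0(prepped$cys_trim_nt[vi], "TGT", cdr3,
                    config$fwr4_nt, tail_nt)
  too_long <- nchar(full_nt) >= 2 * config$read_length
  too_short <- nchar(full_nt) <= config$read_length
  if (any(too_long | too_short)) {
    abort("clone lengths must lie strictly between read_length and 2*read_length")
  }
  binder <- seq_len(n) %in% sample(n, config$n_binders)
  factors <- rep_len(config$enrichment_factor, n)
  raw <- rlnorm(n, meanlog = 0, sdlog = 1)
  clones <- tibble(
    clone_id = sprintf("clone_%04d", seq_len(n)),
    v_gene = prepped$name[vi],
    cdr3_nt = cdr3,
    cdr3_aa = translate_dna(cdr3),
    full_nt = full_nt,
    full_aa = translate_dna(full_nt),
    binder = binder,
    factor = ifelse(binder, factors, 1),
    init_freq = raw / sum(raw)
  )
  structure(list(clones = clones, v_refs = v_refs, fwr4_nt = config$fwr4_nt,
                 config = config),
            class = "sim_truth")
}

#' Expected frequencies and sampled counts across panning rounds
#'
#' Round-on-round, each clone's frequency is multiplied by its enrichment
#' factor (1 for non-binders) and renormalised; observed counts at each
#' round are a multinomial draw of `depth_per_round` reads from the expected
#' frequencies. Replicates are independent multinomial draws from the same
#' expected trajectory (optionally with replicate-specific factors).
#'
#' @param truth a [simulate_library()] result.
#' @param n_replicates number of independent replicate draws.
#' @param factors optional `n_clones x n_replicates` matrix of per-replicate
#'   enrichment factors (default: the truth's factors in every replicate).
#' @return A tibble with columns `clone_id`, `replicate`, `round`,
#'   `exp_freq`, `count`.
#' @export
simulate_panning_counts <- function(truth, n_replicates = 1,
                                    factors = NULL) {
  config <- truth$config
  set.seed(config$seed + 1L)
  n <- nrow(truth$clones)
  if (is.null(factors)) {
    factors <- matrix(truth$clones$factor, n, n_replicates)
  }
  out <- vector("list", n_replicates)
  for (r in seq_len(n_replicates)) {
    freq <- truth$clones$init_freq
    acc <- vector("list", config$rounds + 1)
    for (rd in 0:config$rounds) {
      if (rd > 0) {
        freq <- freq * factors[, r]
        freq <- freq / sum(freq)
      }
      acc[[rd + 1]] <- tibble(
        clone_id = truth$clones$clone_id,
        replicate = sprintf("rep%d", r),
        round = rd,
        exp_freq = freq,
        count = as.integer(rmultinom(1, config$depth_per_round, freq))
      )
    }
    out[[r]] <- list_rbind(acc)
  }
  list_rbind(out)
}

#' Emit sequencing reads (FASTQ pairs or single reads) for sampled counts
#'
#' Each clone copy receives independent per-base substitution errors, then
#' is split into a forward read (first `read_length` bases) and a reverse
#' read (reverse complement of the last `read_length` bases); qualities are
#' uniform. In single-read mode the full (error-corrupted) clone sequence is
#' emitted directly. With `out_dir` set, per-sample FASTQ files and a
#' samplesheet are written; otherwise reads are returned in memory.
#'
#' @param truth a [simulate_library()] result.
#' @param counts a [simulate_panning_counts()] tibble.
#' @param out_dir optional output directory for FASTQ + samplesheet.
#' @param pan pan label used in sample ids and the samplesheet.
#' @param single_read emit unfragmented reads (merge bypass) instead of
#'   pairs.
#' @return A list with `design` (a `pan_design`; file paths filled when
#'   `out_dir` is set) and `samples` (named list of per-sample read tibbles;
#'   `NULL` when written to disk).
#' @export
emit_reads <- function(truth, counts, out_dir = NULL, pan = "panA",
                       single_read = FALSE) {
  config <- truth$config
  set.seed(config$seed + 2L)
  if (any(nchar(truth$clones$full_nt) >= 2 * config$read_length)) {
    abort("clone length >= 2 * read_length: pairs cannot overlap")
  }
  groups <- counts |>
    filter(.data$count > 0) |>
    group_by(.data$replicate, .data$round) |>
    nest(.key = "cnt") |>
    ungroup() |>
    arrange(.data$replicate, .data$round)
  design <- groups |>
    mutate(
      sample_id = sprintf("%s_%s_r%d", pan, .data$replicate, .data$round),
      pan = pan, antigen = pan,
      r1 = NA_character_, r2 = NA_character_
    )
  samples <- vector("list", nrow(groups))
  names(samples) <- design$sample_id
  for (g in seq_len(nrow(groups))) {
    cnt <- groups$cnt[[g]]
    idx <- rep.int(match(cnt$clone_id, truth$clones$clone_id), cnt$count)
    idx <- idx[sample.int(length(idx))] # shuffle read order
    seqs <- cpp_mutate_seqs(truth$clones$full_nt[idx],
                            config$subst_error_rate)
    ids <- sprintf("%s_read%07d_%s", design$sample_id[g], seq_along(idx),
                   truth$clones$clone_id[idx])
    if (single_read) {
      samples[[g]] <- list(reads = tibble(
        id = ids, seq = seqs, qual = strrep("I", nchar(seqs))
      ))
    } else {
      L <- config$read_length
      r1 <- substr(seqs, 1L, L)
      r2 <- cpp_revcomp(substr(seqs, nchar(seqs) - L + 1L, nchar(seqs)))
      q <- strrep("I", L)
      samples[[g]] <- list(
        r1 = tibble(id = ids, seq = r1, qual = q),
        r2 = tibble(id = ids, seq = r2, qual = q)
      )
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (g in seq_len(nrow(design))) {
      sid <- design$sample_id[g]
      if (single_read) {
        p1 <- file.path(out_dir, paste0(sid, ".fastq"))
        write_fastq(samples[[g]]$reads, p1)
        design$r1[g] <- p1
      } else {
        p1 <- file.path(out_dir, paste0(sid, "_R1.fastq"))
        p2 <- file.path(out_dir, paste0(sid, "_R2.fastq"))
        write_fastq(samples[[g]]$r1, p1)
        write_fastq(samples[[g]]$r2, p2)
        design$r1[g] <- p1
        design$r2[g] <- p2
      }
    }
    samples <- NULL
  }
  if (is.null(out_dir)) {
    # in-memory reads: placeholder locators keep the design valid
    design$r1 <- paste0("memory://", design$sample_id, "/R1")
    design$r2 <- if (single_read) NA_character_ else
      paste0("memory://", design$sample_id, "/R2")
  }
  design <- design |>
    select("sample_id", "pan", "antigen", "round", "replicate", "r1", "r2") |>
    as_pan_design()
  if (!is.null(out_dir)) {
    readr::write_csv(as_tibble(design), file.path(out_dir, "samplesheet.csv"))
    readr::write_csv(truth$clones |> select(-"full_nt"),
                     file.path(out_dir, "truth.csv"))
    write_fasta(truth$v_refs, file.path(out_dir, "v_genes.fasta"))
  }
  list(design = design, samples = samples)
}

#' Simulate a complete panning campaign
#'
#' Convenience wrapper chaining [simulate_library()],
#' [simulate_panning_counts()] and [emit_reads()].
#'
#' @inheritParams emit_reads
#' @param config a [sim_config()].
#' @param n_replicates independent replicates of the pan.
#' @return A list with `truth`, `counts`, `design`, `samples`.
#' @export
simulate_campaign <- function(config, out_dir = NULL, pan = "panA",
                              n_replicates = 1, single_read = FALSE) {
  truth <- simulate_library(config)
  counts <- simulate_panning_counts(truth, n_replicates = n_replicates)
  reads <- emit_reads(truth, counts, out_dir = out_dir, pan = pan,
                      single_read = single_read)
  list(truth = truth, counts = counts, design = reads$design,
       samples = reads$samples)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
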