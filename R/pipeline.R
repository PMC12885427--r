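#' Run a complete panning analysis
#'
#' End-to-end driver: per sample, read pairs are trimmed and merged (or
#' passed through in single-read mode), surveyed for their most common V
#' genes and annotated; productive reads are collapsed into CDR3 clones,
#' singleton CDR3s removed and counts CPM-normalised; enrichment is called
#' per pan against round zero; enriched clones are greedy-clustered,
#' low-abundance clusters dropped, representatives aligned all-vs-all
#' (BLOSUM62) and embedded by MDS with a cladogram; a ranked top-N candidate
#' list is drawn per pan; multi-pan campaigns additionally get pooled
#' re-clustering with overlap classes, and replicated pans get concordance
#' tables.
#'
#' @param design a `pan_design` (from [read_samplesheet()] or
#'   [as_pan_design()]) or a path to a samplesheet CSV.
#' @param v_refs V-gene references: a tibble (`name`, `seq`) or a FASTA
#'   path.
#' @param fwr4_nt FWR4 anchor nucleotide sequence.
#' @param params a [pan_params()] list.
#' @param adapter optional adapter sequence to trim (NULL skips trimming).
#' @param out_dir optional directory; when given, result CSVs/Newick and a
#'   static HTML report are written there.
#' @return A `pan_campaign` list: `design`, `params`, `stage_stats`, `qc`,
#'   `clone_table`, `enrichment`, `pans` (per pan: `members`, `clusters`,
#'   `score_matrix`, `mds`, `cladogram`, `selection`), `overlap` (multi-pan
#'   only), `concordance`.
#' @export
pan_run <- function(design, v_refs, fwr4_nt = FWR4_DEFAULT,
                    params = pan_params(), adapter = NULL, out_dir = NULL) {
  params <- as_pan_params(params)
  if (is.character(design) && length(design) == 1) {
    design <- read_samplesheet(design)
  }
  if (is.character(v_refs) && length(v_refs) == 1) {
    v_refs <- read_fasta(v_refs)
  }
  ann_list <- vector("list", nrow(design))
  stage_list <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    entry <- design[i, ]
    pre <- preprocess_sample(entry, params, adapter)
    ann <- annotate_sample(pre$reads, v_refs, fwr4_nt, params)
    ann_list[[i]] <- ann$annotations |>
      filter(.data$productive) |>
      select("cdr3_aa", "full_aa") |>
      mutate(sample_id = entry$sample_id, productive = TRUE)
    stage_list[[i]] <- bind_cols(pre$stats,
                                 ann$stats |> select(-"reads"))
  }
  annotations <- list_rbind(ann_list)
  stage_stats <- list_rbind(stage_list)
  clone_table <- collapse_clones(annotations)
  stage_stats <- stage_stats |>
    left_join(
      clone_table |>
        filter(.data$count > 0) |>
        count(.data$sample_id, name = "clones_retained"),
      by = "sample_id"
    ) |>
    mutate(clones_retained = dplyr::coalesce(.data$clones_retained, 0L))
  enrichment <- call_enriched(clone_table, design, params)
  pans <- unique(design$pan)
  per_pan <- lapply(pans, function(p) {
    enr <- filter(enrichment, .data$pan == p)
    cl <- cluster_enriched(enr, clone_table, design, params)
    score <- mds <- clado <- NULL
    reps <- cl$clusters$representative
    if (length(reps) >= 2) {
      score <- blosum_score_matrix(reps)
      clado <- build_cladogram(score)
      if (length(reps) >= 3) {
        mds <- mds_embed(score) |>
          left_join(cl$clusters |>
                      select(label = "representative", "cluster_id",
                             abundance = "final_cpm", "max_logfc"),
                    by = "label")
        class(mds) <- c("pan_mds", class(mds))
      }
    }
    selection <- pick_top_n(cl$clusters, cl$members, clone_table, params)
    list(members = cl$members, clusters = cl$clusters, score_matrix = score,
         mds = mds, cladogram = clado, selection = selection)
  })
  names(per_pan) <- pans
  overlap <- if (length(pans) >= 2 && any(enrichment$enriched)) {
    compare_pans(enrichment, params)
  }
  concordance <- replicate_concordance(clone_table, design)
  campaign <- structure(
    list(design = design, params = params, stage_stats = stage_stats,
         qc = qc_summary(stage_stats), clone_table = clone_table,
         enrichment = enrichment, pans = per_pan, overlap = overlap,
         concordance = concordance),
    class = "pan_campaign"
  )
  if (!is.null(out_dir)) {
    write_results(campaign, out_dir)
    render_report(campaign, file.path(out_dir, "report.html"))
  }
  campaign
}

#' @export
print.pan_campaign <- function(x, ...) {
  cat(sprintf("<pan_campaign> %d samples, %d pan(s)\n",
              nrow(x$design), length(x$pans)))
  cat(sprintf("  clones retained: %d\n", dplyr::n_distinct(x$clone_table$clone)))
  cat(sprintf("  enriched clones: %d\n", sum(x$enrichment$enriched)))
  for (p in names(x$pans)) {
    cat(sprintf("  pan %s: %d clusters, top-%d list of %d\n", p,
                nrow(x$pans[[p]]$clusters), x$params$top_n,
                nrow(x$pans[[p]]$selection)))
  }
  invisible(x)
}
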