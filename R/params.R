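#' Analysis parameters
#'
#' Collects every tunable threshold of the panning analysis in one validated
#' list. Defaults follow the conventions of CDR3-level panning enrichment
#' analysis: a pseudocount of 10 CPM on both sides of the fold change, an
#' enrichment call at logFC >= 1.5, candidate-priority cutoffs at logFC > 2.5
#' or CPM > 1000, removal of clusters below 100 CPM at the final round,
#' 80% identity / 80% length greedy clustering, a 1000-read V-gene survey
#' keeping the 15 most common genes at a 20% error rate, 30% error rate for
#' the V-gene and FWR4 anchors during annotation, and a 250 bp maximum merge
#' overlap for 2 x 300 bp chemistry.
#'
#' @param pseudocount CPM added to numerator and denominator of the fold
#'   change (CPM units).
#' @param enrich_logfc log2 fold-change threshold for calling a clone
#'   enriched (inclusive).
#' @param priority_logfc log2 fold change above which a cluster is
#'   priority-tier for the top-N list (exclusive).
#' @param priority_cpm final-round CPM above which a cluster is priority-tier
#'   (exclusive).
#' @param min_cluster_cpm clusters below this final-round CPM are discarded.
#' @param cluster_identity minimum member-to-representative identity.
#' @param cluster_length_ratio minimum min(len)/max(len) ratio of member vs
#'   representative.
#' @param survey_size number of reads sampled for the V-gene survey.
#' @param num_v_genes number of most-common V genes kept after the survey.
#' @param v_error_rate edit-rate budget (fraction of reference length) for
#'   the survey matching.
#' @param anchor_error_rate edit-rate budget for V-gene and FWR4 matching
#'   during annotation.
#' @param max_overlap maximum merge overlap in bp.
#' @param min_overlap minimum merge overlap in bp.
#' @param max_mismatch_density maximum mismatch fraction tolerated in the
#'   merge overlap.
#' @param trim_min_match minimum adapter prefix length for 3' trimming.
#' @param trim_error_rate mismatch fraction tolerated in adapter matching.
#' @param top_n size of the candidate list.
#' @param replicate_combine how replicate CPMs are combined for the headline
#'   fold change: "mean" (default) or "max".
#' @param seed integer seed used for the V-gene survey subsample.
#'
#' @return A named list of class `pan_params`.
#' @examples
#' p <- pan_params(top_n = 50)
#' p$enrich_logfc
#' @export
pan_params <- function(pseudocount = 10,
                       enrich_logfc = 1.5,
                       priority_logfc = 2.5,
                       priority_cpm = 1000,
                       min_cluster_cpm = 100,
                       cluster_identity = 0.80,
                       cluster_length_ratio = 0.80,
                       survey_size = 1000,
                       num_v_genes = 15,
                       v_error_rate = 0.20,
                       anchor_error_rate = 0.30,
                       max_overlap = 250,
                       min_overlap = 10,
                       max_mismatch_density = 0.25,
                       trim_min_match = 3,
                       trim_error_rate = 0.1,
                       top_n = 100,
                       replicate_combine = c("mean", "max"),
                       seed = 0L) {
  p <- list(
    pseudocount = pseudocount, enrich_logfc = enrich_logfc,
    priority_logfc = priority_logfc, priority_cpm = priority_cpm,
    min_cluster_cpm = min_cluster_cpm, cluster_identity = cluster_identity,
    cluster_length_ratio = cluster_length_ratio, survey_size = survey_size,
    num_v_genes = num_v_genes, v_error_rate = v_error_rate,
    anchor_error_rate = anchor_error_rate, max_overlap = max_overlap,
    min_overlap = min_overlap, max_mismatch_density = max_mismatch_density,
    trim_min_match = trim_min_match, trim_error_rate = trim_error_rate,
    top_n = top_n, replicate_combine = match.arg(replicate_combine),
    seed = as.integer(seed)
  )
  frac <- c("cluster_identity", "cluster_length_ratio", "v_error_rate",
            "anchor_error_rate", "max_mismatch_density", "trim_error_rate")
  for (f in frac) {
    if (!is.numeric(p[[f]]) || p[[f]] < 0 || p[[f]] > 1) {
      abort(sprintf("`%s` must be a fraction in [0, 1]", f))
    }
  }
  if (p$pseudocount <= 0) abort("`pseudocount` must be > 0")
  if (p$top_n < 1) abort("`top_n` must be >= 1")
  for (f in c("survey_size", "num_v_genes", "max_overlap", "min_overlap")) {
    if (p[[f]] < 1) abort(sprintf("`%s` must be >= 1", f))
  }
  structure(p, class = "pan_params")
}

#' @export
print.pan_params <- function(x, ...) {
  cat("<pan_params>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

as_pan_params <- function(params) {
  if (inherits(params, "pan_params")) return(params)
  if (is.null(params)) return(pan_params())
  do.call(pan_params, params)
}
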