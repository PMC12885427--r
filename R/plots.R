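#' Plot an MDS embedding of cluster representatives
#'
#' Scatter of the first two MDS axes; when the embedding carries an
#' `abundance` column (final-round cluster CPM) the points are sized by it,
#' and coloured by maximum logFC when available.
#'
#' @param object a `pan_mds` tibble from [mds_embed()].
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.pan_mds <- function(object, ...) {
  ve <- attr(object, "var_explained")
  lab <- function(k) {
    if (!is.null(ve) && length(ve) >= k) {
      sprintf("MDS%d (%.1f%%)", k, 100 * ve[k])
    } else {
      sprintf("MDS%d", k)
    }
  }
  p <- ggplot(object, aes(x = .data$PC1, y = .data$PC2))
  if ("abundance" %in% names(object) && "max_logfc" %in% names(object)) {
    p <- p + geom_point(aes(size = .data$abundance,
                            colour = .data$max_logfc), alpha = 0.7) +
      scale_size_area(name = "final CPM") +
      ggplot2::scale_colour_viridis_c(name = "max logFC")
  } else if ("abundance" %in% names(object)) {
    p <- p + geom_point(aes(size = .data$abundance), alpha = 0.7) +
      scale_size_area(name = "final CPM")
  } else {
    p <- p + geom_point(alpha = 0.7)
  }
  p + labs(x = lab(1), y = lab(2),
           title = "Cluster representative diversity (MDS)") +
    theme_bw()
}

#' Plot replicate concordance scatters
#'
#' All-vs-all replicate scatter of clone CPM (log1p scale) per pan and
#' round, with the y = x identity line.
#'
#' @param object a `pan_concordance` tibble from [replicate_concordance()].
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.pan_concordance <- function(object, ...) {
  df <- object |>
    mutate(pair = paste(.data$rep_i, "vs", .data$rep_j),
           round = paste("round", .data$round))
  ggplot(df, aes(x = log1p(.data$cpm_i), y = log1p(.data$cpm_j))) +
    geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    geom_point(alpha = 0.4, size = 0.8) +
    facet_grid(round ~ pan + pair) +
    labs(x = "log1p CPM (replicate i)", y = "log1p CPM (replicate j)",
         title = "Replicate concordance") +
    theme_bw()
}

#' Plot pan-overlap classes (UpSet-style bars)
#'
#' Bar chart of the number of pooled clusters in each pan-membership class.
#'
#' @param object a `pan_overlap` from [compare_pans()].
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.pan_overlap <- function(object, ...) {
  df <- object$classes |>
    mutate(membership = factor(.data$membership,
                               levels = .data$membership))
  ggplot(df, aes(x = .data$membership, y = .data$n_clusters)) +
    geom_col(fill = "#c2608e") +
    labs(x = "pan membership", y = "pooled clusters",
         title = "Enriched-cluster overlap between pans") +
    theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot enrichment landscape
#'
#' Final-round CPM against log fold change for every evaluated clone,
#' coloured by the enrichment call.
#'
#' @param object a `pan_enrichment` tibble from [call_enriched()].
#' @param ... ignored.
#' @return A ggplot object.
#' @export
autoplot.pan_enrichment <- function(object, ...) {
  ggplot(object, aes(x = .data$logfc, y = .data$final_cpm,
                     colour = .data$enriched)) +
    geom_point(alpha = 0.5, size = 0.9) +
    ggplot2::scale_y_log10() +
    facet_wrap(~pan) +
    labs(x = "log2 fold change (pseudocounted)", y = "final-round CPM",
         title = "Clone enrichment") +
    theme_bw()
}
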