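#' Per-sample QC summary
#'
#' Collapses the stage counts collected along the pipeline into per-sample
#' rates: merge rate, productive-annotation rate and the read fraction lost
#' to singleton (count-1) CDR3 removal. Samples with a productive rate below
#' 0.5 are flagged.
#'
#' @param stage_stats tibble of per-sample stage counts as assembled by
#'   [pan_run()] (columns `sample_id`, `reads_in`, `reads_trimmed`,
#'   `reads_merged`, `productive`, and optionally `reads_in_clones`,
#'   `clones_retained`).
#' @return A tibble with one row per sample: counts, `merge_rate`,
#'   `productive_rate`, `singleton_loss`, `clones_retained`, `flag`.
#' @export
qc_summary <- function(stage_stats) {
  df <- as_tibble(stage_stats)
  if (!"reads_in_clones" %in% names(df)) df$reads_in_clones <- NA_integer_
  if (!"clones_retained" %in% names(df)) df$clones_retained <- NA_integer_
  df |>
    mutate(
      merge_rate = if_else(.data$reads_in > 0,
                           .data$reads_merged / .data$reads_in, 0),
      productive_rate = if_else(.data$reads_merged > 0,
                                .data$productive / .data$reads_merged, 0),
      singleton_loss = if_else(
        !is.na(.data$reads_in_clones) & .data$productive > 0,
        1 - .data$reads_in_clones / .data$productive, NA_real_
      ),
      flag = .data$productive_rate < 0.5
    ) |>
    select("sample_id", "reads_in", "reads_trimmed", "reads_merged",
           "productive", "clones_retained", "merge_rate", "productive_rate",
           "singleton_loss", "flag")
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

html_table <- function(df, max_rows = 200) {
  df <- utils::head(as.data.frame(df), max_rows)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) signif(v, 6))
  cells <- vapply(seq_len(nrow(df)), function(i) {
    paste0("<tr>", paste0("<td>", html_escape(as.character(unlist(df[i, ]))),
                          "</td>", collapse = ""), "</tr>")
  }, character(1))
  paste0(
    "<table><thead><tr>",
    paste0("<th>", html_escape(names(df)), "</th>", collapse = ""),
    "</tr></thead><tbody>", paste(cells, collapse = "\n"), "</tbody></table>"
  )
}

# render a plotting closure to an embedded <img> (base64 PNG); returns ""
# if no plot could be produced
html_png <- function(draw, width = 760, height = 520) {
  f <- tempfile(fileext = ".png")
  on.exit(unlink(f), add = TRUE)
  ok <- tryCatch({
    grDevices::png(f, width = width, height = height, res = 96)
    draw()
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    FALSE
  })
  if (!ok || !file.exists(f)) return("")
  b64 <- jsonlite::base64_enc(readBin(f, "raw", file.info(f)$size))
  sprintf('<img src="data:image/png;base64,%s" width="%d"/>',
          gsub("\n", "", b64), width)
}

#' Render a static HTML campaign report
#'
#' Writes a single self-contained HTML file with the QC table, per-pan
#' cluster tables, MDS scatter (points sized by final-round abundance),
#' cladograms, the ranked candidate lists, replicate concordance scatters
#' and, for multi-pan campaigns, the overlap classes. All figures are
#' embedded as base64 PNG; the same campaign renders to identical bytes.
#'
#' @param campaign a `pan_campaign` from [pan_run()].
#' @param path output HTML path.
#' @return `path`, invisibly.
#' @export
render_report <- function(campaign, path) {
  for (need in c("qc", "clone_table", "enrichment", "pans")) {
    if (is.null(campaign[[need]])) {
      abort(sprintf("campaign is missing mandatory section '%s'", need))
    }
  }
  parts <- c(
    "<!DOCTYPE html><html><head><meta charset='utf-8'>",
    "<title>Panning campaign report</title><style>",
    "body{font-family:sans-serif;margin:2em;max-width:70em}",
    "table{border-collapse:collapse;font-size:0.85em}",
    "td,th{border:1px solid #bbb;padding:2px 8px;text-align:left}",
    "h1{color:#333}h2{color:#444;border-bottom:1px solid #ddd}",
    "</style></head><body>",
    "<h1>Nanobody panning campaign report</h1>",
    sprintf("<p>%d samples, %d pan(s); %d clones retained, %d enriched.</p>",
            nrow(campaign$design), length(campaign$pans),
            dplyr::n_distinct(campaign$clone_table$clone),
            sum(campaign$enrichment$enriched)),
    "<h2>Quality control</h2>", html_table(campaign$qc)
  )
  for (p in names(campaign$pans)) {
    res <- campaign$pans[[p]]
    parts <- c(parts, sprintf("<h2>Pan %s</h2>", html_escape(p)))
    parts <- c(parts, sprintf("<h3>Clusters (%d)</h3>", nrow(res$clusters)),
               html_table(res$clusters, 100))
    if (!is.null(res$mds)) {
      parts <- c(parts, "<h3>Sequence diversity (MDS)</h3>",
                 html_png(function() print(autoplot(res$mds))))
    }
    if (!is.null(res$cladogram)) {
      parts <- c(parts, "<h3>Cladogram</h3>",
                 html_png(function() {
                   ape::plot.phylo(res$cladogram, cex = 0.7,
                                   no.margin = TRUE)
                 }, height = 620))
    }
    parts <- c(parts,
               sprintf("<h3>Top %d candidates</h3>", nrow(res$selection)),
               html_table(res$selection, campaign$params$top_n))
  }
  if (!is.null(campaign$concordance) && nrow(campaign$concordance) > 0) {
    parts <- c(parts, "<h2>Replicate concordance</h2>",
               html_table(glance(campaign$concordance)),
               html_png(function() print(autoplot(campaign$concordance))))
  }
  if (!is.null(campaign$overlap)) {
    parts <- c(parts, "<h2>Pan overlap</h2>",
               html_table(campaign$overlap$classes),
               html_png(function() print(autoplot(campaign$overlap))))
  }
  parts <- c(parts, "</body></html>")
  writeLines(parts, path, useBytes = TRUE)
  invisible(path)
}
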