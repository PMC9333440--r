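#' Render a risk chart for reading
#'
#' Lays the chart out block by block in the conventional chart style:
#' within a block, rows are printed highest blood pressure first (the
#' internal canonical orientation stores the lowest category at index 1;
#' printing flips it). The text format is strict enough to be parsed back
#' with [parse_chart_text()] — rendering is presentation only and loses no
#' information. The HTML format adds one colored table per block.
#'
#' @param chart A `risk_chart`.
#' @param format `"text"` or `"html"`.
#' @return A single string (the document).
#' @export
render_chart <- function(chart, format = c("text", "html")) {
  format <- match.arg(format)
  if (format == "text") render_chart_text(chart) else render_chart_html(chart)
}

render_chart_text <- function(chart) {
  spec <- chart$spec
  row_labs <- spec$row_axis$categories
  col_labs <- if (is.null(spec$column_axis)) "risk"
              else spec$column_axis$categories
  wl <- max(nchar(row_labs), nchar(spec$row_axis$name))
  wc <- max(nchar(col_labs), 1L)
  out <- c(paste0("# risk chart: levels 1..", spec$n_levels, " = ",
                  paste(seq_len(spec$n_levels), spec$band_labels,
                        sep = ":", collapse = " ")))
  header <- paste0(formatC(spec$row_axis$name, width = wl), " | ",
                   paste(formatC(col_labs, width = wc), collapse = " "))
  for (key in names(chart$blocks)) {
    g <- chart$blocks[[key]]
    out <- c(out, paste0("== block: ", key, " =="), header)
    for (i in rev(seq_len(nrow(g))))  # highest BP printed first
      out <- c(out, paste0(formatC(row_labs[i], width = wl), " | ",
                           paste(formatC(g[i, ], width = wc), collapse = " ")))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}

#' @rdname render_chart
#' @param text A document produced by the text renderer.
#' @param spec The `chart_spec` of the rendered chart.
#' @return `parse_chart_text()` returns the reconstructed `risk_chart`.
#' @export
parse_chart_text <- function(text, spec) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  starts <- grep("^== block: ", lines)
  R <- n_chart_rows(spec)
  blocks <- list()
  for (s in starts) {
    key <- sub("^== block: (.*) ==$", "\\1", lines[s])
    rows <- lines[(s + 2L):(s + 1L + R)]  # skip the column header
    vals <- lapply(rows, function(l)
      as.integer(strsplit(trimws(sub("^.*\\|", "", l)), "[[:space:]]+")[[1]]))
    blocks[[key]] <- do.call(rbind, rev(vals))  # back to canonical order
  }
  risk_chart(spec, blocks)
}

render_chart_html <- function(chart) {
  spec <- chart$spec
  cols <- c("#2e7d32", "#8bc34a", "#ffeb3b", "#ff9800", "#f4511e", "#b71c1c")
  shade <- function(l) cols[ceiling(l / spec$n_levels * length(cols))]
  col_labs <- if (is.null(spec$column_axis)) "risk"
              else spec$column_axis$categories
  body <- character(0)
  for (key in names(chart$blocks)) {
    g <- chart$blocks[[key]]
    rows <- character(0)
    for (i in rev(seq_len(nrow(g)))) {
      cells <- paste0("<td style=\"background:", shade(g[i, ]),
                      "\">", spec$band_labels[g[i, ]], "</td>",
                      collapse = "")
      rows <- c(rows, paste0("<tr><th>", spec$row_axis$categories[i],
                             "</th>", cells, "</tr>"))
    }
    body <- c(body,
              paste0("<h3>", key, "</h3><table border=\"1\"><tr><th>",
                     spec$row_axis$name, "</th><th>",
                     paste(col_labs, collapse = "</th><th>"),
                     "</th></tr>", paste(rows, collapse = ""), "</table>"))
  }
  paste0("<!DOCTYPE html><html><body><h2>10-year CVD risk chart</h2>",
         paste(body, collapse = "\n"), "</body></html>\n")
}
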