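#' Construct a risk chart
#'
#' A risk chart maps every stratum key of its spec to one valid chromosome.
#' It is the full deployable score: scoring a person is a lookup of the gene
#' at their (blood pressure, cholesterol) cell inside their stratum's block.
#'
#' @param spec A `chart_spec`.
#' @param blocks Named list of chromosomes, one per `block_keys(spec)`. If
#'   `NULL`, every block is initialized to the all-ones (lowest risk) matrix.
#' @return An object of class `risk_chart`.
#' @export
risk_chart <- function(spec, blocks = NULL) {
  keys <- block_keys(spec)
  R <- n_chart_rows(spec); C <- n_chart_cols(spec)
  if (is.null(blocks)) {
    one <- matrix(1L, R, C)
    blocks <- stats::setNames(rep(list(one), length(keys)), keys)
  }
  if (!setequal(names(blocks), keys))
    stop("blocks must cover exactly the stratum keys of the spec")
  blocks <- blocks[keys]
  for (k in keys) {
    blocks[[k]] <- as_chromosome(blocks[[k]])
    if (!identical(dim(blocks[[k]]), c(R, C)))
      stop("block '", k, "' has wrong dimensions")
    if (!is_valid_chromosome(blocks[[k]], spec$n_levels))
      stop("block '", k, "' violates the monotonicity constraint")
  }
  structure(list(spec = spec, blocks = blocks), class = "risk_chart")
}

#' @export
print.risk_chart <- function(x, ...) {
  cat("Risk chart: ", block_count(x$spec), " block(s), ",
      cell_count(x$spec), " cells, levels 1..", x$spec$n_levels, "\n",
      sep = "")
  invisible(x)
}

#' Score records against a risk chart
#'
#' Looks up each record's gene level and risk band. Records must be
#' categorizable against the chart's spec; an absent stratum key means the
#' chart is incomplete and is an error.
#'
#' @param chart A `risk_chart`.
#' @param cohort Categorized cohort data frame (see [categorize_cohort()]);
#'   the `outcome` column is not required for scoring.
#' @return Data frame with columns `level` (integer gene) and `band` (risk
#'   band label).
#' @export
lookup_risk <- function(chart, cohort) {
  spec <- chart$spec
  keys <- stratum_key(cohort, spec)
  miss <- setdiff(unique(keys), names(chart$blocks))
  if (length(miss))
    stop("chart has no block for stratum key(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  ri <- as.integer(cohort$bp_cat)
  ci <- if (is.null(spec$column_axis)) rep(1L, nrow(cohort))
        else as.integer(cohort$chol_cat)
  if (any(is.na(ri)) || any(is.na(ci)))
    stop("records must carry bp_cat", if (!is.null(spec$column_axis))
      " and chol_cat", " categories")
  lev <- integer(nrow(cohort))
  for (k in unique(keys)) {
    sel <- keys == k
    lev[sel] <- chart$blocks[[k]][cbind(ri[sel], ci[sel])]
  }
  data.frame(level = lev, band = spec$band_labels[lev],
             stringsAsFactors = FALSE)
}

# Per-cell positive/negative counts for a categorized cohort: the sufficient
# statistics for every AUROC computation downstream. Returns list(keys,
# pos, neg) where pos/neg are R x C x n_block arrays indexed by block key.
cohort_cell_counts <- function(cohort, spec) {
  keys <- block_keys(spec)
  R <- n_chart_rows(spec); C <- n_chart_cols(spec)
  pos <- array(0, dim = c(R, C, length(keys)), dimnames = list(NULL, NULL, keys))
  neg <- pos
  k <- stratum_key(cohort, spec)
  ri <- as.integer(cohort$bp_cat)
  ci <- if (is.null(spec$column_axis)) rep(1L, nrow(cohort))
        else as.integer(cohort$chol_cat)
  bi <- match(k, keys)
  if (any(is.na(bi))) stop("record stratum key not in spec")
  y <- cohort$outcome == 1L
  # tabulate via 3D linear index
  lin <- (bi - 1L) * (R * C) + (ci - 1L) * R + ri
  posv <- tabulate(lin[y], nbins = R * C * length(keys))
  negv <- tabulate(lin[!y], nbins = R * C * length(keys))
  pos[] <- posv
  neg[] <- negv
  list(keys = keys, pos = pos, neg = neg, R = R, C = C)
}

# Tally positives/negatives by gene level for the whole chart.
chart_level_tallies <- function(chart, counts) {
  L <- chart$spec$n_levels
  pos <- numeric(L); neg <- numeric(L)
  for (b in seq_along(counts$keys)) {
    g <- chart$blocks[[counts$keys[b]]]
    for (l in seq_len(L)) {
      sel <- g == l
      if (any(sel)) {
        pos[l] <- pos[l] + sum(counts$pos[, , b][sel])
        neg[l] <- neg[l] + sum(counts$neg[, , b][sel])
      }
    }
  }
  list(pos = pos, neg = neg)
}

auroc_from_tallies <- function(pos, neg) {
  P <- sum(pos); N <- sum(neg)
  if (P == 0 || N == 0)
    stop("AUROC undefined: labels contain a single class")
  below <- cumsum(neg) - neg
  (sum(pos * below) + 0.5 * sum(pos * neg)) / (P * N)
}

#' Training-data AUROC of a chart
#'
#' Area under the ROC curve of the chart's gene levels as scores against
#' the cohort's outcomes, with tied pairs counted half.
#'
#' @param chart A `risk_chart`.
#' @param cohort Categorized cohort with an `outcome` column.
#' @return AUROC in `[0, 1]`.
#' @export
chart_auroc <- function(chart, cohort) {
  counts <- cohort_cell_counts(cohort, chart$spec)
  t <- chart_level_tallies(chart, counts)
  auroc_from_tallies(t$pos, t$neg)
}
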