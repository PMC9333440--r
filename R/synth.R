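#' Build a planted monotone risk model
#'
#' Constructs the ground truth for simulation: a true 10-year event
#' probability for every chart cell, of the form
#' `plogis(baseline + sum of per-category log-odds increments)`. Increment
#' vectors for the blood-pressure and cholesterol axes must be
#' non-decreasing, so every cell-probability matrix is monotone by
#' construction. The baseline is solved so that the expected event rate
#' over the feature marginals equals `target_rate` exactly (default
#' 705/5432, a ~13% ten-year event rate in a cohort of middle-aged and
#' older adults).
#'
#' @param spec A `chart_spec`.
#' @param effects Named list of per-category log-odds increment vectors
#'   (first category = 0), one per feature; defaults via
#'   `default_effects(spec)`. Setting all increments to zero yields a
#'   constant-risk model.
#' @param marginals Named list of category probability vectors per feature;
#'   defaults via `default_marginals(spec)`.
#' @param target_rate Expected overall event proportion.
#' @return An object of class `planted_model`: the spec, resolved effects,
#'   marginals, solved baseline, and `cell_probs` (stratum key -> matrix).
#' @export
planted_model <- function(spec, effects = NULL, marginals = NULL,
                          target_rate = 705 / 5432) {
  if (is.null(effects)) effects <- default_effects(spec)
  if (is.null(marginals)) marginals <- default_marginals(spec)
  feats <- c(spec$stratifiers, list(spec$row_axis),
             if (!is.null(spec$column_axis)) list(spec$column_axis))
  for (f in feats) {
    nm <- f$name
    if (is.null(effects[[nm]])) effects[[nm]] <- numeric(length(f$categories))
    if (length(effects[[nm]]) != length(f$categories))
      stop("effects$", nm, " must have one increment per category")
    if (is.null(marginals[[nm]]))
      marginals[[nm]] <- rep(1 / length(f$categories), length(f$categories))
    if (length(marginals[[nm]]) != length(f$categories) ||
        any(marginals[[nm]] < 0))
      stop("marginals$", nm, " must be non-negative, one per category")
    marginals[[nm]] <- marginals[[nm]] / sum(marginals[[nm]])
  }
  monotone_axes <- c(spec$row_axis$name,
                     if (!is.null(spec$column_axis)) spec$column_axis$name,
                     "age_group")
  for (nm in intersect(monotone_axes, names(effects)))
    if (any(diff(effects[[nm]]) < 0))
      stop("effects$", nm, " must be non-decreasing (monotone risk axis)")
  stopifnot(target_rate > 0, target_rate < 1)

  # linear predictor (without baseline) and probability weight per cell
  keys <- block_keys(spec)
  strat_cats <- lapply(spec$stratifiers, function(s) s$categories)
  grid <- if (length(strat_cats))
    expand.grid(strat_cats, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  else data.frame(row.names = 1L)
  R <- n_chart_rows(spec); C <- n_chart_cols(spec)
  block_eta <- numeric(length(keys)); block_w <- numeric(length(keys))
  for (b in seq_along(keys)) {
    eta <- 0; w <- 1
    for (si in seq_along(spec$stratifiers)) {
      s <- spec$stratifiers[[si]]
      ci <- match(grid[b, si], s$categories)
      eta <- eta + effects[[s$name]][ci]
      w <- w * marginals[[s$name]][ci]
    }
    block_eta[b] <- eta; block_w[b] <- w
  }
  row_eta <- effects[[spec$row_axis$name]]
  row_w <- marginals[[spec$row_axis$name]]
  col_eta <- if (is.null(spec$column_axis)) 0 else effects[[spec$column_axis$name]]
  col_w <- if (is.null(spec$column_axis)) 1 else marginals[[spec$column_axis$name]]
  cell_eta <- outer(row_eta, col_eta, "+")               # R x C
  cell_w <- outer(row_w, col_w)                          # R x C

  expected_rate <- function(b0) {
    r <- 0
    for (b in seq_along(keys))
      r <- r + block_w[b] * sum(cell_w * stats::plogis(b0 + block_eta[b] + cell_eta))
    r
  }
  baseline <- stats::uniroot(function(b0) expected_rate(b0) - target_rate,
                             lower = -20, upper = 10, tol = 1e-12)$root
  cell_probs <- stats::setNames(vector("list", length(keys)), keys)
  for (b in seq_along(keys))
    cell_probs[[b]] <- stats::plogis(baseline + block_eta[b] + cell_eta)
  structure(list(spec = spec, effects = effects, marginals = marginals,
                 baseline = baseline, target_rate = target_rate,
                 cell_probs = cell_probs),
            class = "planted_model")
}

#' @rdname planted_model
#' @export
default_effects <- function(spec) {
  list(bp = c(0, 0.35, 0.70, 1.05),
       chol = c(0, 0.25, 0.50, 0.75, 1.00),
       age_group = c(0, 0.55, 1.10, 1.65, 2.20),
       sex = c(0, 0.45),
       whr = c(0, 0.35),
       fh_cvd = c(0, 0.40),
       diabetes = c(0, 0.65),
       smoker = c(0, 0.50))
}

#' @rdname planted_model
#' @export
default_marginals <- function(spec) {
  list(sex = c(0.515, 0.485),
       age_group = c(0.32, 0.27, 0.21, 0.13, 0.07),
       whr = c(0.55, 0.45),
       fh_cvd = c(0.83, 0.17),
       diabetes = c(0.91, 0.09),
       smoker = c(0.79, 0.21),
       bp = c(0.38, 0.34, 0.18, 0.10),
       chol = c(0.18, 0.34, 0.30, 0.13, 0.05))
}

#' @export
print.planted_model <- function(x, ...) {
  cat("Planted monotone risk model: ", block_count(x$spec), " block(s), ",
      "target event rate ", sprintf("%.4f", x$target_rate),
      ", baseline log-odds ", sprintf("%.3f", x$baseline), "\n", sep = "")
  invisible(x)
}

#' Simulate a cohort from a planted model
#'
#' Draws each feature independently from the model's marginals and the
#' binary 10-year outcome from a Bernoulli with the record's true cell
#' probability. With `raw_values = TRUE`, continuous measurements (age,
#' systolic BP, cholesterol, waist-to-hip ratio, fasting blood sugar) are
#' generated uniformly within each drawn category's range so that the
#' categorization code path can be exercised end to end; the default
#' returns categorized records directly.
#'
#' @param model A [planted_model()].
#' @param n Number of records.
#' @param seed Optional RNG seed; the same seed reproduces the cohort
#'   exactly.
#' @param raw_values Emit raw continuous measurements instead of category
#'   labels.
#' @return A data frame; categorized (with `"chart_spec"` attribute) unless
#'   `raw_values = TRUE`.
#' @export
simulate_cohort <- function(model, n = 5432L, seed = NULL,
                            raw_values = FALSE) {
  stopifnot(inherits(model, "planted_model"), n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  spec <- model$spec
  df <- data.frame(row.names = seq_len(n))
  strat_idx <- list()
  for (s in spec$stratifiers) {
    idx <- sample.int(length(s$categories), n, replace = TRUE,
                      prob = model$marginals[[s$name]])
    strat_idx[[s$name]] <- idx
    df[[s$name]] <- s$categories[idx]
  }
  bp_cat <- sample.int(n_chart_rows(spec), n, replace = TRUE,
                       prob = model$marginals[[spec$row_axis$name]])
  df$bp_cat <- bp_cat
  chol_cat <- if (is.null(spec$column_axis)) rep(1L, n)
  else sample.int(n_chart_cols(spec), n, replace = TRUE,
                  prob = model$marginals[[spec$column_axis$name]])
  if (!is.null(spec$column_axis)) df$chol_cat <- chol_cat
  key <- stratum_key(df, spec)
  prob <- numeric(n)
  for (k in unique(key)) {
    sel <- key == k
    prob[sel] <- model$cell_probs[[k]][cbind(bp_cat[sel], chol_cat[sel])]
  }
  df$outcome <- stats::rbinom(n, 1L, prob)
  if (!raw_values) {
    attr(df, "chart_spec") <- spec
    return(df)
  }
  raw_cohort(df, spec, strat_idx, bp_cat, chol_cat)
}

# Continuous measurements drawn uniformly inside each category's range.
raw_cohort <- function(df, spec, strat_idx, bp_cat, chol_cat) {
  n <- nrow(df)
  raw <- data.frame(row.names = seq_len(n))
  raw$sex <- df$sex
  if (!is.null(strat_idx$age_group)) {
    ag <- age_feature_of(spec)
    lo <- c(35, ag$edges)[strat_idx$age_group]
    hi <- c(ag$edges, 90)[strat_idx$age_group]
    raw$age <- stats::runif(n, lo, hi)
  }
  lo <- c(90, 120, 140, 160)[bp_cat]
  hi <- c(120, 140, 160, 220)[bp_cat]
  raw$bp <- stats::runif(n, lo, hi)
  if (!is.null(spec$column_axis)) {
    lo <- c(100, 150, 200, 250, 300)[chol_cat]
    hi <- c(150, 200, 250, 300, 400)[chol_cat]
    raw$chol <- stats::runif(n, lo, hi)
  }
  if (!is.null(df$whr)) {
    thr <- unname(whr_thresholds_of(spec)[raw$sex])
    high <- df$whr == "high"
    raw$whr <- ifelse(high, stats::runif(n, thr, thr + 0.20),
                      stats::runif(n, thr - 0.20, thr - 1e-6))
  }
  if (!is.null(df$diabetes)) {
    dia <- df$diabetes == "yes"
    raw$fbs <- ifelse(dia, stats::runif(n, 126, 250), stats::runif(n, 70, 125))
  }
  if (!is.null(df$fh_cvd)) raw$fh_cvd <- as.integer(df$fh_cvd == "yes")
  if (!is.null(df$smoker)) raw$smoker <- as.integer(df$smoker == "yes")
  raw$outcome <- df$outcome
  raw
}

#' Oracle AUROC of the planted probabilities
#'
#' The AUROC obtained by scoring every record with its true cell
#' probability — the ceiling for any scorer that is constant within chart
#' cells on this cohort, used as the reference in recovery experiments.
#'
#' @param model A [planted_model()].
#' @param cohort Categorized cohort simulated from (or compatible with) the
#'   model's spec.
#' @return AUROC in `[0, 1]`; exactly 0.5 for a constant-probability model.
#' @export
bayes_auroc <- function(model, cohort) {
  spec <- model$spec
  key <- stratum_key(cohort, spec)
  ri <- as.integer(cohort$bp_cat)
  ci <- if (is.null(spec$column_axis)) rep(1L, nrow(cohort))
        else as.integer(cohort$chol_cat)
  prob <- numeric(nrow(cohort))
  for (k in unique(key)) {
    sel <- key == k
    prob[sel] <- model$cell_probs[[k]][cbind(ri[sel], ci[sel])]
  }
  fitness_auroc(prob, cohort$outcome)
}

#' Recovery of the planted surface by a trained chart
#'
#' Compares learned gene levels with the planted cell probabilities over
#' cells covered by at least `min_n` cohort records: Spearman rank
#' correlation (1 means the chart perfectly ranks the true risks) and the
#' fraction of covered cells whose learned level equals the planted
#' probability's nearest-band level.
#'
#' @param model A [planted_model()].
#' @param chart A trained `risk_chart` with the same spec geometry.
#' @param cohort Categorized cohort used to count cell coverage.
#' @param min_n Minimum records for a cell to enter the comparison.
#' @return An object of class `recovery_report`: list with `spearman`,
#'   `level_agreement`, `n_cells` and the per-cell data frame `cells`.
#' @export
recovery_report <- function(model, chart, cohort, min_n = 30L) {
  spec <- chart$spec
  if (!identical(block_keys(model$spec), block_keys(spec)) ||
      n_chart_rows(model$spec) != n_chart_rows(spec) ||
      n_chart_cols(model$spec) != n_chart_cols(spec))
    stop("model and chart specs describe different geometries")
  counts <- cohort_cell_counts(cohort, spec)
  mids <- level_midpoints(spec)
  rows <- list()
  for (b in seq_along(counts$keys)) {
    key <- counts$keys[b]
    nm <- matrix(counts$pos[, , b] + counts$neg[, , b], counts$R, counts$C)
    for (i in seq_len(counts$R)) for (j in seq_len(counts$C)) {
      tp <- model$cell_probs[[key]][i, j]
      rows[[length(rows) + 1L]] <- data.frame(
        block_key = key, row = i, col = j, n = nm[i, j],
        true_prob = tp,
        level = chart$blocks[[key]][i, j],
        true_level = which.min(abs(tp - mids)),
        stringsAsFactors = FALSE)
    }
  }
  cells <- do.call(rbind, rows)
  covered <- cells[cells$n >= min_n, , drop = FALSE]
  if (nrow(covered) < 2L)
    stop("fewer than two cells reach min_n coverage")
  structure(list(
    spearman = stats::cor(covered$true_prob, covered$level,
                          method = "spearman"),
    level_agreement = mean(covered$level == covered$true_level),
    n_cells = nrow(covered),
    min_n = min_n,
    cells = cells), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("Recovery over ", x$n_cells, " cells with >= ", x$min_n,
      " records: Spearman ", sprintf("%.3f", x$spearman),
      ", exact-level agreement ", sprintf("%.3f", x$level_agreement),
      "\n", sep = "")
  invisible(x)
}
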