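#' Initialize a chart and its per-block populations
#'
#' `empirical` strategy: each cell's observed 10-year event proportion is
#' mapped to the level whose risk-band midpoint is nearest; empty cells
#' inherit the block-mean level (fully empty blocks the cohort-level
#' proportion), and a monotone smoothing pass — pooled-adjacent-violators
#' along rows then columns, rounded, followed by an upward sweep — makes
#' every block valid. `external` strategy: a user-supplied chart (e.g. one
#' derived from a Cox survival model) becomes the incumbent. Each block's
#' initial population is its incumbent plus seeded one-gene-mutation
#' variants up to `population_size`.
#'
#' @param cohort Categorized cohort with both outcome classes.
#' @param spec A `chart_spec`.
#' @param strategy `"empirical"` or `"external"`.
#' @param external A `risk_chart` (or path to a chart JSON) used as the
#'   incumbent when `strategy = "external"`.
#' @param population_size Initial population size per block.
#' @return List with `chart` (a valid `risk_chart`) and `populations`
#'   (named list of chromosome lists, incumbent first).
#' @export
init_chart <- function(cohort, spec, strategy = c("empirical", "external"),
                       external = NULL, population_size = 20L) {
  strategy <- match.arg(strategy)
  if (strategy == "external") {
    if (is.character(external)) external <- read_chart_json(external)
    if (!inherits(external, "risk_chart"))
      stop("external strategy needs a risk_chart (or a chart JSON path)")
    chart <- risk_chart(spec, external$blocks)
  } else {
    if (sum(cohort$outcome) == 0L)
      stop("empirical initialization requires at least one event")
    counts <- cohort_cell_counts(cohort, spec)
    L <- spec$n_levels
    mids <- level_midpoints(spec)
    overall <- sum(counts$pos) / (sum(counts$pos) + sum(counts$neg))
    overall_level <- which.min(abs(overall - mids))
    blocks <- list()
    for (b in seq_along(counts$keys)) {
      p <- matrix(counts$pos[, , b], counts$R, counts$C)
      q <- matrix(counts$neg[, , b], counts$R, counts$C)
      n <- p + q
      lev <- matrix(NA_real_, counts$R, counts$C)
      covered <- n > 0
      lev[covered] <- vapply(p[covered] / n[covered],
                             function(x) which.min(abs(x - mids)), numeric(1))
      if (all(!covered)) {
        lev[] <- overall_level
      } else if (any(!covered)) {
        lev[!covered] <- round(mean(lev[covered]))
      }
      blocks[[counts$keys[b]]] <- smooth_block_levels(lev, L)
    }
    chart <- risk_chart(spec, blocks)
  }
  populations <- lapply(chart$blocks, make_block_population,
                        size = population_size, n_levels = spec$n_levels)
  list(chart = chart, populations = populations)
}

level_midpoints <- function(spec) {
  if (spec$n_levels == length(band_midpoints())) band_midpoints()
  else seq(0.01, 0.20, length.out = spec$n_levels)
}

# PAVA along rows then columns, round, then an upward sweep: rounding can
# reintroduce a one-step violation, the sweep removes it.
smooth_block_levels <- function(lev, n_levels) {
  if (ncol(lev) > 1L)
    for (i in seq_len(nrow(lev))) lev[i, ] <- stats::isoreg(lev[i, ])$yf
  if (nrow(lev) > 1L)
    for (j in seq_len(ncol(lev))) lev[, j] <- stats::isoreg(lev[, j])$yf
  m <- pmax(1L, pmin(n_levels, as.integer(round(lev))))
  m <- matrix(m, nrow(lev), ncol(lev))
  repair_chromosome(m, +1L)
}

make_block_population <- function(incumbent, size, n_levels) {
  pop <- list(as_chromosome(incumbent))
  while (length(pop) < size) {
    v <- pop[[1L]]
    for (s in seq_len((length(pop) - 1L) %% 3L + 1L))
      v <- mutate_chromosome(v, n_levels)
    pop[[length(pop) + 1L]] <- v
  }
  pop
}

#' Training order of chart blocks
#'
#' Blocks are trained in descending order of the number of cohort records
#' they cover; blocks covering no records are excluded (their initialized
#' chromosome is kept for deployment). Ties break lexicographically by key,
#' making the order deterministic.
#'
#' @param cohort Categorized cohort.
#' @param spec A `chart_spec`.
#' @return Character vector of stratum keys, largest block first.
#' @export
order_blocks <- function(cohort, spec) {
  keys <- stratum_key(cohort, spec)
  all_keys <- block_keys(spec)
  n <- tabulate(match(keys, all_keys), nbins = length(all_keys))
  keep <- n > 0L
  k2 <- all_keys[keep]; n2 <- n[keep]
  k2[order(-n2, k2, method = "radix")]
}

#' Train a risk chart blockwise
#'
#' Full training loop: initialize ([init_chart()]), then run rounds in
#' which every non-empty block, visited largest-data-first
#' ([order_blocks()]), is replaced by the chromosome returned by
#' [evolve_block()]. Rounds stop when the round-over-round gain in training
#' AUROC falls below `tol` or `max_rounds` is reached. The ratio-based
#' post-hoc modifier ([posthoc_adjust()]) is applied once at the end unless
#' disabled. With the incumbent included in every population (the default),
#' the recorded AUROC trace is non-decreasing.
#'
#' @param cohort Categorized cohort with both outcome classes.
#' @param spec A `chart_spec`.
#' @param params A [ga_params()]; `params$seed`, when set, seeds the whole
#'   run, making it bit-reproducible.
#' @param max_rounds Maximum full passes over the blocks.
#' @param tol Minimum round-over-round AUROC gain to continue.
#' @param posthoc Apply the post-hoc event-ratio modifier after the rounds.
#' @param init_strategy,external Passed to [init_chart()].
#' @return An object of class `chart_fit`: list with `chart`, `history`
#'   (data frame: round, block_key, block_n, auroc after each update),
#'   `init_auroc`, `final_auroc` (training AUROC of the returned chart),
#'   `rounds_completed` and `params`.
#' @export
train_chart <- function(cohort, spec, params = ga_params(), max_rounds = 2L,
                        tol = 0.001, posthoc = TRUE,
                        init_strategy = "empirical", external = NULL) {
  if (length(unique(cohort$outcome)) < 2L)
    stop("training requires both outcome classes")
  if (!is.null(params$seed)) set.seed(params$seed)
  init <- init_chart(cohort, spec, strategy = init_strategy,
                     external = external,
                     population_size = params$population_size)
  chart <- init$chart
  counts <- cohort_cell_counts(cohort, spec)
  order <- order_blocks(cohort, spec)
  auroc_now <- chart_auroc(chart, cohort)
  init_auroc <- auroc_now
  hist <- list()
  rounds_done <- 0L
  for (round in seq_len(max_rounds)) {
    round_start <- auroc_now
    first_round <- round == 1L
    for (key in order) {
      ctx <- fitness_context(chart, cohort, key, counts = counts)
      pop0 <- if (first_round) init$populations[[key]]
              else make_block_population(chart$blocks[[key]],
                                         params$population_size,
                                         spec$n_levels)
      if (!isTRUE(params$include_incumbent))
        pop0 <- pop0[-1L]
      res <- evolve_block(ctx, params, pop0)
      chart$blocks[[key]] <- res$best
      auroc_now <- res$fitness
      hist[[length(hist) + 1L]] <-
        data.frame(round = round, block_key = key, block_n = ctx$block_n,
                   auroc = auroc_now, stringsAsFactors = FALSE)
    }
    rounds_done <- round
    if (auroc_now - round_start < tol) break
  }
  if (isTRUE(posthoc)) chart <- posthoc_adjust(chart, cohort)
  structure(list(chart = chart,
                 history = do.call(rbind, hist),
                 init_auroc = init_auroc,
                 final_auroc = chart_auroc(chart, cohort),
                 rounds_completed = rounds_done,
                 params = params),
            class = "chart_fit")
}

#' @export
print.chart_fit <- function(x, ...) {
  cat("Trained risk chart: ", x$rounds_completed, " round(s), training AUROC ",
      sprintf("%.4f", x$init_auroc), " -> ", sprintf("%.4f", x$final_auroc),
      "\n", sep = "")
  invisible(x)
}

#' Post-hoc event-ratio modifier
#'
#' For every cell covering at least one training record, the gene is
#' increased by one level if the cell's proportion of positive outcomes
#' exceeds 50% and decreased by one level otherwise, clamped to
#' `[1, n_levels]`. An adjustment is applied only if the block remains
#' valid; blocked or empty cells are untouched, so re-running the modifier
#' on a blocked cell is a no-op rather than an error.
#'
#' @param chart A valid `risk_chart`.
#' @param cohort Categorized training cohort.
#' @return Adjusted, valid `risk_chart`.
#' @export
posthoc_adjust <- function(chart, cohort) {
  counts <- cohort_cell_counts(cohort, chart$spec)
  L <- chart$spec$n_levels
  for (b in seq_along(counts$keys)) {
    key <- counts$keys[b]
    g <- chart$blocks[[key]]
    p <- matrix(counts$pos[, , b], counts$R, counts$C)
    n <- p + matrix(counts$neg[, , b], counts$R, counts$C)
    for (i in seq_len(counts$R)) for (j in seq_len(counts$C)) {
      if (n[i, j] == 0) next
      ratio <- p[i, j] / n[i, j]
      delta <- if (ratio > 0.5) 1L else -1L
      v <- g[i, j] + delta
      if (v < 1L || v > L) next
      cand <- g
      cand[i, j] <- v
      if (is_valid_chromosome(cand, L)) g <- cand
    }
    chart$blocks[[key]] <- g
  }
  chart
}

#' Stratified fold assignment
#'
#' Assigns records to `k` folds so that fold sizes differ by at most one
#' and each class's counts across folds differ by at most one (the class
#' label distribution is similar across folds). Deterministic given `seed`.
#'
#' @param labels Binary (or categorical) outcome vector.
#' @param k Number of folds (>= 2); every class must have at least `k`
#'   members.
#' @param seed Optional RNG seed.
#' @return Integer fold ids in `1..k`, one per record.
#' @export
stratified_folds <- function(labels, k = 10L, seed = NULL) {
  k <- as.integer(k)
  stopifnot(k >= 2L)
  n <- length(labels)
  classes <- sort(unique(labels))
  for (cl in classes)
    if (sum(labels == cl) < k)
      stop("class '", cl, "' has fewer than k = ", k, " members")
  if (!is.null(seed)) set.seed(seed)
  fold <- integer(n)
  sizes <- integer(k)
  for (cl in classes) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    ord <- order(sizes, seq_len(k))  # fill smallest folds first, stable
    fold[idx] <- rep(ord, length.out = length(idx))
    sizes <- sizes + tabulate(fold[idx], nbins = k)
  }
  fold
}

#' Stratified k-fold cross validation
#'
#' Trains a chart on each set of k-1 folds and evaluates AUROC on the
#' held-out fold; the mean over folds is the reported cross-validated
#' AUROC. Initialization (and the post-hoc modifier, when enabled) uses the
#' training folds only. Per-fold training seeds are derived from `seed`, so
#' a run is fully reproducible.
#'
#' @param cohort Categorized cohort.
#' @param spec A `chart_spec`.
#' @param params A [ga_params()].
#' @param k Number of folds.
#' @param seed RNG seed for fold assignment and per-fold training.
#' @param ... Passed to [train_chart()] (e.g. `max_rounds`, `posthoc`).
#' @return An object of class `cv_result`: list with `fold_auroc` (length
#'   `k`), `mean_auroc`, `k` and `seed`.
#' @export
cross_validate <- function(cohort, spec, params = ga_params(), k = 10L,
                           seed = NULL, ...) {
  fold <- stratified_folds(cohort$outcome, k = k, seed = seed)
  aucs <- numeric(k)
  for (i in seq_len(k)) {
    tr <- cohort[fold != i, , drop = FALSE]
    te <- cohort[fold == i, , drop = FALSE]
    p <- params
    p$seed <- if (!is.null(seed)) seed + i else NULL
    fit <- train_chart(tr, spec, params = p, ...)
    sc <- lookup_risk(fit$chart, te)$level
    aucs[i] <- fitness_auroc(sc, te$outcome)
  }
  structure(list(fold_auroc = aucs, mean_auroc = mean(aucs), k = k,
                 seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(x$k, "-fold CV AUROC: mean ", sprintf("%.4f", x$mean_auroc),
      " (folds ", paste(sprintf("%.3f", x$fold_auroc), collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}
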