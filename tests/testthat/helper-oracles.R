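# Independent oracles and tiny fixtures, built in code.

# O(n^2) pairwise AUROC: concordant + half-tied pairs over pos x neg.
auroc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, ">") + 0.5 * outer(pos, neg, "==")
  sum(cmp) / (length(pos) * length(neg))
}

# Exhaustively enumerate all valid R x C chromosomes with levels 1..L.
enumerate_valid_matrices <- function(R, C, L) {
  cells <- R * C
  grid <- do.call(expand.grid, rep(list(seq_len(L)), cells))
  out <- list()
  for (r in seq_len(nrow(grid))) {
    m <- matrix(as.integer(unlist(grid[r, ])), R, C)
    if (is_valid_chromosome(m, L)) out[[length(out) + 1L]] <- m
  }
  out
}

# Brute-force minimal-L1 repair: among all valid matrices that keep the
# changed cell at its new value, the one with minimal L1 distance to the
# (invalid) input. The constrained minimizer is unique.
repair_oracle <- function(changed, cell_idx, L, valid_pool = NULL) {
  if (is.null(valid_pool))
    valid_pool <- enumerate_valid_matrices(nrow(changed), ncol(changed), L)
  best <- NULL; best_d <- Inf
  for (m in valid_pool) {
    if (m[cell_idx] != changed[cell_idx]) next
    d <- sum(abs(m - changed))
    if (d < best_d) { best <- m; best_d <- d }
  }
  best
}

# Minimal single-block 2D spec (no stratifiers): one 4x5 block, 20 cells.
tiny_spec_2d <- function() {
  chart_spec(stratifiers = list(), row_axis = gachart:::bp_feature(),
             column_axis = gachart:::chol_feature())
}

tiny_spec_1d <- function() {
  chart_spec(stratifiers = list(), row_axis = gachart:::bp_feature())
}

# Two-block 1D spec stratified by sex only.
sex_spec_1d <- function() {
  chart_spec(stratifiers = list(feature_spec("sex", "stratifier", c("F", "M"))),
             row_axis = gachart:::bp_feature())
}

# A categorized cohort built directly from category draws (no simulator),
# with outcome probability increasing in BP when slope > 0.
manual_cohort <- function(n, spec, slope = 0.6, base = -2.2, seed = 1) {
  set.seed(seed)
  df <- data.frame(row.names = seq_len(n))
  for (s in spec$stratifiers)
    df[[s$name]] <- sample(s$categories, n, replace = TRUE)
  df$bp_cat <- sample.int(4L, n, replace = TRUE)
  eta <- base + slope * (df$bp_cat - 1)
  if (!is.null(spec$column_axis)) {
    df$chol_cat <- sample.int(5L, n, replace = TRUE)
    eta <- eta + 0.3 * (df$chol_cat - 1)
  }
  df$outcome <- stats::rbinom(n, 1L, stats::plogis(eta))
  attr(df, "chart_spec") <- spec
  df
}
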