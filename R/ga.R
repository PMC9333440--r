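#' Genetic-algorithm parameters
#'
#' Controls the per-block evolutionary loop. The defaults are desk-scale
#' choices; the search itself (operators, constraint handling, elitism) does
#' not depend on them.
#'
#' @param population_size Number of chromosomes per generation (>= 2).
#' @param generations Maximum generations per block visit.
#' @param stall_limit Stop a block's run after this many generations without
#'   improvement of the best-ever fitness.
#' @param mutation_prob Per-child probability of applying the one-gene
#'   mutation; the default mutates every child.
#' @param include_incumbent Keep the block's current chromosome in the
#'   initial population, guaranteeing the result never scores below it.
#' @param weight_offset If `TRUE`, roulette weights use fitness minus 0.5
#'   (floored at 1e-6) instead of raw AUROC; raw fitness is the default.
#' @param seed Optional RNG seed recorded with training runs.
#' @return A list of class `ga_params`.
#' @export
ga_params <- function(population_size = 20L, generations = 50L,
                      stall_limit = 10L, mutation_prob = 1.0,
                      include_incumbent = TRUE, weight_offset = FALSE,
                      seed = NULL) {
  stopifnot(population_size >= 2L, generations >= 1L, stall_limit >= 1L,
            mutation_prob >= 0, mutation_prob <= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 stall_limit = as.integer(stall_limit),
                 mutation_prob = mutation_prob,
                 include_incumbent = isTRUE(include_incumbent),
                 weight_offset = isTRUE(weight_offset),
                 seed = seed),
            class = "ga_params")
}

#' Mann-Whitney AUROC
#'
#' Area under the ROC curve computed as the Mann-Whitney concordance:
#' (concordant pairs + half the tied pairs) / (positives x negatives).
#' Computed from midranks in O(n log n); agrees with the O(n^2) pairwise
#' definition exactly.
#'
#' @param scores Numeric scores, higher = more at risk.
#' @param labels Binary outcomes (0/1) of the same length.
#' @return AUROC in `[0, 1]`.
#' @examples
#' fitness_auroc(c(1, 2, 2, 3), c(0, 1, 0, 1))  # 0.875
#' @export
fitness_auroc <- function(scores, labels) {
  if (length(scores) != length(labels))
    stop("scores and labels must have the same length")
  labels <- as.integer(labels)
  if (any(is.na(scores)) || any(!(labels %in% c(0L, 1L))))
    stop("scores must be non-missing and labels binary 0/1")
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0L || N == 0L)
    stop("AUROC undefined: labels contain a single class")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - P * (P + 1) / 2) / (P * N)
}

#' Fitness context for one block
#'
#' Packages the sufficient statistics for evaluating candidate chromosomes
#' of one block: the cohort's per-cell positive/negative counts inside the
#' block, and the level tallies contributed by every other block under the
#' current working chart. Because chart scores are constant within a cell,
#' the global AUROC of "working chart with candidate substituted at this
#' block" is computable from these tallies alone, in O(n_levels) per
#' candidate.
#'
#' @param chart Current working `risk_chart`.
#' @param cohort Categorized training cohort.
#' @param block_key Stratum key of the block under optimization.
#' @param counts Optional precomputed [cohort_cell_counts()] result.
#' @return A list of class `fitness_context`.
#' @export
fitness_context <- function(chart, cohort, block_key, counts = NULL) {
  if (!block_key %in% names(chart$blocks))
    stop("block key '", block_key, "' not present in chart")
  if (is.null(counts)) counts <- cohort_cell_counts(cohort, chart$spec)
  b <- match(block_key, counts$keys)
  tot <- chart_level_tallies(chart, counts)
  cell_pos <- matrix(counts$pos[, , b], counts$R, counts$C)
  cell_neg <- matrix(counts$neg[, , b], counts$R, counts$C)
  L <- chart$spec$n_levels
  g <- chart$blocks[[block_key]]
  own_pos <- numeric(L); own_neg <- numeric(L)
  for (l in seq_len(L)) {
    sel <- g == l
    if (any(sel)) {
      own_pos[l] <- sum(cell_pos[sel])
      own_neg[l] <- sum(cell_neg[sel])
    }
  }
  structure(list(block_key = block_key, n_levels = L,
                 cell_pos = cell_pos, cell_neg = cell_neg,
                 other_pos = tot$pos - own_pos,
                 other_neg = tot$neg - own_neg,
                 block_n = sum(cell_pos) + sum(cell_neg)),
            class = "fitness_context")
}

#' Global AUROC of a candidate chromosome
#'
#' Fitness of a candidate for the context's block: the AUROC over the full
#' training cohort when each person is scored by the working chart with the
#' candidate substituted at the block. A candidate identical to the
#' incumbent therefore scores exactly the current chart AUROC, and any
#' candidate scores the same when the block covers no records.
#'
#' @param candidate A valid chromosome with the block's dimensions.
#' @param ctx A [fitness_context()].
#' @return AUROC in `[0, 1]`.
#' @export
chromosome_fitness <- function(candidate, ctx) {
  L <- ctx$n_levels
  pos <- ctx$other_pos; neg <- ctx$other_neg
  for (l in seq_len(L)) {
    sel <- candidate == l
    if (any(sel)) {
      pos[l] <- pos[l] + sum(ctx$cell_pos[sel])
      neg[l] <- neg[l] + sum(ctx$cell_neg[sel])
    }
  }
  auroc_from_tallies(pos, neg)
}

#' Roulette-wheel selection without replacement
#'
#' Draws `k` distinct indices; at each draw the probability of an index is
#' proportional to its weight among the remaining indices. All-zero (or
#' all-equal-after-offset) weights fall back to uniform sampling.
#'
#' @param weights Non-negative weights.
#' @param k Number of draws (`k <= length(weights)`).
#' @return Integer vector of `k` selected indices.
#' @export
roulette_select <- function(weights, k = 1L) {
  n <- length(weights)
  stopifnot(k >= 1L, k <= n)
  if (any(weights < 0)) stop("weights must be non-negative")
  if (sum(weights) <= 0) weights <- rep(1, n)
  remaining <- seq_len(n)
  w <- weights
  out <- integer(k)
  for (i in seq_len(k)) {
    tw <- sum(w)
    p <- if (tw > 0) w / tw else rep(1 / length(w), length(w))
    j <- remaining[sample.int(length(remaining), 1L, prob = p)]
    out[i] <- j
    keep <- remaining != j
    remaining <- remaining[keep]
    w <- w[keep]
  }
  out
}

#' Enumerate splice-crossover offspring
#'
#' Linearizes both parents in row-major order (blood pressure major) and,
#' for every cut point k = 1..L-1, splices the first k genes of one parent
#' with the remaining genes of the other, in both orders — at most 2(L-1)
#' candidates. Candidates violating the monotonicity constraint are
#' discarded and duplicates removed, yielding the offspring pool.
#'
#' @param a,b Valid parent chromosomes of identical dimensions.
#' @param n_levels Number of ordinal levels.
#' @return List of distinct valid chromosomes (possibly empty if parents
#'   share no valid recombination, which cannot occur for identical
#'   parents).
#' @export
enumerate_splice_children <- function(a, b, n_levels = 6L) {
  a <- as_chromosome(a); b <- as_chromosome(b)
  if (!identical(dim(a), dim(b))) stop("parents must share dimensions")
  R <- nrow(a); C <- ncol(a); L <- R * C
  va <- as.vector(t(a)); vb <- as.vector(t(b))
  pool <- list(); seen <- character(0)
  for (k in seq_len(L - 1L)) {
    for (child in list(c(va[seq_len(k)], vb[(k + 1L):L]),
                       c(vb[seq_len(k)], va[(k + 1L):L]))) {
      m <- matrix(child, R, C, byrow = TRUE)
      if (is_valid_chromosome(m, n_levels)) {
        key <- paste(child, collapse = ",")
        if (!key %in% seen) {
          seen <- c(seen, key)
          pool[[length(pool) + 1L]] <- as_chromosome(m)
        }
      }
    }
  }
  pool
}

#' Crossover: two children from two parents
#'
#' Builds the splice-offspring pool and selects two children by roulette
#' wheel weighted by [chromosome_fitness()] in the current chart context.
#' A pool of exactly two is returned whole; a pool smaller than two is
#' padded with copies of the fitter parent.
#'
#' @param a,b Valid parent chromosomes.
#' @param ctx A [fitness_context()].
#' @param params A [ga_params()] (controls the roulette weight offset).
#' @return List of two valid chromosomes.
#' @export
crossover <- function(a, b, ctx, params = ga_params()) {
  pool <- enumerate_splice_children(a, b, ctx$n_levels)
  if (length(pool) < 2L) {
    fitter <- if (chromosome_fitness(a, ctx) >= chromosome_fitness(b, ctx))
      a else b
    while (length(pool) < 2L) pool[[length(pool) + 1L]] <- fitter
    return(pool[1:2])
  }
  if (length(pool) == 2L) return(pool)
  w <- vapply(pool, chromosome_fitness, numeric(1), ctx = ctx)
  pool[roulette_select(roulette_weights(w, params), 2L)]
}

roulette_weights <- function(fitness, params) {
  if (isTRUE(params$weight_offset)) pmax(fitness - 0.5, 1e-6) else fitness
}

#' Mutate one gene by one unit
#'
#' Picks a gene uniformly at random and moves it up or down one level with
#' equal probability. Moves that would leave `[1, n_levels]` are clamped
#' (the chromosome is returned unchanged); otherwise the change is applied
#' and validity restored with [repair_chromosome()].
#'
#' @param genes A valid chromosome.
#' @param n_levels Number of ordinal levels.
#' @return A valid chromosome.
#' @export
mutate_chromosome <- function(genes, n_levels = 6L) {
  m <- as_chromosome(genes)
  i <- sample.int(length(m), 1L)
  d <- if (sample.int(2L, 1L) == 1L) 1L else -1L
  v <- m[i] + d
  if (v < 1L || v > n_levels) return(m)
  m[i] <- v
  repair_chromosome(m, d)
}

#' Evolve one chart block
#'
#' Generational loop for a single block: parents are paired by roulette
#' wheel on fitness, each pair produces two children by [crossover()], each
#' child is mutated with probability `mutation_prob`, and the next
#' generation keeps the best-ever chromosome (elitism) plus a random fill
#' from the current parents and children. Runs for at most
#' `params$generations` generations, stopping early after
#' `params$stall_limit` generations without improvement.
#'
#' @param ctx A [fitness_context()] for the block.
#' @param params A [ga_params()].
#' @param init_population Non-empty list of valid chromosomes; the
#'   incumbent block is prepended when `params$include_incumbent` and
#'   guarantees the result never scores below the current chart.
#' @return List with `best` (chromosome), `fitness` (its global AUROC) and
#'   `trace` (best-ever fitness by generation, non-decreasing).
#' @export
evolve_block <- function(ctx, params = ga_params(), init_population) {
  if (length(init_population) == 0L) stop("initial population is empty")
  pop <- lapply(init_population, as_chromosome)
  size <- max(params$population_size, 2L)
  fit <- vapply(pop, chromosome_fitness, numeric(1), ctx = ctx)
  bi <- which.max(fit)
  best <- pop[[bi]]; best_fit <- fit[bi]
  trace <- best_fit
  stall <- 0L
  for (gen in seq_len(params$generations)) {
    children <- list()
    n_pairs <- max(1L, size %/% 2L)
    w <- roulette_weights(fit, params)
    for (p in seq_len(n_pairs)) {
      idx <- if (length(pop) >= 2L) roulette_select(w, 2L) else c(1L, 1L)
      kids <- crossover(pop[[idx[1L]]], pop[[idx[2L]]], ctx, params)
      for (kid in kids) {
        if (stats::runif(1) < params$mutation_prob)
          kid <- mutate_chromosome(kid, ctx$n_levels)
        children[[length(children) + 1L]] <- kid
      }
    }
    child_fit <- vapply(children, chromosome_fitness, numeric(1), ctx = ctx)
    all_pop <- c(pop, children)
    all_fit <- c(fit, child_fit)
    gi <- which.max(all_fit)
    if (all_fit[gi] > best_fit) {
      best <- all_pop[[gi]]; best_fit <- all_fit[gi]
      stall <- 0L
    } else {
      stall <- stall + 1L
    }
    trace <- c(trace, best_fit)
    # elitist replacement: best-ever plus a seeded random fill
    n_fill <- min(size - 1L, length(all_pop))
    sel <- sample.int(length(all_pop), n_fill)
    pop <- c(list(best), all_pop[sel])
    fit <- c(best_fit, all_fit[sel])
    if (stall >= params$stall_limit) break
  }
  list(best = best, fitness = best_fit, trace = trace)
}
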