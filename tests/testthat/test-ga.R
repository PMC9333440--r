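# Shared context: one 4x5 block over a cohort whose risk rises with BP and
# cholesterol, so fitness differences between candidates are real.
make_ctx <- function(n = 400, seed = 3, spec = tiny_spec_2d()) {
  co <- manual_cohort(n, spec, seed = seed)
  chart <- init_chart(co, spec, population_size = 2)$chart
  fitness_context(chart, co, block_keys(spec)[1],
                  counts = gachart:::cohort_cell_counts(co, spec))
}

test_that("AUROC matches its pairwise definition and known values", {
  expect_equal(fitness_auroc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1.0)
  expect_equal(fitness_auroc(rep(2, 6), c(0, 1, 0, 1, 1, 0)), 0.5)
  expect_equal(fitness_auroc(c(1, 2, 2, 3), c(0, 1, 0, 1)), 0.875)
  expect_error(fitness_auroc(1:3, c(1, 1, 1)), "single class")
  set.seed(21)
  for (rep in 1:25) {
    n <- sample(5:60, 1)
    sc <- sample(1:8, n, replace = TRUE)       # heavy ties
    lb <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(fitness_auroc(sc, lb), auroc_bruteforce(sc, lb),
                 tolerance = 1e-12)
  }
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(31)
  for (rep in 1:10) {
    sc <- stats::rnorm(80)
    lb <- stats::rbinom(80, 1, 0.4)
    if (length(unique(lb)) < 2) next
    ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE,
                                          direction = "<")))
    expect_equal(fitness_auroc(sc, lb), ref, tolerance = 1e-10)
  }
})

test_that("block fitness equals record-level AUROC with substitution", {
  spec <- sex_spec_1d()
  co <- manual_cohort(600, spec, seed = 5)
  chart <- init_chart(co, spec, population_size = 2)$chart
  counts <- gachart:::cohort_cell_counts(co, spec)
  for (key in c("F", "M")) {
    ctx <- fitness_context(chart, co, key, counts = counts)
    # identity: incumbent's fitness is the current chart AUROC
    expect_equal(chromosome_fitness(chart$blocks[[key]], ctx),
                 chart_auroc(chart, co), tolerance = 1e-12)
    # substitution: any candidate's fitness equals scoring the modified
    # chart record by record
    set.seed(7)
    for (rep in 1:5) {
      cand <- random_chromosome(4, 1)
      mod <- chart
      mod$blocks[[key]] <- cand
      expect_equal(chromosome_fitness(cand, ctx),
                   fitness_auroc(lookup_risk(mod, co)$level, co$outcome),
                   tolerance = 1e-12)
    }
  }
})

test_that("fitness is invariant to candidates of an uncovered block", {
  spec <- sex_spec_1d()
  co <- manual_cohort(300, spec, seed = 9)
  co <- co[co$sex == "F", , drop = FALSE]  # block M has no records
  chart <- risk_chart(spec)
  chart$blocks[["F"]] <- matrix(c(1L, 2L, 3L, 4L), ncol = 1)
  ctx <- fitness_context(chart, co, "M")
  base <- chart_auroc(chart, co)
  set.seed(13)
  for (rep in 1:5)
    expect_equal(chromosome_fitness(random_chromosome(4, 1), ctx), base)
})

test_that("a risk-ordered candidate outscores a flat one on planted data", {
  ctx <- make_ctx(n = 2000, seed = 17)
  flat <- matrix(3L, 4, 5)
  ordered <- repair_chromosome(outer(1:4, 0:4, function(i, j)
    pmin(6L, i + as.integer(j > 2))), +1)
  expect_gt(chromosome_fitness(ordered, ctx), chromosome_fitness(flat, ctx))
})

test_that("roulette selection is fitness-proportional without replacement", {
  expect_identical(roulette_select(5, 1), 1L)
  expect_error(roulette_select(c(-1, 2), 1), "non-negative")
  set.seed(41)
  draws <- replicate(10000, roulette_select(c(1, 1), 1))
  p <- mean(draws == 1)
  expect_lt(abs(p - 0.5), 3 * sqrt(0.25 / 10000))
  w <- c(0.5, 0.25, 0.25)
  draws <- replicate(10000, roulette_select(w, 1))
  for (i in 1:3)
    expect_lt(abs(mean(draws == i) - w[i]),
              3 * sqrt(w[i] * (1 - w[i]) / 10000))
  # all-zero weights fall back to uniform, and k items are distinct
  set.seed(42)
  expect_setequal(roulette_select(c(0, 0, 0), 3), 1:3)
})

test_that("splice enumeration yields the valid deduplicated pool", {
  a <- matrix(c(1L, 1L, 2L, 2L), ncol = 1)
  b <- matrix(c(1L, 2L, 2L, 3L), ncol = 1)
  pool <- enumerate_splice_children(a, b)
  keys <- sort(vapply(pool, function(m) paste(m, collapse = ","), ""))
  expect_identical(keys, sort(c("1,2,2,3", "1,1,2,3", "1,1,2,2", "1,2,2,2")))
  # identical parents collapse to a single child
  pool <- enumerate_splice_children(a, a)
  expect_length(pool, 1L)
  expect_identical(pool[[1]], a)
  # bound: at most 2(L-1) distinct children, all valid
  set.seed(51)
  for (rep in 1:20) {
    pa <- random_chromosome(4, 5)
    pb <- random_chromosome(4, 5)
    pool <- enumerate_splice_children(pa, pb)
    expect_lte(length(pool), 2 * (20 - 1))
    for (m in pool) expect_true(is_valid_chromosome(m, 6))
  }
  expect_error(enumerate_splice_children(a, matrix(1L, 2, 1)), "dimensions")
})

test_that("crossover returns two valid children from the pool", {
  ctx <- make_ctx()
  a <- matrix(c(1L, 1L, 2L, 2L, 2L), 1) |> rbind(c(2L, 2L, 2L, 3L, 3L),
                                                 c(2L, 3L, 3L, 3L, 4L),
                                                 c(3L, 3L, 4L, 4L, 5L))
  b <- random_chromosome(4, 5)
  set.seed(61)
  kids <- crossover(a, b, ctx)
  expect_length(kids, 2L)
  for (k in kids) expect_true(is_valid_chromosome(k, 6))
  # identical parents: both children equal the parent
  kids <- crossover(a, a, ctx)
  expect_identical(kids[[1]], a)
  expect_identical(kids[[2]], a)
})

test_that("mutation clamps at the boundary and always emits valid output", {
  top <- matrix(6L, 4, 5)
  one <- matrix(1L, 4, 1)
  set.seed(71)
  seen_same_top <- 0
  for (rep in 1:20) {
    m <- mutate_chromosome(top, 6)
    if (identical(m, top)) seen_same_top <- seen_same_top + 1
    expect_true(is_valid_chromosome(m, 6))
    expect_true(is_valid_chromosome(mutate_chromosome(one, 6), 6))
  }
  expect_gt(seen_same_top, 0)  # upward moves at the ceiling clamp
  # frozen repair example reached through mutation
  set.seed(123)
  base <- matrix(c(1L, 2L, 2L, 3L), ncol = 1)
  for (rep in 1:200) {
    out <- mutate_chromosome(base, 6)
    expect_true(is_valid_chromosome(out, 6))
  }
})

test_that("evolve_block improves monotonically and respects the incumbent", {
  spec <- tiny_spec_2d()
  co <- manual_cohort(2000, spec, seed = 81)
  init <- init_chart(co, spec, population_size = 10)
  ctx <- fitness_context(init$chart, co, "(all)")
  set.seed(82)
  res <- evolve_block(ctx, ga_params(population_size = 10, generations = 15),
                      init$populations[[1]])
  expect_false(is.unsorted(res$trace))
  expect_gte(res$fitness,
             chromosome_fitness(init$chart$blocks[[1]], ctx))
  expect_true(is_valid_chromosome(res$best, 6))
  expect_error(evolve_block(ctx, ga_params(), list()), "empty")
})

test_that("evolution over an uncovered block returns the incumbent", {
  spec <- sex_spec_1d()
  co <- manual_cohort(300, spec, seed = 91)
  co <- co[co$sex == "F", , drop = FALSE]
  chart <- risk_chart(spec)
  chart$blocks[["F"]] <- matrix(c(1L, 2L, 2L, 3L), ncol = 1)
  incumbent <- matrix(c(1L, 1L, 2L, 2L), ncol = 1)
  chart$blocks[["M"]] <- incumbent
  ctx <- fitness_context(chart, co, "M")
  set.seed(92)
  pop <- gachart:::make_block_population(incumbent, 8, 6)
  res <- evolve_block(ctx, ga_params(population_size = 8, generations = 5),
                      pop)
  expect_identical(res$best, incumbent)
})

test_that("identical seeds give bit-identical evolution", {
  spec <- tiny_spec_2d()
  co <- manual_cohort(800, spec, seed = 101)
  init <- init_chart(co, spec, population_size = 8)
  ctx <- fitness_context(init$chart, co, "(all)")
  run <- function() {
    set.seed(103)
    evolve_block(ctx, ga_params(population_size = 8, generations = 10),
                 init$populations[[1]])
  }
  r1 <- run(); r2 <- run()
  expect_identical(r1$best, r2$best)
  expect_identical(r1$trace, r2$trace)
})
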