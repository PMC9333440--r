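test_that("continuous binning follows left-closed right-open cut points", {
  bp <- c(120, 140, 160)
  expect_identical(bin_continuous(119, bp), 1L)
  expect_identical(bin_continuous(120, bp), 2L)
  expect_identical(bin_continuous(159.9, bp), 3L)
  expect_identical(bin_continuous(160, bp), 4L)
  chol <- c(150, 200, 250, 300)
  expect_identical(bin_continuous(300, chol), 5L)
  expect_identical(bin_continuous(149.9, chol), 1L)
  expect_error(bin_continuous(NA_real_, bp, field = "bp"), "bp")
  expect_error(bin_continuous(1, c(2, 2)), "strictly increasing")
  # monotonicity property
  set.seed(4)
  for (rep in 1:20) {
    e <- sort(stats::runif(sample(1:6, 1), 50, 350))
    if (any(diff(e) == 0)) next
    v <- sort(stats::runif(50, 0, 400))
    expect_false(is.unsorted(bin_continuous(v, e)))
  }
})

test_that("derived flags use sex-specific WHR and compound diabetes rules", {
  df <- data.frame(sex = c("F", "M", "F", "M"),
                   whr = c(0.80, 0.94, 0.79, 0.95))
  out <- derive_flags(df)
  expect_identical(out$whr, c("high", "low", "low", "high"))
  dia <- derive_flags(data.frame(
    sex = rep("M", 4),
    fbs = c(126, 125, 100, 110),
    glucose_2h = c(100, 100, 200, 150),
    diabetes_treatment = c(FALSE, FALSE, FALSE, TRUE)))
  expect_identical(dia$diabetes, c("yes", "no", "yes", "yes"))
  expect_error(derive_flags(data.frame(whr = 0.9)), "sex")
})

test_that("chromosome validity requires range and bi-axial monotonicity", {
  expect_true(is_valid_chromosome(matrix(1L, 2, 2), 6))
  expect_true(is_valid_chromosome(rbind(c(1, 2, 3, 4, 5),
                                        c(2, 3, 4, 5, 5)), 6))
  expect_false(is_valid_chromosome(rbind(c(2, 1, 1, 1, 1),
                                         c(2, 2, 2, 2, 2)), 6))
  expect_false(is_valid_chromosome(matrix(c(0L, 1L), 1, 2), 6))
  expect_false(is_valid_chromosome(matrix(c(1L, 7L), 1, 2), 6))
  expect_false(is_valid_chromosome(matrix(c(2L, 1L), 2, 1), 6))  # column drop
})

test_that("repair propagates a one-gene change minimally", {
  # +1 at position 2 of [1,2,2,3] -> [1,3,3,3]
  m <- matrix(c(1L, 3L, 2L, 3L), ncol = 1)
  expect_identical(as.vector(repair_chromosome(m, +1)), c(1L, 3L, 3L, 3L))
  # -1 at position 3 of [1,2,2,3] -> [1,1,1,3]
  m <- matrix(c(1L, 2L, 1L, 3L), ncol = 1)
  expect_identical(as.vector(repair_chromosome(m, -1)), c(1L, 1L, 1L, 3L))
  # still-valid change: untouched elsewhere
  m <- matrix(c(1L, 2L, 2L, 4L), ncol = 1)
  expect_identical(as.vector(repair_chromosome(m, +1)), c(1L, 2L, 2L, 4L))
})

test_that("repair equals the brute-force minimal-change valid matrix", {
  set.seed(7)
  for (dims in list(c(4L, 1L), c(2L, 2L), c(3L, 3L))) {
    L <- 4L
    pool <- enumerate_valid_matrices(dims[1], dims[2], L)
    for (rep in 1:40) {
      m <- pool[[sample.int(length(pool), 1)]]
      i <- sample.int(length(m), 1)
      d <- sample(c(-1L, 1L), 1)
      v <- m[i] + d
      if (v < 1L || v > L) next
      changed <- m; changed[i] <- v
      got <- repair_chromosome(changed, d)
      want <- repair_oracle(changed, i, L, valid_pool = pool)
      expect_identical(got, want)
    }
  }
})

test_that("stratum keys join stratifier categories in spec order", {
  sp <- chart_spec(
    stratifiers = list(feature_spec("sex", "stratifier", c("F", "M")),
                       gachart:::age_feature()),
    row_axis = gachart:::bp_feature())
  co <- data.frame(sex = "M", age_group = "45-54", bp_cat = 1, outcome = 0)
  expect_identical(stratum_key(co, sp), "M|45-54")
  expect_identical(stratum_key(co, tiny_spec_2d()), "(all)")
  k <- block_keys(spec_cvd_2d())[1]
  expect_length(strsplit(k, "|", fixed = TRUE)[[1]], 6L)
  co$sex <- NA
  expect_error(stratum_key(co, sp), "sex")
})

test_that("cell and block counts match the standard chart geometries", {
  expect_identical(cell_count(spec_cvd_2d()), 3200L)
  expect_identical(block_count(spec_cvd_2d()), 160L)
  expect_identical(cell_count(spec_cvd_1d()), 80L)
  expect_identical(block_count(spec_cvd_1d()), 20L)
  expect_identical(cell_count(tiny_spec_2d()), 20L)
  expect_identical(block_count(tiny_spec_2d()), 1L)
  expect_identical(interpretability_score(spec_cvd_1d()), 80L)
  # metamorphic identity over assorted specs
  for (sp in list(spec_cvd_2d(), spec_cvd_1d(), tiny_spec_2d(),
                  tiny_spec_1d(), sex_spec_1d()))
    expect_identical(cell_count(sp),
                     block_count(sp) * length(sp$row_axis$categories) *
                       gachart:::n_chart_cols(sp))
})

test_that("risk lookup returns the block gene and its band label", {
  sp <- tiny_spec_2d()
  g <- matrix(1L, 4, 5); g[4, 5] <- 6L; g[4, 4] <- 3L
  ch <- risk_chart(sp, stats::setNames(list(repair_chromosome(g, -1)), "(all)"))
  co <- data.frame(bp_cat = c(1, 4), chol_cat = c(1, 5), outcome = c(0, 1))
  out <- lookup_risk(ch, co)
  expect_identical(out$level, c(1L, 6L))
  expect_identical(out$band, c("<=1%", ">=15%"))
  # validity implies monotone scores in cholesterol
  co2 <- data.frame(bp_cat = c(2, 2), chol_cat = c(1, 5), outcome = c(0, 0))
  lv <- lookup_risk(ch, co2)$level
  expect_gte(lv[2], lv[1])
  # incomplete chart is a structural error
  sx <- sex_spec_1d()
  ch2 <- risk_chart(sx)
  ch2$blocks[["M"]] <- NULL
  expect_error(lookup_risk(ch2, data.frame(sex = "M", bp_cat = 1)), "M")
})

test_that("charts reject invalid or incomplete block sets", {
  sp <- tiny_spec_2d()
  expect_error(risk_chart(sp, stats::setNames(list(matrix(7L, 4, 5)), "(all)")), "monotonicity")
  expect_error(risk_chart(sp, list(a = matrix(1L, 4, 5))), "stratum keys")
  expect_error(risk_chart(sp, stats::setNames(list(matrix(1L, 4, 4)), "(all)")), "dimensions")
  bad <- matrix(1L, 4, 5); bad[1, 1] <- 2L  # decreasing along the row
  expect_error(risk_chart(sp, stats::setNames(list(bad), "(all)")), "monotonicity")
})

test_that("cohort categorization validates inputs and names offenders", {
  sp <- spec_cvd_1d()
  raw <- data.frame(sex = c("F", "M"), age = c(40, 70),
                    bp = c(119, 165), whr = c(0.85, 0.9),
                    outcome = c(0, 1))
  co <- categorize_cohort(raw, sp)
  expect_identical(co$bp_cat, c(1L, 4L))
  expect_identical(co$age_group, c("35-44", "65-74"))
  expect_identical(co$whr, c("high", "low"))
  raw$outcome[2] <- 2
  expect_error(categorize_cohort(raw, sp), "row\\(s\\) 2")
  raw$outcome[2] <- 1
  raw$age[1] <- 30
  expect_error(categorize_cohort(raw, sp), "floor")
  # 2D chart without cholesterol is an error, not an imputation
  expect_error(categorize_cohort(
    data.frame(sex = "F", age = 50, bp = 130, whr = 0.7, fh_cvd = 0,
               diabetes = 0, smoker = 0, outcome = 0), spec_cvd_2d()),
    "cholesterol")
})

test_that("chart JSON round trips byte-exactly", {
  sp <- sex_spec_1d()
  set.seed(11)
  ch <- risk_chart(sp, list(F = random_chromosome(4, 1),
                            M = random_chromosome(4, 1)))
  f1 <- tempfile(fileext = ".json"); f2 <- tempfile(fileext = ".json")
  write_chart_json(ch, f1)
  back <- read_chart_json(f1)
  expect_identical(back$blocks, ch$blocks)
  write_chart_json(back, f2)
  expect_identical(readLines(f1), readLines(f2))
  # the full 2D spec round trips too (edges, thresholds, bands)
  f3 <- tempfile(fileext = ".json")
  write_spec_json(spec_cvd_2d(), f3)
  sp2 <- read_spec_json(f3)
  expect_identical(block_keys(sp2), block_keys(spec_cvd_2d()))
  expect_identical(sp2$row_axis$edges, c(120, 140, 160))
  expect_identical(sp2$band_labels, risk_bands())
})
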