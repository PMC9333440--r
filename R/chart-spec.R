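#' Risk band labels and midpoints
#'
#' Ten-year CVD risk is reported in six ordinal bands. Numeric output uses
#' the band midpoints; these are a presentation convention, not estimates
#' (the open-ended top band is summarized at 17.5%).
#'
#' @return `risk_bands()` returns the six band labels, lowest risk first;
#'   `band_midpoints()` returns the matching numeric midpoints (proportions).
#' @export
risk_bands <- function() {
  c("<=1%", "2%", "3-4%", "5-9%", "10-14%", ">=15%")
}

#' @rdname risk_bands
#' @export
band_midpoints <- function() {
  c(0.005, 0.02, 0.035, 0.07, 0.12, 0.175)
}

#' Declare a chart feature
#'
#' A feature either stratifies the chart into blocks (`role = "stratifier"`)
#' or indexes rows/columns within a block (`role = "row_axis"` /
#' `"column_axis"`). Continuous features carry strictly increasing cut
#' points; values are binned into left-closed, right-open intervals.
#'
#' @param name Column name of the feature in a cohort data frame.
#' @param role One of `"stratifier"`, `"row_axis"`, `"column_axis"`.
#' @param categories Ordered category labels, lowest first.
#' @param edges Optional strictly increasing numeric cut points; must satisfy
#'   `length(categories) == length(edges) + 1`.
#' @param sex_thresholds Optional named pair `c(F = ..., M = ...)` for
#'   sex-specific dichotomization (waist-to-hip ratio).
#' @return An object of class `feature_spec`.
#' @export
feature_spec <- function(name, role = c("stratifier", "row_axis", "column_axis"),
                         categories, edges = NULL, sex_thresholds = NULL) {
  role <- match.arg(role)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  categories <- as.character(categories)
  if (role == "stratifier" && length(categories) < 2L)
    stop("stratifier feature '", name, "' needs at least 2 categories")
  if (!is.null(edges)) {
    edges <- as.numeric(edges)
    if (any(!is.finite(edges)) || is.unsorted(edges, strictly = TRUE))
      stop("edges for '", name, "' must be finite and strictly increasing")
    if (length(categories) != length(edges) + 1L)
      stop("'", name, "': number of categories must equal number of edges + 1")
  }
  if (!is.null(sex_thresholds)) {
    sex_thresholds <- as.numeric(sex_thresholds[c("F", "M")])
    names(sex_thresholds) <- c("F", "M")
    if (any(!is.finite(sex_thresholds)))
      stop("'", name, "': sex_thresholds must be a named c(F=, M=) pair")
  }
  structure(list(name = name, role = role, categories = categories,
                 edges = edges, sex_thresholds = sex_thresholds),
            class = "feature_spec")
}

#' Declare the geometry of a risk chart
#'
#' A chart is the Cartesian product of stratifier categories (its blocks),
#' each block a rows-by-columns grid indexed by the row axis (blood
#' pressure, 4 categories) and, in the 2D representation, the column axis
#' (total cholesterol, 5 categories). The 1D representation omits the column
#' axis and each block is a single column.
#'
#' @param stratifiers List of `feature_spec` objects with role "stratifier";
#'   may be empty (single-block chart).
#' @param row_axis `feature_spec` with role "row_axis". Required.
#' @param column_axis Optional `feature_spec` with role "column_axis";
#'   present iff the chart is 2D.
#' @param n_levels Number of ordinal gene levels; must equal
#'   `length(band_labels)`.
#' @param band_labels Risk band labels, increasing risk.
#' @return An object of class `chart_spec`.
#' @seealso [spec_cvd_2d()], [spec_cvd_1d()] for the standard charts.
#' @export
chart_spec <- function(stratifiers = list(), row_axis, column_axis = NULL,
                       n_levels = 6L, band_labels = risk_bands()) {
  stopifnot(inherits(row_axis, "feature_spec"), row_axis$role == "row_axis")
  for (s in stratifiers)
    stopifnot(inherits(s, "feature_spec"), s$role == "stratifier")
  if (!is.null(column_axis))
    stopifnot(inherits(column_axis, "feature_spec"),
              column_axis$role == "column_axis")
  n_levels <- as.integer(n_levels)
  if (n_levels != length(band_labels))
    stop("n_levels must equal the number of band labels")
  structure(list(stratifiers = stratifiers, row_axis = row_axis,
                 column_axis = column_axis, n_levels = n_levels,
                 band_labels = as.character(band_labels)),
            class = "chart_spec")
}

#' @export
print.chart_spec <- function(x, ...) {
  dims <- paste0(length(x$row_axis$categories), "x", n_chart_cols(x))
  cat("Risk chart spec (", if (is.null(x$column_axis)) "1D" else "2D",
      "): ", length(x$stratifiers), " stratifier(s), ", dims,
      " blocks, ", block_count(x), " block(s), ", cell_count(x),
      " cells\n", sep = "")
  invisible(x)
}

n_chart_rows <- function(spec) length(spec$row_axis$categories)
n_chart_cols <- function(spec) {
  if (is.null(spec$column_axis)) 1L else length(spec$column_axis$categories)
}

#' Standard chart geometries
#'
#' `spec_cvd_2d()` builds the full eight-feature 2D chart: blocks stratified
#' by sex, age group, waist-to-hip ratio, family history of CVD, diabetes
#' and smoking (2 x 5 x 2 x 2 x 2 x 2 = 160 blocks), each a 4x5 grid of
#' systolic blood pressure by total cholesterol -- 3200 cells. `spec_cvd_1d()`
#' builds the lab-free four-feature 1D chart: sex, age group and
#' waist-to-hip ratio strata with 4x1 blood-pressure columns -- 80 cells.
#'
#' Categorization cut points: systolic BP <120, 120-139, 140-159, >=160
#' mm Hg; total cholesterol <150, 150-199, 200-249, 250-299, >=300 mg/dl
#' (National Cholesterol Education Program groups); age 35-44, 45-54,
#' 55-64, 65-74, >=75 years. Waist-to-hip ratio is dichotomized at >=0.80
#' (women) / >=0.95 (men). Intervals are left-closed, right-open.
#'
#' @param age_edges Age-group cut points (years); five groups by default.
#' @return A `chart_spec`.
#' @export
spec_cvd_2d <- function(age_edges = c(45, 55, 65, 75)) {
  chart_spec(
    stratifiers = c(list(
      feature_spec("sex", "stratifier", c("F", "M")),
      age_feature(age_edges),
      feature_spec("whr", "stratifier", c("low", "high"),
                   sex_thresholds = c(F = 0.80, M = 0.95)),
      feature_spec("fh_cvd", "stratifier", c("no", "yes")),
      feature_spec("diabetes", "stratifier", c("no", "yes")),
      feature_spec("smoker", "stratifier", c("no", "yes")))),
    row_axis = bp_feature(),
    column_axis = chol_feature())
}

#' @rdname spec_cvd_2d
#' @export
spec_cvd_1d <- function(age_edges = c(45, 55, 65, 75)) {
  chart_spec(
    stratifiers = list(
      feature_spec("sex", "stratifier", c("F", "M")),
      age_feature(age_edges),
      feature_spec("whr", "stratifier", c("low", "high"),
                   sex_thresholds = c(F = 0.80, M = 0.95))),
    row_axis = bp_feature())
}

bp_feature <- function() {
  feature_spec("bp", "row_axis", c("<120", "120-139", "140-159", "160+"),
               edges = c(120, 140, 160))
}

chol_feature <- function() {
  feature_spec("chol", "column_axis",
               c("<150", "150-199", "200-249", "250-299", "300+"),
               edges = c(150, 200, 250, 300))
}

age_feature <- function(age_edges = c(45, 55, 65, 75)) {
  labs <- c(paste0("35-", age_edges[1] - 1),
            paste0(age_edges[-length(age_edges)], "-", age_edges[-1] - 1),
            paste0(age_edges[length(age_edges)], "+"))
  feature_spec("age_group", "stratifier", labs, edges = age_edges)
}

#' Bin a continuous value into ordered categories
#'
#' Intervals are left-closed, right-open: values below the first edge map to
#' category 1, values at or above the last edge to the last category.
#' Monotone: `v1 <= v2` implies `bin_continuous(v1, e) <= bin_continuous(v2, e)`.
#'
#' @param value Numeric vector; must be finite.
#' @param edges Strictly increasing cut points.
#' @param field Field name used in error messages.
#' @return Integer category indices (1-based), length of `value`.
#' @examples
#' bin_continuous(c(119, 120, 159, 160), c(120, 140, 160))  # 1 2 3 4
#' @export
bin_continuous <- function(value, edges, field = "value") {
  if (any(!is.finite(value)))
    stop("non-finite ", field, " at record(s) ",
         paste(which(!is.finite(value)), collapse = ", "))
  if (is.unsorted(edges, strictly = TRUE))
    stop("edges must be strictly increasing")
  findInterval(value, edges) + 1L
}

#' Resolve derived dichotomous flags
#'
#' Adds/overwrites `whr` ("low"/"high") and `diabetes` ("no"/"yes") category
#' columns from raw measurements. High waist-to-hip ratio is >=0.80 in women
#' and >=0.95 in men. Diabetes is fasting blood sugar >=126 mg/dL, or 2-hour
#' plasma glucose >=200 mg/dL, or anti-diabetic treatment.
#'
#' @param df Data frame with `sex` ("F"/"M") and a numeric `whr` column,
#'   and/or diabetes inputs `fbs`, `glucose_2h`, `diabetes_treatment` (or an
#'   already-resolved `diabetes` column).
#' @param whr_thresholds Named pair `c(F=, M=)` of WHR cut points.
#' @return `df` with `whr` and `diabetes` as category labels.
#' @export
derive_flags <- function(df, whr_thresholds = c(F = 0.80, M = 0.95)) {
  if (!is.null(df$whr) && is.numeric(df$whr)) {
    if (is.null(df$sex) || any(is.na(df$sex)))
      stop("sex is required to dichotomize waist-to-hip ratio")
    thr <- unname(whr_thresholds[as.character(df$sex)])
    if (any(is.na(thr))) stop("sex must be 'F' or 'M'")
    df$whr <- ifelse(df$whr >= thr, "high", "low")
  }
  has_inputs <- !is.null(df$fbs) || !is.null(df$glucose_2h) ||
    !is.null(df$diabetes_treatment)
  if (has_inputs) {
    n <- nrow(df)
    dia <- rep(FALSE, n)
    if (!is.null(df$fbs)) dia <- dia | (!is.na(df$fbs) & df$fbs >= 126)
    if (!is.null(df$glucose_2h))
      dia <- dia | (!is.na(df$glucose_2h) & df$glucose_2h >= 200)
    if (!is.null(df$diabetes_treatment))
      dia <- dia | (!is.na(df$diabetes_treatment) &
                      as.logical(df$diabetes_treatment))
    df$diabetes <- ifelse(dia, "yes", "no")
  } else if (!is.null(df$diabetes) && !is.character(df$diabetes)) {
    df$diabetes <- ifelse(as.logical(df$diabetes), "yes", "no")
  }
  df
}

#' Categorize a raw cohort against a chart spec
#'
#' Converts raw person-level records to the categorized form used
#' throughout: one label column per stratifier, integer `bp_cat` (and
#' `chol_cat` for 2D charts), and binary `outcome`. Raw continuous columns
#' (`age`, `bp`, `chol`, numeric `whr`, diabetes inputs) are binned /
#' dichotomized; columns already holding category labels pass through after
#' validation. Missing cholesterol under a 2D spec is an error (no
#' imputation); use a 1D spec for lab-free scoring.
#'
#' @param df Cohort data frame.
#' @param spec A `chart_spec`.
#' @param age_floor Minimum allowed age in years.
#' @return Categorized data frame with attribute `"chart_spec"` set.
#' @export
categorize_cohort <- function(df, spec, age_floor = 35) {
  df <- as.data.frame(df)
  df <- derive_flags(df, whr_thresholds = whr_thresholds_of(spec))
  n <- nrow(df)
  out <- data.frame(row.names = seq_len(n))
  for (s in spec$stratifiers) {
    v <- df[[s$name]]
    # age may arrive as a raw `age` column even though the spec names the
    # stratifier `age_group`
    if (is.null(v) && s$name == "age_group" && !is.null(df$age)) v <- df$age
    if (is.null(v)) stop("missing stratifier column '", s$name, "'")
    if (is.numeric(v) && !is.null(s$edges)) {
      if (s$name %in% c("age_group", "age") && any(v < age_floor))
        stop("age below the ", age_floor, "-year floor at record(s) ",
             paste(utils::head(which(v < age_floor), 5), collapse = ", "))
      v <- s$categories[bin_continuous(v, s$edges, field = s$name)]
    } else {
      v <- normalize_category(v, s)
    }
    out[[s$name]] <- v
  }
  out$bp_cat <- axis_category(df, spec$row_axis)
  if (!is.null(spec$column_axis)) {
    if (is.null(df[[spec$column_axis$name]]) && is.null(df$chol_cat))
      stop("cholesterol is required for a 2D chart; use a 1D spec for ",
           "lab-free scoring")
    out$chol_cat <- axis_category(df, spec$column_axis)
  }
  if (is.null(df$outcome)) stop("missing 'outcome' column")
  oc <- df$outcome
  bad <- which(!(oc %in% c(0, 1)))
  if (length(bad))
    stop("outcome must be 0/1; bad value at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  out$outcome <- as.integer(oc)
  attr(out, "chart_spec") <- spec
  out
}

axis_category <- function(df, feat) {
  cat_col <- paste0(feat$name, "_cat")
  if (!is.null(df[[cat_col]])) {
    v <- as.integer(df[[cat_col]])
    if (any(is.na(v) | v < 1L | v > length(feat$categories)))
      stop("'", cat_col, "' out of range 1..", length(feat$categories))
    return(v)
  }
  v <- df[[feat$name]]
  if (is.null(v)) stop("missing axis column '", feat$name, "'")
  if (is.numeric(v)) return(bin_continuous(v, feat$edges, field = feat$name))
  m <- match(as.character(v), feat$categories)
  if (any(is.na(m))) stop("unknown '", feat$name, "' category at row(s) ",
                          paste(utils::head(which(is.na(m)), 5), collapse = ", "))
  m
}

normalize_category <- function(v, s) {
  if (is.logical(v) || all(v %in% c(0, 1, "0", "1")))
    if (identical(s$categories, c("no", "yes")))
      return(ifelse(as.logical(as.integer(as.character(v))) |
                      (is.logical(v) & v), "yes", "no"))
  v <- as.character(v)
  bad <- which(!(v %in% s$categories))
  if (length(bad))
    stop("unknown '", s$name, "' category at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "))
  v
}

whr_thresholds_of <- function(spec) {
  for (s in spec$stratifiers)
    if (!is.null(s$sex_thresholds)) return(s$sex_thresholds)
  c(F = 0.80, M = 0.95)
}

age_feature_of <- function(spec) {
  for (s in spec$stratifiers) if (s$name == "age_group") return(s)
  NULL
}

#' Stratum keys
#'
#' Each combination of stratifier categories identifies one chart block; the
#' key is the `|`-joined tuple of category labels in spec order. A chart
#' with no stratifiers has the empty tuple, rendered as the single key
#' `"(all)"`.
#'
#' `stratum_key()` computes the key for each record of a categorized cohort;
#' `block_keys()` enumerates all keys of a spec in a fixed (first stratifier
#' varying fastest) order.
#'
#' @param cohort Categorized cohort (see [categorize_cohort()]).
#' @param spec A `chart_spec`.
#' @return Character vector of keys.
#' @export
stratum_key <- function(cohort, spec) {
  if (length(spec$stratifiers) == 0L) return(rep("(all)", nrow(cohort)))
  cols <- lapply(spec$stratifiers, function(s) {
    v <- cohort[[s$name]]
    if (is.null(v)) stop("missing stratifier value for '", s$name, "'")
    if (any(is.na(v))) stop("missing stratifier value for '", s$name,
                            "' at row(s) ",
                            paste(utils::head(which(is.na(v)), 5), collapse = ", "))
    as.character(v)
  })
  do.call(paste, c(cols, sep = "|"))
}

#' @rdname stratum_key
#' @export
block_keys <- function(spec) {
  if (length(spec$stratifiers) == 0L) return("(all)")
  grids <- lapply(spec$stratifiers, function(s) s$categories)
  g <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  do.call(paste, c(as.list(g), sep = "|"))
}

#' Chart size measures
#'
#' `block_count()` is the number of blocks (product of stratifier category
#' counts); `cell_count()` multiplies it by the block dimensions and is the
#' interpretability measure reported for a chart: fewer cells, easier to
#' read. `interpretability_score()` is an alias of `cell_count()`.
#'
#' @param spec A `chart_spec`.
#' @return Integer.
#' @examples
#' cell_count(spec_cvd_2d())   # 3200
#' block_count(spec_cvd_2d())  # 160
#' cell_count(spec_cvd_1d())   # 80
#' @export
cell_count <- function(spec) {
  block_count(spec) * n_chart_rows(spec) * n_chart_cols(spec)
}

#' @rdname cell_count
#' @export
block_count <- function(spec) {
  if (length(spec$stratifiers) == 0L) return(1L)
  as.integer(prod(vapply(spec$stratifiers,
                         function(s) length(s$categories), integer(1))))
}

#' @rdname cell_count
#' @export
interpretability_score <- function(spec) cell_count(spec)
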