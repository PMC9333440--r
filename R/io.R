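feature_to_list <- function(f) {
  out <- list(name = f$name, role = f$role, categories = f$categories)
  if (!is.null(f$edges)) out$edges <- f$edges
  if (!is.null(f$sex_thresholds))
    out$sex_thresholds <- as.list(f$sex_thresholds)
  out
}

list_to_feature <- function(x) {
  feature_spec(x$name, x$role, unlist(x$categories),
               edges = if (!is.null(x$edges)) unlist(x$edges),
               sex_thresholds = if (!is.null(x$sex_thresholds))
                 c(F = x$sex_thresholds$F, M = x$sex_thresholds$M))
}

spec_to_list <- function(spec) {
  list(n_levels = spec$n_levels,
       band_labels = spec$band_labels,
       stratifiers = lapply(spec$stratifiers, feature_to_list),
       row_axis = feature_to_list(spec$row_axis),
       column_axis = if (!is.null(spec$column_axis))
         feature_to_list(spec$column_axis))
}

list_to_spec <- function(x) {
  chart_spec(stratifiers = lapply(x$stratifiers, list_to_feature),
             row_axis = list_to_feature(x$row_axis),
             column_axis = if (!is.null(x$column_axis))
               list_to_feature(x$column_axis),
             n_levels = x$n_levels,
             band_labels = unlist(x$band_labels))
}

#' Read and write chart specs and risk charts as JSON
#'
#' Charts serialize to a small versioned JSON schema: the spec (features,
#' categories, cut points, bands), the gene linearization order
#' (`"row-major"`, recorded for reproducibility of crossover), and one 2D
#' integer array per stratum key. Serialization is deterministic:
#' write-read-write round trips are byte-identical.
#'
#' @param chart A `risk_chart`.
#' @param spec A `chart_spec`.
#' @param path File path.
#' @return Readers return the deserialized object; writers return `path`
#'   invisibly.
#' @export
write_chart_json <- function(chart, path) {
  obj <- list(format = "gachart/risk-chart", version = 1L,
              gene_order = "row-major",
              spec = spec_to_list(chart$spec),
              blocks = chart$blocks)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_chart_json
#' @export
read_chart_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$format) || x$format != "gachart/risk-chart")
    stop("not a risk-chart JSON file: ", path)
  spec <- list_to_spec(x$spec)
  blocks <- lapply(x$blocks, function(rows) {
    m <- do.call(rbind, lapply(rows, function(r) as.integer(unlist(r))))
    storage.mode(m) <- "integer"
    m
  })
  risk_chart(spec, blocks)
}

#' @rdname write_chart_json
#' @export
write_spec_json <- function(spec, path) {
  obj <- list(format = "gachart/chart-spec", version = 1L,
              spec = spec_to_list(spec))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_chart_json
#' @export
read_spec_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(x$format) || x$format != "gachart/chart-spec")
    stop("not a chart-spec JSON file: ", path)
  list_to_spec(x$spec)
}

#' Read a cohort CSV
#'
#' Reads person-level records, optionally renames columns via `mapping`
#' (standard name -> file column name), validates and categorizes them
#' against `spec`. Row count and per-field missingness are reported via
#' `message()`.
#'
#' @param path CSV file with one header row.
#' @param spec A `chart_spec`.
#' @param mapping Optional named character vector / list mapping standard
#'   column names (`sex`, `age`, `bp`, `chol`, `whr`, `fh_cvd`,
#'   `diabetes`, `smoker`, `outcome`, `*_cat`) to the file's column names.
#' @param quiet Suppress the row-count/missingness message.
#' @return Categorized cohort data frame.
#' @export
read_cohort_csv <- function(path, spec, mapping = NULL, quiet = FALSE) {
  if (!file.exists(path)) stop("cohort file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(mapping)) {
    for (std in names(mapping)) {
      src <- mapping[[std]]
      if (!src %in% names(df))
        stop("mapped column '", src, "' (for '", std, "') not in ", path)
      names(df)[names(df) == src] <- std
    }
  }
  if (!quiet) {
    miss <- vapply(df, function(v) sum(is.na(v)), integer(1))
    message("read ", nrow(df), " records from ", path,
            if (any(miss > 0)) paste0("; missing: ",
              paste(names(miss)[miss > 0], miss[miss > 0],
                    sep = "=", collapse = ", ")) else "")
  }
  categorize_cohort(df, spec)
}

#' @rdname read_cohort_csv
#' @param cohort Data frame to write.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# 32-bit FNV-1a over a string; used for input fingerprints in manifests.
fnv1a <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256                      # the byte XOR only touches low bits
    h <- h - low + bitwXor(as.integer(low), b)
    # 32-bit modular multiply in 16-bit halves (keeps doubles exact)
    h <- (h %% 65536 * 16777619 + (h %/% 65536 * 16777619) %% 65536 * 65536) %%
      4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Write a training-run manifest
#'
#' Records everything needed to reproduce a training run: a fingerprint of
#' the serialized spec, the GA parameters and seed, rounds completed, the
#' blockwise AUROC trace, and elapsed wall-clock seconds.
#'
#' @param fit A `chart_fit` from [train_chart()].
#' @param path Output JSON path.
#' @param cohort_hash Optional fingerprint of the input cohort file.
#' @param wall_clock Elapsed seconds to record.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(fit, path, cohort_hash = NULL, wall_clock = NA) {
  spec_json <- jsonlite::toJSON(spec_to_list(fit$chart$spec),
                                auto_unbox = TRUE, digits = NA)
  obj <- list(format = "gachart/manifest", version = 1L,
              spec_hash = fnv1a(as.character(spec_json)),
              cohort_hash = cohort_hash,
              params = fit$params[c("population_size", "generations",
                                    "stall_limit", "mutation_prob",
                                    "include_incumbent", "weight_offset",
                                    "seed")],
              rounds_completed = fit$rounds_completed,
              init_auroc = fit$init_auroc,
              final_auroc = fit$final_auroc,
              trace = fit$history,
              wall_clock = wall_clock)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null",
                       dataframe = "rows")
  invisible(path)
}
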