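#' Chromosome validity under the monotone-risk constraint
#'
#' A chromosome is one chart block: an integer matrix of ordinal risk
#' levels, rows indexed by blood-pressure category and columns by
#' cholesterol category (a single column in the 1D representation).
#' Canonical orientation puts the lowest category at index 1 on both axes,
#' so a valid chromosome is non-decreasing along increasing row and column
#' indices, with every gene in `[1, n_levels]`. Monotonicity is non-strict:
#' adjacent cells may share a level.
#'
#' @param genes Integer matrix (a numeric vector is taken as a 1D column).
#' @param n_levels Number of ordinal levels.
#' @return `TRUE` or `FALSE`.
#' @export
is_valid_chromosome <- function(genes, n_levels = 6L) {
  genes <- as_chromosome(genes)
  if (any(genes < 1L | genes > n_levels)) return(FALSE)
  if (nrow(genes) > 1L && any(diff(genes) < 0L)) return(FALSE)
  if (ncol(genes) > 1L && any(t(diff(t(genes))) < 0L)) return(FALSE)
  TRUE
}

as_chromosome <- function(genes) {
  if (!is.matrix(genes)) genes <- matrix(as.integer(genes), ncol = 1L)
  storage.mode(genes) <- "integer"
  if (any(is.na(genes))) stop("chromosome contains missing genes")
  genes
}

#' Minimally repair a chromosome after a one-gene change
#'
#' Restores validity after a single +/-1 change to an otherwise valid
#' chromosome by propagating the change through the cells it forces,
#' recursively, and touching nothing else. After an increase, a forward
#' sweep raises any cell below the maximum of its up/left neighbours; after
#' a decrease, a backward sweep lowers any cell above the minimum of its
#' down/right neighbours. On input satisfying the precondition this equals
#' the unique minimal-L1 valid matrix that preserves the changed gene.
#'
#' @param genes Chromosome with the +/-1 change already applied.
#' @param direction `+1` if a gene was increased, `-1` if decreased.
#' @return A valid chromosome of the same dimensions.
#' @examples
#' repair_chromosome(matrix(c(1, 3, 2, 3), ncol = 1), +1)  # 1 3 3 3
#' @export
repair_chromosome <- function(genes, direction) {
  m <- as_chromosome(genes)
  R <- nrow(m); C <- ncol(m)
  if (direction > 0) {
    for (i in seq_len(R)) for (j in seq_len(C)) {
      lo <- m[i, j]
      if (i > 1L && m[i - 1L, j] > lo) lo <- m[i - 1L, j]
      if (j > 1L && m[i, j - 1L] > lo) lo <- m[i, j - 1L]
      m[i, j] <- lo
    }
  } else {
    for (i in rev(seq_len(R))) for (j in rev(seq_len(C))) {
      hi <- m[i, j]
      if (i < R && m[i + 1L, j] < hi) hi <- m[i + 1L, j]
      if (j < C && m[i, j + 1L] < hi) hi <- m[i, j + 1L]
      m[i, j] <- hi
    }
  }
  m
}

#' Draw a random valid chromosome
#'
#' Generates a uniform random integer matrix and makes it valid with
#' cumulative maxima along both axes (values stay within `[1, n_levels]`).
#' Used for property tests and to seed populations in the absence of data.
#'
#' @param nrow,ncol Block dimensions.
#' @param n_levels Number of ordinal levels.
#' @return A valid chromosome.
#' @export
random_chromosome <- function(nrow = 4L, ncol = 5L, n_levels = 6L) {
  m <- matrix(sample.int(n_levels, nrow * ncol, replace = TRUE),
              nrow = nrow, ncol = ncol)
  m <- apply(m, 2L, cummax)
  if (!is.matrix(m)) m <- matrix(m, nrow = nrow)
  m <- t(apply(m, 1L, cummax))
  if (nrow == 1L) m <- matrix(m, nrow = 1L)
  if (ncol == 1L) m <- matrix(as.vector(m), ncol = 1L)
  as_chromosome(m)
}
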