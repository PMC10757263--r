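#' @title Singleton theory of matrices
#' @description
#' A row with exactly one nonzero entry is a singleton row; that entry is a
#' singleton element of its column. A matrix is singleton complete when
#' every column owns at least one singleton element, singleton deficient
#' otherwise. The singleton row rank (number of singleton rows) and the
#' deficiency index (number of singleton-free columns) drive both the
#' pivot choice in the elimination that builds basic pathways and the
#' decomposition of admissible fluxes afterwards: a singleton row i(j) of
#' column j pins its coefficient via v[i(j)] = r_j * w[i(j), j].
#'
#' "Singleton row index" and "singleton row rank" are used interchangeably
#' for the same count.
#' @name singleton
NULL

#' Singleton profile of a rational matrix
#'
#' @param M a `rat_mat`.
#' @return object of class `singleton_profile`: `singleton_rows` (integer
#'   indices), `column_singletons` (list, per column, of its singleton-row
#'   indices — the i(j) map), `row_rank`, `deficiency_index`,
#'   `deficient_columns`, `complete`.
#' @export
singleton_profile <- function(M) {
  nz <- M$num != 0
  rows_nnz <- rowSums(nz)
  srows <- which(rows_nnz == 1)
  col_single <- lapply(seq_len(ncol(nz)), function(j) srows[nz[srows, j]])
  defic <- which(vapply(col_single, length, integer(1)) == 0)
  structure(list(singleton_rows = srows,
                 column_singletons = col_single,
                 row_rank = length(srows),
                 deficiency_index = length(defic),
                 deficient_columns = defic,
                 complete = length(defic) == 0),
            class = "singleton_profile")
}

#' @export
print.singleton_profile <- function(x, ...) {
  cat(sprintf("<singleton_profile: row rank %d, deficiency index %d (%s)>\n",
              x$row_rank, x$deficiency_index,
              if (x$complete) "complete" else "deficient"))
  invisible(x)
}

#' Sparsity: exact fraction of zero entries
#'
#' @param M a nonempty `rat_mat`.
#' @param digits optional rounding (e.g. 2 to compare with reported
#'   two-decimal values); default `NULL` returns the exact fraction.
#' @return numeric in [0, 1].
#' @export
sparsity <- function(M, digits = NULL) {
  n <- length(M$num)
  if (n == 0) stop("sparsity of an empty matrix is undefined", call. = FALSE)
  s <- sum(M$num == 0) / n
  if (!is.null(digits)) s <- round(s, digits)
  s
}

#' Singleton cost of transforming one matrix into another
#'
#' Type-I cost is the drop in singleton row rank, Type-II the rise in the
#' deficiency index; positive values mean degradation in both conventions.
#'
#' @param M_before,M_after `rat_mat` objects of the same shape.
#' @return list with `type_I` and `type_II` (signed integers).
#' @export
singleton_cost <- function(M_before, M_after) {
  if (!identical(dim(M_before$num), dim(M_after$num)))
    stop("singleton_cost requires matrices of equal shape", call. = FALSE)
  pb <- singleton_profile(M_before)
  pa <- singleton_profile(M_after)
  list(type_I = pb$row_rank - pa$row_rank,
       type_II = pa$deficiency_index - pb$deficiency_index)
}
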