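#' @title Column-operation engine and basic-pathways elimination
#' @description
#' The basic-pathways matrix W is obtained from the fundamental null basis
#' G by column operations that preserve both the null-basis property and
#' the nonnegativity of the top r rows: positive scalings, swaps, and
#' additions of positive multiples of one column to another. Negative
#' entries of the bottom (dilution) block are cleared one row at a time,
#' sweeping the dilution rows in metabolite order; within each row, the
#' pivot column is chosen to minimize the measured singleton cost of the
#' operation. Since an operation only adds a positive multiple of a column
#' that is nonnegative in every already-processed row, processed rows never
#' regain negative entries, for any sweep order.
#' @name transform
NULL

#' Build a column operation descriptor
#'
#' @param kind `"scale"`, `"swap"` or `"add_multiple"`.
#' @param target target column index.
#' @param source source column index (swap / add_multiple).
#' @param coef_num,coef_den integer numerator/denominator of the coefficient.
#' @export
column_op <- function(kind, target, source = NA_integer_,
                      coef_num = 1, coef_den = 1) {
  kind <- match.arg(kind, c("scale", "swap", "add_multiple"))
  structure(list(kind = kind, target = as.integer(target),
                 source = as.integer(source),
                 coef_num = coef_num, coef_den = coef_den),
            class = "column_op")
}

#' Apply a column operation to a rational matrix
#'
#' Scale coefficients must be nonzero; the elimination only ever uses
#' strictly positive coefficients (enforced there, not here, since the
#' guarded sparsification pass legitimately subtracts).
#'
#' @param M a `rat_mat`.
#' @param op a [column_op()].
#' @return a new `rat_mat`; the input is not modified.
#' @export
apply_column_op <- function(M, op) {
  nc <- ncol(M$num)
  if (op$target < 1 || op$target > nc) stop("column index out of range", call. = FALSE)
  out <- M
  if (op$kind == "scale") {
    if (op$coef_num == 0) stop("zero scale coefficient", call. = FALSE)
    col <- rat_scale(rat_sub(M, j = op$target), op$coef_num, op$coef_den)
    out$num[, op$target] <- col$num[, 1]; out$den[, op$target] <- col$den[, 1]
  } else if (op$kind == "swap") {
    if (op$source < 1 || op$source > nc) stop("column index out of range", call. = FALSE)
    out$num[, c(op$target, op$source)] <- M$num[, c(op$source, op$target)]
    out$den[, c(op$target, op$source)] <- M$den[, c(op$source, op$target)]
  } else {
    if (op$source < 1 || op$source > nc) stop("column index out of range", call. = FALSE)
    if (op$coef_num == 0) stop("zero add_multiple coefficient", call. = FALSE)
    col <- rat_sub(M, j = op$target) +
      rat_scale(rat_sub(M, j = op$source), op$coef_num, op$coef_den)
    out$num[, op$target] <- col$num[, 1]; out$den[, op$target] <- col$den[, 1]
  }
  rat_mat(out$num, out$den)
}

#' Replay a list of column operations
#' @param M a `rat_mat`.
#' @param ops list of [column_op()] objects.
#' @export
replay_column_ops <- function(M, ops) {
  for (op in ops) M <- apply_column_op(M, op)
  M
}

# A row of the bottom block whose entries are all <= 0 with at least one
# < 0 can never be repaired: positive column combinations only decrease its
# entries further. Pivot choice therefore rejects (when possible) any
# operation that creates such a stuck row.
.has_stuck_row <- function(M, r) {
  n <- nrow(M$num)
  for (i in seq(r + 1, n)) {
    row <- M$num[i, ]
    if (all(row <= 0) && any(row < 0)) return(TRUE)
  }
  FALSE
}

# Depth-first elimination over pivot choices. At each step the first
# (leftmost) negative entry of the current row is cleared; candidate pivot
# columns are ordered by the lexicographic key (measured Type-I cost,
# measured Type-II cost, nnz of pivot column, column index) and tried in
# that order. Branches whose matrix contains a stuck row are pruned — they
# can never complete — so the first completed leaf is returned. On
# singleton-cost ties the search is a plain greedy pass; backtracking only
# occurs when a greedy prefix runs a later row out of positive entries.
.eliminate_dfs <- function(M, rows_todo, r) {
  while (length(rows_todo) > 0) {
    i <- rows_todo[1]
    negs <- which(M$num[i, ] < 0)
    if (length(negs) == 0) { rows_todo <- rows_todo[-1]; next }
    j <- negs[1]
    candidates <- setdiff(which(M$num[i, ] > 0), j)
    if (length(candidates) == 0) return(NULL)
    before <- singleton_profile(M)
    ranked <- list()
    for (k in candidates) {
      a_num <- -M$num[i, j] * M$den[i, k]
      a_den <- M$den[i, j] * M$num[i, k]
      trial <- apply_column_op(M, column_op("add_multiple", j, k, a_num, a_den))
      if (.has_stuck_row(trial, r)) next
      after <- singleton_profile(trial)
      ranked[[length(ranked) + 1]] <- list(
        k = k, a_num = a_num, a_den = a_den, trial = trial,
        key = c(before$row_rank - after$row_rank,
                after$deficiency_index - before$deficiency_index,
                sum(M$num[, k] != 0), k))
    }
    if (length(ranked) == 0) return(NULL)
    ord <- order(vapply(ranked, function(x) x$key[1], numeric(1)),
                 vapply(ranked, function(x) x$key[2], numeric(1)),
                 vapply(ranked, function(x) x$key[3], numeric(1)),
                 vapply(ranked, function(x) x$key[4], numeric(1)))
    ranked <- ranked[ord]
    if (length(ranked) == 1) {
      pick <- ranked[[1]]
      op <- column_op("add_multiple", j, pick$k, pick$a_num, pick$a_den)
      attr(op, "cost") <- list(type_I = pick$key[1], type_II = pick$key[2])
      M <- pick$trial
      res <- .eliminate_dfs(M, rows_todo, r)
      if (is.null(res)) return(NULL)
      res$ops <- c(list(op), res$ops)
      return(res)
    }
    for (pick in ranked) {
      op <- column_op("add_multiple", j, pick$k, pick$a_num, pick$a_den)
      attr(op, "cost") <- list(type_I = pick$key[1], type_II = pick$key[2])
      res <- .eliminate_dfs(pick$trial, rows_todo, r)
      if (!is.null(res)) {
        res$ops <- c(list(op), res$ops)
        return(res)
      }
    }
    return(NULL)
  }
  list(M = M, ops = list())
}

.lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' Eliminate negative entries of G, producing the basic-pathways matrix W
#'
#' Processes the dilution-block rows r + 1 to n in metabolite order (the
#' frozen sweep; see the methods vignette for why this order is the
#' package's choice). For each negative entry w[i, j] the
#' operation c_j <- c_j + a c_k uses a pivot column k with w[i, k] > 0 and
#' a = -w[i, j] / w[i, k] > 0; among candidate pivots the one minimizing
#' (measured Type-I cost, measured Type-II cost, pivot nonzero count,
#' column index) lexicographically is chosen, and negatives within a row
#' are cleared left to right. Columns are finally scaled to primitive
#' integer vectors (the scalings are logged too, so replaying the log on G
#' reproduces W bit-exactly).
#'
#' @param G a `fundamental_null_basis` (see [build_fundamental_null_basis()]).
#' @return object of class `basic_pathway_basis`: `W` (`rat_mat`, all
#'   entries >= 0), `op_log` (list of [column_op()] with attached measured
#'   costs), `profile` (singleton profile of W), `source` (the input G),
#'   `model`, `row_labels`, `col_labels` (`BP1..BPr`).
#' @export
eliminate_negatives <- function(G) {
  if (!inherits(G, "fundamental_null_basis"))
    stop("eliminate_negatives expects a fundamental_null_basis", call. = FALSE)
  M <- G$G
  n <- nrow(M$num); r <- ncol(M$num)
  res <- .eliminate_dfs(M, seq(r + 1, n), r)
  if (is.null(res))
    stop("elimination failed: every pivot sequence reaches a row without ",
         "a positive entry; run reduce_network first", call. = FALSE)
  M <- res$M
  op_log <- res$ops
  stopifnot(all(M$num[seq(r + 1, n), ] >= 0))
  canon <- rat_canonicalize_columns(M)
  for (j in seq_len(r)) {
    l <- canon$scales[1, j]; g <- canon$scales[2, j]
    if (l != g) op_log[[length(op_log) + 1]] <- column_op("scale", j, NA, l, g)
  }
  W <- canon$mat
  structure(list(W = W, op_log = op_log, profile = singleton_profile(W),
                 source = G, model = G$model,
                 row_labels = G$row_labels,
                 col_labels = paste0("BP", seq_len(r))),
            class = "basic_pathway_basis")
}

#' @export
print.basic_pathway_basis <- function(x, ...) {
  p <- x$profile
  cat(sprintf(paste0("<basic_pathway_basis: %d x %d, singleton row rank %d, ",
                     "deficiency index %d, sparsity %.2f>\n"),
              nrow(x$W$num), ncol(x$W$num), p$row_rank, p$deficiency_index,
              sparsity(x$W)))
  invisible(x)
}

#' Guarded sparsification of a basic-pathways basis
#'
#' Greedy pass over ordered column pairs (j, k): replaces c_j by
#' c_j - a c_k with the largest rational a > 0 keeping every entry of c_j
#' nonnegative (a = min over rows i with w[i,k] > 0 of w[i,j]/w[i,k]).
#' A replacement is kept only if it strictly reduces
#' (deficiency index, total nonzero count) lexicographically; the pass
#' iterates to a fixed point. Nonnegativity and the null-basis rank are
#' preserved by construction (c_j keeps coefficient 1, and proportional
#' basis columns cannot occur).
#'
#' @param basis a `basic_pathway_basis`.
#' @return a `basic_pathway_basis` with the extra operations appended to
#'   `op_log`.
#' @export
sparsify <- function(basis) {
  W <- basis$W
  r <- ncol(W$num)
  op_log <- basis$op_log
  repeat {
    improved <- FALSE
    prof <- singleton_profile(W)
    for (j in seq_len(r)) for (k in seq_len(r)) {
      if (j == k) next
      rows <- which(W$num[, k] > 0)
      if (length(rows) == 0) next
      # largest a with c_j - a c_k >= 0
      ratios_num <- W$num[rows, j] * W$den[rows, k]
      ratios_den <- W$den[rows, j] * W$num[rows, k]
      vals <- ratios_num / ratios_den
      a_i <- rows[which.min(vals)]
      a_num <- W$num[a_i, j] * W$den[a_i, k]
      a_den <- W$den[a_i, j] * W$num[a_i, k]
      if (a_num <= 0) next
      trial <- apply_column_op(W, column_op("add_multiple", j, k, -a_num, a_den))
      if (all(trial$num[, j] == 0)) next
      tprof <- singleton_profile(trial)
      old_key <- c(prof$deficiency_index, sum(W$num != 0))
      new_key <- c(tprof$deficiency_index, sum(trial$num != 0))
      if (.lex_less(new_key, old_key)) {
        op <- column_op("add_multiple", j, k, -a_num, a_den)
        attr(op, "cost") <- singleton_cost(W, trial)
        op_log[[length(op_log) + 1]] <- op
        W <- trial
        prof <- tprof
        improved <- TRUE
      }
    }
    if (!improved) break
  }
  canon <- rat_canonicalize_columns(W)
  for (j in seq_len(r)) {
    l <- canon$scales[1, j]; g <- canon$scales[2, j]
    if (l != g) op_log[[length(op_log) + 1]] <- column_op("scale", j, NA, l, g)
  }
  out <- basis
  out$W <- canon$mat
  out$op_log <- op_log
  out$profile <- singleton_profile(out$W)
  out
}

#' Run the full pipeline under a metabolite row permutation
#'
#' Permutes the rows of S0, builds G and eliminates, then un-permutes the
#' bottom m rows of the result. The output is a (generally different) valid
#' basic-pathway basis for the original model — basic-pathway bases are not
#' unique, and row order is one of the choices that selects among them.
#'
#' @param model a `stoichiometric_model`.
#' @param row_permutation integer permutation of `seq_along(metabolite_ids)`.
#' @return a `basic_pathway_basis` for the original (unpermuted) model.
#' @export
permuted_basis <- function(model, row_permutation) {
  m <- length(model$metabolite_ids)
  if (length(row_permutation) != m ||
      !setequal(row_permutation, seq_len(m)))
    stop("row_permutation must be a permutation of the metabolite indices", call. = FALSE)
  perm_model <- stoichiometric_model(
    model$metabolite_ids[row_permutation],
    model$reaction_ids,
    rat_sub(model$S0, row_permutation),
    model$reversible,
    rat_sub(model$dilution_rates, row_permutation, 1))
  basis <- eliminate_negatives(build_fundamental_null_basis(perm_model))
  r <- length(model$reaction_ids)
  inv <- order(row_permutation)
  W <- rat_rbind(rat_sub(basis$W, seq_len(r)),
                 rat_sub(basis$W, r + inv))
  structure(list(W = W, op_log = basis$op_log, profile = singleton_profile(W),
                 source = basis$source, model = model,
                 row_labels = flux_labels(model),
                 col_labels = basis$col_labels),
            class = "basic_pathway_basis")
}
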