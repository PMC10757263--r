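#' @title Flux-cone operations
#' @description
#' The admissible steady-state fluxes form the pointed convex polyhedral
#' cone \{v >= 0 : S v = 0\}. Basic pathways span the null space but need
#' not be a frame for the cone: when W is singleton deficient, some
#' admissible fluxes require negative coefficients on the deficient
#' columns, bounded below by explicit rational inequalities. This module
#' decomposes pathways in basic-pathway coordinates, computes those
#' coefficient bounds, tests vectors for extreme-ray status by the
#' support-rank criterion, and provides a brute-force extreme-ray
#' enumerator used as an oracle in the test suite.
#' @name cone
NULL

#' Test admissibility: S v = 0 exactly and v >= 0
#'
#' @param S a `rat_mat` (m x n).
#' @param v a `rat_mat` column vector of length n.
#' @export
is_admissible <- function(S, v) {
  if (nrow(v$num) != ncol(S$num) || ncol(v$num) != 1)
    stop("flux vector length does not match S", call. = FALSE)
  all(v$num >= 0) && rat_is_zero(rat_mult(S, v))
}

#' Decompose a null vector in basic-pathway coordinates
#'
#' For singleton-complete columns j the coefficient is read off a singleton
#' row: r_j = v[i(j)] / w[i(j), j]. Coefficients of the d deficient columns
#' are then obtained by solving the exact residual system on rows where
#' they appear. The reconstruction W r = v is verified exactly; the m flux
#' components outside the independent set i(j) are reported as dependent,
#' reconstructed values (the compatibility relations).
#'
#' @param basis a `basic_pathway_basis`.
#' @param v `rat_mat` column vector in the null space of S (need not be
#'   nonnegative; only S v = 0 is required).
#' @return list with `coefficients` (`rat_mat` r x 1), `independent_components`
#'   (flux indices used as free parameters), `dependent_components`
#'   (data.frame: flux index, reconstructed value as string), `residual_zero`
#'   (TRUE; exact check).
#' @export
decompose_pathway <- function(basis, v) {
  W <- basis$W
  n <- nrow(W$num); r <- ncol(W$num)
  if (nrow(v$num) != n || ncol(v$num) != 1)
    stop("pathway vector length does not match W", call. = FALSE)
  S <- augment_with_dilution(basis$model)$S
  resid <- rat_mult(S, v)
  if (!rat_is_zero(resid)) {
    bad <- which(resid$num[, 1] != 0)
    stop("vector is not in the null space of S; violated rows: ",
         paste(basis$model$metabolite_ids[bad], collapse = ", "), call. = FALSE)
  }
  prof <- basis$profile
  coef_num <- rep(0, r); coef_den <- rep(1, r)
  iofj <- rep(NA_integer_, r)
  for (j in seq_len(r)) {
    s <- prof$column_singletons[[j]]
    if (length(s) > 0) {
      i <- s[1]
      iofj[j] <- i
      coef_num[j] <- v$num[i, 1] * W$den[i, j]
      coef_den[j] <- v$den[i, 1] * W$num[i, j]
    }
  }
  defic <- prof$deficient_columns
  if (length(defic) > 0) {
    # residual = v - sum over complete columns; solve on rows where the
    # deficient columns live
    fixed <- rat_mat(coef_num, coef_den)
    fixed$num[defic, 1] <- 0; fixed$den[defic, 1] <- 1
    resid2 <- v - rat_mult(W, rat_mat(fixed$num, fixed$den))
    rows <- which(apply(W$num[, defic, drop = FALSE] != 0, 1, any))
    A <- rat_sub(W, rows, defic)
    b <- rat_sub(resid2, rows, 1)
    sol <- .rat_solve_ls(A, b)
    if (is.null(sol))
      stop("inconsistent residual system; input is not a null vector", call. = FALSE)
    coef_num[defic] <- sol$num[, 1]
    coef_den[defic] <- sol$den[, 1]
    # the rows that pinned the deficient coefficients join the free set
    iofj[defic] <- rows[attr(sol, "pivot_rows")]
  }
  coefficients <- rat_mat(coef_num, coef_den)
  stopifnot(rat_equal(rat_mult(W, coefficients), v))
  indep <- iofj[!is.na(iofj)]
  dep <- setdiff(seq_len(n), indep)
  dep_vals <- rat_format(rat_sub(v, dep, 1))[, 1]
  list(coefficients = coefficients,
       independent_components = indep,
       dependent_components = data.frame(flux = dep, value = dep_vals,
                                         stringsAsFactors = FALSE),
       residual_zero = TRUE)
}

# exact least-structure solve A x = b for a (possibly overdetermined)
# consistent rational system; returns NULL if inconsistent
.rat_solve_ls <- function(A, b) {
  nr <- nrow(A$num); nc <- ncol(A$num)
  Aug <- rat_cbind(A, b)
  R <- Aug
  perm <- seq_len(nr)
  pivots <- integer(0); pivot_rows <- integer(0); row <- 1L
  for (col in seq_len(nc)) {
    if (row > nr) break
    piv <- which(R$num[row:nr, col] != 0)
    if (length(piv) == 0) next
    piv <- piv[1] + row - 1L
    if (piv != row) {
      R$num[c(row, piv), ] <- R$num[c(piv, row), ]
      R$den[c(row, piv), ] <- R$den[c(piv, row), ]
      perm[c(row, piv)] <- perm[c(piv, row)]
    }
    pivot_rows <- c(pivot_rows, perm[row])
    pn <- R$num[row, col]; pd <- R$den[row, col]
    rr <- .rat_reduce(R$num[row, ] * pd, R$den[row, ] * pn)
    R$num[row, ] <- rr$num; R$den[row, ] <- rr$den
    for (i in seq_len(nr)[-row]) {
      fn <- R$num[i, col]; fd <- R$den[i, col]
      if (fn != 0) {
        rr <- .rat_reduce(R$num[i, ] * R$den[row, ] * fd - R$num[row, ] * R$den[i, ] * fn,
                          R$den[i, ] * R$den[row, ] * fd)
        R$num[i, ] <- rr$num; R$den[i, ] <- rr$den
      }
    }
    pivots <- c(pivots, col); row <- row + 1L
  }
  # inconsistency: a row 0 ... 0 | nonzero
  for (i in seq_len(nr)) {
    if (all(R$num[i, seq_len(nc)] == 0) && R$num[i, nc + 1] != 0) return(NULL)
  }
  x_num <- rep(0, nc); x_den <- rep(1, nc)
  for (ri in seq_along(pivots)) {
    x_num[pivots[ri]] <- R$num[ri, nc + 1]
    x_den[pivots[ri]] <- R$den[ri, nc + 1]
  }
  sol <- rat_mat(x_num, x_den)
  attr(sol, "pivot_rows") <- pivot_rows
  sol
}

#' Lower bounds on deficient-column coefficients
#'
#' With the coefficients of all singleton-complete columns fixed at
#' nonnegative values, the deficient-column coefficients may go negative
#' only within explicit bounds. For deficiency d = 1 the closed-form bound
#' is r_1 >= -min over rows i with w[i,1] > 0 of
#' (sum_j fixed_j w[i,j]) / w[i,1]. For d >= 2 the constraint system
#' |r_1| w[j,1] + ... + |r_d| w[j,d] <= c_j is returned over the rows j
#' where every deficient-column entry is strictly positive, together with
#' a membership predicate. Bounds are closures of the strict inequalities
#' (the admissible set is the closed cone).
#'
#' @param basis a `basic_pathway_basis` with deficiency index >= 1.
#' @param fixed `rat_mat` column vector of length r: nonnegative
#'   coefficients for the singleton-complete columns (entries at deficient
#'   columns are ignored).
#' @return list with `deficient_columns`; for d = 1 also `lower_bound`
#'   (`rat_mat` 1 x 1); for any d: `constraint_rows` (row indices),
#'   `c_values` (`rat_mat`), and `feasible(rvec)` — a predicate taking the
#'   full-length coefficient vector and testing W r >= 0 exactly.
#' @export
coefficient_lower_bounds <- function(basis, fixed) {
  prof <- basis$profile
  d <- prof$deficiency_index
  if (d == 0)
    stop("basis is singleton complete: every coefficient must simply be ",
         "nonnegative (no further bounds apply)", call. = FALSE)
  W <- basis$W
  r <- ncol(W$num)
  defic <- prof$deficient_columns
  comp <- setdiff(seq_len(r), defic)
  if (any(fixed$num[comp, 1] < 0))
    stop("fixed coefficients of singleton-complete columns must be nonnegative",
         call. = FALSE)
  fx <- fixed
  fx$num[defic, 1] <- 0; fx$den[defic, 1] <- 1
  cvals <- rat_mult(W, rat_mat(fx$num, fx$den))  # c_j per row
  rows_all_pos <- which(apply(W$num[, defic, drop = FALSE] > 0, 1, all))
  out <- list(deficient_columns = defic,
              constraint_rows = rows_all_pos,
              c_values = rat_sub(cvals, rows_all_pos, 1))
  if (d == 1) {
    jd <- defic[1]
    rows <- which(W$num[, jd] > 0)
    # bound = -min over rows of c_i / w_i
    best_num <- NULL; best_den <- NULL
    for (i in rows) {
      # minimize q = c_i / w_i over rows with w_i > 0 (denominators positive)
      q_num <- cvals$num[i, 1] * W$den[i, jd]
      q_den <- cvals$den[i, 1] * W$num[i, jd]
      if (is.null(best_num) || q_num * best_den < best_num * q_den) {
        best_num <- q_num; best_den <- q_den
      }
    }
    out$lower_bound <- rat_mat(-best_num, best_den)
  }
  out$feasible <- function(rvec) {
    all(rat_mult(W, rvec)$num >= 0)
  }
  out
}

#' Directional bound r_Min for deficient-coefficient magnitudes
#'
#' For a direction g >= 0 (not all zero) in the d-dimensional space of
#' deficient-coefficient magnitudes, returns the largest rho such that the
#' magnitude vector |r| = rho g keeps W r >= 0 when the deficient
#' coefficients are set to -rho g and the complete ones to `fixed`:
#' r_Min(g) = min over rows j with positive deficient entries of
#' c_j / (sum_k g_k w[j,k]). The direction is used as given (rational
#' scaling; callers wanting a unit direction normalize beforehand), so
#' rho is measured in units of |g|.
#'
#' @param basis a `basic_pathway_basis` with deficiency index d >= 1.
#' @param fixed `rat_mat` r x 1 of nonnegative complete-column coefficients.
#' @param direction numeric/`rat_mat` vector of length d, componentwise >= 0.
#' @return `rat_mat` 1 x 1: the exact rational r_Min (possibly +Inf-like
#'   large when no constraint row exists, in which case an error is raised).
#' @export
r_min_surface <- function(basis, fixed, direction) {
  prof <- basis$profile
  d <- prof$deficiency_index
  if (d < 1) stop("basis is singleton complete; no deficient directions", call. = FALSE)
  if (!inherits(direction, "rat_mat")) direction <- rat_mat(direction)
  if (nrow(direction$num) != d)
    stop("direction must have one component per deficient column", call. = FALSE)
  if (any(direction$num < 0) || all(direction$num == 0))
    stop("direction components must be nonnegative and not all zero", call. = FALSE)
  W <- basis$W
  defic <- prof$deficient_columns
  fx <- fixed
  fx$num[defic, 1] <- 0; fx$den[defic, 1] <- 1
  cvals <- rat_mult(W, rat_mat(fx$num, fx$den))
  denom <- rat_mult(rat_sub(W, j = defic), direction)  # per-row sum g_k w_jk
  rows <- which(apply(W$num[, defic, drop = FALSE] > 0, 1, all))
  rows <- rows[denom$num[rows, 1] > 0]
  if (length(rows) == 0)
    stop("no active constraint rows for this direction", call. = FALSE)
  best_num <- NULL; best_den <- NULL
  for (i in rows) {
    q_num <- cvals$num[i, 1] * denom$den[i, 1]
    q_den <- cvals$den[i, 1] * denom$num[i, 1]
    if (is.null(best_num) || q_num * best_den < best_num * q_den) {
      best_num <- q_num; best_den <- q_den
    }
  }
  rat_mat(best_num, best_den)
}

#' Extreme-ray test by the support-rank criterion
#'
#' An admissible v != 0 spans an extreme ray of \{v >= 0 : S v = 0\} iff
#' the exact rank of S restricted to the support columns of v equals
#' |support| - 1 (the standard criterion for pointed polyhedral cones).
#'
#' @param S a `rat_mat`.
#' @param v admissible `rat_mat` column vector, nonzero.
#' @export
is_extreme_ray <- function(S, v) {
  if (!is_admissible(S, v)) stop("v is not an admissible pathway", call. = FALSE)
  supp <- which(v$num[, 1] != 0)
  if (length(supp) == 0) stop("zero vector spans no ray", call. = FALSE)
  rat_rank(rat_sub(S, j = supp)) == length(supp) - 1L
}

#' Brute-force extreme-ray enumeration (test oracle)
#'
#' Enumerates column supports in increasing size; for each support whose
#' restricted matrix has nullity one, checks that the (sign-normalized)
#' null vector is nonnegative with full support and passes the
#' support-rank criterion. Intended for small instances only.
#'
#' @param S a `rat_mat` with at most `max_cols` columns unless `force`.
#' @param max_cols size guard (default 16).
#' @param force set TRUE to override the guard.
#' @return list of primitive `rat_mat` column vectors (the complete
#'   extreme-ray set), deduplicated.
#' @export
enumerate_extreme_rays_bruteforce <- function(S, max_cols = 16, force = FALSE) {
  n <- ncol(S$num)
  if (n > max_cols && !force)
    stop("matrix has ", n, " columns; brute-force enumeration is exponential ",
         "(pass force = TRUE to override)", call. = FALSE)
  rays <- list()
  seen <- character(0)
  for (size in seq_len(n)) {
    combs <- utils::combn(n, size)
    for (ci in seq_len(ncol(combs))) {
      supp <- combs[, ci]
      sub <- rat_sub(S, j = supp)
      if (rat_rank(sub) != size - 1L) next
      ns <- rat_nullspace(sub)
      if (ncol(ns$num) != 1) next
      vals <- ns$num[, 1]
      if (all(vals == 0)) next
      sgn <- sign(vals[which(vals != 0)[1]])
      ns <- rat_scale(ns, sgn)
      if (any(ns$num < 0)) next
      if (any(ns$num[, 1] == 0)) next  # support must be exactly supp
      v_num <- rep(0, n); v_den <- rep(1, n)
      v_num[supp] <- ns$num[, 1]; v_den[supp] <- ns$den[, 1]
      v <- rat_canonicalize_columns(rat_mat(v_num, v_den))$mat
      key <- paste(rat_format(v)[, 1], collapse = ",")
      if (!(key %in% seen)) {
        seen <- c(seen, key)
        rays[[length(rays) + 1]] <- v
      }
    }
  }
  rays
}
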