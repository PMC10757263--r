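#' @title Exact rational matrices
#' @description
#' Dense matrices of exact rational numbers, stored as a pair of numeric
#' matrices (numerator, denominator) holding integer values. Every operation
#' reduces entries to lowest terms with a positive denominator, so tests for
#' exact zero (`num == 0`) are reliable. Magnitudes are limited to the range
#' where double-precision integers are exact (|p|, |q| < 2^53); arithmetic
#' aborts if that range is exceeded.
#'
#' These matrices are the substrate for the stoichiometric matrix S, the
#' fundamental null basis G, the basic-pathways matrix W and all intermediate
#' matrices of the elimination: singleton counting and admissibility checks
#' are all exact-zero tests, which floating point cannot provide.
#' @name rational
NULL

.INT_MAX_EXACT <- 2^53

.gcd2 <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (any(b != 0)) {
    t <- b
    b <- ifelse(b != 0, a %% b, 0)
    a <- ifelse(t != 0, t, a)
  }
  a
}

.check_exact <- function(x) {
  if (any(abs(x) >= .INT_MAX_EXACT))
    stop("rational arithmetic overflow: integer magnitude exceeds 2^53", call. = FALSE)
  invisible(x)
}

.rat_reduce <- function(num, den) {
  if (any(den == 0)) stop("zero denominator in rational entry", call. = FALSE)
  .check_exact(num); .check_exact(den)
  s <- sign(den)
  num <- num * s; den <- den * s
  g <- .gcd2(num, den)
  g[g == 0] <- 1
  list(num = num / g, den = den / g)
}

#' Construct an exact rational matrix
#'
#' @param num numeric matrix (or vector) of integer-valued numerators.
#' @param den numeric matrix/vector of integer-valued denominators
#'   (recycled; default 1).
#' @param nrow,ncol optional dimensions when `num` is a vector.
#' @return an object of class `rat_mat` with fields `num` and `den`.
#' @export
rat_mat <- function(num, den = 1, nrow = NULL, ncol = NULL) {
  if (!is.matrix(num)) {
    if (is.null(nrow) && is.null(ncol)) nrow <- length(num)
    num <- matrix(num, nrow = if (is.null(nrow)) length(num) %/% ncol else nrow,
                  ncol = if (is.null(ncol)) 1L else ncol)
  }
  if (any(num != round(num)) || any(den != round(den)))
    stop("rat_mat expects integer-valued numerators and denominators", call. = FALSE)
  den <- matrix(rep_len(den, length(num)), nrow = nrow(num))
  r <- .rat_reduce(num, den)
  structure(list(num = r$num, den = r$den), class = "rat_mat")
}

#' @export
dim.rat_mat <- function(x) dim(x$num)

#' @export
print.rat_mat <- function(x, ...) {
  cat(sprintf("<rat_mat %d x %d>\n", nrow(x$num), ncol(x$num)))
  print(rat_format(x), quote = FALSE)
  invisible(x)
}

#' Format rational entries as "p" or "p/q" strings
#' @param x a `rat_mat`.
#' @return character matrix.
#' @export
rat_format <- function(x) {
  out <- ifelse(x$den == 1,
                format_int(x$num),
                paste0(format_int(x$num), "/", format_int(x$den)))
  matrix(out, nrow = nrow(x$num), dimnames = dimnames(x$num))
}

format_int <- function(v) formatC(v, format = "f", digits = 0)

#' Parse strings/numbers into an exact rational matrix
#'
#' Accepts integers, `"p/q"` strings and finite decimal strings (converted
#' exactly, e.g. `"0.5"` becomes 1/2).
#'
#' @param x character or numeric matrix/vector.
#' @param nrow,ncol optional dimensions for vector input.
#' @return a `rat_mat`.
#' @export
rat_parse <- function(x, nrow = NULL, ncol = NULL) {
  dm <- if (is.matrix(x)) dim(x) else c(if (is.null(nrow)) length(x) else nrow,
                                        if (is.null(ncol)) 1L else ncol)
  xs <- trimws(as.character(x))
  num <- numeric(length(xs)); den <- numeric(length(xs))
  for (i in seq_along(xs)) {
    pq <- .parse_rational_scalar(xs[i])
    num[i] <- pq[1]; den[i] <- pq[2]
  }
  rat_mat(matrix(num, nrow = dm[1], ncol = dm[2]),
          matrix(den, nrow = dm[1], ncol = dm[2]))
}

.parse_rational_scalar <- function(s) {
  if (!nzchar(s)) stop("empty rational literal", call. = FALSE)
  if (grepl("/", s, fixed = TRUE)) {
    parts <- strsplit(s, "/", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("malformed rational literal: ", s, call. = FALSE)
    p <- suppressWarnings(as.numeric(parts[1])); q <- suppressWarnings(as.numeric(parts[2]))
    if (is.na(p) || is.na(q) || p != round(p) || q != round(q) || q == 0)
      stop("malformed rational literal: ", s, call. = FALSE)
    return(c(p, q))
  }
  if (grepl("^[+-]?[0-9]+$", s)) return(c(as.numeric(s), 1))
  if (grepl("^[+-]?[0-9]*\\.[0-9]+$", s)) {
    frac <- sub("^[+-]?[0-9]*\\.", "", s)
    k <- nchar(frac)
    val <- as.numeric(sub("\\.", "", s))
    return(c(val, 10^k))
  }
  stop("malformed rational literal: ", s, call. = FALSE)
}

.rat_binop <- function(a, b, op) {
  if (!identical(dim(a$num), dim(b$num))) stop("rational matrix shape mismatch", call. = FALSE)
  if (op == "+") r <- .rat_reduce(a$num * b$den + b$num * a$den, a$den * b$den)
  else if (op == "-") r <- .rat_reduce(a$num * b$den - b$num * a$den, a$den * b$den)
  else if (op == "*") r <- .rat_reduce(a$num * b$num, a$den * b$den)
  else stop("unsupported op")
  structure(r, class = "rat_mat")
}

#' Elementwise arithmetic on rational matrices
#' @param e1,e2 `rat_mat` objects of equal shape.
#' @export
Ops.rat_mat <- function(e1, e2) {
  if (.Generic %in% c("+", "-", "*")) return(.rat_binop(e1, e2, .Generic))
  if (.Generic == "==") return(e1$num * e2$den == e2$num * e1$den)
  if (.Generic == "!=") return(e1$num * e2$den != e2$num * e1$den)
  stop("operation not supported for rat_mat: ", .Generic, call. = FALSE)
}

#' Exact rational matrix product
#' @param a,b conformable `rat_mat` objects.
#' @return a `rat_mat` equal to `a %*% b` computed exactly.
#' @export
rat_mult <- function(a, b) {
  if (ncol(a$num) != nrow(b$num)) stop("non-conformable rational matrices", call. = FALSE)
  n <- nrow(a$num); m <- ncol(b$num)
  num <- matrix(0, n, m); den <- matrix(1, n, m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    pn <- 0; pd <- 1
    for (k in seq_len(ncol(a$num))) {
      tn <- a$num[i, k] * b$num[k, j]
      td <- a$den[i, k] * b$den[k, j]
      if (tn != 0) {
        nn <- pn * td + tn * pd
        nd <- pd * td
        g <- .gcd2(abs(nn), nd); if (g == 0) g <- 1
        pn <- nn / g; pd <- nd / g
        .check_exact(c(pn, pd))
      }
    }
    num[i, j] <- pn; den[i, j] <- pd
  }
  rat_mat(num, den)
}

#' Scale a rational matrix by an exact rational scalar p/q
#' @param x a `rat_mat`.
#' @param p,q integer numerator and denominator of the scalar.
#' @export
rat_scale <- function(x, p, q = 1) {
  r <- .rat_reduce(x$num * p, x$den * q)
  structure(r, class = "rat_mat")
}

#' Subset a rational matrix (rows/columns), keeping exactness
#' @param x a `rat_mat`.
#' @param i,j row and column index vectors (missing = all).
#' @export
rat_sub <- function(x, i = seq_len(nrow(x$num)), j = seq_len(ncol(x$num))) {
  rat_mat(x$num[i, j, drop = FALSE], x$den[i, j, drop = FALSE])
}

#' Bind rational matrices by rows or columns
#' @param ... `rat_mat` objects.
#' @export
rat_rbind <- function(...) {
  xs <- list(...)
  rat_mat(do.call(rbind, lapply(xs, `[[`, "num")),
          do.call(rbind, lapply(xs, `[[`, "den")))
}

#' @rdname rat_rbind
#' @export
rat_cbind <- function(...) {
  xs <- list(...)
  rat_mat(do.call(cbind, lapply(xs, `[[`, "num")),
          do.call(cbind, lapply(xs, `[[`, "den")))
}

#' Test whether every entry is exactly zero
#' @param x a `rat_mat`.
#' @export
rat_is_zero <- function(x) all(x$num == 0)

#' Exact equality of two rational matrices
#' @param a,b `rat_mat` objects.
#' @export
rat_equal <- function(a, b) {
  identical(dim(a$num), dim(b$num)) && all(a$num == b$num) && all(a$den == b$den)
}

#' Numeric (double) view of a rational matrix
#' @param x a `rat_mat`.
#' @export
rat_numeric <- function(x) x$num / x$den

#' Exact rank by fraction-free Gaussian elimination
#'
#' Rows are first cleared to integers (multiplying by the lcm of the row's
#' denominators), then a Bareiss-style fraction-free elimination counts
#' pivots. All divisions are exact, so the result is the true rank.
#'
#' @param x a `rat_mat`.
#' @return integer rank.
#' @export
rat_rank <- function(x) {
  m <- x$num / x$den  # start from reduced entries
  A <- .integer_rows(x)
  nr <- nrow(A); nc <- ncol(A)
  rank <- 0L; prev <- 1
  row <- 1L
  for (col in seq_len(nc)) {
    piv <- which(A[row:nr, col] != 0)
    if (length(piv) == 0) next
    piv <- piv[1] + row - 1L
    if (piv != row) A[c(row, piv), ] <- A[c(piv, row), ]
    for (i in seq_len(nr)[-seq_len(row)]) {
      A[i, ] <- (A[i, ] * A[row, col] - A[row, ] * A[i, col]) / prev
    }
    .check_exact(A)
    prev <- A[row, col]
    rank <- rank + 1L
    row <- row + 1L
    if (row > nr) break
  }
  rank
}

.integer_rows <- function(x) {
  A <- matrix(0, nrow(x$num), ncol(x$num))
  for (i in seq_len(nrow(A))) {
    dens <- x$den[i, ]
    l <- 1
    for (d in unique(dens)) l <- l * d / .gcd2(l, d)
    A[i, ] <- x$num[i, ] * (l / x$den[i, ])
  }
  .check_exact(A)
  A
}

#' Exact null-space basis of a rational matrix
#'
#' Reduced row echelon form over the rationals; free columns generate the
#' basis. Used by the brute-force extreme-ray oracle, not by the
#' basic-pathways pipeline itself (which has its null basis in closed form).
#'
#' @param x a `rat_mat` with n columns.
#' @return a `rat_mat` with n rows whose columns span the null space
#'   (zero columns omitted; a 0-column matrix if the null space is trivial).
#' @export
rat_nullspace <- function(x) {
  n <- ncol(x$num)
  R <- x
  nr <- nrow(R$num)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > nr) break
    piv <- which(R$num[row:nr, col] != 0)
    if (length(piv) == 0) next
    piv <- piv[1] + row - 1L
    if (piv != row) {
      R$num[c(row, piv), ] <- R$num[c(piv, row), ]
      R$den[c(row, piv), ] <- R$den[c(piv, row), ]
    }
    # normalize pivot row to leading 1
    pn <- R$num[row, col]; pd <- R$den[row, col]
    rr <- .rat_reduce(R$num[row, ] * pd, R$den[row, ] * pn)
    R$num[row, ] <- rr$num; R$den[row, ] <- rr$den
    for (i in seq_len(nr)[-row]) {
      f_n <- R$num[i, col]; f_d <- R$den[i, col]
      if (f_n != 0) {
        rr <- .rat_reduce(R$num[i, ] * R$den[row, ] * f_d - R$num[row, ] * R$den[i, ] * f_n,
                          R$den[i, ] * R$den[row, ] * f_d)
        R$num[i, ] <- rr$num; R$den[i, ] <- rr$den
      }
    }
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  free <- setdiff(seq_len(n), pivots)
  if (length(free) == 0) return(rat_mat(matrix(0, n, 0)))
  num <- matrix(0, n, length(free)); den <- matrix(1, n, length(free))
  for (k in seq_along(free)) {
    fc <- free[k]
    num[fc, k] <- 1
    for (ri in seq_along(pivots)) {
      num[pivots[ri], k] <- -R$num[ri, fc]
      den[pivots[ri], k] <- R$den[ri, fc]
    }
  }
  rat_mat(num, den)
}

#' Canonical primitive scaling of each column
#'
#' Clears denominators and divides by the gcd of the numerators so every
#' column becomes a primitive integer vector; the leading nonzero entry is
#' made positive only when `positive = TRUE` is not requested (columns of a
#' basic-pathways matrix are already nonnegative, so no sign flip occurs).
#'
#' @param x a `rat_mat`.
#' @return list with `mat` (the canonicalized `rat_mat`) and `scales`
#'   (per-column rational scale applied, as a 2 x ncol matrix of p/q).
#' @export
rat_canonicalize_columns <- function(x) {
  nc <- ncol(x$num)
  scales <- matrix(1, 2, nc)
  num <- x$num; den <- x$den
  for (j in seq_len(nc)) {
    if (all(num[, j] == 0)) next
    l <- 1
    for (d in unique(den[, j])) l <- l * d / .gcd2(l, d)
    v <- num[, j] * (l / den[, j])
    .check_exact(v)
    g <- 0
    for (e in v) g <- .gcd2(g, e)
    v <- v / g
    num[, j] <- v; den[, j] <- 1
    scales[1, j] <- l; scales[2, j] <- g
  }
  list(mat = rat_mat(num, den), scales = scales)
}
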