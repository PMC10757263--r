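#' @title Stoichiometric models of growing cells
#' @description
#' A `stoichiometric_model` holds the internal-reaction stoichiometry S0
#' (metabolites x reactions, exact rationals), per-reaction reversibility
#' flags and per-metabolite dilution rates. In a cell growing exponentially,
#' every metabolite is drained by a dilution pseudo-reaction; augmenting S0
#' with the diagonal block -Lambda yields the full stoichiometric matrix
#' S = (S0 | -Lambda) whose null space is the object of study.
#' @name model_core
NULL

#' Construct a validated stoichiometric model
#'
#' @param metabolite_ids character vector of unique metabolite identifiers.
#' @param reaction_ids character vector of unique internal-reaction ids.
#' @param S0 a `rat_mat`, metabolites x reactions, of net stoichiometric
#'   coefficients (products positive, substrates negative).
#' @param reversible logical vector per reaction (default all FALSE).
#' @param dilution_rates a `rat_mat` column vector of strictly positive
#'   per-metabolite dilution/degradation rates (units 1/time; default 1,
#'   the pure exponential-growth case with the growth rate absorbed into
#'   the dilution fluxes).
#' @return an object of class `stoichiometric_model`.
#' @export
stoichiometric_model <- function(metabolite_ids, reaction_ids, S0,
                                 reversible = NULL, dilution_rates = NULL) {
  m <- length(metabolite_ids); r <- length(reaction_ids)
  if (m < 1 || r < 1) stop("model needs at least one metabolite and one reaction", call. = FALSE)
  if (anyDuplicated(metabolite_ids)) stop("duplicate metabolite ids", call. = FALSE)
  if (anyDuplicated(reaction_ids)) stop("duplicate reaction ids", call. = FALSE)
  if (!inherits(S0, "rat_mat")) stop("S0 must be a rat_mat", call. = FALSE)
  if (nrow(S0$num) != m || ncol(S0$num) != r)
    stop("S0 dimensions do not match id lists", call. = FALSE)
  zero_cols <- which(colSums(S0$num != 0) == 0)
  if (length(zero_cols) > 0)
    stop("all-zero stoichiometry for reaction(s): ",
         paste(reaction_ids[zero_cols], collapse = ", "), call. = FALSE)
  if (is.null(reversible)) reversible <- rep(FALSE, r)
  if (length(reversible) != r) stop("reversible flag per reaction required", call. = FALSE)
  if (is.null(dilution_rates)) dilution_rates <- rat_mat(rep(1, m))
  if (!inherits(dilution_rates, "rat_mat") || nrow(dilution_rates$num) != m ||
      ncol(dilution_rates$num) != 1)
    stop("dilution_rates must be an m x 1 rat_mat", call. = FALSE)
  if (any(dilution_rates$num <= 0))
    stop("dilution rates must be strictly positive", call. = FALSE)
  structure(list(metabolite_ids = as.character(metabolite_ids),
                 reaction_ids = as.character(reaction_ids),
                 S0 = S0, reversible = as.logical(reversible),
                 dilution_rates = dilution_rates,
                 provenance = character(0)),
            class = "stoichiometric_model")
}

#' @export
print.stoichiometric_model <- function(x, ...) {
  cat(sprintf("<stoichiometric_model: %d metabolites, %d internal reactions>\n",
              length(x$metabolite_ids), length(x$reaction_ids)))
  invisible(x)
}

#' Load a model from its JSON description
#'
#' Schema: `{"metabolites":[{"id":str,"dilution_rate":"p/q" optional}],
#' "reactions":[{"id":str,"reversible":bool,"stoichiometry":{met:"p/q"}}]}`.
#' Coefficients may be integers, `"p/q"` strings or finite decimal strings;
#' all are converted to exact rationals.
#'
#' @param path path to the JSON model file.
#' @return a validated `stoichiometric_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$metabolites) || is.null(doc$reactions))
    stop("model schema requires 'metabolites' and 'reactions' fields", call. = FALSE)
  mets <- vapply(doc$metabolites, function(m) {
    if (is.null(m$id)) stop("metabolite entry missing 'id'", call. = FALSE)
    as.character(m$id)
  }, character(1))
  dil_num <- numeric(length(mets)); dil_den <- numeric(length(mets))
  for (i in seq_along(doc$metabolites)) {
    dr <- doc$metabolites[[i]]$dilution_rate
    pq <- if (is.null(dr)) c(1, 1) else .parse_rational_scalar(as.character(dr))
    dil_num[i] <- pq[1]; dil_den[i] <- pq[2]
  }
  rids <- vapply(doc$reactions, function(r) {
    if (is.null(r$id)) stop("reaction entry missing 'id'", call. = FALSE)
    as.character(r$id)
  }, character(1))
  rev <- vapply(doc$reactions, function(r) isTRUE(r$reversible), logical(1))
  num <- matrix(0, length(mets), length(rids))
  den <- matrix(1, length(mets), length(rids))
  for (j in seq_along(doc$reactions)) {
    st <- doc$reactions[[j]]$stoichiometry
    if (is.null(st) || length(st) == 0)
      stop("reaction '", rids[j], "' has empty stoichiometry", call. = FALSE)
    for (met in names(st)) {
      i <- match(met, mets)
      if (is.na(i))
        stop("reaction '", rids[j], "' references unknown metabolite '", met, "'",
             call. = FALSE)
      pq <- .parse_rational_scalar(as.character(st[[met]]))
      num[i, j] <- pq[1]; den[i, j] <- pq[2]
    }
  }
  stoichiometric_model(mets, rids, rat_mat(num, den), rev,
                       rat_mat(dil_num, dil_den))
}

#' Write a model to its JSON description
#' @param model a `stoichiometric_model`.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  dil <- rat_format(model$dilution_rates)
  mets <- lapply(seq_along(model$metabolite_ids), function(i)
    list(id = model$metabolite_ids[i], dilution_rate = unname(dil[i, 1])))
  rxns <- lapply(seq_along(model$reaction_ids), function(j) {
    nz <- which(model$S0$num[, j] != 0)
    st <- as.list(rat_format(rat_sub(model$S0, nz, j))[, 1])
    names(st) <- model$metabolite_ids[nz]
    list(id = model$reaction_ids[j],
         reversible = model$reversible[j],
         stoichiometry = st)
  })
  jsonlite::write_json(list(metabolites = mets, reactions = rxns), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Augment a model with growth-dilution columns
#'
#' Appends one dilution pseudo-reaction per metabolite, giving the full
#' stoichiometric matrix S = (S0 | -Lambda) of shape m x (r + m). Dilution
#' columns come last, in metabolite order.
#'
#' @param model a `stoichiometric_model`.
#' @return list with `S` (`rat_mat`), `column_roles` (character: reaction id
#'   or `"dilution:<metabolite>"`), and `model` (the source model).
#' @export
augment_with_dilution <- function(model) {
  m <- length(model$metabolite_ids)
  lam_num <- diag(-model$dilution_rates$num[, 1], m, m)
  lam_den <- matrix(1, m, m)
  diag(lam_den) <- model$dilution_rates$den[, 1]
  S <- rat_cbind(model$S0, rat_mat(lam_num, lam_den))
  roles <- c(model$reaction_ids, paste0("dilution:", model$metabolite_ids))
  structure(list(S = S, column_roles = roles, model = model),
            class = "augmented_stoichiometry")
}

#' Flux labels for the augmented system (reaction ids then dilution ids)
#' @param model a `stoichiometric_model`.
#' @export
flux_labels <- function(model) {
  c(model$reaction_ids, paste0("delta_", model$metabolite_ids))
}

#' Reverse the direction of named reactions
#'
#' Negates the corresponding columns of S0, the convention for treating a
#' reversible reaction as running in its reverse direction while keeping all
#' fluxes nonnegative. Applying it twice restores the model.
#'
#' @param model a `stoichiometric_model`.
#' @param reaction_ids reaction ids to reverse.
#' @return a new `stoichiometric_model`.
#' @export
reverse_reactions <- function(model, reaction_ids) {
  idx <- match(reaction_ids, model$reaction_ids)
  if (anyNA(idx))
    stop("unknown reaction id(s): ",
         paste(reaction_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  S0 <- model$S0
  S0$num[, idx] <- -S0$num[, idx]
  out <- stoichiometric_model(model$metabolite_ids, model$reaction_ids, S0,
                              model$reversible, model$dilution_rates)
  out$provenance <- c(model$provenance,
                      paste0("reversed:", paste(reaction_ids, collapse = ",")))
  out
}

#' Split reversible reactions into forward/reverse column pairs
#'
#' For each named reaction a new column equal to its negation is inserted
#' immediately after it (id suffix `"_rev"`), so both directions carry
#' nonnegative fluxes.
#'
#' @param model a `stoichiometric_model`.
#' @param reaction_ids reaction ids to split (may be empty).
#' @return a new `stoichiometric_model` with r + length(reaction_ids) reactions.
#' @export
split_reversible <- function(model, reaction_ids) {
  if (length(reaction_ids) == 0) return(model)
  idx <- match(reaction_ids, model$reaction_ids)
  if (anyNA(idx))
    stop("unknown reaction id(s): ",
         paste(reaction_ids[is.na(idx)], collapse = ", "), call. = FALSE)
  cols <- list(); ids <- character(0); rev <- logical(0)
  for (j in seq_along(model$reaction_ids)) {
    cols[[length(cols) + 1]] <- rat_sub(model$S0, j = j)
    ids <- c(ids, model$reaction_ids[j]); rev <- c(rev, model$reversible[j])
    if (j %in% idx) {
      cols[[length(cols) + 1]] <- rat_scale(rat_sub(model$S0, j = j), -1)
      ids <- c(ids, paste0(model$reaction_ids[j], "_rev")); rev <- c(rev, FALSE)
    }
  }
  out <- stoichiometric_model(model$metabolite_ids, ids, do.call(rat_cbind, cols),
                              rev, model$dilution_rates)
  out$provenance <- c(model$provenance,
                      paste0("split:", paste(reaction_ids, collapse = ",")))
  out
}

#' Save / load a rational matrix as labelled TSV
#'
#' First row holds column labels, first column row labels; cells are integer
#' or `"p/q"` strings, so the round trip is lossless.
#'
#' @param M a `rat_mat`.
#' @param path file path.
#' @param row_labels,col_labels label vectors matching the matrix shape.
#' @export
save_matrix <- function(M, path, row_labels = NULL, col_labels = NULL) {
  if (is.null(row_labels)) row_labels <- paste0("r", seq_len(nrow(M$num)))
  if (is.null(col_labels)) col_labels <- paste0("c", seq_len(ncol(M$num)))
  if (length(row_labels) != nrow(M$num) || length(col_labels) != ncol(M$num))
    stop("label lengths do not match matrix dimensions", call. = FALSE)
  cells <- rat_format(M)
  lines <- c(paste(c("", col_labels), collapse = "\t"),
             vapply(seq_len(nrow(cells)), function(i)
               paste(c(row_labels[i], cells[i, ]), collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname save_matrix
#' @return `load_matrix` returns a list with `M` (`rat_mat`), `row_labels`,
#'   `col_labels`.
#' @export
load_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2) stop("matrix TSV needs a header and at least one row", call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  header <- parts[[1]]
  ncol <- length(header) - 1
  body <- parts[-1]
  if (any(vapply(body, length, integer(1)) != ncol + 1))
    stop("ragged rows in matrix TSV: ", path, call. = FALSE)
  row_labels <- vapply(body, `[[`, character(1), 1)
  cells <- t(vapply(body, function(p) p[-1], character(ncol)))
  if (ncol == 1) cells <- matrix(unlist(lapply(body, `[[`, 2)), ncol = 1)
  M <- rat_parse(cells)
  list(M = M, row_labels = row_labels, col_labels = header[-1])
}
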