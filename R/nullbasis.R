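#' @title Fundamental null basis and degeneracy reduction
#' @description
#' For S = (S0 | -Lambda) the null space has dimension r and a basis in
#' closed form: G = (I_r ; Lambda^-1 S0). Each column g_j sets internal flux
#' j to one and reads off the dilution fluxes that balance it. No linear
#' solve is needed; S G = 0 by construction.
#'
#' A metabolite whose S0 row has no strictly positive entry can never be
#' produced, so at steady state its concentration (hence its dilution flux)
#' and every flux consuming it must vanish. `reduce_network` removes such
#' rows and their incident columns to a fixed point before the pipeline runs.
#' @name nullbasis
NULL

#' Build the fundamental null basis G = (I_r ; Lambda^-1 S0)
#'
#' @param model a `stoichiometric_model` in which every row of S0 has at
#'   least one strictly positive entry (run [reduce_network()] first if not).
#' @return object of class `fundamental_null_basis` with fields `G`
#'   (`rat_mat`, (r + m) x r), `model`, `row_labels` (flux labels),
#'   `col_labels` (`g1..gr`).
#' @export
build_fundamental_null_basis <- function(model) {
  m <- length(model$metabolite_ids); r <- length(model$reaction_ids)
  bad <- which(apply(model$S0$num, 1, function(x) all(x <= 0)))
  if (length(bad) > 0)
    stop("degenerate row(s) without a positive entry (metabolites: ",
         paste(model$metabolite_ids[bad], collapse = ", "),
         "); run reduce_network first", call. = FALSE)
  # bottom block Lambda^-1 S0
  inv_num <- model$dilution_rates$den[, 1]
  inv_den <- model$dilution_rates$num[, 1]
  bot <- rat_mat(model$S0$num * inv_num, model$S0$den * inv_den)
  G <- rat_rbind(rat_mat(diag(1, r, r)), bot)
  structure(list(G = G, model = model,
                 row_labels = flux_labels(model),
                 col_labels = paste0("g", seq_len(r))),
            class = "fundamental_null_basis")
}

#' @export
print.fundamental_null_basis <- function(x, ...) {
  cat(sprintf("<fundamental_null_basis: %d x %d>\n", nrow(x$G$num), ncol(x$G$num)))
  invisible(x)
}

#' Remove degenerate metabolites and their incident reactions
#'
#' Iterates to a fixed point: drop every S0 row lacking a strictly positive
#' entry, then every column with a nonzero entry in a dropped row (removing
#' columns can create new positive-free rows, hence the loop). Removed
#' metabolites have steady-state concentration zero; removed reactions have
#' flux zero in every admissible pathway.
#'
#' @param model a `stoichiometric_model`.
#' @return list with `reduced_model` (a `stoichiometric_model`, or `NULL`
#'   when everything is removed and the only admissible pathway is v = 0),
#'   `removed_metabolites`, `removed_reactions`, `iterations`.
#' @export
reduce_network <- function(model) {
  keep_m <- seq_along(model$metabolite_ids)
  keep_r <- seq_along(model$reaction_ids)
  num <- model$S0$num
  iterations <- 0L
  repeat {
    sub <- num[keep_m, keep_r, drop = FALSE]
    bad_rows <- keep_m[apply(sub, 1, function(x) all(x <= 0))]
    if (length(bad_rows) == 0 || length(keep_r) == 0) break
    iterations <- iterations + 1L
    touch <- apply(num[bad_rows, keep_r, drop = FALSE] != 0, 2, any)
    keep_r <- keep_r[!touch]
    keep_m <- setdiff(keep_m, bad_rows)
    if (length(keep_m) == 0 || length(keep_r) == 0) {
      keep_m <- if (length(keep_r) == 0) integer(0) else keep_m
      if (length(keep_r) == 0) keep_m <- integer(0)
      break
    }
  }
  removed_m <- setdiff(seq_along(model$metabolite_ids), keep_m)
  removed_r <- setdiff(seq_along(model$reaction_ids), keep_r)
  reduced <- NULL
  if (length(keep_m) > 0 && length(keep_r) > 0) {
    reduced <- stoichiometric_model(
      model$metabolite_ids[keep_m], model$reaction_ids[keep_r],
      rat_sub(model$S0, keep_m, keep_r),
      model$reversible[keep_r],
      rat_sub(model$dilution_rates, keep_m, 1))
    reduced$provenance <- c(model$provenance, "reduced")
  }
  list(reduced_model = reduced,
       removed_metabolites = model$metabolite_ids[removed_m],
       removed_reactions = model$reaction_ids[removed_r],
       iterations = iterations)
}

#' Zero-pad a reduced-system flux vector back to the original indexing
#'
#' Removed internal reactions and the dilution fluxes of removed metabolites
#' get exact zeros; remaining entries are placed at their original positions.
#'
#' @param model the original `stoichiometric_model`.
#' @param reduction result of [reduce_network()] on `model`.
#' @param v_reduced `rat_mat` column vector of length r' + m' for the
#'   reduced augmented system.
#' @return `rat_mat` column vector of length r + m for the original system.
#' @export
pad_reduced_pathway <- function(model, reduction, v_reduced) {
  red <- reduction$reduced_model
  if (is.null(red)) stop("reduction removed the whole network; only v = 0 remains", call. = FALSE)
  r <- length(model$reaction_ids); m <- length(model$metabolite_ids)
  rp <- length(red$reaction_ids); mp <- length(red$metabolite_ids)
  if (nrow(v_reduced$num) != rp + mp)
    stop("reduced vector has wrong length", call. = FALSE)
  num <- matrix(0, r + m, 1); den <- matrix(1, r + m, 1)
  ridx <- match(red$reaction_ids, model$reaction_ids)
  midx <- match(red$metabolite_ids, model$metabolite_ids)
  num[ridx, 1] <- v_reduced$num[seq_len(rp), 1]
  den[ridx, 1] <- v_reduced$den[seq_len(rp), 1]
  num[r + midx, 1] <- v_reduced$num[rp + seq_len(mp), 1]
  den[r + midx, 1] <- v_reduced$den[rp + seq_len(mp), 1]
  rat_mat(num, den)
}

#' Null-space dimension by exact rank
#'
#' @param S a `rat_mat`.
#' @return `ncol(S) - rank(S)`, with rank from fraction-free elimination.
#' @export
nullity <- function(S) {
  ncol(S$num) - rat_rank(S)
}
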