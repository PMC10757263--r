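#' @title Built-in case model and random-model generator
#' @description
#' A compact coupled glycolysis / TCA-cycle model in a growing cell:
#' thirteen species A, B, C, D, E, F, G, H, I, K, L, T, P (K, L, T, P are
#' NADH, NAD+, ATP and ADP) and twelve internal reactions — three nutrient
#' imports (glucose A, NAD+ L, ADP P), the investment and payback phases of
#' glycolysis, pyruvate fates (entry into the TCA cycle or anaerobic
#' reduction to lactate E), and the four lumped TCA steps. With one
#' dilution pseudo-reaction per species the full stoichiometric matrix is
#' 13 x 25 and the null space has dimension 12.
#' @name fixtures
NULL

.case_reactions <- function() {
  # each entry: id, stoichiometry (metabolite = coefficient)
  list(
    v1  = c(A = 1),                              # glucose import
    v2  = c(L = 1),                              # NAD+ import
    v3  = c(P = 1),                              # ADP import
    v4  = c(A = -1, T = -2, B = 1, P = 2),       # investment phase
    v5  = c(B = -1, L = -1, C = 1, K = 1),       # oxidation to 1,3-BPG
    v6  = c(C = -1, P = -2, D = 1, T = 2),       # payback: pyruvate + ATP
    v7  = c(D = -1, L = -1, F = 1, K = 1),       # pyruvate -> citrate pool
    v8  = c(D = -1, K = -1, E = 1, L = 1),       # pyruvate -> lactate
    v9  = c(F = -1, H = 1),                      # citrate -> isocitrate
    v10 = c(H = -1, I = 1),                      # isocitrate -> succinyl-CoA
    v11 = c(I = -1, P = -3, G = 1, T = 3),       # oxidative ATP-coupled leg
    v12 = c(G = -1, L = -1, F = 1, K = 1)        # cycle closure to citrate
  )
}

#' Construct the coupled glycolysis / TCA-cycle case model
#'
#' Metabolite order A, B, C, D, E, F, G, H, I, K, L, T, P and reaction
#' order v1..v12 are frozen so that flux positions (v13..v25 are the
#' dilution fluxes delta_A..delta_P) are stable across the package. All
#' dilution rates are 1.
#'
#' @return a `stoichiometric_model` with m = 13, r = 12.
#' @export
build_glycolysis_tca_model <- function() {
  mets <- c("A", "B", "C", "D", "E", "F", "G", "H", "I", "K", "L", "T", "P")
  rxns <- .case_reactions()
  num <- matrix(0, length(mets), length(rxns))
  for (j in seq_along(rxns)) {
    st <- rxns[[j]]
    num[match(names(st), mets), j] <- st
  }
  stoichiometric_model(mets, names(rxns), rat_mat(num))
}

#' The reference TCA-only basic pathway (BP12s)
#'
#' The 25-entry nonnegative null vector that runs the full TCA cycle with
#' no glycolysis: NAD+ and ADP imports feed the cycle, NADH and ATP leave
#' by dilution.
#'
#' @return a 25 x 1 `rat_mat`.
#' @export
bp12s_reference <- function() {
  rat_mat(c(0, 1, 3, 0, 0, 0, 0, 0, 1, 1, 1, 1,
            0, 0, 0, 0, 0, 0, 0, 0, 0, 1, 0, 3, 0))
}

#' Case-study variants
#'
#' * `forward`: the base model.
#' * `tca_reversed`: the four TCA reactions v9, v10, v11, v12 reversed
#'   (column negation) — the cycle running clockwise; no degeneracy.
#' * `v12_reversed`: only v12 reversed; no degeneracy.
#' * `v9_reversed`: only v9 reversed; metabolite H loses its only producer,
#'   so reduction removes it (included to exercise the degenerate path).
#' * `v9_split`: the reverse of v9 appended as an extra column, giving 13
#'   internal reactions.
#'
#' `expected_metrics` carries the reference values each variant should
#' reproduce (null-space dimension, W shape, singleton row rank,
#' deficiency index) used by the validation suite.
#'
#' @param name variant name.
#' @return list with `name`, `model`, `expected_metrics`.
#' @export
build_variant <- function(name) {
  base <- build_glycolysis_tca_model()
  switch(name,
    forward = list(
      name = name, model = base,
      expected_metrics = list(nullity = 12, W_rows = 25, W_cols = 12,
                              G_row_rank = 13, G_sparsity = 0.84,
                              W_row_rank = 11, W_deficiency = 2,
                              W_sparsity = 0.84, type_I_cost = 2)),
    tca_reversed = list(
      name = name,
      model = reverse_reactions(base, c("v9", "v10", "v11", "v12")),
      expected_metrics = list(nullity = 12, W_rows = 25, W_cols = 12,
                              non_extreme_columns = 1)),
    v12_reversed = list(
      name = name, model = reverse_reactions(base, "v12"),
      expected_metrics = list(nullity = 12, W_rows = 25, W_cols = 12,
                              W_row_rank = 12, W_deficiency = 2)),
    v9_reversed = list(
      name = name, model = reverse_reactions(base, "v9"),
      expected_metrics = list(removed_metabolites = "H")),
    v9_split = list(
      name = name, model = split_reversible(base, "v9"),
      expected_metrics = list(W_rows = 26, W_cols = 13)),
    stop("unknown case-study variant: ", name, call. = FALSE)
  )
}

#' Run the full pipeline on a case-study variant and report its metrics
#'
#' Computes, for the named variant: the augmented S and its null-space
#' dimension, the fundamental-basis metrics (singleton row index,
#' sparsity), the basic-pathways metrics on the elimination output W
#' (singleton row rank, deficiency index, sparsity, Type-I transform
#' cost G -> W), and the post-sparsification metrics. Where the variant
#' carries `expected_metrics`, each computed value is compared and an
#' `all_match` flag is set. For the `tca_reversed` variant the flux cone
#' does not span the null space and the elimination reports failure; the
#' report then carries the diagnosis instead of W metrics.
#'
#' @param name variant name (see [build_variant()]).
#' @return list of computed metrics (flat, suitable for JSON).
#' @export
case_study_report <- function(name = "forward") {
  variant <- build_variant(name)
  model <- variant$model
  red <- reduce_network(model)
  out <- list(variant = name,
              removed_metabolites = length(red$removed_metabolites),
              removed_reactions = length(red$removed_reactions))
  if (length(red$removed_metabolites) == 0) {
    work <- model
  } else if (!is.null(red$reduced_model)) {
    work <- red$reduced_model
  } else {
    out$elimination <- "empty"
    return(out)
  }
  S <- augment_with_dilution(work)$S
  out$S_rows <- nrow(S$num); out$S_cols <- ncol(S$num)
  out$nullity <- nullity(S)
  G <- build_fundamental_null_basis(work)
  pg <- singleton_profile(G$G)
  out$G_row_rank <- pg$row_rank
  out$G_sparsity <- sparsity(G$G, 2)
  basis <- tryCatch(eliminate_negatives(G), error = function(e) e)
  if (inherits(basis, "error")) {
    out$elimination <- "failed"
    out$elimination_error <- conditionMessage(basis)
  } else {
    out$elimination <- "ok"
    p <- basis$profile
    out$W_rows <- nrow(basis$W$num); out$W_cols <- ncol(basis$W$num)
    out$W_row_rank <- p$row_rank
    out$W_deficiency <- p$deficiency_index
    out$W_sparsity <- sparsity(basis$W, 2)
    out$type_I_cost <- singleton_cost(G$G, basis$W)$type_I
    sp <- sparsify(basis)
    out$Ws_row_rank <- sp$profile$row_rank
    out$Ws_deficiency <- sp$profile$deficiency_index
    out$Ws_sparsity <- sparsity(sp$W, 2)
  }
  exp <- variant$expected_metrics
  cmp <- intersect(names(exp), names(out))
  if (length(cmp) > 0)
    out$all_match <- all(vapply(cmp, function(k)
      isTRUE(all.equal(out[[k]], exp[[k]])), logical(1)))
  out
}

#' Random stoichiometric models for property tests
#'
#' Generates S0 with small integer entries (magnitude 1..3) at the given
#' density; every row is resampled until its entries sum to a strictly
#' positive value, and no column is all-zero. Positive row sums make the
#' uniform flux v0 = 1 strictly admissible, so the flux cone is solid
#' (full-dimensional in the null space) and a nonnegative basis is
#' guaranteed to exist — the pipeline runs without reduction.
#' `degenerate_rows` plants that many extra
#' positive-free rows (all entries <= 0, at least one negative) to exercise
#' [reduce_network()]; the planted metabolite ids are recorded in the
#' `planted_degenerate` attribute.
#'
#' @param m,r metabolite and reaction counts.
#' @param density fraction of nonzero entries in (0, 1].
#' @param seed integer seed; the generator is the only randomness in the
#'   package.
#' @param degenerate_rows number of planted positive-free rows (default 0).
#' @return a `stoichiometric_model` (with attribute `planted_degenerate`).
#' @export
random_model <- function(m, r, density = 0.5, seed = 1, degenerate_rows = 0) {
  if (m < 1 || r < 1 || density <= 0 || density > 1)
    stop("invalid random_model parameters", call. = FALSE)
  set.seed(seed)
  num <- matrix(0, m, r)
  for (i in seq_len(m)) {
    repeat {
      row <- ifelse(stats::runif(r) < density,
                    sample(c(-3:-1, 1:3), r, replace = TRUE), 0)
      if (sum(row) > 0) break
    }
    num[i, ] <- row
  }
  # no all-zero column: drop a random positive unit into empty columns
  # (keeps row sums positive)
  for (j in which(colSums(num != 0) == 0)) num[sample(m, 1), j] <- 1
  mets <- paste0("M", seq_len(m))
  planted <- character(0)
  if (degenerate_rows > 0) {
    extra <- matrix(0, degenerate_rows, r)
    for (k in seq_len(degenerate_rows)) {
      repeat {
        row <- ifelse(stats::runif(r) < density,
                      -sample(1:3, r, replace = TRUE), 0)
        if (any(row < 0)) break
      }
      extra[k, ] <- row
    }
    num <- rbind(num, extra)
    planted <- paste0("D", seq_len(degenerate_rows))
    mets <- c(mets, planted)
  }
  model <- stoichiometric_model(mets, paste0("R", seq_len(r)), rat_mat(num))
  attr(model, "planted_degenerate") <- planted
  model
}
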