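# shared shortcuts for the suite

run_pipeline <- function(model, sparsify_pass = FALSE) {
  basis <- eliminate_negatives(build_fundamental_null_basis(model))
  if (sparsify_pass) basis <- sparsify(basis)
  basis
}

# a bare basic_pathway_basis around a given W, for cone-module tests that
# need no model context
fake_basis <- function(W) {
  structure(list(W = W, op_log = list(), profile = singleton_profile(W),
                 source = NULL, model = NULL,
                 row_labels = paste0("f", seq_len(nrow(W$num))),
                 col_labels = paste0("BP", seq_len(ncol(W$num)))),
            class = "basic_pathway_basis")
}

# independent floating-point rank oracle (base R QR), safe for the small
# integer matrices used in tests
qr_rank <- function(M) qr(rat_numeric(M))$rank

rat_vec <- function(...) rat_mat(c(...))
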