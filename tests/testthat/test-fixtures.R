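test_that("case model reconstruction satisfies its validation constraints", {
  m <- build_glycolysis_tca_model()
  expect_identical(m$metabolite_ids,
                   c("A", "B", "C", "D", "E", "F", "G", "H", "I", "K", "L", "T", "P"))
  expect_identical(length(m$reaction_ids), 12L)
  aug <- augment_with_dilution(m)
  expect_identical(dim(aug$S$num), c(13L, 25L))
  # the reference TCA pathway is an exact null vector
  expect_true(rat_is_zero(rat_mult(aug$S, bp12s_reference())))
  # exactly one singleton row in S0: lactate E, produced only by v8
  s0_singles <- which(rowSums(m$S0$num != 0) == 1)
  expect_identical(m$metabolite_ids[s0_singles], "E")
  # hence G has r + 1 = 13 singleton rows
  G <- build_fundamental_null_basis(m)$G
  expect_identical(singleton_profile(G)$row_rank, 13L)
  expect_equal(sparsity(G, 2), 0.84)
})

test_that("reversing v9 alone makes isocitrate H degenerate", {
  v <- build_variant("v9_reversed")
  red <- reduce_network(v$model)
  expect_true("H" %in% red$removed_metabolites)
  # the reactions touching H go with it
  expect_true(all(c("v9", "v10") %in% red$removed_reactions))
})

test_that("v9-split variant yields a 26 x 13 basis", {
  v <- build_variant("v9_split")
  basis <- run_pipeline(v$model)
  expect_identical(dim(basis$W$num), c(26L, 13L))
  S <- augment_with_dilution(v$model)$S
  expect_true(rat_is_zero(rat_mult(S, basis$W)))
})

test_that("v12-reversed variant reduces to nothing and gives a singleton-complete basis", {
  v <- build_variant("v12_reversed")
  red <- reduce_network(v$model)
  expect_identical(length(red$removed_metabolites), 0L)
  basis <- run_pipeline(v$model)
  # the computed basis is singleton complete: all 12 columns are extreme rays
  expect_true(basis$profile$complete)
  expect_identical(basis$profile$row_rank, 13L)
  S <- augment_with_dilution(v$model)$S
  for (j in seq_len(12))
    expect_true(is_extreme_ray(S, rat_sub(basis$W, j = j)))
})

test_that("TCA-reversed flux cone does not span: elimination reports failure", {
  v <- build_variant("tca_reversed")
  red <- reduce_network(v$model)
  expect_identical(length(red$removed_metabolites), 0L)
  S <- augment_with_dilution(v$model)$S
  expect_identical(nullity(S), 12L)
  # glycolysis nets no spare ATP, so the reversed oxidative leg can never
  # run; no nonnegative basis of the 12-dim null space exists
  expect_error(run_pipeline(v$model), "elimination failed")
  rep <- case_study_report("tca_reversed")
  expect_identical(rep$elimination, "failed")
})

test_that("random models are seed-reproducible with guaranteed structure", {
  a <- random_model(3, 4, density = 0.5, seed = 7)
  b <- random_model(3, 4, density = 0.5, seed = 7)
  expect_true(rat_equal(a$S0, b$S0))
  expect_false(rat_equal(a$S0, random_model(3, 4, density = 0.5, seed = 8)$S0))
  for (seed in 1:10) {
    m <- random_model(sample(2:6, 1), sample(2:7, 1), density = 0.4,
                      seed = 400 + seed)
    expect_true(all(apply(m$S0$num, 1, function(x) any(x > 0))))
    expect_true(all(colSums(m$S0$num != 0) > 0))
  }
  expect_error(random_model(0, 3), "invalid")
})

test_that("case-study report reproduces the frozen forward metrics", {
  rep <- case_study_report("forward")
  expect_identical(rep$S_rows, 13L)
  expect_identical(rep$S_cols, 25L)
  expect_identical(rep$nullity, 12L)
  expect_identical(rep$G_row_rank, 13L)
  expect_equal(rep$G_sparsity, 0.84)
  expect_identical(rep$W_row_rank, 11L)
  expect_identical(rep$W_deficiency, 2L)
  expect_identical(rep$type_I_cost, 2L)
  # computed W sparsity: 97 nonzeros of 300 entries
  expect_equal(rep$W_sparsity, 0.68)
  expect_identical(rep$Ws_deficiency, 1L)
})
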