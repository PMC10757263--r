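test_that("column operations behave and leave the input untouched", {
  M <- rat_mat(matrix(c(1, 0, -1, 0, 1, 1), 3, 2))
  expect_true(rat_equal(apply_column_op(M, column_op("scale", 1)), M))
  sw <- apply_column_op(M, column_op("swap", 1, 2))
  expect_true(rat_equal(apply_column_op(sw, column_op("swap", 1, 2)), M))
  ad <- apply_column_op(M, column_op("add_multiple", 1, 2))
  expect_equal(rat_numeric(ad), matrix(c(1, 1, 0, 0, 1, 1), 3, 2))
  expect_equal(rat_numeric(M)[2, 1], 0)  # original unchanged
  expect_error(apply_column_op(M, column_op("scale", 5)), "out of range")
  expect_error(apply_column_op(M, column_op("scale", 1, coef_num = 0)), "zero")
})

test_that("hand-checked toy elimination matches", {
  # S0 = [[-1, 1], [1, 0]]: one op c1 <- c1 + c2 clears the single negative
  m <- stoichiometric_model(c("A", "B"), c("R1", "R2"),
                            rat_mat(matrix(c(-1, 1, 1, 0), 2, 2)))
  basis <- run_pipeline(m)
  expect_equal(rat_numeric(basis$W),
               matrix(c(1, 0, 1, 1, 0, 1, 1, 0), 4, 2, byrow = TRUE))
  expect_identical(length(basis$op_log), 1L)
  S <- augment_with_dilution(m)$S
  expect_true(rat_is_zero(rat_mult(S, basis$W)))
})

test_that("an already-nonnegative G passes through unchanged", {
  m <- stoichiometric_model(c("A", "B"), c("R1", "R2"),
                            rat_mat(matrix(c(1, 0, 0, 2), 2, 2)))
  basis <- run_pipeline(m)
  expect_true(rat_equal(basis$W, build_fundamental_null_basis(m)$G))
  expect_identical(length(basis$op_log), 0L)
})

test_that("end-to-end on random models: W >= 0, S W = 0, rank r", {
  for (seed in 1:40) {
    m <- random_model(sample(2:6, 1), sample(2:8, 1), density = 0.55,
                      seed = 1000 + seed)
    basis <- run_pipeline(m)
    expect_true(all(basis$W$num >= 0))
    S <- augment_with_dilution(m)$S
    expect_true(rat_is_zero(rat_mult(S, basis$W)))
    expect_identical(rat_rank(basis$W), ncol(basis$W$num))
  }
})

test_that("replaying the operation log on G reproduces W bit-exactly", {
  m <- build_glycolysis_tca_model()
  G <- build_fundamental_null_basis(m)
  basis <- eliminate_negatives(G)
  expect_true(rat_equal(replay_column_ops(G$G, basis$op_log), basis$W))
  sp <- sparsify(basis)
  expect_true(rat_equal(replay_column_ops(G$G, sp$op_log), sp$W))
})

test_that("nonnegativity iff nonnegative coefficients on singleton-complete W", {
  set.seed(71)
  tested <- 0
  for (seed in 1:30) {
    m <- random_model(sample(2:5, 1), sample(2:6, 1), density = 0.6,
                      seed = 2000 + seed)
    basis <- run_pipeline(m)
    if (!basis$profile$complete) next
    tested <- tested + 1
    r <- ncol(basis$W$num)
    # forward: r >= 0 implies W r >= 0
    rv <- rat_mat(sample(0:4, r, TRUE))
    expect_true(all(rat_mult(basis$W, rv)$num >= 0))
    # reverse: any r with a negative component gives a negative flux
    rv$num[sample(r, 1), 1] <- -sample(1:3, 1)
    expect_true(any(rat_mult(basis$W, rv)$num < 0))
  }
  expect_gte(tested, 5)
})

test_that("singleton-complete W columns coincide with the brute-force extreme rays", {
  tested <- 0
  for (seed in c(2, 15, 21, 32, 33, 37, 40, 41)) {
    m <- random_model(3, 4, density = 0.6, seed = seed)
    basis <- run_pipeline(m)
    if (!basis$profile$complete) next
    tested <- tested + 1
    S <- augment_with_dilution(m)$S
    rays <- enumerate_extreme_rays_bruteforce(S)
    keys <- vapply(rays, function(v) paste(rat_format(v)[, 1], collapse = ","),
                   character(1))
    for (j in seq_len(ncol(basis$W$num))) {
      col <- rat_canonicalize_columns(rat_sub(basis$W, j = j))$mat
      expect_true(paste(rat_format(col)[, 1], collapse = ",") %in% keys)
    }
  }
  expect_gte(tested, 3)
})

test_that("sparsify preserves nonnegativity, rank and the null space", {
  m <- build_glycolysis_tca_model()
  basis <- run_pipeline(m)
  sp <- sparsify(basis)
  expect_true(all(sp$W$num >= 0))
  expect_identical(rat_rank(sp$W), 12L)
  S <- augment_with_dilution(m)$S
  expect_true(rat_is_zero(rat_mult(S, sp$W)))
  expect_lte(sum(sp$W$num != 0), sum(basis$W$num != 0))
  # disjoint column supports leave nothing to cancel
  id_m <- stoichiometric_model(c("A", "B"), c("R1", "R2"),
                               rat_mat(matrix(c(1, 0, 0, 2), 2, 2)))
  b2 <- run_pipeline(id_m)
  expect_true(rat_equal(sparsify(b2)$W, b2$W))
})

test_that("permuted pipelines yield valid (possibly different) bases", {
  m <- build_glycolysis_tca_model()
  basis <- run_pipeline(m)
  idperm <- permuted_basis(m, seq_along(m$metabolite_ids))
  expect_true(rat_equal(idperm$W, basis$W))

  S <- augment_with_dilution(m)$S
  perm <- rev(seq_along(m$metabolite_ids))
  pb <- permuted_basis(m, perm)
  expect_true(all(pb$W$num >= 0))
  expect_true(rat_is_zero(rat_mult(S, pb$W)))
  expect_identical(rat_rank(pb$W), 12L)
  expect_error(permuted_basis(m, c(1, 1, 3:13)), "permutation")
})
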