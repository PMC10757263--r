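test_that("admissibility is exact nonnegative null membership", {
  S <- rat_mat(matrix(c(1, -1), 1, 2))
  expect_true(is_admissible(S, rat_vec(0, 0)))
  expect_true(is_admissible(S, rat_vec(2, 2)))
  expect_false(is_admissible(S, rat_vec(1, 2)))
  expect_false(is_admissible(S, rat_vec(-1, -1)))
  expect_error(is_admissible(S, rat_vec(1)), "length")
})

test_that("the reference TCA pathway is admissible for the case model", {
  S <- augment_with_dilution(build_glycolysis_tca_model())$S
  bp <- bp12s_reference()
  expect_true(is_admissible(S, bp))
  flipped <- bp
  flipped$num[2, 1] <- -flipped$num[2, 1]
  expect_false(is_admissible(S, flipped))
})

test_that("decomposition recovers unit and mixed coefficients exactly", {
  m <- build_glycolysis_tca_model()
  basis <- run_pipeline(m)
  r <- ncol(basis$W$num)
  # v = BP3 -> e3
  d <- decompose_pathway(basis, rat_sub(basis$W, j = 3))
  expect_equal(d$coefficients$num[, 1], replace(rep(0, r), 3, 1))
  # v = 2 BP1 + 3 BP5
  v <- rat_sub(basis$W, j = 1)
  v <- rat_scale(v, 2) + rat_scale(rat_sub(basis$W, j = 5), 3)
  d2 <- decompose_pathway(basis, v)
  expect_equal(d2$coefficients$num[, 1], replace(replace(rep(0, r), 1, 2), 5, 3))
  expect_true(rat_equal(rat_mult(basis$W, d2$coefficients), v))
  expect_identical(length(d2$independent_components), r)
  expect_identical(nrow(d2$dependent_components), nrow(basis$W$num) - r)
  expect_error(decompose_pathway(basis, rat_mat(rep(1, 25))), "null space")
})

test_that("round trip is exact for random coefficients, deficient or not", {
  for (seed in c(2, 6, 11, 18)) {
    m <- random_model(sample(2:5, 1), sample(3:6, 1), density = 0.6,
                      seed = 3000 + seed)
    basis <- run_pipeline(m)
    r <- ncol(basis$W$num)
    set.seed(seed)
    rv <- rat_mat(sample(0:5, r, TRUE))
    v <- rat_mult(basis$W, rv)
    d <- decompose_pathway(basis, v)
    expect_true(rat_equal(rat_mult(basis$W, d$coefficients), v))
    if (basis$profile$complete) expect_true(rat_equal(d$coefficients, rv))
  }
})

test_that("a deficient-basis decomposition can carry a negative coefficient", {
  m <- build_glycolysis_tca_model()
  basis <- run_pipeline(m)            # deficiency 2 on the case model
  expect_identical(basis$profile$deficiency_index, 2L)
  # v = BP12 - BP7 is admissible (it is the TCA-only pathway)
  v <- rat_sub(basis$W, j = 12) - rat_sub(basis$W, j = 7)
  S <- augment_with_dilution(m)$S
  expect_true(is_admissible(S, v))
  d <- decompose_pathway(basis, v)
  expect_equal(d$coefficients$num[7, 1], -1)
  expect_equal(d$coefficients$num[12, 1], 1)
  expect_true(rat_equal(rat_mult(basis$W, d$coefficients), v))
})

test_that("deficiency-one lower bound matches a direct-evaluation oracle", {
  W <- rat_mat(matrix(c(1, 2, 0, 2, 1, 1), 3, 2))
  basis <- fake_basis(W)
  expect_identical(basis$profile$deficient_columns, 1L)
  fixed <- rat_vec(0, 1)
  b <- coefficient_lower_bounds(basis, fixed)
  expect_equal(rat_numeric(b$lower_bound)[1, 1], -1 / 2)
  # oracle: scan r1 on a rational grid around the bound
  for (r1 in c(-1, -3 / 4, -1 / 2, -1 / 4, 0, 1)) {
    rv <- rat_mat(c(r1 * 4, 4), den = c(4, 4))
    expect_identical(all(rat_mult(W, rv)$num >= 0), r1 >= -1 / 2)
    expect_identical(b$feasible(rv), r1 >= -1 / 2)
  }
  # boundary point has a zero flux
  at_bound <- rat_mat(c(-1, 2), den = c(2, 2))
  expect_true(any(rat_mult(W, at_bound)$num == 0))

  complete <- fake_basis(rat_mat(diag(2)))
  expect_error(coefficient_lower_bounds(complete, rat_vec(1, 1)), "complete")
})

test_that("directional r_Min reproduces the 1-D bound and is boundary-tight", {
  W <- rat_mat(matrix(c(1, 2, 0, 2, 1, 1), 3, 2))
  basis <- fake_basis(W)
  fixed <- rat_vec(0, 1)
  rmin <- r_min_surface(basis, fixed, 1)
  expect_equal(rat_numeric(rmin)[1, 1], 1 / 2)
  # rho slightly inside feasible, outside infeasible, at bound a zero entry
  inside <- rat_mat(c(-1, 4), den = c(4, 4))
  outside <- rat_mat(c(-3, 4), den = c(4, 4))
  expect_true(all(rat_mult(W, inside)$num >= 0))
  expect_true(any(rat_mult(W, outside)$num < 0))
  at <- rat_mat(c(-1, 2), den = c(2, 2))
  expect_true(any(rat_mult(W, at)$num == 0))
  expect_error(r_min_surface(basis, fixed, -1), "nonnegative")
})

test_that("deficiency-two constraint system and directional bound are consistent", {
  # columns 1 and 2 deficient, 3 and 4 pinned by singleton rows 4 and 5
  W <- rat_mat(matrix(c(1, 2, 1, 0, 0, 1,
                        2, 1, 1, 0, 0, 3,
                        1, 0, 1, 1, 0, 1,
                        0, 1, 1, 0, 1, 0), 6, 4))
  basis <- fake_basis(W)
  expect_identical(basis$profile$deficiency_index, 2L)
  expect_identical(basis$profile$deficient_columns, c(1L, 2L))
  fixed <- rat_vec(0, 0, 2, 2)
  b <- coefficient_lower_bounds(basis, fixed)
  # constraint rows are exactly those with both deficient entries positive
  expect_identical(b$constraint_rows, which(W$num[, 1] > 0 & W$num[, 2] > 0))
  # c_j equals the complete-column combination on those rows
  fixed0 <- rat_vec(0, 0, 2, 2)
  expect_true(rat_equal(b$c_values,
                        rat_sub(rat_mult(W, fixed0), b$constraint_rows, 1)))
  # directional bound: at rho = r_Min the flux hits the boundary exactly
  g <- rat_vec(1, 1)
  rmin <- r_min_surface(basis, fixed, g)
  mk <- function(rho_n, rho_d) {
    rv <- fixed
    rv$num[1:2, 1] <- -rho_n; rv$den[1:2, 1] <- rho_d
    rat_mat(rv$num, rv$den)
  }
  at <- rat_mult(W, mk(rmin$num[1, 1], rmin$den[1, 1]))
  expect_true(all(at$num >= 0))
  expect_true(any(at$num == 0))
  # strictly inside is feasible, strictly outside is not (direct evaluation)
  expect_true(all(rat_mult(W, mk(rmin$num[1, 1], 2 * rmin$den[1, 1]))$num >= 0))
  expect_true(any(rat_mult(W, mk(2 * rmin$num[1, 1], rmin$den[1, 1]))$num < 0))
})

test_that("support-rank extreme test matches known cases", {
  S <- rat_mat(matrix(c(1, -1), 1, 2))
  expect_true(is_extreme_ray(S, rat_vec(1, 1)))
  expect_error(is_extreme_ray(S, rat_vec(0, 0)), "admissible|ray")
  chain <- rat_mat(matrix(c(1, 0, -1, 1, 0, -1), 2, 3))
  expect_true(is_extreme_ray(chain, rat_vec(1, 1, 1)))
})

test_that("brute-force enumeration finds complete extreme-ray sets", {
  S <- rat_mat(matrix(c(1, -1), 1, 2))
  rays <- enumerate_extreme_rays_bruteforce(S)
  expect_identical(length(rays), 1L)
  expect_equal(rays[[1]]$num[, 1], c(1, 1))
  chain <- rat_mat(matrix(c(1, 0, -1, 1, 0, -1), 2, 3))
  rays2 <- enumerate_extreme_rays_bruteforce(chain)
  expect_identical(length(rays2), 1L)
  expect_equal(rays2[[1]]$num[, 1], c(1, 1, 1))
  expect_error(enumerate_extreme_rays_bruteforce(rat_mat(matrix(1, 1, 20))),
               "force")
})

test_that("every enumerated ray passes the rank test; rays have minimal support", {
  for (seed in c(12, 29)) {
    m <- random_model(3, 4, density = 0.6, seed = seed)
    S <- augment_with_dilution(m)$S
    rays <- enumerate_extreme_rays_bruteforce(S)
    expect_gt(length(rays), 0)
    supports <- lapply(rays, function(v) which(v$num[, 1] != 0))
    for (i in seq_along(rays)) {
      expect_true(is_extreme_ray(S, rays[[i]]))
      for (j in seq_along(rays)) {
        if (i != j)
          expect_false(all(supports[[j]] %in% supports[[i]]) &&
                         length(supports[[j]]) < length(supports[[i]]))
      }
    }
  }
})
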