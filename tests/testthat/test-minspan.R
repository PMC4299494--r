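test_that("the chain model yields the single pathway (1,1,1)", {
  red <- preprocess(chain_model())
  pm <- minspan(red, solver_fast())
  expect_equal(ncol(pm$P), 1L)
  v <- pm$P[, 1]
  expect_equal(unname(v / v["R1"]), c(1, 1, 1), tolerance = 1e-9)
  # maxspan and randspan coincide: only one direction exists
  expect_equal(abs(maxspan(red, solver_fast())$P),
               abs(pm$P), tolerance = 1e-9)
  rs <- randspan(red, 1, solver_fast())
  expect_equal(abs(rs[[1]]$P), abs(pm$P), tolerance = 1e-9)
})

test_that("the toy model yields four pathways including glycolysis and TCA", {
  toy <- toy_glycolysis_tca()
  red <- preprocess(toy)
  pm <- minspan(red, solver_fast())
  expect_equal(ncol(pm$P), 4L)
  sup <- lapply(seq_len(4), function(j)
    sort(rownames(pm$P)[abs(pm$P[, j]) > 1e-6]))
  expect_true(list(sort(attr(toy, "glycolysis_support"))) %in% sup)
  expect_true(list(sort(attr(toy, "tca_support"))) %in% sup)
  expect_true(verify_basis(pm, red)$pass)
})

test_that("replacement columns extend the basis rank by construction", {
  red <- preprocess(toy_glycolysis_tca())
  N <- orthonormal_nullspace(red)
  x <- N[, 1]
  r <- solve_replacement(red, x, solver_fast())
  expect_equal(r$status, "optimal")
  expect_gt(abs(sum(x * r$v)), 0.1 - 1e-9)
  expect_equal(qr(cbind(N[, -1], r$v))$rank, 4L)
  # support matches the sparsest circuit that spans this direction
  orc <- brute_force_sparsest_basis(red)
  xw <- abs(as.numeric(crossprod(orc$P, x)))
  spans <- which(xw > 1e-8)
  expect_gt(length(spans), 0L)
  best <- min(colSums(abs(orc$P[, spans, drop = FALSE]) > 1e-6))
  expect_lte(sum(abs(r$v) > 1e-6), best)
})

test_that("the MILP sweep equals the brute-force optimum on small models", {
  for (sd in 1:8) {
    nm <- 3 + (sd %% 4); nr <- nm + 2 + (sd %% 3)
    red <- preprocess(random_consistent_model(nm, nr, 0.3, seed = 200 + sd))
    o <- brute_force_sparsest_basis(red)
    ms <- minspan(red, solver_options(rel_gap = 1e-6, time_limit = 10))
    expect_equal(ms$nnz, o$nnz)
    expect_true(verify_basis(ms, red)$pass)
    expect_true(verify_basis(o, red)$pass)
  }
})

test_that("disjoint-support cycles are returned exactly by the oracle", {
  red <- preprocess(two_cycle_model())
  orc <- brute_force_sparsest_basis(red)
  sup <- lapply(seq_len(ncol(orc$P)), function(j)
    which(abs(orc$P[, j]) > 1e-6))
  expect_equal(sort(vapply(sup, length, integer(1))), c(2L, 2L))
  expect_length(intersect(sup[[1]], sup[[2]]), 0L)
})

test_that("total nnz is stable across solver seeds even if supports differ", {
  red <- preprocess(toy_glycolysis_tca())
  a <- minspan(red, solver_options(time_limit = 10, seed = 1))
  b <- minspan(red, solver_options(time_limit = 10, seed = 99))
  expect_equal(a$nnz, b$nnz)
})

test_that("randspan is reproducible under a fixed seed", {
  red <- preprocess(toy_glycolysis_tca())
  r1 <- randspan(red, 2, solver_options(time_limit = 5, seed = 3))
  r2 <- randspan(red, 2, solver_options(time_limit = 5, seed = 3))
  expect_equal(r1[[1]]$P, r2[[1]]$P)
  expect_equal(r1[[2]]$P, r2[[2]]$P)
})

test_that("verify_basis flags constructed violations", {
  red <- preprocess(toy_glycolysis_tca())
  pm <- minspan(red, solver_fast())
  ok <- verify_basis(pm, red)
  expect_true(ok$pass)
  expect_lt(ok$residual, 1e-9)
  broken <- pm$P; broken[, 2] <- 0
  expect_false(verify_basis(broken, red)$checks[["rank"]])
  flipped <- pm$P
  irr <- which(red$base$lb >= 0)
  j <- which(colSums(abs(flipped[irr, , drop = FALSE]) > 1e-6) > 0)[1]
  i <- irr[abs(flipped[irr, j]) > 1e-6][1]
  flipped[i, j] <- -abs(flipped[i, j])
  expect_gt(verify_basis(flipped, red)$sign_violations, 0)
})

test_that("the oracle guard rejects oversized instances", {
  red <- preprocess(random_consistent_model(12, 24, 0.3, seed = 5))
  expect_error(brute_force_sparsest_basis(red), "too large")
})
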