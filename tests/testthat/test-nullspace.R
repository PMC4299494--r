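test_that("the bounded simplex agrees with an independent LP solver", {
  skip_if_not_installed("pracma")
  set.seed(42)
  checked <- 0L
  for (trial in 1:40) {
    m <- sample(2:6, 1); n <- m + sample(1:6, 1)
    A <- matrix(sample(-2:2, m * n, TRUE), m, n)
    lower <- stats::runif(n, -6, 0); upper <- stats::runif(n, 0, 8)
    x0 <- stats::runif(n, lower, upper)
    rhs <- as.numeric(A %*% x0); obj <- stats::rnorm(n)
    r <- minspan:::lp_bounded(obj, A, rhs, lower, upper)
    pr <- tryCatch(pracma::linprog(cc = obj, A = diag(n), b = upper - lower,
                                   Aeq = A, beq = rhs - as.numeric(A %*% lower),
                                   maxiter = 1000),
                   error = function(e) NULL, warning = function(w) NULL)
    if (is.null(pr) || pr$errno != 1) next
    checked <- checked + 1L
    expect_equal(r$status, "optimal")
    expect_equal(r$objval, pr$fval + sum(obj * lower),
                 tolerance = 1e-6)
  }
  expect_gte(checked, 20L)
  inf <- minspan:::lp_bounded(c(1, 1), matrix(c(1, 1), 1, 2), 10,
                              c(0, 0), c(2, 2))
  expect_equal(inf$status, "infeasible")
})

test_that("preprocessing retains the toy network whole at rank 14", {
  red <- preprocess(toy_glycolysis_tca())
  expect_equal(length(red$base$rxns), 18L)
  expect_equal(red$r, 14L)
  expect_equal(red$kept_index, 1:18)
})

test_that("dead-end reactions are removed as blocked", {
  m <- chain_model()
  # append a reaction producing a metabolite nothing consumes
  S <- rbind(cbind(m$S, 0), c(0, 0, 0, 1))
  rownames(S)[3] <- "C"; colnames(S)[4] <- "DEAD"
  m2 <- metabolic_model(c("A", "B", "C"), colnames(S), S,
                        lb = c(m$lb, 0), ub = c(m$ub, 1000))
  red <- preprocess(m2)
  expect_false("DEAD" %in% red$base$rxns)
  expect_true(any(red$report$rxn == "DEAD" & red$report$action == "removed"))
})

test_that("preprocessing is idempotent on already-reduced models", {
  red <- preprocess(toy_glycolysis_tca())
  red2 <- preprocess(red$base)
  expect_equal(length(red2$base$rxns), length(red$base$rxns))
  expect_equal(red2$kept_index, seq_along(red$base$rxns))
})

test_that("the orthonormal basis spans null(S) with the rank-nullity count", {
  red <- preprocess(toy_glycolysis_tca())
  N <- orthonormal_nullspace(red)
  expect_equal(ncol(N), 4L)
  expect_lt(max(abs(red$base$S %*% N)), 1e-9)
  expect_equal(crossprod(N), diag(4), tolerance = 1e-9)
  for (sd in 1:5) {
    m <- random_consistent_model(3 + sd, 6 + 2 * sd, 0.4, seed = sd)
    red <- preprocess(m)
    N <- orthonormal_nullspace(red)
    expect_equal(ncol(N), length(red$base$rxns) - red$r)
    expect_lt(max(abs(red$base$S %*% N)), 1e-9)
  }
})

test_that("the chain's unique null direction is (1,1,1)/sqrt(3)", {
  red <- preprocess(chain_model())
  N <- orthonormal_nullspace(red)
  expect_equal(abs(as.numeric(N)), rep(1 / sqrt(3), 3), tolerance = 1e-9)
})

test_that("blocked detection agrees with circuit enumeration on small models", {
  for (sd in 1:5) {
    m <- random_consistent_model(3, 6, 0.5, seed = 100 + sd)
    red <- preprocess(m)
    orc <- brute_force_sparsest_basis(red)
    # every reaction of a consistent model appears in some feasible circuit
    blocked <- blocked_reactions(red$base)
    covered <- rowSums(abs(orc$P) > 1e-6) > 0
    expect_false(any(blocked))
    # and conversely circuits only use unblocked reactions
    expect_true(all(!blocked[covered]))
  }
})

test_that("an empty null space is reported as 'no pathways exist'", {
  S <- matrix(c(-1, 1), 2, 1, dimnames = list(c("A", "B"), "R1"))
  m <- metabolic_model(c("A", "B"), "R1", S, lb = 0, ub = 1000)
  expect_error(preprocess(m), "no pathways")
})
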