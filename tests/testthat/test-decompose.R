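red_toy <- preprocess(toy_glycolysis_tca())
pm_toy <- minspan(red_toy, solver_fast())

test_that("hit-and-run samples are feasible, seeded, and ray-bound on chains", {
  red <- preprocess(chain_model())
  s <- sample_fluxes(red, NULL, 100, seed = 3)
  expect_equal(nrow(s$V), 100L)
  ratio <- s$V / s$V[, 2]
  expect_equal(max(abs(ratio - 1), na.rm = TRUE), 0, tolerance = 1e-9)
  expect_true(all(s$V >= matrix(red$base$lb, 100, 3, byrow = TRUE) - 1e-9))
  s1 <- sample_fluxes(red_toy, NULL, 300, seed = 11)
  s2 <- sample_fluxes(red_toy, NULL, 300, seed = 11)
  expect_identical(s1$V, s2$V)
  expect_lt(max(abs(red_toy$base$S %*% t(s1$V))), 1e-6)
})

test_that("growth normalisation divides by the median and is idempotent", {
  s <- sample_fluxes(red_toy, NULL, 50, seed = 2)
  halved <- normalize_by_growth(s, rep(2, 50))
  expect_equal(halved$V, s$V / 2)
  again <- normalize_by_growth(halved, rep(1, 50))
  expect_equal(again$V, halved$V)
  expect_error(normalize_by_growth(s, rep(0, 50)), "positive")
})

test_that("decomposition inverts the pathway expansion exactly", {
  d <- ncol(pm_toy$P)
  a1 <- decompose(pm_toy, t(pm_toy$P[, 1, drop = FALSE]))
  expect_equal(as.numeric(a1$A), c(1, rep(0, d - 1)), tolerance = 1e-9)
  v <- 2 * pm_toy$P[, 1] + 3 * pm_toy$P[, 2]
  a2 <- decompose(pm_toy, t(v))
  expect_equal(as.numeric(a2$A), c(2, 3, rep(0, d - 2)), tolerance = 1e-9)
  set.seed(4)
  Al <- matrix(stats::rnorm(200 * d), 200, d)
  back <- decompose(pm_toy, Al %*% t(pm_toy$P))
  expect_lt(max(abs(back$A - Al)), 1e-8)
  # vectors outside the null space are rejected
  bad <- matrix(stats::rnorm(ncol(pm_toy$P[, 1, drop = FALSE]) * 0 +
                             nrow(pm_toy$P)), 1)
  expect_error(decompose(pm_toy, bad), "tol_decomp")
})

test_that("the shift test flags planted shifts and nothing under identity", {
  s <- sample_fluxes(red_toy, NULL, 200, seed = 5)
  a <- decompose(pm_toy, s)
  none <- pathway_shift_test(a, a)
  expect_false(any(none$changed))
  expect_true(all(none$p == 1))
  shifted <- a
  sd2 <- stats::sd(shifted$A[, 2])
  shifted$A[, 2] <- shifted$A[, 2] + 10 * max(sd2, 1)
  res <- pathway_shift_test(a, shifted)
  expect_true(res$changed[2])
  expect_false(any(res$changed[-2]))
})

test_that("TF-pathway association excludes underpowered TFs", {
  toy <- toy_glycolysis_tca()
  memb <- pathway_gene_sets(pm_toy, toy, "gene")
  reg <- synthetic_regulon(memb, 3, 0, seed = 4)
  assoc <- tf_pathway_enrichment(memb, reg, p_cut = 0.01, model = toy)
  planted <- attr(reg, "planted")
  for (tf in names(planted))
    expect_true(planted[tf] %in% assoc$pathway[assoc$tf == tf])
  # a TF regulating a single reaction in a single pathway is removed
  reg1 <- structure(list(TFx = "gPYK"), class = "regulon")
  expect_equal(nrow(tf_pathway_enrichment(memb, reg1, model = toy)), 0L)
  # zero overlap yields no associations
  reg0 <- structure(list(TFy = c("nogene1", "nogene2")), class = "regulon")
  expect_equal(nrow(tf_pathway_enrichment(memb, reg0, model = toy)), 0L)
})

test_that("TF activity needs enrichment, not mere overlap", {
  assoc <- data.frame(tf = c("X", "X", "X", "Y"),
                      pathway = c("p1", "p2", "p3", "p9"),
                      p = 1e-4)
  K <- 40
  changed <- stats::setNames(rep(FALSE, K), sprintf("p%d", 1:K))
  none <- predict_tf_activity(changed, assoc)
  expect_false(any(none$active))
  changed[c("p1", "p2", "p3")] <- TRUE
  act <- predict_tf_activity(changed, assoc)
  x <- act[act$tf == "X", ]
  expect_true(x$active)
  expect_equal(x$p, stats::phyper(2, 3, 37, 3, lower.tail = FALSE))
  expect_equal(x$pct_changed_assoc, 100)
  expect_false(act[act$tf == "Y", "active"])
})

test_that("adding a changed associated pathway never weakens a TF's call", {
  assoc <- data.frame(tf = "X", pathway = c("p1", "p2", "p3"), p = 1e-4)
  K <- 20
  base_changed <- stats::setNames(c(TRUE, rep(FALSE, K - 1)),
                                  sprintf("p%d", 1:K))
  p_prev <- predict_tf_activity(base_changed, assoc)$p
  for (extra in c("p2", "p3")) {
    base_changed[extra] <- TRUE
    p_now <- predict_tf_activity(base_changed, assoc)$p
    expect_lte(p_now, p_prev + 1e-12)
    p_prev <- p_now
  }
})

test_that("type-I error of the shift test is controlled under the null", {
  flagged <- 0L; total <- 0L
  for (rep in 1:20) {
    s1 <- sample_fluxes(red_toy, NULL, 60, seed = 300 + rep)
    s2 <- sample_fluxes(red_toy, NULL, 60, seed = 300 + rep)
    res <- pathway_shift_test(decompose(pm_toy, s1), decompose(pm_toy, s2))
    flagged <- flagged + sum(res$changed); total <- total + nrow(res)
  }
  expect_lte(flagged / total, 0.075)
})

test_that("condition bounds implement atom flow, supplements and anaerobiosis", {
  # model with oxygen and two carbon sources (C6 and C2) plus biomass
  mets <- c("glc", "ac", "o2", "x", "bio")
  rx <- list(
    EX_glc = list(c(glc = -1), -10, 1000),
    EX_ac  = list(c(ac = -1), 0, 1000),
    EX_o2  = list(c(o2 = -1), -20, 1000),
    T1     = list(c(glc = -1, x = 1), 0, 1000),
    T2     = list(c(ac = -1, x = 1), 0, 1000),
    R_o2   = list(c(o2 = -1, x = 1), 0, 1000),
    BIO    = list(c(x = -1, bio = 1), 0, 1000),
    EX_bio = list(c(bio = -1), 0, 1000))
  S <- matrix(0, 5, 8, dimnames = list(mets, names(rx)))
  for (j in seq_along(rx)) S[names(rx[[j]][[1]]), j] <- rx[[j]][[1]]
  m <- metabolic_model(mets, names(rx), S,
                       vapply(rx, `[[`, numeric(1), 2),
                       vapply(rx, `[[`, numeric(1), 3),
                       biomass_id = "BIO",
                       formulas = c(glc = "C6H12O6", ac = "C2H4O2",
                                    o2 = "O2", x = "C3H6O3", bio = "C1"))
  an <- build_shift_bounds(m, condition_spec("anaerobic"))
  expect_equal(an$lb[an$rxn == "EX_o2"], 0)
  # biomass lower bound at 90% of the optimum under the new bounds
  expect_equal(an$lb[an$rxn == "BIO"], 0.9 * 10)
  ca <- build_shift_bounds(m, condition_spec("carbon", "ac"))
  expect_equal(ca$lb[ca$rxn == "EX_glc"], 0)
  expect_equal(ca$lb[ca$rxn == "EX_ac"], -30)   # 3x uptake for C2 vs C6
  expect_error(build_shift_bounds(m, condition_spec("carbon", "o2")),
               "lacks element")
})
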