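test_that("the toy fixture matches its printed dimensional facts", {
  toy <- toy_glycolysis_tca()
  expect_equal(dim(toy$S), c(14L, 18L))
  red <- preprocess(toy)
  expect_equal(red$r, 14L)
  expect_equal(length(red$base$rxns) - red$r, 4L)
  # immutable across calls and versions: checksum of the serialised fixture
  p <- withr::local_tempfile(fileext = ".json")
  write_model(toy, p, "json")
  expect_identical(unname(tools::md5sum(p)),
                   "cf48941b007e87ec98c2742abc3ec26c")
  expect_identical(toy_glycolysis_tca(), toy)
})

test_that("random consistent models are deterministic and unblocked", {
  m1 <- random_consistent_model(4, 7, 0.5, seed = 1)
  m2 <- random_consistent_model(4, 7, 0.5, seed = 1)
  expect_identical(m1, m2)
  expect_false(any(blocked_reactions(m1)))
  # preprocessing removes nothing (generator output is already consistent)
  red <- preprocess(m1)
  expect_equal(length(red$base$rxns), length(m1$rxns))
})

test_that("a minimal generated model has a one-dimensional null space", {
  m <- random_consistent_model(2, 3, 0.0, seed = 7)
  red <- preprocess(m)
  expect_equal(length(red$base$rxns) - red$r, 1L)
})

test_that("modular models are block-diagonal with block-local pathways", {
  mod <- random_modular_model(3, 4, 7, 0.3, seed = 5)
  blk <- attr(mod, "block")
  expect_equal(length(blk), length(mod$rxns))
  met_blk <- sub("_.*", "", mod$mets)
  rxn_blk <- sub("_.*", "", mod$rxns)
  nz <- which(mod$S != 0, arr.ind = TRUE)
  expect_true(all(met_blk[nz[, 1]] == rxn_blk[nz[, 2]]))
  expect_false(any(blocked_reactions(mod)))
})

test_that("planted regulons are deterministic subsets at zero noise", {
  red <- preprocess(toy_glycolysis_tca())
  pm <- minspan(red, solver_fast())
  memb <- pathway_gene_sets(pm, toy_glycolysis_tca(), "gene")
  r1 <- synthetic_regulon(memb, 3, 0, seed = 4)
  r2 <- synthetic_regulon(memb, 3, 0, seed = 4)
  expect_identical(unclass(r1)[], unclass(r2)[])
  planted <- attr(r1, "planted")
  for (tf in names(planted)) {
    pw_genes <- rownames(memb$M)[memb$M[, planted[tf]] == 1]
    expect_true(all(r1[[tf]] %in% pw_genes))
  }
})

test_that("noisy planted regulons are recovered by hypergeometric enrichment", {
  # 4 anti-correlated gene modules across many single-module pathways give
  # well-separated pathway gene sets for the planted TFs
  set.seed(77)
  n_mod <- 5; per <- 6; K <- 20
  module <- rep(seq_len(n_mod), each = per)
  gid <- sprintf("g%02d", seq_len(n_mod * per))
  M <- matrix(0L, length(gid), K,
              dimnames = list(gid, sprintf("pw%02d", seq_len(K))))
  for (j in seq_len(K))
    M[module == ((j - 1L) %% n_mod) + 1L & stats::runif(length(gid)) < 0.9, j] <- 1L
  memb <- membership_from_sets(apply(M, 2, function(c) gid[c == 1]))
  reg <- synthetic_regulon(memb, 20, 0.2, seed = 9)
  planted <- attr(reg, "planted")
  assoc <- tf_pathway_enrichment(memb, reg, p_cut = 0.01)
  hit <- vapply(names(planted), function(tf)
    planted[tf] %in% assoc$pathway[assoc$tf == tf], logical(1))
  expect_gte(mean(hit), 0.9)
})
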