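toy <- toy_glycolysis_tca()
red_p <- preprocess(toy)
pm_p <- minspan(red_p, solver_fast())

test_that("membership follows GPRs at gene and protein level", {
  memb <- pathway_gene_sets(pm_p, toy, "gene")
  expect_equal(ncol(memb$M), 4L)
  # the TCA column contains the full dehydrogenase complex
  tca <- which(apply(abs(pm_p$P) > 1e-6, 2, function(s)
    setequal(rownames(pm_p$P)[s], attr(toy, "tca_support"))))
  expect_true(all(c("gPDHa", "gPDHb", "gPDHc") %in%
                  rownames(memb$M)[memb$M[, tca] == 1]))
  # isozymes appear as two separate proteins
  mp <- pathway_gene_sets(pm_p, toy, "protein")
  prot <- rownames(mp$M)
  expect_true(all(c("gMEa", "gMEb") %in% prot))
  expect_true("gPDHa&gPDHb&gPDHc" %in% prot)
  expect_true(all(memb$M %in% c(0L, 1L)))
  expect_true(all(rowSums(memb$M) > 0))
})

test_that("the ubiquitous-gene filter removes only near-universal genes", {
  M <- matrix(0L, 6, 8,
              dimnames = list(sprintf("g%d", 1:6), sprintf("p%d", 1:8)))
  M["g1", ] <- 1L                       # in every pathway
  M["g2", 1] <- 1L                      # in exactly one
  for (g in 3:6) M[g, sample(8, 3)] <- 1L
  memb <- structure(list(M = M, level = "gene"), class = "membership_matrix")
  filt <- representative_gene_filter(memb, p_cut = 0.85)
  expect_false("g1" %in% rownames(filt$M))
  expect_true("g2" %in% rownames(filt$M))
  # no ubiquitous genes: identity
  memb2 <- structure(list(M = M[2:6, ], level = "gene"),
                     class = "membership_matrix")
  expect_equal(rownames(representative_gene_filter(memb2, 0.85)$M),
               rownames(M[2:6, ])[rowSums(M[2:6, ]) > 0])
})

test_that("binary co-occurrence correlation hits the degenerate corners", {
  M <- rbind(a = c(1L, 1L, 0L, 0L, 1L, 0L),
             b = c(1L, 1L, 0L, 0L, 1L, 0L),
             c = c(0L, 0L, 1L, 1L, 0L, 1L),
             d = c(1L, 0L, 1L, 0L, 1L, 1L))
  colnames(M) <- sprintf("p%d", 1:6)
  memb <- structure(list(M = M, level = "gene"), class = "membership_matrix")
  ct <- cooccurrence_correlation(memb, n_perm = 200, seed = 1)
  expect_equal(ct$rho[ct$id_a == "a" & ct$id_b == "b"], 1)
  expect_equal(ct$rho[ct$id_a == "a" & ct$id_b == "c"], -1)
  # Spearman on binary rows equals the phi coefficient used internally
  expect_equal(ct$rho[ct$id_a == "a" & ct$id_b == "d"],
               suppressWarnings(stats::cor(M["a", ], M["d", ],
                                           method = "spearman")))
  Mc <- rbind(M, e = rep(1L, 6))
  membc <- structure(list(M = Mc, level = "gene"),
                     class = "membership_matrix")
  expect_warning(cooccurrence_correlation(membc, n_perm = 50, seed = 1),
                 "constant")
})

test_that("permutation p-values are uniform under independence", {
  set.seed(9)
  M0 <- matrix(stats::rbinom(14 * 40, 1, 0.4), 14, 40,
               dimnames = list(sprintf("g%02d", 1:14), sprintf("p%d", 1:40)))
  M0 <- M0[apply(M0, 1, stats::sd) > 0, ]
  memb <- structure(list(M = M0, level = "gene"), class = "membership_matrix")
  ct <- cooccurrence_correlation(memb, n_perm = 500, seed = 3)
  ks <- suppressWarnings(stats::ks.test(ct$p, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("ROC analysis separates, calibrates and dominates its raw curve", {
  ct <- data.frame(id_a = sprintf("a%02d", 1:40),
                   id_b = sprintf("b%02d", 1:40),
                   rho = c(seq(0.5, 1, length.out = 20),
                           seq(-1, 0.4, length.out = 20)),
                   p = 0, kept = TRUE)
  gp <- ct[1:20, c("id_a", "id_b")]
  gn <- ct[21:40, c("id_a", "id_b")]
  perfect <- roc_analysis(ct, gp, gn)
  expect_equal(perfect$auc, 1)
  set.seed(2)
  aucs <- replicate(20, {
    lab <- sample(rep(c(TRUE, FALSE), 20))
    roc_analysis(ct, ct[lab, c("id_a", "id_b")],
                 ct[!lab, c("id_a", "id_b")])$raw_auc
  })
  se <- sqrt(stats::var(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * se)
  mixed <- c(1, 25, 3, 30, 7, 22, 15, 36, 9, 28)   # interleaved scores
  r <- roc_analysis(ct, ct[mixed, c("id_a", "id_b")],
                    ct[-mixed, c("id_a", "id_b")])
  expect_gte(r$auc, r$raw_auc)
})

test_that("AUC comparison follows the normal approximation of the SE", {
  ct <- data.frame(id_a = sprintf("a%02d", 1:40), id_b = sprintf("b%02d", 1:40),
                   rho = c(seq(0.5, 1, length.out = 20),
                           seq(-1, 0.4, length.out = 20)),
                   p = 0, kept = TRUE)
  gp <- ct[1:20, c("id_a", "id_b")]; gn <- ct[21:40, c("id_a", "id_b")]
  r <- roc_analysis(ct, gp, gn)
  expect_equal(compare_auc(r, r), 1)
  ra <- list(auc = 1, n_pos = 100, n_neg = 100)
  rb <- list(auc = 0.5, n_pos = 100, n_neg = 100)
  p <- compare_auc(ra, rb)
  expect_lt(p, 1e-6)
  expect_equal(compare_auc(rb, ra), p)
})

test_that("CSI is symmetric, maximal for duplicates, and top-15% calls", {
  set.seed(6)
  sets1 <- lapply(1:8, function(i) sample(sprintf("g%02d", 1:25), 6))
  names(sets1) <- sprintf("A%d", 1:8)
  sets2 <- c(sets1[1], lapply(1:5, function(i)
    sample(sprintf("g%02d", 1:25), 6)))
  names(sets2) <- sprintf("B%d", 1:6)      # B1 duplicates A1
  cs <- csi(list(defA = membership_from_sets(sets1),
                 defB = membership_from_sets(sets2)), t = 0.05)
  expect_equal(cs$C, t(cs$C))
  expect_true(all(cs$C >= 0 & cs$C <= 1))
  dup <- cs$C["defA:A1", "defB:B1"]
  expect_equal(dup, max(cs$C["defA:A1", -which(colnames(cs$C) == "defA:A1")]))
  offC <- cs$C[upper.tri(cs$C)]
  n_called <- sum(offC >= cs$similar_cut)
  expect_lte(abs(n_called - ceiling(0.15 * length(offC))),
             sum(offC == cs$similar_cut))
  # preset threshold is honoured
  cs2 <- csi(list(defA = membership_from_sets(sets1),
                  defB = membership_from_sets(sets2)), t = 0.0350)
  expect_equal(cs2$t, 0.0350)
})

test_that("nearest-neighbour assignment maps clones and flags uniques", {
  set.seed(8)
  sets <- lapply(1:6, function(i) sample(sprintf("g%02d", 1:20), 5))
  names(sets) <- sprintf("P%d", 1:6)
  cs <- csi(list(defA = membership_from_sets(sets),
                 defB = membership_from_sets(sets)), t = 0.05)
  kn <- knn_assign(cs, "defA")
  expect_true(all(kn$assignments$nearest_definition == "defB"))
  expect_equal(sub("defB:", "", kn$assignments$nearest),
               sub("defA:", "", kn$assignments$pathway))
  # a definition of unrelated random pathways is depleted as a knn target
  setsC <- lapply(1:6, function(i) sample(sprintf("h%02d", 1:20), 5))
  names(setsC) <- sprintf("R%d", 1:6)
  cs3 <- csi(list(defA = membership_from_sets(sets),
                  defB = membership_from_sets(sets),
                  defC = membership_from_sets(setsC)), t = 0.05)
  kn3 <- knn_assign(cs3, "defA")
  expect_equal(sum(kn3$assignments$nearest_definition == "defC"), 0L)
})

test_that("dual-perturbation set algebra matches its definition", {
  expect_equal(dual_perturbation_set(E1 = c("a", "b"), E2 = c("b", "c"),
                                     G1 = "c", G2 = c("c", "d")),
               c("a", "d"))
  expect_equal(dual_perturbation_set(c("a", "b"), c("a", "b"),
                                     c("x"), c("x")), character(0))
  expect_equal(dual_perturbation_set(c("a"), c("b"), character(0), c("z")),
               sort(c("a", "b", "z")))
})

test_that("gene-set TF enrichment ranks the true regulon first", {
  universe <- sprintf("g%03d", 1:100)
  reg <- list(TF1 = universe[1:10], TF2 = universe[41:60])
  res <- gene_set_tf_enrichment(universe[1:10], reg, universe)
  expect_equal(res$tf[1], "TF1")
  expect_lt(res$p[1], 1e-6)
  res0 <- gene_set_tf_enrichment(universe[90:95], reg, universe,
                                 correction = "none")
  expect_true(all(res0$p > 0.05))
  resb <- gene_set_tf_enrichment(universe[1:10], reg, universe, "bonferroni")
  expect_equal(resb$p_adj, pmin(1, resb$p * 2))
})

test_that("set statistics are equivariant under entity relabelling", {
  set.seed(3)
  M <- matrix(stats::rbinom(10 * 12, 1, 0.4), 10, 12,
              dimnames = list(sprintf("g%02d", 1:10), sprintf("p%d", 1:12)))
  M <- M[apply(M, 1, stats::sd) > 0, ]
  memb <- structure(list(M = M, level = "gene"), class = "membership_matrix")
  perm <- sample(nrow(M))
  M2 <- M[perm, ]
  memb2 <- structure(list(M = M2, level = "gene"),
                     class = "membership_matrix")
  ct1 <- cooccurrence_correlation(memb, n_perm = 100, seed = 5)
  ct2 <- cooccurrence_correlation(memb2, n_perm = 100, seed = 5)
  key <- function(ct) {
    k <- paste(pmin(ct$id_a, ct$id_b), pmax(ct$id_a, ct$id_b))
    stats::setNames(ct$rho, k)[order(k)]
  }
  expect_equal(key(ct1), key(ct2))
})
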