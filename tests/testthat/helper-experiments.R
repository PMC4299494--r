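# Study-scale experiments shared by the acceptance suite and scripts.

# Planted TF-activity recovery on a modular synthetic network: a regulon is
# planted on one pathway, the reference condition closes a reaction feeding
# that pathway, and the shifted condition reopens it.  Returns TRUE when
# the planted TF is predicted active.
tf_recovery_once <- function(mod, red, pm, memb, seed,
                             n_tfs = 8L, noise = 0.2, n_samples = 150L) {
  tolz <- 1e-6
  reg <- synthetic_regulon(memb, n_tfs, noise, seed = seed)
  planted <- attr(reg, "planted")
  assoc <- tf_pathway_enrichment(memb, reg, p_cut = 0.01, model = mod)
  tfs <- names(planted)[names(planted) %in% assoc$tf]
  if (!length(tfs)) return(NA)
  t_star <- tfs[which.max(vapply(tfs, function(t)
    sum(assoc$tf == t), numeric(1)))]
  p_hat <- planted[t_star]
  apaths <- assoc$pathway[assoc$tf == t_star]
  sup <- rownames(pm$P)[abs(pm$P[, p_hat]) > tolz]
  internal <- sup[!red$base$exchange[match(sup, red$base$rxns)]]
  if (length(internal)) sup <- internal
  score <- vapply(sup, function(r) {
    inpw <- colnames(pm$P)[abs(pm$P[r, ]) > tolz]
    sum(inpw %in% apaths) - 0.5 * sum(!inpw %in% apaths)
  }, numeric(1))
  r_star <- sup[which.max(score)]
  ref_b <- data.frame(rxn = r_star, lb = 0, ub = 0)
  v_ref <- sample_fluxes(red, ref_b, n_samples, seed = seed,
                         directions = pm$P)
  v_shf <- sample_fluxes(red, NULL, n_samples, seed = seed,
                         directions = pm$P)
  sh <- pathway_shift_test(decompose(pm, v_ref), decompose(pm, v_shf))
  act <- predict_tf_activity(stats::setNames(sh$changed, sh$pathway), assoc)
  isTRUE(act$active[act$tf == t_star])
}

# Modular planted membership for the correlation/ROC calibration: gene
# modules shared across single-module pathway draws; the gold-standard
# interaction list is co-membership with a fraction of spurious entries.
roc_recovery_once <- function(seed, n_mod = 4L, per = 8L, K = 60L,
                              incl = 0.9, noise = 0.1, n_perm = 300L) {
  set.seed(seed + 500L)
  module <- rep(seq_len(n_mod), each = per)
  gid <- sprintf("g%02d", seq_len(n_mod * per))
  M <- matrix(0L, length(gid), K,
              dimnames = list(gid, sprintf("pw%d", seq_len(K))))
  for (j in seq_len(K)) {
    mods <- sample(n_mod, 1)
    M[module %in% mods & stats::runif(length(gid)) < incl, j] <- 1L
  }
  M <- M[rowSums(M) > 0, , drop = FALSE]
  memb <- structure(list(M = M, level = "gene"), class = "membership_matrix")
  ct <- cooccurrence_correlation(memb, n_perm = n_perm, seed = seed)
  ents <- rownames(M)
  co <- tcrossprod(M) > 0
  pairs <- which(upper.tri(co), arr.ind = TRUE)
  lab <- co[upper.tri(co)]
  nsw <- round(noise * sum(lab))
  drop <- sample(which(lab), nsw); add <- sample(which(!lab), nsw)
  lab[drop] <- FALSE; lab[add] <- TRUE
  roc_analysis(ct,
               data.frame(id_a = ents[pairs[lab, 1]],
                          id_b = ents[pairs[lab, 2]]),
               data.frame(id_a = ents[pairs[!lab, 1]],
                          id_b = ents[pairs[!lab, 2]]))
}
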