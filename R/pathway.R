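# Gene/protein set extraction and pathway-set statistics: co-occurrence
# correlation against interaction gold standards, ROC convex-hull AUC with
# the Hanley-McNeil comparison, connection-specificity-index similarity
# across pathway definitions, representative-gene filtering, and the
# dual-perturbation gene-set algebra.

#' Gene or protein membership of pathways
#'
#' An entity belongs to a pathway when it appears in the GPR of any
#' reaction carrying a non-zero coefficient in that pathway's column.  At
#' protein level, each disjunct of the GPR's disjunctive normal form is one
#' protein (complexes keep their member genes joined by "&"), so isozymes
#' contribute one protein each.
#'
#' @param P a \code{\link{pathway_matrix}} (or plain matrix with reaction
#'   rownames).
#' @param model the \code{metabolic_model} supplying the GPRs.
#' @param level "gene" or "protein".
#' @param tol_zero coefficient threshold for pathway membership.
#' @return object of class \code{membership_matrix}: list with binary
#'   \code{M} (entities x pathways) and \code{level}.
#' @export
pathway_gene_sets <- function(P, model, level = c("gene", "protein"),
                              tol_zero = 1e-6) {
  level <- match.arg(level)
  M <- if (inherits(P, "pathway_matrix")) P$P else P
  if (is.null(rownames(M))) stop("pathway matrix lacks reaction rownames")
  missing_rxn <- setdiff(rownames(M), model$rxns)
  if (length(missing_rxn))
    stop("reactions not in model: ", paste(missing_rxn, collapse = ", "))
  extract <- if (level == "gene") gpr_genes else gpr_proteins
  ent_by_rxn <- lapply(model$gpr[match(rownames(M), model$rxns)],
                       function(g) extract(parse_gpr(g)))
  entities <- sort(unique(unlist(ent_by_rxn)))
  B <- matrix(0L, length(entities), ncol(M),
              dimnames = list(entities, colnames(M)))
  for (j in seq_len(ncol(M))) {
    act <- which(abs(M[, j]) > tol_zero)
    ents <- unique(unlist(ent_by_rxn[act]))
    if (length(ents)) B[ents, j] <- 1L
  }
  B <- B[rowSums(B) > 0, , drop = FALSE]
  structure(list(M = B, level = level), class = "membership_matrix")
}

#' Build a membership matrix from explicit sets
#' @param sets named list of member-id vectors (e.g. from
#'   \code{\link{read_gmt}}).
#' @param level "gene" or "protein".
#' @return a \code{membership_matrix}.
#' @export
membership_from_sets <- function(sets, level = "gene") {
  entities <- sort(unique(unlist(sets)))
  B <- matrix(0L, length(entities), length(sets),
              dimnames = list(entities, names(sets)))
  for (j in seq_along(sets)) B[unique(sets[[j]]), j] <- 1L
  structure(list(M = B, level = level), class = "membership_matrix")
}

#' Remove near-ubiquitous genes
#'
#' Pathway-enumeration bases assign mass-balancing gene products (e.g.
#' transporters) to nearly every pathway.  A gene is removed when the
#' hypergeometric probability of observing its pathway count or fewer --
#' treating the matrix's membership entries as draws over the gene x
#' pathway grid -- exceeds \code{p_cut}.
#'
#' @param membership a \code{membership_matrix}.
#' @param p_cut removal threshold (default 0.85).
#' @return a filtered \code{membership_matrix} (all-zero rows dropped).
#' @export
representative_gene_filter <- function(membership, p_cut = 0.85) {
  stopifnot(p_cut > 0, p_cut < 1)
  M <- membership$M
  G <- nrow(M); K <- ncol(M); Tot <- sum(M)
  kg <- rowSums(M)
  pg <- stats::phyper(kg - 1, K, G * K - K, Tot)
  keep <- pg <= p_cut
  if (!any(keep))
    stop("representative-gene filter removed every gene; raise p_cut")
  out <- M[keep, , drop = FALSE]
  out <- out[rowSums(out) > 0, , drop = FALSE]
  structure(list(M = out, level = membership$level),
            class = "membership_matrix")
}

#' Pairwise co-occurrence correlation with permutation filter
#'
#' Spearman rank correlation of the binary pathway-membership profiles for
#' every entity pair (for binary rows this equals the Pearson/phi
#' coefficient, which is used for speed).  Significance by a permutation
#' test that shuffles each entity's memberships across pathways (preserving
#' row sums); pairs with p > 0.05 are flagged not kept.
#'
#' @param membership a \code{membership_matrix} with >= 2 pathways.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @param keep_alpha significance cut for the kept flag (default 0.05).
#' @return data.frame of class \code{correlation_table}: columns
#'   \code{id_a}, \code{id_b}, \code{rho}, \code{p}, \code{kept}.
#' @export
cooccurrence_correlation <- function(membership, n_perm = 1000L, seed = 1L,
                                     keep_alpha = 0.05) {
  M <- membership$M
  if (ncol(M) < 2L) stop("need at least two pathways")
  sds <- apply(M, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping constant entity row(s): ",
            paste(rownames(M)[sds == 0], collapse = ", "))
    M <- M[sds > 0, , drop = FALSE]
  }
  G <- nrow(M)
  rho <- stats::cor(t(M))
  pr <- which(upper.tri(rho), arr.ind = TRUE)
  obs <- abs(rho[pr])
  n_gt <- n_eq <- numeric(nrow(pr))
  rng <- local_rng(seed)
  on.exit(rng$restore())
  K <- ncol(M)
  for (b in seq_len(n_perm)) {
    Mp <- t(apply(M, 1L, function(r) r[sample.int(K)]))
    rp <- abs(stats::cor(t(Mp))[pr])
    n_gt <- n_gt + (rp > obs + 1e-12)
    n_eq <- n_eq + (abs(rp - obs) <= 1e-12)
  }
  # randomised permutation p-value: exactly uniform under the null despite
  # the discreteness of binary-profile correlations
  u <- stats::runif(nrow(pr))
  p <- (n_gt + u * (1 + n_eq)) / (n_perm + 1)
  out <- data.frame(id_a = rownames(M)[pr[, 1]], id_b = rownames(M)[pr[, 2]],
                    rho = rho[pr], p = p, kept = p <= keep_alpha,
                    stringsAsFactors = FALSE)
  class(out) <- c("correlation_table", "data.frame")
  out
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' ROC analysis of correlations against a gold standard
#'
#' The correlation coefficient is the varied discrimination threshold; the
#' operating points are reduced to their convex hull (the attainable upper
#' envelope) and the area under the hull is reported.
#'
#' @param corr a \code{correlation_table}; only kept pairs are scored.
#' @param gold_pos,gold_neg data.frames of pairs (\code{id_a},
#'   \code{id_b}); must be disjoint.
#' @return list of class \code{roc_result}: \code{points} (fpr, tpr on the
#'   hull), \code{auc}, \code{raw_auc}, \code{coverage} (scored pair
#'   count), \code{n_pos}, \code{n_neg}.
#' @export
roc_analysis <- function(corr, gold_pos, gold_neg) {
  kp <- corr[corr$kept, , drop = FALSE]
  keys <- pair_key(kp$id_a, kp$id_b)
  pos <- unique(pair_key(gold_pos$id_a, gold_pos$id_b))
  neg <- unique(pair_key(gold_neg$id_a, gold_neg$id_b))
  if (length(intersect(pos, neg)))
    stop("gold standard positive and negative sets overlap")
  lab <- ifelse(keys %in% pos, 1L, ifelse(keys %in% neg, 0L, NA_integer_))
  use <- !is.na(lab)
  if (!any(lab[use] == 1L)) stop("no scored pairs overlap the positive set")
  if (!any(lab[use] == 0L)) stop("no scored pairs overlap the negative set")
  sc <- kp$rho[use]; y <- lab[use]
  np <- sum(y == 1L); nn <- sum(y == 0L)
  ths <- c(Inf, sort(unique(sc), decreasing = TRUE))
  tpr <- vapply(ths, function(t) sum(y == 1L & sc >= t) / np, numeric(1))
  fpr <- vapply(ths, function(t) sum(y == 0L & sc >= t) / nn, numeric(1))
  raw_auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  hull <- roc_hull(fpr, tpr)
  auc <- sum(diff(hull$fpr) * (utils::head(hull$tpr, -1) +
                               utils::tail(hull$tpr, -1)) / 2)
  structure(list(points = hull, auc = auc, raw_auc = raw_auc,
                 coverage = sum(use), n_pos = np, n_neg = nn),
            class = "roc_result")
}

# upper concave envelope of ROC points from (0,0) to (1,1)
roc_hull <- function(fpr, tpr) {
  pts <- unique(data.frame(fpr = c(0, fpr, 1), tpr = c(0, tpr, 1)))
  pts <- pts[order(pts$fpr, pts$tpr), ]
  hull <- list()
  for (i in seq_len(nrow(pts))) {
    while (length(hull) >= 2L) {
      a <- hull[[length(hull) - 1L]]; b <- hull[[length(hull)]]
      cross <- (b[1] - a[1]) * (pts$tpr[i] - a[2]) -
               (b[2] - a[2]) * (pts$fpr[i] - a[1])
      if (cross >= 0) hull[[length(hull)]] <- NULL else break
    }
    hull[[length(hull) + 1L]] <- c(pts$fpr[i], pts$tpr[i])
  }
  m <- do.call(rbind, hull)
  data.frame(fpr = m[, 1], tpr = m[, 2])
}

# Hanley-McNeil standard error of an AUC
auc_se <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
        (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' Compare two AUCs (Hanley-McNeil)
#'
#' Two-sided normal-approximation p-value for the difference between two
#' areas under ROC curves computed against the same gold standard.
#'
#' @param roc_a,roc_b \code{roc_result} objects.
#' @return p-value.
#' @export
compare_auc <- function(roc_a, roc_b) {
  se_a <- auc_se(roc_a$auc, roc_a$n_pos, roc_a$n_neg)
  se_b <- auc_se(roc_b$auc, roc_b$n_pos, roc_b$n_neg)
  if ((roc_a$auc %in% c(0, 1) && roc_a$n_pos + roc_a$n_neg < 10) ||
      (roc_b$auc %in% c(0, 1) && roc_b$n_pos + roc_b$n_neg < 10))
    warning("degenerate AUC with few pairs; p-value unreliable")
  den <- sqrt(se_a^2 + se_b^2)
  if (den == 0) return(if (roc_a$auc == roc_b$auc) 1 else 0)
  z <- (roc_a$auc - roc_b$auc) / den
  2 * stats::pnorm(-abs(z))
}

#' Connection specificity index across pathway definitions
#'
#' Pathways (from one or several definitions) are compared by the Pearson
#' correlation of their membership vectors over the shared entity universe;
#' the CSI of pathways A and B is the fraction of all pathways whose
#' correlation with A and with B both fall below \code{PCC(A,B) - t}.
#' Pathways with fewer than two entities are dropped.  A pair is called
#' similar when its CSI ranks in the top 15\% of off-diagonal CSI values.
#'
#' @param memberships named list of \code{membership_matrix} objects, one
#'   per pathway definition.
#' @param t threshold subtracted from PCC(A,B); \code{NULL} derives it as
#'   the 5th percentile of the absolute off-diagonal correlations.  Presets
#'   from genome-scale practice are 0.0350 (E. coli-sized) and 0.0562
#'   (yeast-sized).
#' @param top_frac fraction of CSI values deemed similar (default 0.15).
#' @return object of class \code{csi_matrix}: \code{C} (CSI), \code{pcc},
#'   \code{t}, \code{definition} (per-pathway definition label),
#'   \code{similar_cut}, \code{n_y}.
#' @export
csi <- function(memberships, t = NULL, top_frac = 0.15) {
  if (inherits(memberships, "membership_matrix"))
    memberships <- list(def = memberships)
  if (is.null(names(memberships)))
    names(memberships) <- sprintf("def%d", seq_along(memberships))
  universe <- sort(unique(unlist(lapply(memberships,
                                        function(m) rownames(m$M)))))
  cols <- list(); defs <- character(0)
  for (dn in names(memberships)) {
    M <- memberships[[dn]]$M
    for (j in seq_len(ncol(M))) {
      v <- stats::setNames(numeric(length(universe)), universe)
      v[rownames(M)] <- M[, j]
      if (sum(v) < 2) next                 # fewer than two entities
      cols[[paste(dn, colnames(M)[j], sep = ":")]] <- v
      defs <- c(defs, dn)
    }
  }
  if (length(cols) < 2L) stop("fewer than two usable pathways")
  X <- do.call(cbind, cols)
  keep <- apply(X, 2L, stats::sd) > 0
  X <- X[, keep, drop = FALSE]; defs <- defs[keep]
  pcc <- stats::cor(X)
  n_y <- ncol(pcc)
  if (is.null(t)) {
    off <- abs(pcc[upper.tri(pcc)])
    t <- stats::quantile(off, 0.05, names = FALSE)
  }
  C <- matrix(0, n_y, n_y, dimnames = dimnames(pcc))
  for (a in seq_len(n_y)) for (b in seq_len(n_y)) {
    cut <- pcc[a, b] - t
    C[a, b] <- sum(pcc[a, ] < cut & pcc[b, ] < cut) / n_y
  }
  offC <- C[upper.tri(C)]
  similar_cut <- stats::quantile(offC, 1 - top_frac, names = FALSE)
  structure(list(C = C, pcc = pcc, t = t, definition = defs,
                 similar_cut = similar_cut, n_y = n_y),
            class = "csi_matrix")
}

#' Nearest-neighbour assignment across definitions
#'
#' For every pathway of the query definition, the closest pathway of any
#' other definition by Pearson correlation distance; the hit counts only
#' if its CSI is in the top 15\% (\code{similar_cut}), otherwise the
#' pathway is deemed unique.  Definition-pair assignment counts are tested
#' for enrichment/depletion against the size-proportional expectation
#' (two-sided binomial, Bonferroni over target definitions).
#'
#' @param cs a \code{csi_matrix}.
#' @param query_definition name of the query definition.
#' @param alpha significance level after correction (default 0.05).
#' @return list with \code{assignments} (data.frame: pathway, nearest,
#'   nearest_definition — "unique" when below the CSI cut) and
#'   \code{enrichment} (data.frame per target definition: count, expected,
#'   p_adj, call).
#' @export
knn_assign <- function(cs, query_definition, alpha = 0.05) {
  defs <- unique(cs$definition)
  if (length(defs) < 2L) stop("need at least two definitions")
  if (!query_definition %in% defs) stop("unknown definition: ", query_definition)
  qi <- which(cs$definition == query_definition)
  oi <- which(cs$definition != query_definition)
  rows <- lapply(qi, function(a) {
    ord <- oi[order(-cs$pcc[a, oi], -cs$C[a, oi],
                    colnames(cs$pcc)[oi])]     # ties: higher CSI, then id
    b <- ord[1]
    if (cs$C[a, b] >= cs$similar_cut)
      data.frame(pathway = colnames(cs$pcc)[a],
                 nearest = colnames(cs$pcc)[b],
                 nearest_definition = cs$definition[b],
                 stringsAsFactors = FALSE)
    else
      data.frame(pathway = colnames(cs$pcc)[a], nearest = NA_character_,
                 nearest_definition = "unique", stringsAsFactors = FALSE)
  })
  asg <- do.call(rbind, rows)
  targets <- setdiff(defs, query_definition)
  n_other <- length(oi)
  n_assigned <- sum(asg$nearest_definition != "unique")
  enr <- lapply(targets, function(dn) {
    cnt <- sum(asg$nearest_definition == dn)
    pr <- sum(cs$definition == dn) / n_other
    expected <- n_assigned * pr
    p <- if (n_assigned > 0)
      stats::binom.test(cnt, n_assigned, pr)$p.value else 1
    p_adj <- min(1, p * length(targets))
    call <- if (p_adj < alpha) {
      if (cnt > expected) "enriched" else "depleted"
    } else "ns"
    data.frame(definition = dn, count = cnt, expected = expected,
               p_adj = p_adj, call = call, stringsAsFactors = FALSE)
  })
  list(assignments = asg, enrichment = do.call(rbind, enr))
}

#' Dual-perturbation differential gene set
#'
#' Combines the four differential-expression sets of a TF-knockout x
#' nutrient-shift experiment (E1: WT vs WT+shift, E2: KO vs KO+shift,
#' G1: WT vs KO, G2: WT+shift vs KO+shift) into the genes responding
#' specifically to the combined perturbation:
#' \code{((E2 symdiff E1) minus G1) union (G2 minus G1)}.
#'
#' @param E1,E2,G1,G2 character vectors of gene identifiers.
#' @return character vector.
#' @export
dual_perturbation_set <- function(E1, E2, G1, G2) {
  symdiff <- union(setdiff(E2, E1), setdiff(E1, E2))
  sort(union(setdiff(symdiff, G1), setdiff(G2, G1)))
}

#' TF enrichment of a gene set
#'
#' Hypergeometric upper-tail test of the overlap between a gene set and
#' each TF's regulon over a stated universe, optionally Bonferroni
#' corrected across TFs.
#'
#' @param gene_set character vector, a subset of \code{universe}.
#' @param regulon named list of TF gene sets.
#' @param universe character vector of all considered genes.
#' @param correction "none" or "bonferroni".
#' @return data.frame: \code{tf}, \code{overlap}, \code{p}, \code{p_adj}.
#' @export
gene_set_tf_enrichment <- function(gene_set, regulon, universe,
                                   correction = c("bonferroni", "none")) {
  correction <- match.arg(correction)
  if (!length(universe)) stop("empty universe")
  if (!all(gene_set %in% universe)) stop("gene_set must be within universe")
  k_tf <- length(regulon)
  rows <- lapply(names(regulon), function(tf) {
    reg <- intersect(regulon[[tf]], universe)
    ov <- length(intersect(gene_set, reg))
    p <- stats::phyper(ov - 1L, length(reg),
                       length(universe) - length(reg),
                       length(gene_set), lower.tail = FALSE)
    data.frame(tf = tf, overlap = ov, p = p,
               p_adj = if (correction == "bonferroni") min(1, p * k_tf) else p,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res[order(res$p), ]
}
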