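# Flux sampling, decomposition onto a pathway basis, and prediction of
# transcription-factor activity from significantly shifted pathways.
#
# Sampled steady-state flux vectors live in the null space of the reduced
# model, so each one decomposes uniquely into linear weights (alpha) of the
# pathway matrix P.  Comparing alpha distributions between a reference and
# a shifted nutrient condition yields significantly changed pathways
# (paired Wilcoxon signed-rank, P < 0.05); a TF whose associated pathways
# are enriched among the changed ones (hypergeometric, P < 0.05) is
# predicted active in the shift.

#' Nutrient-condition specification
#'
#' @param shift one of "carbon", "nitrogen", "phosphorus", "sulfur",
#'   "supplement", "anaerobic".
#' @param substrate_id replacement or supplemented metabolite identifier
#'   (ignored for "anaerobic").
#' @param base_medium named list of exchange-bound overrides
#'   (\code{list(EX_x = c(lb, ub))}) defining the reference medium.
#' @param biomass_fraction required fraction of the optimal growth rate
#'   (default 0.9).
#' @return list of class \code{condition_spec}.
#' @export
condition_spec <- function(shift, substrate_id = NA_character_,
                           base_medium = list(), biomass_fraction = 0.9) {
  shift <- match.arg(shift, c("carbon", "nitrogen", "phosphorus", "sulfur",
                              "supplement", "anaerobic"))
  stopifnot(biomass_fraction > 0, biomass_fraction <= 1)
  if (shift != "anaerobic" && is.na(substrate_id))
    stop("substrate_id required for shift '", shift, "'")
  structure(list(shift = shift, substrate_id = substrate_id,
                 base_medium = base_medium,
                 biomass_fraction = biomass_fraction),
            class = "condition_spec")
}

element_count <- function(formula, element) {
  if (is.na(formula)) return(NA_real_)
  # tokens like C6, H12, O6, S, P ...
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  toks <- regmatches(formula, list(m))[[1]]
  tot <- 0
  for (tk in toks) {
    el <- sub("[0-9]*$", "", tk)
    if (el == element) {
      cnt <- sub("^[A-Za-z]+", "", tk)
      tot <- tot + if (nzchar(cnt)) as.numeric(cnt) else 1
    }
  }
  tot
}

exchange_of <- function(model, met) {
  j <- which(model$exchange & model$S[met, ] != 0)
  if (!length(j)) NA_integer_ else j[1]
}

# maximize biomass under bounds; returns optimum (flux of biomass reaction)
fba_optimum <- function(model, lb = model$lb, ub = model$ub) {
  if (is.na(model$biomass_id)) stop("model has no biomass reaction")
  j <- match(model$biomass_id, model$rxns)
  obj <- numeric(length(model$rxns)); obj[j] <- 1
  r <- lp_bounded(obj, model$S, numeric(nrow(model$S)), lb, ub,
                  maximize = TRUE)
  if (r$status != "optimal") stop("growth optimisation infeasible")
  r$objval
}

#' Build bounds overrides for a nutrient shift
#'
#' Applies the base medium, then the shift: anaerobic closes oxygen uptake;
#' an alternate carbon/nitrogen/phosphorus/sulfur source zeroes the
#' original source's uptake and admits the replacement at an equal rate of
#' atom flow for the defining element; a supplement is admitted at the
#' minimum rate covering the corresponding biomass constituent at the
#' wild-type growth rate.  Finally the biomass flux is bounded below by
#' \code{biomass_fraction} times the optimum under the new bounds.
#'
#' @param model a \code{metabolic_model} with a biomass reaction; formulas
#'   are required for atom-flow shifts.
#' @param spec a \code{\link{condition_spec}}.
#' @return data.frame with columns \code{rxn}, \code{lb}, \code{ub}.
#' @export
build_shift_bounds <- function(model, spec) {
  lb <- model$lb; ub <- model$ub
  for (rx in names(spec$base_medium)) {
    j <- match(rx, model$rxns)
    if (is.na(j)) stop("base_medium reaction not in model: ", rx)
    lb[j] <- spec$base_medium[[rx]][1]; ub[j] <- spec$base_medium[[rx]][2]
  }
  touched <- match(names(spec$base_medium), model$rxns)
  element <- switch(spec$shift, carbon = "C", nitrogen = "N",
                    phosphorus = "P", sulfur = "S", NULL)
  if (spec$shift == "anaerobic") {
    o2 <- which(vapply(model$mets, function(mt) {
      f <- if (!is.null(model$formulas)) model$formulas[mt] else NA
      identical(unname(f), "O2") || grepl("^o2", mt, ignore.case = TRUE)
    }, logical(1)))
    if (!length(o2)) stop("no oxygen metabolite found for anaerobic shift")
    j <- exchange_of(model, model$mets[o2[1]])
    if (is.na(j)) stop("no oxygen exchange reaction found")
    lb[j] <- 0
    touched <- c(touched, j)
  } else if (!is.null(element)) {
    if (is.null(model$formulas)) stop("atom-flow shift requires formulas")
    if (!spec$substrate_id %in% model$mets)
      stop("substrate not in model: ", spec$substrate_id)
    new_atoms <- element_count(model$formulas[spec$substrate_id], element)
    if (is.na(new_atoms) || new_atoms == 0)
      stop("substrate ", spec$substrate_id, " lacks element ", element)
    # original source: the base-medium uptake with the largest atom inflow
    upt <- which(model$exchange & lb < 0)
    atoms <- vapply(upt, function(j) {
      mt <- model$mets[model$S[, j] != 0]
      a <- element_count(model$formulas[mt], element)
      if (is.na(a)) 0 else a * abs(lb[j])
    }, numeric(1))
    if (!any(atoms > 0)) stop("no original ", element, " source in medium")
    src <- upt[which.max(atoms)]
    flow <- atoms[which.max(atoms)]
    lb[src] <- 0
    jn <- exchange_of(model, spec$substrate_id)
    if (is.na(jn)) stop("no exchange reaction for ", spec$substrate_id)
    lb[jn] <- -flow / new_atoms
    touched <- c(touched, src, jn)
  } else {   # supplement
    if (is.na(model$biomass_id)) stop("supplement shift requires biomass")
    if (!spec$substrate_id %in% model$mets)
      stop("substrate not in model: ", spec$substrate_id)
    coef <- model$S[spec$substrate_id, match(model$biomass_id, model$rxns)]
    if (coef >= 0)
      stop("substrate ", spec$substrate_id, " is not a biomass constituent")
    g_wt <- fba_optimum(model, lb, ub)
    jn <- exchange_of(model, spec$substrate_id)
    if (is.na(jn)) stop("no exchange reaction for ", spec$substrate_id)
    lb[jn] <- -abs(coef) * g_wt
    touched <- c(touched, jn)
  }
  if (!is.na(model$biomass_id)) {
    gopt <- fba_optimum(model, lb, ub)
    jb <- match(model$biomass_id, model$rxns)
    lb[jb] <- spec$biomass_fraction * gopt
    if (lb[jb] > ub[jb])
      stop("infeasible at requested biomass fraction; binding constraint: ",
           "biomass upper bound")
    touched <- unique(c(touched, jb))
  }
  data.frame(rxn = model$rxns[touched], lb = lb[touched], ub = ub[touched],
             stringsAsFactors = FALSE)
}

apply_bounds <- function(model, overrides) {
  if (is.null(overrides)) return(model)
  for (i in seq_len(nrow(overrides))) {
    j <- match(overrides$rxn[i], model$rxns)
    if (is.na(j)) next       # e.g. biomass removed during preprocessing
    model$lb[j] <- overrides$lb[i]; model$ub[j] <- overrides$ub[i]
  }
  model
}

#' Sample steady-state flux distributions
#'
#' Seeded coordinate hit-and-run over the flux polytope
#' \code{\{v : S v = 0, lb <= v <= ub\}}, parameterised in null-space
#' coordinates.  Warm-up of \code{10 n} steps, thinning of \code{n} steps
#' between kept samples.
#'
#' @param reduced a \code{reduced_model}.
#' @param bounds optional overrides data.frame (\code{rxn}, \code{lb},
#'   \code{ub}); entries for reactions absent from the reduced model are
#'   ignored.
#' @param n_samples number of samples to keep.
#' @param seed integer seed; identical seeds give identical samples.
#' @param condition_label label stored with the samples.
#' @param directions optional matrix of chord directions (columns must lie
#'   in the null space and span it); defaults to the orthonormal basis.
#'   Passing a sparse pathway basis keeps each move local to that
#'   pathway's reactions, which sharpens seed-paired condition
#'   comparisons.
#' @return object of class \code{flux_samples}: list with \code{V}
#'   (samples x reactions), \code{condition_label}.
#' @export
sample_fluxes <- function(reduced, bounds = NULL, n_samples = 1000L,
                          seed = 1L, condition_label = "reference",
                          directions = NULL) {
  mod <- apply_bounds(reduced$base, bounds)
  S <- mod$S; lb <- mod$lb; ub <- mod$ub
  n <- ncol(S)
  N <- if (is.null(directions)) orthonormal_nullspace(reduced) else {
    D <- as.matrix(directions)
    if (max(abs(S %*% D)) > 1e-6)
      stop("directions are not in the null space")
    sweep(D, 2L, sqrt(colSums(D^2)), "/")
  }
  d <- ncol(N)
  # interior-ish start: mean of the flux-variability vertex solutions
  # Start point: the origin whenever the bounds admit it (deterministic and
  # independent of the condition, which keeps seed-paired trajectories of
  # unaffected polytope regions identical); otherwise the mean of the
  # flux-variability vertices.
  v0 <- if (all(lb <= 0 & ub >= 0)) numeric(n) else fva_center(mod)
  if (max(abs(S %*% v0)) > 1e-6)
    stop("infeasible sampling region: start point violates steady state")
  rng <- local_rng(seed)
  on.exit(rng$restore())
  warmup <- 10L * n; thin <- n
  total <- warmup + thin * n_samples
  V <- matrix(NA_real_, n_samples, n, dimnames = list(NULL, mod$rxns))
  kept <- 0L
  v <- v0
  for (step in seq_len(total)) {
    k <- sample.int(d, 1L)
    dir <- N[, k]
    # chord limits: lb <= v + t*dir <= ub
    pos <- dir > 1e-12; neg <- dir < -1e-12
    tmax <- min(c((ub[pos] - v[pos]) / dir[pos],
                  (lb[neg] - v[neg]) / dir[neg], Inf))
    tmin <- max(c((lb[pos] - v[pos]) / dir[pos],
                  (ub[neg] - v[neg]) / dir[neg], -Inf))
    # one uniform per step regardless of chord validity, so that runs under
    # different bounds share an aligned random stream (only chords whose
    # limits differ produce different moves)
    u <- stats::runif(1)
    t <- if (is.finite(tmax) && is.finite(tmin) && tmax >= tmin)
      tmin + u * (tmax - tmin) else 0
    v <- v + t * dir
    v <- pmin(pmax(v, lb), ub)
    if (step > warmup && (step - warmup) %% thin == 0L) {
      kept <- kept + 1L
      V[kept, ] <- v
      if (kept == n_samples) break
    }
  }
  structure(list(V = V, condition_label = condition_label),
            class = "flux_samples")
}

# interior point: average of all FVA extreme solutions
fva_center <- function(model) {
  n <- length(model$rxns)
  acc <- numeric(n); cnt <- 0L
  for (j in seq_len(n)) {
    obj <- numeric(n); obj[j] <- 1
    for (mx in c(FALSE, TRUE)) {
      r <- lp_bounded(obj, model$S, numeric(nrow(model$S)), model$lb,
                      model$ub, maximize = mx)
      if (r$status != "optimal")
        stop("infeasible sampling region (reaction ", model$rxns[j], ")")
      acc <- acc + r$x; cnt <- cnt + 1L
    }
  }
  acc / cnt
}

#' Normalise flux samples by median growth
#'
#' Divides every flux by the condition's median growth value so that
#' conditions with different growth rates are comparable.
#'
#' @param samples a \code{flux_samples}.
#' @param growth_values per-sample growth flux (externally tracked).
#' @return a \code{flux_samples} with rescaled \code{V}.
#' @export
normalize_by_growth <- function(samples, growth_values) {
  med <- stats::median(growth_values)
  if (!is.finite(med) || med <= 0) stop("median growth must be positive")
  samples$V <- samples$V / med
  samples
}

#' Decompose flux samples into pathway weights
#'
#' Each sampled flux vector \code{v} in the null space decomposes uniquely
#' as \code{v = P alpha}; the least-squares coefficients are exact up to
#' \code{tol_decomp} because P has full column rank spanning the null
#' space.
#'
#' @param P a \code{\link{pathway_matrix}} (or plain matrix).
#' @param samples a \code{flux_samples} (or plain samples x reactions
#'   matrix).
#' @param tol_decomp maximal admissible reconstruction residual (infinity
#'   norm) per sample.
#' @return object of class \code{pathway_weights}: list with \code{A}
#'   (samples x pathways) and \code{residuals}.
#' @export
decompose <- function(P, samples, tol_decomp = 1e-6) {
  M <- if (inherits(P, "pathway_matrix")) P$P else P
  V <- if (inherits(samples, "flux_samples")) samples$V else samples
  if (is.null(dim(V))) V <- matrix(V, 1L)
  if (ncol(V) != nrow(M)) stop("samples' reactions do not align with P's rows")
  qrP <- qr(M)
  A <- t(qr.coef(qrP, t(V)))
  recon <- A %*% t(M)
  resid <- apply(abs(recon - V), 1L, max)
  bad <- which(resid > tol_decomp)
  if (length(bad))
    stop("flux sample(s) outside the pathway span (residual > tol_decomp): ",
         paste(utils::head(bad, 10L), collapse = ", "))
  colnames(A) <- colnames(M)
  structure(list(A = A, residuals = resid), class = "pathway_weights")
}

#' Per-pathway shift test
#'
#' Two-sided paired Wilcoxon signed-rank test of the pathway weights
#' between a reference and a shifted condition; rows are paired by sample
#' index (a shared sampler seed makes the pairing deterministic).
#'
#' @param A_ref,A_shift \code{pathway_weights} with equal sample counts.
#' @param alpha_level significance level for the changed call (default
#'   0.05).
#' @return data.frame with columns \code{pathway}, \code{p}, \code{changed},
#'   \code{constant}.
#' @export
pathway_shift_test <- function(A_ref, A_shift, alpha_level = 0.05) {
  R <- if (inherits(A_ref, "pathway_weights")) A_ref$A else A_ref
  Sh <- if (inherits(A_shift, "pathway_weights")) A_shift$A else A_shift
  if (nrow(R) != nrow(Sh)) stop("sample counts differ; pairing impossible")
  if (ncol(R) != ncol(Sh)) stop("pathway counts differ")
  p <- numeric(ncol(R)); const <- logical(ncol(R))
  for (j in seq_len(ncol(R))) {
    dif <- Sh[, j] - R[, j]
    if (all(abs(dif) < 1e-12)) { p[j] <- 1; const[j] <- TRUE; next }
    p[j] <- suppressWarnings(
      stats::wilcox.test(Sh[, j], R[, j], paired = TRUE)$p.value)
  }
  data.frame(pathway = colnames(R) %||% sprintf("pw%02d", seq_len(ncol(R))),
             p = p, changed = p < alpha_level, constant = const,
             stringsAsFactors = FALSE)
}

#' Associate transcription factors with pathways
#'
#' Hypergeometric enrichment of each TF's regulated genes in each pathway's
#' gene set over the universe of metabolic genes (genes appearing in the
#' membership matrix).  TFs regulating at most one metabolic reaction, or
#' whose genes appear in at most one pathway, are removed beforehand for
#' lack of statistical power.
#'
#' @param membership a \code{membership_matrix} at gene level.
#' @param regulon named list mapping TF ids to gene sets.
#' @param p_cut association threshold (default 0.01).
#' @param model optional \code{metabolic_model} used for the
#'   one-metabolic-reaction filter; when absent the filter uses pathway
#'   appearance only.
#' @return data.frame with columns \code{tf}, \code{pathway}, \code{p};
#'   one row per association with \code{p < p_cut}.
#' @export
tf_pathway_enrichment <- function(membership, regulon, p_cut = 0.01,
                                  model = NULL) {
  M <- membership$M
  universe <- rownames(M)
  if (!length(universe)) stop("empty gene universe")
  gene_rxns <- NULL
  if (!is.null(model)) {
    gene_rxns <- lapply(model$rxns, function(r) character(0))
    trees <- lapply(model$gpr, parse_gpr)
    gene2rxn <- list()
    for (k in seq_along(trees)) for (g in gpr_genes(trees[[k]]))
      gene2rxn[[g]] <- c(gene2rxn[[g]], model$rxns[k])
  }
  rows <- list()
  for (tf in names(regulon)) {
    genes <- intersect(regulon[[tf]], universe)
    if (length(genes) == 0L) next
    n_pw <- sum(colSums(M[genes, , drop = FALSE]) > 0)
    if (n_pw <= 1L) next                 # appears in at most one pathway
    if (!is.null(model)) {
      rxns <- unique(unlist(gene2rxn[genes]))
      if (length(rxns) <= 1L) next       # regulates one metabolic reaction
    }
    for (j in seq_len(ncol(M))) {
      pw_genes <- universe[M[, j] == 1]
      k <- length(intersect(genes, pw_genes))
      if (k == 0L) next
      p <- stats::phyper(k - 1L, length(genes),
                         length(universe) - length(genes),
                         length(pw_genes), lower.tail = FALSE)
      if (p < p_cut)
        rows[[length(rows) + 1L]] <- data.frame(
          tf = tf, pathway = colnames(M)[j], p = p,
          stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(tf = character(0), pathway = character(0),
                      p = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Predict transcription-factor activity from changed pathways
#'
#' For each TF, a hypergeometric test of how many of its associated
#' pathways are among the significantly changed ones, against all pathways.
#' Also reports the percentage of the changed (differential) pathways that
#' are associated with the TF.
#'
#' @param changed named logical vector over pathways (changed flags).
#' @param assoc TF-to-pathway association table from
#'   \code{\link{tf_pathway_enrichment}}.
#' @param p_cut activity threshold (default 0.05).
#' @return data.frame with columns \code{tf}, \code{n_assoc},
#'   \code{n_changed_assoc}, \code{p}, \code{active},
#'   \code{pct_changed_assoc}.
#' @export
predict_tf_activity <- function(changed, assoc, p_cut = 0.05) {
  if (!nrow(assoc)) stop("empty TF-pathway association map")
  K <- length(changed); k_ch <- sum(changed)
  ch_names <- names(changed)[changed]
  tfs <- unique(assoc$tf)
  out <- lapply(tfs, function(tf) {
    pws <- assoc$pathway[assoc$tf == tf]
    m <- length(intersect(pws, ch_names))
    p <- stats::phyper(m - 1L, k_ch, K - k_ch, length(pws),
                       lower.tail = FALSE)
    data.frame(tf = tf, n_assoc = length(pws), n_changed_assoc = m,
               p = p, active = p < p_cut,
               pct_changed_assoc = if (k_ch > 0) 100 * m / k_ch else 0,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res[order(res$p), ]
}

#' End-to-end TF activity prediction for one nutrient shift
#'
#' Convenience pipeline: preprocess the model, compute (or accept) the
#' pathway basis, map TFs to pathways, sample fluxes under the reference
#' medium and under the shift, normalise by median growth, decompose both
#' onto the basis, test pathway shifts, and predict active TFs.
#'
#' @param model a \code{metabolic_model} (biomass optional; growth
#'   normalisation requires it).
#' @param regulon named list mapping TFs to gene sets.
#' @param spec a \code{\link{condition_spec}} describing the shift.
#' @param pathways optional precomputed \code{\link{pathway_matrix}};
#'   computed by \code{\link{minspan}} when absent.
#' @param n_samples flux samples per condition (default 500).
#' @param seed integer seed shared by both conditions (pairs samples).
#' @param opts \code{\link{solver_options}} for the basis computation.
#' @param assoc_p,shift_alpha,activity_p thresholds for TF-pathway
#'   association (0.01), pathway change (0.05) and TF activity (0.05).
#' @return list with \code{pathways}, \code{membership}, \code{assoc},
#'   \code{shift_test}, \code{activity}.
#' @export
tf_activity_pipeline <- function(model, regulon, spec, pathways = NULL,
                                 n_samples = 500L, seed = 1L,
                                 opts = solver_options(),
                                 assoc_p = 0.01, shift_alpha = 0.05,
                                 activity_p = 0.05) {
  red <- preprocess(model)
  pm <- if (is.null(pathways)) minspan(red, opts) else pathways
  memb <- pathway_gene_sets(pm, model, level = "gene")
  assoc <- tf_pathway_enrichment(memb, regulon, p_cut = assoc_p,
                                 model = model)
  if (!nrow(assoc)) stop("no TF-pathway associations at p < ", assoc_p)
  ref_bounds <- if (length(spec$base_medium))
    data.frame(rxn = names(spec$base_medium),
               lb = vapply(spec$base_medium, `[[`, numeric(1), 1),
               ub = vapply(spec$base_medium, `[[`, numeric(1), 2),
               stringsAsFactors = FALSE) else NULL
  shift_bounds <- build_shift_bounds(model, spec)
  v_ref <- sample_fluxes(red, ref_bounds, n_samples, seed, "reference",
                         directions = pm$P)
  v_shf <- sample_fluxes(red, shift_bounds, n_samples, seed, "shift",
                         directions = pm$P)
  if (!is.na(model$biomass_id)) {
    lb_ref <- apply_bounds(model, ref_bounds)
    g_ref <- fba_optimum(model, lb_ref$lb, lb_ref$ub)
    lb_shf <- apply_bounds(model, shift_bounds)
    g_shf <- fba_optimum(model, lb_shf$lb, lb_shf$ub)
    if (g_ref > 0) v_ref <- normalize_by_growth(v_ref, rep(g_ref, n_samples))
    if (g_shf > 0) v_shf <- normalize_by_growth(v_shf, rep(g_shf, n_samples))
  }
  a_ref <- decompose(pm, v_ref)
  a_shf <- decompose(pm, v_shf)
  sh <- pathway_shift_test(a_ref, a_shf, alpha_level = shift_alpha)
  changed <- stats::setNames(sh$changed, sh$pathway)
  act <- predict_tf_activity(changed, assoc, p_cut = activity_p)
  list(pathways = pm, membership = memb, assoc = assoc,
       shift_test = sh, activity = act)
}
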