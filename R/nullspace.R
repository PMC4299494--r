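# Preprocessing and null-space computation.
#
# Before pathway enumeration the model is reduced: every exchange is opened
# to [-1000, 1000], the biomass pseudo-reaction is removed, and reactions
# that cannot carry flux (flux-variability min and max both ~ 0) are
# dropped.  Irreversibility of internal reactions is preserved; those
# thermodynamic constraints are part of the pathway definition.

FLUX_BOUND <- 1000
TOL_BLOCKED <- 1e-9

#' Flux variability analysis
#'
#' Minimum and maximum steady-state flux for each reaction under
#' \code{S v = 0} and the model bounds.
#'
#' @param model a \code{metabolic_model}.
#' @return data.frame with columns \code{rxn}, \code{min}, \code{max}.
#' @export
flux_variability <- function(model) {
  n <- length(model$rxns)
  vmin <- vmax <- numeric(n)
  for (j in seq_len(n)) {
    obj <- numeric(n); obj[j] <- 1
    lo <- lp_bounded(obj, model$S, numeric(nrow(model$S)), model$lb, model$ub)
    hi <- lp_bounded(obj, model$S, numeric(nrow(model$S)), model$lb, model$ub,
                     maximize = TRUE)
    if (lo$status != "optimal" || hi$status != "optimal")
      stop("flux variability LP not optimal for reaction ", model$rxns[j],
           " (", lo$status, "/", hi$status, ")")
    vmin[j] <- lo$objval; vmax[j] <- hi$objval
  }
  data.frame(rxn = model$rxns, min = vmin, max = vmax,
             stringsAsFactors = FALSE)
}

#' Blocked reactions
#'
#' A reaction is blocked when its flux-variability minimum and maximum are
#' both within \code{tol} of zero.
#'
#' @param model a \code{metabolic_model}.
#' @param tol numeric tolerance (default \code{1e-9}).
#' @return logical vector over reactions.
#' @export
blocked_reactions <- function(model, tol = TOL_BLOCKED) {
  fva <- flux_variability(model)
  abs(fva$min) <= tol & abs(fva$max) <= tol
}

#' Reduce a model for pathway enumeration
#'
#' Opens all exchange bounds to \code{[-1000, 1000]}, removes the biomass
#' reaction if present, removes blocked reactions, and computes the rank of
#' the reduced stoichiometric matrix.  Exchanges are opened before blocked
#' detection so that every uptake/secretion route is available.
#'
#' @param model a \code{metabolic_model}.
#' @param tol_blocked blocked-reaction tolerance.
#' @return object of class \code{reduced_model}: list with \code{base} (the
#'   reduced \code{metabolic_model}), \code{kept_index} (positions of the
#'   retained reactions in the original model), \code{r} (rank of the
#'   reduced S), and \code{report} (data.frame: reaction, action, reason).
#' @export
preprocess <- function(model, tol_blocked = TOL_BLOCKED) {
  m <- model
  m$lb[m$exchange] <- -FLUX_BOUND
  m$ub[m$exchange] <- FLUX_BOUND
  report <- data.frame(rxn = character(0), action = character(0),
                       reason = character(0), stringsAsFactors = FALSE)
  if (sum(m$exchange))
    report <- rbind(report, data.frame(
      rxn = m$rxns[m$exchange], action = "opened",
      reason = "exchange bounds set to [-1000, 1000]"))
  keep <- rep(TRUE, length(m$rxns))
  if (!is.na(m$biomass_id)) {
    keep[m$rxns == m$biomass_id] <- FALSE
    report <- rbind(report, data.frame(
      rxn = m$biomass_id, action = "removed", reason = "biomass reaction"))
  }
  sub <- subset_model(m, which(keep))
  blocked <- blocked_reactions(sub, tol_blocked)
  if (any(blocked)) {
    report <- rbind(report, data.frame(
      rxn = sub$rxns[blocked], action = "removed",
      reason = "blocked (flux variability min and max ~ 0)"))
    kept_pos <- which(keep)[!blocked]
  } else kept_pos <- which(keep)
  base <- subset_model(m, kept_pos)
  r <- matrix_rank(base$S)
  if (length(base$rxns) - r < 1L)
    stop("no pathways exist: the reduced model has an empty null space")
  structure(list(base = base, kept_index = kept_pos, r = r, report = report),
            class = "reduced_model")
}

#' @export
print.reduced_model <- function(x, ...) {
  cat(sprintf("reduced_model: %d reactions retained, rank %d, null dim %d\n",
              length(x$base$rxns), x$r, length(x$base$rxns) - x$r))
  invisible(x)
}

subset_model <- function(m, cols) {
  keep_met <- rowSums(m$S[, cols, drop = FALSE] != 0) > 0
  out <- m
  out$S <- m$S[keep_met, cols, drop = FALSE]
  out$mets <- m$mets[keep_met]
  out$rxns <- m$rxns[cols]
  out$lb <- m$lb[cols]; out$ub <- m$ub[cols]
  out$gpr <- m$gpr[cols]
  out$exchange <- detect_exchanges(out$S)
  out$biomass_id <- if (!is.na(m$biomass_id) && m$biomass_id %in% out$rxns)
    m$biomass_id else NA_character_
  out$formulas <- if (!is.null(m$formulas)) m$formulas[out$mets] else NULL
  out
}

# numerical rank: singular values > max(dim) * eps * sigma_max
matrix_rank <- function(A) {
  if (length(A) == 0) return(0L)
  sv <- svd(A, nu = 0, nv = 0)$d
  if (length(sv) == 0 || sv[1] == 0) return(0L)
  sum(sv > max(dim(A)) * .Machine$double.eps * sv[1])
}

#' Orthonormal null-space basis
#'
#' Orthonormal basis of \code{null(S)} of the reduced model, from the
#' singular value decomposition.  Errors when the singular-value gap around
#' the rank cutoff is too small to decide the rank reliably.
#'
#' @param reduced a \code{reduced_model}.
#' @param tol_gap minimal acceptable ratio between the smallest retained
#'   and the largest discarded singular value.
#' @return matrix (n x (n - r)) with orthonormal columns; rownames are
#'   reaction identifiers.
#' @export
orthonormal_nullspace <- function(reduced, tol_gap = 1e3) {
  S <- reduced$base$S
  n <- ncol(S)
  dec <- svd(S, nu = 0, nv = n)
  sv <- dec$d
  cut <- max(dim(S)) * .Machine$double.eps * max(sv)
  r <- sum(sv > cut)
  if (r > 0 && r < length(sv) && sv[r + 1] > 0 && sv[r] / sv[r + 1] < tol_gap)
    stop(sprintf("rank estimation unstable: singular-value gap %.3e",
                 sv[r] / sv[r + 1]))
  if (n - r < 1L) stop("empty null space")
  N <- dec$v[, (r + 1L):n, drop = FALSE]
  rownames(N) <- reduced$base$rxns
  N
}
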