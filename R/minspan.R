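# The pathway-basis sweep (MinSpan / MaxSpan / RandSpan), the brute-force
# sparsest-basis oracle for small models, and the basis verifier.

#' Construct a pathway matrix object
#' @param P numeric matrix, reactions x pathways; rownames are reaction ids.
#' @param provenance one of minspan, maxspan, randspan, oracle, orthonormal.
#' @param tol_zero threshold for counting non-zero entries.
#' @return object of class \code{pathway_matrix} with fields \code{P},
#'   \code{nnz} and \code{provenance}.
#' @export
pathway_matrix <- function(P, provenance, tol_zero = 1e-6) {
  if (is.null(colnames(P))) colnames(P) <- sprintf("pw%02d", seq_len(ncol(P)))
  structure(list(P = P, nnz = sum(abs(P) > tol_zero), provenance = provenance),
            class = "pathway_matrix")
}

#' @export
print.pathway_matrix <- function(x, ...) {
  cat(sprintf("pathway_matrix (%s): %d reactions x %d pathways, nnz = %d\n",
              x$provenance, nrow(x$P), ncol(x$P), x$nnz))
  invisible(x)
}

#' Shortest linearly independent pathway basis (MinSpan)
#'
#' Starts from the orthonormal null-space basis and sweeps its columns,
#' replacing each by the sparsest feasible flux vector that spans the
#' removed column's direction, until the total number of non-zero entries
#' is unchanged between consecutive sweeps.  Columns are normalised by
#' their smallest non-zero magnitude.
#'
#' @param reduced a \code{reduced_model} from \code{\link{preprocess}}.
#' @param opts a \code{\link{solver_options}}.
#' @return a \code{\link{pathway_matrix}} with provenance "minspan".
#' @export
#' @examples
#' red <- preprocess(toy_glycolysis_tca())
#' ms <- minspan(red)
#' ncol(ms$P)   # 4 pathways
minspan <- function(reduced, opts = solver_options()) {
  span_sweep(reduced, opts, variant = "minspan")
}

#' Densest pathway basis (MaxSpan)
#'
#' Same sweep as \code{\link{minspan}} with the objective switched to
#' maximising the number of active reactions per column (binaries linked to
#' fluxes so that an active reaction carries at least \code{epsilon} flux).
#'
#' @inheritParams minspan
#' @return a \code{\link{pathway_matrix}} with provenance "maxspan".
#' @export
maxspan <- function(reduced, opts = solver_options()) {
  span_sweep(reduced, opts, variant = "maxspan")
}

#' Randomly weighted pathway bases (RandSpan)
#'
#' Each basis is built by the same sweep with a per-reaction objective
#' weight drawn uniformly from [-0.5, 0.5] (drawn once per basis), so
#' reaction use is randomly rewarded or penalised.
#'
#' @inheritParams minspan
#' @param n_bases number of bases to generate.
#' @return list of \code{\link{pathway_matrix}} objects, provenance
#'   "randspan".
#' @export
randspan <- function(reduced, n_bases, opts = solver_options()) {
  stopifnot(n_bases >= 1)
  rng <- local_rng(opts$seed)
  seeds <- sample.int(.Machine$integer.max, n_bases)
  rng$restore()
  lapply(seq_len(n_bases), function(k) {
    rngk <- local_rng(seeds[k])
    w <- stats::runif(length(reduced$base$rxns), -0.5, 0.5)
    rngk$restore()
    span_sweep(reduced, opts, variant = "randspan", weights = w)
  })
}

span_sweep <- function(reduced, opts, variant, weights = NULL) {
  S <- reduced$base$S
  n <- ncol(S); d <- n - reduced$r
  lb <- reduced$base$lb
  N <- orthonormal_nullspace(reduced)
  w <- switch(variant,
              minspan = rep(1, n),
              maxspan = rep(-1, n),
              randspan = weights)
  stopifnot(!is.null(w))
  P <- N
  feasible <- rep(FALSE, d)   # initial orthonormal columns are not feasible
  tolz <- opts$tol_zero
  nnz_col <- function(v) sum(abs(v) > tolz)
  deadline_total <- proc.time()[["elapsed"]] + opts$time_limit * d * opts$max_sweeps
  for (sweep in seq_len(opts$max_sweeps)) {
    nnz0 <- sum(abs(P) > tolz)
    for (j in seq_len(d)) {
      x <- replacement_direction(P, j)
      if (is.null(x)) stop("internal error: pathway columns became dependent")
      inc <- NULL
      if (feasible[j]) {
        inc <- scale_into_constraint(P[, j], x, lb, reduced$base$ub,
                                     opts$epsilon)
      }
      res <- solve_replacement(reduced, x, opts, weights = w,
                               incumbent_v = inc)
      if (is.null(res$v)) {
        if (!feasible[j])
          stop("no feasible pathway spans column ", j,
               ": null space not spanned by sign-feasible flux vectors")
        next   # timeout without incumbent: keep previous column
      }
      old_cost <- if (feasible[j]) sum(w[abs(P[, j]) > tolz]) else Inf
      if (res$cost <= old_cost + 1e-9 || !feasible[j]) {
        P[, j] <- normalize_pathway(res$v, S, lb, tolz)
        feasible[j] <- TRUE
      }
      if (proc.time()[["elapsed"]] > deadline_total) break
    }
    nnz1 <- sum(abs(P) > tolz)
    if (all(feasible) && nnz1 == nnz0) break
  }
  rownames(P) <- reduced$base$rxns
  pathway_matrix(P, variant, tolz)
}

# Direction spanned by column j and orthogonal to the remaining columns.
replacement_direction <- function(P, j) {
  pj <- P[, j]
  if (ncol(P) > 1L) {
    Q <- qr.Q(qr(P[, -j, drop = FALSE]))
    pj <- pj - Q %*% crossprod(Q, pj)
  }
  nrm <- sqrt(sum(pj^2))
  if (nrm < 1e-10) return(NULL)
  as.numeric(pj) / nrm
}

# Rescale a feasible column so it also satisfies |x'v| >= eps, if possible.
scale_into_constraint <- function(v, x, lb, ub, eps) {
  xv <- sum(x * v)
  if (abs(xv) < 1e-12) return(NULL)
  sc <- eps * 1.000001 / abs(xv)
  if (sc > 1) {
    v2 <- v * sc
    if (any(v2 < lb - 1e-9) || any(v2 > ub + 1e-9)) return(NULL)
    return(v2)
  }
  v
}

# Threshold, re-project onto the null space restricted to the support (so
# zeroed noise does not leave a steady-state residual), scale by the
# smallest non-zero magnitude, and orient.
normalize_pathway <- function(v, S, lb, tol_zero) {
  v[abs(v) <= tol_zero] <- 0
  sup <- which(v != 0)
  if (length(sup)) {
    Nsub <- nullspace_of(S[, sup, drop = FALSE])
    if (!is.null(Nsub)) {
      z <- crossprod(Nsub, v[sup])
      v2 <- as.numeric(Nsub %*% z)
      if (max(abs(v2 - v[sup])) < 1e-6 * max(1, max(abs(v)))) v[sup] <- v2
    }
    v[abs(v) <= .Machine$double.eps * 100] <- 0
    sup <- which(v != 0)
  }
  if (!length(sup)) return(v)
  v <- v / min(abs(v[sup]))
  irr <- which(lb >= 0)
  if (!any(v[irr] != 0) && v[sup[1]] < 0) v <- -v
  v
}

nullspace_of <- function(A) {
  n <- ncol(A)
  dec <- svd(A, nu = 0, nv = n)
  r <- sum(dec$d > max(dim(A)) * .Machine$double.eps * max(dec$d, 0))
  if (n - r < 1L) return(NULL)
  dec$v[, (r + 1L):n, drop = FALSE]
}

#' Brute-force sparsest feasible basis (oracle)
#'
#' Enumerates all support-minimal, sign-feasible null-space vectors
#' (circuits) by exhaustive search over row subsets of the orthonormal
#' basis, then greedily selects them by ascending support size subject to
#' linear independence.  By the greedy optimality of the sparse null-space
#' basis problem, the resulting total non-zero count is globally minimal.
#' Guarded to small instances.
#'
#' @param reduced a \code{reduced_model} with at most 20 reactions and a
#'   null space of dimension at most 5.
#' @param tol_zero zero threshold for supports.
#' @return a \code{\link{pathway_matrix}} with provenance "oracle".
#' @export
brute_force_sparsest_basis <- function(reduced, tol_zero = 1e-6) {
  n <- length(reduced$base$rxns)
  d <- n - reduced$r
  if (n > 20 || d > 5)
    stop("instance too large for the brute-force oracle (n <= 20, n - r <= 5)")
  N <- orthonormal_nullspace(reduced)
  lb <- reduced$base$lb
  irr <- which(lb >= 0)
  cands <- list(); seen <- character(0)
  consider <- function(v) {
    v[abs(v) <= 1e-9 * max(abs(v))] <- 0
    if (all(v == 0)) return()
    if (any(v[irr] < 0)) {
      if (any(v[irr] > 0)) return()      # sign-infeasible both ways
      v <- -v
    }
    if (any(v[irr] < 0)) return()
    key <- paste(which(v != 0), collapse = ",")
    if (key %in% seen) return()
    seen <<- c(seen, key)
    cands[[length(cands) + 1L]] <<- v
  }
  if (d == 1L) consider(as.numeric(N)) else {
    subsets <- utils::combn(n, d - 1L)
    for (k in seq_len(ncol(subsets))) {
      Tset <- subsets[, k]
      A <- N[Tset, , drop = FALSE]
      ns <- nullspace_of(A)
      if (is.null(ns) || ncol(ns) != 1L) next
      consider(as.numeric(N %*% ns))
    }
  }
  if (!length(cands)) stop("no sign-feasible null-space vectors found")
  sizes <- vapply(cands, function(v) sum(v != 0), integer(1))
  ord <- order(sizes, vapply(cands, function(v)
    paste(which(v != 0), collapse = ","), character(1)))
  chosen <- matrix(0, n, 0)
  for (k in ord) {
    cand <- cbind(chosen, cands[[k]])
    if (matrix_rank(cand) > ncol(chosen)) chosen <- cand
    if (ncol(chosen) == d) break
  }
  if (ncol(chosen) < d)
    stop("null space not spanned by sign-feasible vectors")
  for (j in seq_len(d))
    chosen[, j] <- normalize_pathway(chosen[, j], reduced$base$S, lb, tol_zero)
  rownames(chosen) <- reduced$base$rxns
  pathway_matrix(chosen, "oracle", tol_zero)
}

#' Verify a pathway basis
#'
#' Checks the pathway-matrix invariants: steady-state residual, rank equal
#' to the null-space dimension, sign feasibility at irreversible reactions,
#' and the non-zero count.  Always returns a report.
#'
#' @param P a \code{\link{pathway_matrix}} (or plain matrix).
#' @param reduced the \code{reduced_model} the basis was computed on.
#' @param tol_null residual tolerance (default 1e-6).
#' @param tol_sign sign-violation tolerance (default 1e-6).
#' @param tol_zero non-zero threshold.
#' @return list with per-check values and booleans, and overall \code{pass}.
#' @export
verify_basis <- function(P, reduced, tol_null = 1e-6, tol_sign = 1e-6,
                         tol_zero = 1e-6) {
  M <- if (inherits(P, "pathway_matrix")) P$P else P
  S <- reduced$base$S
  d <- ncol(S) - reduced$r
  resid <- if (ncol(M)) max(abs(S %*% M)) else 0
  rk <- matrix_rank(M)
  irr <- reduced$base$lb >= 0
  sign_viol <- sum(M[irr, , drop = FALSE] < -tol_sign)
  nnz <- sum(abs(M) > tol_zero)
  checks <- c(residual = resid <= tol_null,
              rank = rk == d,
              signs = sign_viol == 0)
  list(residual = resid, rank = rk, expected_rank = d,
       sign_violations = sign_viol, nnz = nnz,
       checks = checks, pass = all(checks))
}
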