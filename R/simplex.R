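# Bounded-variable two-phase primal simplex.
#
# Solves   min  obj' x
#          s.t. A x = rhs,  lower <= x <= upper
#
# All bounds must be finite (callers encode "unbounded" with a large finite
# box; flux bounds in this package are +/- 1000 so conditioning is benign).
# Dense implementation intended for the small LPs arising from desk-scale
# metabolic models; basis systems are re-factorised at every pivot, which is
# robust and cheap at these sizes.

#' Solve a bounded-variable linear program
#'
#' Minimises \code{obj \%*\% x} subject to \code{A \%*\% x = rhs} and
#' \code{lower <= x <= upper}, using a two-phase primal simplex with bound
#' flips and Bland's anti-cycling rule.
#'
#' @param obj numeric objective vector (length n).
#' @param A constraint matrix (m x n); equality constraints only.
#' @param rhs right-hand side (length m).
#' @param lower,upper finite variable bounds (length n).
#' @param maximize if \code{TRUE}, maximises instead.
#' @param tol numeric feasibility/optimality tolerance.
#' @param max_iter iteration cap across both phases.
#'
#' @return list with \code{status} (\code{"optimal"}, \code{"infeasible"} or
#'   \code{"unbounded"}), \code{x} (solution, or \code{NULL}), and
#'   \code{objval}.
#' @keywords internal
lp_bounded <- function(obj, A, rhs, lower, upper, maximize = FALSE,
                       tol = 1e-9, max_iter = 10000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m,
            length(lower) == n, length(upper) == n)
  if (any(!is.finite(lower)) || any(!is.finite(upper)))
    stop("lp_bounded requires finite bounds")
  if (any(lower > upper + tol))
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  obj <- if (maximize) -as.numeric(obj) else as.numeric(obj)

  # Fixed variables with lower == upper are handled like any other (width 0).
  # Append one artificial per row; sign chosen so artificials start >= 0.
  start <- ifelse(abs(lower) <= abs(upper), lower, upper)
  resid <- rhs - as.numeric(A %*% start)
  sgn <- ifelse(resid >= 0, 1, -1)
  Aall <- cbind(A, diag(sgn, m))
  big <- max(1, sum(abs(resid))) * 2
  lo <- c(lower, rep(0, m))
  up <- c(upper, rep(big, m))

  nt <- n + m
  basis <- (n + 1L):nt
  # status of nonbasic vars: TRUE = at lower bound, FALSE = at upper
  at_lower <- c(abs(start - lower) <= abs(start - upper), rep(TRUE, m))
  in_basis <- c(rep(FALSE, n), rep(TRUE, m))

  xval <- c(start, abs(resid))

  Binv <- NULL
  refactor <- function() {
    B <- Aall[, basis, drop = FALSE]
    Binv <<- tryCatch(solve(B), error = function(e) NULL)
    if (is.null(Binv)) {            # near-singular basis: pseudo-inverse
      sv <- svd(B)
      dinv <- ifelse(sv$d > max(sv$d) * 1e-12, 1 / sv$d, 0)
      Binv <<- sv$v %*% (dinv * t(sv$u))
    }
  }

  run_phase <- function(cost, phase1) {
    it <- 0L; since_refactor <- 1000L
    repeat {
      it <- it + 1L
      if (it > max_iter) stop("simplex iteration limit reached")
      if (since_refactor > 40L) { refactor(); since_refactor <- 0L }
      nb <- which(!in_basis)
      xN <- xval[nb]
      xB <- as.numeric(Binv %*% (rhs - Aall[, nb, drop = FALSE] %*% xN))
      xval[basis] <<- xB
      y <- as.numeric(crossprod(Binv, cost[basis]))
      rc <- cost[nb] - as.numeric(crossprod(Aall[, nb, drop = FALSE], y))
      # candidate entering variables
      improving <- (at_lower[nb] & rc < -tol) | (!at_lower[nb] & rc > tol)
      if (!any(improving)) {
        return(list(optimal = TRUE, objval = sum(cost * xval)))
      }
      use_bland <- it > 0.6 * max_iter
      cand <- nb[improving]
      if (use_bland) {
        j <- min(cand)
      } else {
        j <- cand[which.max(abs(rc[improving]))]
      }
      # direction: entering moves up from lower (+1) or down from upper (-1)
      s <- if (at_lower[j]) 1 else -1
      d <- as.numeric(Binv %*% Aall[, j])   # xB changes by -s*d*t
      t_own <- up[j] - lo[j]                # bound-to-bound flip distance
      t_best <- t_own; leave <- 0L; leave_to_lower <- TRUE
      for (k in seq_len(m)) {
        dk <- s * d[k]
        if (abs(dk) <= 1e-9) next
        bi <- basis[k]
        if (dk > 0) {                        # xB[k] decreases
          tk <- (xval[bi] - lo[bi]) / dk
          if (tk < t_best - 1e-12) { t_best <- tk; leave <- k; leave_to_lower <- TRUE }
        } else {                             # xB[k] increases
          tk <- (xval[bi] - up[bi]) / dk
          if (tk < t_best - 1e-12) { t_best <- tk; leave <- k; leave_to_lower <- FALSE }
        }
      }
      if (!is.finite(t_best)) return(list(optimal = FALSE, objval = -Inf))
      t_best <- max(t_best, 0)
      # apply step
      xval[basis] <<- xval[basis] - s * d * t_best
      xval[j] <<- xval[j] + s * t_best
      if (leave == 0L) {                     # bound flip, basis unchanged
        at_lower[j] <<- !at_lower[j]
      } else {
        bi <- basis[leave]
        in_basis[bi] <<- FALSE
        at_lower[bi] <<- leave_to_lower
        xval[bi] <<- if (leave_to_lower) lo[bi] else up[bi]
        in_basis[j] <<- TRUE
        basis[leave] <<- j
        dl <- d[leave]
        if (abs(dl) < 1e-10) { since_refactor <- 1000L } else {
          # eta update of the maintained inverse
          row_l <- Binv[leave, ] / dl
          Binv <<- Binv - outer(d, row_l)
          Binv[leave, ] <<- row_l
          since_refactor <- since_refactor + 1L
        }
      }
    }
  }

  # Phase 1: drive artificials to zero.
  c1 <- c(rep(0, n), rep(1, m))
  r1 <- run_phase(c1, phase1 = TRUE)
  if (!r1$optimal || r1$objval > 1e-7 * max(1, max(abs(rhs))))
    return(list(status = "infeasible", x = NULL, objval = NA_real_))
  # Freeze artificials at zero for phase 2 (keep basic degenerate ones).
  up[(n + 1L):nt] <- 0
  xval[(n + 1L):nt][!in_basis[(n + 1L):nt]] <- 0

  c2 <- c(obj, rep(0, m))
  r2 <- run_phase(c2, phase1 = FALSE)
  if (!r2$optimal)
    return(list(status = "unbounded", x = NULL,
                objval = if (maximize) Inf else -Inf))
  x <- xval[seq_len(n)]
  ov <- sum(obj * x)
  list(status = "optimal", x = x, objval = if (maximize) -ov else ov)
}
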