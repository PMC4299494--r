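# Branch-and-bound MILP for the sparsest (or densest / randomly weighted)
# feasible null-space column spanning a prescribed direction.
#
# One replacement subproblem of the pathway sweep is, in MILP form:
#
#   minimise   sum_i w_i * b_i                  (b_i binary)
#   subject to S v = 0
#              lb <= v <= ub
#              |v_i| <= M b_i                   (M = 1000, the flux bound)
#              x' v != 0, encoded as the disjunction
#                x'v >= eps  (f+ = 1)   or   x'v <= -eps  (f- = 1)
#              and, when w_i < 0 must be rewarded (MaxSpan/RandSpan),
#              b_i = 1 => |v_i| >= eps          ("OR" linking binaries)
#
# with w = 1 (MinSpan), w = -1 (MaxSpan) or w ~ U(-0.5, 0.5) (RandSpan),
# and eps = 0.1.  The two f branches are solved as separate trees.  The
# branch-and-bound branches directly on the b_i:
#   w_i > 0:  b_i = 0 (v_i fixed 0)  |  b_i = 1 (cost w_i committed)
#   w_i < 0:  b_i = 0 (v_i fixed 0)  |  b_i = 1 with v_i >= eps
#                                    |  b_i = 1 with v_i <= -eps
# Every node LP solution is itself a feasible flux vector, so b = the
# support indicator of the LP solution supplies incumbents throughout.

#' Solver options for the pathway sweep
#'
#' @param rel_gap relative optimality gap for each MILP (default 1e-3).
#' @param time_limit seconds per MILP (default 60; genome-scale runs in the
#'   field use 1800).
#' @param seed integer seed for randomised objective weights.
#' @param epsilon margin of the not-equal constraint (default 0.1).
#' @param tol_zero threshold separating solver noise from structural zeros
#'   when counting non-zero entries (default 1e-6).
#' @param max_sweeps cap on full sweeps of the column loop.
#' @return list of class \code{solver_options}.
#' @export
solver_options <- function(rel_gap = 1e-3, time_limit = 60, seed = 1L,
                           epsilon = 0.1, tol_zero = 1e-6, max_sweeps = 20L) {
  stopifnot(rel_gap > 0, time_limit > 0, epsilon > 0)
  structure(list(rel_gap = rel_gap, time_limit = time_limit,
                 seed = as.integer(seed), epsilon = epsilon,
                 tol_zero = tol_zero, max_sweeps = as.integer(max_sweeps)),
            class = "solver_options")
}

# Solve one sign branch (s = +1 or -1 on x'v >= eps) by branch-and-bound.
# weights: per-reaction cost of support membership.
# Returns list(v, cost, status, nodes); v = NULL when infeasible/no incumbent.
bb_column <- function(S, lb, ub, x, s, weights, opts,
                      incumbent_v = NULL, incumbent_cost = Inf,
                      deadline = Inf) {
  n <- ncol(S); m <- nrow(S)
  eps <- opts$epsilon; tolz <- opts$tol_zero
  w <- weights
  cost_of <- function(v) sum(w[abs(v) > tolz])

  best_v <- NULL; best_cost <- incumbent_cost
  if (!is.null(incumbent_v)) {
    best_v <- incumbent_v; best_cost <- min(best_cost, cost_of(incumbent_v))
  }
  nodes <- 0L; timed_out <- FALSE

  # Node LP.  Variables: v (n), t (|v| surrogates for the free
  # positive-weight reactions), slack for the x-constraint, slacks for the
  # t links.
  node_lp <- function(zfix, pay, fpos, fneg) {
    lo <- lb; up <- ub
    lo[zfix] <- 0; up[zfix] <- 0
    lo[fpos] <- pmax(lo[fpos], eps)
    up[fneg] <- pmin(up[fneg], -eps)
    if (any(lo > up)) return(NULL)
    pos_w <- setdiff(which(w > 0), c(zfix, pay, fpos, fneg))
    npos <- length(pos_w)
    # columns: v (n), t (npos), sx (1), st (2*npos)
    nv <- n + npos + 1L + 2L * npos
    nrow_ <- m + 1L + 2L * npos
    A <- matrix(0, nrow_, nv)
    A[seq_len(m), seq_len(n)] <- S
    rhs <- numeric(nrow_)
    # s * x'v - sx = eps
    A[m + 1L, seq_len(n)] <- s * x
    A[m + 1L, n + npos + 1L] <- -1
    rhs[m + 1L] <- eps
    # t_i - v_i - st1 = 0 ; t_i + v_i - st2 = 0  => t_i >= |v_i|
    for (k in seq_along(pos_w)) {
      i <- pos_w[k]
      r1 <- m + 1L + 2L * k - 1L; r2 <- m + 1L + 2L * k
      A[r1, i] <- -1; A[r1, n + k] <- 1; A[r1, n + npos + 1L + 2L * k - 1L] <- -1
      A[r2, i] <-  1; A[r2, n + k] <- 1; A[r2, n + npos + 1L + 2L * k] <- -1
    }
    big <- sum(abs(x)) * FLUX_BOUND + abs(eps) + 1
    lower <- c(lo, rep(0, npos), 0, rep(0, 2L * npos))
    upper <- c(up, rep(FLUX_BOUND, npos), big, rep(2 * FLUX_BOUND, 2L * npos))
    objv <- c(rep(0, n), rep(1, npos), 0, rep(0, 2L * npos))
    r <- lp_bounded(objv, A, rhs, lower, upper)
    if (r$status != "optimal") return(NULL)
    r$x[seq_len(n)]
  }

  # DFS over nodes
  stack <- list(list(zfix = integer(0), pay = integer(0),
                     fpos = integer(0), fneg = integer(0)))
  while (length(stack)) {
    if (proc.time()[["elapsed"]] > deadline) { timed_out <- TRUE; break }
    nd <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    fixed <- c(nd$pay, nd$fpos, nd$fneg)
    free <- setdiff(seq_len(n), c(nd$zfix, fixed))
    lbound <- sum(w[fixed]) + sum(pmin(w[free], 0))
    if (is.finite(best_cost) &&
        lbound >= best_cost - opts$rel_gap * max(1, abs(best_cost)) - 1e-9) next
    v <- node_lp(nd$zfix, nd$pay, nd$fpos, nd$fneg)
    nodes <- nodes + 1L
    if (is.null(v)) next
    cv <- cost_of(v)
    if (cv < best_cost - 1e-9) { best_cost <- cv; best_v <- v }
    insupp <- abs(v) > tolz
    cand_drop <- free[w[free] > 0 & insupp[free]]    # costly, try excluding
    cand_add <- free[w[free] < 0 & !insupp[free]]    # rewarded, try forcing in
    if (!length(cand_drop) && !length(cand_add)) next   # leaf
    if (length(cand_drop)) {
      i <- cand_drop[which.min(abs(v[cand_drop]))]
      # depth-first: exclusion branch explored first (pushed last)
      stack[[length(stack) + 1L]] <- modifyList(nd, list(pay = c(nd$pay, i)))
      stack[[length(stack) + 1L]] <- modifyList(nd, list(zfix = c(nd$zfix, i)))
    } else {
      i <- cand_add[which.max(abs(w[cand_add]))]
      stack[[length(stack) + 1L]] <- modifyList(nd, list(zfix = c(nd$zfix, i)))
      stack[[length(stack) + 1L]] <- modifyList(nd, list(fneg = c(nd$fneg, i)))
      stack[[length(stack) + 1L]] <- modifyList(nd, list(fpos = c(nd$fpos, i)))
    }
  }
  status <- if (timed_out) "timeout"
  else if (is.null(best_v)) "infeasible" else "optimal"
  list(v = best_v, cost = best_cost, status = status, nodes = nodes)
}

# Dense feasible heuristic: positive combination of per-reaction extremal
# feasible points (all honouring s*x'v >= eps), used to seed MaxSpan /
# RandSpan incumbents.  Deterministic.
dense_heuristic <- function(S, lb, ub, x, s, eps) {
  n <- ncol(S); m <- nrow(S)
  A <- rbind(cbind(S, 0), c(s * x, -1))
  rhs <- c(numeric(m), eps)
  big <- sum(abs(x)) * FLUX_BOUND + eps + 1
  lower <- c(lb, 0); upper <- c(ub, big)
  sols <- list()
  for (j in seq_len(n)) {
    obj <- numeric(n + 1L); obj[j] <- 1
    hi <- lp_bounded(obj, A, rhs, lower, upper, maximize = TRUE)
    if (hi$status == "optimal" && abs(hi$x[j]) > 1e-7)
      sols[[length(sols) + 1L]] <- hi$x[seq_len(n)]
    if (lb[j] < 0) {
      lo <- lp_bounded(obj, A, rhs, lower, upper)
      if (lo$status == "optimal" && abs(lo$x[j]) > 1e-7)
        sols[[length(sols) + 1L]] <- lo$x[seq_len(n)]
    }
  }
  if (!length(sols)) return(NULL)
  phi <- (sqrt(5) - 1) / 2
  lam <- 0.5 + 0.5 * ((seq_along(sols) * phi) %% 1)
  v <- Reduce(`+`, Map(`*`, sols, lam))
  sc <- min(1, FLUX_BOUND / max(abs(v)))
  v <- v * sc
  if (s * sum(x * v) < eps) return(NULL)
  v
}

#' Solve one column-replacement subproblem
#'
#' Finds the feasible steady-state flux vector with minimal weighted
#' support that spans the direction \code{x} (enforced through
#' \code{|x'v| >= epsilon}); both orientations of the not-equal constraint
#' are solved and the better kept.
#'
#' @param reduced a \code{reduced_model}.
#' @param x unit direction vector in the null space, orthogonal to the
#'   retained columns.
#' @param opts a \code{\link{solver_options}}.
#' @param weights per-reaction support costs (1 = MinSpan, -1 = MaxSpan,
#'   uniform random = RandSpan).
#' @param incumbent_v optional feasible starting solution.
#' @return list with \code{v} (the column, or \code{NULL} if no incumbent
#'   was found in time), \code{cost}, \code{status}, \code{nodes}.
#' @export
solve_replacement <- function(reduced, x, opts = solver_options(),
                              weights = NULL, incumbent_v = NULL) {
  S <- reduced$base$S; lb <- reduced$base$lb; ub <- reduced$base$ub
  n <- ncol(S)
  if (is.null(weights)) weights <- rep(1, n)
  deadline <- proc.time()[["elapsed"]] + opts$time_limit
  inc <- list(v = NULL, cost = Inf)
  if (!is.null(incumbent_v)) inc <- list(v = incumbent_v,
                                         cost = sum(weights[abs(incumbent_v) > opts$tol_zero]))
  best <- list(v = inc$v, cost = inc$cost, status = "infeasible", nodes = 0L)
  for (s in c(1, -1)) {
    seed_v <- best$v
    if (s * sum(x * (seed_v %||% 0)) < opts$epsilon) seed_v <- NULL
    if (any(weights < 0)) {
      dh <- dense_heuristic(S, lb, ub, x, s, opts$epsilon)
      if (!is.null(dh)) {
        ch <- sum(weights[abs(dh) > opts$tol_zero])
        if (is.null(seed_v) || ch < sum(weights[abs(seed_v) > opts$tol_zero]))
          seed_v <- dh
      }
    }
    r <- bb_column(S, lb, ub, x, s, weights, opts,
                   incumbent_v = seed_v, incumbent_cost = best$cost,
                   deadline = deadline)
    r$nodes <- r$nodes + best$nodes
    if (!is.null(r$v) && r$cost < best$cost - 1e-9)
      best <- list(v = r$v, cost = r$cost, status = r$status, nodes = r$nodes)
    else best$nodes <- r$nodes
    if (r$status == "timeout") best$status <- "timeout"
  }
  if (!is.null(best$v) && best$status == "infeasible") best$status <- "optimal"
  best
}

`%||%` <- function(a, b) if (is.null(a)) b else a
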