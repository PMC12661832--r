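# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# The metabolic models handled here are deliberately small (tens of
# reactions), so a dense tableau is both adequate and easy to audit.
# Constraint: Bland's rule guarantees termination; the iteration cap is a
# safety net only.

#' Solve a linear program
#'
#' Minimises or maximises \code{obj \%*\% x} subject to
#' \code{A_ub \%*\% x <= b_ub}, \code{A_eq \%*\% x == b_eq} and \code{x >= 0}.
#' Intended for the small flux-balance problems built by [solve_fba()]; the
#' implementation is a textbook two-phase tableau simplex using Bland's
#' pivoting rule so that degenerate bases cannot cycle.
#'
#' @param obj numeric objective coefficient vector.
#' @param A_ub,b_ub inequality constraints (may be `NULL`).
#' @param A_eq,b_eq equality constraints (may be `NULL`).
#' @param maximize logical; maximise instead of minimise.
#' @param tol numerical feasibility/pivot tolerance.
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   `objective` and the primal solution `x`.
#' @keywords internal
lp_solve <- function(obj, A_ub = NULL, b_ub = NULL, A_eq = NULL, b_eq = NULL,
                     maximize = FALSE, tol = 1e-9) {
  n <- length(obj)
  A_ub <- if (is.null(A_ub)) matrix(0, 0L, n) else matrix(A_ub, ncol = n)
  A_eq <- if (is.null(A_eq)) matrix(0, 0L, n) else matrix(A_eq, ncol = n)
  b_ub <- as.numeric(b_ub)
  b_eq <- as.numeric(b_eq)
  stopifnot(nrow(A_ub) == length(b_ub), nrow(A_eq) == length(b_eq))

  m_ub <- nrow(A_ub)
  m_eq <- nrow(A_eq)
  m <- m_ub + m_eq
  A <- rbind(A_ub, A_eq)
  b <- c(b_ub, b_eq)

  # slack columns: +1 for each <= row (surplus -1 once the row is negated)
  slack <- matrix(0, m, m_ub)
  if (m_ub > 0L) slack[cbind(seq_len(m_ub), seq_len(m_ub))] <- 1

  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    slack[neg, ] <- -slack[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }

  # artificials wherever the slack column cannot serve as the initial basis:
  # every equality row and every negated inequality row
  need_art <- c(neg[seq_len(m_ub)], rep(TRUE, m_eq))
  art_rows <- which(need_art)
  n_art <- length(art_rows)
  art <- matrix(0, m, n_art)
  if (n_art > 0L) art[cbind(art_rows, seq_len(n_art))] <- 1

  Tbl <- cbind(A, slack, art, b)
  n_tot <- n + m_ub + n_art

  basis <- integer(m)
  if (m_ub > 0L) basis[seq_len(m_ub)] <- n + seq_len(m_ub)
  basis[art_rows] <- n + m_ub + seq_len(n_art)

  run_phase <- function(Tbl, basis, cost, allowed) {
    # cost: full-length cost vector to minimise over allowed columns
    repeat_count <- 0L
    max_iter <- 20000L
    repeat {
      repeat_count <- repeat_count + 1L
      if (repeat_count > max_iter) stop("simplex iteration limit exceeded")
      cb <- cost[basis]
      red <- cost[seq_len(n_tot)] -
        as.numeric(crossprod(cb, Tbl[, seq_len(n_tot), drop = FALSE]))
      red[!allowed] <- Inf
      enter_candidates <- which(red < -tol)
      if (length(enter_candidates) == 0L) {
        return(list(Tbl = Tbl, basis = basis, status = "optimal"))
      }
      j <- enter_candidates[1L]                     # Bland: smallest index
      col <- Tbl[, j]
      pos <- which(col > tol)
      if (length(pos) == 0L) {
        return(list(Tbl = Tbl, basis = basis, status = "unbounded"))
      }
      ratio <- Tbl[pos, n_tot + 1L] / col[pos]
      rmin <- min(ratio)
      cand <- pos[ratio <= rmin + tol]
      i <- cand[which.min(basis[cand])]             # Bland on ties
      piv <- Tbl[i, j]
      Tbl[i, ] <- Tbl[i, ] / piv
      fac <- Tbl[, j]
      fac[i] <- 0
      Tbl <- Tbl - tcrossprod(fac, Tbl[i, ])
      basis[i] <- j
    }
  }

  if (n_art > 0L) {
    cost1 <- c(rep(0, n + m_ub), rep(1, n_art), 0)
    ph1 <- run_phase(Tbl, basis, cost1, allowed = rep(TRUE, n_tot))
    Tbl <- ph1$Tbl; basis <- ph1$basis
    ph1_obj <- sum(cost1[basis] * Tbl[, n_tot + 1L])
    if (ph1_obj > 1e-7) {
      return(list(status = "infeasible", objective = NA_real_, x = NULL))
    }
    # pivot lingering degenerate artificials out of the basis where possible
    art_idx <- n + m_ub + seq_len(n_art)
    for (i in which(basis %in% art_idx)) {
      row <- Tbl[i, seq_len(n + m_ub)]
      j <- which(abs(row) > tol)[1L]
      if (!is.na(j)) {
        piv <- Tbl[i, j]
        Tbl[i, ] <- Tbl[i, ] / piv
        other <- setdiff(seq_len(m), i)
        if (length(other) > 0L) {
          Tbl[other, ] <- Tbl[other, , drop = FALSE] -
            outer(Tbl[other, j], Tbl[i, ])
        }
        basis[i] <- j
      }
    }
    allowed <- rep(TRUE, n_tot)
    allowed[art_idx] <- FALSE
  } else {
    allowed <- rep(TRUE, n_tot)
  }

  cost2 <- c(if (maximize) -obj else obj, rep(0, m_ub + n_art), 0)
  ph2 <- run_phase(Tbl, basis, cost2, allowed)
  if (ph2$status == "unbounded") {
    return(list(status = "unbounded", objective = NA_real_, x = NULL))
  }
  Tbl <- ph2$Tbl; basis <- ph2$basis
  x <- numeric(n_tot)
  x[basis] <- Tbl[, n_tot + 1L]
  xr <- x[seq_len(n)]
  objv <- sum(obj * xr)
  list(status = "optimal", objective = objv, x = xr)
}

#' Solve a bounded-variable linear program
#'
#' Wrapper around [lp_solve()] handling general finite variable bounds
#' `lower <= v <= upper` and equality constraints `S v = b` by shifting to
#' non-negative variables. Infinite bounds are clamped to a large finite box
#' (1e6), generous relative to any flux magnitude arising in these models.
#'
#' @param obj objective over the original variables.
#' @param S equality constraint matrix (may have zero rows).
#' @param b equality right-hand side.
#' @param lower,upper variable bounds.
#' @param maximize maximise instead of minimise.
#' @return list(status, objective, x) on the original variable scale.
#' @keywords internal
lp_solve_bounded <- function(obj, S, b, lower, upper, maximize = FALSE) {
  n <- length(obj)
  big <- 1e6
  lower <- pmax(lower, -big)
  upper <- pmin(upper, big)
  if (any(lower > upper + 1e-12)) {
    stop("infeasible bounds: lower bound exceeds upper bound")
  }
  S <- if (is.null(S) || length(S) == 0L) matrix(0, 0L, n) else matrix(S, ncol = n)
  b <- as.numeric(b)
  # shift x = v - lower, x >= 0
  b_eq <- b - as.numeric(S %*% lower)
  span <- upper - lower
  A_ub <- diag(1, n)
  res <- lp_solve(obj,
                  A_ub = A_ub, b_ub = span,
                  A_eq = S, b_eq = b_eq,
                  maximize = maximize)
  if (res$status != "optimal") return(res)
  v <- res$x + lower
  list(status = "optimal", objective = sum(obj * v), x = v)
}
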