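# Independent oracles used to cross-check the package's implementations.
# Each deliberately takes a different computational route than the code it
# verifies.

# Brute-force LP: enumerate all basic solutions of the standard form
# (inequalities get slacks), keep the best feasible one.
brute_lp <- function(obj, A_ub = NULL, b_ub = NULL, A_eq = NULL,
                     b_eq = NULL, maximize = FALSE) {
  n <- length(obj)
  A_ub <- if (is.null(A_ub)) matrix(0, 0, n) else matrix(A_ub, ncol = n)
  A_eq <- if (is.null(A_eq)) matrix(0, 0, n) else matrix(A_eq, ncol = n)
  A <- rbind(cbind(A_ub, diag(1, nrow(A_ub))),
             cbind(A_eq, matrix(0, nrow(A_eq), nrow(A_ub))))
  b <- c(b_ub, b_eq)
  m <- nrow(A); N <- ncol(A)
  best <- NULL
  for (cols in utils::combn(N, min(m, N), simplify = FALSE)) {
    B <- A[, cols, drop = FALSE]
    if (nrow(B) != ncol(B) || abs(det(B)) < 1e-10) next
    x <- tryCatch(solve(B, b), error = function(e) NULL)
    if (is.null(x) || any(x < -1e-8)) next
    full <- numeric(N); full[cols] <- x
    v <- sum(obj * full[seq_len(n)])
    if (is.null(best) || (maximize && v > best) ||
        (!maximize && v < best)) best <- v
  }
  best
}

# Brute-force FBA optimum of a gem under given uptake caps, via the
# vertex-enumeration LP on the bounded problem converted to standard form.
brute_fba <- function(model, uptake_bounds = numeric(), big = 1e6) {
  S <- stoichiometric_matrix(model)
  rxn_ids <- colnames(S)
  lb <- vapply(model$reactions, `[[`, 0, "lower_bound")[rxn_ids]
  ub <- vapply(model$reactions, `[[`, 0, "upper_bound")[rxn_ids]
  for (r in model$reactions) {
    if (r$is_exchange) {
      met <- names(r$stoichiometry)
      cap <- if (met %in% names(uptake_bounds)) uptake_bounds[[met]] else 0
      lb[r$id] <- max(lb[r$id], -cap)
    }
  }
  lb <- pmax(lb, -big); ub <- pmin(ub, big)
  n <- length(rxn_ids)
  obj <- as.numeric(rxn_ids == model$biomass_reaction_id)
  # shift x = v - lb >= 0; upper bounds become inequality rows
  b_eq <- -as.numeric(S %*% lb)
  brute_lp(obj, A_ub = diag(1, n), b_ub = ub - lb,
           A_eq = S, b_eq = b_eq, maximize = TRUE) + sum(obj * lb)
}

# MI via the entropy identity H(X) + H(Y) - H(X,Y) computed from table()
brute_mi <- function(x, y) {
  ent <- function(tab) {
    p <- tab / sum(tab)
    p <- p[p > 0]
    -sum(p * log(p))
  }
  ent(table(x)) + ent(table(y)) - ent(table(paste(x, y)))
}

# Spearman rho as Pearson correlation of midranks
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Exact two-sided Wilcoxon rank-sum p by enumerating all group assignments
# (valid without ties; the null distribution is symmetric so the
# tail-doubling and extremity definitions agree)
enum_wilcoxon <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(nx)])
  combs <- utils::combn(nx + ny, nx, simplify = FALSE)
  w_all <- vapply(combs, function(idx) sum(r[idx]), 0)
  mu <- nx * (nx + ny + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-12)
}

# Benjamini-Hochberg step-up by hand
manual_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in seq(n, 1)) {
    val <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# hand-written Jaccard / Bray-Curtis
manual_jaccard <- function(a, b) {
  u <- sum(a == 1 | b == 1)
  if (u == 0) return(0)
  1 - sum(a == 1 & b == 1) / u
}
manual_bray <- function(a, b) {
  s <- sum(a + b)
  if (s == 0) return(0)
  sum(abs(a - b)) / s
}

# naive complete-linkage agglomeration returning k cluster labels
naive_complete_linkage <- function(X, k) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  clusters <- as.list(seq_len(n))
  while (length(clusters) > k) {
    best <- c(Inf, NA, NA)
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (j <= i) next
      d <- max(D[clusters[[i]], clusters[[j]]])
      if (d < best[1]) best <- c(d, i, j)
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
  }
  lab <- integer(n)
  for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
  lab
}
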