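# Dense two-phase primal simplex with Bland's anti-cycling rule.
#
# Solves   min cost' z   s.t.  A z = b,  z >= 0
# by the classical full-tableau method: phase 1 minimises the sum of
# artificial variables to find a basic feasible solution, phase 2 optimises
# the true objective with artificials banned from re-entering. Bland's rule
# (always the lowest-index eligible column; lowest-index basic variable on
# ratio ties) guarantees termination and makes every solve deterministic.
#
# This is the computational core under fba()/fva(). It is intentionally
# simple — problems here are toy-to-medium scale and correctness is policed
# by an independent vertex-enumeration oracle in the test suite.

simplex_solve <- function(cost, A, b, eps = 1e-9, max_iter = 100000L) {
  m <- nrow(A)
  n <- ncol(A)
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
  }

  # phase 1: artificials n+1 .. n+m form the initial identity basis
  Tb <- cbind(A, diag(m), b, deparse.level = 0)
  basis <- n + seq_len(m)
  cost1 <- c(rep(0, n), rep(1, m))
  ph1 <- simplex_iterate(Tb, basis, cost1, n + m, banned = integer(0),
                         eps = eps, max_iter = max_iter)
  if (ph1$status != "optimal") return(list(status = ph1$status))
  Tb <- ph1$T
  basis <- ph1$basis
  feas <- sum(cost1[basis] * Tb[, ncol(Tb)])
  if (feas > 1e-7 * max(1, max(abs(b)))) return(list(status = "infeasible"))

  # drive leftover artificials out of the basis; drop redundant rows
  drop_rows <- integer(0)
  for (i in seq_along(basis)) {
    if (basis[i] <= n) next
    piv <- which(abs(Tb[i, seq_len(n)]) > eps)
    if (length(piv)) {
      Tb <- simplex_pivot(Tb, i, piv[1L])
      basis[i] <- piv[1L]
    } else {
      drop_rows <- c(drop_rows, i)  # redundant constraint
    }
  }
  if (length(drop_rows)) {
    Tb <- Tb[-drop_rows, , drop = FALSE]
    basis <- basis[-drop_rows]
  }

  cost2 <- c(cost, rep(0, m))
  ph2 <- simplex_iterate(Tb, basis, cost2, n + m,
                         banned = n + seq_len(m), eps = eps,
                         max_iter = max_iter)
  if (ph2$status != "optimal") return(list(status = ph2$status))
  z <- numeric(n)
  sel <- ph2$basis <= n
  z[ph2$basis[sel]] <- ph2$T[sel, ncol(ph2$T)]
  list(status = "optimal", z = z, value = sum(cost * z))
}

simplex_pivot <- function(Tb, pr, pc) {
  Tb[pr, ] <- Tb[pr, ] / Tb[pr, pc]
  other <- setdiff(seq_len(nrow(Tb)), pr)
  Tb[other, ] <- Tb[other, ] - outer(Tb[other, pc], Tb[pr, ])
  Tb
}

simplex_iterate <- function(Tb, basis, cost, ncols, banned, eps, max_iter) {
  rhs_col <- ncol(Tb)
  for (iter in seq_len(max_iter)) {
    cb <- cost[basis]
    # reduced costs r = c - cb' B^-1 A  (tableau rows are already B^-1 A)
    r <- cost - as.numeric(cb %*% Tb[, seq_len(ncols), drop = FALSE])
    elig <- which(r < -eps)
    elig <- setdiff(setdiff(elig, banned), basis)
    if (length(elig) == 0L)
      return(list(status = "optimal", T = Tb, basis = basis))
    j <- min(elig)  # Bland: lowest index enters
    col <- Tb[, j]
    pos <- which(col > eps)
    if (length(pos) == 0L)
      return(list(status = "unbounded"))
    ratios <- Tb[pos, rhs_col] / col[pos]
    best <- min(ratios)
    tie <- pos[ratios <= best + eps * max(1, abs(best))]
    pr <- tie[which.min(basis[tie])]  # Bland: lowest basic index leaves
    Tb <- simplex_pivot(Tb, pr, j)
    basis[pr] <- j
  }
  list(status = "maxiter")
}
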