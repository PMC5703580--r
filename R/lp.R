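#' Solve a small dense linear program
#'
#' Minimal solver contract used by all flux-balance computations in the
#' package: a dense constraint matrix with equality / less-than rows, simple
#' variable bounds, and a linear objective. Solved with a two-phase primal
#' simplex using Bland's anti-cycling rule; intended for the small, dense
#' programs arising from curated metabolic networks (tens of variables), not
#' for genome-scale work.
#'
#' @param obj numeric objective coefficients (length n).
#' @param A dense constraint matrix (m x n).
#' @param b right-hand side (length m).
#' @param sense character vector of "=" or "<=" per row.
#' @param lb,ub variable bounds; `lb` must be finite (split free variables
#'   before calling), `ub` may be `Inf`.
#' @param maximize maximize instead of minimize.
#' @param eps optimality / feasibility tolerance on reduced costs and the
#'   phase-1 objective.
#' @return list with `status` ("optimal", "infeasible" or "unbounded"),
#'   primal vector `x`, objective `objval`, and for unbounded problems
#'   `unbounded_var`, the index of the offending column.
#' @keywords internal
#' @export
solve_lp <- function(obj, A, b, sense, lb = rep(0, length(obj)),
                     ub = rep(Inf, length(obj)), maximize = FALSE,
                     eps = 1e-9) {
  A <- as.matrix(A)
  n <- length(obj)
  stopifnot(ncol(A) == n, nrow(A) == length(b), length(sense) == length(b),
            all(sense %in% c("=", "<=")), all(is.finite(lb)), all(ub >= lb))

  ## shift variables so that all lower bounds are zero
  if (any(lb != 0)) {
    b <- b - as.vector(A %*% lb)
    ubs <- ub - lb
  } else ubs <- ub
  cvec <- if (maximize) -obj else obj

  ## slacks for "<=" rows
  le <- which(sense == "<=")
  if (length(le)) {
    S <- matrix(0, nrow(A), length(le))
    S[cbind(le, seq_along(le))] <- 1
    A <- cbind(A, S)
    cvec <- c(cvec, rep(0, length(le)))
    ubs <- c(ubs, rep(Inf, length(le)))
  }
  ## finite upper bounds as extra rows x_j + s = ub_j
  fin <- which(is.finite(ubs))
  if (length(fin)) {
    U <- matrix(0, length(fin), ncol(A))
    U[cbind(seq_along(fin), fin)] <- 1
    A <- rbind(A, U)
    b <- c(b, ubs[fin])
    S <- rbind(matrix(0, nrow(A) - length(fin), length(fin)), diag(length(fin)))
    A <- cbind(A, S)
    cvec <- c(cvec, rep(0, length(fin)))
  }

  m <- nrow(A); ntot <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]

  ## phase 1: artificial basis
  Tm <- cbind(A, diag(m), b)
  basis <- ntot + seq_len(m)
  c1 <- c(rep(0, ntot), rep(1, m))
  r1 <- simplex_iterate(Tm, basis, c1, ncols = ntot + m, eps = eps)
  Tm <- r1$Tm; basis <- r1$basis
  p1 <- sum(Tm[basis > ntot, ntot + m + 1])
  if (r1$status == "unbounded")
    stop("phase-1 simplex reported an unbounded problem; malformed input")
  if (p1 > eps * max(1, max(abs(b))))
    return(list(status = "infeasible", x = NULL, objval = NA_real_))

  ## drive remaining (degenerate) artificials out of the basis
  keep_rows <- rep(TRUE, m)
  for (i in seq_len(m)) {
    if (basis[i] > ntot) {
      piv <- which(abs(Tm[i, seq_len(ntot)]) > 1e-9)
      piv <- setdiff(piv, basis)
      if (length(piv)) {
        Tm <- simplex_pivot(Tm, i, piv[1])
        basis[i] <- piv[1]
      } else keep_rows[i] <- FALSE  # redundant row
    }
  }
  Tm <- Tm[keep_rows, , drop = FALSE]
  basis <- basis[keep_rows]

  ## phase 2 on decision + slack columns only
  Tm2 <- Tm[, c(seq_len(ntot), ntot + m + 1), drop = FALSE]
  r2 <- simplex_iterate(Tm2, basis, cvec, ncols = ntot, eps = eps)
  if (r2$status == "unbounded")
    return(list(status = "unbounded", x = NULL, objval = NA_real_,
                unbounded_var = r2$entering))
  Tm2 <- r2$Tm; basis <- r2$basis
  x <- numeric(ntot)
  x[basis] <- Tm2[, ntot + 1]
  x <- pmax(x, 0)
  xdec <- x[seq_len(n)] + lb
  objval <- sum(obj * xdec)
  list(status = "optimal", x = xdec, objval = objval)
}

## One simplex phase on tableau Tm (rows = constraints, last column = rhs),
## minimizing cvec over the first `ncols` columns. Bland's rule throughout.
simplex_iterate <- function(Tm, basis, cvec, ncols, eps = 1e-9,
                            max_iter = 10000L) {
  m <- nrow(Tm)
  rhs_col <- ncol(Tm)
  for (it in seq_len(max_iter)) {
    cb <- cvec[basis]
    red <- cvec[seq_len(ncols)] -
      as.vector(crossprod(Tm[, seq_len(ncols), drop = FALSE], cb))
    red[basis[basis <= ncols]] <- 0
    cand <- which(red < -eps)
    if (!length(cand))
      return(list(status = "optimal", Tm = Tm, basis = basis))
    j <- cand[1]                       # Bland: lowest index enters
    col <- Tm[, j]
    pos <- which(col > 1e-11)
    if (!length(pos))
      return(list(status = "unbounded", Tm = Tm, basis = basis, entering = j))
    ratio <- Tm[pos, rhs_col] / col[pos]
    rmin <- min(ratio)
    ties <- pos[ratio <= rmin + 1e-12]
    i <- ties[which.min(basis[ties])]  # Bland: lowest basis index leaves
    Tm <- simplex_pivot(Tm, i, j)
    basis[i] <- j
  }
  stop("simplex failed to converge within ", max_iter, " iterations")
}

simplex_pivot <- function(Tm, i, j) {
  Tm[i, ] <- Tm[i, ] / Tm[i, j]
  other <- setdiff(seq_len(nrow(Tm)), i)
  Tm[other, ] <- Tm[other, , drop = FALSE] -
    outer(Tm[other, j], Tm[i, ])
  Tm[other, j] <- 0
  Tm
}
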