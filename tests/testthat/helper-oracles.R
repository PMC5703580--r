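## Independent oracles used across the suite. Nothing here calls the
## package's own simplex: the vertex enumerator solves tiny LPs by brute
## force over basic solutions, and pracma::linprog (when available) gives a
## third opinion in pure-inequality form.

## Brute-force LP maximizer: enumerate every basic solution of the
## standard-form system (equalities + slacked inequalities + slacked finite
## upper bounds, all variables >= 0) and return the best feasible objective.
## Only sensible for a handful of variables.
enum_lp_max <- function(obj, A, b, sense, ub, tol = 1e-9) {
  n <- length(obj)
  Afull <- as.matrix(A)
  le <- which(sense == "<=")
  if (length(le)) {
    S <- matrix(0, nrow(Afull), length(le))
    S[cbind(le, seq_along(le))] <- 1
    Afull <- cbind(Afull, S)
  }
  fin <- which(is.finite(ub))
  if (length(fin)) {
    extra <- matrix(0, length(fin), ncol(Afull))
    extra[cbind(seq_along(fin), fin)] <- 1
    Afull <- rbind(Afull, extra)
    Afull <- cbind(Afull, rbind(matrix(0, nrow(Afull) - length(fin),
                                       length(fin)),
                                diag(length(fin))))
    b <- c(b, ub[fin])
  }
  m <- nrow(Afull); ntot <- ncol(Afull)
  cfull <- c(obj, rep(0, ntot - n))
  best <- -Inf; best_x <- NULL
  for (cols in utils::combn(ntot, m, simplify = FALSE)) {
    B <- Afull[, cols, drop = FALSE]
    if (abs(det(B)) < 1e-12) next
    xb <- tryCatch(solve(B, b), error = function(e) NULL)
    if (is.null(xb) || any(xb < -tol)) next
    x <- numeric(ntot); x[cols] <- xb
    val <- sum(cfull * x)
    if (val > best + tol) { best <- val; best_x <- x[seq_len(n)] }
  }
  list(objval = best, x = best_x, feasible = is.finite(best))
}

## pracma::linprog cross-check, equalities doubled into inequalities (the
## only form that solver accepts reliably).
pracma_lp_max <- function(obj, A, b, sense, ub) {
  eq <- sense == "="
  Ai <- rbind(A[!eq, , drop = FALSE], A[eq, , drop = FALSE],
              -A[eq, , drop = FALSE])
  bi <- c(b[!eq], b[eq], -b[eq])
  fin <- which(is.finite(ub))
  if (length(fin)) {
    U <- matrix(0, length(fin), ncol(A))
    U[cbind(seq_along(fin), fin)] <- 1
    Ai <- rbind(Ai, U); bi <- c(bi, ub[fin])
  }
  res <- pracma::linprog(obj, A = Ai, b = bi, maxiter = 1000, maximize = TRUE)
  list(objval = res$fval, x = res$x)
}

## The toy-network LP in raw matrix form (variables: uptake part of S,
## secretion part of W, gly, resp, sec, z), for feeding the oracles above
## without going through the package's model builder.
toy_raw_lp <- function(params = chemofba::toy_params(), xi = 0) {
  with(params, {
    Aeq <- rbind(c(1, 0, -1, 0, 0, 0),
                 c(0, 0, 1, -1, -1, 0),
                 c(0, 0, N_F, N_R, 0, -y),
                 c(0, -1, 0, 0, 1, 0))
    A <- rbind(Aeq, c(0, 0, 0, 1 / r_max, 0, 0))
    u_cap <- if (xi == 0) V else min(V, c / xi)
    list(obj = c(0, 0, 0, 0, 0, 1), A = A,
         b = c(0, 0, e, 0, 1), sense = c(rep("=", 4), "<="),
         ub = c(u_cap, Inf, Inf, Inf, Inf, Inf))
  })
}

expect_feasible_solution <- function(bundle, xi, sol, tol = 1e-6) {
  v <- chemofba::validate_solution(bundle$model, bundle$medium, xi, sol, tol)
  expect_identical(nrow(v), 0L)
}
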