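#' Linear-programming backend
#'
#' The flux-balance engine talks to its solver through the narrow interface
#' `lp_solve(obj, S, lb, ub)`: maximize `obj . v` subject to `S v = 0` and
#' `lb <= v <= ub`. The default (and only built-in) backend is a dense
#' bounded-variable two-phase primal simplex with Bland's anti-cycling rule,
#' suitable for the model sizes this package targets. All bounds must be
#' finite; constraint-based models conventionally use +/-1000 mmol/gDW/h as
#' "unbounded".
#'
#' @param obj numeric objective coefficients, one per column of `S`.
#' @param S stoichiometric (equality-constraint) matrix.
#' @param lb,ub finite lower/upper variable bounds.
#' @param tol pivot tolerance on reduced costs.
#' @param max_iter simplex iteration cap per phase.
#' @return A list with `status` (`"optimal"`, `"infeasible"`, or
#'   `"numfail"`), and for optimal solutions `objective` and the primal
#'   vector `v`.
#' @export
lp_solve <- function(obj, S, lb, ub, tol = 1e-9, max_iter = 20000L) {
  S <- as.matrix(S)
  m <- nrow(S)
  n <- ncol(S)
  stopifnot(length(obj) == n, length(lb) == n, length(ub) == n)
  if (!all(is.finite(lb)) || !all(is.finite(ub))) {
    stop("lp_solve requires finite bounds on every variable", call. = FALSE)
  }
  if (any(lb > ub)) return(list(status = "infeasible"))
  if (m == 0L) {
    v <- ifelse(obj > 0, ub, ifelse(obj < 0, lb, pmax(lb, pmin(ub, 0))))
    return(list(status = "optimal", objective = sum(obj * v), v = v))
  }

  # Phase-1 start: structural variables at the bound of smaller magnitude,
  # one artificial per row absorbing the residual with a +/-1 column.
  x0 <- ifelse(abs(lb) <= abs(ub), lb, ub)
  resid <- -as.vector(S %*% x0)
  A <- cbind(S, diag(ifelse(resid >= 0, 1, -1), m))
  lo <- c(lb, rep(0, m))
  hi <- c(ub, rep(Inf, m))
  x <- c(x0, abs(resid))
  basis <- n + seq_len(m)
  at_upper <- logical(n + m)
  at_upper[seq_len(n)] <- (x0 == ub) & (lb != ub)

  phase1 <- simplex_phase(A, c(rep(0, n), rep(-1, m)), lo, hi,
                          x, basis, at_upper, tol, max_iter)
  if (!phase1$ok) return(list(status = "numfail"))
  if (sum(phase1$x[n + seq_len(m)]) > 1e-7) return(list(status = "infeasible"))

  hi[n + seq_len(m)] <- 0  # clamp artificials for phase 2
  phase2 <- simplex_phase(A, c(obj, rep(0, m)), lo, hi,
                          phase1$x, phase1$basis, phase1$at_upper, tol, max_iter)
  if (!phase2$ok) {
    return(list(status = if (isTRUE(phase2$unbounded)) "unbounded" else "numfail"))
  }
  v <- phase2$x[seq_len(n)]
  list(status = "optimal", objective = sum(obj * v), v = v)
}

# One simplex phase on max cc.x s.t. A x[basis-part] balanced, lo <= x <= hi.
simplex_phase <- function(A, cc, lo, hi, x, basis, at_upper, tol, max_iter) {
  m <- nrow(A)
  ncols <- ncol(A)
  for (iter in seq_len(max_iter)) {
    B <- A[, basis, drop = FALSE]
    y <- tryCatch(solve(t(B), cc[basis]), error = function(e) NULL)
    if (is.null(y)) return(list(ok = FALSE))
    nonbasic <- setdiff(seq_len(ncols), basis)
    d <- cc[nonbasic] - as.vector(crossprod(A[, nonbasic, drop = FALSE], y))
    movable <- lo[nonbasic] < hi[nonbasic]
    elig <- sort(c(
      nonbasic[d > tol & !at_upper[nonbasic] & movable],
      nonbasic[d < -tol & at_upper[nonbasic] & movable]
    ))
    if (!length(elig)) {
      return(list(ok = TRUE, x = x, basis = basis, at_upper = at_upper))
    }
    q <- elig[1]  # Bland's rule
    dir <- if (at_upper[q]) -1 else 1
    w <- tryCatch(solve(B, A[, q]), error = function(e) NULL)
    if (is.null(w)) return(list(ok = FALSE))
    xB <- x[basis]
    delta <- hi[q] - lo[q]  # distance to a bound flip of q itself
    leave <- 0L
    leave_to_upper <- FALSE
    for (i in seq_len(m)) {
      wi <- w[i] * dir
      if (wi > tol) {
        r <- (xB[i] - lo[basis[i]]) / wi
        if (r < delta) { delta <- r; leave <- i; leave_to_upper <- FALSE }
      } else if (wi < -tol && is.finite(hi[basis[i]])) {
        r <- (hi[basis[i]] - xB[i]) / (-wi)
        if (r < delta) { delta <- r; leave <- i; leave_to_upper <- TRUE }
      }
    }
    if (!is.finite(delta)) return(list(ok = FALSE, unbounded = TRUE))
    delta <- max(delta, 0)
    x[basis] <- x[basis] - w * dir * delta
    x[q] <- x[q] + dir * delta
    if (leave == 0L) {
      at_upper[q] <- !at_upper[q]
    } else {
      p <- basis[leave]
      x[p] <- if (leave_to_upper) hi[p] else lo[p]
      at_upper[p] <- leave_to_upper
      basis[leave] <- q
      at_upper[q] <- FALSE
    }
  }
  list(ok = FALSE)
}
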