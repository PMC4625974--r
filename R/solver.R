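# Self-contained LP / MILP solver used by every optimization in the package.
#
# The LP engine is a dense two-phase bounded-variable revised simplex.
# Problems here are small (tens of rows), so the basis inverse is recomputed
# from scratch every iteration via solve(); that trades speed we do not need
# for numerical robustness we do.

#' Build an empty linear problem
#'
#' A light container for assembling LPs/MILPs column by column and row by
#' row. Used internally by the FBA and flux-sum machinery; exposed so the
#' indicator-constraint block can be inspected and reused.
#'
#' @return An object of class `lp_problem` with zero variables and rows.
#' @keywords internal
#' @export
new_lp_problem <- function() {
  structure(
    list(
      var_names = character(), obj = numeric(),
      lb = numeric(), ub = numeric(),
      rows = list(), # each: list(idx, coef, sense, rhs, name)
      binary = character()
    ),
    class = "lp_problem"
  )
}

#' Add variables to a linear problem
#'
#' @param prob an `lp_problem`.
#' @param names unique variable names.
#' @param lb,ub bounds, recycled; `-Inf`/`Inf` allowed.
#' @param obj objective coefficients, recycled (default 0).
#' @param binary logical, recycled; binary variables are restricted to
#'   \{0, 1\} by the branch-and-bound layer.
#' @return the updated problem.
#' @keywords internal
#' @export
lp_add_vars <- function(prob, names, lb = 0, ub = Inf, obj = 0, binary = FALSE) {
  stopifnot(!anyDuplicated(names), !any(names %in% prob$var_names))
  n <- length(names)
  prob$var_names <- c(prob$var_names, names)
  prob$lb <- c(prob$lb, rep_len(as.numeric(lb), n))
  prob$ub <- c(prob$ub, rep_len(as.numeric(ub), n))
  prob$obj <- c(prob$obj, rep_len(as.numeric(obj), n))
  prob$binary <- c(prob$binary, names[rep_len(binary, n)])
  prob
}

#' Add a linear constraint row
#'
#' @param prob an `lp_problem`.
#' @param vars variable names with nonzero coefficients.
#' @param coefs coefficients, same length as `vars`.
#' @param sense one of `"<="`, `">="`, `"="`.
#' @param rhs right-hand side.
#' @param name optional row label (used in error messages).
#' @return the updated problem.
#' @keywords internal
#' @export
lp_add_row <- function(prob, vars, coefs, sense, rhs, name = NULL) {
  idx <- match(vars, prob$var_names)
  if (anyNA(idx)) {
    stop("unknown variable(s) in constraint: ",
         paste(vars[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  stopifnot(length(coefs) == length(idx), sense %in% c("<=", ">=", "="))
  prob$rows[[length(prob$rows) + 1L]] <-
    list(idx = idx, coef = as.numeric(coefs), sense = sense,
         rhs = as.numeric(rhs), name = name)
  prob
}

lp_set_objective <- function(prob, vars, coefs) {
  prob$obj[] <- 0
  idx <- match(vars, prob$var_names)
  stopifnot(!anyNA(idx))
  prob$obj[idx] <- as.numeric(coefs)
  prob
}

lp_set_bounds <- function(prob, var, lb = NULL, ub = NULL) {
  idx <- match(var, prob$var_names)
  stopifnot(!anyNA(idx))
  if (!is.null(lb)) prob$lb[idx] <- lb
  if (!is.null(ub)) prob$ub[idx] <- ub
  prob
}

# Assemble the dense constraint matrix of a problem.
lp_dense <- function(prob) {
  m <- length(prob$rows); n <- length(prob$var_names)
  A <- matrix(0, m, n)
  sense <- character(m); rhs <- numeric(m)
  for (i in seq_len(m)) {
    r <- prob$rows[[i]]
    A[i, r$idx] <- A[i, r$idx] + r$coef
    sense[i] <- r$sense; rhs[i] <- r$rhs
  }
  list(A = A, sense = sense, rhs = rhs)
}

#' Solve a linear program
#'
#' Two-phase bounded-variable revised simplex. Variables may have infinite
#' bounds on either side; fully free variables are split internally.
#' Deterministic: identical inputs give identical results.
#'
#' @param prob an `lp_problem` (binary markers are ignored here; see
#'   [solve_milp()]).
#' @param maximize logical; maximize instead of minimize.
#' @param tol feasibility/optimality tolerance.
#' @param max_iter simplex iteration cap.
#' @return list with `status` (`"optimal"`, `"infeasible"`, `"unbounded"`,
#'   `"iteration_limit"`), `x` (named vector, only when optimal) and
#'   `objval`.
#' @keywords internal
#' @export
solve_lp <- function(prob, maximize = FALSE, tol = 1e-9, max_iter = 20000L) {
  d <- lp_dense(prob)
  res <- simplex_solve(d$A, d$sense, d$rhs, prob$lb, prob$ub,
                       if (maximize) -prob$obj else prob$obj,
                       tol = tol, max_iter = max_iter)
  if (res$status == "optimal") {
    names(res$x) <- prob$var_names
    if (maximize) res$objval <- -res$objval
  }
  res
}

# Core simplex on   min c'x  s.t.  A x (sense) rhs,  lb <= x <= ub.
simplex_solve <- function(A, sense, rhs, lb, ub, cc,
                          tol = 1e-9, max_iter = 20000L) {
  m <- nrow(A); n <- ncol(A)
  if (any(lb > ub)) return(list(status = "infeasible"))

  # -- normalize variables -------------------------------------------------
  # negate columns whose only finite bound is the upper one; split free vars
  flip <- is.infinite(lb) & is.finite(ub)
  if (any(flip)) {
    A[, flip] <- -A[, flip, drop = FALSE]
    cc[flip] <- -cc[flip]
    tmp <- lb[flip]; lb[flip] <- -ub[flip]; ub[flip] <- -tmp
  }
  free <- is.infinite(lb) & is.infinite(ub)
  n_free <- sum(free)
  if (n_free > 0) { # x = xp - xn, both >= 0
    A <- cbind(A, -A[, free, drop = FALSE])
    cc <- c(cc, -cc[free])
    lb[free] <- 0
    lb <- c(lb, rep(0, n_free)); ub <- c(ub, rep(Inf, n_free))
  }

  # -- slacks for inequality rows -----------------------------------------
  ineq <- which(sense != "=")
  if (length(ineq) > 0) {
    Sl <- matrix(0, m, length(ineq))
    for (k in seq_along(ineq)) {
      Sl[ineq[k], k] <- if (sense[ineq[k]] == "<=") 1 else -1
    }
    A <- cbind(A, Sl)
    cc <- c(cc, rep(0, length(ineq)))
    lb <- c(lb, rep(0, length(ineq))); ub <- c(ub, rep(Inf, length(ineq)))
  }
  ntot <- ncol(A)

  # -- phase 1 with artificial basis --------------------------------------
  resid <- rhs - drop(A %*% lb)
  sg <- ifelse(resid >= 0, 1, -1)
  A1 <- cbind(A, diag(sg, m, m))
  lb1 <- c(lb, rep(0, m)); ub1 <- c(ub, rep(Inf, m))
  c1 <- c(rep(0, ntot), rep(1, m))

  basis <- ntot + seq_len(m)
  vstat <- rep("L", ntot + m)
  vstat[basis] <- "B"
  ph1 <- simplex_run(A1, rhs, lb1, ub1, c1, basis, vstat, tol, max_iter,
                     allow_unbounded = FALSE)
  if (ph1$status == "iteration_limit") return(list(status = "iteration_limit"))
  if (ph1$objval > max(1e-7, tol * 100)) return(list(status = "infeasible"))

  # -- phase 2: artificials frozen at zero --------------------------------
  lb1[ntot + seq_len(m)] <- 0
  ub1[ntot + seq_len(m)] <- 0
  c2 <- c(cc, rep(0, m))
  ph2 <- simplex_run(A1, rhs, lb1, ub1, c2, ph1$basis, ph1$vstat, tol,
                     max_iter, allow_unbounded = TRUE)
  if (ph2$status != "optimal") return(list(status = ph2$status))

  xfull <- ph2$x[seq_len(ntot)]
  x <- xfull[seq_len(n)]
  if (n_free > 0) x[free] <- x[free] - xfull[n + seq_len(n_free)]
  if (any(flip)) x[flip] <- -x[flip]
  list(status = "optimal", x = x, objval = sum(cc[seq_len(ntot)] * xfull))
}

# One simplex run on  min c'x, A x = b, lb <= x <= ub  from a given basis.
# vstat: "B" basic, "L"/"U" nonbasic at lower/upper bound.
simplex_run <- function(A, b, lb, ub, cc, basis, vstat, tol, max_iter,
                        allow_unbounded) {
  m <- nrow(A)
  nidx <- seq_len(ncol(A))
  fixed <- (ub - lb) <= tol # never allowed to enter
  bland_after <- 2000L

  iter <- 0L
  repeat {
    iter <- iter + 1L
    if (iter > max_iter) return(list(status = "iteration_limit"))

    Bmat <- A[, basis, drop = FALSE]
    xval <- ifelse(vstat == "U", ub, lb)
    xval[basis] <- 0
    xB <- tryCatch(solve(Bmat, b - drop(A %*% xval)),
                   error = function(e) NULL)
    if (is.null(xB)) stop("singular basis encountered in simplex", call. = FALSE)
    xval[basis] <- xB

    y <- solve(t(Bmat), cc[basis])
    d <- cc - drop(crossprod(A, y))

    enter_lo <- vstat == "L" & !fixed & d < -tol
    enter_hi <- vstat == "U" & !fixed & d > tol
    cand <- which(enter_lo | enter_hi)
    if (length(cand) == 0L) {
      return(list(status = "optimal", x = xval,
                  objval = sum(cc * xval), basis = basis, vstat = vstat))
    }
    q <- if (iter > bland_after) {
      cand[1L] # Bland's rule: smallest index
    } else {
      cand[which.max(abs(d[cand]))]
    }
    dir <- if (vstat[q] == "L") 1 else -1

    w <- solve(Bmat, A[, q])
    wd <- dir * w
    # ratio test: t >= 0 is the movement of x_q toward its opposite bound
    lim <- rep(Inf, m)
    up <- wd > tol    # basic value decreases, blocked by its lower bound
    dn <- wd < -tol   # basic value increases, blocked by its upper bound
    lim[up] <- (xB[up] - lb[basis[up]]) / wd[up]
    lim[dn] <- (ub[basis[dn]] - xB[dn]) / (-wd[dn])
    lim[lim < 0] <- 0 # tiny infeasibilities give tiny negative ratios
    t_bound <- ub[q] - lb[q]
    t_star <- min(lim, t_bound)

    if (!is.finite(t_star)) {
      if (allow_unbounded) return(list(status = "unbounded"))
      stop("phase-1 simplex reported an unbounded direction", call. = FALSE)
    }

    if (t_bound <= t_star + 1e-12 && is.finite(t_bound) &&
        t_bound <= min(lim)) {
      # bound flip: entering variable jumps to its other bound
      vstat[q] <- if (vstat[q] == "L") "U" else "L"
      next
    }
    r_cand <- which(lim <= t_star + 1e-12)
    # tie-break on the largest |pivot| for stability
    r <- r_cand[which.max(abs(wd[r_cand]))]
    if (iter > bland_after) r <- r_cand[which.min(basis[r_cand])]
    leaving <- basis[r]
    vstat[leaving] <- if (wd[r] > 0) "L" else "U"
    basis[r] <- q
    vstat[q] <- "B"
  }
}

#' Solve a mixed-integer linear program by branch and bound
#'
#' Depth-first branch and bound over the problem's binary variables, with LP
#' relaxations solved by the bounded-variable simplex. Binaries come from the
#' `binary` markers set via [lp_add_vars()].
#'
#' @inheritParams solve_lp
#' @param int_tol integrality tolerance on binary variables.
#' @return as [solve_lp()]; an optimal solution has every binary within
#'   `int_tol` of 0 or 1.
#' @keywords internal
#' @export
solve_milp <- function(prob, maximize = FALSE, tol = 1e-9, int_tol = 1e-6,
                       max_iter = 20000L) {
  bin_idx <- match(prob$binary, prob$var_names)
  if (length(bin_idx) == 0L) return(solve_lp(prob, maximize, tol, max_iter))

  d <- lp_dense(prob)
  sgn <- if (maximize) -1 else 1
  cc <- sgn * prob$obj

  best <- list(objval = Inf, x = NULL)
  any_feasible <- FALSE
  unbounded <- FALSE

  # stack of nodes: bound overrides for binaries
  nodes <- list(list(lb = prob$lb, ub = prob$ub))
  while (length(nodes) > 0L) {
    nd <- nodes[[length(nodes)]]
    nodes[[length(nodes)]] <- NULL
    rel <- simplex_solve(d$A, d$sense, d$rhs, nd$lb, nd$ub, cc,
                         tol = tol, max_iter = max_iter)
    if (rel$status == "infeasible") next
    if (rel$status == "unbounded") { unbounded <- TRUE; break }
    if (rel$status == "iteration_limit") {
      stop("simplex iteration limit reached inside branch and bound",
           call. = FALSE)
    }
    any_feasible <- TRUE
    if (rel$objval >= best$objval - 1e-9) next # cannot improve
    frac <- abs(rel$x[bin_idx] - round(rel$x[bin_idx]))
    if (all(frac <= int_tol)) {
      best <- list(objval = rel$objval, x = rel$x)
      next
    }
    j <- bin_idx[which.max(frac)]
    v <- rel$x[j]
    lo <- nd; lo$ub[j] <- 0
    hi <- nd; hi$lb[j] <- 1
    # explore the rounded side first (pushed last = popped first)
    if (v >= 0.5) nodes <- c(nodes, list(lo), list(hi))
    else nodes <- c(nodes, list(hi), list(lo))
  }

  if (unbounded) return(list(status = "unbounded"))
  if (!is.finite(best$objval)) {
    return(list(status = if (any_feasible) "infeasible" else "infeasible"))
  }
  x <- best$x
  names(x) <- prob$var_names
  list(status = "optimal", x = x, objval = sgn * best$objval)
}
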