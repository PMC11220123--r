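#' Solve a small dense linear program
#'
#' Two-phase primal simplex on the full tableau with Bland's anti-cycling
#' rule. Intended for the small, often degenerate envelopment LPs that
#' radial DEA generates (tens of variables, a handful of constraints);
#' it trades speed for determinism and robustness at that scale.
#'
#' Solves: minimise \code{c'x} subject to \code{A x (dir) b}, \code{x >= 0},
#' where \code{dir} is one of \code{"<="}, \code{">="}, \code{"="} per row.
#'
#' @param cvec objective coefficients (length n).
#' @param A constraint matrix (k x n).
#' @param dir character vector of row directions, each "<=", ">=" or "=".
#' @param b right-hand sides (length k).
#' @param tol pivot / feasibility tolerance.
#' @param maxit iteration cap (Bland's rule guarantees finite termination;
#'   the cap guards against pathological inputs).
#' @return list with \code{status} (0 optimal, 1 infeasible, 2 unbounded,
#'   3 iteration limit), \code{objval}, and \code{x} (primal solution).
#' @keywords internal
#' @noRd
lp_solve_simplex <- function(cvec, A, dir, b, tol = 1e-9, maxit = 10000L) {
  A <- as.matrix(A)
  k <- nrow(A)
  n <- ncol(A)
  stopifnot(length(cvec) == n, length(b) == k, length(dir) == k)

  # normalise rows so that b >= 0
  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    dir[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[neg]]
  }

  n_slack <- sum(dir == "<=")
  n_surp <- sum(dir == ">=")
  n_art <- sum(dir != "<=")
  ntot <- n + n_slack + n_surp + n_art

  T <- matrix(0, k, ntot + 1L)
  T[, seq_len(n)] <- A
  T[, ntot + 1L] <- b
  basis <- integer(k)
  is_art <- rep(FALSE, ntot)
  js <- n
  ja <- n + n_slack + n_surp
  for (i in seq_len(k)) {
    if (dir[i] == "<=") {
      js <- js + 1L
      T[i, js] <- 1
      basis[i] <- js
    } else if (dir[i] == ">=") {
      js_s <- n + n_slack + sum(dir[seq_len(i)] == ">=")
      T[i, js_s] <- -1
      ja <- ja + 1L
      T[i, ja] <- 1
      basis[i] <- ja
      is_art[ja] <- TRUE
    } else {
      ja <- ja + 1L
      T[i, ja] <- 1
      basis[i] <- ja
      is_art[ja] <- TRUE
    }
  }

  run_phase <- function(T, basis, obj, allowed) {
    # obj: full-length objective; reduced costs recomputed each pivot from
    # the basis inverse implicit in the tableau (price-out form).
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > maxit) return(list(T = T, basis = basis, status = 3L))
      cb <- obj[basis]
      red <- obj - as.vector(crossprod(T[, seq_along(obj), drop = FALSE], cb))
      red[!allowed] <- Inf
      enter <- which(red < -tol)
      if (!length(enter)) return(list(T = T, basis = basis, status = 0L))
      e <- enter[1L]  # Bland: smallest index
      col <- T[, e]
      pos <- which(col > tol)
      if (!length(pos)) return(list(T = T, basis = basis, status = 2L))
      ratio <- T[pos, ncol(T)] / col[pos]
      cand <- pos[ratio <= min(ratio) + tol]
      lv <- cand[which.min(basis[cand])]  # Bland: smallest basic index leaves
      piv <- T[lv, e]
      T[lv, ] <- T[lv, ] / piv
      other <- setdiff(seq_len(nrow(T)), lv)
      T[other, ] <- T[other, ] - outer(T[other, e], T[lv, ])
      basis[lv] <- e
    }
  }

  allowed <- rep(TRUE, ntot)
  if (n_art > 0L) {
    obj1 <- c(rep(0, ntot - n_art), rep(1, n_art))
    ph1 <- run_phase(T, basis, obj1, allowed)
    if (ph1$status != 0L) return(list(status = ph1$status, objval = NA_real_, x = rep(NA_real_, n)))
    T <- ph1$T
    basis <- ph1$basis
    ph1_val <- sum(obj1[basis] * T[, ntot + 1L])
    if (ph1_val > 1e-7) return(list(status = 1L, objval = NA_real_, x = rep(NA_real_, n)))
    # drive any residual artificial out of the basis if possible
    for (i in which(is_art[basis])) {
      row <- T[i, seq_len(ntot - n_art)]
      j <- which(abs(row) > tol & !is_art[seq_len(ntot - n_art)])
      if (length(j)) {
        e <- j[1L]
        piv <- T[i, e]
        T[i, ] <- T[i, ] / piv
        other <- setdiff(seq_len(k), i)
        T[other, ] <- T[other, ] - outer(T[other, e], T[i, ])
        basis[i] <- e
      }
    }
    allowed[is_art] <- FALSE
  }

  obj2 <- c(cvec, rep(0, ntot - n))
  ph2 <- run_phase(T, basis, obj2, allowed)
  if (ph2$status != 0L) return(list(status = ph2$status, objval = NA_real_, x = rep(NA_real_, n)))
  T <- ph2$T
  basis <- ph2$basis
  x <- numeric(ntot)
  x[basis] <- T[, ntot + 1L]
  x <- x[seq_len(n)]
  list(status = 0L, objval = sum(cvec * x), x = x)
}
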