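# Bounded-variable revised simplex.
#
# Solves   max/min  c'x   s.t.  A x = b,  l <= x <= u  (all bounds finite)
# with a textbook two-phase bounded-variable simplex: nonbasic variables sit
# at one of their bounds, the ratio test allows bound flips, and phase 1
# drives artificial variables out of the basis (redundant rows leave an
# artificial basic at zero, which is harmless). Because every variable is
# boxed the problem is never unbounded.
#
# Implemented in the package because the flux problems solved here mix
# zero-width measured bounds with wide default bounds and per-column
# coefficient scales spanning four orders of magnitude; columns are
# equilibrated internally before pivoting.

simplex_bounded <- function(obj, A, b, lb, ub, maximize = TRUE,
                            tol = 1e-9, max_iter = 20000L) {
  n <- length(obj)
  m <- nrow(A)
  stopifnot(ncol(A) == n, length(b) == m, length(lb) == n, length(ub) == n)
  if (any(!is.finite(lb)) || any(!is.finite(ub)))
    stop("simplex_bounded requires finite bounds")
  if (any(lb > ub + 1e-12))
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))

  # column equilibration: x = d * z
  d <- pmax(apply(abs(A), 2, max), 1e-12)
  d <- 1 / d
  Asc <- sweep(A, 2, d, `*`)
  lsc <- lb / d
  usc <- ub / d
  csc <- obj * d
  if (!maximize) csc <- -csc

  # artificial variables: one per row
  start <- ifelse(abs(lsc) <= abs(usc), lsc, usc)
  r <- b - as.numeric(Asc %*% start)
  Aart <- diag(ifelse(r >= 0, 1, -1), m)
  Afull <- cbind(Asc, Aart)
  lfull <- c(lsc, rep(0, m))
  ufull <- c(usc, rep(Inf, m))   # artificials capped after phase 1
  ntot <- n + m

  # state: basis (indices), at_upper flag for nonbasic
  basis <- n + seq_len(m)
  at_upper <- rep(FALSE, ntot)
  at_upper[seq_len(n)] <- start == usc & lsc != usc
  xval <- c(start, abs(r))

  run_phase <- function(cvec, basis, at_upper, xval, phase1) {
    bland <- FALSE
    stall <- 0L
    last_obj <- -Inf
    for (it in seq_len(max_iter)) {
      B <- Afull[, basis, drop = FALSE]
      Blu <- tryCatch(solve(B), error = function(e) NULL)
      if (is.null(Blu)) return(list(status = "singular"))
      nonbasic <- setdiff(seq_len(ntot), basis)
      xN <- xval[nonbasic]
      xB <- as.numeric(Blu %*% (b - Afull[, nonbasic, drop = FALSE] %*% xN))
      xval[basis] <- xB
      y <- as.numeric(crossprod(Blu, cvec[basis]))
      dj <- cvec[nonbasic] - as.numeric(crossprod(Afull[, nonbasic, drop = FALSE], y))

      cur_obj <- sum(cvec * xval)
      if (cur_obj <= last_obj + 1e-11 * (1 + abs(cur_obj))) stall <- stall + 1L
      else stall <- 0L
      last_obj <- cur_obj
      if (stall > 60L) bland <- TRUE

      up <- at_upper[nonbasic]
      # maximizing cvec: improve if (at lb and dj > tol) or (at ub and dj < -tol)
      cand <- which((!up & dj > tol) | (up & dj < -tol))
      if (length(cand) == 0)
        return(list(status = "optimal", basis = basis, at_upper = at_upper,
                    xval = xval))
      pick <- if (bland) cand[which.min(nonbasic[cand])]
              else cand[which.max(abs(dj[cand]))]
      e <- nonbasic[pick]
      sign_e <- if (at_upper[e]) -1 else 1   # direction of change of x_e
      w <- as.numeric(Blu %*% Afull[, e])    # xB changes by -w * sign_e * t

      # ratio test
      t_max <- ufull[e] - lfull[e]           # bound flip distance
      leave <- 0L
      leave_to_upper <- FALSE
      delta <- -sign_e * w
      for (i in seq_len(m)) {
        if (delta[i] > tol) {
          tt <- (ufull[basis[i]] - xval[basis[i]]) / delta[i]
          if (tt < t_max - 1e-12) { t_max <- tt; leave <- i; leave_to_upper <- TRUE }
        } else if (delta[i] < -tol) {
          tt <- (lfull[basis[i]] - xval[basis[i]]) / delta[i]
          if (tt < t_max - 1e-12) { t_max <- tt; leave <- i; leave_to_upper <- FALSE }
        }
      }
      if (!is.finite(t_max)) return(list(status = "unbounded"))
      t_max <- max(t_max, 0)
      # apply step
      xval[basis] <- xval[basis] + delta * t_max
      xval[e] <- xval[e] + sign_e * t_max
      if (leave == 0L) {
        at_upper[e] <- !at_upper[e]          # bound flip, basis unchanged
      } else {
        lv <- basis[leave]
        at_upper[lv] <- leave_to_upper
        xval[lv] <- if (leave_to_upper) ufull[lv] else lfull[lv]
        basis[leave] <- e
      }
    }
    list(status = "maxiter")
  }

  # phase 1: minimize sum of artificials == maximize -sum
  c1 <- c(rep(0, n), rep(-1, m))
  p1 <- run_phase(c1, basis, at_upper, xval, TRUE)
  if (!identical(p1$status, "optimal"))
    return(list(status = p1$status, x = rep(NA_real_, n), objective = NA_real_))
  art_sum <- sum(p1$xval[n + seq_len(m)])
  scale1 <- max(1, max(abs(b)))
  if (art_sum > 1e-6 * scale1)
    return(list(status = "infeasible", x = rep(NA_real_, n), objective = NA_real_))

  # fix artificials to zero and run phase 2
  ufull[n + seq_len(m)] <- 0
  xv <- p1$xval
  xv[n + seq_len(m)] <- 0
  c2 <- c(csc, rep(0, m))
  p2 <- run_phase(c2, p1$basis, p1$at_upper, xv, FALSE)
  if (!identical(p2$status, "optimal"))
    return(list(status = p2$status, x = rep(NA_real_, n), objective = NA_real_))
  x <- p2$xval[seq_len(n)] * d
  x <- pmin(pmax(x, lb), ub)
  objective <- sum(obj * x)
  list(status = "optimal", x = x, objective = objective)
}
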