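# Monte Carlo sampling of the constrained flux polytope.
#
# The feasible set {v : S v = 0, lb <= v <= ub} is parameterized in the
# null space of S (v = v0 + N u). An artificial-centering hit-and-run
# (ACHR) walk mixes within it: a pure random-direction warm-up walk
# builds a fixed pool of feasible points, and the sampling chains then
# alternate directions drawn through the pool (relative to its center,
# which adapts steps to elongated polytopes) with isotropic random
# directions. Freezing the pool keeps the direction law independent of
# the chain state, so the uniform distribution is exactly stationary.
# Chord endpoints come from the closed-form line search against the box.

# null space of S via SVD
null_space <- function(S, tol = 1e-9) {
  sv <- svd(S, nu = 0, nv = ncol(S))
  d <- sv$d
  rank <- sum(d > tol * max(d, 1))
  if (rank == ncol(S)) return(matrix(0, ncol(S), 0))
  sv$v[, seq(rank + 1, ncol(S)), drop = FALSE]
}

# null space restricted to directions that keep pinned variables fixed:
# rows of the identity for every pinned coordinate are appended to S
# before the decomposition
free_null_space <- function(S, pinned) {
  if (length(pinned)) {
    P <- matrix(0, length(pinned), ncol(S))
    P[cbind(seq_along(pinned), pinned)] <- 1
    S <- rbind(S, P)
  }
  null_space(S)
}

# chord [t_lo, t_hi] with x + t*dir feasible for lb <= x <= ub
line_search_box <- function(x, dir, lb, ub, tol = 1e-12) {
  t_lo <- -Inf; t_hi <- Inf
  for (i in seq_along(x)) {
    d <- dir[i]
    if (abs(d) < tol) next
    a <- (lb[i] - x[i]) / d
    b <- (ub[i] - x[i]) / d
    if (d > 0) { t_lo <- max(t_lo, a); t_hi <- min(t_hi, b) }
    else       { t_lo <- max(t_lo, b); t_hi <- min(t_hi, a) }
  }
  c(t_lo, t_hi)
}

# Relative-interior feasible point.
#
# Some fluxes are constant on the feasible polytope even though their box
# bounds are wide (e.g. the NADPH balance pins the oxidative PPP when the
# biomass flux is fixed to zero). Stage 1 maximizes a sum of per-variable
# slack margins capped at a tiny value: on the relative interior every
# non-constant coordinate can reach its cap simultaneously, so variables
# that end below their cap are exactly the constant ones. Stage 2
# re-centers within that face by maximizing the common margin of the
# remaining variables. Returns the point plus the index set of pinned
# coordinates.
interior_point <- function(problem) {
  S <- problem$S; lb <- problem$lb; ub <- problem$ub
  n <- ncol(S)
  free <- which(ub - lb > 1e-9)
  if (length(free) == 0) {
    sol <- solve_lp(problem$objective, S, lb, ub, maximize = TRUE)
    assert_that(sol$status == "optimal", "infeasible problem")
    return(list(v0 = sol$flux, pinned = seq_len(n)))
  }
  k <- length(free)
  margin_rows <- function(cols) {
    # rows -v_i + r_i <= -lb_i and v_i + r_i <= ub_i for i in cols
    E <- diag(n)[cols, , drop = FALSE]
    R <- matrix(0, length(cols), length(cols))
    diag(R) <- 1
    list(A = rbind(cbind(-E, R), cbind(E, R)),
         b = c(-lb[cols], ub[cols]))
  }
  # stage 1: tiny caps, sum objective -> detect constant coordinates
  caps <- pmin((ub[free] - lb[free]) / 2,
               1e-6 * pmax(1, abs(lb[free]) + abs(ub[free])))
  mr <- margin_rows(free)
  Sx <- cbind(S, matrix(0, nrow(S), k))
  res1 <- solve_lp(c(numeric(n), rep(1, k)), Sx,
                   c(lb, rep(0, k)), c(ub, caps), maximize = TRUE,
                   extra_A = mr$A, extra_b = mr$b)
  assert_that(res1$status == "optimal", "no feasible point (%s)", res1$status)
  r1 <- res1$flux[n + seq_len(k)]
  movable <- free[r1 > caps / 2]
  pinned <- setdiff(seq_len(n), movable)
  if (length(movable) == 0)
    return(list(v0 = res1$flux[seq_len(n)], pinned = pinned))
  # stage 2: common margin over movable coordinates
  k2 <- length(movable)
  r_cap <- min((ub[movable] - lb[movable]) / 2)
  E <- diag(n)[movable, , drop = FALSE]
  extra_A <- rbind(cbind(-E, 1), cbind(E, 1))
  extra_b <- c(-lb[movable], ub[movable])
  res2 <- solve_lp(c(numeric(n), 1), cbind(S, 0),
                   c(lb, 0), c(ub, r_cap), maximize = TRUE,
                   extra_A = extra_A, extra_b = extra_b)
  assert_that(res2$status == "optimal", "interior centering failed (%s)", res2$status)
  list(v0 = res2$flux[seq_len(n)], pinned = pinned)
}

#' Sample the constrained flux polytope
#'
#' Artificial-centering hit-and-run in the null-space parameterization
#' of the steady-state constraint. `n_chains` chains start from warm-up
#' points spread along the polytope axes; each chain contributes
#' `n_points / n_chains` samples after a per-chain warm-up.
#'
#' @param problem a `chofba_flux_problem`.
#' @param n_points total number of sampled flux vectors (default 2500;
#'   the study-scale preset of 2.5e6 points / 2500 chains is available
#'   but not the default).
#' @param n_chains number of chains (default 25).
#' @param seed RNG seed; fixed seed gives a bit-identical sample stream.
#' @param warmup warm-up steps per chain for the direction-pool walk (default 1000).
#' @param thin keep every `thin`-th step after warm-up (default 10);
#'   thinning trades chain length against autocorrelation of the kept
#'   points.
#' @return A `chofba_flux_samples`: matrix `points` (n_points x
#'   n_reactions), plus `chain` ids and the seed.
#' @export
sample_fluxes <- function(problem, n_points = 2500, n_chains = 25, seed = 1,
                          warmup = 1000, thin = 10) {
  assert_that(n_points >= n_chains && n_chains >= 1,
              "need n_points >= n_chains >= 1")
  S <- problem$S; lb <- problem$lb; ub <- problem$ub
  rxn_ids <- colnames(S)
  ip <- interior_point(problem)
  v0 <- ip$v0
  N <- free_null_space(S, ip$pinned)
  # dimensions that are actually free within the box
  d <- ncol(N)
  if (d == 0 || max(ub - lb) < 1e-9) {
    pts <- matrix(rep(v0, n_points), n_points, byrow = TRUE,
                  dimnames = list(NULL, rxn_ids))
    return(structure(list(points = pts, chain = rep(seq_len(n_chains),
                                                    length.out = n_points),
                          seed = seed),
                     class = "chofba_flux_samples"))
  }
  # precondition: flux coordinates span many orders of magnitude (growth
  # in 1/day and a fraction-of-a-fmol antibody flux next to exchanges in
  # 1e3 fmol/cell/day), which turns the polytope into a thin slab and
  # cripples hit-and-run mixing. Rescale every free coordinate by its
  # bound width, capping unmeasured (default-bound) widths at the largest
  # measured width so default bounds do not dominate the geometry.
  width <- ub - lb
  finite_w <- width[width > 1e-9 & width < BIG_BOUND]
  wcap <- if (length(finite_w)) max(finite_w) else 1
  scal <- pmin(pmax(width, 1e-9), wcap)
  Ssc <- sweep(S, 2, scal, `*`)
  lb <- lb / scal; ub <- ub / scal
  # re-center in the scaled geometry: maximize the common margin of the
  # movable coordinates so every chord through the start has useful length
  movable <- setdiff(seq_len(length(v0)), ip$pinned)
  E <- diag(length(v0))[movable, , drop = FALSE]
  r_cap <- min((ub - lb)[movable]) / 2
  cen <- solve_lp(c(numeric(length(v0)), 1), cbind(Ssc, 0),
                  c(lb, 0), c(ub, r_cap), maximize = TRUE,
                  extra_A = rbind(cbind(-E, 1), cbind(E, 1)),
                  extra_b = c(-lb[movable], ub[movable]))
  v0 <- if (cen$status == "optimal") cen$flux[seq_along(v0)] else v0 / scal
  N <- free_null_space(Ssc, ip$pinned)
  d <- ncol(N)
  set.seed(seed)

  # one hit-and-run step; returns NULL when the chord is degenerate
  hr_step <- function(vcur, dir) {
    vdir <- as.numeric(N %*% dir)
    pos <- vdir > 1e-12
    neg <- vdir < -1e-12
    t1 <- (lb - vcur) / vdir
    t2 <- (ub - vcur) / vdir
    t_lo <- max(c(t1[pos], t2[neg], -Inf))
    t_hi <- min(c(t2[pos], t1[neg], Inf))
    if (!is.finite(t_lo) || !is.finite(t_hi) || t_hi <= t_lo) return(NULL)
    tt <- stats::runif(1, t_lo, t_hi)
    vcur + tt * vdir
  }

  # warm-up exploration: a pure random-direction hit-and-run walk from
  # the center builds the (fixed) direction pool of the sampling stage;
  # fixing the pool keeps the sampling directions independent of the
  # chain state, so the uniform distribution stays exactly stationary
  pool_size <- max(2 * d + 2, n_chains, 100L)
  pool <- matrix(NA_real_, pool_size, length(v0))
  vcur <- v0
  total_warm <- warmup * n_chains
  burn <- total_warm %/% 2L          # pool keeps only the mixed second half
  pool_every <- max(1L, (total_warm - burn) %/% pool_size)
  i_pool <- 0L
  step <- 0L
  fails <- 0L
  while (i_pool < pool_size) {
    step <- step + 1L
    nxt <- hr_step(vcur, stats::rnorm(d))
    if (is.null(nxt)) {
      fails <- fails + 1L
      assert_that(fails <= 1000L + 10L * step,
                  "hit-and-run warm-up failed to move; degenerate polytope geometry")
      next
    }
    vcur <- nxt
    if (step > burn && (step - burn) %% pool_every == 0L) {
      i_pool <- i_pool + 1L
      pool[i_pool, ] <- vcur
    }
  }
  center_v <- colMeans(pool)

  per_chain <- ceiling(n_points / n_chains)
  pts <- matrix(NA_real_, n_chains * per_chain, length(v0))
  row <- 0L
  wchain <- max(50L, warmup %/% 10L)  # chains start from warmed-up points
  for (ch in seq_len(n_chains)) {
    vcur <- pool[((ch - 1) %% pool_size) + 1, ]
    collected <- 0L
    step <- 0L
    fails <- 0L
    while (collected < per_chain) {
      step <- step + 1L
      # alternate artificial-centering directions (through the fixed
      # warm-up pool) with isotropic random directions: the pool adapts
      # the step geometry to the polytope, the random share guarantees
      # irreducibility
      if (step %% 2L == 0L) {
        vref <- pool[sample.int(pool_size, 1), ] - center_v
        # project the v-space direction back into u-coordinates
        dir <- as.numeric(crossprod(N, vref))
        nd <- sqrt(sum(dir^2))
        if (nd < 1e-12) { dir <- stats::rnorm(d); nd <- sqrt(sum(dir^2)) }
      } else {
        dir <- stats::rnorm(d)
        nd <- sqrt(sum(dir^2))
      }
      nxt <- hr_step(vcur, dir / nd)
      if (is.null(nxt)) {
        fails <- fails + 1L
        assert_that(fails <= 1000L + 10L * step,
                    "hit-and-run chain failed to move; degenerate polytope geometry")
        next
      }
      vcur <- nxt
      if (step > wchain && step %% thin == 0L) {
        collected <- collected + 1L
        row <- row + 1L
        pts[row, ] <- vcur * scal
      }
    }
  }
  pts <- pts[seq_len(n_points), , drop = FALSE]
  colnames(pts) <- rxn_ids
  structure(list(points = pts,
                 chain = rep(seq_len(n_chains), each = per_chain)[seq_len(n_points)],
                 seed = seed),
            class = "chofba_flux_samples")
}

#' @export
print.chofba_flux_samples <- function(x, ...) {
  cat(sprintf("chofba flux samples: %d points x %d reactions (%d chains, seed %d)\n",
              nrow(x$points), ncol(x$points), length(unique(x$chain)), x$seed))
  invisible(x)
}

#' Per-reaction statistics of flux samples
#'
#' @param samples a `chofba_flux_samples`.
#' @return data frame with per-reaction `mean`, `sd` (the Monte Carlo
#'   flux error), and 2.5% / 97.5% percentiles.
#' @export
flux_statistics <- function(samples) {
  pts <- samples$points
  assert_that(nrow(pts) >= 2, "need at least 2 sample points")
  data.frame(
    reaction = colnames(pts),
    mean = colMeans(pts),
    sd = apply(pts, 2, stats::sd),
    q2.5 = apply(pts, 2, stats::quantile, probs = 0.025),
    q97.5 = apply(pts, 2, stats::quantile, probs = 0.975),
    row.names = NULL)
}

#' Rejection-sampling oracle for low-dimensional polytopes
#'
#' Uniform rejection sampling from the bounding box of the null-space
#' coordinates. Exponentially slow beyond a few dimensions; intended as
#' an independent check of the hit-and-run sampler on test polytopes.
#'
#' @param problem a `chofba_flux_problem` with at most `max_dim` free
#'   dimensions.
#' @param n number of samples.
#' @param seed RNG seed.
#' @param max_dim guard on the polytope dimension (default 3).
#' @return A `chofba_flux_samples`.
#' @export
rejection_oracle <- function(problem, n = 1000, seed = 1, max_dim = 3) {
  S <- problem$S; lb <- problem$lb; ub <- problem$ub
  ip <- interior_point(problem)
  v0 <- ip$v0
  N <- free_null_space(S, ip$pinned)
  d <- ncol(N)
  if (d == 0) {
    pts <- matrix(rep(v0, n), n, byrow = TRUE,
                  dimnames = list(NULL, colnames(S)))
    return(structure(list(points = pts, chain = rep(1L, n), seed = seed),
                     class = "chofba_flux_samples"))
  }
  assert_that(d <= max_dim,
              "rejection oracle limited to %d free dimensions (got %d)", max_dim, d)
  # bounding box of u via line searches along +-e_i
  lo <- hi <- numeric(d)
  for (i in seq_len(d)) {
    tr <- line_search_box(v0, as.numeric(N[, i]), lb, ub)
    lo[i] <- tr[1]; hi[i] <- tr[2]
  }
  set.seed(seed)
  pts <- matrix(NA_real_, n, length(v0))
  got <- 0L; tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    assert_that(tries < n * 1e6 + 1000,
                "rejection acceptance rate below 1e-6; oracle unsuitable")
    u <- stats::runif(d, lo, hi)
    v <- v0 + as.numeric(N %*% u)
    if (all(v >= lb - 1e-9) && all(v <= ub + 1e-9)) {
      got <- got + 1L
      pts[got, ] <- v
    }
  }
  colnames(pts) <- colnames(S)
  structure(list(points = pts, chain = rep(1L, n), seed = seed),
            class = "chofba_flux_samples")
}
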