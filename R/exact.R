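# Exact absorbing-chain computations for the Birth-death process with
# global resource-competition fitness. Fitness depends only on the total
# mutant count (well-mixed resources), so symmetric structures reduce to
# small chains: the well-mixed population to a 1-D birth-death chain, the
# star to 2(N-1) states and the PA star to (i+1)(N-i+1) states. Tiny graphs
# are solved over the full 2^N occupancy space as the ground-truth oracle.

# log-sum-exp, stable sums of products of step ratios
.lse <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# cumulative log pi_j = sum_{i<=j} log(1/f_mut(i)), j = 0..N-1 (pi_0 = 1)
.log_pi <- function(params) {
  f <- fmut_table(params)
  c(0, cumsum(-log(f)))
}

#' Establishment threshold in mutant individuals
#'
#' Establishment is the first passage of the mutant count from one to the
#' interior-equilibrium count, rounded up to the next integer:
#' `ceil(N x*)`.
#'
#' @param params An [eco_params()].
#' @return Integer mutant count.
#' @export
establishment_threshold <- function(params) {
  x <- equilibrium_frequency(params, method = if (params$symmetric)
    "closed_form" else "root")
  if (is.na(x)) {
    stop("establishment undefined: no interior equilibrium (alpha = 0.5)")
  }
  if (attr(x, "flag") == "out_of_range") {
    stop("establishment undefined: equilibrium outside (1/N, 1 - 1/N)")
  }
  as.integer(ceiling(params$N * as.numeric(x)))
}

#' Exact fixation probability in the well-mixed population
#'
#' Classical birth-death absorption with frequency-dependent step-ratio
#' `T-/T+ = 1/f_mut(n)`: the probability of absorbing at `N` from `start`
#' mutants is a ratio of partial sums of products of the step ratios.
#' Computed in log space for numerical stability at strong selection.
#'
#' @param params An [eco_params()].
#' @param start Initial mutant count (default one mutant).
#' @return Fixation probability.
#' @export
wellmixed_fixation <- function(params, start = 1L) {
  stopifnot(start >= 0, start <= params$N)
  if (start == 0L) return(0)
  if (start == params$N) return(1)
  lp <- .log_pi(params)
  exp(.lse(lp[seq_len(start)]) - .lse(lp))
}

#' Exact establishment / conditional-fixation decomposition, well-mixed
#'
#' First-passage split of fixation from a single mutant at the establishment
#' threshold `m* = ceil(N x*)`: `p_est` is the probability of reaching `m*`
#' mutants before loss, `p_cfix` the fixation probability from `m*` mutants,
#' and `p_fix = p_est * p_cfix` exactly.
#'
#' @param params An [eco_params()].
#' @return List with `p_est`, `p_cfix`, `p_fix` and the threshold `m_star`.
#' @export
wellmixed_decomposition <- function(params) {
  m <- establishment_threshold(params)
  lp <- .log_pi(params)
  p_est <- exp(lp[1] - .lse(lp[seq_len(m)]))   # hit m before 0 from 1
  p_cfix <- wellmixed_fixation(params, start = m)
  list(p_est = p_est, p_cfix = p_cfix, p_fix = p_est * p_cfix,
       m_star = m)
}

# Solve absorption probabilities for a sparse transient chain.
# trans: data.frame(from, to, p) over transient-state indices 1..n_tr
# b: n_tr x k matrix (or vector) of one-step absorption probabilities
.solve_absorbing <- function(from, to, p, n_tr, b) {
  Q <- Matrix::sparseMatrix(i = from, j = to, x = p,
                            dims = c(n_tr, n_tr))
  A <- Matrix::Diagonal(n_tr) - Q
  b <- as.matrix(b)
  tryCatch(as.matrix(Matrix::solve(A, b)),
           error = function(e) {
             # strongly absorbing chains can trip the sparse-LU condition
             # check; LAPACK on the dense system still solves them fine
             solve(as.matrix(A), b, tol = 0)
           })
}

# Level-structured solver. Every Birth-death transition changes the total
# mutant count n by +1, -1 or 0, so the reduced chains are block-tridiagonal
# in n. Fixation probabilities are computed by the matrix analog of the 1-D
# gambler's-ruin recursion h_n = U_n h_{n+1}: a forward sweep
#   U_n = (I - diag(stay_n) - A_n U_{n-1})^{-1} B_n
# over levels n = 1..N-1 (A_n: one-step probabilities to level n-1, B_n: to
# level n+1), followed by back-substitution from the fixation boundary
# h_N = 1. Unlike a global linear solve this stays numerically stable even
# when the chain is quasi-stationary at the interior equilibrium (strong
# ecological selection), and it makes the establishment decomposition exact
# by construction.
# Subtraction-free solve of (D - C) X = Y for an M-matrix given its
# nonnegative off-diagonal part C (zero diagonal), nonnegative row sums
# r = (D - C) 1 and nonnegative right-hand sides Y; the implied diagonal is
# D_jj = r_j + sum_k C_jk. GTH-style elimination: every update is an
# addition of nonnegative terms, so no cancellation occurs even when the
# chain is quasi-stationary and r is many orders below C.
.mmatrix_solve_pos <- function(C, r, Y) {
  k <- length(r)
  Y <- as.matrix(Y)
  if (k == 1L) return(Y / (r + 0))
  D <- numeric(k)
  for (j in seq_len(k)) {
    above <- if (j < k) (j + 1L):k else integer(0)
    D[j] <- r[j] + (if (length(above)) sum(C[j, above]) else 0)
    for (t in above) {
      f <- C[t, j] / D[j]
      if (f > 0) {
        if (length(above)) C[t, above] <- C[t, above] + f * C[j, above]
        r[t] <- r[t] + f * r[j]
        Y[t, ] <- Y[t, ] + f * Y[j, ]
      }
    }
  }
  X <- matrix(0, k, ncol(Y))
  for (t in rev(seq_len(k))) {
    acc <- Y[t, ]
    if (t < k) acc <- acc + C[t, (t + 1L):k, drop = FALSE] %*%
        X[(t + 1L):k, , drop = FALSE]
    X[t, ] <- acc / D[t]
  }
  X
}

# Forward sweep over levels. U_n maps fixation values at level n+1 to level
# n (h_n = U_n h_{n+1}); sigma_n is the per-state probability of absorption
# at loss before ever passing up to level n+1. Both are propagated in
# positive arithmetic: the level-n system matrix is
#   M_n = I - diag(S_n) - A_n U_{n-1},
# whose row sums equal B_n 1 + A_n sigma_{n-1} (all nonnegative), so the
# cancellation-prone diagonal is never formed explicitly.
.sweep_levels <- function(lv) {
  n_lev <- length(lv$S)
  U <- vector("list", n_lev)
  sigma_prev <- 1  # level 0 is the loss state
  for (n in seq_len(n_lev)) {
    k <- length(lv$S[[n]])
    Uprev <- if (n > 1) U[[n - 1]] else matrix(0, ncol(lv$A[[n]]), k)
    C <- lv$A[[n]] %*% Uprev
    diag(C) <- 0
    b_up <- rowSums(lv$B[[n]])
    r <- b_up + as.numeric(lv$A[[n]] %*% sigma_prev)
    Y <- cbind(lv$B[[n]], as.numeric(lv$A[[n]] %*% sigma_prev))
    X <- .mmatrix_solve_pos(C, r, Y)
    U[[n]] <- X[, -ncol(X), drop = FALSE]
    sigma_prev <- X[, ncol(X)]
  }
  U
}

.levels_fixation <- function(U) {
  n_lev <- length(U)
  h <- vector("list", n_lev)
  h[[n_lev]] <- U[[n_lev]] %*% rep(1, ncol(U[[n_lev]]))
  for (n in rev(seq_len(n_lev - 1))) h[[n]] <- U[[n]] %*% h[[n + 1]]
  h
}

# Star chain levels. Interior level n holds two states,
# [ (hub wt, n mutant leaves), (hub mutant, n-1 mutant leaves) ].
.star_levels <- function(params) {
  N <- params$N
  L <- N - 1L
  f <- fmut_table(params)
  A <- B <- S <- vector("list", N - 1L)
  for (n in seq_len(N - 1L)) {
    r <- f[n]
    W <- n * r + (N - n)
    # state 1: (0, n); state 2: (1, n-1)
    d1 <- (1 / W) * (n / L)            # hub replaces a mutant leaf
    u1 <- n * r / W                    # a mutant leaf replaces the hub
    m2 <- n - 1L
    u2 <- (r / W) * (L - m2) / L       # hub replaces a wt leaf
    d2 <- (L - m2) / W                 # a wt leaf replaces the hub
    k_dn <- if (n == 1L) 1L else 2L
    k_up <- if (n == N - 1L) 1L else 2L
    An <- matrix(0, 2, k_dn)
    An[1, 1] <- d1
    An[2, 1] <- d2
    Bn <- matrix(0, 2, k_up)
    Bn[1, if (n == N - 1L) 1L else 2L] <- u1
    Bn[2, if (n == N - 1L) 1L else 2L] <- u2
    A[[n]] <- An
    B[[n]] <- Bn
    S[[n]] <- c(1 - d1 - u1, 1 - d2 - u2)
  }
  # single mutant: leaf start with prob (N-1)/N, hub start with prob 1/N
  list(A = A, B = B, S = S, w1 = c(L / N, 1 / N))
}

#' Exact fixation probability on the star graph
#'
#' Uses the symmetry reduction of the star to the chain over (hub occupant,
#' number of mutant leaves) with global frequency-dependent fitness, solved
#' by a stable level sweep over the total mutant count; the mutant starts on
#' the hub with probability `1/N` and on a leaf otherwise.
#'
#' @param params An [eco_params()].
#' @param by_start If `TRUE`, also return the hub-start and leaf-start
#'   fixation probabilities.
#' @return Fixation probability (uniform initial placement).
#' @export
star_fixation <- function(params, by_start = FALSE) {
  N <- params$N
  stopifnot(N >= 3L)
  lv <- .star_levels(params)
  h1 <- .levels_fixation(.sweep_levels(lv))[[1]]
  p <- sum(lv$w1 * h1)
  if (by_start) list(p_fix = p, hub = h1[2], leaf = h1[1]) else p
}

# PA-star chain levels: i core nodes (degree N-1) and J = N - i leaves
# (degree i). Level n holds states c = max(0, n - J)..min(i, n) mutant
# cores (l = n - c mutant leaves).
.pastar_levels <- function(params, i) {
  N <- params$N
  J <- N - i
  f <- fmut_table(params)
  cmin <- function(n) max(0L, n - J)
  cmax <- function(n) min(i, n)
  A <- B <- S <- vector("list", N - 1L)
  for (n in seq_len(N - 1L)) {
    cs <- cmin(n):cmax(n)
    k <- length(cs)
    r <- f[n]
    W <- n * r + (N - n)
    k_dn <- if (n == 1L) 1L else cmax(n - 1L) - cmin(n - 1L) + 1L
    k_up <- if (n == N - 1L) 1L else cmax(n + 1L) - cmin(n + 1L) + 1L
    An <- matrix(0, k, k_dn)
    Bn <- matrix(0, k, k_up)
    Sn <- numeric(k)
    for (j in seq_len(k)) {
      cc <- cs[j]
      ll <- n - cc
      p_uc <- cc * r / W * (i - cc) / (N - 1) + ll * r / W * (i - cc) / i
      p_ul <- cc * r / W * (J - ll) / (N - 1)
      p_dc <- (i - cc) / W * cc / (N - 1) + (J - ll) / W * cc / i
      p_dl <- (i - cc) / W * ll / (N - 1)
      col_up_c <- if (n == N - 1L) 1L else cc + 1L - cmin(n + 1L) + 1L
      col_up_l <- if (n == N - 1L) 1L else cc - cmin(n + 1L) + 1L
      col_dn_c <- if (n == 1L) 1L else cc - 1L - cmin(n - 1L) + 1L
      col_dn_l <- if (n == 1L) 1L else cc - cmin(n - 1L) + 1L
      if (p_uc > 0) Bn[j, col_up_c] <- Bn[j, col_up_c] + p_uc
      if (p_ul > 0) Bn[j, col_up_l] <- Bn[j, col_up_l] + p_ul
      if (p_dc > 0) An[j, col_dn_c] <- An[j, col_dn_c] + p_dc
      if (p_dl > 0) An[j, col_dn_l] <- An[j, col_dn_l] + p_dl
      Sn[j] <- 1 - p_uc - p_ul - p_dc - p_dl
    }
    A[[n]] <- An
    B[[n]] <- Bn
    S[[n]] <- Sn
  }
  # level-1 start weights: (c=0, l=1) for a leaf start, (c=1, l=0) for core
  cs1 <- cmin(1L):cmax(1L)
  w1 <- vapply(cs1, function(cc) if (cc == 1L) i / N else J / N, numeric(1))
  list(A = A, B = B, S = S, w1 = w1, cmin = cmin, cmax = cmax)
}

#' Exact fixation decomposition on a preferential-attachment star
#'
#' A PA star has `i` core nodes connected to every other node and `N - i`
#' leaves connected to all cores; `i = 1` is the star, `i = N - 1` the
#' complete graph. Its symmetry reduces the `2^N` occupancy space to
#' `(i+1)(N-i+1)` states over (mutant cores, mutant leaves), organized as a
#' block-tridiagonal chain in the total mutant count and solved by a stable
#' level sweep. When an interior equilibrium exists, fixation is decomposed
#' into establishment (first passage of the total mutant count to
#' `ceil(N x*)`) and conditional fixation from the hitting distribution over
#' the establishment frontier; the product identity `p_fix = p_est * p_cfix`
#' holds to solver precision.
#'
#' @param params An [eco_params()].
#' @param i Number of core nodes, `1 <= i <= N - 1`.
#' @return List with `p_fix`, and `p_est`, `p_cfix`, `m_star` when the
#'   equilibrium exists (`NA` otherwise).
#' @export
pastar_fixation <- function(params, i) {
  N <- params$N
  i <- as.integer(i)
  stopifnot(i >= 1L, i <= N - 1L)
  lv <- .pastar_levels(params, i)
  U <- .sweep_levels(lv)
  h <- .levels_fixation(U)
  p_fix <- sum(lv$w1 * h[[1]])

  res <- list(p_fix = p_fix, p_est = NA_real_, p_cfix = NA_real_,
              m_star = NA_integer_)
  m_star <- tryCatch(establishment_threshold(params), error = function(e) NULL)
  if (is.null(m_star) || m_star < 2L || m_star > N - 1L) return(res)

  # hitting distribution over the level-m* frontier: product of the U's
  hit <- matrix(lv$w1, nrow = 1)
  for (n in seq_len(m_star - 1L)) hit <- hit %*% U[[n]]
  p_est <- sum(hit)
  p_cfix <- sum(hit * as.numeric(h[[m_star]])) / p_est
  res$p_est <- p_est
  res$p_cfix <- p_cfix
  res$m_star <- m_star
  res
}

#' Brute-force fixation probabilities over the full occupancy space
#'
#' Builds the exact `2^N`-state absorbing chain of the Birth-death process
#' on an arbitrary graph (fitness from the well-mixed-resource model, so it
#' depends on the mutant count only) and solves for the fixation probability
#' from every single-mutant start. This is the ground-truth oracle for all
#' reduced solvers; it refuses graphs with more than 14 nodes.
#'
#' @param graph An igraph object (simple, connected, undirected).
#' @param params An [eco_params()] with `N = vcount(graph)`.
#' @return List with `per_node` (fixation probability by starting node) and
#'   `uniform` (their mean, i.e. uniform initial placement).
#' @export
brute_force_fixation <- function(graph, params) {
  N <- igraph::vcount(graph)
  if (N > 14L) stop("brute force limited to N <= 14 (2^N states)")
  stopifnot(N == params$N)
  validate_graph(graph)
  adj <- igraph::as_adj_list(graph)
  adj <- lapply(adj, as.integer)
  deg <- lengths(adj)
  f <- c(NA_real_, fmut_table(params), NA_real_)  # index by n+1
  n_states <- bitwShiftL(1L, N)
  pop <- integer(n_states)
  for (v in 0:(N - 1L)) {
    bit <- bitwShiftL(1L, v)
    sel <- bitwAnd(0:(n_states - 1L), bit) > 0L
    pop[sel] <- pop[sel] + 1L
  }
  loss <- 1L; fixs <- n_states
  trans_ids <- setdiff(seq_len(n_states), c(loss, fixs))
  tix <- integer(n_states); tix[trans_ids] <- seq_along(trans_ids)

  from <- integer(0); to <- integer(0); pr <- numeric(0)
  bvec <- numeric(length(trans_ids))
  for (st in trans_ids) {
    mask <- st - 1L
    n <- pop[st]
    r <- f[n + 1L]
    W <- n * r + (N - n)
    ft <- numeric(0)
    self_p <- 0
    for (v in seq_len(N)) {
      v_mut <- bitwAnd(mask, bitwShiftL(1L, v - 1L)) > 0L
      fv <- if (v_mut) r else 1
      pv <- fv / W / deg[v]
      for (u in adj[[v]]) {
        u_bit <- bitwShiftL(1L, u - 1L)
        u_mut <- bitwAnd(mask, u_bit) > 0L
        if (u_mut == v_mut) {
          self_p <- self_p + pv
        } else {
          new_mask <- if (v_mut) bitwOr(mask, u_bit) else
            bitwAnd(mask, bitwNot(u_bit))
          k2 <- new_mask + 1L
          if (k2 == fixs) {
            bvec[tix[st]] <- bvec[tix[st]] + pv
          } else if (k2 != loss) {
            from <- c(from, tix[st]); to <- c(to, tix[k2]); pr <- c(pr, pv)
          }
        }
      }
    }
    if (self_p > 0) {
      from <- c(from, tix[st]); to <- c(to, tix[st]); pr <- c(pr, self_p)
    }
  }
  h <- .solve_absorbing(from, to, pr, length(trans_ids), bvec)[, 1]
  per_node <- vapply(seq_len(N), function(v) {
    h[tix[bitwShiftL(1L, v - 1L) + 1L]]
  }, numeric(1))
  list(per_node = per_node, uniform = mean(per_node))
}

#' Exact fixation probability dispatcher
#'
#' @param params An [eco_params()].
#' @param structure `"wellmixed"`, `"star"` or `"pastar"`.
#' @param i Core size (PA star only).
#' @return Fixation probability from a uniformly placed single mutant.
#' @export
exact_fixation <- function(params, structure = c("wellmixed", "star", "pastar"),
                           i = NULL) {
  structure <- match.arg(structure)
  switch(structure,
         wellmixed = wellmixed_fixation(params),
         star = star_fixation(params),
         pastar = pastar_fixation(params, i)$p_fix)
}

#' Role-reversal crossing point between a structure and the well-mixed model
#'
#' Finds the intrinsic selection coefficient `s*` at which the exact fixation
#' probability on the structure equals the exact well-mixed probability, at
#' fixed niche overlap. For an amplifier with ecological selection the
#' crossing sits at `s* < 0`: deleterious mutants with `s* < s < 0` are
#' amplified. Without ecological selection (`alpha = 0.5`) the only crossing
#' is at `s = 0`, which is returned with flag `"at_zero"`.
#'
#' @param N Population size.
#' @param alpha Niche overlap.
#' @param structure `"star"` or `"pastar"`.
#' @param i Core size when `structure = "pastar"`.
#' @param s_lo Lower end of the bracket on `s` (negative).
#' @param tol Root tolerance.
#' @param env A [resource_env()].
#' @return List with `s_star`, `Ns_star` and `flag` (`"crossing"`,
#'   `"at_zero"` or `"none"`).
#' @export
intersection_point <- function(N, alpha, structure = c("star", "pastar"),
                               i = NULL, s_lo = -0.1, tol = 1e-8,
                               env = resource_env()) {
  structure <- match.arg(structure)
  # log-ratio keeps the root finder well conditioned when both
  # probabilities are small
  pg <- function(s) {
    p <- eco_params(N, s, alpha, env = env)
    log(exact_fixation(p, structure, i = i)) - log(wellmixed_fixation(p))
  }
  if (alpha == 0.5) {
    # constant selection: amplifiers and suppressors cross exactly at s = 0
    return(list(s_star = 0, Ns_star = 0, flag = "at_zero"))
  }
  s_hi <- -tol / N
  g_hi <- pg(s_hi)
  if (g_hi <= 0) {
    return(list(s_star = NA_real_, Ns_star = NA_real_, flag = "none"))
  }
  lo <- s_lo
  g_lo <- pg(lo)
  while (g_lo > 0 && lo > -0.9) {
    lo <- max(lo * 2, -0.9)
    g_lo <- pg(lo)
  }
  if (g_lo > 0 || !is.finite(g_lo)) {
    return(list(s_star = NA_real_, Ns_star = NA_real_, flag = "none"))
  }
  root <- stats::uniroot(pg, c(lo, s_hi), tol = tol)$root
  list(s_star = root, Ns_star = N * root, flag = "crossing")
}

#' Crossing curve over a grid of niche overlaps
#'
#' Sweeps `alpha` and reports the crossing point `s*(alpha)` between the
#' exact structure and well-mixed fixation probabilities, tracing the
#' role-reversal boundary for deleterious mutants.
#'
#' @param N Population size.
#' @param alphas Grid of niche overlaps in `(0.5, 1)`.
#' @param structure,i Passed to [intersection_point()].
#' @param s_lo Bracket lower end.
#' @return `data.frame` with columns `alpha`, `s_star`, `N_s_star`.
#' @export
crossing_curve <- function(N, alphas, structure = "star", i = NULL,
                           s_lo = -0.5) {
  rows <- lapply(alphas, function(a) {
    cp <- intersection_point(N, a, structure, i = i, s_lo = s_lo)
    data.frame(alpha = a, s_star = cp$s_star, N_s_star = cp$Ns_star)
  })
  do.call(rbind, rows)
}
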