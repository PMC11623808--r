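#' Simulation configuration
#'
#' @param replicates Number of independent Monte-Carlo replicates.
#' @param seed Master seed; each replicate draws its own stream from it by a
#'   counter-based spawn, so results do not depend on batching.
#' @param resource_mode `"well_mixed"` (fitness from the global composition)
#'   or `"diffusible"` (resources diffuse along edges with constant `D` and
#'   per-node steady states are re-solved after every replacement).
#' @param D Diffusion constant (diffusible mode).
#' @param max_steps Safety cap on Moran steps per replicate; default
#'   `10 * N^3`, resolved at run time. Truncated replicates are excluded
#'   from estimates and counted separately.
#' @param track_establishment Record the first passage of the mutant count
#'   to the establishment threshold `ceil(N x*)`.
#' @param refresh_every Diffusible mode: number of rank-1 inverse updates
#'   between full re-factorizations.
#' @return A `sim_config` object.
#' @export
sim_config <- function(replicates = 10000, seed = 1,
                       resource_mode = c("well_mixed", "diffusible"),
                       D = 1, max_steps = NULL,
                       track_establishment = FALSE,
                       refresh_every = 128L) {
  resource_mode <- match.arg(resource_mode)
  stopifnot(replicates >= 1, D > 0)
  structure(list(replicates = as.integer(replicates), seed = seed,
                 resource_mode = resource_mode, D = D,
                 max_steps = max_steps,
                 track_establishment = isTRUE(track_establishment),
                 refresh_every = as.integer(refresh_every)),
            class = "sim_config")
}

# igraph -> 0-based CSR adjacency
graph_csr <- function(graph) {
  adj <- igraph::as_adj_list(graph)
  deg <- lengths(adj)
  list(ptr = as.integer(c(0L, cumsum(deg))),
       idx = as.integer(unlist(adj, use.names = FALSE) - 1L))
}

.resolve_engine_inputs <- function(graph, params, config) {
  validate_graph(graph)
  N <- igraph::vcount(graph)
  if (N != params$N) stop("graph size and params$N disagree")
  est_thr <- 0L
  if (config$track_establishment) {
    est_thr <- establishment_threshold(params)
  }
  max_steps <- if (is.null(config$max_steps)) 10 * N^3 else config$max_steps
  list(csr = graph_csr(graph), est_thr = est_thr, max_steps = max_steps)
}

.run_engine <- function(graph, params, config, start_nodes = -1L) {
  inp <- .resolve_engine_inputs(graph, params, config)
  seed <- as.double(config$seed) %% 2^31
  if (config$resource_mode == "well_mixed") {
    f <- c(0, fmut_table(params))  # 0-based in C++: f[n] = f_mut(n)
    raw <- sim_wellmixed_cpp(inp$csr$ptr, inp$csr$idx,
                             f, config$replicates, seed,
                             inp$est_thr, inp$max_steps,
                             as.integer(start_nodes))
  } else {
    if (!params$symmetric && params$env$n_resources != 2L) {
      stop("diffusible mode supports two resources")
    }
    L <- as.matrix(igraph::laplacian_matrix(graph))
    raw <- sim_diffusible_cpp(inp$csr$ptr, inp$csr$idx, L,
                              params$wt$alphas, params$mut$alphas,
                              params$mut$intrinsic, config$D,
                              params$env$supply[1],
                              config$replicates, seed, inp$est_thr,
                              inp$max_steps, as.integer(start_nodes),
                              config$refresh_every)
  }
  raw
}

#' Run a single Moran Birth-death trajectory
#'
#' One mutant is placed uniformly at random (or on `start_node`); each step a
#' reproducer is sampled over all nodes proportional to overall fitness and
#' its offspring replaces a uniformly chosen neighbor; the run ends at
#' fixation or loss.
#'
#' @param graph igraph object.
#' @param params An [eco_params()].
#' @param config A [sim_config()]; its seed is used (one replicate).
#' @param start_node Optional 1-based starting node.
#' @return A trajectory record: `outcome` (`"fixation"`, `"loss"` or
#'   `"truncated"`), `steps`, `established`, `establishment_step`.
#' @export
moran_run <- function(graph, params, config = sim_config(replicates = 1),
                      start_node = NULL) {
  config$replicates <- 1L
  start <- if (is.null(start_node)) -1L else as.integer(start_node) - 1L
  raw <- .run_engine(graph, params, config, start_nodes = start)
  outcome <- if (is.na(raw$outcome[1])) "truncated" else
    if (raw$outcome[1] == 1L) "fixation" else "loss"
  list(outcome = outcome, steps = raw$steps[1],
       established = raw$established[1],
       establishment_step = raw$establishment_step[1])
}

#' Monte-Carlo estimate of fixation, establishment and times
#'
#' Aggregates independent replicates of the Moran Birth-death process.
#' Probabilities get binomial standard errors; times get sample standard
#' errors. When establishment is tracked, `p_est` is the fraction of
#' replicates whose mutant count reaches `ceil(N x*)` and `p_cfix` the
#' fraction fixing among those, so `p_est * p_cfix` estimates `p_fix`.
#'
#' @param graph igraph object.
#' @param params An [eco_params()].
#' @param config A [sim_config()].
#' @return A `fixation_estimate` list.
#' @export
estimate_fixation <- function(graph, params, config = sim_config()) {
  if (config$track_establishment && params$symmetric && params$alpha == 0.5) {
    stop("establishment undefined at alpha = 0.5 (no interior equilibrium)")
  }
  raw <- .run_engine(graph, params, config)
  ok <- !is.na(raw$outcome)
  n_trunc <- sum(!ok)
  fixed <- raw$outcome[ok] == 1L
  n <- sum(ok)
  p_fix <- mean(fixed)
  se <- function(p, m) sqrt(p * (1 - p) / m)
  out <- list(
    p_fix = p_fix, p_fix_se = se(p_fix, n),
    p_est = NA_real_, p_est_se = NA_real_,
    p_cfix = NA_real_, p_cfix_se = NA_real_,
    t_unconditional = mean(raw$steps[ok]),
    t_unconditional_se = stats::sd(raw$steps[ok]) / sqrt(n),
    t_conditional_fix = if (any(fixed)) mean(raw$steps[ok][fixed]) else NA_real_,
    t_conditional_fix_se = if (sum(fixed) > 1)
      stats::sd(raw$steps[ok][fixed]) / sqrt(sum(fixed)) else NA_real_,
    replicates_used = n, truncated = n_trunc,
    seed = config$seed, resource_mode = config$resource_mode
  )
  if (config$track_establishment) {
    est <- raw$established[ok]
    out$p_est <- mean(est)
    out$p_est_se <- se(out$p_est, n)
    if (any(est)) {
      out$p_cfix <- mean(fixed[est])
      out$p_cfix_se <- se(out$p_cfix, sum(est))
    }
  }
  class(out) <- "fixation_estimate"
  out
}

#' @export
print.fixation_estimate <- function(x, ...) {
  cat(sprintf("Fixation estimate (%d replicates, %s resources)\n",
              x$replicates_used, x$resource_mode))
  cat(sprintf("  p_fix  = %.6g (SE %.2g)\n", x$p_fix, x$p_fix_se))
  if (!is.na(x$p_est)) {
    cat(sprintf("  p_est  = %.6g (SE %.2g)\n", x$p_est, x$p_est_se))
    cat(sprintf("  p_cfix = %.6g (SE %.2g)\n", x$p_cfix, x$p_cfix_se))
  }
  cat(sprintf("  mean steps = %.4g (fixing runs: %.4g)\n",
              x$t_unconditional, x$t_conditional_fix))
  if (x$truncated > 0) cat("  truncated replicates:", x$truncated, "\n")
  invisible(x)
}

#' Per-node steady-state resource field with diffusible resources
#'
#' Solves `(D L + diag(alpha_i)) c_i = S_i` for each resource, where `L` is
#' the graph Laplacian and `alpha_i` the per-node consumption rates implied
#' by the occupancy.
#'
#' @param graph igraph object.
#' @param occupancy Character or integer vector over nodes: `"mut"`/1 for
#'   mutant, `"wt"`/0 for wild type.
#' @param params An [eco_params()].
#' @param D Diffusion constant.
#' @return Matrix (nodes x resources) of steady-state concentrations.
#' @export
diffusible_steady_state <- function(graph, occupancy, params, D) {
  N <- igraph::vcount(graph)
  is_mut <- .as_mut_logical(occupancy, N)
  L <- igraph::laplacian_matrix(graph, sparse = TRUE)
  nres <- params$env$n_resources
  out <- matrix(NA_real_, N, nres)
  for (i in seq_len(nres)) {
    a <- ifelse(is_mut, params$mut$alphas[i], params$wt$alphas[i])
    if (all(a == 0)) {
      stop("degenerate environment: no consumption of resource ", i)
    }
    M <- D * L + Matrix::Diagonal(N, a)
    cvec <- as.numeric(Matrix::solve(M, rep(params$env$supply[i], N)))
    resid <- max(abs(as.numeric(M %*% cvec) - params$env$supply[i]))
    if (resid > 1e-9) stop("steady-state solve residual too large: ", resid)
    out[, i] <- cvec
  }
  out
}

.as_mut_logical <- function(occupancy, N) {
  stopifnot(length(occupancy) == N)
  if (is.character(occupancy)) occupancy == "mut" else as.logical(occupancy)
}

#' Per-node overall fitness under diffusible resources
#'
#' `f_j = s_j * sum_i alpha_ij c_ij*`: each node earns fitness from its own
#' consumption of the local steady-state concentrations. These are the
#' Birth-death reproduction weights in diffusible mode.
#'
#' @param field Node x resource matrix from [diffusible_steady_state()].
#' @param occupancy Per-node ecotype labels (as in
#'   [diffusible_steady_state()]).
#' @param params An [eco_params()].
#' @return Numeric vector of per-node fitness values.
#' @export
diffusible_fitness <- function(field, occupancy, params) {
  N <- nrow(field)
  is_mut <- .as_mut_logical(occupancy, N)
  alphas <- rbind(params$wt$alphas, params$mut$alphas)[is_mut + 1L, , drop = FALSE]
  s_vec <- ifelse(is_mut, params$mut$intrinsic, params$wt$intrinsic)
  f <- s_vec * rowSums(alphas * field)
  stopifnot(all(f > 0))
  f
}
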