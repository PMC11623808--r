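#' Resource environment
#'
#' Describes the externally supplied resources that the two ecotypes compete
#' for: per-resource supply rates, per-resource biomass values and the
#' consumption law. The default is the two-resource environment with equal
#' supply `S = 0.5` per resource, equal unit values and a linear consumption
#' law `mu(c) = c`.
#'
#' @param supply Per-resource supply rate, recycled to `n_resources`.
#' @param values Per-resource biomass value `v_i`, recycled to `n_resources`.
#' @param n_resources Number of substitutable resources.
#' @param consumption_law Function giving the consumption rate per enzyme
#'   molecule as a function of concentration. Only the linear default is used
#'   by the closed-form results; a different law still works for the generic
#'   fitness evaluations.
#' @return An object of class `resource_env`.
#' @export
resource_env <- function(supply = 0.5, values = 1, n_resources = 2L,
                         consumption_law = identity) {
  n_resources <- as.integer(n_resources)
  supply <- rep_len(as.numeric(supply), n_resources)
  values <- rep_len(as.numeric(values), n_resources)
  stopifnot(n_resources >= 1L, all(supply > 0), all(values > 0),
            is.function(consumption_law))
  structure(list(supply = supply, values = values,
                 n_resources = n_resources,
                 consumption_law = consumption_law),
            class = "resource_env")
}

#' Ecotype metabolic strategy
#'
#' An ecotype is defined by its intrinsic fitness and its enzyme allocation
#' vector across resources (units of enzyme molecules). Allocations must be
#' non-negative with at least one positive entry; scaling all allocations by
#' a positive constant does not change relative fitnesses.
#'
#' @param label `"wt"` or `"mut"`.
#' @param intrinsic Intrinsic fitness `s_sigma` (wild type 1, mutant `1 + s`).
#' @param alphas Per-resource enzyme allocation.
#' @return An object of class `ecotype_strategy`.
#' @export
ecotype_strategy <- function(label, intrinsic, alphas) {
  alphas <- as.numeric(alphas)
  stopifnot(label %in% c("wt", "mut"), intrinsic > 0,
            all(alphas >= 0), any(alphas > 0))
  structure(list(label = label, intrinsic = as.numeric(intrinsic),
                 alphas = alphas),
            class = "ecotype_strategy")
}

#' Eco-evolutionary model parameters
#'
#' Bundles the population size, intrinsic selection coefficient and the two
#' metabolic strategies. In the symmetric parameterization the niche-overlap
#' parameter `alpha` in `[0.5, 1]` sets `alpha_wt = (1 - alpha, alpha)` and
#' `alpha_mut = (alpha, 1 - alpha)`: the mutant swaps the preferred resource
#' while keeping the metabolic budget fixed. `alpha = 0.5` recovers constant
#' directional selection (identical generalists); `alpha = 1` is complete
#' niche separation (pure specialists). Alternatively, explicit `wt`/`mut`
#' strategies may be supplied for asymmetric utilization or more resources.
#'
#' @param N Population size (`N >= 2`).
#' @param s Intrinsic selection coefficient (`s > -1`); mutant intrinsic
#'   fitness is `1 + s`.
#' @param alpha Niche overlap in `[0.5, 1]` (symmetric mode). Ignored when
#'   `wt`/`mut` are given.
#' @param wt,mut Optional explicit [ecotype_strategy()] objects.
#' @param env A [resource_env()].
#' @return An object of class `eco_params`.
#' @export
eco_params <- function(N, s, alpha = NULL, wt = NULL, mut = NULL,
                       env = resource_env()) {
  N <- as.integer(N)
  stopifnot(N >= 2L, is.numeric(s), length(s) == 1L, s > -1)
  symmetric <- is.null(wt) && is.null(mut)
  if (symmetric) {
    stopifnot(is.numeric(alpha), length(alpha) == 1L,
              alpha >= 0.5, alpha <= 1)
    stopifnot(env$n_resources == 2L)
    wt <- ecotype_strategy("wt", 1, c(1 - alpha, alpha))
    mut <- ecotype_strategy("mut", 1 + s, c(alpha, 1 - alpha))
  } else {
    stopifnot(inherits(wt, "ecotype_strategy"), inherits(mut, "ecotype_strategy"))
    stopifnot(length(wt$alphas) == env$n_resources,
              length(mut$alphas) == env$n_resources)
    mut$intrinsic <- 1 + s
    wt$intrinsic <- 1
    alpha <- NA_real_
  }
  structure(list(N = N, s = s, alpha = alpha, symmetric = symmetric,
                 wt = wt, mut = mut, env = env),
            class = "eco_params")
}

#' @export
print.eco_params <- function(x, ...) {
  cat("Eco-evolutionary parameters\n")
  cat("  N =", x$N, "  s =", x$s, "\n")
  if (x$symmetric) {
    cat("  niche overlap alpha =", x$alpha, "(symmetric strategies)\n")
  } else {
    cat("  wt alphas:", x$wt$alphas, "\n  mut alphas:", x$mut$alphas, "\n")
  }
  invisible(x)
}

#' Steady-state resource concentrations (well-mixed resources)
#'
#' Sets the resource supply/consumption balance to zero under the linear
#' consumption law: `c_i* = S_i / (n_wt alpha_wt,i + n_mut alpha_mut,i)`.
#' The mutant count may be a real number (continuous-frequency extension
#' `n_mut = x N` used by root finders).
#'
#' @param n_mut Number of mutants (real-valued allowed).
#' @param params An [eco_params()].
#' @return Numeric vector of per-resource equilibrium concentrations.
#' @export
equilibrium_concentrations <- function(n_mut, params) {
  stopifnot(inherits(params, "eco_params"), n_mut >= 0, n_mut <= params$N)
  n_wt <- params$N - n_mut
  tot <- n_wt * params$wt$alphas + n_mut * params$mut$alphas
  if (any(tot <= 0)) {
    stop("degenerate environment: total consumption of a resource is zero")
  }
  params$env$supply / tot
}

#' Overall fitness of one ecotype
#'
#' The overall fitness multiplies the intrinsic component by the ecological
#' component earned from resource consumption:
#' `f_sigma = s_sigma * sum_i v_i alpha_sigma,i mu(c_i*)`.
#'
#' @param strategy An [ecotype_strategy()].
#' @param concentrations Per-resource equilibrium concentrations.
#' @param env A [resource_env()].
#' @return Positive scalar fitness.
#' @export
overall_fitness <- function(strategy, concentrations, env = resource_env()) {
  stopifnot(inherits(strategy, "ecotype_strategy"), all(concentrations > 0))
  strategy$intrinsic *
    sum(env$values * strategy$alphas * env$consumption_law(concentrations))
}

#' Relative mutant overall fitness
#'
#' `f_mut = f~_mut / f~_wt` evaluated at a mutant count, with resources at
#' their steady state for that count. With well-mixed resources this depends
#' on the composition only. The continuous extension (`continuous = TRUE`,
#' `n_mut` real in `(0, N)`) is used for equilibrium root finding.
#'
#' @param n_mut Mutant count (integer in `1..N-1`, or real when
#'   `continuous = TRUE`).
#' @param params An [eco_params()].
#' @param continuous Allow real-valued `n_mut`.
#' @return Positive scalar `f_mut`.
#' @export
relative_mutant_fitness <- function(n_mut, params, continuous = FALSE) {
  stopifnot(inherits(params, "eco_params"))
  if (!continuous) {
    if (n_mut <= 0 || n_mut >= params$N) {
      stop("absorbing state: both ecotypes must be present (0 < n_mut < N)")
    }
  } else {
    stopifnot(n_mut > 0, n_mut < params$N)
  }
  cc <- equilibrium_concentrations(n_mut, params)
  overall_fitness(params$mut, cc, params$env) /
    overall_fitness(params$wt, cc, params$env)
}

# f_mut for every interior count 1..N-1; the engine and exact chains consume
# this table (fitness depends on the composition only with well-mixed
# resources).
fmut_table <- function(params) {
  vapply(seq_len(params$N - 1L), relative_mutant_fitness, numeric(1),
         params = params)
}

#' Interior equilibrium mutant frequency
#'
#' The negative frequency dependence created by resource competition pushes
#' the mutant frequency towards an unstable interior equilibrium `x*` where
#' the relative overall fitness is one. For the symmetric strategies it has
#' the closed form `x* = 1/2 + (1/2) (2 alpha - 1)^{-2} s / (2 + s)`;
#' `method = "root"` instead bisects `f_mut(x) = 1` on the continuous
#' frequency line (and is the only method in asymmetric mode).
#'
#' At `alpha = 0.5` there is no ecological selection and no equilibrium:
#' `NA` is returned with `attr(, "flag") = "none"`. An `x*` falling outside
#' `(1/N, 1 - 1/N)` is returned with `attr(, "flag") = "out_of_range"`
#' (establishment is undefined there).
#'
#' @param params An [eco_params()].
#' @param method `"closed_form"` (symmetric only) or `"root"`.
#' @param tol Bisection tolerance for `method = "root"`.
#' @return Frequency in (0, 1), possibly flagged; `NA` when no equilibrium
#'   exists.
#' @export
equilibrium_frequency <- function(params,
                                  method = c("closed_form", "root"),
                                  tol = 1e-12) {
  method <- match.arg(method)
  if (params$symmetric && params$alpha == 0.5) {
    return(structure(NA_real_, flag = "none"))
  }
  if (method == "closed_form") {
    if (!params$symmetric) {
      stop("closed form requires the symmetric (alpha, 1-alpha) strategies")
    }
    d <- 2 * params$alpha - 1
    x <- 0.5 + 0.5 * d^-2 * params$s / (2 + params$s)
  } else {
    g <- function(x) {
      relative_mutant_fitness(x * params$N, params, continuous = TRUE) - 1
    }
    eps <- 1 / (params$N * 1e6)
    lo <- eps
    hi <- 1 - eps
    if (g(lo) * g(hi) > 0) {
      return(structure(NA_real_, flag = "none"))
    }
    x <- stats::uniroot(g, c(lo, hi), tol = tol)$root
  }
  flag <- "interior"
  if (x <= 1 / params$N || x >= 1 - 1 / params$N) flag <- "out_of_range"
  structure(x, flag = flag)
}

#' Effective selection coefficient at a given mutant frequency
#'
#' For symmetric strategies returns the weak-ecological-selection expansion
#' `s(x) = s + 2 (2 alpha - 1)^2 (1 - 2 x)`: the frequency-dependent
#' competition behaves to first order like constant selection whose strength
#' decays linearly through the interior equilibrium. For asymmetric
#' strategies the exact selection differential `f_mut(x) - 1` is returned.
#' The constant effective coefficient governing fixation is the value at
#' frequency 1/3, `s_e = s + (2/3)(2 alpha - 1)^2`.
#'
#' @param x Mutant frequency in `[0, 1]`.
#' @param params An [eco_params()].
#' @return Selection differential at frequency `x`.
#' @export
effective_selection <- function(x, params) {
  stopifnot(x >= 0, x <= 1)
  if (params$symmetric) {
    d <- 2 * params$alpha - 1
    params$s + 2 * d^2 * (1 - 2 * x)
  } else {
    n <- x * params$N
    n <- min(max(n, 1e-9), params$N - 1e-9)
    relative_mutant_fitness(n, params, continuous = TRUE) - 1
  }
}

#' Classify the ecological-selection regime
#'
#' Weak ecological selection means the scaled effective ecological coefficient
#' `N (2/3)(2 alpha - 1)^2` is small: drift dominates and the dynamics behave
#' like constant selection with coefficient `s_e`. Strong ecological
#' selection means the establishment odds ratio
#' `[(2 alpha - 1)^-2 - 1 + 2/N] / [(2 alpha - 1)^-2 + 1 - 2/N]`
#' is small: establishment is near deterministic and fixation decomposes into
#' establishment and conditional-fixation stages. Everything else is
#' intermediate.
#'
#' @param params An [eco_params()].
#' @param weak_threshold Cutoff on `N (2/3)(2 alpha - 1)^2`.
#' @param strong_threshold Cutoff on the establishment odds ratio.
#' @return Character scalar: `"weak"`, `"strong"` or `"intermediate"`, with
#'   attribute `conditions` carrying both condition values.
#' @export
classify_regime <- function(params, weak_threshold = 0.3,
                            strong_threshold = 0.05) {
  stopifnot(params$symmetric)
  d <- 2 * params$alpha - 1
  weak_cond <- params$N * (2 / 3) * d^2
  strong_cond <- if (d == 0) Inf else {
    (d^-2 - 1 + 2 / params$N) / (d^-2 + 1 - 2 / params$N)
  }
  out <- if (weak_cond < weak_threshold) {
    "weak"
  } else if (strong_cond < strong_threshold) {
    "strong"
  } else {
    "intermediate"
  }
  structure(out, conditions = c(weak = weak_cond, strong = strong_cond))
}
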