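# Closed-form approximations for fixation, establishment and conditional
# fixation in the weak and strong ecological-selection regimes, each
# reported together with its validity-condition value. Approximations are
# clipped to [0, 1] with the raw formula value retained.

.approx_report <- function(value, regime, validity, formula_id) {
  structure(list(value = min(max(value, 0), 1), raw = value,
                 regime = regime, validity = validity,
                 formula_id = formula_id),
            class = "approx_report")
}

#' @export
print.approx_report <- function(x, ...) {
  cat(sprintf("%s approximation [%s]: %.6g (raw %.6g, validity %.4g)\n",
              x$regime, x$formula_id, x$value, x$raw, x$validity))
  invisible(x)
}

#' Weak-regime fixation probability
#'
#' In the weak ecological-selection regime the frequency-dependent dynamics
#' behave like constant selection with effective coefficient
#' `s_e = s + (2/3)(2 alpha - 1)^2`, rescaled by the network amplification
#' factor: `p_fix ~ 1/N + (1/2) a_bd s_e`. With `a_bd = 1` this is the
#' well-mixed formula. The report's validity value is `|N a_bd s_e|`, which
#' must be small for the linearization to hold.
#'
#' @param params An [eco_params()].
#' @param a_bd Amplification factor of the structure (1 = well-mixed).
#' @return An `approx_report`.
#' @export
pfix_weak <- function(params, a_bd = 1) {
  stopifnot(params$symmetric, a_bd > 0)
  d <- 2 * params$alpha - 1
  s_e <- params$s + (2 / 3) * d^2
  val <- 1 / params$N + 0.5 * a_bd * s_e
  .approx_report(val, "weak", abs(params$N * a_bd * s_e),
                 if (a_bd == 1) "weak_wellmixed" else "weak_graph")
}

#' Invasion fitness of a rare mutant
#'
#' The relative ecological fitness of the mutant when it is a single
#' individual among `N`; this effective constant fitness governs
#' establishment. For the symmetric strategies in the large-N limit
#' `r_inv = (alpha/(1-alpha) + (1-alpha)/alpha) / 2`, which exceeds one for
#' any `alpha > 0.5` (the rare specialist taps an under-used resource).
#'
#' @param params An [eco_params()].
#' @param limit Use the large-N limit (frequency 0) instead of one mutant in
#'   `N`.
#' @return Invasion fitness (ecological component only; equals 1 at
#'   `alpha = 0.5`).
#' @export
invasion_fitness <- function(params, limit = FALSE) {
  if (params$symmetric && params$alpha == 0.5) return(1)
  if (limit && params$symmetric) {
    a <- params$alpha
    return((a / (1 - a) + (1 - a) / a) / 2)
  }
  cc <- equilibrium_concentrations(1, params)
  eco <- function(strat) sum(params$env$values * strat$alphas *
                               params$env$consumption_law(cc))
  eco(params$mut) / eco(params$wt)
}

#' Strong-regime establishment probability
#'
#' Establishment behaves like fixation of a mutant with constant fitness
#' `r_inv`: `p_est ~ 1 - [(2a-1)^-2 - 1 + 2/N] / [(2a-1)^-2 + 1 - 2/N]`
#' for the well-mixed population (equivalently `1 - 1/r_inv` at large `N`).
#' The star squares the effective fitness, giving `1 - 1/r_inv^2`. The value
#' is independent of `s`, and saturates at 1 as `alpha` approaches 1.
#'
#' @param params An [eco_params()].
#' @param structure `"wellmixed"` or `"star"`.
#' @return An `approx_report`; validity is the strong-regime condition value
#'   from [classify_regime()].
#' @export
pest_strong <- function(params, structure = c("wellmixed", "star")) {
  structure <- match.arg(structure)
  stopifnot(params$symmetric, params$alpha > 0.5)
  d <- 2 * params$alpha - 1
  validity <- (d^-2 - 1 + 2 / params$N) / (d^-2 + 1 - 2 / params$N)
  val <- if (structure == "wellmixed") {
    1 - validity
  } else {
    1 - invasion_fitness(params, limit = TRUE)^-2
  }
  .approx_report(val, "strong", validity,
                 if (structure == "wellmixed") "est_wellmixed" else "est_star")
}

#' Strong-regime conditional fixation probability
#'
#' From the interior equilibrium the dynamics are dominated by the intrinsic
#' coefficient alone, rescaled by the structure:
#' `p_cfix ~ (1 - (1 + a_bd s)^-N) / (1 - (1 + a_bd s)^-2N)`;
#' `a_bd = 1` gives the well-mixed formula and `a_bd = 2` the star closed
#' form. The `s = 0` limit is 1/2.
#'
#' @param params An [eco_params()].
#' @param a_bd Amplification factor.
#' @return An `approx_report`.
#' @export
pcfix_strong <- function(params, a_bd = 1) {
  stopifnot(params$symmetric)
  s_eff <- a_bd * params$s
  if (s_eff <= -1) stop("a_bd * s <= -1: conditional-fixation formula undefined")
  d <- 2 * params$alpha - 1
  validity <- if (d == 0) Inf else
    (d^-2 - 1 + 2 / params$N) / (d^-2 + 1 - 2 / params$N)
  val <- if (s_eff == 0) 0.5 else {
    (1 - (1 + s_eff)^(-params$N)) / (1 - (1 + s_eff)^(-2 * params$N))
  }
  .approx_report(val, "strong", validity,
                 if (a_bd == 1) "cfix_wellmixed" else "cfix_graph")
}

#' Linear interpolation of fixation probability in the amplification factor
#'
#' In the strong regime the fixation probability is approximately linear in
#' the amplification factor; the two exactly solvable anchors, the
#' well-mixed population (`a_bd = 1`) and the star (`a_bd = 2`), pin the
#' line: `p_fix(a) ~ (p_fix^star - p_fix^WM)(a - 1) + p_fix^WM`. The anchor
#' values come from the exact chain solvers.
#'
#' @param params An [eco_params()].
#' @param a_bd Amplification factor of the target structure.
#' @return An `approx_report`; `validity` is the strong-regime condition.
#' @export
pfix_strong_linear <- function(params, a_bd) {
  p_wm <- wellmixed_fixation(params)
  p_star <- star_fixation(params)
  val <- (p_star - p_wm) * (a_bd - 1) + p_wm
  d <- 2 * params$alpha - 1
  validity <- if (d == 0) Inf else
    (d^-2 - 1 + 2 / params$N) / (d^-2 + 1 - 2 / params$N)
  .approx_report(val, "strong", validity, "fix_linear")
}
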