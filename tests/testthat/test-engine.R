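test_that("single runs respect the trajectory contract", {
  g <- graph_family("complete", 20)
  p <- eco_params(20, 0.01, 0.6)
  rec <- moran_run(g, p, sim_config(seed = 5))
  expect_true(rec$outcome %in% c("fixation", "loss"))
  expect_gte(rec$steps, 1)
  rec2 <- moran_run(g, p, sim_config(seed = 5))
  expect_identical(rec, rec2)
})

test_that("neutral Monte-Carlo fixation matches the exact 1/N law", {
  # exact check via the full-state-space oracle on five random graphs
  set.seed(42)
  fams <- list(
    graph_family("erdos_renyi", 7, p = 0.45, seed = 1),
    graph_family("random_tree", 8, seed = 2),
    graph_family("pa_star", 8, i = 2),
    path_graph(6),
    graph_family("star", 7)
  )
  for (g in fams) {
    N <- igraph::vcount(g)
    bf <- brute_force_fixation(g, eco_params(N, 0, 0.5))
    expect_equal(bf$uniform, 1 / N, tolerance = 1e-10)
  }
  # Monte-Carlo check at a size the oracle cannot reach
  g100 <- graph_family("erdos_renyi", 100, p = 0.08, seed = 3)
  est <- estimate_fixation(g100, eco_params(100, 0, 0.5),
                           sim_config(5e4, seed = 1))
  expect_lt(abs(est$p_fix - 0.01) / est$p_fix_se, 3)
})

test_that("constant-selection simulation matches the Moran closed form", {
  g <- graph_family("complete", 100)
  est <- estimate_fixation(g, eco_params(100, 0.02, 0.5),
                           sim_config(3e4, seed = 1))
  pexact <- (1 - 1.02^-1) / (1 - 1.02^-100)
  expect_lt(abs(est$p_fix - pexact) / est$p_fix_se, 3)
})

test_that("estimates are reproducible under the master seed", {
  g <- graph_family("k_regular", 30, k = 4, seed = 2)
  p <- eco_params(30, -0.01, 0.7)
  e1 <- estimate_fixation(g, p, sim_config(2000, seed = 13))
  e2 <- estimate_fixation(g, p, sim_config(2000, seed = 13))
  expect_identical(e1$p_fix, e2$p_fix)
  expect_identical(e1$t_unconditional, e2$t_unconditional)
})

test_that("establishment tracking satisfies the product identity", {
  # moderate attraction to the interior equilibrium, so no replicate can
  # linger past the step cap and bias the first-passage estimates
  g <- graph_family("complete", 50)
  p <- eco_params(50, -0.01, 0.65)
  est <- estimate_fixation(g, p, sim_config(3e4, seed = 7,
                                            track_establishment = TRUE))
  prod_se <- sqrt(est$p_est_se^2 * est$p_cfix^2 +
                    est$p_cfix_se^2 * est$p_est^2) + est$p_fix_se
  expect_lt(abs(est$p_est * est$p_cfix - est$p_fix), 3 * prod_se + 1e-12)
  # and the estimates agree with the exact chain decomposition
  wmd <- wellmixed_decomposition(p)
  expect_lt(abs(est$p_est - wmd$p_est) / est$p_est_se, 4)
  expect_lt(abs(est$p_fix - wmd$p_fix) / est$p_fix_se, 4)
  expect_error(
    estimate_fixation(g, eco_params(50, -0.01, 0.5),
                      sim_config(10, seed = 1, track_establishment = TRUE)),
    "establishment")
})

test_that("fixation time grows with the strength of ecological selection", {
  g <- graph_family("complete", 50)
  cfg <- function(seed) sim_config(5e3, seed = seed)
  t_lo <- estimate_fixation(g, eco_params(50, 0, 0.5), cfg(3))$t_unconditional
  t_hi <- estimate_fixation(g, eco_params(50, 0, 0.7), cfg(3))$t_unconditional
  expect_gt(t_hi, t_lo)
})

test_that("diffusible steady states solve the Laplacian system", {
  g <- graph_family("star", 10)
  p <- eco_params(10, -0.005, 0.8)
  # uniform occupancy: constant concentrations S / alpha for any D
  for (D in c(0.1, 1, 50)) {
    f1 <- diffusible_steady_state(g, rep("wt", 10), p, D = D)
    expect_equal(f1[, 1], rep(0.5 / 0.2, 10))
    expect_equal(f1[, 2], rep(0.5 / 0.8, 10))
  }
  # 3-node path with one mutant: dense direct-solve oracle
  g3 <- path_graph(3)
  p3 <- eco_params(3, 0, 0.7)
  occ <- c("mut", "wt", "wt")
  fs <- diffusible_steady_state(g3, occ, p3, D = 1)
  L <- as.matrix(igraph::laplacian_matrix(g3))
  for (i in 1:2) {
    a <- ifelse(occ == "mut", p3$mut$alphas[i], p3$wt$alphas[i])
    expect_equal(fs[, i], solve(L + diag(a), rep(0.5, 3)), tolerance = 1e-12)
  }
  expect_error(
    diffusible_steady_state(g3, rep("wt", 3), eco_params(3, 0, 1), D = 1),
    "degenerate")
})

test_that("diffusible fitness reduces to the well-mixed form", {
  g3 <- path_graph(3)
  occ <- c("mut", "wt", "wt")
  # alpha = 0.5: fitness is 1 or 1 + s by occupancy, independent of D
  p5 <- eco_params(3, 0.02, 0.5)
  for (D in c(0.5, 10)) {
    ff <- diffusible_fitness(diffusible_steady_state(g3, occ, p5, D), occ, p5)
    expect_equal(ff / ff[2], c(1.02, 1, 1))
  }
  # all wild type: every node has the same fitness
  pw <- eco_params(3, 0.1, 0.8)
  fw <- diffusible_fitness(diffusible_steady_state(g3, rep("wt", 3), pw, 1),
                           rep("wt", 3), pw)
  expect_equal(fw, rep(fw[1], 3))
  # large D: the mutant/wild-type fitness ratio converges to the well-mixed
  # relative fitness (per-node supply rescales both types equally)
  p3 <- eco_params(3, 0.01, 0.7)
  fbig <- diffusible_fitness(diffusible_steady_state(g3, occ, p3, 1e4),
                             occ, p3)
  expect_equal(fbig[1] / fbig[2], relative_mutant_fitness(1, p3),
               tolerance = 1e-4)
})

test_that("large diffusion reproduces well-mixed-resource fixation", {
  g <- graph_family("star", 20)
  p <- eco_params(20, -0.005, 0.6)
  ed <- estimate_fixation(g, p, sim_config(1e4, seed = 4,
                                           resource_mode = "diffusible",
                                           D = 100))
  ew <- estimate_fixation(g, p, sim_config(1e4, seed = 4))
  z <- (ed$p_fix - ew$p_fix) / sqrt(ed$p_fix_se^2 + ew$p_fix_se^2)
  expect_lt(abs(z), 3)
  expect_identical(ed$truncated, 0L)
})
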