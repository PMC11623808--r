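test_that("well-mixed chain matches the constant-selection closed form", {
  p <- eco_params(100, 0.02, 0.5)
  expect_equal(wellmixed_fixation(p),
               (1 - 1.02^-1) / (1 - 1.02^-100), tolerance = 1e-12)
  expect_equal(wellmixed_fixation(eco_params(30, 0, 0.5)), 1 / 30,
               tolerance = 1e-12)
  expect_equal(wellmixed_fixation(p, start = 0), 0)
  expect_equal(wellmixed_fixation(p, start = 100), 1)
})

test_that("well-mixed chain matches an independent dense absorption solve", {
  for (prm in list(c(-0.01, 0.8), c(0.03, 0.6), c(-0.05, 0.95))) {
    p <- eco_params(10, prm[1], prm[2])
    expect_equal(wellmixed_fixation(p), wellmixed_fixation_oracle(p),
                 tolerance = 1e-10)
  }
  # frozen value for the dense-oracle-verified case
  expect_equal(wellmixed_fixation(eco_params(10, -0.01, 0.8)),
               0.198438503815, tolerance = 1e-10)
})

test_that("reduced solvers agree with the 2^N brute-force oracle", {
  graphs <- list(
    star = graph_family("star", 6),
    complete = graph_family("complete", 6),
    pastar = graph_family("pa_star", 8, i = 3),
    path = path_graph(5)
  )
  for (s in c(-0.05, 0, 0.05)) {
    for (alpha in c(0.5, 0.7, 0.9)) {
      p6 <- eco_params(6, s, alpha)
      p8 <- eco_params(8, s, alpha)
      p5 <- eco_params(5, s, alpha)
      info <- sprintf("s=%g alpha=%g", s, alpha)
      expect_equal(star_fixation(p6),
                   brute_force_fixation(graphs$star, p6)$uniform,
                   tolerance = 1e-8, info = info)
      expect_equal(wellmixed_fixation(p6),
                   brute_force_fixation(graphs$complete, p6)$uniform,
                   tolerance = 1e-8, info = info)
      expect_equal(pastar_fixation(p8, 3)$p_fix,
                   brute_force_fixation(graphs$pastar, p8)$uniform,
                   tolerance = 1e-8, info = info)
      # neutral law: uniform placement fixes with probability 1/N everywhere
      if (s == 0 && alpha == 0.5) {
        expect_equal(brute_force_fixation(graphs$path, p5)$uniform, 1 / 5,
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("brute force refuses oversized graphs", {
  g <- graph_family("star", 15)
  expect_error(brute_force_fixation(g, eco_params(15, 0, 0.5)), "N <= 14")
})

test_that("path-graph fixation regression value is stable", {
  # frozen from the verified 2^N oracle
  bf <- brute_force_fixation(path_graph(5), eco_params(5, 0.05, 0.7))
  expect_equal(bf$uniform, 0.248317009877, tolerance = 1e-9)
  expect_equal(bf$per_node[1], bf$per_node[5], tolerance = 1e-12)
})

test_that("PA star interpolates between the star and the complete graph", {
  p <- eco_params(12, -0.02, 0.75)
  expect_equal(pastar_fixation(p, 1)$p_fix, star_fixation(p),
               tolerance = 1e-10)
  expect_equal(pastar_fixation(p, 11)$p_fix, wellmixed_fixation(p),
               tolerance = 1e-10)
})

test_that("establishment decomposition multiplies back to fixation", {
  for (i in c(1, 3, 10)) {
    dec <- pastar_fixation(eco_params(50, -0.01, 0.8), i)
    expect_equal(dec$p_fix, dec$p_est * dec$p_cfix, tolerance = 1e-12,
                 info = paste("i =", i))
    expect_true(dec$p_est > 0 && dec$p_est < 1)
    expect_true(dec$p_cfix > 0 && dec$p_cfix < 1)
  }
  wmd <- wellmixed_decomposition(eco_params(50, -0.01, 0.8))
  expect_equal(wmd$p_fix, wellmixed_fixation(eco_params(50, -0.01, 0.8)),
               tolerance = 1e-12)
  expect_equal(wmd$m_star, ceiling(50 * as.numeric(
    equilibrium_frequency(eco_params(50, -0.01, 0.8)))))
  # the reduced-chain decomposition agrees with the 1-D chain at i = N-1
  dec_wm <- pastar_fixation(eco_params(50, -0.01, 0.8), 49)
  expect_equal(dec_wm$p_est, wmd$p_est, tolerance = 1e-10)
  expect_equal(dec_wm$p_cfix, wmd$p_cfix, tolerance = 1e-10)
})

test_that("fixation probability is monotone in s and non-monotone in alpha", {
  ss <- seq(-0.03, 0.03, by = 0.01)
  for (alpha in c(0.5, 0.7)) {
    pf <- vapply(ss, function(s)
      wellmixed_fixation(eco_params(60, s, alpha)), numeric(1))
    expect_true(all(diff(pf) > 0), info = paste("alpha =", alpha))
  }
  # ecological selection lifts a deleterious mutant above its no-ecology
  # fixation probability
  pf_a <- vapply(c(0.5, 0.7), function(a)
    wellmixed_fixation(eco_params(60, -0.01, a)), numeric(1))
  expect_gt(pf_a[2], pf_a[1])
})

test_that("star/well-mixed crossing sits at zero without ecology", {
  ip <- intersection_point(50, 0.5)
  expect_identical(ip$Ns_star, 0)
  expect_identical(ip$flag, "at_zero")
})

test_that("weak-regime crossing matches the effective-selection prediction", {
  # s* ~ -(2/3)(2 alpha - 1)^2 where N (2/3)(2a-1)^2 is small
  for (alpha in c(0.53, 0.55)) {
    ip <- intersection_point(50, alpha)
    expect_identical(ip$flag, "crossing")
    pred <- -(2 / 3) * (2 * alpha - 1)^2
    expect_equal(ip$s_star, pred, tolerance = 0.2)
  }
})

test_that("crossing curve is negative and non-monotonic over alpha", {
  cc <- crossing_curve(50, c(0.55, 0.65, 0.8, 0.95))
  expect_true(all(cc$s_star < 0))
  expect_gt(cc$N_s_star[4], cc$N_s_star[2])  # shrinks again at strong alpha
})
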