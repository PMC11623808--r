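test_that("weak-regime fixation formula reproduces its worked values", {
  expect_equal(pfix_weak(eco_params(100, 0, 0.5))$value, 0.01)
  r <- pfix_weak(eco_params(100, -0.001, 0.53))
  expect_equal(r$value, 0.01 - 0.0005 + (1 / 3) * 0.06^2)
  r2 <- pfix_weak(eco_params(100, -0.001, 0.53), a_bd = 2)
  expect_equal(r2$value, 0.01 + 2 * 0.0007)
  # an amplifier promotes this deleterious mutant relative to well-mixed
  expect_gt(r2$value, r$value)
})

test_that("weak formula tracks the exact chain where the regime holds", {
  for (N in c(50, 100)) {
    for (alpha in c(0.5, 0.52, 0.53)) {
      for (s in c(-0.002, 0, 0.002)) {
        p <- eco_params(N, s, alpha)
        s_e <- s + (2 / 3) * (2 * alpha - 1)^2
        if (abs(N * s_e) < 0.3) {
          expect_equal(pfix_weak(p)$value, wellmixed_fixation(p),
                       tolerance = 0.1,
                       info = sprintf("N=%d s=%g a=%g", N, s, alpha))
        }
      }
    }
  }
})

test_that("invasion fitness has the stated limits", {
  expect_equal(invasion_fitness(eco_params(100, 0, 0.5)), 1)
  expect_equal(invasion_fitness(eco_params(1e4, 0, 0.8)), 2.125,
               tolerance = 1e-3)
  expect_equal(invasion_fitness(eco_params(100, 0, 0.8), limit = TRUE), 2.125)
  # complete niche separation: invasion fitness grows with N
  r1 <- invasion_fitness(eco_params(100, 0, 1))
  r2 <- invasion_fitness(eco_params(1000, 0, 1))
  expect_gt(r2, r1)
  expect_gt(r1, 10)
})

test_that("strong-regime establishment formula and its properties hold", {
  r <- pest_strong(eco_params(500, -0.01, 0.8))
  expect_equal(r$value, 0.5278, tolerance = 1e-3)
  # independence from s
  expect_identical(pest_strong(eco_params(500, -0.01, 0.8))$value,
                   pest_strong(eco_params(500, 0.01, 0.8))$value)
  # saturation at complete niche separation, both structures
  expect_gt(pest_strong(eco_params(500, 0, 0.999))$value, 0.99)
  expect_gt(pest_strong(eco_params(500, 0, 0.999), "star")$value, 0.99)
  # the two printed forms agree at large N
  for (alpha in c(0.7, 0.85, 0.95)) {
    p <- eco_params(2e6, 0, alpha)
    expect_equal(pest_strong(p)$value,
                 1 - 1 / invasion_fitness(p, limit = TRUE),
                 tolerance = 1e-6)
  }
})

test_that("strong-regime conditional fixation formula behaves", {
  expect_equal(pcfix_strong(eco_params(500, 0, 0.8))$value, 0.5)
  expect_equal(pcfix_strong(eco_params(500, -0.01, 0.8))$value, 0.006527594,
               tolerance = 1e-6)
  # independence from alpha
  expect_identical(pcfix_strong(eco_params(500, -0.01, 0.8))$value,
                   pcfix_strong(eco_params(500, -0.01, 0.99))$value)
  expect_error(pcfix_strong(eco_params(100, -0.6, 0.8), a_bd = 2), "a_bd")
})

test_that("strong-regime formulas track the exact chains (2% / 5%)", {
  for (alpha in c(0.8, 0.9, 0.95)) {
    for (s in c(-0.01, -0.002, 0.01)) {
      p <- eco_params(500, s, alpha)
      wmd <- wellmixed_decomposition(p)
      expect_equal(pest_strong(p)$value, wmd$p_est, tolerance = 0.02,
                   info = sprintf("est s=%g a=%g", s, alpha))
      expect_equal(pcfix_strong(p)$value, wmd$p_cfix, tolerance = 0.05,
                   info = sprintf("cfix s=%g a=%g", s, alpha))
    }
  }
  # on the boundary of the regime the agreement degrades gracefully
  p_edge <- eco_params(500, -0.01, 0.7)
  wmd_edge <- wellmixed_decomposition(p_edge)
  expect_equal(pest_strong(p_edge)$value, wmd_edge$p_est, tolerance = 0.05)
  expect_equal(pcfix_strong(p_edge)$value, wmd_edge$p_cfix, tolerance = 0.10)
  # star variant: amplification factor 2 on the intrinsic coefficient
  p <- eco_params(500, -0.01, 0.8)
  star_dec <- pastar_fixation(p, 1)
  expect_equal(pcfix_strong(p, a_bd = 2)$value, star_dec$p_cfix,
               tolerance = 0.05)
})

test_that("exact establishment is insensitive to s in the strong regime", {
  vals <- vapply(c(-0.01, 0, 0.01), function(s)
    wellmixed_decomposition(eco_params(500, s, 0.8))$p_est, numeric(1))
  expect_lt(diff(range(vals)) / mean(vals), 0.02)
})

test_that("linear interpolation in a_bd hits its exact anchors", {
  p <- eco_params(100, -0.001, 0.9)
  p_wm <- wellmixed_fixation(p)
  p_st <- star_fixation(p)
  expect_equal(pfix_strong_linear(p, 1)$value, p_wm, tolerance = 1e-12)
  expect_equal(pfix_strong_linear(p, 2)$value, p_st, tolerance = 1e-12)
  expect_equal(pfix_strong_linear(p, 1.5)$value, (p_wm + p_st) / 2,
               tolerance = 1e-12)
})

test_that("amplification helps or hurts fixation depending on the regime", {
  # establishment-dominated: fixation rises with amplification
  p_est_dom <- eco_params(100, -0.001, 0.9)
  expect_gt(star_fixation(p_est_dom), wellmixed_fixation(p_est_dom))
  # conditional-fixation-dominated (no niche overlap left to exploit):
  # amplification suppresses the deleterious mutant
  p_cfix_dom <- eco_params(100, -0.001, 1)
  expect_lt(star_fixation(p_cfix_dom), wellmixed_fixation(p_cfix_dom))
})
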