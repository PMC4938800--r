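test_that("structure vectors resolve as documented", {
  co <- rbind(c(0, 0, 0), c(0, 0, 2), c(1, 0, 0), c(0, 1, 0))
  rownames(co) <- paste0("A:", 1:4)
  defs <- list(L1 = vector_def("L1", "line", "A", c(1, 2)),
               P1 = vector_def("P1", "plane_normal", "A", c(1, 3, 4)))
  v <- resolve_vectors(co, defs)
  expect_equal(v$L1, c(0, 0, 1))
  expect_equal(v$P1, c(0, 0, 1)) # (e1 x e2) order fixes orientation
  # reversed anchor order flips the normal
  defs2 <- list(P2 = vector_def("P2", "plane_normal", "A", c(1, 4, 3)))
  expect_equal(resolve_vectors(co, defs2)$P2, c(0, 0, -1))
  # collinear anchors error
  co2 <- rbind(c(0, 0, 0), c(0, 0, 1), c(0, 0, 2))
  rownames(co2) <- paste0("A:", 1:3)
  expect_error(resolve_vectors(co2, list(
    vector_def("P", "plane_normal", "A", 1:3))), "collinear")
  expect_error(resolve_vectors(co, list(
    vector_def("L", "line", "A", c(1, 9)))), "missing")
  expect_error(vector_def("x", "line", "A", c(2, 2)), "distinct")
})

test_that("difference-angle series and widths behave analytically", {
  s <- ca_structure(helix_ca(38))
  ref <- ca_coords(s)
  rigid <- ensemble_from_list(s, lapply(1:4, function(k) random_rigid(ref, k)))
  rigid <- superpose(rigid)
  defs <- hinge_vector_defs(c(19, 19))
  a <- angle_series(rigid, c("AX1", "AX2"), defs)
  expect_equal(as.numeric(a), rep(0, 4), tolerance = 1e-7)

  # pair within one rigid segment of a flexing ensemble: sigma ~ 0
  ens <- make_hinge_ensemble(c(19, 19), bend_sd = 10, n = 256, seed = 1)
  defs$S1 <- vector_def("S1", "line", "A", c(1, 10))
  defs$S2 <- vector_def("S2", "line", "A", c(10, 19))
  intra <- angle_series(ens, c("S1", "S2"), defs)
  expect_lt(angle_sigma(intra), 1e-6)

  # pair straddling the hinge recovers the generator sd within 5%
  span <- angle_series(ens, c("AX1", "AX2"), defs, signed = TRUE,
                       sign_ref = "RN1")
  expect_equal(angle_sigma(span), 10, tolerance = 0.05)

  # angle_sigma trivials and formula oracle
  expect_equal(angle_sigma(rep(2.5, 9)), 0)
  expect_equal(angle_sigma(c(-1, 1)), 1)
  set.seed(2)
  x <- rnorm(100)
  expect_equal(angle_sigma(x), sqrt(mean((x - mean(x))^2)), tolerance = 1e-12)
})

test_that("angle series are invariant to per-conformer rigid motions", {
  ens <- make_hinge_ensemble(c(19, 19), bend_sd = 8, n = 64, seed = 3)
  defs <- hinge_vector_defs(c(19, 19))
  a0 <- angle_series(ens, c("AX1", "AX2"), defs, signed = TRUE,
                     sign_ref = "RN1")
  moved <- ens$coords
  for (r in seq_len(dim(moved)[1]))
    moved[r, , ] <- random_rigid(moved[r, , ], r + 7)
  ens2 <- superpose(new_ensemble(ens$reference, moved))
  a1 <- angle_series(ens2, c("AX1", "AX2"), defs, signed = TRUE,
                     sign_ref = "RN1")
  expect_equal(as.numeric(a1), as.numeric(a0), tolerance = 1e-6)
})

test_that("amplification ratios are exact on constructed series", {
  expect_equal(amplification(structure(c(-1, 1), class = "angle_series"),
                             structure(c(-1, 1), class = "angle_series")), 1)
  expect_equal(amplification(structure(c(-10, 10), class = "angle_series"),
                             structure(c(-5, 5), class = "angle_series")), 2)
  expect_error(amplification(structure(c(-1, 1), class = "angle_series"),
                             structure(c(0, 0), class = "angle_series")),
               "zero width")

  # serial two-hinge fixture: ratio matches the generator-derived
  # expectation within 10%
  ens <- make_hinge_ensemble(c(19, 19, 19), bend_sd = c(8, 8), n = 1024,
                             seed = 4)
  defs <- hinge_vector_defs(c(19, 19, 19))
  prox <- angle_series(ens, c("AX1", "AX2"), defs, signed = TRUE,
                       sign_ref = "RN1")
  dist_ <- angle_series(ens, c("AX1", "AX3"), defs, signed = TRUE,
                        sign_ref = "RN1")
  tr <- attr(ens, "truth")
  expected <- sd(tr$bends[, 1] + tr$bends[, 2]) / sd(tr$bends[, 1])
  expect_gt(amplification(dist_, prox), 1)
  expect_equal(amplification(dist_, prox), expected, tolerance = 0.10)
})

test_that("Gaussian histogram models evaluate and fit as printed forms", {
  # published-parameter formula check: y(x0) = a for the single form
  expect_equal(ensmech:::gauss_single(0.2, a = 2904, b = 5.48, x0 = 0.2),
               2904)
  expect_equal(ensmech:::gauss_double(3.55, a = 2701, b = 2.72, x0 = 3.55),
               2701 * (1 + exp(-0.5 * (7.1 / 2.72)^2)))

  # samples from a symmetric two-state mixture: double fit recovers the
  # separation within 0.3 degrees and beats the single fit
  set.seed(5)
  x <- c(rnorm(4096, -3.55, 2.72), rnorm(4096, 3.55, 2.72))
  fit <- fit_angle_models(structure(x, class = "angle_series"))
  expect_equal(fit$double$x0, 3.55, tolerance = 0.3 / 3.55)
  expect_gt(fit$double$r2, fit$single$r2)
  expect_equal(fit$preferred, "double")

  # unimodal normal samples: parsimony, single is not materially worse
  y <- rnorm(4096, 0, 5)
  fit2 <- fit_angle_models(structure(y, class = "angle_series"))
  expect_gte(fit2$single$r2, fit2$double$r2 - 0.02)
  expect_equal(fit2$single$b, 5, tolerance = 0.1)
})

test_that("torsional stiffness follows kBT / width^2", {
  one_rad <- torsional_stiffness(180 / pi, temperature = 300)
  expect_equal(one_rad$kappa_pn_nm, 4.114, tolerance = 1e-12)
  expect_equal(torsional_stiffness(0.1 * 180 / pi)$kappa_pn_nm, 411.4,
               tolerance = 1e-9)
  # halving the width quadruples the stiffness
  k1 <- torsional_stiffness(10)$kappa_pn_nm
  k2 <- torsional_stiffness(5)$kappa_pn_nm
  expect_equal(k2 / k1, 4, tolerance = 1e-12)
  expect_error(torsional_stiffness(0), "positive")
  expect_equal(torsional_stiffness(5, model = "two_state")$model, "two_state")
})

test_that("coupling relations are classified by adjusted R^2", {
  set.seed(6)
  x <- runif(600, -20, 20)

  # linear with known slope 8
  y <- 8 * x + rnorm(600, 0, 5)
  cl <- coupling_relation(x, y)
  expect_equal(cl$winner, "linear")
  expect_equal(cl$fits$linear$slope, 8, tolerance = 0.05)
  expect_lt(abs(cl$fits$linear$slope - 8), 3 * cl$fits$linear$slope_se + 0.2)

  # exact parabola
  cp <- coupling_relation(x, x^2)
  expect_equal(cp$winner, "parabolic")
  expect_equal(cp$fits$parabolic$c, 1, tolerance = 1e-8)
  expect_equal(cp$fits$parabolic$r2, 1, tolerance = 1e-12)

  # saturating end-state response: clamp(8x, -L, L)
  yc <- pmin(pmax(8 * x, -60), 60) + rnorm(600, 0, 2)
  ce <- coupling_relation(x, yc)
  expect_equal(ce$winner, "end_state")
  expect_equal(ce$fits$end_state$s, 8, tolerance = 0.1)
  expect_equal(ce$fits$end_state$L, 60, tolerance = 0.05)
})

test_that("single-PC variances add up to the full ensemble variance", {
  ens <- make_hinge_ensemble(c(19, 19), bend_sd = 10, twist_sd = 6,
                             n = 2048, seed = 7)
  m <- suppressWarnings(fit_pca(ens))
  defs <- hinge_vector_defs(c(19, 19))
  full <- angle_series(ens, c("AX1", "AX2"), defs, signed = TRUE,
                       sign_ref = "RN1")
  per_pc <- vapply(seq_len(10), function(k) {
    if (m$values[k] / m$values[1] < 1e-8) return(0)
    tr <- pc_trajectory(m, k, gaussian_amplitude_grid(65))
    angle_sigma(angle_series(tr, c("AX1", "AX2"), defs, signed = TRUE,
                             sign_ref = "RN1"))^2
  }, 0)
  expect_equal(sum(per_pc), angle_sigma(full)^2,
               tolerance = 0.10)
})
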