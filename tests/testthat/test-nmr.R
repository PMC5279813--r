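## Hand-evaluated Karplus oracle, independent of the implementation.
karplus_oracle <- function(phi, A, B, C) {
  th <- (phi - 60) * pi / 180
  A * cos(th)^2 + B * cos(th) + C
}

test_that("Karplus couplings match hand-evaluated closed forms", {
  pardi <- karplus_coefficients("pardi")
  ## phi = -60: cos(-120 deg) = -1/2 -> 6.4/4 - 1.4*(-1/2) + 1.9 = 4.2
  expect_equal(karplus_j(-60, pardi), 4.2, tolerance = 1e-12)
  ## phi = 60: cos(0) = 1 -> A + B + C
  expect_equal(karplus_j(60, pardi), 6.4 - 1.4 + 1.9, tolerance = 1e-12)
  brue <- karplus_coefficients("brueschweiler")
  expect_equal(karplus_j(-60, brue), 9.5 / 4 + 0.7 + 0.3, tolerance = 1e-12)

  for (label in c("pardi", "brueschweiler", "vuister")) {
    co <- karplus_coefficients(label)
    for (phi in c(-180, -120, -60, 0, 60, 120)) {
      expect_equal(karplus_j(phi, co),
                   karplus_oracle(phi, co[["A"]], co[["B"]], co[["C"]]),
                   tolerance = 1e-12)
    }
    ## 360-degree periodicity
    phis <- seq(-180, 175, by = 5)
    expect_equal(karplus_j(phis + 360, co), karplus_j(phis, co),
                 tolerance = 1e-9)
    ## extrema of the cos-quadratic: with A > 0 and B < 0 the maximum sits
    ## at cos(phi - 60) = -1 (phi = -120) and the minima at the
    ## arccos(-B / 2A) branches around 60
    grid <- seq(-179.75, 180, by = 0.25)
    scan <- karplus_j(grid, co)
    expect_equal(grid[which.max(scan)], -120)
    branch <- acos(-co[["B"]] / (2 * co[["A"]])) * 180 / pi
    for (m in c(60 - branch, 60 + branch)) {
      win <- abs(grid - m) < 10
      expect_lt(abs(grid[win][which.min(scan[win])] - m), 0.5)
    }
  }
})

test_that("ensemble J-couplings exclude the N-terminus and average frames", {
  ens <- generate_ensemble(basins_coil(), 6, seed = 61, n_residues = 10)
  jc <- ensemble_jcouplings(ens)
  expect_false("10" %in% names(jc))   # first residue excluded
  expect_equal(length(jc), 9)

  one <- pep_ensemble(ens$frames[1])
  j1 <- ensemble_jcouplings(one)
  d <- extract_dihedrals(one)
  expect_equal(unname(j1), unname(karplus_j(d$phi[1, -1])), tolerance = 1e-12)

  ## uniform weights equal an explicit frame loop
  brute <- Reduce(`+`, lapply(ens$frames, function(f) {
    ensemble_jcouplings(pep_ensemble(list(f)))
  })) / 6
  expect_equal(jc, brute, tolerance = 1e-12)
})

test_that("steric alignment tensors are symmetric, traceless and shaped by the molecule", {
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  A <- steric_alignment_tensor(cube)
  expect_equal(A, t(A), tolerance = 1e-12)
  expect_lt(abs(sum(diag(A))), 1e-9)
  expect_true(all(abs(eigen(A)$values) < 1e-3))  # near-isotropic

  rod <- cbind(0.3 * cos(1:21), 0.3 * sin(1:21), seq(-10, 10, length.out = 21))
  Ar <- steric_alignment_tensor(rod)
  ev <- sort(eigen(Ar)$values)
  expect_lt(abs(ev[2] - ev[3]), 1e-3)       # axially symmetric pair
  expect_gt(abs(ev[1] - ev[2]), 0.05)       # distinct third eigenvalue

  ## rotation equivariance within grid discretization error
  set.seed(71)
  P <- matrix(rnorm(60), 20, 3) %*% diag(c(3, 1.5, 1))
  for (rep in 1:3) {
    R <- random_rot()
    A1 <- steric_alignment_tensor(P, grid_size = 4000)
    A2 <- steric_alignment_tensor(P %*% t(R), grid_size = 4000)
    expect_lt(max(abs(R %*% A1 %*% t(R) - A2)), 5e-3)
  }
  expect_error(steric_alignment_tensor(cbind(1:5, 0, 0)), "collinear")
})

test_that("unscaled RDCs follow the tensor spectral identities", {
  expect_equal(rdc_unscaled(c(0, 0, 1), matrix(0, 3, 3)), 0)
  set.seed(81)
  S <- crossprod(matrix(rnorm(9), 3))
  S <- (S + t(S)) / 2
  S <- S - diag(sum(diag(S)) / 3, 3)
  eg <- eigen(S)
  for (k in 1:3) {
    expect_equal(rdc_unscaled(eg$vectors[, k], S), eg$values[k],
                 tolerance = 1e-9)
  }
  ## isotropic average vanishes by tracelessness
  U <- pepensemble:::fibonacci_sphere(5000)
  expect_lt(abs(mean(rdc_unscaled(U, S))), 1e-3)
})

test_that("ensemble RDCs align helical stretches coherently", {
  h <- ideal_helix(12)
  rdc <- ensemble_rdc(pep_ensemble(list(h)), grid_size = 1152)
  interior <- as.character(14:19)  # helix core (numbering starts at 10)
  expect_true(all(rdc[interior] > 0) || all(rdc[interior] < 0))

  ## two identical frames equal one frame; uniform weights equal frame loop
  e1 <- pep_ensemble(list(h))
  e2 <- pep_ensemble(list(h, h))
  expect_equal(ensemble_rdc(e1, grid_size = 288),
               ensemble_rdc(e2, grid_size = 288), tolerance = 1e-12)
  ens <- generate_ensemble(basins_coil(), 3, seed = 82, n_residues = 8)
  full <- ensemble_rdc(ens, grid_size = 288)
  brute <- Reduce(`+`, lapply(ens$frames, function(f)
    ensemble_rdc(pep_ensemble(list(f)), grid_size = 288))) / 3
  expect_equal(full, brute, tolerance = 1e-12)
})

test_that("least-squares scaling has its closed form and grid optimum", {
  x <- stats::setNames(c(1, 2, 3, 4), 11:14)
  expect_equal(fit_scale(x, 2 * x), 2, tolerance = 1e-12)
  y <- stats::setNames(c(2, -1, 0, 0), 11:14)  # orthogonal to x
  expect_equal(fit_scale(x, y), 0, tolerance = 1e-12)
  expect_error(fit_scale(stats::setNames(c(0, 0), 11:12),
                         stats::setNames(c(1, 2), 11:12)), "zero")

  set.seed(91)
  xc <- stats::setNames(rnorm(15), 1:15)
  ye <- stats::setNames(rnorm(15), 1:15)
  s_hat <- fit_scale(xc, ye)
  grid <- seq(-5, 5, length.out = 10001)
  loss <- vapply(grid, function(s) sum((s * xc - ye)^2), numeric(1))
  expect_lt(abs(s_hat - grid[which.min(loss)]), diff(grid[1:2]))
})

test_that("the full RDC path is self-consistent at zero noise", {
  ens <- generate_ensemble(basins_coil(), 5, seed = 92, n_residues = 10)
  rdc <- ensemble_rdc(ens, grid_size = 1152)
  tab <- generate_synthetic_experiment(ens, "RDC", noise_sd = 0,
                                       grid_size = 1152)
  s <- fit_scale(rdc, tab$entries)
  expect_equal(s, 1, tolerance = 1e-12)
  expect_equal(metric_q(s * rdc, tab$entries), 0)
  expect_equal(metric_pcc(s * rdc, tab$entries), 1)
})
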