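## Brute-force contact oracle: exhaustive all-pairs double loop.
brute_contacts <- function(conf, cutoff = 6.5, min_separation = 2) {
  cen <- centroid_matrix(conf)
  idx <- conf$seq_index
  out <- NULL
  for (a in seq_along(idx)) {
    for (b in seq_along(idx)) {
      if (b <= a) next
      if (abs(idx[b] - idx[a]) < min_separation) next
      if (sqrt(sum((cen[a, ] - cen[b, ])^2)) < cutoff)
        out <- rbind(out, c(idx[a], idx[b]))
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2) else out
}

test_that("contact detection uses a strict 6.5 A boundary", {
  ## two residues with centroids exactly at / just inside the cutoff
  mk <- function(x) {
    r1 <- toy_residue(10L, sidechain = matrix(c(0, 0, 0), 1, 3,
                                              dimnames = list("CB", NULL)))
    r2 <- toy_residue(13L, shift = c(3, 0, 0),
                      sidechain = matrix(c(x, 0, 0), 1, 3,
                                         dimnames = list("CB", NULL)))
    conformation(list(r1, r2), check = FALSE)
  }
  expect_equal(nrow(frame_contacts(mk(6.5))), 0)
  expect_equal(nrow(frame_contacts(mk(6.49))), 1)
})

test_that("contact sets equal the exhaustive double loop on random frames", {
  set.seed(200)
  ens <- generate_ensemble(basins_coil(), 200, seed = 201)
  for (f in seq_along(ens$frames)) {
    fast <- frame_contacts(ens$frames[[f]])
    slow <- brute_contacts(ens$frames[[f]])
    expect_equal(unname(fast[order(fast[, 1], fast[, 2]), , drop = FALSE]),
                 unname(slow[order(slow[, 1], slow[, 2]), , drop = FALSE]))
  }
})

test_that("range classification uses |j - i| >= 5 inclusive", {
  expect_equal(classify_range(16, 23), "long")
  expect_equal(classify_range(17, 19), "short")
  expect_equal(classify_range(10, 15), "long")  # boundary |d| = 5
  expect_equal(classify_range(10, 14), "short")
  expect_error(classify_range(10, 10), "differ")
})

test_that("contact maps accumulate weighted occupancies and counts", {
  bias <- list(pair = c(16, 23), prob = 1)
  ens <- generate_ensemble(basins_coil(), 10, seed = 77, contact_bias = bias)
  cm <- contact_map(ens)
  expect_equal(cm$occupancy["16", "23"], 1.0)
  expect_equal(cm$occupancy, t(cm$occupancy))
  expect_true(all(cm$occupancy >= 0 & cm$occupancy <= 1))
  expect_lte(cm$n_long, cm$n_all)
  ## <C> equals the sum of occupancies over i < j
  expect_equal(cm$n_all, sum(cm$occupancy[upper.tri(cm$occupancy)]),
               tolerance = 1e-9)
  ## separation below min_separation is always zero
  idx <- cm$seq_index
  for (i in seq_along(idx)) {
    near <- abs(idx - idx[i]) < cm$min_separation
    expect_true(all(cm$occupancy[i, near] == 0))
  }

  ## weighted two-frame case: contact only in frame 2 at weight 0.75
  two <- pep_ensemble(ens$frames[1:2])
  c1 <- frame_contacts(two$frames[[1]])
  c2 <- frame_contacts(two$frames[[2]])
  only2 <- setdiff(paste(c2[, 1], c2[, 2]), paste(c1[, 1], c1[, 2]))
  if (length(only2) > 0) {
    ij <- as.integer(strsplit(only2[1], " ")[[1]])
    cmw <- contact_map(two, weights = c(0.25, 0.75))
    expect_equal(cmw$occupancy[as.character(ij[1]), as.character(ij[2])],
                 0.75)
  }

  ## single frame with a known number of qualifying pairs
  one <- pep_ensemble(ens$frames[1])
  cm1 <- contact_map(one)
  expect_equal(cm1$n_all, nrow(frame_contacts(one$frames[[1]])))
})

test_that("top contacts rank by occupancy with documented tie-break", {
  ens <- generate_ensemble(basins_coil(), 30, seed = 88)
  cm <- contact_map(ens)
  for (rc in c("long", "short")) {
    top <- top_contacts(cm, 5, rc)
    lf <- pepensemble:::contact_long_format(cm)
    lf <- lf[lf$range == rc, ]
    ord <- lf[order(-lf$occupancy, lf$i, lf$j), ][1:5, ]
    expect_equal(top$i, ord$i)
    expect_equal(top$j, ord$j)
    expect_equal(top$occupancy, ord$occupancy)
    expect_true(all(diff(top$occupancy) <= 0))
  }
  ## tie-break: equal occupancies ordered by ascending (i, j)
  fake <- cm
  fake$occupancy[] <- 0
  fake$occupancy["12", "20"] <- fake$occupancy["20", "12"] <- 0.4
  fake$occupancy["10", "22"] <- fake$occupancy["22", "10"] <- 0.4
  top2 <- top_contacts(fake, 2, "long")
  expect_equal(top2$i, c(10, 12))
})

test_that("stable contacts use a strict threshold and generator round-trip", {
  ens <- generate_ensemble(basins_coil(), 10, seed = 5)
  cm <- contact_map(ens)
  cm$occupancy[] <- 0
  cm$occupancy["16", "23"] <- cm$occupancy["23", "16"] <- 0.35
  st <- stable_contacts(cm, 0.35)
  expect_equal(nrow(st$long) + nrow(st$short), 0)
  cm$occupancy["16", "23"] <- cm$occupancy["23", "16"] <- 0.351
  st2 <- stable_contacts(cm, 0.35)
  expect_equal(nrow(st2$long), 1)
  expect_equal(st2$long$i, 16)

  bias <- list(pair = c(16, 23), prob = 1)
  ensb <- generate_ensemble(basins_coil(), 15, seed = 6, contact_bias = bias)
  stb <- stable_contacts(contact_map(ensb))
  expect_true(any(stb$long$i == 16 & stb$long$j == 23))
})

test_that("radius of gyration and end-to-end behave geometrically", {
  ## two points 2 A apart -> Rg = 1 (CA pair with coincident centroids)
  r1 <- residue(1L, "GLY", rbind(N = c(-1.2, 0, 0), CA = c(0, 0, 0),
                                 C = c(0.8, 1, 0)))
  r2 <- residue(2L, "GLY", rbind(N = c(0.9, 2.1, 0), CA = c(2, 0, 0),
                                 C = c(2.8, 1, 0)))
  conf <- conformation(list(r1, r2), check = FALSE)
  ## point set: COM==CA for Gly, so {(0,0,0) x2, (2,0,0) x2}
  expect_equal(radius_of_gyration(conf), 1.0)
  expect_equal(end_to_end(conf), 2.0)

  set.seed(303)
  conf2 <- generate_ensemble(basins_coil(), 1, seed = 9)$frames[[1]]
  rg0 <- radius_of_gyration(conf2)
  e0 <- end_to_end(conf2)
  for (rep in 1:3) {
    moved <- transform_conformation(conf2, random_rot(), rnorm(3, 0, 15))
    expect_equal(radius_of_gyration(moved), rg0, tolerance = 1e-9)
    expect_equal(end_to_end(moved), e0, tolerance = 1e-9)
  }
  ## Rg scales linearly under coordinate scaling
  scaled <- transform_conformation(conf2, diag(3) * 2)
  expect_equal(radius_of_gyration(scaled), 2 * rg0, tolerance = 1e-9)
})

test_that("Rg distributions normalize and separate helix from strand", {
  ens <- generate_ensemble(basins_coil(), 25, seed = 31)
  rgd <- rg_distribution(ens)
  expect_equal(sum(rgd$histogram$density) * rgd$bin_width, 1,
               tolerance = 1e-6)

  one <- rg_distribution(pep_ensemble(ens$frames[1]))
  expect_equal(sum(one$histogram$density > 0), 1)

  helix <- rg_distribution(generate_ensemble(basins_helix(), 40, seed = 32))
  strand <- rg_distribution(generate_ensemble(basins_strand(), 40, seed = 33))
  expect_gt(strand$mean_rg, helix$mean_rg)
})
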