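test_that("multi-model PDB writing and reading round-trip", {
  ens <- generate_ensemble(basins_coil(), 3, seed = 42, n_residues = 8)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(ens, path)
  txt <- readLines(path)
  expect_equal(sum(grepl("^MODEL", txt)), 3)
  expect_equal(sum(grepl("^ENDMDL", txt)), 3)

  back <- read_multimodel_pdb(path)
  expect_equal(length(back$frames), 3)
  for (f in 1:3) {
    expect_equal(back$frames[[f]]$seq_index, ens$frames[[f]]$seq_index)
    for (k in seq_along(back$frames[[f]]$residues)) {
      a <- ens$frames[[f]]$residues[[k]]
      b <- back$frames[[f]]$residues[[k]]
      expect_equal(b$name, a$name)
      expect_equal(sort(rownames(b$backbone)), sort(rownames(a$backbone)))
      expect_equal(b$backbone[rownames(a$backbone), ], a$backbone,
                   tolerance = 2e-3)
    }
  }
})

test_that("a file without MODEL records yields exactly one frame", {
  ens <- generate_ensemble(basins_coil(), 1, seed = 7, n_residues = 6)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(ens, path)
  txt <- readLines(path)
  bare <- txt[!grepl("^(MODEL|ENDMDL)", txt)]
  path2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(bare, path2)
  expect_equal(length(read_multimodel_pdb(path2)$frames), 1)
})

test_that("writing an empty ensemble and unreadable files error", {
  expect_error(write_multimodel_pdb(structure(list(frames = list()),
                                              class = "pep_ensemble"),
                                    tempfile()),
               "empty")
  expect_error(read_multimodel_pdb(tempfile("nope")), "no such file")
})

test_that("histidine tautomer aliases normalize to HIS", {
  conf <- build_backbone(rep(-70, 5), rep(140, 5),
                         sequence = c("ALA", "HSD", "HSE", "HIP", "GLY"),
                         start_index = 1L)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_multimodel_pdb(pep_ensemble(list(conf)), path)
  back <- read_multimodel_pdb(path)
  names <- vapply(back$frames[[1]]$residues, function(r) r$name, "")
  expect_equal(names, c("ALA", "HIS", "HIS", "HIS", "GLY"))
})

test_that("side-chain centroid is the unweighted mean with Gly fallback", {
  r1 <- toy_residue(sidechain = matrix(c(1, 0, 0), 1, 3,
                                       dimnames = list("CB", NULL)))
  expect_equal(side_chain_centroid(r1), c(1, 0, 0))

  r2 <- toy_residue(sidechain = matrix(c(0, 0, 0, 2, 0, 0), 2, 3,
                                       byrow = TRUE,
                                       dimnames = list(c("CB", "CG"), NULL)))
  expect_equal(side_chain_centroid(r2), c(1, 0, 0))

  gly <- toy_residue(name = "GLY")
  expect_equal(side_chain_centroid(gly), gly$backbone["CA", ])
  expect_equal(side_chain_com(gly), gly$backbone["CA", ])
})

test_that("side-chain center of mass weights by atomic mass", {
  ## CB (carbon, 12.011) at origin, OG (oxygen, 15.999) at (1,0,0)
  r <- toy_residue(name = "SER",
                   sidechain = matrix(c(0, 0, 0, 1, 0, 0), 2, 3, byrow = TRUE,
                                      dimnames = list(c("CB", "OG"), NULL)))
  com <- side_chain_com(r)
  expect_equal(com[1], 15.999 / (12.011 + 15.999), tolerance = 1e-12)
  ## equal masses reduce to the centroid exactly
  r2 <- toy_residue(sidechain = matrix(rnorm(9), 3, 3,
                                       dimnames = list(c("CB", "CG", "CD"),
                                                       NULL)))
  expect_equal(side_chain_com(r2), side_chain_centroid(r2),
               tolerance = 1e-15)
})

test_that("centroid is equivariant under rigid motion", {
  set.seed(31)
  for (rep in 1:5) {
    sc <- matrix(rnorm(12), 4, 3,
                 dimnames = list(c("CB", "CG", "CD", "CE"), NULL))
    r <- toy_residue(sidechain = sc)
    R <- random_rot(); t <- rnorm(3)
    conf_r <- r
    conf_r$sidechain <- sc %*% t(R) + matrix(t, 4, 3, byrow = TRUE)
    expect_equal(side_chain_centroid(conf_r),
                 as.vector(R %*% side_chain_centroid(r)) + t,
                 tolerance = 1e-9)
  }
})

test_that("experimental tables read, filter and validate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("residue\tvalue", "11\t6.5", "12\t7.1"), path)
  tab <- read_experimental_table(path, "JHNHA")
  expect_equal(length(tab$entries), 2)
  expect_equal(unname(tab$entries["12"]), 7.1)

  writeLines(c("residue\tvalue", "11\t6.5", "11\t7.1"), path)
  expect_error(read_experimental_table(path, "JHNHA"), "duplicate")

  writeLines(c("residue\tvalue", "11\tsix"), path)
  expect_error(read_experimental_table(path, "JHNHA"), "line 2")

  writeLines(c("residue\tvalue", "5\t6.5", "12\t7.1"), path)
  expect_warning(tab <- read_experimental_table(path, "JHNHA",
                                                residue_range = c(10, 40)),
                 "outside")
  expect_equal(names(tab$entries), "12")
})

test_that("round trip preserves randomized ensembles to format precision", {
  for (seed in c(1, 2)) {
    ens <- generate_ensemble(basins_coil(), 2, seed = seed, n_residues = 12)
    path <- withr::local_tempfile(fileext = ".pdb")
    write_multimodel_pdb(ens, path)
    back <- read_multimodel_pdb(path)
    for (f in seq_along(ens$frames)) {
      for (k in seq_along(ens$frames[[f]]$residues)) {
        a <- ens$frames[[f]]$residues[[k]]
        b <- back$frames[[f]]$residues[[k]]
        expect_lt(max(abs(b$backbone[rownames(a$backbone), ] - a$backbone)),
                  1e-3 + 1e-9)
      }
    }
  }
})
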