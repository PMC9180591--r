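test_that("extended peptide has the right residues, caps and geometry", {
  p1 <- build_extended_peptide("RKKRRQRRRGGAGVTDFGVFVEI")
  expect_equal(n_residues(p1), 23)
  g <- build_extended_peptide("G")
  # capped glycine: N, CA, C, O plus H and OXT caps
  expect_setequal(g$atoms$name, c("N", "H", "CA", "C", "O", "OXT"))
  # backbone bond lengths preserved from ideal values
  p <- build_extended_peptide("GAVLKWDE")
  xyz <- as.matrix(p$atoms[, c("x", "y", "z")])
  blen <- sqrt(rowSums((xyz[p$bonds[, 1], ] - xyz[p$bonds[, 2], ])^2))
  nm <- paste(p$atoms$name[p$bonds[, 1]], p$atoms$name[p$bonds[, 2]])
  expect_true(all(abs(blen[nm == "N CA"] - 1.458) < 0.05))
  expect_true(all(abs(blen[nm == "CA C"] - 1.525) < 0.05))
  expect_true(all(abs(blen[nm == "C N"] - 1.329) < 0.05))
  # principal axis along x: x-extent dominates
  ext <- apply(xyz, 2, function(v) diff(range(v)))
  expect_gt(ext[1], 2 * max(ext[2:3]))
  expect_error(build_extended_peptide("GAX"), "position")
})

test_that("layer replication produces the grid and respects clashes", {
  tmpl <- make_minilipid_template()
  expect_length(replicate_layer(tmpl, build_config(n_y = 8, n_z = 8)), 64)
  one <- replicate_layer(tmpl, build_config(n_y = 1, n_z = 1))
  expect_length(one, 1)
  expect_equal(one[[1]]$atoms$x, tmpl$atoms$x)
  sixes <- replicate_layer(tmpl, build_config(n_y = 2, n_z = 3))
  expect_length(sixes, 6)
  # brute-force pairwise min distance over all copy pairs
  dmin <- Inf
  for (i in 1:5) for (j in (i + 1):6) {
    xa <- as.matrix(sixes[[i]]$atoms[, c("x", "y", "z")])
    xb <- as.matrix(sixes[[j]]$atoms[, c("x", "y", "z")])
    d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
    dmin <- min(dmin, sqrt(min(d2)))
  }
  expect_gte(dmin, build_config()$clash_cutoff)
  # too-tight spacing is a build error
  expect_error(replicate_layer(tmpl, build_config(lipid_spacing = 0.5)),
               "clash")
})

test_that("bilayer doubles the leaflet by a proper rotation", {
  cfg <- mini_build_config()
  layer <- replicate_layer(make_minilipid_template(), cfg)
  bil <- make_bilayer(layer, cfg)
  expect_length(bil, 2 * length(layer))
  # 64-lipid layer -> 128 lipids
  cfg8 <- build_config()
  bil8 <- make_bilayer(replicate_layer(make_minilipid_template(), cfg8),
                       cfg8)
  expect_length(bil8, 128)
  # the transform is a proper rotation (det +1), not a reflection
  R <- rotation_matrix("y", 180)
  expect_equal(det(R), 1)
  # applying the 180-degree rotation twice restores coordinates
  m <- layer[[1]]
  m2 <- pepsmd:::transform_molecule(
    pepsmd:::transform_molecule(m, R, center = c(1, 2, 3)),
    R, center = c(1, 2, 3))
  expect_equal(as.matrix(m2$atoms[, c("x", "y", "z")]),
               as.matrix(m$atoms[, c("x", "y", "z")]), tolerance = 1e-12)
  # leaflet congruence: sorted intra-leaflet distance multisets agree
  upper <- do.call(rbind, lapply(bil[1:4], function(m)
    as.matrix(m$atoms[, c("x", "y", "z")])))
  lower <- do.call(rbind, lapply(bil[5:8], function(m)
    as.matrix(m$atoms[, c("x", "y", "z")])))
  expect_equal(sort(as.numeric(dist(upper))),
               sort(as.numeric(dist(lower))), tolerance = 1e-9)
})

test_that("peptide insertion sits above the membrane without clashes", {
  cfg <- mini_build_config()
  sys <- build_system("VTDFGVFVEI", cfg, solvent = FALSE)
  lip <- sys$atoms[sys$atoms$role == "lipid", ]
  pep <- sys$atoms[sys$atoms$role == "peptide", ]
  expect_gt(mean(pep$x), max(lip$x))  # COM above the head plane
  # brute-force min peptide-lipid distance >= clash cutoff
  xa <- as.matrix(pep[, c("x", "y", "z")])
  xb <- as.matrix(lip[, c("x", "y", "z")])
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), `+`) - 2 * xa %*% t(xb)
  expect_gte(sqrt(min(d2)), cfg$clash_cutoff)
  # degenerate config: zero gap and zero cutoff still places
  cfg0 <- mini_build_config(peptide_gap = 0, clash_cutoff = 0)
  expect_s3_class(build_system("GA", cfg0, solvent = FALSE), "mol_system")
})

test_that("lipid counts follow 2 * n_y * n_z for any configuration", {
  for (ny in c(1, 2, 4)) {
    for (nz in c(1, 3)) {
      cfg <- build_config(n_y = ny, n_z = nz)
      sys <- build_system(NULL, cfg, solvent = FALSE)
      expect_equal(count_molecules(sys, "lipid"), 2 * ny * nz)
    }
  }
})

test_that("solvation fills the lattice and respects exclusion", {
  # empty box: pure lattice count floor(L/s)^3
  empty <- mol_system(list(), character(0), box = c(10, 10, 10))
  cfg <- build_config(water_spacing = 3.1)
  solv <- solvate(empty, cfg)
  expect_equal(attr(solv, "n_waters"), 27)  # floor(10/3.1)^3
  # solvated build: every water O at least clash_cutoff from solute
  cfg2 <- mini_build_config()
  sys <- build_system("GA", cfg2, solvent = TRUE)
  ow <- sys$atoms[sys$atoms$role == "water" & sys$atoms$name == "OW", ]
  sol <- sys$atoms[sys$atoms$role != "water", ]
  xa <- as.matrix(ow[, c("x", "y", "z")])
  xb <- as.matrix(sol[, c("x", "y", "z")])
  dmin <- Inf
  for (ax in 1:3) {
    dd <- outer(xa[, ax], xb[, ax], `-`)
    dd <- dd - sys$box[ax] * round(dd / sys$box[ax])
    if (ax == 1) d2 <- dd^2 else d2 <- d2 + dd^2
  }
  expect_gte(sqrt(min(d2)), cfg2$clash_cutoff)
})

test_that("built systems are wrapped and deterministic", {
  cfg <- mini_build_config()
  s1 <- build_system("GAV", cfg, solvent = TRUE)
  s2 <- build_system("GAV", cfg, solvent = TRUE)
  expect_identical(s1, s2)
  xyz <- as.matrix(s1$atoms[, c("x", "y", "z")])
  expect_true(all(xyz >= 0 & xyz < rep(s1$box, each = nrow(xyz))))
})

test_that("PDB round trip preserves counts, names, coordinates and box", {
  cfg <- mini_build_config()
  sys <- build_system("GAV", cfg, solvent = FALSE)
  f <- tempfile(fileext = ".pdb")
  write_pdb(sys, f)
  # identical output on rewrite (deterministic build + write)
  f2 <- tempfile(fileext = ".pdb")
  write_pdb(build_system("GAV", cfg, solvent = FALSE), f2)
  expect_identical(readLines(f), readLines(f2))
  back <- read_pdb(f)
  expect_equal(nrow(back$atoms), nrow(sys$atoms))
  expect_equal(back$atoms$name, sys$atoms$name)
  expect_equal(back$atoms$x, round(sys$atoms$x, 3))
  expect_equal(back$box, round(sys$box, 3))
  expect_equal(count_molecules(back, "lipid"), count_molecules(sys, "lipid"))
})

test_that("hand-written five-atom fixture parses to known coordinates", {
  lines <- c(
    "CRYST1   20.000   21.000   22.000  90.00  90.00  90.00 P 1           1",
    "ATOM      1  N   GLY A   1       1.000   2.000   3.000  1.00  0.00           N",
    "ATOM      2  CA  GLY A   1       2.458   2.000   3.000  1.00  0.00           C",
    "ATOM      3  C   GLY A   1       3.000   3.400   3.000  1.00  0.00           C",
    "ATOM      4  O   GLY A   1       2.300   4.400   3.100  1.00  0.00           O",
    "ATOM      5  OXT GLY A   1       4.250   3.500   3.000  1.00  0.00           O",
    "END")
  f <- tempfile(fileext = ".pdb")
  writeLines(lines, f)
  sys <- read_pdb(f)
  expect_equal(nrow(sys$atoms), 5)
  expect_equal(sys$box, c(20, 21, 22))
  expect_equal(sys$atoms$x[1], 1.0)
  expect_equal(sys$atoms$name[5], "OXT")
  expect_equal(unique(sys$atoms$role), "peptide")
  expect_error(read_pdb(tempfile(fileext = ".pdb")))
})

test_that("synthetic idealized lipid templates have the documented sites", {
  expect_equal(nrow(make_minilipid_template()$atoms), 12)
  popc <- make_popc_template()
  expect_equal(nrow(popc$atoms), 52)  # heavy atoms of C42H82NO8P
  expect_equal(sum(popc$atoms$element == "P"), 1)
  expect_equal(sum(popc$atoms$element == "O"), 8)
  expect_equal(sum(popc$atoms$element == "N"), 1)
  expect_equal(sum(popc$atoms$element == "C"), 42)
  # head toward +x on both templates
  for (t in list(make_minilipid_template(), popc)) {
    headx <- t$atoms$x[t$atoms$element %in% c("N", "P")]
    expect_true(all(headx >= mean(t$atoms$x)))
  }
})
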