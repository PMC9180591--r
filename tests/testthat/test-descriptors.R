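test_that("sequence validation names the offending position", {
  expect_s3_class(pep_seq("ACDEFG"), "pep_seq")
  expect_error(pep_seq("ACXDE"), "position 3")
  expect_error(pep_seq(""), "at least one residue")
  expect_silent(pep_seq("acdef"))  # case-insensitive
})

test_that("molecular weight matches published values and additivity", {
  # printed values: residue-mass sums + one water
  expect_equal(round(molecular_weight("EMEVVVLNID"), 1), 1160.3)
  expect_equal(round(molecular_weight("VTDFGVFVEI"), 1), 1125.3)
  expect_equal(round(molecular_weight("RKKRRQRRRGGAGVTDFGVFVEI"), 1), 2689.1)
  # single glycine: residue mass + water
  expect_equal(round(molecular_weight("G"), 1), 75.1)
  # peptide-bond water loss on concatenation
  s1 <- "GAVK"; s2 <- "WDEF"
  expect_equal(molecular_weight(paste0(s1, s2)),
               molecular_weight(s1) + molecular_weight(s2) - 18.01524,
               tolerance = 1e-10)
})

test_that("net charge follows Henderson-Hasselbalch limits", {
  expect_equal(net_charge("RRRRRRRRRR", 7), 10, tolerance = 0.1)
  expect_equal(net_charge("EEEEEEEEEE", 7), -10, tolerance = 0.2)
  expect_error(net_charge("GA", 0), "pH")
  expect_error(net_charge("GA", 14.5), "pH")
  # strictly decreasing in pH (uniqueness of the pI root)
  for (s in c("EMEVVVLNID", "RKKRRQRRR", "GAVLK")) {
    z <- vapply(seq(0.5, 13.5, by = 0.5), function(p) net_charge(s, p),
                numeric(1))
    expect_true(all(diff(z) < 0), info = s)
  }
})

test_that("isoelectric point reproduces printed values and zeroes charge", {
  expect_equal(round(isoelectric_point("EMEVVVLNID"), 1), 3.4)
  expect_equal(round(isoelectric_point("VTDFGVFVEI"), 1), 3.5)
  expect_equal(round(isoelectric_point("RKKRRQRRRGGAGVTDFGVFVEI")), 12)
  for (s in c("EMEVVVLNID", "DEITVKVLKF", "RKKRRQRRR")) {
    expect_equal(net_charge(s, isoelectric_point(s)), 0, tolerance = 2e-4)
  }
})

test_that("pKa sets are swappable and only Sillero reproduces the
           printed isoelectric points", {
  sill <- scale_tables(pka_set = "sillero")
  bjell <- scale_tables(pka_set = "bjellqvist")
  expect_equal(round(isoelectric_point("EMEVVVLNID", sill), 1), 3.4)
  expect_equal(round(isoelectric_point("EMEVVVLNID", bjell), 1), 3.6)
  custom <- scale_tables(pka_set = c(Nterm = 9, Cterm = 2, D = 4, E = 4.4,
                                     C = 8.5, Y = 10.5, H = 6.5, K = 10.5,
                                     R = 12.5))
  expect_true(is.finite(isoelectric_point("GAVLK", custom)))
  expect_error(scale_tables(pka_set = "nope"), "unknown pKa set")
  expect_error(scale_tables(pka_set = c(Nterm = 9)), "must name groups")
})

test_that("hydrophobicity is the scale mean", {
  sc <- scale_tables()
  zero <- sc
  zero$hydrophobicity_scale[] <- 0
  expect_equal(hydrophobicity("EMEVVVLNID", zero), 0)
  expect_equal(hydrophobicity("LLLLLLLLLL", sc),
               sc$hydrophobicity_scale[["L"]])
  # hand summation oracle
  h <- sc$hydrophobicity_scale
  manual <- mean(h[strsplit("EMEVVVLNID", "")[[1]]])
  expect_equal(hydrophobicity("EMEVVVLNID", sc), manual)
})

test_that("hydrophobic moment matches closed forms and is phase-invariant", {
  sc <- scale_tables()
  zero <- sc; zero$hydrophobicity_scale[] <- 0
  expect_equal(hydrophobic_moment("GAVLK", zero), 0)
  expect_equal(hydrophobic_moment("L", sc),
               abs(sc$hydrophobicity_scale[["L"]]))
  # homo-repeat: h_A * |geometric sum of unit phasors| / N
  hA <- sc$hydrophobicity_scale[["A"]]
  d <- 100 * pi / 180
  gsum <- abs(sum(exp(1i * (1:10) * d)))
  expect_equal(hydrophobic_moment("AAAAAAAAAA", sc), hA * gsum / 10,
               tolerance = 1e-12)
  # modulus is invariant under a constant phase offset of the helix angle
  mu_ref <- hydrophobic_moment("EMEVVVLNID", sc, delta_deg = 100)
  h <- sc$hydrophobicity_scale[strsplit("EMEVVVLNID", "")[[1]]]
  n <- seq_along(h)
  for (offset in c(0.3, 1.1, 2.7)) {
    ang <- n * d + offset
    mu <- sqrt(sum(h * sin(ang))^2 + sum(h * cos(ang))^2) / length(h)
    expect_equal(mu, mu_ref, tolerance = 1e-12)
  }
  expect_error(hydrophobic_moment("GA", delta_deg = 0), "delta")
})

test_that("aliphatic index follows the mole-percent formula", {
  expect_equal(aliphatic_index("RRRRRRRRRR"), 0)
  expect_equal(aliphatic_index("AAAAAAAAAA"), 100)
  expect_equal(aliphatic_index("LLLLLLLLLL"), 390)
  # mixed composition oracle: X in mole percent
  s <- "AAVVILRRRR"
  expect_equal(aliphatic_index(s), 20 + 2.9 * 20 + 3.9 * (10 + 10))
})

test_that("instability index is the scaled dipeptide weight sum", {
  sc <- scale_tables()
  waa <- sc$diwv["A", "A"]
  expect_equal(instability_index("AAAAAAAAAA", sc), waa * 9)
  expect_equal(instability_index("RK", sc), 5 * sc$diwv["R", "K"])
  ones <- sc
  ones$diwv[] <- 1
  expect_equal(instability_index("ACDEFGHIKL", ones), 9)
  expect_error(instability_index("A"), "2 residues")
  # homo-repeat identity: 10 (L-1)/L * DIWV(X,X)
  for (x in c("L", "M", "R")) {
    s <- strrep(x, 7)
    expect_equal(instability_index(s, sc),
                 10 * 6 / 7 * sc$diwv[x, x])
  }
})

test_that("descriptor table covers the roster with finite values", {
  d <- peptide_descriptors(study_peptides())
  expect_equal(nrow(d), 13)
  expect_true(all(is.finite(as.matrix(d[, c("mw", "z", "pI", "Hn",
                                            "muHn", "alpha", "II")]))))
  expect_true(all(d$pI > 0 & d$pI < 14))
  expect_true(all(d$alpha >= 0))
})

test_that("correlation report behaves at the limits", {
  forces <- load_published_forces()
  # descriptor proportional to a force column gives r = 1; negated, -1
  sub <- forces[forces$velocity == 0.1, ]
  desc <- data.frame(id = sub$peptide, up = sub$com * 2,
                     down = -sub$com)
  rep <- correlate_descriptors(desc, forces)
  r_up <- rep$r[rep$descriptor == "up" & rep$mode == "com" &
                  rep$velocity == 0.1]
  r_dn <- rep$r[rep$descriptor == "down" & rep$mode == "com" &
                  rep$velocity == 0.1]
  expect_equal(r_up, 1)
  expect_equal(r_dn, -1)
  # self-correlation of any non-constant column is 1 (best = 1)
  expect_equal(unname(attr(rep, "best")[["up"]]), 1)
  # too few shared peptides
  expect_error(correlate_descriptors(desc[1:2, ], forces),
               "insufficient")
  # zero-variance column reported missing, not an error
  desc$flat <- 5
  rep2 <- correlate_descriptors(desc, forces)
  expect_true(all(is.na(rep2$r[rep2$descriptor == "flat"])))
})

test_that("peptide input parses from FASTA and two-column TSV", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">P2 test peptide", "EMEVV", "VLNID", ">CPP", "RKKRRQRRR"),
             fa)
  seqs <- read_peptides(fa)
  expect_named(seqs, c("P2", "CPP"))
  expect_equal(unclass(seqs$P2), "EMEVVVLNID", ignore_attr = TRUE)
  tsv <- tempfile(fileext = ".tsv")
  writeLines(c("A1\tGAVLK", "A2\tWDEF"), tsv)
  seqs2 <- read_peptides(tsv)
  expect_named(seqs2, c("A1", "A2"))
  expect_equal(nchar(seqs2$A2), 4)
})
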