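test_that("PDB parsing handles minimal input and unit conventions", {
  pdb <- paste(
    "ATOM      1  CA  ALA A   1       1.000   2.000   3.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       4.000   5.000   6.000  1.00  0.00           C",
    "END", sep = "\n")
  s <- readStructure(pdb, "pdb")
  expect_equal(nAtoms(s), 2L)
  expect_false(isPeriodic(s))
  expect_equal(coords(s)[2L, ], c(4, 5, 6))
  expect_equal(atoms(s)$moleculeClass, c("protein", "protein"))

  gro <- paste("t", " 1",
               "    1POPC    P    1   1.000   2.000   3.000",
               "   5.00000   5.00000   9.00000", sep = "\n")
  g <- readStructure(gro, "gro")
  expect_equal(boxDims(g), c(50, 50, 90))
  expect_equal(coords(g)[1L, ], c(10, 20, 30))
  expect_equal(atoms(g)$moleculeClass, "lipid")
})

test_that("malformed structure input is rejected with line diagnostics", {
  bad <- paste(
    "ATOM      1  CA  ALA A   1       1.000   x.000   3.000  1.00  0.00           C",
    "END", sep = "\n")
  expect_error(readStructure(bad, "pdb"), "line 1")
  alt <- paste(
    "ATOM      1  CA AALA A   1       1.000   1.000   3.000  1.00  0.00           C",
    "END", sep = "\n")
  expect_error(readStructure(alt, "pdb"), "alternate")
  expect_error(readStructure("no atoms here", "pdb"), "parse error")
  expect_error(readStructure("t\n x\n", "gro"), "line 2|too short")
})

test_that("structure round trips preserve topology and coordinates", {
  set.seed(42)
  xyz <- matrix(runif(300, -40, 40), ncol = 3L)
  s <- pointResidueSystem(xyz, box = c(90, 90, 90))
  for (fmt in c("pdb", "gro")) {
    s2 <- readStructure(writeStructure(s, format = fmt), fmt)
    expect_equal(nAtoms(s2), nAtoms(s))
    expect_equal(atoms(s2)$name, atoms(s)$name)
    expect_equal(atoms(s2)$resid, atoms(s)$resid)
    # both formats print 3 decimals: PDB in Angstrom, GRO in nm
    tol <- if (fmt == "pdb") 5.1e-4 else 5.1e-3
    expect_lt(max(abs(coords(s2) - coords(s))), tol)
    expect_true(isPeriodic(s2))
    expect_equal(boxDims(s2), boxDims(s), tolerance = 1e-6)
  }
})

test_that("PDB writer agrees with the bio3d reader", {
  skip_if_not_installed("bio3d")
  d <- buildDimer(abeta42Sequence())
  f <- tempfile(fileext = ".pdb")
  writeStructure(d, f, "pdb")
  ref <- bio3d::read.pdb(f)
  expect_equal(nrow(ref$atom), nAtoms(d))
  expect_equal(unname(ref$atom$resno), atoms(d)$resid)
  got <- cbind(ref$atom$x, ref$atom$y, ref$atom$z)
  expect_lt(max(abs(got - coords(d))), 1e-3)
})

test_that("multi-model trajectories read with stride and congruence checks", {
  d <- buildDimer("AG", n_chains = 1L)
  tr0 <- oneFrameTrajectory(d, 0)
  tr3 <- new("MDTrajectory", system = d, times = c(0, 0.5, 1),
             frames = array(rep(coords(d), 3), c(nAtoms(d), 3L, 3L)))
  txt <- writeTrajectory(tr3)
  back <- readTrajectory(txt, dt = 0.5)
  expect_equal(nFrames(back), 3L)
  expect_equal(frameTimes(back), c(0, 0.5, 1))
  one <- readTrajectory(writeTrajectory(tr0))
  expect_equal(nFrames(one), 1L)
  expect_error(readTrajectory(txt, times = c(0, 1, 0.5)),
               "strictly increasing")
  # drop one atom from model 2 -> congruence error
  lines <- strsplit(txt, "\n")[[1L]]
  atom2 <- which(grepl("^ATOM", lines))
  broken <- paste(lines[-atom2[nAtoms(d) + 1L]], collapse = "\n")
  expect_error(readTrajectory(broken), "congruence")
})

test_that("dimer construction matches the 84-residue two-chain layout", {
  d <- buildDimer(abeta42Sequence(), n_chains = 2L)
  a <- atoms(d)
  expect_equal(nResidues(d), 84L)
  expect_equal(sort(unique(a$resid[a$chain == "B"])), 43:84)
  basic <- unique(a$resid[a$resname %in% c("LYS", "ARG")])
  expect_length(basic, 6L)
  expect_equal(nAtoms(d), 4L * 84L)  # backbone N, CA, C, O
  # ideal bond lengths as constructed
  n1 <- coords(d)[1L, ]; ca1 <- coords(d)[2L, ]; c1 <- coords(d)[3L, ]
  expect_equal(sqrt(sum((ca1 - n1)^2)), 1.458, tolerance = 1e-9)
  expect_equal(sqrt(sum((c1 - ca1)^2)), 1.525, tolerance = 1e-9)
})

test_that("invalid sequences are rejected with the offending position", {
  expect_error(buildDimer(""), "non-empty")
  expect_error(buildDimer("ACDBX"), "position 4")
})

test_that("C-terminal truncation gives the 40-residue isoform", {
  d42 <- buildDimer(abeta42Sequence())
  d40 <- truncateCterm(d42, 2L)
  a <- atoms(d40)
  lastA <- max(a$resid[a$chain == "A"])
  expect_equal(lastA, 40L)
  expect_equal(unique(a$resname[a$resid == lastA]), "VAL")
  expect_equal(sort(unique(a$resid[a$chain == "B"])), 41:80)
  expect_identical(truncateCterm(d42, 0L), d42)
  mono <- buildDimer(abeta42Sequence(), n_chains = 1L)
  expect_error(truncateCterm(mono, 42L), "cannot remove")
})

test_that("domain partition splits chains exhaustively and disjointly", {
  d42 <- buildDimer(abeta42Sequence())
  p <- assignDomains(d42, 17L)
  t <- p@table
  nA <- t[t$chain == "A" & t$domain == "N", ]
  cA <- t[t$chain == "A" & t$domain == "C", ]
  expect_equal(nA$to - nA$from + 1L, 17L)
  expect_equal(cA$to - cA$from + 1L, 25L)
  p40 <- assignDomains(truncateCterm(d42, 2L), 17L)
  c40 <- p40@table[p40@table$chain == "A" & p40@table$domain == "C", ]
  expect_equal(c40$to - c40$from + 1L, 23L)
  # partition property: |N| + |C| = chain length, no overlap
  for (ch in c("A", "B")) {
    sub <- t[t$chain == ch, ]
    res <- unlist(Map(seq, sub$from, sub$to))
    expect_equal(length(res), 42L)
    expect_false(anyDuplicated(res) > 0)
  }
  expect_error(assignDomains(d42, 42L), "split_residue")
})
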