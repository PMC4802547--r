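test_that("hydrogen-bond energies follow the electrostatic model", {
  # degenerate square: rON = rCH = rOH = rCN = sqrt(2) -> terms cancel
  sq <- hbondEnergy(n = c(1, 1, 0), h = c(1, -1, 0),
                    c = c(2, 0, 0), o = c(0, 0, 0))
  expect_equal(sq$energy, 0, tolerance = 1e-12)
  expect_false(sq$bonded)

  # rON = 2.9, rCH = 3.9, rOH = 1.9, rCN = 3.9 (coordinates frozen from
  # solving the distance constraints); hand-evaluated formula value:
  # 0.084 * 332 * (1/2.9 + 1/3.9 - 1/1.9 - 1/3.9) = -5.0613429
  hb <- hbondEnergy(n = c(0, 2.9, 0), h = c(1.9, 0, 0),
                    c = c(3.872232, 3.364566, 0), o = c(0, 0, 0))
  expect_equal(hb$energy, -5.0613429, tolerance = 1e-4)
  expect_true(hb$bonded)

  # distant pair: all reciprocal terms nearly cancel, no bond
  far <- hbondEnergy(n = c(10, 0, 0), h = c(11, 0, 0),
                     c = c(0.5, 1, 0), o = c(0, 0, 0))
  expect_lt(abs(far$energy), 0.5)
  expect_false(far$bonded)

  expect_error(hbondEnergy(c(0, 0, 0), c(0.3, 0, 0), c(5, 0, 0),
                           c(5, 1, 0)), "geometry error")
})

test_that("amide hydrogens are placed on the standard geometry", {
  h <- placeAmideHydrogens(makeIdealHelix(8L))
  a <- atoms(h)
  hs <- which(a$name == "H")
  expect_length(hs, 7L)  # chain-initial residue has no amide H
  expect_false(any(a$resid[hs] == 1L))
  for (i in hs) {
    nrow_ <- which(a$name == "N" & a$resid == a$resid[i])
    expect_equal(sqrt(sum((coords(h)[i, ] - coords(h)[nrow_, ])^2)), 1,
                 tolerance = 1e-9)
  }
  # prolines never receive an amide hydrogen
  p <- placeAmideHydrogens(buildDimer("APA", n_chains = 1L))
  ap <- atoms(p)
  expect_false(any(ap$resid[ap$name == "H"] == 2L))
})

test_that("assignment matches the reference implementation on fixtures", {
  # expected codes computed once with the mdtraj DSSP implementation on
  # the written-out fixtures (blank mapped to C)
  expect_equal(unname(assignSS(makeIdealHelix(12L))),
               strsplit("CHHHHHHHHHHC", "")[[1L]])
  expect_equal(unname(assignSS(makeBetaPair(6L))),
               strsplit("CEEEECCEEEEC", "")[[1L]])

  # live cross-check: >= 90% residue-wise identity on both fixtures
  for (sys in list(makeIdealHelix(12L), makeBetaPair(6L))) {
    ref <- mdtrajDssp(sys)
    expect_false(is.null(ref))
    mine <- unname(assignSS(sys))
    expect_gte(mean(mine == ref), 0.9)
  }
})

test_that("assignment is invariant under rigid rotation and translation", {
  h <- makeIdealHelix(10L)
  before <- assignSS(h)
  th <- 0.83; ph <- 2.1
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  Rx <- matrix(c(1, 0, 0, 0, cos(ph), sin(ph), 0, -sin(ph), cos(ph)), 3)
  h@coords <- sweep(coords(h) %*% (Rz %*% Rx), 2L, c(5, -3, 12), "+")
  expect_equal(assignSS(h), before)
})

test_that("an isolated extended chain carries no hydrogen-bonded classes", {
  ext <- buildDimer("GAVLIGAVLI", n_chains = 1L)
  expect_false(any(assignSS(ext) %in% c("H", "G", "I", "E", "B")))
})

test_that("structure matrices stack frames with chain separators", {
  bp <- makeBetaPair(6L)
  tr <- new("MDTrajectory", system = bp, times = c(0, 1, 2),
            frames = array(rep(coords(bp), 3), c(nAtoms(bp), 3L, 3L)))
  sm <- ssMatrix(tr)
  expect_equal(dim(ssCodes(sm)), c(13L, 3L))       # 12 residues + separator
  sep <- which(is.na(sm@residues))
  expect_equal(sep, 7L)
  expect_true(all(ssCodes(sm)[sep, ] == "X"))
  expect_true(all(ssCodes(sm) %in% c("H", "G", "I", "E", "B", "T", "S",
                                     "C", "X")))
  expect_equal(ssCodes(sm)[, 1L], ssCodes(sm)[, 2L])
  expect_equal(ssCodes(sm)[, 1L], ssCodes(sm)[, 3L])
  one <- ssMatrix(oneFrameTrajectory(bp))
  expect_equal(ncol(ssCodes(one)), 1L)
})

test_that("reduced class counts satisfy the BEGHIT identity", {
  sm <- randomSSMatrix(84L, 1000L, seed = 123L)
  part <- assignDomains(buildDimer(abeta42Sequence()), 17L)
  rc <- reduceCounts(sm, part)
  expect_equal(rc$BEGHIT, rc$BE + rc$GHI + rc$T)
  # independent recount straight from the code matrix
  lab <- memsurf:::domainLabels(part, sm@residues[!is.na(sm@residues)])
  codes <- ssCodes(sm)[!is.na(sm@residues), ]
  for (d in c("N", "C")) {
    sub <- codes[substr(lab, 1, 1) == d, , drop = FALSE]
    expect_equal(rc$BE[rc$domain == d],
                 unname(colSums(sub == "B" | sub == "E")))
    expect_equal(rc$GHI[rc$domain == d],
                 unname(colSums(sub == "G" | sub == "H" | sub == "I")))
    expect_equal(rc$T[rc$domain == d], unname(colSums(sub == "T")))
    expect_true(all(rc$BEGHIT[rc$domain == d] <=
                      if (d == "N") 34L else 50L))
  }
})

test_that("all-H and all-C columns reduce to the expected counts", {
  part <- assignDomains(buildDimer(abeta42Sequence()), 17L)
  allH <- randomSSMatrix(84L, 1L, seed = 1L)
  allH@codes[!is.na(allH@residues), 1L] <- "H"
  rc <- reduceCounts(allH, part)
  expect_equal(rc$GHI[rc$domain == "N"], 34L)  # 17 per chain, both chains
  expect_equal(rc$GHI[rc$domain == "C"], 50L)
  expect_equal(rc$BE, c(0L, 0L))
  expect_equal(rc$T, c(0L, 0L))
  allC <- allH; allC@codes[!is.na(allC@residues), 1L] <- "C"
  rc0 <- reduceCounts(allC, part)
  expect_true(all(rc0[, c("BE", "GHI", "T", "BEGHIT")] == 0L))
  # residues outside the partition are rejected
  off <- allH; off@residues[1L] <- 200L
  expect_error(reduceCounts(off, part), "outside")
})
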