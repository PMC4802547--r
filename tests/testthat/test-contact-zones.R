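test_that("contact maps hold minimum inter-residue distances in nm", {
  s <- pointResidueSystem(rbind(c(0, 0, 0), c(5, 0, 0)))
  cm <- contactMap(s)
  expect_equal(contactMatrix(cm)[1L, 2L], 0.5)
  expect_equal(contactMatrix(cm)[2L, 1L], 0.5)
  expect_equal(diag(contactMatrix(cm)), c(0, 0))
})

test_that("contact maps equal the all-image brute force on random frames", {
  for (trial in 1:20) {
    set.seed(100 + trial)
    box <- c(25, 25, 25)
    n <- 10L
    xyz <- matrix(runif(n * 2L * 3L, 0, 30), ncol = 3L)
    s <- pointResidueSystem(xyz, box = box,
                            resid = rep(seq_len(n), each = 2L))
    m <- contactMatrix(contactMap(s))
    expect_true(isSymmetric(m))
    expect_true(all(diag(m) == 0))
    for (pair in list(c(1L, 2L), c(3L, 9L), c(5L, 10L))) {
      i <- pair[1L]; j <- pair[2L]
      brute <- bruteMinDistance(xyz[(2 * i - 1):(2 * i), , drop = FALSE],
                                xyz[(2 * j - 1):(2 * j), , drop = FALSE],
                                box) / 10
      expect_equal(m[i, j], brute, tolerance = 1e-12)
    }
  }
})

test_that("hydrogens are excluded from heavy-atom contact minima", {
  h <- placeAmideHydrogens(makeIdealHelix(6L))
  heavy <- contactMatrix(contactMap(h, heavy_only = TRUE))
  all_ <- contactMatrix(contactMap(h, heavy_only = FALSE))
  expect_true(all(all_ <= heavy + 1e-12))
  expect_true(any(all_ < heavy - 1e-9))
})

test_that("two-stage averaging matches an independent flat recomputation", {
  s <- pointResidueSystem(rbind(c(0, 0, 0), c(5, 0, 0)))
  one <- list(times = 0, maps = list(contactMap(s)))
  avg1 <- averageMaps(list(rep1 = one), window_ns = 0)
  expect_equal(contactMatrix(avg1), contactMatrix(one$maps[[1L]]))

  M <- contactMap(s)
  M3 <- M; M3@map <- 3 * M@map
  two <- list(rep1 = list(times = 0, maps = list(M)),
              rep2 = list(times = 0, maps = list(M3)))
  expect_equal(contactMatrix(averageMaps(two, 0)), 2 * M@map)

  # 3 replicates x 5 frames of random symmetric maps
  set.seed(11)
  mkmap <- function() {
    m <- matrix(runif(16, 0, 3), 4L)
    m <- (m + t(m)) / 2; diag(m) <- 0
    new("ContactMap", residues = 1:4, map = m, frameCount = 1L)
  }
  reps <- lapply(1:3, function(r)
    list(times = 0:4, maps = replicate(5, mkmap(), simplify = FALSE)))
  names(reps) <- paste0("rep", 1:3)
  got <- contactMatrix(averageMaps(reps, window_ns = 4))
  flat <- Reduce(`+`, lapply(reps, function(r)
    Reduce(`+`, lapply(r$maps, contactMatrix)) / 5)) / 3
  expect_equal(got, flat, tolerance = 1e-12)
  expect_true(isSymmetric(got))
  expect_true(all(diag(got) == 0))
  short <- list(times = c(0, 1), maps = reps[[1L]]$maps[1:2])
  expect_error(averageMaps(list(bad = short), window_ns = 50), "bad")
})

test_that("the zone directory enumerates the 10 domain pairings", {
  part <- assignDomains(buildDimer(abeta42Sequence()), 17L)
  zd <- zoneDirectory(part)
  z <- zoneTable(zd)
  expect_equal(nrow(z), 10L)
  expect_equal(z$zone, 1:10)
  # zones 1-3 within chain A, 4-6 within chain B, 7-10 inter-chain
  chainOf <- function(d) sub("^[NC]_", "", d)
  expect_true(all(chainOf(z$domainA[1:3]) == "A" &
                    chainOf(z$domainB[1:3]) == "A"))
  expect_true(all(chainOf(z$domainA[4:6]) == "B" &
                    chainOf(z$domainB[4:6]) == "B"))
  expect_true(all(chainOf(z$domainA[7:10]) != chainOf(z$domainB[7:10])))
  expect_equal(zoneOf(zd, 1L, 1L), 1L)
  expect_equal(zoneOf(zd, 5L, 60L), 8L)   # N_A with C_B
  mono <- assignDomains(buildDimer(abeta42Sequence(), n_chains = 1L), 17L)
  expect_error(zoneDirectory(mono), "2 chains")
})

test_that("every residue pair maps to exactly one zone", {
  zd <- zoneDirectory(assignDomains(buildDimer(abeta42Sequence()), 17L))
  pairs <- which(upper.tri(matrix(0, 84, 84), diag = TRUE), arr.ind = TRUE)
  ids <- zoneOf(zd, pairs[, 1L], pairs[, 2L])
  expect_false(anyNA(ids))
  expect_equal(length(ids), 84L * 85L / 2L)
  expect_setequal(unique(ids), 1:10)
})

test_that("zone statistics aggregate replicates with correct SEMs", {
  part <- assignDomains(buildDimer("DAEFRHDSGY"), 4L)
  zd <- zoneDirectory(part)
  s <- buildDimer("DAEFRHDSGY")
  base <- contactMap(s)
  mkrep <- function(f) list(times = 0, maps = list({
    m <- base; m@map <- base@map * f; m
  }))
  four <- lapply(rep(1, 4), mkrep)
  zs4 <- zoneStats(four, zd, window_ns = 0)
  expect_equal(nrow(zs4), 10L)
  expect_equal(zs4$sem, rep(0, 10L))

  two <- list(mkrep(1), mkrep(2))  # replicate zone means are {m, 2m}
  zs2 <- zoneStats(two, zd, window_ns = 0)
  base1 <- zoneStats(list(mkrep(1)), zd, window_ns = 0)
  expect_equal(zs2$mean, 1.5 * base1$mean, tolerance = 1e-12)
  # {x, 2x}: sd = x / sqrt(2), SEM = sd / sqrt(2) = x / 2
  expect_equal(zs2$sem, base1$mean / 2, tolerance = 1e-12)
  expect_true(all(is.na(base1$sem)))   # single replicate: SEM not available
  expect_equal(base1$n_replicates, rep(1L, 10L))
})
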