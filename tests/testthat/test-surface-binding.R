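test_that("minimum-image distances match direct and wrapped cases", {
  s <- pointResidueSystem(rbind(c(0, 0, 0), c(0, 0, 3)),
                          box = c(1000, 1000, 1000))
  tr <- oneFrameTrajectory(s)
  expect_equal(minDistanceSeries(tr, 1L, 2L)$distance, 3)
  w <- pointResidueSystem(rbind(c(1, 0, 0), c(49, 0, 0)),
                          box = c(50, 50, 50))
  expect_equal(minDistanceSeries(oneFrameTrajectory(w), 1L, 2L)$distance, 2)
  expect_error(minDistanceSeries(tr, integer(0), 2L), "selection")
})

test_that("minimum distance equals the 27-image brute force on random systems", {
  for (trial in 1:30) {
    set.seed(trial)
    box <- c(40, 40, 40)
    a <- matrix(runif(50 * 3, 0, 40), ncol = 3L)
    b <- matrix(runif(80 * 3, 0, 40), ncol = 3L)
    got <- memsurf:::minPairDistance(a, b, box, periodic = TRUE)
    expect_equal(got, bruteMinDistance(a, b, box), tolerance = 1e-12)
  }
})

test_that("minimum distance is symmetric and rigid-translation invariant", {
  set.seed(7)
  box <- c(30, 30, 30)
  a <- matrix(runif(30, 0, 30), ncol = 3L)
  b <- matrix(runif(45, 0, 30), ncol = 3L)
  d0 <- memsurf:::minPairDistance(a, b, box, TRUE)
  expect_equal(memsurf:::minPairDistance(b, a, box, TRUE), d0)
  shift <- c(11.3, -40.2, 7.7)
  expect_equal(memsurf:::minPairDistance(sweep(a, 2, shift, "+"),
                                         sweep(b, 2, shift, "+"), box, TRUE),
               d0, tolerance = 1e-9)
})

test_that("attachment detection recovers a noiseless kink exactly", {
  t <- seq(0, 20, 0.5)
  y <- pmax(2, 20 - 2 * t)  # kink at t = 9
  r <- detectAttachment(data.frame(time = t, distance = y))
  expect_equal(r$t_attach, 9, tolerance = 1e-9)
  expect_equal(r$decline_slope, -2, tolerance = 1e-9)
  expect_equal(r$plateau_level, 2, tolerance = 1e-9)
  expect_lt(r$sse, 1e-18)
})

test_that("attachment detection is equivariant under time shifts", {
  set.seed(5)
  t <- seq(0, 30, 0.25)
  y <- pmax(3, 25 - 1.7 * t) + rnorm(length(t), 0, 0.4)
  r0 <- detectAttachment(data.frame(time = t, distance = y))
  r1 <- detectAttachment(data.frame(time = t + 12.5, distance = y))
  expect_equal(r1$t_attach - r0$t_attach, 12.5, tolerance = 1e-9)
  expect_equal(r1$decline_slope, r0$decline_slope, tolerance = 1e-9)
})

test_that("degenerate traces raise no-attachment errors", {
  t <- seq(0, 10, 0.5)
  expect_error(detectAttachment(data.frame(time = t, distance = t + 1)),
               "no attachment")
  expect_error(detectAttachment(data.frame(time = t,
                                           distance = rep(4, length(t)))),
               "no attachment")
  expect_error(detectAttachment(data.frame(time = 1:5, distance = 5:1)),
               "at least 8")
})

test_that("orientation angles follow the z-axis convention", {
  base <- rbind(c(0, 0, 0), c(0, 0, 7))    # +z
  down <- rbind(c(0, 0, 0), c(0, 0, -7))   # -z
  side <- rbind(c(0, 0, 0), c(7, 0, 0))    # +x
  for (case in list(list(base, 0), list(down, 180), list(side, 90))) {
    tr <- oneFrameTrajectory(pointResidueSystem(case[[1L]]))
    expect_equal(orientationSeries(tr, 1L, 2L)$angle, case[[2L]],
                 tolerance = 1e-9)
  }
  same <- oneFrameTrajectory(pointResidueSystem(rbind(c(1, 1, 1),
                                                      c(1, 1, 1))))
  expect_error(orientationSeries(same, 1L, 2L), "degenerate")
})
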