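# Contour extraction, resampling and the snake energy.

test_that("contours extracted from a circular field recover the radius", {
  g <- expand.grid(r = 1:61, c = 1:61)
  phi <- matrix(sqrt((g$r - 31)^2 + (g$c - 31)^2) - 15, 61, 61)
  cts <- extract_contour(phi)
  expect_length(cts, 1)
  expect_true(cts[[1]]$closed)
  radii <- sqrt(rowSums((cts[[1]]$points - 30)^2))  # 0-based centre at 30
  expect_lt(max(abs(radii - 15)), 0.5)
})

test_that("contour extraction handles empty and multi-component fields", {
  expect_length(extract_contour(matrix(1, 10, 10)), 0)
  two <- matrix(FALSE, 40, 40)
  g <- expand.grid(r = 1:40, c = 1:40)
  two[(g$r - 12)^2 + (g$c - 12)^2 <= 36] <- TRUE
  two[(g$r - 30)^2 + (g$c - 30)^2 <= 36] <- TRUE
  cts <- extract_contour(signed_distance(two))
  expect_length(cts, 2)
  expect_true(all(vapply(cts, `[[`, TRUE, "closed")))
})

test_that("equal arc-length resampling preserves length and recovers corners", {
  sq <- contour_path(rbind(c(0, 0), c(0, 10), c(10, 10), c(10, 0)))
  r4 <- sample_contour(sq, 4)
  expect_equal(r4$points, sq$points)
  # length is preserved within 1%
  theta <- seq(0, 2 * pi, length.out = 200)[-200]
  circ <- contour_path(cbind(20 + 7 * cos(theta), 20 + 7 * sin(theta)))
  r <- sample_contour(circ, 50)
  expect_lt(abs(arc_length(r) - arc_length(circ)) / arc_length(circ), 0.01)
  # resampling an already-uniform contour at the same n is the identity
  r2 <- sample_contour(circ, nrow(circ$points))
  expect_lt(max(abs(r2$points - circ$points)), 1e-9)
  expect_error(sample_contour(circ, 2), ">= 3")
})

test_that("snake tension term follows the closed-form circle value", {
  img <- matrix(0, 64, 64)
  p <- snake_params(alpha = 2, beta_curv = 0, mu = 0)
  for (r in c(5, 10, 15)) {
    n <- 64
    theta <- 2 * pi * (0:(n - 1)) / n
    circ <- contour_path(cbind(30 + r * cos(theta), 30 + r * sin(theta)))
    en <- snake_energy(circ, img, p)
    # discretized closed form: |C'| = n r sin(2pi/n) at every sample, so the
    # tension integral is alpha * n^2 * r^2 * sin^2(2pi/n) -> alpha (2 pi r)^2
    expect_lt(abs(en$tension - 2 * n^2 * r^2 * sin(2 * pi / n)^2) /
                en$tension, 1e-9)
    expect_equal(en$rigidity, 0)
    expect_equal(en$edge, 0)
  }
})

test_that("a straight open segment has zero rigidity", {
  seg <- contour_path(cbind(seq(5, 25, length.out = 21), rep(10, 21)),
                      closed = FALSE)
  en <- snake_energy(seg, matrix(0, 32, 32),
                     snake_params(alpha = 1, beta_curv = 3, mu = 0))
  expect_lt(en$rigidity, 1e-9)
})

test_that("the edge term rewards contours lying on strong gradients", {
  img <- matrix(0, 40, 40)
  img[, 20:40] <- 100                      # vertical step edge at column ~19.5
  p <- snake_params(alpha = 0, beta_curv = 0, mu = 1)
  on_edge <- contour_path(cbind(seq(5, 35, length.out = 30), rep(19, 30)),
                          closed = FALSE)
  off_edge <- contour_path(cbind(seq(5, 35, length.out = 30), rep(5, 30)),
                           closed = FALSE)
  expect_lt(snake_energy(on_edge, img, p)$total,
            snake_energy(off_edge, img, p)$total)
})

test_that("snake evolution drags a circle towards an edge", {
  img <- matrix(0, 64, 64)
  g <- expand.grid(r = 1:64, c = 1:64)
  img[(g$r - 32)^2 + (g$c - 32)^2 <= 12^2] <- 100
  theta <- 2 * pi * (0:47) / 48
  init <- contour_path(cbind(31 + 20 * cos(theta), 31 + 20 * sin(theta)))
  out <- snake_evolve(init, img, snake_params(alpha = 0.05, beta_curv = 0.01,
                                              mu = 5), dt = 0.05,
                      iterations = 200)
  radii <- sqrt(rowSums((out$points - 31)^2))
  expect_lt(mean(abs(radii - 12)), mean(abs(sqrt(rowSums(
    (init$points - 31)^2)) - 12)))
})

test_that("degenerate contours are rejected", {
  expect_error(contour_path(rbind(c(0, 0), c(1, 1)), closed = TRUE), ">= 3")
  expect_error(snake_energy(contour_path(cbind(1:5, 1:5), closed = FALSE)[
    c("points", "closed")], matrix(0, 4, 4)), "contour_path")
})
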