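# Parametric contours: extraction from level sets, equal arc-length
# resampling, and the classical snake energy (tension + rigidity + edge
# attraction) used as an auxiliary diagnostic next to the level-set model.
# Contour points are (row, col) coordinates in the package's 0-based grid
# convention.

#' Contour object
#'
#' @param points numeric n x 2 matrix of (row, col) coordinates.
#' @param closed logical; closed contours need at least 3 points.
#' @export
contour_path <- function(points, closed = TRUE) {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, all(is.finite(points)))
  # drop duplicated consecutive points (and a duplicated closing point)
  if (nrow(points) > 1) {
    keep <- c(TRUE, rowSums(abs(diff(points))) > 1e-12)
    points <- points[keep, , drop = FALSE]
  }
  if (closed && nrow(points) > 1 &&
      sum(abs(points[1, ] - points[nrow(points), ])) < 1e-12) {
    points <- points[-nrow(points), , drop = FALSE]
  }
  if (closed && nrow(points) < 3) stop("a closed contour needs >= 3 points")
  structure(list(points = points, closed = closed), class = "contour_path")
}

#' @export
print.contour_path <- function(x, ...) {
  cat(sprintf("<contour_path> %d points, %s\n", nrow(x$points),
              if (x$closed) "closed" else "open"))
  invisible(x)
}

contour_segments <- function(ct) {
  p <- ct$points
  if (ct$closed) p <- rbind(p, p[1, ])
  p
}

#' Total arc length of a contour
#' @param ct a [contour_path()].
#' @export
arc_length <- function(ct) {
  p <- contour_segments(ct)
  sum(sqrt(rowSums(diff(p)^2)))
}

#' Extract zero-level contours of a level-set field
#'
#' Sub-pixel zero crossings by linear interpolation (marching-squares
#' convention), one polyline per connected piece of the zero set. Returns an
#' empty list when the field does not change sign.
#'
#' @param phi a [level_set_field()] or numeric matrix.
#' @param level contour level (default 0).
#' @return list of [contour_path()] objects in 0-based (row, col)
#'   coordinates.
#' @export
extract_contour <- function(phi, level = 0) {
  phi <- as_phi_matrix(phi)
  if (all(phi > level) || all(phi < level)) return(list())
  cl <- grDevices::contourLines(x = seq_len(nrow(phi)) - 1,
                                y = seq_len(ncol(phi)) - 1,
                                z = phi, levels = level)
  lapply(cl, function(p) {
    pts <- cbind(p$x, p$y)
    closed <- sum(abs(pts[1, ] - pts[nrow(pts), ])) < 1e-9
    contour_path(pts, closed = closed)
  })
}

#' Resample a contour at equal arc-length spacing
#'
#' Linear interpolation along the polyline; the first point is kept as the
#' phase anchor. Total arc length is preserved to within the polygonal
#' approximation (< 1% for smooth contours at moderate n).
#'
#' @param ct a [contour_path()].
#' @param n number of output points (>= 3).
#' @export
sample_contour <- function(ct, n) {
  stopifnot(inherits(ct, "contour_path"))
  if (n < 3) stop("n must be >= 3")
  p <- contour_segments(ct)
  seg <- sqrt(rowSums(diff(p)^2))
  s <- c(0, cumsum(seg))
  L <- s[length(s)]
  target <- if (ct$closed) L * (0:(n - 1)) / n else L * (0:(n - 1)) / (n - 1)
  out <- cbind(stats::approx(s, p[, 1], xout = target, ties = "ordered")$y,
               stats::approx(s, p[, 2], xout = target, ties = "ordered")$y)
  contour_path(out, closed = ct$closed)
}

#' Snake (parametric active contour) parameters
#'
#' @param alpha tension weight (first-derivative term, >= 0).
#' @param beta_curv rigidity weight (second-derivative term, >= 0).
#' @param mu edge-attraction weight (image-gradient term).
#' @export
snake_params <- function(alpha = 0.1, beta_curv = 0.1, mu = 1) {
  stopifnot(is.finite(alpha), is.finite(beta_curv), is.finite(mu),
            alpha >= 0, beta_curv >= 0)
  structure(list(alpha = alpha, beta_curv = beta_curv, mu = mu),
            class = "snake_params")
}

# bilinear interpolation of matrix `m` at 0-based (row, col) positions
interp_bilinear <- function(m, pts) {
  H <- nrow(m); W <- ncol(m)
  r <- pmin(pmax(pts[, 1], 0), H - 1)
  c <- pmin(pmax(pts[, 2], 0), W - 1)
  r0 <- pmin(floor(r), H - 2); c0 <- pmin(floor(c), W - 2)
  fr <- r - r0; fc <- c - c0
  i00 <- cbind(r0 + 1, c0 + 1); i10 <- cbind(r0 + 2, c0 + 1)
  i01 <- cbind(r0 + 1, c0 + 2); i11 <- cbind(r0 + 2, c0 + 2)
  m[i00] * (1 - fr) * (1 - fc) + m[i10] * fr * (1 - fc) +
    m[i01] * (1 - fr) * fc + m[i11] * fr * fc
}

# squared gradient magnitude |grad f|^2 by central differences
grad_sq_image <- function(image) {
  H <- nrow(image); W <- ncol(image)
  gr <- (image[c(2:H, H), ] - image[c(1, 1:(H - 1)), ]) / 2
  gc <- (image[, c(2:W, W)] - image[, c(1, 1:(W - 1))]) / 2
  gr^2 + gc^2
}

#' Snake energy of a contour on an image
#'
#' Finite-difference evaluation of
#' `alpha * int |C'|^2 + beta_curv * int |C''| - mu * int |grad f(C)|^2`
#' over the sampled contour points (parameter s in `[0, 1]`). The rigidity
#' term uses `|C''|` unsquared as stated by the model this package
#' implements; `squared_rigidity = TRUE` switches to the classical `|C''|^2`.
#'
#' @param ct a [contour_path()] with >= 3 points.
#' @param image numeric matrix.
#' @param params a [snake_params()].
#' @param squared_rigidity use `|C''|^2` in the middle term.
#' @return list with `total` and terms `tension`, `rigidity`, `edge`.
#' @export
snake_energy <- function(ct, image, params = snake_params(),
                         squared_rigidity = FALSE) {
  stopifnot(inherits(ct, "contour_path"))
  p <- ct$points
  n <- nrow(p)
  if (n < 3) stop("snake energy needs >= 3 contour points")
  ds <- 1 / if (ct$closed) n else (n - 1)
  nxt <- if (ct$closed) c(2:n, 1) else c(2:n, n)
  prv <- if (ct$closed) c(n, 1:(n - 1)) else c(1, 1:(n - 1))
  d1 <- (p[nxt, , drop = FALSE] - p[prv, , drop = FALSE]) / (2 * ds)
  d2 <- (p[nxt, , drop = FALSE] - 2 * p + p[prv, , drop = FALSE]) / ds^2
  if (!ct$closed) {
    # open contour: one-sided first derivative and natural (zero-curvature)
    # boundary conditions at the endpoints
    d1[1, ] <- (p[2, ] - p[1, ]) / ds
    d1[n, ] <- (p[n, ] - p[n - 1, ]) / ds
    d2[c(1, n), ] <- 0
  }
  t1 <- params$alpha * sum(rowSums(d1^2)) * ds
  c2 <- sqrt(rowSums(d2^2))
  t2 <- params$beta_curv * sum(if (squared_rigidity) c2^2 else c2) * ds
  g2 <- interp_bilinear(grad_sq_image(image), p)
  t3 <- -params$mu * sum(g2) * ds
  list(total = t1 + t2 + t3, tension = t1, rigidity = t2, edge = t3)
}

#' Simple gradient-descent snake evolution (diagnostic)
#'
#' Explicit iteration of the classical snake forces (tension `alpha C''`,
#' squared-variant rigidity `-beta C''''`, edge attraction
#' `mu grad |grad f|^2`). Provided as an auxiliary initial-prediction tool;
#' the level-set path is the production segmenter.
#'
#' @param ct starting [contour_path()] (closed).
#' @param image numeric matrix.
#' @param params a [snake_params()].
#' @param dt step size.
#' @param iterations iteration count.
#' @export
snake_evolve <- function(ct, image, params = snake_params(), dt = 0.1,
                         iterations = 100) {
  stopifnot(inherits(ct, "contour_path"), ct$closed)
  p <- ct$points
  n <- nrow(p)
  gsq <- grad_sq_image(image)
  H <- nrow(image); W <- ncol(image)
  gr <- (gsq[c(2:H, H), ] - gsq[c(1, 1:(H - 1)), ]) / 2
  gc <- (gsq[, c(2:W, W)] - gsq[, c(1, 1:(W - 1))]) / 2
  for (t in seq_len(iterations)) {
    nxt <- c(2:n, 1); prv <- c(n, 1:(n - 1))
    d2 <- p[nxt, ] - 2 * p + p[prv, ]
    d4 <- d2[nxt, ] - 2 * d2 + d2[prv, ]
    fedge <- cbind(interp_bilinear(gr, p), interp_bilinear(gc, p))
    p <- p + dt * (params$alpha * d2 - params$beta_curv * d4 +
                     params$mu * fedge)
    p[, 1] <- pmin(pmax(p[, 1], 0), H - 1)
    p[, 2] <- pmin(pmax(p[, 2], 0), W - 1)
  }
  contour_path(p, closed = TRUE)
}
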