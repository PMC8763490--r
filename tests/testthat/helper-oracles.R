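# Independent oracles used across the suite. These re-derive quantities by
# the most direct route available (explicit loops, closed forms, brute
# force) and deliberately share no code with the package internals.

# brute-force Euclidean distance: pointwise minimum over all pixels of the
# target set
brute_distance <- function(target, spacing = c(1, 1)) {
  idx <- which(target, arr.ind = TRUE)
  out <- matrix(Inf, nrow(target), ncol(target))
  for (i in seq_len(nrow(target))) {
    for (j in seq_len(ncol(target))) {
      d2 <- ((idx[, 1] - i) * spacing[1])^2 + ((idx[, 2] - j) * spacing[2])^2
      out[i, j] <- sqrt(min(d2))
    }
  }
  out
}

# direct loop evaluation of the smoothed-indicator region means and the
# four-term energy (the energy approximation with its area and length
# penalties), sign convention phi < 0 inside
brute_region_energy <- function(image, phi, eps, gamma, beta_len) {
  H <- nrow(image); W <- ncol(image)
  hin <- matrix(0, H, W)
  del <- matrix(0, H, W)
  for (i in 1:H) {
    for (j in 1:W) {
      hin[i, j] <- 0.5 * (1 + (2 / pi) * atan(-phi[i, j] / eps))
      del[i, j] <- (1 / pi) * eps / (eps^2 + phi[i, j]^2)
    }
  }
  i1 <- sum(image * hin) / sum(hin)
  i2 <- sum(image * (1 - hin)) / sum(1 - hin)
  din <- dout <- area <- len <- 0
  cl <- function(v, lo, hi) min(max(v, lo), hi)
  for (i in 1:H) {
    for (j in 1:W) {
      din <- din + (image[i, j] - i1)^2 * hin[i, j]
      dout <- dout + (image[i, j] - i2)^2 * (1 - hin[i, j])
      area <- area + hin[i, j]
      gr <- (phi[cl(i + 1, 1, H), j] - phi[cl(i - 1, 1, H), j]) / 2
      gc <- (phi[i, cl(j + 1, 1, W)] - phi[i, cl(j - 1, 1, W)]) / 2
      len <- len + del[i, j] * sqrt(gr^2 + gc^2)
    }
  }
  list(i1 = i1, i2 = i2, data_in = din, data_out = dout,
       area = gamma * area, length = beta_len * len,
       total = din + dout + gamma * area + beta_len * len)
}

# direct implementation of the classical two-phase piecewise-constant
# level-set iteration (global region means over the sharp partition,
# Dirac-gated force with area and curvature terms, normalized step with
# energy backtracking) used for the field-level equality check
classical_two_phase <- function(f, phi0, params, iters) {
  eps <- params$epsilon
  shift <- function(m, dr, dc) {
    H <- nrow(m); W <- ncol(m)
    m[pmin(pmax(seq_len(H) + dr, 1), H),
      pmin(pmax(seq_len(W) + dc, 1), W)]
  }
  heavi <- function(t) 0.5 * (1 + (2 / pi) * atan(t / eps))
  dirac <- function(t) (1 / pi) * eps / (eps^2 + t^2)
  energy_at <- function(phi) {
    hin <- heavi(-phi)
    ins <- phi < 0
    i1 <- if (any(ins)) mean(f[ins]) else mean(f)
    i2 <- if (any(!ins)) mean(f[!ins]) else mean(f)
    gr <- (shift(phi, 1, 0) - shift(phi, -1, 0)) / 2
    gc <- (shift(phi, 0, 1) - shift(phi, 0, -1)) / 2
    sum((f - i1)^2 * hin) + sum((f - i2)^2 * (1 - hin)) +
      params$gamma * sum(hin) +
      params$beta_len * sum(dirac(phi) * sqrt(gr^2 + gc^2))
  }
  force_at <- function(phi) {
    ins <- phi < 0
    i1 <- if (any(ins)) mean(f[ins]) else mean(f)
    i2 <- if (any(!ins)) mean(f[!ins]) else mean(f)
    gr <- (shift(phi, 1, 0) - shift(phi, -1, 0)) / 2
    gc <- (shift(phi, 0, 1) - shift(phi, 0, -1)) / 2
    prr <- shift(phi, 1, 0) - 2 * phi + shift(phi, -1, 0)
    pcc <- shift(phi, 0, 1) - 2 * phi + shift(phi, 0, -1)
    prc <- (shift(phi, 1, 1) - shift(phi, 1, -1) -
              shift(phi, -1, 1) + shift(phi, -1, -1)) / 4
    g2 <- gr^2 + gc^2
    kap <- (prr * gc^2 - 2 * gr * gc * prc + pcc * gr^2) /
      (g2^1.5 + params$grad_floor)
    kap <- pmin(pmax(kap, -1), 1)
    (f - i1)^2 - (f - i2)^2 + params$gamma + params$beta_len * kap
  }
  phi <- phi0
  dt_cur <- params$dt
  phi_acc <- NULL
  upd <- NULL
  E_acc <- NA_real_
  accepted <- 0
  while (accepted < iters) {
    E <- energy_at(phi)
    if (!is.null(phi_acc) && E > E_acc) {
      dt_cur <- dt_cur / 2
      if (dt_cur < 1e-10) break
      phi <- phi_acc + dt_cur * upd
      next
    }
    E_acc <- E
    Fo <- force_at(phi)
    u <- dirac(phi) * Fo
    fmax <- max(abs(u))
    if (fmax <= 0) break
    upd <- u / fmax
    phi_acc <- phi
    dt_cur <- min(params$dt, dt_cur * 1.2)
    phi <- phi_acc + dt_cur * upd
    accepted <- accepted + 1
  }
  phi
}

# quick phantom slice for segmentation tests
phantom_slice <- function(d_mm, contrast, sigma, spacing = 1, seed = 1,
                          dims = c(64, 64)) {
  spec <- phantom_spec(d_mm, contrast, noise_sigma = sigma,
                       slab_shape = c(dims, 1), voxel_spacing_mm = spacing)
  ph <- generate_phantom(spec, seed = seed)
  list(image = ph$volume$intensities[, , 1], mask = ph$truth$mask[, , 1],
       truth = ph$truth)
}

# rasterized shapes for shape-metric tests
raster_disc <- function(radius, dims = 2 * radius + 21,
                        center = (dims + 1) / 2) {
  g <- expand.grid(r = seq_len(dims), c = seq_len(dims))
  matrix((g$r - center)^2 + (g$c - center)^2 <= radius^2, dims, dims)
}

raster_ellipse <- function(a, b, dims = 151) {
  ctr <- (dims + 1) / 2
  g <- expand.grid(r = seq_len(dims), c = seq_len(dims))
  matrix(((g$r - ctr) / a)^2 + ((g$c - ctr) / b)^2 <= 1, dims, dims)
}
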