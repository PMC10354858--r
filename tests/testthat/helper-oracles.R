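# Independent reference implementations used as oracles. These deliberately
# use naive loops / brute force so they share no code with the package paths
# they check.

# Dose model evaluated directly at arbitrary 3D points (same mathematical
# model as the C++ kernel, independent code).
oracle_dose_at <- function(plan, pts, sigma_x = 2.5, sigma_y = 2,
                           transmission = 0.02, mu_atten = 0.005,
                           phantom_radius = 110) {
  sstep <- function(u) 0.5 * (1 + u / sqrt(1 + u^2))
  n_rows <- ncol(plan$leaf_a)
  out <- numeric(nrow(pts))
  for (cp in seq_along(plan$gantry)) {
    phi <- plan$gantry[cp] * pi / 180
    for (i in seq_len(nrow(pts))) {
      x <- pts[i, 1]; y <- pts[i, 2]; z <- pts[i, 3]
      xb <- x * cos(phi) - z * sin(phi)
      depth <- max(phantom_radius - (x * sin(phi) + z * cos(phi)), 0)
      f <- 0
      for (j in seq_len(n_rows)) {
        w <- sstep((y - plan$row_edges[j]) / sigma_y) -
          sstep((y - plan$row_edges[j + 1]) / sigma_y)
        if (w < 1e-8) next
        gate <- transmission + (1 - transmission) *
          max(sstep((xb - plan$leaf_a[cp, j]) / sigma_x) -
                sstep((xb - plan$leaf_b[cp, j]) / sigma_x), 0)
        f <- f + w * gate
      }
      out[i] <- out[i] + plan$mu_weight[cp] * exp(-mu_atten * depth) * f
    }
  }
  out
}

# Brute-force KL divergence (loop sum), sigma = variance vector.
oracle_kl <- function(mu, sigma) {
  acc <- 0
  for (i in seq_along(mu))
    acc <- acc + 1 + log(sigma[i]) - mu[i]^2 - sigma[i]
  -acc / 2
}

# Brute-force Mahalanobis distance: explicit solve() and loop quadratic form.
oracle_md <- function(x, xbar, Sigma) {
  Sinv <- solve(Sigma)
  d <- x - xbar
  acc <- 0
  for (i in seq_along(d))
    for (j in seq_along(d))
      acc <- acc + d[i] * Sinv[i, j] * d[j]
  sqrt(acc)
}

# AUC by Mann-Whitney pair counting.
oracle_auc <- function(neg, pos) {
  acc <- 0
  for (p in pos)
    for (q in neg)
      acc <- acc + (p > q) + 0.5 * (p == q)
  acc / (length(pos) * length(neg))
}

# Brute-force gamma on a much finer search lattice.
oracle_gamma <- function(px, py, ref_dose, eval_dist, dd_abs, dta,
                         radius = 3, step_div = 50) {
  ev <- eval_dist$values
  bil <- function(x, y) {
    fx <- (x - eval_dist$origin[1]) / eval_dist$step
    fy <- (y - eval_dist$origin[2]) / eval_dist$step
    fx <- min(max(fx, 0), nrow(ev) - 1)
    fy <- min(max(fy, 0), ncol(ev) - 1)
    i0 <- min(floor(fx), nrow(ev) - 2); j0 <- min(floor(fy), ncol(ev) - 2)
    tx <- fx - i0; ty <- fy - j0
    (ev[i0 + 1, j0 + 1] * (1 - tx) + ev[i0 + 2, j0 + 1] * tx) * (1 - ty) +
      (ev[i0 + 1, j0 + 2] * (1 - tx) + ev[i0 + 2, j0 + 2] * tx) * ty
  }
  offs <- seq(-radius * dta, radius * dta, by = dta / step_div)
  best <- Inf
  for (dx in offs) for (dy in offs) {
    r2 <- dx^2 + dy^2
    if (r2 > (radius * dta)^2) next
    g2 <- ((bil(px + dx, py + dy) - ref_dose) / dd_abs)^2 + r2 / dta^2
    if (g2 < best) best <- g2
  }
  sqrt(best)
}

# Numerical gradient check of a network: returns the worst relative error
# over sampled parameters and inputs.
gradcheck_net <- function(net, x, n_per_param = 4, eps = 1e-6) {
  fwd <- function() sum(net_forward(net, x, training = TRUE)^2)
  y <- net_forward(net, x, training = TRUE)
  dx <- net_backward(net, 2 * y)
  grads <- lapply(net, function(l) l$grads)
  worst <- 0
  for (li in seq_along(net)) {
    for (nm in names(net[[li]]$params)) {
      p0 <- net[[li]]$params[[nm]]
      g <- grads[[li]][[nm]]
      for (k in sample(length(p0), min(n_per_param, length(p0)))) {
        net[[li]]$params[[nm]][k] <- p0[k] + eps; f1 <- fwd()
        net[[li]]$params[[nm]][k] <- p0[k] - eps; f2 <- fwd()
        net[[li]]$params[[nm]][k] <- p0[k]
        gn <- (f1 - f2) / (2 * eps)
        worst <- max(worst, abs(gn - g[k]) / max(1, abs(gn) + abs(g[k])))
      }
    }
  }
  for (k in sample(length(x), 6)) {
    x0 <- x[k]
    x[k] <- x0 + eps; f1 <- fwd()
    x[k] <- x0 - eps; f2 <- fwd()
    x[k] <- x0
    gn <- (f1 - f2) / (2 * eps)
    worst <- max(worst, abs(gn - dx[k]) / max(1, abs(gn) + abs(dx[k])))
  }
  worst
}
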