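#' Sample a synthetic full-arc VMAT plan
#'
#' Generates a prostate-like arc: control points spaced over a full gantry
#' rotation, with a smoothly varying, roughly elliptical aperture whose radius
#' and transverse centroid drift over the arc, plus smooth random per-leaf
#' modulation. Leaf positions are given at the isocenter plane; bank A (`a`)
#' is always left of bank B (`b`).
#'
#' @param seed integer seed; the same seed reproduces the plan bit-identically.
#' @param n_cp number of control points over the arc.
#' @param leaf_pitch leaf width at isocenter, mm.
#' @param field_halfwidth half-extent of the leaf bank along y, mm.
#' @param aperture_radius nominal aperture radius, mm.
#' @return An object of class `vmat_plan` with `gantry` (degrees), `mu_weight`,
#'   `leaf_a`/`leaf_b` (`n_cp x n_rows` matrices) and `row_edges`.
#' @examples
#' plan <- sample_plan(seed = 1)
#' all(plan$leaf_a <= plan$leaf_b)
#' @export
sample_plan <- function(seed, n_cp = 20, leaf_pitch = 5,
                        field_halfwidth = 70, aperture_radius = 25) {
  if (missing(seed)) stop("a seed is required")
  if (n_cp < 1) stop("n_cp must be >= 1")
  with_seed(seed, {
    row_edges <- seq(-field_halfwidth, field_halfwidth, by = leaf_pitch)
    n_rows <- length(row_edges) - 1L
    row_centers <- (row_edges[-1] + row_edges[-length(row_edges)]) / 2
    gantry <- seq(0, 360, length.out = n_cp + 1L)[seq_len(n_cp)]
    phi <- gantry * pi / 180

    # smooth arc-level modulation of radius and transverse centroid
    r_arc <- aperture_radius *
      (1 + 0.15 * sin(phi + runif(1, 0, 2 * pi)) +
         0.08 * sin(2 * phi + runif(1, 0, 2 * pi)))
    c_arc <- 5 * sin(phi + runif(1, 0, 2 * pi)) +
      3 * sin(3 * phi + runif(1, 0, 2 * pi))

    # smooth per-leaf random modulation: low-order Fourier noise in cp index
    leaf_noise <- function() {
      amp <- 2.5
      n1 <- matrix(rnorm(n_rows * 2, sd = amp), n_rows, 2)
      n2 <- matrix(rnorm(n_rows * 2, sd = amp / 2), n_rows, 2)
      t(sapply(seq_len(n_rows), function(j)
        n1[j, 1] * cos(phi) + n1[j, 2] * sin(phi) +
          n2[j, 1] * cos(2 * phi) + n2[j, 2] * sin(2 * phi)))
    }
    jit_a <- leaf_noise()  # n_rows x n_cp
    jit_b <- leaf_noise()

    leaf_a <- matrix(0, n_cp, n_rows)
    leaf_b <- matrix(0, n_cp, n_rows)
    for (cp in seq_len(n_cp)) {
      h <- sqrt(pmax(r_arc[cp]^2 - row_centers^2, 0))
      open <- h > 0
      a <- c_arc[cp] - h - ifelse(open, pmax(jit_a[, cp], -h / 2), 0)
      b <- c_arc[cp] + h + ifelse(open, pmax(jit_b[, cp], -h / 2), 0)
      # closed rows park at the aperture centroid
      a[!open] <- c_arc[cp]
      b[!open] <- c_arc[cp]
      bad <- a > b
      if (any(bad)) { m <- (a[bad] + b[bad]) / 2; a[bad] <- m; b[bad] <- m }
      leaf_a[cp, ] <- a
      leaf_b[cp, ] <- b
    }
    mu_weight <- runif(n_cp, 0.8, 1.2)
    structure(list(gantry = gantry, mu_weight = mu_weight,
                   leaf_a = leaf_a, leaf_b = leaf_b,
                   row_edges = row_edges, leaf_pitch = leaf_pitch,
                   seed = seed),
              class = "vmat_plan")
  })
}

#' @export
print.vmat_plan <- function(x, ...) {
  cat(sprintf("Synthetic VMAT arc: %d control points, %d leaf pairs (pitch %g mm), seed %d\n",
              length(x$gantry), ncol(x$leaf_a), x$leaf_pitch, x$seed))
  invisible(x)
}
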