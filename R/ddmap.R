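#' Normalize a planar dose by the measured isocenter dose
#'
#' Both the measured and the calculated planar doses of a pair are divided by
#' the same measured isocenter dose, removing the prescription-dose scale.
#'
#' @param planar_dose per-diode dose vector.
#' @param isocenter_dose measured dose at the isocenter (> 0).
#' @return the normalized vector.
#' @export
normalize_by_isocenter <- function(planar_dose, isocenter_dose) {
  if (!is.numeric(isocenter_dose) || length(isocenter_dose) != 1L ||
      isocenter_dose <= 0)
    stop("isocenter_dose must be a single positive number")
  planar_dose / isocenter_dose
}

# Measured dose at the in-plane origin of a plane (the isocenter projection);
# a diode sits there in the default layout, otherwise nearest diode.
isocenter_dose_of <- function(planar, geometry, plane = 1) {
  ip <- geometry$planes[[plane]]$inplane
  i <- which(ip[, "a"] == 0 & ip[, "b"] == 0)
  if (length(i) == 0L) i <- which.min(ip[, "a"]^2 + ip[, "b"]^2)
  planar[i[1]]
}

#' Build a clipped dose-difference map from a normalized planar dose pair
#'
#' Per-diode differences (measured minus calculated) are placed on the
#' uniform fine-pitch in-plane lattice. Lattice nodes carrying a diode keep
#' the exact diode difference (no smoothing); nodes in the coarse-pitch
#' region are filled by linear interpolation from neighboring diode values
#' (separable: along diode-bearing rows first, then along columns). The
#' central `size x size` block around the isocenter projection is extracted
#' and clipped to `clip`.
#'
#' @param measured_plane,calculated_plane normalized per-diode doses of the
#'   same plane.
#' @param geometry detector geometry.
#' @param plane plane index (1 or 2).
#' @param size map edge length in nodes (odd).
#' @param clip symmetric clipping limit.
#' @return A `dd_map`: `size x size` matrix (rows = transverse coordinate
#'   increasing, columns = longitudinal coordinate increasing) with plane and
#'   pitch attributes.
#' @export
build_dd_map <- function(measured_plane, calculated_plane, geometry,
                         plane = 1, size = 27, clip = 0.2) {
  if (length(measured_plane) != length(calculated_plane))
    stop("measured and calculated planes have different diode counts (plane mismatch?)")
  pl <- geometry$planes[[plane]]
  if (length(measured_plane) != nrow(pl$inplane))
    stop("planar dose length does not match the diode count of this plane")
  pitch <- geometry$pitch_central
  half <- (size - 1) / 2 * pitch
  lat <- seq(-half, half, by = pitch)
  diff <- measured_plane - calculated_plane
  ap <- pl$inplane[, "a"]
  bp <- pl$inplane[, "b"]

  # pass 1: along every diode-bearing row (all b values with >= 2 diodes),
  # values at the lattice a positions; NA outside the row's diode span
  brows <- sort(unique(bp))
  m1 <- matrix(NA_real_, length(lat), length(brows))
  for (j in seq_along(brows)) {
    sel <- bp == brows[j]
    if (sum(sel) >= 2L)
      m1[, j] <- approx(ap[sel], diff[sel], xout = lat, rule = 1,
                        ties = "ordered")$y
    else if (sum(sel) == 1L)
      m1[match(ap[sel], lat), j] <- diff[sel]
  }
  # pass 2: along columns, using all filled rows (including those outside
  # the cropped block)
  m <- matrix(NA_real_, length(lat), length(lat))
  for (i in seq_along(lat)) {
    known <- !is.na(m1[i, ])
    if (sum(known) >= 2L)
      m[i, ] <- approx(brows[known], m1[i, known], xout = lat, rule = 1,
                       ties = "ordered")$y
    else if (sum(known) == 1L)
      m[i, match(brows[known], lat)] <- m1[i, known]
  }
  # fallback for nodes outside the diode convex hull: nearest filled value
  if (anyNA(m)) {
    for (i in seq_along(lat)) {
      known <- which(!is.na(m[i, ]))
      if (length(known) > 0L && length(known) < length(lat)) {
        miss <- which(is.na(m[i, ]))
        m[i, miss] <- m[i, known[vapply(miss, function(k)
          which.min(abs(known - k)), integer(1))]]
      }
    }
    for (j in seq_along(lat)) {
      known <- which(!is.na(m[, j]))
      if (length(known) > 0L && length(known) < length(lat)) {
        miss <- which(is.na(m[, j]))
        m[miss, j] <- m[known[vapply(miss, function(k)
          which.min(abs(known - k)), integer(1))], j]
      }
    }
  }
  m <- pmin(pmax(m, -clip), clip)
  structure(m, class = c("dd_map", class(m)), plane = plane, pitch = pitch,
            clip = clip)
}

#' Four-fold flip augmentation of a dose-difference map
#'
#' @param map a `dd_map` (or plain matrix).
#' @return list of 4 maps: original, horizontal flip, vertical flip, both.
#' @export
augment_flips <- function(map) {
  flip_h <- map[, rev(seq_len(ncol(map))), drop = FALSE]
  flip_v <- map[rev(seq_len(nrow(map))), , drop = FALSE]
  flip_b <- flip_v[, rev(seq_len(ncol(flip_v))), drop = FALSE]
  out <- list(map, flip_h, flip_v, flip_b)
  lapply(out, function(m) structure(m, class = class(map),
                                    plane = attr(map, "plane"),
                                    pitch = attr(map, "pitch"),
                                    clip = attr(map, "clip")))
}

# Build the two DD maps of one beam-condition (daily output correction and
# isocenter normalization applied; the same measured isocenter dose
# normalizes measured and calculated doses of the pair).
build_case_maps <- function(dataset, beam, kind, size = 27, clip = 0.2) {
  geo <- dataset$geometry
  meas <- apply_daily_correction(beam$measured)
  iso <- isocenter_dose_of(meas[[1]], geo, plane = 1)
  cond <- beam$conditions[[kind]]
  if (is.null(cond)) stop("missing condition '", kind, "' for beam ",
                          beam$beam_id)
  lapply(1:2, function(k) {
    mm <- normalize_by_isocenter(meas[[k]], iso)
    cc <- normalize_by_isocenter(cond$planar[[k]], iso)
    map <- build_dd_map(mm, cc, geo, plane = k, size = size, clip = clip)
    attr(map, "beam_id") <- beam$beam_id
    attr(map, "error_kind") <- kind
    map
  })
}

#' Assemble the VAE training, validation and test datasets
#'
#' Training maps are the error-free maps of the training beams (two planes
#' per beam), expanded four-fold by flipping; validation maps are the
#' error-free maps of the validation beams; test cases pair the two planes of
#' every test beam-condition (error-free plus each error kind).
#'
#' @param dataset a [generate_dataset()] result.
#' @param augment expand training maps four-fold by flipping.
#' @param size,clip map geometry, passed to [build_dd_map()].
#' @return list with `train` (list of maps), `validation` (list of maps) and
#'   `test_cases` (list of beam cases: `beam_id`, `error_kind`, `maps`).
#' @export
assemble_vae_datasets <- function(dataset, augment = TRUE, size = 27,
                                  clip = 0.2) {
  stopifnot(inherits(dataset, "qa_dataset"))
  splits <- vapply(dataset$beams, `[[`, "", "split")
  grab_maps <- function(which_split) {
    maps <- list()
    for (beam in dataset$beams[splits == which_split])
      maps <- c(maps, build_case_maps(dataset, beam, "none", size, clip))
    maps
  }
  train <- grab_maps("train")
  if (augment) train <- do.call(c, lapply(train, augment_flips))
  validation <- grab_maps("validation")
  test_cases <- list()
  for (beam in dataset$beams[splits == "test"]) {
    for (kind in names(beam$conditions)) {
      test_cases[[length(test_cases) + 1L]] <-
        list(beam_id = beam$beam_id, error_kind = kind,
             maps = build_case_maps(dataset, beam, kind, size, clip))
    }
  }
  missing <- vapply(test_cases, function(cs) length(cs$maps) != 2L, logical(1))
  if (any(missing)) stop("test cases with missing plane maps: ",
                         paste(which(missing), collapse = ", "))
  list(train = train, validation = validation, test_cases = test_cases)
}
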