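#' Cell geometry for normalized-distance computation
#'
#' @param centroid numeric (x, y) in pixels.
#' @param axis long-axis direction; normalized to unit length.
#' @param half_length half of the cell length, in pixels (> 0).
#' @param cell_id identifier.
#' @param mask optional logical matrix marking cell pixels.
#' @return an object of class `cell_geometry`.
#' @export
cell_geometry <- function(centroid, axis = c(1, 0), half_length,
                          cell_id = 1L, mask = NULL) {
  assert_that(half_length > 0, "half_length must be positive")
  nrm <- sqrt(sum(axis^2))
  assert_that(nrm > 0, "axis vector must be non-zero")
  structure(list(cell_id = cell_id, centroid = as.numeric(centroid),
                 axis = as.numeric(axis) / nrm,
                 half_length = half_length, mask = mask),
            class = "cell_geometry")
}

#' Normalized axial distance of spots to the cell centroid
#'
#' \eqn{d = |(p - c)\cdot u| / L_{1/2}} where `u` is the long-axis unit
#' vector and `L_half` the cell half-length; clipped to [0, 1]. The distance
#' is axial (not radial): pole versus mid/quarter localization differs along
#' the long axis. Spots projecting beyond the pole are flagged in the
#' `"outside"` attribute but still get a (clipped) d.
#'
#' @param position numeric (x, y) or an n x 2 matrix of positions (pixels).
#' @param geometry a [cell_geometry()].
#' @return numeric vector of d values in [0, 1] with attribute `outside`.
#' @export
normalized_distance <- function(position, geometry) {
  p <- if (is.matrix(position)) position else matrix(position, ncol = 2)
  rel <- sweep(p, 2, geometry$centroid)
  proj <- abs(rel %*% geometry$axis) / geometry$half_length
  d <- pmin(pmax(as.vector(proj), 0), 1)
  attr(d, "outside") <- as.vector(proj) > 1
  d
}

#' Classify a spot channel from its normalized distance
#'
#' Spots at `d >= threshold` are pole-localized and report CI; spots at
#' `d < threshold` are mid/quarter-localized and report Cro. The boundary is
#' assigned to the pole side.
#'
#' @param d normalized distance(s) in [0, 1].
#' @param threshold classification threshold (default 0.6).
#' @return character vector, `"CI"` (pole) or `"Cro"` (mid).
#' @export
classify_spot <- function(d, threshold = 0.6) {
  assert_that(all(d >= 0 & d <= 1), "d must lie in [0, 1]")
  ifelse(d >= threshold, "CI", "Cro")
}

#' Calibrate the single-molecule fluorescence intensity
#'
#' Gaussian fit (maximum likelihood) to a sample of single-molecule
#' integrated intensities; the fitted peak is the unit later used to convert
#' intensities to molecule numbers.
#'
#' @param intensities numeric sample of single-molecule intensities.
#' @param min_n minimum sample size (default 30).
#' @return an `intensity_calibration`: list with `peak`, `fit_sd`,
#'   `n_samples`.
#' @export
calibrate_single_molecule_intensity <- function(intensities, min_n = 30) {
  intensities <- intensities[is.finite(intensities)]
  if (length(intensities) < min_n) {
    stop(sprintf("need at least %d intensity samples, got %d",
                 min_n, length(intensities)), call. = FALSE)
  }
  peak <- mean(intensities)
  s <- sd(intensities)
  if (is.na(s)) s <- 0
  if (peak <= 0 || s > peak) {
    stop("calibration quality failure: fitted sd exceeds the peak (bimodal or non-positive sample?)",
         call. = FALSE)
  }
  structure(list(peak = peak, fit_sd = s, n_samples = length(intensities)),
            class = "intensity_calibration")
}

#' Convert integrated intensity to molecule number
#'
#' Rounds `intensity / peak` to the nearest integer, floored at zero.
#' Negative intensities (over-subtracted background) give 0 and are flagged.
#'
#' @param intensity numeric integrated intensities.
#' @param calibration an [calibrate_single_molecule_intensity()] result.
#' @return integer molecule counts with attribute `flagged` (logical).
#' @export
intensity_to_molecules <- function(intensity, calibration) {
  n <- pmax(0L, as.integer(round(intensity / calibration$peak)))
  attr(n, "flagged") <- intensity < 0
  n
}

#' Quantify delocalized (cloud) molecules from total cell fluorescence
#'
#' For high-expression regimes where the mid-cell reporter no longer forms
#' discrete spots: subtract the pole-localized spot fluorescence from the
#' total integrated cellular fluorescence and convert the remainder to
#' molecules.
#'
#' @param total_intensity total integrated cell fluorescence (>= 0).
#' @param pole_intensities intensities of pole-localized spots.
#' @param calibration intensity calibration.
#' @return integer molecule count with attribute `flagged` (TRUE when the
#'   pole sum exceeded the total).
#' @export
quantify_cloud <- function(total_intensity, pole_intensities, calibration) {
  assert_that(total_intensity >= 0, "total intensity must be >= 0")
  rest <- total_intensity - sum(pole_intensities)
  n <- max(0L, as.integer(round(rest / calibration$peak)))
  attr(n, "flagged") <- rest < 0
  n
}

#' Simulate a fluorescence frame of localized spots
#'
#' Places pole-targeted (CI reporter) and mid/quarter-targeted (Cro
#' reporter) spots along a rod-shaped cell, jitters them with the
#' localization precision, and renders 2D Gaussian point-spread peaks on a
#' pixel grid with background, shot noise and read noise. The axial
#' placement distributions emulate the observed pole/mid separability
#' (roughly 92-95% on either side of d = 0.6): pole spots at an axial
#' fraction ~N(0.87, 0.15) of the half-length, mid spots an equal mixture of
#' midcell ~N(0, 0.12) and quarter-cell ~N(0.5, 0.08) positions.
#'
#' @param n_pole,n_mid spot counts (>= 0).
#' @param cell_length_nm cell length in nm (default 2500).
#' @param localization_sd_nm localization precision in nm (default 35).
#' @param image_params list overriding any of `pixel_nm` (100),
#'   `psf_sd_nm` (130), `photons` per molecule (1500), `background` (100),
#'   `read_noise` (3), `pad_px` (6), `cell_radius_nm` (400).
#' @param seed integer seed.
#' @return list with `image` (numeric matrix, rows = y), `truth`
#'   (data.frame x_px, y_px, class, intensity, axial_frac), `geometry`
#'   (a [cell_geometry()]), and `crowded` (TRUE when the spot density
#'   exceeds the resolvability bound, with a warning).
#' @export
simulate_spot_frame <- function(n_pole, n_mid, cell_length_nm = 2500,
                                localization_sd_nm = 35,
                                image_params = list(), seed = 1L) {
  assert_that(n_pole >= 0 && n_mid >= 0, "spot counts must be >= 0")
  ip <- modifyList(list(pixel_nm = 100, psf_sd_nm = 130, photons = 1500,
                        background = 100, read_noise = 3, pad_px = 6,
                        cell_radius_nm = 400), image_params)
  set.seed(seed)
  half_nm <- cell_length_nm / 2
  ax_pole <- ax_mid <- numeric(0)
  if (n_pole > 0) {
    ax_pole <- sample(c(-1, 1), n_pole, replace = TRUE) *
      pmin(abs(rnorm(n_pole, 0.87, 0.15)), 1)
  }
  if (n_mid > 0) {
    quarter <- runif(n_mid) < 0.5
    ax <- ifelse(quarter,
                 sample(c(-1, 1), n_mid, replace = TRUE) *
                   rnorm(n_mid, 0.5, 0.08),
                 rnorm(n_mid, 0, 0.12))
    ax_mid <- pmin(pmax(ax, -1), 1)
  }
  axial <- c(ax_pole, ax_mid)
  cls <- rep(c("pole", "mid"), c(n_pole, n_mid))
  n <- length(axial)
  x_nm <- axial * half_nm + rnorm(n, 0, localization_sd_nm)
  y_nm <- rnorm(n, 0, ip$cell_radius_nm / 3) + rnorm(n, 0, localization_sd_nm)
  y_nm <- pmin(pmax(y_nm, -ip$cell_radius_nm), ip$cell_radius_nm)
  # pixel grid: cell axis along x, centroid at image center
  width <- ceiling(cell_length_nm / ip$pixel_nm) + 2 * ip$pad_px
  height <- ceiling(2 * ip$cell_radius_nm / ip$pixel_nm) + 2 * ip$pad_px
  cx <- (width + 1) / 2; cy <- (height + 1) / 2
  x_px <- cx + x_nm / ip$pixel_nm
  y_px <- cy + y_nm / ip$pixel_nm
  psf_px <- ip$psf_sd_nm / ip$pixel_nm
  img <- matrix(ip$background, nrow = height, ncol = width)
  if (n > 0) {
    xs <- seq_len(width); ys <- seq_len(height)
    for (i in seq_len(n)) {
      gx <- exp(-(xs - x_px[i])^2 / (2 * psf_px^2))
      gy <- exp(-(ys - y_px[i])^2 / (2 * psf_px^2))
      amp <- ip$photons / (2 * pi * psf_px^2)
      img <- img + amp * outer(gy, gx)
    }
  }
  img <- matrix(rpois(length(img), as.vector(img)), nrow = height) +
    matrix(rnorm(length(img), 0, ip$read_noise), nrow = height)
  crowded <- FALSE
  if (n > 0) {
    cell_area_px <- (cell_length_nm / ip$pixel_nm) *
      (2 * ip$cell_radius_nm / ip$pixel_nm)
    if (n * pi * (2 * psf_px)^2 > 0.5 * cell_area_px) {
      crowded <- TRUE
      warning("spot density exceeds the resolvability bound; detections will merge")
    }
  }
  truth <- data.frame(x_px = x_px, y_px = y_px, class = cls,
                      intensity = rep(ip$photons, n), axial_frac = axial)
  geom <- cell_geometry(centroid = c(cx, cy), axis = c(1, 0),
                        half_length = half_nm / ip$pixel_nm)
  list(image = img, truth = truth, geometry = geom, crowded = crowded,
       params = ip)
}

#' Detect fluorescent spots in a 2D image
#'
#' Local-maximum candidates above a robust background threshold, refined by
#' least-squares 2D Gaussian fitting in a small window. Positions are
#' sub-pixel; intensities are background-subtracted integrated Gaussian
#' volumes. Deterministic for fixed parameters. Spots whose fit window
#' touches saturated pixels are flagged, not dropped.
#'
#' @param image numeric matrix (rows = y, columns = x).
#' @param detection_params list overriding `threshold_sd` (5), `psf_sd_px`
#'   (1.3), `window` (3, half-width), `sat_level` (Inf), `min_separation_px`
#'   (2).
#' @return data.frame with columns `x_px`, `y_px`, `intensity`, `peak`,
#'   `saturated`; zero rows when nothing is found.
#' @export
detect_spots <- function(image, detection_params = list()) {
  dp <- modifyList(list(threshold_sd = 5, psf_sd_px = 1.3, window = 3,
                        sat_level = Inf, min_separation_px = 2),
                   detection_params)
  assert_that(is.matrix(image), "image must be a 2D numeric matrix")
  bg <- median(image)
  noise <- mad(image)
  if (noise == 0) noise <- sd(image)
  thr <- bg + dp$threshold_sd * max(noise, 1e-12)
  H <- nrow(image); W <- ncol(image)
  cand <- which(image > thr, arr.ind = TRUE)
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, 1]; c <- cand[i, 2]
    rr <- max(1, r - 1):min(H, r + 1); cc <- max(1, c - 1):min(W, c + 1)
    keep[i] <- image[r, c] == max(image[rr, cc])
  }
  cand <- cand[keep, , drop = FALSE]
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      intensity = numeric(0), peak = numeric(0),
                      saturated = logical(0))
  if (nrow(cand) == 0) return(empty)
  w <- dp$window
  fits <- lapply(seq_len(nrow(cand)), function(i) {
    r <- cand[i, 1]; c <- cand[i, 2]
    rr <- max(1, r - w):min(H, r + w); cc <- max(1, c - w):min(W, c + w)
    patch <- image[rr, cc, drop = FALSE]
    fit <- fit_gaussian2d(patch, xs = cc, ys = rr,
                          x0 = c, y0 = r, sigma0 = dp$psf_sd_px, bg0 = bg)
    fit$saturated <- any(patch >= dp$sat_level)
    fit
  })
  out <- do.call(rbind, lapply(fits, function(f) {
    data.frame(x_px = f$x0, y_px = f$y0, intensity = f$intensity,
               peak = f$amp, saturated = f$saturated)
  }))
  out <- out[is.finite(out$intensity) & out$intensity > 0, , drop = FALSE]
  # merge duplicate detections of the same spot: keep the brighter one
  if (nrow(out) > 1) {
    ord <- order(-out$intensity)
    out <- out[ord, , drop = FALSE]
    kept <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      if (!kept[i]) next
      if (i < nrow(out)) {
        later <- (i + 1):nrow(out)
        dd <- sqrt((out$x_px[later] - out$x_px[i])^2 +
                     (out$y_px[later] - out$y_px[i])^2)
        kept[later[dd < dp$min_separation_px]] <- FALSE
      }
    }
    out <- out[kept, , drop = FALSE]
    out <- out[order(out$y_px, out$x_px), , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

# least-squares circular 2D Gaussian + flat background on a pixel patch
fit_gaussian2d <- function(patch, xs, ys, x0, y0, sigma0, bg0) {
  z <- as.vector(patch)
  X <- rep(xs, each = length(ys))
  Y <- rep(ys, times = length(xs))
  a0 <- max(patch) - bg0
  par0 <- c(x0 = x0, y0 = y0, log_amp = log(max(a0, 1e-6)),
            log_sigma = log(sigma0), bg = bg0)
  obj <- function(p) {
    mu <- p[5] + exp(p[3]) *
      exp(-((X - p[1])^2 + (Y - p[2])^2) / (2 * exp(2 * p[4])))
    sum((z - mu)^2)
  }
  res <- tryCatch(optim(par0, obj, method = "BFGS",
                        control = list(maxit = 200)),
                  error = function(e) list(par = par0))
  p <- res$par
  sig <- exp(p[4])
  amp <- exp(p[3])
  list(x0 = unname(p[1]), y0 = unname(p[2]), sigma = unname(sig),
       amp = unname(amp), intensity = unname(2 * pi * amp * sig^2))
}
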