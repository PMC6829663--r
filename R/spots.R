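#' Spot-detection parameters
#'
#' Parameters of the prominence-based local-maxima detector. Prominence
#' follows the noise-tolerance semantics of the ImageJ "find maxima"
#' routine: a maximum counts only if it rises at least \code{prominence}
#' above the highest saddle connecting it to a higher maximum. When
#' \code{prominence} is \code{NULL} it defaults, per frame, to 5 times the
#' robust background sd (MAD) of the smoothed image.
#'
#' @param prominence minimum prominence in image AU, or \code{NULL} for the
#'   adaptive default.
#' @param min_separation minimum distance between reported spots, pixels;
#'   of two closer maxima the less prominent is dropped.
#' @param smoothing_sigma Gaussian pre-smoothing sd, pixels (0 disables).
#' @return an object of class \code{detection_params}.
#' @export
detection_params <- function(prominence = NULL, min_separation = 3,
                             smoothing_sigma = 1) {
  if (!is.null(prominence)) stopifnot_scalar_pos(prominence, "prominence")
  if (min_separation < 1) stop("min_separation must be >= 1", call. = FALSE)
  stopifnot_scalar_pos(smoothing_sigma, "smoothing_sigma", strict = FALSE)
  structure(list(prominence = prominence, min_separation = min_separation,
                 smoothing_sigma = smoothing_sigma),
            class = "detection_params")
}

# 3x3 centre-of-mass sub-pixel refinement on the (smoothed) image, using
# intensities above the local 3x3 minimum as weights.
refine_subpixel <- function(img, row, col) {
  h <- nrow(img); w <- ncol(img)
  n <- length(row)
  rx <- numeric(n); ry <- numeric(n)
  for (i in seq_len(n)) {
    rr <- max(1L, row[i] - 1L):min(h, row[i] + 1L)
    cc <- max(1L, col[i] - 1L):min(w, col[i] + 1L)
    patch <- img[rr, cc, drop = FALSE] - min(img[rr, cc])
    s <- sum(patch)
    if (s <= 0) { ry[i] <- row[i]; rx[i] <- col[i]; next }
    ry[i] <- sum(rowSums(patch) * rr) / s
    rx[i] <- sum(colSums(patch) * cc) / s
  }
  list(x = rx, y = ry)
}

#' Detect diffraction-limited spots in one frame
#'
#' Gaussian-smooths the frame, finds all local maxima whose prominence
#' (height above the highest saddle to a higher maximum) reaches
#' \code{params$prominence}, refines positions by 3 x 3 centre of mass, and
#' enforces the minimum separation. Coordinates are 1-based pixel centres
#' with \code{x} along columns and \code{y} along rows.
#'
#' @param frame numeric matrix (one movie frame), finite-valued.
#' @param params a \code{\link{detection_params}}.
#' @param mask optional logical/0-1 matrix of the cell footprint; maxima
#'   outside the mask are excluded.
#' @return data.frame(x, y, peak_intensity, prominence), one row per spot.
#' @export
detect_maxima <- function(frame, params = detection_params(), mask = NULL) {
  if (!is.matrix(frame) || length(frame) == 0L)
    stop("frame must be a non-empty matrix", call. = FALSE)
  if (!all(is.finite(frame)))
    stop("frame contains non-finite pixels", call. = FALSE)
  if (!is.null(mask) && !all(dim(mask) == dim(frame)))
    stop("mask must have the same shape as frame", call. = FALSE)
  frame <- frame * 1.0
  sm <- if (params$smoothing_sigma > 0)
    EBImage::gblur(frame, sigma = params$smoothing_sigma) else frame
  prom <- params$prominence
  if (is.null(prom)) {
    prom <- 5 * stats::mad(sm)
    if (prom <= 0) prom <- 5 * stats::sd(sm)
    if (!is.finite(prom) || prom <= 0) prom <- .Machine$double.eps
  }
  pk <- .find_maxima_cpp(sm, prom)
  # the global maximum of any image has prominence equal to the full
  # range, so additionally require peaks to rise `prom` above the image
  # background (smoothed median); otherwise a spot-free noise frame always
  # yields one spurious detection
  if (nrow(pk))
    pk <- pk[pk$value >= stats::median(sm) + prom, , drop = FALSE]
  if (nrow(pk) == 0L)
    return(data.frame(x = numeric(), y = numeric(),
                      peak_intensity = numeric(), prominence = numeric()))
  if (!is.null(mask)) {
    keep <- mask[cbind(pk$row, pk$col)] > 0
    pk <- pk[keep, , drop = FALSE]
  }
  if (nrow(pk) == 0L)
    return(data.frame(x = numeric(), y = numeric(),
                      peak_intensity = numeric(), prominence = numeric()))
  sub <- refine_subpixel(sm, pk$row, pk$col)
  out <- data.frame(x = sub$x, y = sub$y,
                    peak_intensity = frame[cbind(pk$row, pk$col)],
                    prominence = pk$prominence)
  # enforce min_separation: keep the more prominent of any close pair
  out <- out[order(-out$prominence), , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    if (i < nrow(out)) {
      j <- (i + 1):nrow(out)
      d2 <- (out$x[j] - out$x[i])^2 + (out$y[j] - out$y[i])^2
      keep[j[d2 < params$min_separation^2]] <- FALSE
    }
  }
  out <- out[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect spots in every frame of a movie
#'
#' @param movie integer/numeric H x W x T array.
#' @param params a \code{\link{detection_params}}.
#' @param mask optional footprint mask shared by all frames.
#' @return data.frame(frame, x, y, peak_intensity, prominence).
#' @export
detect_movie <- function(movie, params = detection_params(), mask = NULL) {
  stopifnot(length(dim(movie)) == 3L)
  out <- lapply(seq_len(dim(movie)[3]), function(t) {
    d <- detect_maxima(movie[, , t], params, mask)
    if (nrow(d)) cbind(frame = t, d) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(frame = integer(), x = numeric(), y = numeric(),
                      peak_intensity = numeric(), prominence = numeric())
  rownames(out) <- NULL
  out
}

#' Default cell-footprint mask from the temporal mean image
#'
#' Otsu threshold of the temporal-mean image, as an automated stand-in for
#' a manually drawn footprint.
#'
#' @param movie H x W x T array.
#' @return logical matrix.
#' @export
footprint_mask <- function(movie) {
  m <- apply(movie, c(1, 2), mean)
  rng <- range(m)
  if (diff(rng) == 0) return(matrix(TRUE, nrow(m), ncol(m)))
  norm <- (m - rng[1]) / diff(rng)
  norm > EBImage::otsu(EBImage::Image(norm))
}

#' Granule density per footprint area
#'
#' @param spots data.frame of detections (one frame, or provide the mean
#'   per-frame count yourself).
#' @param footprint_area footprint area in square micrometres, or
#'   \code{NULL} to derive it from \code{mask} and \code{pixel_size}.
#' @param mask optional footprint mask (logical matrix).
#' @param pixel_size nm per pixel (default 100), used with \code{mask}.
#' @return density in granules per square micrometre.
#' @export
granule_density <- function(spots, footprint_area = NULL, mask = NULL,
                            pixel_size = 100) {
  if (is.null(footprint_area)) {
    if (is.null(mask)) stop("give footprint_area or mask", call. = FALSE)
    footprint_area <- sum(mask > 0) * (pixel_size / 1000)^2
  }
  if (footprint_area <= 0) stop("footprint area must be > 0", call. = FALSE)
  nrow(spots) / footprint_area
}
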