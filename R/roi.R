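#' Specification of a synthetic two-channel cell image
#'
#' Describes a synthetic fluorescence scene standing in for a fibroblast
#' imaged in a biosensor channel (cytosol-filled cell) and a paxillin
#' channel (elongated focal-adhesion spots in a peripheral band). Used to
#' benchmark the ROI-targeting pipeline against known ground truth.
#'
#' @param size Image side length in pixels (square frames).
#' @param center Cell centre `(row, col)` in 0-based pixels; default the
#'   image centre.
#' @param axes Ellipse semi-axes `(a, b)` of the cell mask in pixels.
#' @param n_fa Number of focal adhesions to place.
#' @param fa_length,fa_width FA spot Gaussian sigmas (px) along/across its
#'   long axis.
#' @param band Peripheral band: FA centres lie at a distance to the cell
#'   edge between `band[1]` and `band[2]` pixels (inside the mask).
#' @param bg,cytosol,fa_peak Intensity levels (arbitrary units); must be
#'   increasing.
#' @param noise_sd Additive Gaussian noise SD per frame (same units).
#' @param min_sep Minimal distance between FA centres (px).
#' @param seed Integer seed for FA placement and noise.
#' @return An object of class `synthetic_cell_spec`.
#' @export
synthetic_cell_spec <- function(size = 256, center = NULL,
                                axes = c(100, 80), n_fa = 12,
                                fa_length = 4, fa_width = 1.5,
                                band = c(3, 12), bg = 100, cytosol = 400,
                                fa_peak = 1200, noise_sd = 20,
                                min_sep = 20, seed = 1L) {
  if (is.null(center)) center <- c(size, size) / 2
  stopifnot(size > 16, length(axes) == 2, all(axes > 0),
            n_fa >= 0, length(band) == 2, band[1] < band[2])
  if (!(bg < cytosol && cytosol < fa_peak))
    stop("intensities must satisfy bg < cytosol < fa_peak")
  structure(list(size = size, center = center, axes = axes, n_fa = n_fa,
                 fa_length = fa_length, fa_width = fa_width, band = band,
                 bg = bg, cytosol = cytosol, fa_peak = fa_peak,
                 noise_sd = noise_sd, min_sep = min_sep, seed = seed),
            class = "synthetic_cell_spec")
}

# 0-based pixel coordinate grids (row, col) for a square frame
pixel_grids <- function(size) {
  list(row = matrix(rep(0:(size - 1), size), size, size),
       col = matrix(rep(0:(size - 1), each = size), size, size))
}

ellipse_mask <- function(spec) {
  g <- pixel_grids(spec$size)
  ((g$row - spec$center[1]) / spec$axes[1])^2 +
    ((g$col - spec$center[2]) / spec$axes[2])^2 <= 1
}

#' Synthesize a two-channel cell image stack with ground truth
#'
#' Renders the scene described by a [synthetic_cell_spec()]: the biosensor
#' channel is the cytosol-filled cell over background (optionally
#' modulated in time by `time_course`, emulating a global activity
#' transient inside the cell), and the paxillin channel adds elongated
#' Gaussian FA spots whose centres are placed uniformly in the peripheral
#' band, tangentially oriented, at least `min_sep` px apart. Per-frame
#' Gaussian noise is added to both channels. Deterministic under `seed`.
#'
#' @param spec A [synthetic_cell_spec()].
#' @param n_frames Number of frames.
#' @param time_course Optional numeric vector (length `n_frames`) of
#'   multiplicative factors applied to the cell's biosensor intensity
#'   above background.
#' @return A list: `biosensor` and `paxillin` (size x size x n_frames
#'   arrays), `cell_mask` (logical matrix), `fa_centers` (n_fa x 2 matrix
#'   of 0-based (row, col)), `spec`.
#' @export
synthesize_cell_image <- function(spec, n_frames = 1,
                                  time_course = NULL) {
  stopifnot(inherits(spec, "synthetic_cell_spec"), n_frames >= 1)
  if (is.null(time_course)) time_course <- rep(1, n_frames)
  stopifnot(length(time_course) == n_frames)
  set.seed(spec$seed)
  size <- spec$size
  mask <- ellipse_mask(spec)
  g <- pixel_grids(size)

  # place FA centres in the peripheral band with a minimal separation
  centers <- matrix(numeric(0), 0, 2)
  if (spec$n_fa > 0) {
    tries <- 0L
    while (nrow(centers) < spec$n_fa) {
      if ((tries <- tries + 1L) > 200L * spec$n_fa)
        stop("could not place ", spec$n_fa, " FAs without overlap; ",
             "loosen min_sep or widen the band")
      th <- stats::runif(1, 0, 2 * pi)
      # radial fraction so that distance to the ellipse edge falls in band
      r_edge <- sqrt(1 / ((cos(th) / spec$axes[1])^2 +
                          (sin(th) / spec$axes[2])^2))
      d <- stats::runif(1, spec$band[1], spec$band[2])
      if (d >= r_edge) next
      r <- r_edge - d
      cand <- spec$center + r * c(cos(th), sin(th))
      if (nrow(centers) &&
          min(sqrt(rowSums(sweep(centers, 2, cand)^2))) < spec$min_sep)
        next
      centers <- rbind(centers, cand)
    }
  }

  # paxillin FA texture: anisotropic Gaussian spots, long axis tangential
  fa_tex <- matrix(0, size, size)
  if (nrow(centers)) {
    for (i in seq_len(nrow(centers))) {
      cc <- centers[i, ]
      radial <- cc - spec$center
      phi <- atan2(radial[2], radial[1]) + pi / 2
      u <- (g$row - cc[1]) * cos(phi) + (g$col - cc[2]) * sin(phi)
      v <- -(g$row - cc[1]) * sin(phi) + (g$col - cc[2]) * cos(phi)
      fa_tex <- fa_tex + exp(-0.5 * ((u / spec$fa_length)^2 +
                                     (v / spec$fa_width)^2))
    }
  }
  fa_tex <- fa_tex * (spec$fa_peak - spec$cytosol)

  bio <- array(0, c(size, size, n_frames))
  pax <- array(0, c(size, size, n_frames))
  cell_lift <- spec$cytosol - spec$bg
  for (f in seq_len(n_frames)) {
    base_bio <- spec$bg + mask * cell_lift * time_course[f]
    base_pax <- spec$bg + mask * (cell_lift + fa_tex)
    bio[, , f] <- base_bio + matrix(stats::rnorm(size^2, 0, spec$noise_sd),
                                    size, size)
    pax[, , f] <- base_pax + matrix(stats::rnorm(size^2, 0, spec$noise_sd),
                                    size, size)
  }
  list(biosensor = bio, paxillin = pax, cell_mask = mask,
       fa_centers = centers, spec = spec)
}

#' Segment the cell from a biosensor frame
#'
#' Otsu global threshold, retention of the largest connected component and
#' hole filling. Set `invert = TRUE` for inverted-contrast frames (dark
#' cell on bright background).
#'
#' @param frame Numeric matrix (single channel).
#' @param invert Flip contrast before thresholding.
#' @return Logical matrix, the cell mask.
#' @export
segment_cell <- function(frame, invert = FALSE) {
  stopifnot(is.matrix(frame))
  if (invert) frame <- max(frame) - frame
  rng <- range(frame)
  if (diff(rng) <= 0) stop("empty foreground: frame has no contrast")
  norm <- (frame - rng[1]) / diff(rng)
  th <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
  fg <- norm > th
  if (!any(fg)) stop("empty foreground after thresholding")
  lab <- EBImage::bwlabel(EBImage::Image(fg))
  tab <- tabulate(as.integer(lab)[as.integer(lab) > 0])
  biggest <- which.max(tab)
  comp <- EBImage::Image(lab == biggest)
  filled <- EBImage::fillHull(comp)
  matrix(as.logical(filled), nrow(frame), ncol(frame))
}

#' Detect focal adhesions in a paxillin frame
#'
#' FA candidates are pixels inside the cell whose paxillin intensity
#' exceeds the within-cell mean by `min_intensity_k` standard deviations;
#' connected components are then filtered by area and by centroid distance
#' to the cell boundary (FAs localise at the periphery).
#'
#' @param paxillin Numeric matrix.
#' @param cell_mask Logical matrix from [segment_cell()].
#' @param min_intensity_k Threshold in SDs above the within-cell mean.
#' @param size_range Length-2 numeric, admissible component area (px^2).
#' @param max_edge_distance Max centroid distance to the mask boundary
#'   (px).
#' @return A list: `labels` (integer matrix, 0 = background), `centers`
#'   (n x 2 matrix of 0-based (row, col) centroids), `areas`.
#' @export
detect_focal_adhesions <- function(paxillin, cell_mask,
                                   min_intensity_k = 2,
                                   size_range = c(10, 500),
                                   max_edge_distance = 15) {
  stopifnot(is.matrix(paxillin), identical(dim(paxillin), dim(cell_mask)))
  vals <- paxillin[cell_mask]
  thr <- mean(vals) + min_intensity_k * stats::sd(vals)
  cand <- (paxillin > thr) & cell_mask
  lab <- EBImage::bwlabel(EBImage::Image(cand))
  labm <- matrix(as.integer(lab), nrow(paxillin))
  n <- max(labm)
  if (n == 0)
    return(list(labels = labm, centers = matrix(numeric(0), 0, 2),
                areas = numeric(0)))
  dist_in <- matrix(as.numeric(EBImage::distmap(EBImage::Image(cell_mask))),
                    nrow(paxillin))
  keep <- integer(0)
  centers <- NULL
  areas <- numeric(0)
  for (k in seq_len(n)) {
    px <- which(labm == k, arr.ind = TRUE)
    area <- nrow(px)
    if (area < size_range[1] || area > size_range[2]) next
    ctr <- colMeans(px) - 1 # 0-based
    ed <- dist_in[round(ctr[1]) + 1, round(ctr[2]) + 1]
    if (ed > max_edge_distance) next
    keep <- c(keep, k)
    centers <- rbind(centers, ctr)
    areas <- c(areas, area)
  }
  out <- labm
  out[!(labm %in% keep)] <- 0L
  # relabel sequentially
  if (length(keep)) {
    map <- integer(n)
    map[keep] <- seq_along(keep)
    out[out > 0] <- map[out[out > 0]]
  }
  if (is.null(centers)) centers <- matrix(numeric(0), 0, 2)
  rownames(centers) <- NULL
  list(labels = out, centers = centers, areas = areas)
}

#' Select paired FA / non-FA stimulation ROIs
#'
#' Places one circular ROI on each detected FA centroid and pairs it with
#' a non-FA ROI at the nearest valid site: inside the cell, within the
#' same peripheral distance band as the FA, outside all FA components
#' dilated by `exclusion_dilation`, and not overlapping other ROIs. Pairs
#' without a valid site are dropped with a warning.
#'
#' @param fa A detection result from [detect_focal_adhesions()].
#' @param cell_mask Logical matrix.
#' @param radius ROI disk radius (px).
#' @param exclusion_dilation Dilation of FA components defining the
#'   exclusion zone (px).
#' @param band_halfwidth Half-width (px) of the edge-distance band around
#'   each FA's own edge distance within which its partner must lie.
#' @return A `roi_set`: data.frame with `row`, `col` (0-based), `radius`,
#'   `class` (`"FA"`/`"non-FA"`), `pair_id`.
#' @export
select_stimulation_rois <- function(fa, cell_mask, radius = 3,
                                    exclusion_dilation = 3,
                                    band_halfwidth = 6) {
  if (nrow(fa$centers) < 1) stop("need at least one detected FA")
  size <- nrow(cell_mask)
  dist_in <- matrix(as.numeric(EBImage::distmap(EBImage::Image(cell_mask))),
                    size)
  excl <- fa$labels > 0
  if (exclusion_dilation > 0) {
    brush <- EBImage::makeBrush(2 * ceiling(exclusion_dilation) + 1,
                                shape = "disc")
    excl <- matrix(as.logical(EBImage::dilate(EBImage::Image(excl), brush)),
                   size)
  }
  g <- pixel_grids(size)
  taken <- matrix(FALSE, size, size)
  rois <- NULL
  for (i in seq_len(nrow(fa$centers))) {
    ctr <- fa$centers[i, ]
    ed <- dist_in[round(ctr[1]) + 1, round(ctr[2]) + 1]
    ok <- cell_mask & !excl & !taken &
      abs(dist_in - ed) <= band_halfwidth & dist_in > radius
    if (!any(ok)) {
      warning("no valid non-FA site for FA ", i, "; pair dropped")
      next
    }
    d2 <- (g$row - ctr[1])^2 + (g$col - ctr[2])^2
    d2[!ok] <- Inf
    j <- arrayInd(which.min(d2), dim(d2))
    partner <- as.numeric(j) - 1
    rois <- rbind(rois,
                  data.frame(row = ctr[1], col = ctr[2], radius = radius,
                             class = "FA", pair_id = i),
                  data.frame(row = partner[1], col = partner[2],
                             radius = radius, class = "non-FA",
                             pair_id = i))
    blocked <- (g$row - partner[1])^2 + (g$col - partner[2])^2 <=
      (2 * radius)^2
    taken <- taken | blocked
  }
  if (is.null(rois)) {
    warning("all FA/non-FA pairs dropped")
    rois <- data.frame(row = numeric(0), col = numeric(0),
                       radius = numeric(0), class = character(0),
                       pair_id = integer(0))
  }
  class(rois) <- c("roi_set", class(rois))
  rois
}

#' Extract mean-intensity traces for a set of ROIs
#'
#' @param stack Numeric array (rows x cols x frames) or matrix (single
#'   frame).
#' @param rois A `roi_set` from [select_stimulation_rois()].
#' @param t Optional time grid (s); defaults to frame index starting at 0.
#' @return A `trace_ensemble` whose rows follow the rows of `rois`.
#' @export
extract_roi_traces <- function(stack, rois, t = NULL) {
  if (is.matrix(stack)) stack <- array(stack, c(dim(stack), 1))
  stopifnot(length(dim(stack)) == 3, nrow(rois) >= 1)
  size_r <- dim(stack)[1]
  size_c <- dim(stack)[2]
  n_f <- dim(stack)[3]
  if (is.null(t)) t <- seq_len(n_f) - 1
  g <- pixel_grids(size_r)
  traces <- matrix(NA_real_, nrow(rois), n_f)
  for (i in seq_len(nrow(rois))) {
    r0 <- rois$row[i]
    c0 <- rois$col[i]
    rad <- rois$radius[i]
    if (r0 - rad < 0 || r0 + rad > size_r - 1 ||
        c0 - rad < 0 || c0 + rad > size_c - 1)
      stop("ROI ", i, " (", rois$class[i], ", pair ", rois$pair_id[i],
           ") extends outside the frame")
    disk <- (g$row - r0)^2 + (g$col - c0)^2 <= rad^2
    for (f in seq_len(n_f)) {
      fr <- stack[, , f]
      traces[i, f] <- mean(fr[disk])
    }
  }
  structure(list(t = t, traces = traces,
                 labels = data.frame(condition = rep(NA_character_,
                                                     nrow(rois)),
                                     compartment = rois$class,
                                     stringsAsFactors = FALSE),
                 provenance = list(rois = rois)),
            class = "trace_ensemble")
}

#' Normalised paxillin intensity of each ROI
#'
#' Mean paxillin intensity inside each ROI disk divided by the mean
#' paxillin intensity over the whole cell - the quality-control contrast
#' separating FA from non-FA ROIs.
#'
#' @param paxillin Numeric matrix.
#' @param rois A `roi_set`.
#' @param cell_mask Logical matrix.
#' @return Numeric vector, one value per ROI row.
#' @export
roi_paxillin_contrast <- function(paxillin, rois, cell_mask) {
  cell_mean <- mean(paxillin[cell_mask])
  ens <- extract_roi_traces(paxillin, rois)
  as.numeric(ens$traces[, 1]) / cell_mean
}
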