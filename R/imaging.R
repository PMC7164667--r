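#' Construct a time-lapse frame
#'
#' One phase-contrast frame of a spheroid series: an 8-bit grayscale pixel
#' grid with its physical pixel size and acquisition time.
#'
#' @param pixels Numeric matrix of intensities in 0..255 (rows = image rows,
#'   origin top-left, 0-based pixel coordinates in all reported geometry).
#' @param pixel_size_um Micrometres per pixel (> 0).
#' @param day Acquisition time in days since seeding.
#' @return Object of class `frame_image`.
#' @export
frame_image <- function(pixels, pixel_size_um, day = NA_real_) {
  pixels <- as.matrix(pixels)
  if (nrow(pixels) < 64 || ncol(pixels) < 64) {
    stop("frame must be at least 64 x 64 pixels")
  }
  if (pixel_size_um <= 0) stop("pixel_size_um must be positive")
  structure(
    list(pixels = pixels, pixel_size_um = pixel_size_um, day = day),
    class = "frame_image"
  )
}

#' Default segmentation settings
#'
#' @param polarity `"dark"` (default; dark spheroid on bright background,
#'   the usual phase-contrast appearance) or `"bright"`.
#' @param brush_size Diameter in pixels of the disc structuring element used
#'   for morphological opening and closing.
#' @return Named list of settings.
#' @export
segmentation_config <- function(polarity = c("dark", "bright"), brush_size = 3L) {
  list(polarity = match.arg(polarity), brush_size = as.integer(brush_size))
}

#' Segment the spheroid in one frame
#'
#' Conventional binarization plus morphological clean-up: Otsu's threshold on
#' the intensity histogram, binary opening then closing with a small disc
#' element, hole filling, and retention of the single largest connected
#' component. The retained region is summarized as the circle of equal area.
#'
#' @param frame A [frame_image()].
#' @param config Settings from [segmentation_config()].
#' @return Object of class `segmentation_result`: list with `mask` (logical
#'   matrix, one connected component), `area_px`, `equivalent_radius_um`.
#' @export
segment_spheroid <- function(frame, config = segmentation_config()) {
  stopifnot(inherits(frame, "frame_image"))
  px <- frame$pixels / 255
  if (config$polarity == "dark") px <- 1 - px
  if (diff(range(px)) < 1e-12) {
    stop("empty segmentation: frame at day ", format(frame$day),
         " has no contrast")
  }
  img <- EBImage::Image(t(px)) # EBImage is column-major x,y
  thr <- EBImage::otsu(img, range = c(0, 1))
  bw <- img > thr
  if (sum(bw) == 0) {
    stop("empty segmentation: no foreground pixels in frame at day ",
         format(frame$day))
  }
  brush <- EBImage::makeBrush(odd(config$brush_size), shape = "disc")
  bw <- EBImage::closing(EBImage::opening(bw, brush), brush)
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  tab <- tabulate(as.integer(EBImage::imageData(lab)))
  if (length(tab) == 0 || all(tab == 0)) {
    stop("empty segmentation: morphology removed all foreground in frame at day ",
         format(frame$day))
  }
  keep <- which.max(tab)
  mask <- t(EBImage::imageData(lab) == keep)
  area_px <- sum(mask)
  structure(
    list(
      mask = mask,
      area_px = area_px,
      equivalent_radius_um = equivalent_circle_radius(area_px, frame$pixel_size_um)
    ),
    class = "segmentation_result"
  )
}

odd <- function(n) if (n %% 2 == 1) n else n + 1L

#' Radius of the circle with the same area as a segmented region
#'
#' @param area_px Region area in pixels (>= 1).
#' @param pixel_size_um Micrometres per pixel.
#' @return Equivalent-circle radius in micrometres:
#'   `pixel_size_um * sqrt(area_px / pi)`.
#' @export
equivalent_circle_radius <- function(area_px, pixel_size_um) {
  if (any(area_px <= 0)) stop("area_px must be positive")
  if (any(pixel_size_um <= 0)) stop("pixel_size_um must be positive")
  pixel_size_um * sqrt(area_px / pi)
}

#' Growth curve from a time-lapse frame series
#'
#' Segments every frame, converts each region to its equivalent circle, and
#' estimates the cell count by face-centred cubic packing of cells of
#' `cell_diameter_um` in the sphere of the same diameter. Frames that fail
#' segmentation are dropped with a warning.
#'
#' @param series List of [frame_image()] objects (>= 2), in time order.
#' @param cell_diameter_um Single-cell diameter (um); see
#'   [estimate_single_cell_size()].
#' @param config Settings from [segmentation_config()].
#' @return A [growth_curve()] with `equiv_diameter_um` column.
#' @export
extract_growth_curve <- function(series, cell_diameter_um,
                                 config = segmentation_config()) {
  stopifnot(length(series) >= 2, cell_diameter_um > 0)
  days <- vapply(series, function(f) f$day, numeric(1))
  if (any(diff(days) <= 0)) stop("frame timestamps must be strictly increasing")
  res <- lapply(series, function(f) {
    tryCatch(segment_spheroid(f, config), error = function(e) e)
  })
  failed <- vapply(res, inherits, logical(1), "error")
  if (any(failed)) {
    warning(
      sum(failed), " frame(s) dropped (",
      paste(vapply(res[failed], conditionMessage, character(1)), collapse = "; "),
      ")"
    )
  }
  if (sum(!failed) < 2) {
    stop("insufficient series: fewer than 2 frames segmented successfully")
  }
  keep <- which(!failed)
  diam <- vapply(res[keep], function(r) 2 * r$equivalent_radius_um, numeric(1))
  counts <- pmax(1, estimate_cell_count(pmax(diam, cell_diameter_um), cell_diameter_um))
  growth_curve(days[keep], counts,
    equiv_diameter_um = diam,
    cell_diameter_um = cell_diameter_um
  )
}

#' Estimate the single-cell diameter from one- or two-cell-stage frames
#'
#' Segments each early frame and converts the region to an equivalent-circle
#' diameter; frames flagged as two-cell have their area halved before
#' conversion (two cells share the region). Returns the mean per-cell
#' diameter across frames.
#'
#' @param frames List of [frame_image()] objects from the one- or two-cell
#'   stage.
#' @param n_cells Integer vector (1 or 2) per frame; default all 1.
#' @param config Settings from [segmentation_config()].
#' @return Mean single-cell diameter in micrometres.
#' @export
estimate_single_cell_size <- function(frames, n_cells = rep(1L, length(frames)),
                                      config = segmentation_config()) {
  if (length(frames) < 1) stop("need at least one frame")
  stopifnot(length(n_cells) == length(frames), all(n_cells %in% 1:2))
  diams <- mapply(function(f, nc) {
    r <- tryCatch(segment_spheroid(f, config), error = function(e) NULL)
    if (is.null(r)) return(NA_real_)
    2 * equivalent_circle_radius(r$area_px / nc, f$pixel_size_um)
  }, frames, n_cells)
  if (all(is.na(diams))) stop("empty segmentation on all single-cell frames")
  mean(diams, na.rm = TRUE)
}
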