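#' Load a simulation configuration from YAML or JSON
#'
#' Reads a flat mapping of [sim_config()] fields, applies the standard
#' defaults for everything absent, rejects unknown keys, and validates. An
#' empty file yields the full default configuration. All validation problems
#' are reported together.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [sim_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(vals)) vals <- list()
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  vals <- lapply(vals, function(v) if (identical(v, "Inf")) Inf else v)
  do.call(sim_config, vals)
}

#' Save a simulation configuration to YAML
#'
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  vals <- unclass(config)
  vals <- lapply(vals, function(v) if (identical(v, Inf)) "Inf" else v)
  yaml::write_yaml(vals, path)
  invisible(path)
}

curve_schema <- c("day", "cell_count", "equiv_diameter_um")

#' Write / read a growth curve as CSV
#'
#' Schema: `day,cell_count[,equiv_diameter_um]` with unit-suffixed headers.
#' Reading rejects files whose columns do not match the schema, naming the
#' offending columns.
#'
#' @param curve A [growth_curve()].
#' @param path CSV path.
#' @return `write_growth_curve_csv`: `path` invisibly;
#'   `read_growth_curve_csv`: a [growth_curve()].
#' @export
write_growth_curve_csv <- function(curve, path) {
  stopifnot(is.data.frame(curve))
  utils::write.csv(as.data.frame(curve)[, intersect(curve_schema, names(curve))],
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_growth_curve_csv
#' @export
read_growth_curve_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(c("day", "cell_count"), names(df))
  extra <- setdiff(names(df), curve_schema)
  if (length(missing) || length(extra)) {
    stop(
      "growth curve schema mismatch in ", path,
      if (length(missing)) paste0("; missing column(s): ", paste(missing, collapse = ", ")),
      if (length(extra)) paste0("; unknown column(s): ", paste(extra, collapse = ", "))
    )
  }
  growth_curve(df$day, df$cell_count, equiv_diameter_um = df$equiv_diameter_um)
}

snapshot_schema <- c(
  "id", "x_um", "y_um", "z_um", "generation", "cycle_age_min",
  "N", "density", "mobility"
)

#' Write / read a particle snapshot as CSV
#'
#' Schema: `id,x_um,y_um,z_um,generation,cycle_age_min,N,density,mobility`.
#'
#' @param state A `spheroid_state` (or its `particles` data frame).
#' @param path CSV path.
#' @return `write_snapshot_csv`: `path` invisibly; `read_snapshot_csv`: the
#'   particle data frame.
#' @export
write_snapshot_csv <- function(state, path) {
  particles <- if (inherits(state, "spheroid_state")) state$particles else state
  stopifnot(all(snapshot_schema %in% names(particles)))
  utils::write.csv(particles[, snapshot_schema], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snapshot_csv
#' @export
read_snapshot_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  missing <- setdiff(snapshot_schema, names(df))
  extra <- setdiff(names(df), snapshot_schema)
  if (length(missing) || length(extra)) {
    stop(
      "snapshot schema mismatch in ", path,
      if (length(missing)) paste0("; missing column(s): ", paste(missing, collapse = ", ")),
      if (length(extra)) paste0("; unknown column(s): ", paste(extra, collapse = ", "))
    )
  }
  df
}

#' Read a frame series from image files
#'
#' Frames are listed either through a sidecar CSV with columns
#' `frame,path,day` (paths relative to the CSV's directory) or by globbing a
#' directory for TIFF/PNG files in lexical order with a fixed spacing.
#' Images must be single-channel 8-bit grayscale.
#'
#' @param source Path to a sidecar CSV or to a directory of frames.
#' @param pixel_size_um Micrometres per pixel.
#' @param frame_interval_h Frame spacing in hours (used only without a
#'   sidecar).
#' @param day_start Day of the first frame (used only without a sidecar).
#' @return List of [frame_image()] objects in time order.
#' @export
read_frames <- function(source, pixel_size_um, frame_interval_h = 3,
                        day_start = 2) {
  if (dir.exists(source)) {
    paths <- sort(list.files(source,
      pattern = "\\.(tiff?|png)$",
      ignore.case = TRUE, full.names = TRUE
    ))
    if (!length(paths)) stop("no TIFF/PNG frames found in ", source)
    days <- day_start + (seq_along(paths) - 1) * frame_interval_h / 24
  } else {
    sidecar <- utils::read.csv(source, check.names = FALSE)
    missing <- setdiff(c("frame", "path", "day"), names(sidecar))
    if (length(missing)) {
      stop("sidecar schema mismatch; missing column(s): ",
           paste(missing, collapse = ", "))
    }
    sidecar <- sidecar[order(sidecar$day), ]
    paths <- file.path(dirname(source), sidecar$path)
    days <- sidecar$day
  }
  mapply(function(p, d) {
    img <- EBImage::readImage(p)
    dat <- EBImage::imageData(img)
    if (length(dim(dat)) > 2) dat <- dat[, , 1]
    frame_image(t(dat) * 255, pixel_size_um, day = d)
  }, paths, days, SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write a frame as an 8-bit grayscale image
#'
#' @param frame A [frame_image()].
#' @param path Output path; extension selects TIFF or PNG.
#' @return `path`, invisibly.
#' @export
write_frame <- function(frame, path) {
  stopifnot(inherits(frame, "frame_image"))
  EBImage::writeImage(EBImage::Image(t(frame$pixels / 255)), path,
                      bits.per.sample = 8L)
  invisible(path)
}
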