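#' Write an image stack as multi-page float TIFF with a calibration sidecar
#'
#' TIFF float samples are stored in [0,1]; the data are therefore written as
#' `(value - offset) / scale` and the affine transform, together with the
#' voxel size in um and any frame interval, is recorded in a JSON sidecar
#' (`<path>.json`). [read_stack()] restores intensities and calibration.
#'
#' @param stack an [image_stack()].
#' @param path output file (`.tif`).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  d <- stack$data
  offset <- min(d)
  scale <- max(d) - offset
  if (scale <= 0) scale <- 1
  norm <- (d - offset) / scale
  pages <- if (length(dim(d)) == 2L) list(norm) else {
    lapply(seq_len(dim(d)[1]), function(z) norm[z, , ])
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  meta <- list(
    voxel_size_um = as.list(stack$voxel_size),
    intensity_offset = offset,
    intensity_scale = scale,
    axes = paste(names(stack$voxel_size), collapse = ""),
    frame_interval_s = stack$frame_interval
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_stack()] or a plain TIFF
#'
#' Axis order is canonical (z,y,x) after loading. Voxel calibration comes
#' from the JSON sidecar when present; for plain TIFFs it must be supplied
#' via `voxel_size_um` -- a missing calibration is an error, never a silent
#' default.
#'
#' @param path TIFF file.
#' @param voxel_size_um optional calibration override in um (z,y,x for 3D
#'   stacks, y,x for single planes).
#' @return an [image_stack()].
#' @export
read_stack <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nz <- length(pages)
  d <- if (nz == 1L) pages[[1]] else {
    a <- array(0, c(nz, dim(pages[[1]])))
    for (z in seq_len(nz)) a[z, , ] <- pages[[z]]
    a
  }
  sidecar <- paste0(path, ".json")
  frame_interval <- NULL
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    d <- d * meta$intensity_scale + meta$intensity_offset
    vs <- unlist(meta$voxel_size_um)
    frame_interval <- meta$frame_interval_s
    if (!is.null(voxel_size_um)) vs <- voxel_size_um
  } else if (!is.null(voxel_size_um)) {
    vs <- voxel_size_um
  } else {
    stop("no voxel calibration for ", path,
         ": no sidecar found and no `voxel_size_um` override given")
  }
  image_stack(d, vs, frame_interval = frame_interval)
}

#' Write / read a spot table as CSV
#'
#' Fixed-schema CSV (see [spot_table()]); coordinates are physical (um).
#' The round trip is lossless for all fields. Tables with an `NA` category
#' are rejected on write -- categories must be explicit (use
#' `"unassigned"`).
#'
#' @param spots a [spot_table()].
#' @param path CSV path.
#' @return `path` invisibly (write); a `spot_table` (read).
#' @export
write_spot_table <- function(spots, path) {
  spots <- spot_table(spots)
  if (anyNA(spots$category)) {
    stop("spot table has NA categories; set them to \"unassigned\" explicitly")
  }
  write.csv(as.data.frame(spots), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spot_table
#' @export
read_spot_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cols <- spot_table_columns()
  df <- tryCatch(
    read.csv(path, colClasses = unname(cols), stringsAsFactors = FALSE),
    error = function(e) stop("malformed spot table ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  if (!identical(names(df), names(cols))) {
    stop("spot table ", path, " does not match the expected schema (",
         paste(names(cols), collapse = ", "), ")")
  }
  spot_table(df)
}

#' Write / read a FRAP trace as CSV
#'
#' Columns: `frame`, `time_s`, `bleached`, `reference`, `background`, plus
#' `corrected` when present; the number of pre-bleach frames is stored in a
#' `n_prebleach` column (constant).
#'
#' @param trace a [frap_trace()].
#' @param path CSV path.
#' @return `path` invisibly (write); a `frap_trace` (read).
#' @export
write_frap_trace <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  keep <- c("time_s", "bleached", "reference", "background", "corrected")
  keep <- keep[!vapply(trace[keep], is.null, logical(1))]
  df <- as.data.frame(trace[keep], stringsAsFactors = FALSE)
  df <- cbind(frame = seq_along(trace$time_s) - 1L, df)
  df$n_prebleach <- attr(trace, "n_prebleach")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_frap_trace
#' @export
read_frap_trace <- function(path) {
  df <- read.csv(path)
  need <- c("frame", "time_s", "bleached", "reference", "background",
            "n_prebleach")
  if (!all(need %in% names(df))) {
    stop("FRAP trace ", path, " must have columns: ",
         paste(need, collapse = ", "))
  }
  tr <- frap_trace(time_s = df$time_s, bleached = df$bleached,
                   reference = df$reference, background = df$background,
                   n_prebleach = df$n_prebleach[1])
  if (!is.null(df$corrected)) tr$corrected <- df$corrected
  tr
}

#' Write generator ground truth as CSV with a JSON parameter sidecar
#'
#' One row per spot: id, class, z_um, y_um, x_um, membrane_distance_um,
#' pair_id (NA when unpaired). Scene or kinetic parameters, when given, are
#' stored next to the table as `<path>.json`.
#'
#' @param truth ground-truth data frame from a generator
#'   ([place_and_render_spots()], [place_categorized_spots()]).
#' @param path CSV path.
#' @param params optional parameter object (e.g. a `spot_params`) for the
#'   sidecar.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path, params = NULL) {
  cols <- c("id", "class", "z_um", "y_um", "x_um", "membrane_distance_um",
            "pair_id")
  for (nm in cols) if (is.null(truth[[nm]])) truth[[nm]] <- NA
  write.csv(truth[, cols], path, row.names = FALSE)
  if (!is.null(params)) {
    jsonlite::write_json(lapply(unclass(params), function(x) x),
                         paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, null = "null")
  }
  invisible(path)
}
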