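#' Image stack with physical voxel calibration
#'
#' The basic substrate of the pipeline: a single-channel 2D (y,x) or 3D
#' (z,y,x) intensity array together with its physical voxel size in
#' micrometres. Axis order is canonical (z,y,x); anisotropic calibration
#' (e.g. 0.4 um z-steps with 0.13 um pixels) is the norm for confocal
#' embryo stacks. Voxel index `i` (1-based) maps to physical coordinate
#' `(i - 1) * voxel_size` um at the voxel centre.
#'
#' @param data numeric array, 2 or 3 dimensions, axis order (z,y,x) or (y,x).
#' @param voxel_size positive numeric, one value per spatial axis, in um.
#' @param frame_interval optional frame interval in seconds (time-lapse data).
#' @return an `image_stack` object.
#' @export
image_stack <- function(data, voxel_size, frame_interval = NULL) {
  if (!is.array(data) && !is.matrix(data)) stop("`data` must be an array")
  nd <- length(dim(data))
  if (nd < 2L || nd > 3L) stop("`data` must have 2 (y,x) or 3 (z,y,x) dimensions")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != nd) {
    stop("`voxel_size` must have one entry per spatial axis (got ",
         length(voxel_size), ", need ", nd, ")")
  }
  if (any(!is.finite(voxel_size)) || any(voxel_size <= 0)) {
    stop("all voxel sizes must be positive and finite")
  }
  names(voxel_size) <- if (nd == 3L) c("z", "y", "x") else c("y", "x")
  structure(
    list(data = data, voxel_size = voxel_size, frame_interval = frame_interval),
    class = "image_stack"
  )
}

#' @export
dim.image_stack <- function(x) dim(x$data)

#' @export
print.image_stack <- function(x, ...) {
  cat("<image_stack> ", paste(dim(x$data), collapse = " x "),
      " voxels; voxel size (",
      paste(names(x$voxel_size), collapse = ","), ") = (",
      paste(signif(x$voxel_size, 4), collapse = ", "), ") um\n", sep = "")
  invisible(x)
}

#' Voxel calibration of a stack, label volume or distance map
#' @param x an `image_stack`, `label_volume` or `distance_map`.
#' @return named numeric vector of voxel sizes in um.
#' @export
voxel_size <- function(x) x$voxel_size

#' Integer-labelled cell segmentation volume
#'
#' Shares the grid and calibration of the membrane `image_stack` it was
#' derived from. Label 0 means outside the embryo; labels >= 1 are cells.
#' The membrane is represented by the boundary voxel set: voxels inside a
#' label that touch (face adjacency) a different nonzero label or label 0.
#'
#' @param labels integer array (2D or 3D), values >= 0.
#' @param voxel_size physical voxel size per axis in um.
#' @return a `label_volume` object.
#' @export
label_volume <- function(labels, voxel_size) {
  if (!is.array(labels) && !is.matrix(labels)) stop("`labels` must be an array")
  if (any(labels < 0)) stop("labels must be nonnegative")
  storage.mode(labels) <- "integer"
  st <- image_stack(array(0, dim(labels)), voxel_size) # reuse validation
  structure(list(labels = labels, voxel_size = st$voxel_size),
            class = "label_volume")
}

#' @export
dim.label_volume <- function(x) dim(x$labels)

#' @export
print.label_volume <- function(x, ...) {
  cat("<label_volume> ", paste(dim(x$labels), collapse = " x "),
      " voxels; ", max(x$labels), " labels\n", sep = "")
  invisible(x)
}

#' Relabel a label volume contiguously
#'
#' Maps the nonzero labels to 1..K preserving their order of first occurrence
#' in column-major scan order; 0 stays 0.
#'
#' @param lv a `label_volume`.
#' @return a `label_volume` with contiguous labels.
#' @export
relabel <- function(lv) {
  stopifnot(inherits(lv, "label_volume"))
  u <- unique(as.vector(lv$labels))
  u <- u[u != 0L]
  map <- integer(max(c(u, 0L)) + 1L)
  map[u + 1L] <- seq_along(u)
  out <- lv$labels
  nz <- out != 0L
  out[nz] <- map[out[nz] + 1L]
  label_volume(out, lv$voxel_size)
}

#' Per-voxel distance to the nearest membrane boundary voxel
#'
#' @param dist numeric array of distances in um (0 exactly on the boundary).
#' @param voxel_size physical voxel size per axis in um.
#' @return a `distance_map` object.
#' @export
distance_map <- function(dist, voxel_size) {
  st <- image_stack(dist, voxel_size)
  structure(list(dist = dist, voxel_size = st$voxel_size),
            class = "distance_map")
}

#' @export
dim.distance_map <- function(x) dim(x$dist)

# physical <-> index conversions (1-based voxel centres)
um_to_index <- function(um, voxel_size) um / voxel_size + 1
index_to_um <- function(idx, voxel_size) (idx - 1) * voxel_size

#' Table of detected or simulated point sources
#'
#' A data frame with one row per spot and a fixed schema: `id`, `channel`,
#' `z_um`, `y_um`, `x_um` (physical coordinates of the sub-voxel centre;
#' `z_um` is `NA` for 2D detections), `peak_intensity`, `integrated_intensity`
#' (background-corrected, arbitrary detector units), `category` (one of
#' `"unassigned"`, `"membrane"`, `"nuclear_pore"`, `"cytosol"`) and
#' `membrane_distance_um` (filled by [spot_membrane_distances()]).
#'
#' @param df data frame carrying at least the coordinate and intensity columns.
#' @return a `spot_table` (a classed data frame).
#' @export
spot_table <- function(df = NULL) {
  cols <- spot_table_columns()
  if (is.null(df)) {
    df <- as.data.frame(lapply(cols, function(cl) vector(cl, 0L)),
                        stringsAsFactors = FALSE)
    names(df) <- names(cols)
  } else {
    df <- as.data.frame(df, stringsAsFactors = FALSE)
    for (nm in names(cols)) {
      if (is.null(df[[nm]])) {
        df[[nm]] <- vector(cols[[nm]], nrow(df))
        df[[nm]][] <- NA
        if (nm == "category") df[[nm]] <- rep("unassigned", nrow(df))
      }
    }
    df <- df[, names(cols), drop = FALSE]
  }
  validate_spot_table(df)
  class(df) <- c("spot_table", "data.frame")
  df
}

spot_table_columns <- function() {
  c(id = "integer", channel = "character",
    z_um = "numeric", y_um = "numeric", x_um = "numeric",
    peak_intensity = "numeric", integrated_intensity = "numeric",
    category = "character", membrane_distance_um = "numeric")
}

validate_spot_table <- function(df) {
  if (anyDuplicated(df$id)) stop("spot ids must be unique within a table")
  ok <- df$integrated_intensity >= 0 | is.na(df$integrated_intensity)
  if (!all(ok)) stop("integrated_intensity must be nonnegative")
  allowed <- c("unassigned", "membrane", "nuclear_pore", "cytosol",
               "translation", "mature", "mrna")
  bad <- !is.na(df$category) & !(df$category %in% allowed)
  if (any(bad)) {
    stop("unknown spot category: ", paste(unique(df$category[bad]), collapse = ", "))
  }
  invisible(df)
}
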