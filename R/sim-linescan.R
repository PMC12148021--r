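#' Synthetic line-scan test image (apical ridge / cytoplasm / background)
#'
#' A 2D fixture for the enrichment-ratio assays: a bright vertical ridge
#' (the apical membrane) at `apical_value`, flanked by a cytoplasm plateau
#' at `cyto_value`, with outside-background margins at `background_value`.
#' By construction the background-subtracted apical/cytoplasm ratio equals
#' `(apical - background) / (cyto - background)`.
#'
#' @param apical_value ridge intensity (ADU); must be >= `cyto_value`.
#' @param cyto_value cytoplasm intensity; must be >= `background_value`.
#' @param background_value outside intensity (>= 0).
#' @param shape image shape (rows y, columns x).
#' @param pixel_size_um pixel size in um.
#' @param noise_sd Gaussian noise sd (0 = off).
#' @param seed integer seed (used only when noise is on).
#' @return list with `image` ([image_stack()]) and `layout` (named list of
#'   column ranges: `background_cols`, `cyto_cols`, `ridge_cols`, plus
#'   `ridge_center_col`).
#' @export
generate_linescan_image <- function(apical_value, cyto_value, background_value,
                                    shape = c(100L, 120L),
                                    pixel_size_um = 0.1,
                                    noise_sd = 0, seed = 1L) {
  if (!(apical_value >= cyto_value && cyto_value >= background_value &&
        background_value >= 0)) {
    stop("need apical_value >= cyto_value >= background_value >= 0")
  }
  shape <- as.integer(shape)
  stopifnot(length(shape) == 2L, all(shape >= 60L))
  nx <- shape[2]
  bg_left <- 1:20
  bg_right <- (nx - 19):nx
  ridge_center <- as.integer(round(nx * 0.45))
  ridge_cols <- (ridge_center - 1):(ridge_center + 1)
  cyto_cols <- setdiff(21:(nx - 20), ridge_cols)
  img <- matrix(background_value, shape[1], nx)
  img[, cyto_cols] <- cyto_value
  img[, ridge_cols] <- apical_value
  if (noise_sd > 0) {
    img <- img + withr::with_seed(seed,
                                  matrix(rnorm(length(img), 0, noise_sd),
                                         shape[1], nx))
  }
  list(
    image = image_stack(img, c(pixel_size_um, pixel_size_um)),
    layout = list(background_cols = c(bg_left, bg_right),
                  cyto_cols = cyto_cols, ridge_cols = ridge_cols,
                  ridge_center_col = ridge_center)
  )
}
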