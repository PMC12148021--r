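#' Pipeline run configuration
#'
#' All tunable stage parameters with their defaults. Intensity gates are in
#' arbitrary detector units (ADU) and are camera-specific: the defaults are
#' the values used for the original acquisitions and must be recalibrated for
#' other cameras or for synthetic scenes (set them relative to the simulated
#' intensity law).
#'
#' Fields:
#' \describe{
#'   \item{proximity_cutoff_um}{membrane-proximity band, 0.35 um; a spot is
#'     membrane-proximal when its distance is within 0-0.35 um (inclusive).}
#'   \item{categorize_cutoff_um}{distance cutoff used to assign spots to
#'     nuclear pore / membrane; defaults to the proximity cutoff.}
#'   \item{gate_translation_overlap}{integrated-intensity gate (> 25000 ADU)
#'     classifying bright GFP spots as translation spots in the overlap assay.}
#'   \item{gate_translation_count}{gate (> 2000 ADU) separating translation
#'     spots from dim mature-protein spots in the counting/re-localization
#'     assay.}
#'   \item{gate_mrna}{gate (> 50000 ADU) classifying mRNA spots in the probe
#'     efficiency assay.}
#'   \item{projection_slices_overlap, projection_slices_count}{number of
#'     z-slices max-projected for the overlap (6) and counting (5) assays.}
#'   \item{min_spots_localization}{embryo inclusion for the proximity assay:
#'     at least 25 translation spots (inclusive).}
#'   \item{min_spots_overlap}{inclusion for the overlap assay: more than 3
#'     translation spots (strict).}
#'   \item{min_spots_relocalization}{inclusion for re-localization efficiency:
#'     more than 7 translation spots (strict).}
#'   \item{linescan_width_apical, linescan_width_frap, linescan_width_act5}{
#'     line-scan widths in pixels (30 / 20 / 15) for the apical-ratio, FRAP
#'     and actin-enrichment assays.}
#'   \item{detect_scale_um}{expected spot sigma per axis in um (z,y,x for 3D).}
#'   \item{detect_threshold}{band-pass (difference-of-Gaussians) response
#'     threshold; the analogue of a blob finder's probability threshold.}
#'   \item{detect_split_h}{maxima-merging depth (split sensitivity): two local
#'     maxima closer in height than this to their connecting saddle are one
#'     spot.}
#'   \item{seg_sharpen_amount, seg_sharpen_sigma_um, seg_edge_gain,
#'     seg_smooth_sigma_um, seg_h_min}{membrane enhancement and watershed
#'     seeding parameters, see [enhance_membrane()] and [segment_cells()].}
#'   \item{match_radius_um}{colocalization match radius; default two detected
#'     spot sigmas.}
#'   \item{frap_n_prebleach}{pre-bleach frames used for normalization (5).}
#'   \item{frap_frame_interval_s}{acquisition interval of the recovery series
#'     (20 s).}
#'   \item{frap_per_animal}{FRAP measurements averaged per animal (2).}
#' }
#'
#' @param ... named overrides of the defaults.
#' @return a `run_config` (named list with a provenance attribute).
#' @export
run_config <- function(...) {
  cfg <- list(
    proximity_cutoff_um = 0.35,
    categorize_cutoff_um = 0.35,
    gate_translation_overlap = 25000,
    gate_translation_count = 2000,
    gate_mrna = 50000,
    projection_slices_overlap = 6L,
    projection_slices_count = 5L,
    min_spots_localization = 25L,
    min_spots_overlap = 3L,
    min_spots_relocalization = 7L,
    linescan_width_apical = 30L,
    linescan_width_frap = 20L,
    linescan_width_act5 = 15L,
    detect_scale_um = c(0.4, 0.15, 0.15),
    detect_threshold = 1,
    detect_split_h = 1,
    seg_sharpen_amount = 1,
    seg_sharpen_sigma_um = 0.5,
    seg_edge_gain = 0.2,
    seg_smooth_sigma_um = 0.3,
    seg_h_min = 100,
    match_radius_um = 0.3,
    frap_n_prebleach = 5L,
    frap_frame_interval_s = 20,
    frap_per_animal = 2L
  )
  prov <- setNames(rep("default", length(cfg)), names(cfg))
  over <- list(...)
  if (length(over)) {
    cfg <- apply_config_values(cfg, over, "user")
    prov[names(over)] <- "user"
  }
  validate_config(cfg)
  structure(cfg, class = "run_config", provenance = prov)
}

apply_config_values <- function(cfg, values, source) {
  if (anyDuplicated(names(values))) {
    stop("duplicated configuration key(s): ",
         paste(unique(names(values)[duplicated(names(values))]),
               collapse = ", "))
  }
  unknown <- setdiff(names(values), names(cfg))
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  }
  for (nm in names(values)) {
    v <- values[[nm]]
    tmpl <- cfg[[nm]]
    if (is.integer(tmpl)) v <- as.integer(v) else v <- as.numeric(v)
    cfg[[nm]] <- v
  }
  cfg
}

validate_config <- function(cfg) {
  pos <- c("proximity_cutoff_um", "categorize_cutoff_um", "detect_scale_um",
           "seg_sharpen_sigma_um", "match_radius_um", "frap_frame_interval_s")
  for (nm in pos) {
    if (any(!is.finite(cfg[[nm]])) || any(cfg[[nm]] <= 0)) {
      stop("config field `", nm, "` must be positive")
    }
  }
  nonneg <- c("gate_translation_overlap", "gate_translation_count", "gate_mrna",
              "detect_threshold", "detect_split_h", "seg_sharpen_amount",
              "seg_edge_gain", "seg_smooth_sigma_um", "seg_h_min")
  for (nm in nonneg) {
    if (any(!is.finite(cfg[[nm]])) || any(cfg[[nm]] < 0)) {
      stop("config field `", nm, "` must be nonnegative")
    }
  }
  counts <- c("projection_slices_overlap", "projection_slices_count",
              "min_spots_localization", "min_spots_overlap",
              "min_spots_relocalization", "linescan_width_apical",
              "linescan_width_frap", "linescan_width_act5",
              "frap_n_prebleach", "frap_per_animal")
  for (nm in counts) {
    if (any(is.na(cfg[[nm]])) || any(cfg[[nm]] < 1L)) {
      stop("config field `", nm, "` must be a positive count")
    }
  }
  invisible(cfg)
}

#' Load a run configuration from YAML or JSON
#'
#' Precedence: package defaults, then file values, then `overrides` (e.g.
#' command-line arguments). Unknown keys and out-of-range values are
#' rejected. The provenance of every resolved value (`"default"`, `"file"`,
#' `"cli"`) is kept so it can be persisted next to the analysis outputs with
#' [write_config()].
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file, or `NULL` for
#'   defaults only.
#' @param overrides named list applied last, recorded with provenance `"cli"`.
#' @return a `run_config`.
#' @export
load_config <- function(path = NULL, overrides = list()) {
  cfg <- run_config()
  prov <- attr(cfg, "provenance")
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::read_json(path, simplifyVector = TRUE)
    } else {
      stop("config must be .yaml/.yml or .json: ", path)
    }
    if (length(vals)) {
      cfg <- apply_config_values(unclass(cfg), vals, "file")
      prov[names(vals)] <- "file"
    }
  }
  if (length(overrides)) {
    cfg <- apply_config_values(unclass(cfg), overrides, "cli")
    prov[names(overrides)] <- "cli"
  }
  cfg <- unclass(cfg)
  validate_config(cfg)
  structure(cfg, class = "run_config", provenance = prov)
}

#' Persist a resolved configuration (with provenance) as JSON
#'
#' @param cfg a `run_config`.
#' @param path output path (`.json`).
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  out <- list(values = unclass(cfg),
              provenance = as.list(attr(cfg, "provenance")))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.run_config <- function(x, ...) {
  prov <- attr(x, "provenance")
  cat("<run_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-28s %s  [%s]\n", nm,
                paste(format(x[[nm]]), collapse = ", "), prov[[nm]]))
  }
  invisible(x)
}
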