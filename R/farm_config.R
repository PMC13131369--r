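#' Farm configuration
#'
#' A static description of a study farm: herd size, barn geometry and
#' equipment. Three reference configurations matching typical western-European
#' commercial freestall farms (70, 140 and 250 lactating cows) ship with the
#' package under `inst/extdata/`.
#'
#' @param farm_id short label, e.g. `"H1"`.
#' @param n_cows number of lactating cows (strictly positive integer).
#' @param barn_area barn area in square meters (strictly positive).
#' @param n_cubicles number of lying cubicles.
#' @param n_water_troughs number of water troughs.
#' @param n_ams number of automatic milking systems (AMS).
#' @param n_cameras number of ceiling cameras; at least 1 is required before
#'   any emulation or evaluation can be requested.
#' @param camera_height optional camera mounting height in meters (metadata
#'   only; no coverage geometry is modelled).
#' @param camera_spacing optional camera spacing in meters (metadata only).
#' @return an object of class `farm_config`.
#' @seealso [validate_farm_config()], [read_farm_config()],
#'   [stocking_density()], [camera_to_cow_ratio()]
#' @export
farm_config <- function(farm_id, n_cows, barn_area, n_cubicles,
                        n_water_troughs, n_ams, n_cameras,
                        camera_height = NULL, camera_spacing = NULL) {
  raw <- list(
    farm_id = farm_id, n_cows = n_cows, barn_area = barn_area,
    n_cubicles = n_cubicles, n_water_troughs = n_water_troughs,
    n_ams = n_ams, n_cameras = n_cameras
  )
  if (!is.null(camera_height)) raw$camera_height <- camera_height
  if (!is.null(camera_spacing)) raw$camera_spacing <- camera_spacing
  validate_farm_config(raw)
}

.farm_required <- c("farm_id", "n_cows", "barn_area", "n_cubicles",
                    "n_water_troughs", "n_ams", "n_cameras")
.farm_counts <- c("n_cows", "n_cubicles", "n_water_troughs", "n_ams",
                  "n_cameras")
.farm_optional <- c("camera_height", "camera_spacing")

#' Validate a raw farm-configuration mapping
#'
#' Checks a flat key-value mapping (e.g. parsed from a YAML or JSON file) and
#' returns a validated [farm_config()]. Errors name the offending field.
#' Unknown keys are kept but raise a warning, so older readers tolerate newer
#' config files.
#'
#' @param raw a named list with at least the required fields `farm_id`,
#'   `n_cows`, `barn_area`, `n_cubicles`, `n_water_troughs`, `n_ams`,
#'   `n_cameras`.
#' @return an object of class `farm_config`.
#' @export
validate_farm_config <- function(raw) {
  if (!is.list(raw) || is.null(names(raw))) {
    stop("farm config must be a named mapping", call. = FALSE)
  }
  missing <- setdiff(.farm_required, names(raw))
  if (length(missing)) stop_field(missing[1L], "missing")

  unknown <- setdiff(names(raw), c(.farm_required, .farm_optional))
  if (length(unknown)) {
    warning(sprintf("ignoring unknown farm config key(s): %s",
                    paste(unknown, collapse = ", ")), call. = FALSE)
  }

  fid <- raw$farm_id
  if (!is.character(fid) && !is.numeric(fid) || length(fid) != 1L) {
    stop_field("farm_id", "must be a single label")
  }

  numeric_fields <- c(.farm_counts, "barn_area",
                      intersect(.farm_optional, names(raw)))
  for (f in numeric_fields) {
    v <- raw[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop_field(f, "must be a single finite number")
    }
  }
  for (f in .farm_counts) {
    v <- raw[[f]]
    if (v <= 0 || v != trunc(v)) {
      stop_field(f, "must be a strictly positive integer count")
    }
  }
  if (raw$barn_area <= 0) stop_field("barn_area", "must be strictly positive")

  cfg <- raw[c(.farm_required, intersect(.farm_optional, names(raw)))]
  cfg$farm_id <- as.character(fid)
  class(cfg) <- "farm_config"
  cfg
}

#' Read a farm configuration from a YAML file
#'
#' @param path path to a flat key-value YAML (or JSON, which YAML subsumes)
#'   file with the [farm_config()] field names.
#' @return a validated `farm_config`.
#' @export
read_farm_config <- function(path) {
  validate_farm_config(yaml::read_yaml(path))
}

#' Stocking density of a farm
#'
#' Barn area per cow in square meters, rounded half-up to one decimal.
#' Densities below the EFSA guideline of 9 m2/cow indicate overcrowding.
#'
#' @param cfg a [farm_config()].
#' @return square meters per cow, one decimal.
#' @examples
#' h1 <- farm_config("H1", 70, 625, 66, 2, 1, 3)
#' stocking_density(h1) # 8.9
#' @export
stocking_density <- function(cfg) {
  stopifnot(inherits(cfg, "farm_config"))
  round_half_up(cfg$barn_area / cfg$n_cows, 1)
}

#' Camera-to-cow ratio of a farm
#'
#' Cows per camera, rounded half-up to one decimal (a ratio of 23.3 means one
#' camera per 23.3 cows).
#'
#' @param cfg a [farm_config()].
#' @return cows per camera, one decimal.
#' @examples
#' h1 <- farm_config("H1", 70, 625, 66, 2, 1, 3)
#' camera_to_cow_ratio(h1) # 23.3
#' @export
camera_to_cow_ratio <- function(cfg) {
  stopifnot(inherits(cfg, "farm_config"))
  if (cfg$n_cameras < 1) stop_field("n_cameras", "at least one camera required")
  round_half_up(cfg$n_cows / cfg$n_cameras, 1)
}

#' @export
print.farm_config <- function(x, ...) {
  cat(sprintf("<farm_config %s>\n", x$farm_id))
  cat(sprintf("  %d cows, %.0f m2 barn, %d cubicles, %d water troughs\n",
              x$n_cows, x$barn_area, x$n_cubicles, x$n_water_troughs))
  cat(sprintf("  %d AMS, %d cameras (%.1f m2/cow, 1:%.1f cows/camera)\n",
              x$n_ams, x$n_cameras, stocking_density(x),
              camera_to_cow_ratio(x)))
  invisible(x)
}
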