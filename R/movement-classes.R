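#' The seven Bafa Wubu movement classes
#'
#' Bafa Wubu is the fundamental tai chi routine combining the eight methods
#' and five steps. For recognition purposes the routine decomposes into seven
#' motion sets, each with a distinct direction of travel and force pattern:
#' two advancing, two retreating, two lateral, and one stationary stance.
#'
#' @return A tibble with one row per movement class:
#' \describe{
#'   \item{code}{three-letter class code (`WOF`, `LF`, `RBB`, `PB`, `PPS`,
#'     `ELS`, `SKR`), in the canonical order used by every confusion matrix
#'     and class map in this package}
#'   \item{long_name}{descriptive movement name}
#'   \item{direction}{gross direction of travel}
#' }
#' @examples
#' movement_classes()
#' @export
movement_classes <- function() {
  tibble::tibble(
    code = bafa_codes(),
    long_name = c(
      "progressive ward-off", "progressive press", "retreating roll-back",
      "retreating pluck", "lateral push and pull", "lateral elbow and lean",
      "static knee lift"
    ),
    direction = c(
      "forward", "forward", "backward", "backward",
      "lateral", "lateral", "stationary"
    )
  )
}

#' Canonical movement class codes
#'
#' @return Character vector of the seven class codes in canonical order.
#' @examples
#' bafa_codes()
#' @export
bafa_codes <- function() {
  c("WOF", "LF", "RBB", "PB", "PPS", "ELS", "SKR")
}

# label used for samples that fall between scripted movements
TRANSITION_LABEL <- "transition"

# six IMU channel names: accelerometer (g), gyroscope (deg/s)
IMU_CHANNELS <- c("ax", "ay", "az", "gx", "gy", "gz")

ACCEL_RANGE_G <- 16
GYRO_RANGE_DPS <- 2000

assert_known_classes <- function(labels, allow_transition = FALSE) {
  ok <- bafa_codes()
  if (allow_transition) ok <- c(ok, TRANSITION_LABEL)
  bad <- setdiff(unique(labels[!is.na(labels)]), ok)
  if (length(bad) > 0) {
    rlang::abort(paste0(
      "unknown movement label(s): ", paste(bad, collapse = ", ")
    ))
  }
  invisible(labels)
}
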