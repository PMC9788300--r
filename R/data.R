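#' Detector array
#'
#' A replicate sampling unit: a set of proximity detectors with known
#' planar coordinates, sampled over a common number of occasions.
#' Coordinates are Euclidean metres in a projected frame; no geographic
#' CRS handling is attempted.
#'
#' @param array_id Character scalar naming the array.
#' @param x,y Numeric vectors of detector coordinates in metres.
#' @param detector_id Optional character vector of detector names; unique
#'   within the array. Defaults to `"D1" ... "DK"`.
#' @param n_occasions Positive integer number of sampling occasions.
#' @return An object of class `"detector_array"`: a list with elements
#'   `array_id`, `detectors` (data frame `id`, `x`, `y`) and `n_occasions`.
#' @examples
#' detector_array("A1", x = c(0, 2000), y = c(0, 0), n_occasions = 6)
#' @export
detector_array <- function(array_id, x, y, detector_id = NULL,
                           n_occasions) {
  stopifnot(is.character(array_id), length(array_id) == 1L,
            length(x) == length(y))
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    stop("detector coordinates must be finite")
  }
  if (is.null(detector_id)) detector_id <- paste0("D", seq_along(x))
  detector_id <- as.character(detector_id)
  if (anyDuplicated(detector_id)) {
    stop("detector ids must be unique within an array")
  }
  n_occasions <- as.integer(n_occasions)
  if (is.na(n_occasions) || n_occasions < 1L) {
    stop("'n_occasions' must be a positive integer")
  }
  structure(
    list(array_id = array_id,
         detectors = data.frame(id = detector_id, x = as.numeric(x),
                                y = as.numeric(y),
                                stringsAsFactors = FALSE),
         n_occasions = n_occasions),
    class = "detector_array")
}

#' Regular grid array
#'
#' Build an axis-aligned `nx` x `ny` grid of detectors centred on a point,
#' the array geometry used by clustered survey designs.
#'
#' @param array_id Array name.
#' @param nx,ny Number of detector columns (x) and rows (y).
#' @param spacing_m Detector spacing in metres.
#' @param centre Length-2 numeric, array centre in metres.
#' @param n_occasions Number of sampling occasions.
#' @return A [detector_array].
#' @export
grid_array <- function(array_id, nx = 5L, ny = 8L, spacing_m = 2000,
                       centre = c(0, 0), n_occasions = 6L) {
  xs <- (seq_len(nx) - (nx + 1) / 2) * spacing_m + centre[1L]
  ys <- (seq_len(ny) - (ny + 1) / 2) * spacing_m + centre[2L]
  g <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  detector_array(array_id, g$x, g$y, n_occasions = n_occasions)
}

#' @export
print.detector_array <- function(x, ...) {
  cat(sprintf("Detector array '%s': %d proximity detectors, %d occasions\n",
              x$array_id, nrow(x$detectors), x$n_occasions))
  ext <- apply(x$detectors[, c("x", "y")], 2L, range)
  cat(sprintf("  extent: x [%.0f, %.0f] m, y [%.0f, %.0f] m\n",
              ext[1L, 1L], ext[2L, 1L], ext[1L, 2L], ext[2L, 2L]))
  invisible(x)
}

n_detectors <- function(array) nrow(array$detectors)

# Minimum nearest-neighbour spacing between detectors; used for default
# mask resolution.
detector_spacing <- function(array) {
  xy <- as.matrix(array$detectors[, c("x", "y")])
  if (nrow(xy) < 2L) return(NA_real_)
  d <- as.matrix(stats::dist(xy))
  diag(d) <- Inf
  min(apply(d, 1L, min))
}

#' Capture data for one array
#'
#' Binary proximity-detector capture histories: one record per detection
#' event (animal, occasion, detector). Each animal can be detected at most
#' once at a given detector on a given occasion; animals never detected do
#' not appear.
#'
#' @param array_id Array the detections belong to.
#' @param events Data frame with columns `animal` (id), `occasion`
#'   (integer in `1..n_occasions`) and `detector` (a detector id of
#'   `array`). Zero rows give an empty capture set (`n = 0`).
#' @param array The [detector_array] the detections were made on.
#' @return An object of class `"capture_data"`: list with `array_id`,
#'   `animals` (ids in first-seen order), `events`, and `n`.
#' @export
capture_data <- function(array_id, events, array) {
  stopifnot(inherits(array, "detector_array"))
  if (!identical(array_id, array$array_id)) {
    stop("'array_id' does not match the supplied detector array")
  }
  need <- c("animal", "occasion", "detector")
  if (!all(need %in% names(events))) {
    stop("'events' must have columns animal, occasion, detector")
  }
  events <- data.frame(animal = as.character(events$animal),
                       occasion = as.integer(events$occasion),
                       detector = as.character(events$detector),
                       stringsAsFactors = FALSE)
  if (nrow(events)) {
    if (any(is.na(events$occasion)) ||
        any(events$occasion < 1L | events$occasion > array$n_occasions)) {
      stop(sprintf("occasions must be integers in 1..%d", array$n_occasions))
    }
    bad <- !(events$detector %in% array$detectors$id)
    if (any(bad)) {
      stop(sprintf("unknown detector id(s): %s",
                   paste(unique(events$detector[bad]), collapse = ", ")))
    }
    key <- paste(events$animal, events$occasion, events$detector)
    if (anyDuplicated(key)) {
      stop("duplicate detection of an animal at one detector and occasion")
    }
    # first-seen order: by occasion, then detector position within array
    det_pos <- match(events$detector, array$detectors$id)
    ord <- order(events$occasion, det_pos)
    animals <- unique(events$animal[ord])
  } else {
    animals <- character(0L)
  }
  structure(
    list(array_id = array_id, animals = animals, events = events,
         n = length(animals)),
    class = "capture_data")
}

#' @export
print.capture_data <- function(x, ...) {
  s <- capture_stats(x)
  cat(sprintf(
    "Capture data '%s': %d animals, %d detections (%d recaptures, %d spatial)\n",
    x$array_id, x$n, s$detections, s$recaptures, s$spatial_recaptures))
  invisible(x)
}

#' Summary counts for capture data
#'
#' @param capt A [capture_data] object.
#' @return A one-row data frame: `n` unique animals, total `detections`,
#'   `recaptures` (detections minus animals) and `spatial_recaptures`
#'   (detections at a detector other than that of the animal's previous
#'   detection, i.e. movements between successive detections, ordered by
#'   occasion with within-occasion ties in detector order).
#' @export
capture_stats <- function(capt) {
  stopifnot(inherits(capt, "capture_data"))
  ev <- capt$events
  if (!nrow(ev)) {
    return(data.frame(array_id = capt$array_id, n = 0L, detections = 0L,
                      recaptures = 0L, spatial_recaptures = 0L,
                      stringsAsFactors = FALSE))
  }
  n_det <- nrow(ev)
  spl <- split(seq_len(n_det), ev$animal)
  spatial <- 0L
  for (idx in spl) {
    det <- ev$detector[idx][order(ev$occasion[idx])]
    spatial <- spatial + sum(det[-1L] != det[-length(det)])
  }
  data.frame(array_id = capt$array_id, n = capt$n, detections = n_det,
             recaptures = n_det - capt$n, spatial_recaptures = spatial,
             stringsAsFactors = FALSE)
}

# animals x detectors matrix of detection counts (occasions summed).
# Sufficient statistic for the occasion-constant likelihood.
detection_counts <- function(capt, array) {
  C <- matrix(0L, nrow = capt$n, ncol = n_detectors(array),
              dimnames = list(capt$animals, array$detectors$id))
  if (nrow(capt$events)) {
    i <- match(capt$events$animal, capt$animals)
    k <- match(capt$events$detector, array$detectors$id)
    for (r in seq_along(i)) C[i[r], k[r]] <- C[i[r], k[r]] + 1L
  }
  C
}

#' Capture histories as a binary array
#'
#' Expand capture data to the full binary history tensor
#' `omega[animal, occasion, detector]`.
#'
#' @param capt A [capture_data] object.
#' @param array The owning [detector_array].
#' @return A 3-d 0/1 array, `n` x `n_occasions` x `K`.
#' @export
capture_tensor <- function(capt, array) {
  om <- array(0L, dim = c(capt$n, array$n_occasions, n_detectors(array)),
              dimnames = list(capt$animals, NULL, array$detectors$id))
  if (nrow(capt$events)) {
    i <- match(capt$events$animal, capt$animals)
    k <- match(capt$events$detector, array$detectors$id)
    om[cbind(i, capt$events$occasion, k)] <- 1L
  }
  om
}

# Number of spatial recaptures (shared by the minimum-data rule).
n_spatial_recaptures <- function(capt) {
  capture_stats(capt)$spatial_recaptures
}
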