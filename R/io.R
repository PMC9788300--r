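#' Read a detector layout table
#'
#' CSV dialect: comma-separated, UTF-8, `.` decimal, mandatory header
#' with columns `array_id`, `detector_id`, `x_m`, `y_m`.
#'
#' @param path File path.
#' @param n_occasions Number of sampling occasions to attach to every
#'   array (the layout file does not carry it).
#' @return Named list of [detector_array], in order of first appearance.
#' @export
read_traps <- function(path, n_occasions = 6L) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("array_id", "detector_id", "x_m", "y_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("trap file missing column(s): ", paste(miss, collapse = ", "))
  }
  for (col in c("x_m", "y_m")) {
    bad <- which(!is.finite(suppressWarnings(as.numeric(df[[col]]))))
    if (length(bad)) {
      stop(sprintf("non-numeric %s in trap file at data row(s) %s",
                   col, paste(utils::head(bad, 5L), collapse = ", ")))
    }
  }
  key <- paste(df$array_id, df$detector_id)
  if (anyDuplicated(key)) {
    stop(sprintf("duplicated (array_id, detector_id) at data row %d",
                 which(duplicated(key))[1L]))
  }
  ids <- unique(df$array_id)
  arrays <- lapply(ids, function(a) {
    sub <- df[df$array_id == a, ]
    detector_array(a, as.numeric(sub$x_m), as.numeric(sub$y_m),
                   detector_id = sub$detector_id,
                   n_occasions = n_occasions)
  })
  names(arrays) <- ids
  arrays
}

#' Write a detector layout table
#'
#' @param arrays A [detector_array] or list of them.
#' @param path Output CSV path.
#' @export
write_traps <- function(arrays, path) {
  if (inherits(arrays, "detector_array")) arrays <- list(arrays)
  rows <- lapply(arrays, function(a) {
    data.frame(array_id = a$array_id, detector_id = a$detectors$id,
               x_m = a$detectors$x, y_m = a$detectors$y,
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a detection-event table
#'
#' CSV columns: `array_id`, `animal_id`, `occasion` (1-based integer),
#' `detector_id`; one row per detection event. Duplicate
#' (animal, occasion, detector) rows, unknown detectors and out-of-range
#' occasions are errors with row numbers.
#'
#' @param path File path.
#' @param arrays Named list of [detector_array] the detections resolve
#'   against.
#' @return Named list of [capture_data], one per array in `arrays`
#'   (arrays with no detections get empty capture sets).
#' @export
read_captures <- function(path, arrays) {
  if (inherits(arrays, "detector_array")) {
    arrays <- stats::setNames(list(arrays), arrays$array_id)
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("array_id", "animal_id", "occasion", "detector_id")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("capture file missing column(s): ", paste(miss, collapse = ", "))
  }
  unknown <- !(df$array_id %in% names(arrays))
  if (any(unknown)) {
    stop(sprintf("capture file references unknown array '%s' at data row %d",
                 df$array_id[which(unknown)[1L]], which(unknown)[1L]))
  }
  out <- lapply(names(arrays), function(a) {
    sub <- df[df$array_id == a, ]
    arr <- arrays[[a]]
    if (nrow(sub)) {
      badk <- !(sub$detector_id %in% arr$detectors$id)
      if (any(badk)) {
        stop(sprintf("detection at unknown detector '%s' (array %s) at data row %d",
                     sub$detector_id[which(badk)[1L]], a,
                     match(rownames(sub)[which(badk)[1L]], rownames(df))))
      }
      occ <- suppressWarnings(as.integer(sub$occasion))
      if (any(is.na(occ)) || any(occ < 1L | occ > arr$n_occasions)) {
        stop(sprintf("occasion out of range 1..%d in array %s",
                     arr$n_occasions, a))
      }
      key <- paste(sub$animal_id, occ, sub$detector_id)
      if (anyDuplicated(key)) {
        stop(sprintf("duplicate detection row (array %s, animal %s)",
                     a, sub$animal_id[which(duplicated(key))[1L]]))
      }
    }
    capture_data(a, data.frame(animal = sub$animal_id,
                               occasion = as.integer(sub$occasion),
                               detector = sub$detector_id,
                               stringsAsFactors = FALSE), arr)
  })
  names(out) <- names(arrays)
  out
}

#' Write a detection-event table
#'
#' @param captures A [capture_data] or list of them.
#' @param path Output CSV path.
#' @export
write_captures <- function(captures, path) {
  if (inherits(captures, "capture_data")) captures <- list(captures)
  rows <- lapply(captures, function(cp) {
    if (!nrow(cp$events)) return(NULL)
    data.frame(array_id = cp$array_id, animal_id = cp$events$animal,
               occasion = cp$events$occasion,
               detector_id = cp$events$detector,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  df <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(array_id = character(0L), animal_id = character(0L),
               occasion = integer(0L), detector_id = character(0L))
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

run_config_keys <- c("scenario", "iterations", "seed", "out_dir",
                     "buffer_m", "cell_side_m", "sharing", "estimator",
                     "variance", "n_occasions", "analyses", "verbose")

#' Read a run configuration file
#'
#' YAML file whose keys mirror the simulation / fitting / combination
#' options of the package functions. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return Named list of class `"run_config"`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.list(cfg)) stop("config must be a YAML mapping")
  extra <- setdiff(names(cfg), run_config_keys)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "),
         "; known keys are: ", paste(run_config_keys, collapse = ", "))
  }
  structure(cfg, class = "run_config")
}

#' Write a run configuration file
#'
#' @param config A named list (or `run_config`) of options.
#' @param path Output YAML path.
#' @export
write_run_config <- function(config, path) {
  extra <- setdiff(names(config), run_config_keys)
  if (length(extra)) {
    stop("unknown config key(s): ", paste(extra, collapse = ", "))
  }
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}
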