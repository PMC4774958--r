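# Readers and writers for measurement tables, landmark files, the occurrence
# fixture and run configurations.

MEASUREMENT_COLUMNS <- c("species", "activity", "size_class", "feather_id",
                         "position", "serration_index", "inclination_deg",
                         "tip_displacement_deg", "length_mm")

#' Read a long-format measurement table
#'
#' One row per measured serration.  Every record is validated (numeric
#' fields, vane position in 0.2/0.4/0.6/0.8, positive length); validation
#' errors carry the offending row number and field.
#'
#' @param path CSV file with the columns `species`, `activity`, `size_class`,
#'   `feather_id`, `position`, `serration_index`, `inclination_deg`,
#'   `tip_displacement_deg`, `length_mm`.
#' @return A validated data.frame of measurement records.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("measurement file not found: ", path)
  d <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(MEASUREMENT_COLUMNS, names(d))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  d <- d[MEASUREMENT_COLUMNS]
  num <- c("feather_id", "position", "serration_index", "inclination_deg",
           "tip_displacement_deg", "length_mm")
  for (col in num) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v))
    if (length(bad))
      stop("row ", bad[1], ": non-numeric value in '", col, "'")
    d[[col]] <- v
  }
  bad <- which(!(d$position %in% POSITIONS))
  if (length(bad))
    stop("row ", bad[1], ": position ", d$position[bad[1]],
         " is not one of ", paste(POSITIONS, collapse = "/"))
  bad <- which(d$length_mm <= 0)
  if (length(bad))
    stop("row ", bad[1], ": length_mm must be > 0")
  d
}

#' Write a measurement table
#'
#' Numeric columns are written with 17 significant digits so that
#' [read_measurements()] round-trips every value exactly.
#'
#' @param dataset a measurement table.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(dataset, path) {
  d <- dataset[MEASUREMENT_COLUMNS]
  for (col in c("inclination_deg", "tip_displacement_deg", "length_mm"))
    d[[col]] <- sprintf("%.17g", d[[col]])
  write.csv(d, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Serration occurrence matrix across wing feathers
#'
#' The packaged presence/absence table of leading-edge serrations on the
#' investigated wing feathers (10th--7th primaries, 3rd alula, 10th greater
#' primary covert) of the seven owl species.
#'
#' @return data.frame: rows species, logical columns `P10`, `P9`, `P8`, `P7`,
#'   `Alula3`, `gpc10`.
#' @export
#' @examples
#' serrated_feathers("B. scandiacus", occurrence_matrix())
occurrence_matrix <- function() {
  path <- system.file("extdata", "occurrence_matrix.csv",
                      package = "serrmorph", mustWork = TRUE)
  d <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  rownames(d) <- d$species
  m <- d[setdiff(names(d), "species")]
  m[] <- lapply(m, function(col) col == "+")
  m
}

#' Feathers of a species carrying serrations
#'
#' @param species species label as in [species_table()].
#' @param matrix occurrence matrix from [occurrence_matrix()].
#' @return Character vector of feather labels with serrations present, in
#'   column order.
#' @export
serrated_feathers <- function(species, matrix = occurrence_matrix()) {
  if (!species %in% rownames(matrix))
    stop("unknown species: ", species)
  names(matrix)[unlist(matrix[species, ])]
}

#' Read digitized serration landmarks
#'
#' @param path CSV with columns `element_id`, `point_label` (`origin`,
#'   `separation`, `tip`, `path_1` ... `path_k`, optional `calamus_start` and
#'   `rachis_tip`), `x_mm`, `y_mm`, `wing_side`, optional logical `detached`.
#' @return Named list of [serration_landmarks()], one per element.
#' @export
read_landmarks <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("element_id", "point_label", "x_mm", "y_mm", "wing_side")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  out <- lapply(split(d, d$element_id), function(e) {
    pt <- function(lab) {
      r <- e[e$point_label == lab, ]
      if (nrow(r) != 1) stop("element ", e$element_id[1],
                             ": need exactly one '", lab, "' point")
      c(r$x_mm, r$y_mm)
    }
    frame_pts <- e$point_label %in% c("calamus_start", "rachis_tip")
    frame <- if (any(frame_pts)) {
      feather_frame(pt("calamus_start"), pt("rachis_tip"), e$wing_side[1])
    } else {
      feather_frame(c(0, -10), c(0, 10), e$wing_side[1])
    }
    pk <- e[grepl("^path_", e$point_label), ]
    path <- NULL
    if (nrow(pk)) {
      ord <- order(as.integer(sub("^path_", "", pk$point_label)))
      path <- rbind(pt("separation"),
                    as.matrix(pk[ord, c("x_mm", "y_mm")]),
                    pt("tip"))
      dimnames(path) <- NULL
    }
    detached <- if ("detached" %in% names(e)) isTRUE(as.logical(e$detached[1]))
                else TRUE
    serration_landmarks(frame, pt("origin"), pt("separation"), pt("tip"),
                        path = path, detached = detached)
  })
  out
}

#' Read a JSON run configuration
#'
#' @param path JSON file with any of the fields accepted by
#'   [run_pipeline()]'s `config` list.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
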