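#' Write a frequency heat map as PLY plus CSV companion
#'
#' The PLY carries the template surface with a per-vertex scalar
#' \code{frequency} (percent) and RGB colors from \code{\link{colorize}};
#' the CSV companion (same path with extension \code{.csv}) holds
#' \code{vertex_id}, \code{count}, \code{frequency}. Floats are formatted
#' at 6 significant digits so identical maps produce byte-identical files.
#'
#' @param map a \code{frequency_map} from \code{\link{accumulate_frequency}}.
#' @param path output PLY path.
#' @param comments extra PLY header comment lines (e.g. config hash).
#' @return Paths of the two files written, invisibly.
#' @export
write_frequency_map <- function(map, path, comments = character()) {
  stopifnot(inherits(map, "frequency_map"))
  mesh <- map$template
  if (length(map$count) != nrow(mesh$vertices))
    stop("map vertex count (", length(map$count), ") does not match template (",
         nrow(mesh$vertices), ")")
  rgb <- colorize(map)
  props <- data.frame(count = as.integer(map$count),
                      frequency = as.numeric(map$frequency),
                      red = rgb[, 1], green = rgb[, 2], blue = rgb[, 3])
  write_ply(mesh, path, vertex_props = props,
            comments = c(sprintf("fracmap3d %s map kind=%s n_cases=%d dilation_radius_mm=%s",
                                 fm_version(), map$kind, map$n_cases,
                                 fmt6(map$dilation_radius)),
                         "counting rule: binary per case per vertex",
                         comments))
  csv_path <- sub("\\.ply$", ".csv", path)
  if (identical(csv_path, path)) csv_path <- paste0(path, ".csv")
  df <- data.frame(vertex_id = seq_along(map$count),
                   count = as.integer(map$count),
                   frequency = fmt6(map$frequency))
  write.csv(df, csv_path, row.names = FALSE, quote = FALSE)
  invisible(c(ply = path, csv = csv_path))
}

#' Read a frequency-map CSV companion back into counts
#'
#' @param path the CSV written by \code{\link{write_frequency_map}}.
#' @return data.frame with vertex_id, count, frequency.
#' @export
read_frequency_map_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("vertex_id", "count", "frequency") %in% names(df)))
    stop("not a frequency-map CSV: ", path)
  df
}

cohort_levels <- list(sex = c("male", "female"),
                      side = c("left", "right"),
                      mechanism = c("MVA", "slip", "fall", "crushing"),
                      ao_class = c("33A", "33C"))

#' Read and validate a cohort table
#'
#' @param path CSV with columns case_id, age, sex, side, height, weight,
#'   bmi, mechanism, ao_class (extra metric columns are kept).
#' @return data.frame of case records.
#' @export
read_cohort_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(df) == 0L) {
    warning("cohort table is empty: ", path)
    return(df)
  }
  required <- c("case_id", "age", "sex", "side", "height", "weight", "bmi",
                "mechanism", "ao_class")
  missing <- setdiff(required, names(df))
  if (length(missing)) stop("cohort table missing column(s): ", paste(missing, collapse = ", "))
  for (col in names(cohort_levels)) {
    bad <- which(!df[[col]] %in% cohort_levels[[col]])
    if (length(bad))
      stop(sprintf("unknown %s level '%s' in row %d (allowed: %s)",
                   col, df[[col]][bad[1]], bad[1],
                   paste(cohort_levels[[col]], collapse = ", ")))
  }
  ok <- is.na(df$bmi) | is.na(df$weight) | is.na(df$height) |
    abs(df$bmi - df$weight / df$height^2) < 0.5
  if (!all(ok)) stop("bmi inconsistent with weight/height^2 in row ", which(!ok)[1])
  df
}

#' Write a cohort table
#' @param df cohort data.frame.
#' @param path output CSV.
#' @return \code{path}, invisibly.
#' @export
write_cohort_table <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], fmt6)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write simulation ground truth as JSON
#' @param gt a \code{ground_truth} object from \code{\link{simulate_fracture}}.
#' @param path output JSON path.
#' @return \code{path}, invisibly.
#' @export
write_ground_truth <- function(gt, path) {
  if (length(gt$true_displacements) &&
      inherits(gt$true_displacements[[1]], "rigid_transform"))
    gt$true_displacements <- lapply(gt$true_displacements, transform_to_list)
  jsonlite::write_json(unclass(gt), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read simulation ground truth from JSON
#' @param path JSON written by \code{\link{write_ground_truth}}.
#' @return A \code{ground_truth} object.
#' @export
read_ground_truth <- function(path) {
  gt <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  for (nm in c("true_line_points", "true_comminution_points"))
    if (!is.null(gt[[nm]]) && !is.matrix(gt[[nm]]))
      gt[[nm]] <- matrix(unlist(gt[[nm]]), ncol = 3, byrow = TRUE)
  if (!is.null(gt$true_displacements))
    gt$true_displacements <- lapply(gt$true_displacements, function(tf)
      rigid_transform(matrix(as.numeric(tf$rotation), 3, 3, byrow = TRUE),
                      as.numeric(tf$translation)))
  class(gt) <- "ground_truth"
  gt
}

# 6-significant-digit formatting for reproducible text output
fmt6 <- function(x) formatC(x, digits = 6, format = "g")

fm_version <- function() as.character(utils::packageVersion("fracmap3d"))

# Polynomial rolling hash of a string (mod 2^31 - 1), for embedding a
# config fingerprint in outputs.
fm_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

fm_log <- function(fmt, ...) message(sprintf(paste0("[fracmap3d] ", fmt), ...))
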