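## Interchange I/O: TSV payloads with JSON metadata sidecars for every core
## data type, plus a schema-checked table reader.

sidecar_path <- function(path) paste0(path, ".json")

write_sidecar <- function(meta, path) {
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
}

read_sidecar <- function(path) {
  sp <- sidecar_path(path)
  if (!file.exists(sp)) stop("missing metadata sidecar: ", sp)
  jsonlite::read_json(sp, simplifyVector = TRUE)
}

#' Read a delimited table against a schema
#'
#' Reads a TSV/CSV with a header and checks that every schema column is
#' present and of the declared type, with errors naming the offending
#' row and column.
#'
#' @param path file path.
#' @param schema named character vector mapping required column names to
#'   types (`"numeric"`, `"integer"`, `"character"`).
#' @param sep field separator (tab by default).
#' @return data frame with the columns coerced to the schema types.
#' @export
read_table <- function(path, schema, sep = "\t") {
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   colClasses = "character")
  missing <- setdiff(names(schema), names(df))
  if (length(missing))
    stop("missing column(s) in ", path, ": ", paste(missing, collapse = ", "))
  for (col in names(schema)) {
    raw <- df[[col]]
    val <- suppressWarnings(switch(schema[[col]],
      numeric = as.numeric(raw), integer = as.integer(raw),
      character = raw,
      stop("unknown schema type: ", schema[[col]])))
    bad <- which(is.na(val) & !is.na(raw) & !(raw %in% c("", "null")))
    if (length(bad))
      stop(sprintf("non-%s value '%s' at row %d, column '%s' of %s",
                   schema[[col]], raw[bad[1]], bad[1], col, path))
    df[[col]] <- val
  }
  df
}

#' Write and read particle track sets
#'
#' Tracks travel as a long TSV (`frame`, `id`, `x_A`, `y_A`; gaps as `NA`
#' rows) with a JSON sidecar (`<path>.json`) holding the fluence per frame,
#' tilt and hole geometry. The write-read round trip is the identity.
#'
#' @param tracks a [particle_tracks()] object.
#' @param path TSV path.
#' @return `read_tracks` returns a `particle_tracks`; `write_tracks`
#'   returns `path` invisibly.
#' @export
write_tracks <- function(tracks, path) {
  stopifnot(inherits(tracks, "particle_tracks"))
  df <- data.frame(
    frame = rep(seq_len(tracks$n_frames), tracks$n_particles),
    id = rep(seq_len(tracks$n_particles), each = tracks$n_frames),
    x_A = as.vector(tracks$x), y_A = as.vector(tracks$y))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  write_sidecar(list(fluence_per_frame = tracks$fluence_per_frame,
                     tilt_angle = tracks$tilt_angle,
                     tilt_axis = I(tracks$tilt_axis),
                     hole_center = I(tracks$hole_center),
                     hole_diameter = tracks$hole_diameter,
                     temperature_label = tracks$temperature_label), path)
  invisible(path)
}

#' @rdname write_tracks
#' @export
read_tracks <- function(path) {
  df <- read_table(path, c(frame = "integer", id = "integer",
                           x_A = "numeric", y_A = "numeric"))
  meta <- read_sidecar(path)
  nf <- max(df$frame); np <- max(df$id)
  x <- matrix(NA_real_, nf, np); y <- matrix(NA_real_, nf, np)
  x[cbind(df$frame, df$id)] <- df$x_A
  y[cbind(df$frame, df$id)] <- df$y_A
  particle_tracks(x, y, fluence_per_frame = meta$fluence_per_frame,
                  tilt_angle = meta$tilt_angle,
                  tilt_axis = unlist(meta$tilt_axis),
                  hole_center = unlist(meta$hole_center),
                  hole_diameter = meta$hole_diameter %||% NA_real_,
                  temperature_label = meta$temperature_label %||% NA_real_)
}

#' Write and read 1-D profiles and spectra
#'
#' Two-column TSV plus JSON sidecar. Diffraction profiles use columns
#' `q_invA`/`intensity`; EELS spectra use `energy_eV`/`counts`.
#'
#' @param profile a `radial_profile`.
#' @param spectrum an `eels_spectrum`.
#' @param path TSV path.
#' @return readers return the reconstructed object; writers return `path`
#'   invisibly.
#' @export
write_profile <- function(profile, path) {
  stopifnot(inherits(profile, "radial_profile"))
  write.table(data.frame(q_invA = profile$q, intensity = profile$intensity),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  write_sidecar(list(calibration = profile$calibration, frame = profile$frame,
                     fluence = profile$fluence, units = profile$units), path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_profile <- function(path) {
  df <- read_table(path, c(q_invA = "numeric", intensity = "numeric"))
  meta <- read_sidecar(path)
  as_radial_profile(df$q_invA, df$intensity,
                    calibration = meta$calibration %||% NA_real_,
                    frame = meta$frame %||% NA_integer_,
                    fluence = meta$fluence %||% NA_real_,
                    units = meta$units %||% "A^-1")
}

#' @rdname write_profile
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "eels_spectrum"))
  write.table(data.frame(energy_eV = spectrum$energy, counts = spectrum$counts),
              path, sep = "\t", row.names = FALSE, quote = FALSE)
  write_sidecar(list(temperature_label = spectrum$temperature_label), path)
  invisible(path)
}

#' @rdname write_profile
#' @export
read_spectrum <- function(path) {
  df <- read_table(path, c(energy_eV = "numeric", counts = "numeric"))
  meta <- read_sidecar(path)
  eels_spectrum(df$energy_eV, df$counts,
                temperature_label = meta$temperature_label %||% NA_real_)
}

#' Write and read per-frame FSC series
#'
#' Multi-column TSV (`q`, `fsc_frame1` ... `fsc_frameM`) with a JSON
#' sidecar holding the fluence per frame.
#'
#' @param fsc an [fsc_series()].
#' @param path TSV path.
#' @export
write_fsc <- function(fsc, path) {
  stopifnot(inherits(fsc, "fsc_series"))
  df <- data.frame(q = fsc$q, t(fsc$fsc))
  names(df) <- c("q", paste0("fsc_frame", seq_len(fsc$n_frames)))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  write_sidecar(list(fluence_per_frame = fsc$fluence_per_frame), path)
  invisible(path)
}

#' @rdname write_fsc
#' @export
read_fsc <- function(path) {
  df <- read.delim(path, sep = "\t", check.names = FALSE)
  if (names(df)[1] != "q" || ncol(df) < 2L)
    stop("FSC table must have a 'q' column followed by per-frame columns")
  meta <- read_sidecar(path)
  if (is.null(meta$fluence_per_frame))
    stop("FSC sidecar missing 'fluence_per_frame'")
  fsc_series(df$q, unname(t(as.matrix(df[, -1, drop = FALSE]))),
             fluence_per_frame = meta$fluence_per_frame)
}

#' Write a motion summary as TSV
#'
#' Fluence column first, then the per-fluence metrics.
#'
#' @param summary a [motion_summary()] result.
#' @param path TSV path.
#' @export
write_motion_summary <- function(summary, path) {
  stopifnot(inherits(summary, "motion_summary"))
  write.table(as.data.frame(summary), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}
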