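PARTICLE_COLUMNS <- c("id", "x", "y", "z", "tdrot", "tilt", "narot",
                      "dx", "dy", "dz", "cc", "class", "halfset")

#' Particle metadata table
#'
#' Validates and classes a per-particle metadata table with the columns
#' `id` (integer), `x/y/z` (tomogram position, Angstrom), `tdrot/tilt/narot`
#' (Z-X-Z Euler angles, degrees), `dx/dy/dz` (shift, Angstrom), `cc` (last
#' correlation score in `[-1, 1]`, `NA` before scoring), `class` (integer,
#' 0 = unassigned) and `halfset` (`"A"`/`"B"`, `NA` if unassigned).
#' Positions use 0-based voxel conventions with x the fastest axis.
#'
#' @param df A data frame with the columns above.
#' @return A `particle_set` (a classed data frame).
#' @export
particle_set <- function(df) {
  missing_cols <- setdiff(PARTICLE_COLUMNS, names(df))
  if (length(missing_cols) > 0L)
    stop("particle table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  df <- df[, PARTICLE_COLUMNS]
  cc <- df$cc[!is.na(df$cc)]
  if (length(cc) && (any(cc < -1 - 1e-9) || any(cc > 1 + 1e-9)))
    stop("`cc` values outside [-1, 1]", call. = FALSE)
  hs <- df$halfset[!is.na(df$halfset)]
  if (length(hs) && !all(hs %in% c("A", "B")))
    stop("`halfset` must be \"A\" or \"B\"", call. = FALSE)
  df$id <- as.integer(df$id)
  df$class <- as.integer(df$class)
  class(df) <- c("particle_set", "data.frame")
  df
}

#' Read / write a particle table
#'
#' Tab-separated with a header line; angles in degrees, positions and
#' shifts in Angstrom. The round trip preserves all fields.
#'
#' @param path File path.
#' @return A `particle_set` (for the reader).
#' @export
read_particle_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE,
                          colClasses = c(
                            id = "integer", x = "numeric", y = "numeric",
                            z = "numeric", tdrot = "numeric",
                            tilt = "numeric", narot = "numeric",
                            dx = "numeric", dy = "numeric", dz = "numeric",
                            cc = "numeric", class = "integer",
                            halfset = "character"))
  particle_set(df)
}

#' @rdname read_particle_table
#' @param ps A `particle_set`.
#' @export
write_particle_table <- function(ps, path) {
  stopifnot(inherits(ps, "data.frame"))
  ps <- particle_set(as.data.frame(ps))
  utils::write.table(ps, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.particle_set <- function(x, ...) {
  cat(sprintf("<particle_set> %d particles, %d classed, mean cc %.3f\n",
              nrow(x), sum(x$class > 0, na.rm = TRUE),
              mean(x$cc, na.rm = TRUE)))
  NextMethod()
}
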