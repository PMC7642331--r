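#' Assemble a validated species trait table
#'
#' Builds the trait records the collision model consumes: morphometry, mean
#' group size and speeds. Missing speeds are filled from body mass via
#' [vmax_from_mass()] and [traverse_speed()]; supplied (field-measured)
#' speeds take precedence.
#'
#' @param name species name(s).
#' @param mass_kg body mass in kg.
#' @param body_length_m body length \eqn{L_a} in m.
#' @param body_width_m body width \eqn{W_a} in m.
#' @param mean_group_size mean group size (>= 1); 1 for solitary species.
#' @param vmax_ms maximum running speed in m/s; `NA` to compute from mass.
#' @param traverse_speed_ms road-crossing speed \eqn{V_a} in m/s; `NA` to use
#'   `vmax_ms / 6`.
#' @return a `species_traits` data frame with one row per species.
#' @examples
#' species_traits("chital", 65, 1.55, 0.6, 8.15)
#' @export
species_traits <- function(name, mass_kg, body_length_m, body_width_m,
                           mean_group_size = 1, vmax_ms = NA_real_,
                           traverse_speed_ms = NA_real_) {
  n <- length(name)
  df <- data.frame(
    name = as.character(name),
    mass_kg = as.numeric(mass_kg),
    body_length_m = as.numeric(body_length_m),
    body_width_m = as.numeric(body_width_m),
    mean_group_size = rep_len(as.numeric(mean_group_size), n),
    vmax_ms = rep_len(as.numeric(vmax_ms), n),
    traverse_speed_ms = rep_len(as.numeric(traverse_speed_ms), n),
    stringsAsFactors = FALSE
  )
  validate_species(df)
}

validate_species <- function(df) {
  num_cols <- c("mass_kg", "body_length_m", "body_width_m", "mean_group_size")
  for (col in num_cols) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad)) {
      stop(sprintf("species table: column '%s', row %d ('%s'): must be a positive number",
                   col, bad[1], df$name[bad[1]]), call. = FALSE)
    }
  }
  if (any(df$mean_group_size < 1)) {
    bad <- which(df$mean_group_size < 1)[1]
    stop(sprintf("species table: row %d ('%s'): mean_group_size must be >= 1",
                 bad, df$name[bad]), call. = FALSE)
  }
  fill <- is.na(df$vmax_ms)
  df$vmax_ms[fill] <- vmax_from_mass(df$mass_kg[fill])
  fill <- is.na(df$traverse_speed_ms)
  df$traverse_speed_ms[fill] <- traverse_speed(df$vmax_ms[fill])
  for (col in c("vmax_ms", "traverse_speed_ms")) {
    bad <- which(!is.finite(df[[col]]) | df[[col]] <= 0)
    if (length(bad)) {
      stop(sprintf("species table: column '%s', row %d ('%s'): must be a positive number",
                   col, bad[1], df$name[bad[1]]), call. = FALSE)
    }
  }
  bad <- which(df$traverse_speed_ms >= df$vmax_ms)
  if (length(bad)) {
    stop(sprintf("species table: row %d ('%s'): traverse_speed_ms must be below vmax_ms",
                 bad[1], df$name[bad[1]]), call. = FALSE)
  }
  class(df) <- c("species_traits", "data.frame")
  df
}

#' Read a species trait table from CSV
#'
#' Expects a header row with columns `name`, `mass_kg`, `body_length_m`,
#' `body_width_m`, `mean_group_size`; optional `vmax_ms` and
#' `traverse_speed_ms` columns override the allometric speeds.
#'
#' @param path path to a UTF-8 CSV file.
#' @return a `species_traits` data frame.
#' @export
read_species_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  required <- c("name", "mass_kg", "body_length_m", "body_width_m",
                "mean_group_size")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(sprintf("species table '%s': missing column(s) %s",
                 path, paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0) stop(sprintf("species table '%s' has no rows", path), call. = FALSE)
  for (opt in c("vmax_ms", "traverse_speed_ms")) {
    if (!opt %in% names(df)) df[[opt]] <- NA_real_
  }
  for (col in setdiff(names(df), "name")) {
    if (!is.numeric(df[[col]]) && !all(is.na(df[[col]]))) {
      stop(sprintf("species table '%s': column '%s' is not numeric", path, col),
           call. = FALSE)
    }
  }
  species_traits(df$name, df$mass_kg, df$body_length_m, df$body_width_m,
                 df$mean_group_size, df$vmax_ms, df$traverse_speed_ms)
}

#' Default study species: six large mammals of central Indian forest
#'
#' Morphometry and mean group sizes for chital (*Axis axis*), gaur
#' (*Bos gaurus*), leopard (*Panthera pardus*), sambar (*Rusa unicolor*),
#' tiger (*Panthera tigris*) and wild pig (*Sus scrofa*), the dominant
#' large-mammal community of dry deciduous tiger landscapes crossed by
#' national highways. Speeds are filled allometrically from body mass.
#'
#' @return a `species_traits` data frame with six rows.
#' @examples
#' default_species()
#' @export
default_species <- function() {
  species_traits(
    name = c("chital", "gaur", "leopard", "sambar", "tiger", "wild_pig"),
    mass_kg = c(65, 825, 49.25, 202.5, 173.75, 90),
    body_length_m = c(1.55, 3.3, 2.43, 2.1, 3.1, 2),
    body_width_m = c(0.6, 1, 0.4, 0.8, 0.6, 0.5),
    mean_group_size = c(8.15, 4.75, 1, 2.85, 1, 5.87)
  )
}

#' @export
print.species_traits <- function(x, ...) {
  cat(sprintf("Species traits (%d species)\n", nrow(x)))
  y <- as.data.frame(x)
  y$vmax_ms <- round(y$vmax_ms, 2)
  y$traverse_speed_ms <- round(y$traverse_speed_ms, 2)
  print(y, row.names = FALSE)
  invisible(x)
}
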