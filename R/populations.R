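#' Read a population table
#'
#' Reads a tab-delimited table of populations with geographic coordinates,
#' an optional group label and an optional comma-separated set of
#' geographic-neighbor population ids. The table is the geography backbone
#' of every sharing analysis: coordinates feed the geodesic distance matrix
#' and neighbor sets feed the subtraction-accumulation scan and the
#' permutation test.
#'
#' @param path Path to a tab-delimited file with a header naming at least
#'   `population_id`, `latitude` and `longitude`. Optional columns: `group`
#'   (free categorical label, e.g. "focal", "neighbor", "reference") and
#'   `neighbor_set` (comma-separated population ids; empty or absent means
#'   no neighbors).
#' @return A `pop_table`: a data frame with columns `population_id`,
#'   `latitude`, `longitude`, `group` and a list-column `neighbor_set` of
#'   character vectors.
#' @export
read_population_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("population_id", "latitude", "longitude")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    stop("population table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  lat <- as.numeric(df$latitude)
  lon <- as.numeric(df$longitude)
  bad_lat <- which(is.na(lat) | lat < -90 | lat > 90)
  if (length(bad_lat) > 0) {
    stop(sprintf("latitude out of range [-90, 90] at row %d (value '%s')",
                 bad_lat[1], df$latitude[bad_lat[1]]))
  }
  bad_lon <- which(is.na(lon) | lon < -180 | lon > 180)
  if (length(bad_lon) > 0) {
    stop(sprintf("longitude out of range [-180, 180] at row %d (value '%s')",
                 bad_lon[1], df$longitude[bad_lon[1]]))
  }
  ids <- df$population_id
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    stop("duplicate population_id: ", paste(unique(dup), collapse = ", "))
  }
  group <- if ("group" %in% names(df)) df$group else rep(NA_character_, nrow(df))
  nbs <- if ("neighbor_set" %in% names(df)) df$neighbor_set else rep("", nrow(df))
  neighbor_set <- lapply(nbs, function(x) {
    if (is.na(x) || !nzchar(trimws(x))) return(character(0))
    trimws(strsplit(x, ",", fixed = TRUE)[[1]])
  })
  pop_table(ids, lat, lon, group = group, neighbor_set = neighbor_set)
}

#' Construct a population table in code
#'
#' @param population_id Character vector of unique population ids.
#' @param latitude,longitude Numeric coordinates in degrees.
#' @param group Optional character vector of group labels.
#' @param neighbor_set Optional list of character vectors of neighbor ids.
#' @return A `pop_table` data frame.
#' @export
pop_table <- function(population_id, latitude, longitude,
                      group = NULL, neighbor_set = NULL) {
  population_id <- as.character(population_id)
  n <- length(population_id)
  if (is.null(group)) group <- rep(NA_character_, n)
  if (is.null(neighbor_set)) neighbor_set <- rep(list(character(0)), n)
  stopifnot(length(latitude) == n, length(longitude) == n,
            length(group) == n, length(neighbor_set) == n)
  if (anyDuplicated(population_id)) {
    stop("duplicate population_id: ",
         paste(unique(population_id[duplicated(population_id)]), collapse = ", "))
  }
  if (any(latitude < -90 | latitude > 90, na.rm = FALSE)) {
    stop("latitude out of range [-90, 90]")
  }
  if (any(longitude < -180 | longitude > 180)) {
    stop("longitude out of range [-180, 180]")
  }
  for (i in seq_len(n)) {
    nb <- neighbor_set[[i]]
    unknown <- setdiff(nb, population_id)
    if (length(unknown) > 0) {
      stop(sprintf("neighbor_set of '%s' references unknown id(s): %s",
                   population_id[i], paste(unknown, collapse = ", ")))
    }
    if (population_id[i] %in% nb) {
      stop(sprintf("population '%s' lists itself as a neighbor",
                   population_id[i]))
    }
  }
  out <- data.frame(population_id = population_id,
                    latitude = as.numeric(latitude),
                    longitude = as.numeric(longitude),
                    group = as.character(group),
                    stringsAsFactors = FALSE)
  out$neighbor_set <- neighbor_set
  class(out) <- c("pop_table", "data.frame")
  out
}

#' Geodesic distance matrix between populations
#'
#' Great-circle distances in kilometers between all population pairs,
#' computed with the haversine formula on a sphere of radius 6371.0 km.
#'
#' @param pops A `pop_table`.
#' @return A symmetric numeric matrix (km) with zero diagonal, dimnames set
#'   to the population ids.
#' @export
geodesic_matrix <- function(pops) {
  lat <- pops$latitude * pi / 180
  lon <- pops$longitude * pi / 180
  n <- nrow(pops)
  d <- matrix(0, n, n, dimnames = list(pops$population_id, pops$population_id))
  R <- 6371.0
  for (i in seq_len(n)) {
    dlat <- lat - lat[i]
    dlon <- lon - lon[i]
    a <- sin(dlat / 2)^2 + cos(lat[i]) * cos(lat) * sin(dlon / 2)^2
    a <- pmin(pmax(a, 0), 1)
    d[i, ] <- 2 * R * asin(sqrt(a))
  }
  diag(d) <- 0
  (d + t(d)) / 2
}
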