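# Occurrence ingestion, deduplication and spatial thinning.

#' Read occurrence records from CSV
#'
#' Parses georeferenced presence records. Rows with missing or out-of-range
#' coordinates (longitude outside [-180, 180], latitude outside [-90, 90])
#' are skipped and counted in the attached report; valid rows keep their
#' input order.
#'
#' @param file CSV path.
#' @param lonField,latField column names holding longitude and latitude.
#' @param idField,dateField optional columns carried through.
#' @return data.frame with columns \code{lon}, \code{lat} (and \code{id},
#'   \code{date} if requested) plus a \code{"report"} attribute with
#'   \code{n_read}, \code{n_kept}, \code{n_skipped}.
#' @export
readOccurrences <- function(file, lonField = "lon", latField = "lat",
                            idField = NULL, dateField = NULL) {
  if (!file.exists(file)) stop("file not found: ", file)
  raw <- utils::read.csv(file, stringsAsFactors = FALSE)
  missing <- setdiff(c(lonField, latField, idField, dateField), names(raw))
  if (length(missing))
    stop("schema error: missing column(s): ", paste(missing, collapse = ", "))
  lon <- suppressWarnings(as.numeric(raw[[lonField]]))
  lat <- suppressWarnings(as.numeric(raw[[latField]]))
  ok <- !is.na(lon) & !is.na(lat) &
    lon >= -180 & lon <= 180 & lat >= -90 & lat <= 90
  out <- data.frame(lon = lon[ok], lat = lat[ok])
  if (!is.null(idField)) out$id <- raw[[idField]][ok]
  if (!is.null(dateField)) out$date <- raw[[dateField]][ok]
  attr(out, "report") <- list(n_read = nrow(raw), n_kept = sum(ok),
                              n_skipped = sum(!ok))
  if (nrow(out) == 0) warning("no valid occurrence records in ", file)
  out
}

#' Remove exact coordinate duplicates
#'
#' Keeps the first record of each exact (lon, lat) pair; order is otherwise
#' preserved.
#'
#' @param occ occurrence data.frame with \code{lon}, \code{lat} columns.
#' @return the deduplicated data.frame.
#' @export
deduplicate <- function(occ) {
  keep <- !duplicated(occ[, c("lon", "lat")])
  out <- occ[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Spatially thin occurrences to a minimum separation
#'
#' Greedy keep-first pass in record order: a record is retained iff its
#' great-circle (haversine, Earth radius 6371 km) distance to every
#' previously retained record is at least \code{radiusKm}. Guarantees no two
#' retained points are closer than \code{radiusKm}; used to reduce sampling
#' bias and avoid double-counting individuals.
#'
#' @param occ occurrence data.frame with \code{lon}, \code{lat} columns.
#' @param radiusKm minimum separation in kilometres (default 16).
#' @return the thinned data.frame with a \code{"report"} attribute
#'   (\code{n_in}, \code{n_kept}, \code{n_dropped}, \code{min_kept_dist_km}).
#' @export
thinOccurrences <- function(occ, radiusKm = 16) {
  stopifnot(radiusKm > 0)
  n <- nrow(occ)
  if (n <= 1) {
    out <- occ
    attr(out, "report") <- list(n_in = n, n_kept = n, n_dropped = 0L,
                                min_kept_dist_km = NA_real_)
    return(out)
  }
  pts <- as.matrix(occ[, c("lon", "lat")])
  keptIdx <- 1L
  for (i in 2:n) {
    d <- geosphere::distHaversine(pts[i, , drop = FALSE],
                                  pts[keptIdx, , drop = FALSE],
                                  r = 6371) # km
    if (all(d >= radiusKm)) keptIdx <- c(keptIdx, i)
  }
  out <- occ[keptIdx, , drop = FALSE]
  rownames(out) <- NULL
  minD <- if (length(keptIdx) > 1) {
    md <- Inf
    for (i in seq_along(keptIdx)[-1]) {
      d <- geosphere::distHaversine(pts[keptIdx[i], , drop = FALSE],
                                    pts[keptIdx[seq_len(i - 1)], , drop = FALSE],
                                    r = 6371)
      md <- min(md, min(d))
    }
    md
  } else NA_real_
  attr(out, "report") <- list(n_in = n, n_kept = length(keptIdx),
                              n_dropped = n - length(keptIdx),
                              min_kept_dist_km = minD)
  out
}

#' Write a thinning report as JSON
#'
#' @param occ a thinned occurrence set (output of [thinOccurrences()]).
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
writeThinReport <- function(occ, path) {
  rep <- attr(occ, "report")
  if (is.null(rep)) stop("no thinning report attached")
  jsonlite::write_json(rep, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write occurrences as CSV
#'
#' @param occ occurrence data.frame.
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
writeOccurrences <- function(occ, path) {
  utils::write.csv(occ, path, row.names = FALSE)
  invisible(path)
}
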