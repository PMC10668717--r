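#' Reference-grid cell of a point
#'
#' Maps coordinates to the 10 x 10 km reference grid by floor division.
#' Cells are half-open squares: a point on the southern/western edge of a
#' cell belongs to that cell.
#'
#' @param x,y coordinates.
#' @param units `"m"` or `"km"` — the unit of `x`/`y`.
#' @param cell_km cell side in km (default 10).
#' @return data frame with `easting_index`, `northing_index` and the
#'   rendered `cell_id` (`"10kmE{e}N{n}"`).
#' @examples
#' cell_of(432500, 2431200)          # metres -> 10kmE43N243
#' cell_of(15, 7, units = "km")      # km      -> 10kmE1N0
#' @export
cell_of <- function(x, y, units = c("m", "km"), cell_km = 10) {
  units <- match.arg(units)
  side <- if (units == "m") cell_km * 1000 else cell_km
  e <- floor(as.numeric(x) / side)
  n <- floor(as.numeric(y) / side)
  data.frame(easting_index = as.integer(e), northing_index = as.integer(n),
             cell_id = sprintf("%dkmE%dN%d", cell_km, as.integer(e), as.integer(n)),
             stringsAsFactors = FALSE)
}

#' Are two C2 signs independent observations?
#'
#' Two C2 signs count as independent when they fall on different calendar
#' dates, or lie more than `min_km` apart while not stemming from the same
#' track event (shared non-missing `track_id`).
#'
#' @param s1,s2 single-row data frames of classified signs.
#' @param min_km spatial independence threshold (default 1 km).
#' @return logical.
#' @export
c2_independent <- function(s1, s2, min_km = 1) {
  same_track <- !is.na(attr_col(s1, "track_id", NA_character_)) &&
    !is.na(attr_col(s2, "track_id", NA_character_)) &&
    attr_col(s1, "track_id", NA_character_) == attr_col(s2, "track_id", NA_character_)
  if (same_track) return(FALSE)
  if (as.Date(s1$date) != as.Date(s2$date)) return(TRUE)
  sqrt((s1$x - s2$x)^2 + (s1$y - s2$y)^2) > min_km
}

#' Confirm occurrence grid cells for a monitoring year
#'
#' A cell is confirmed when it holds at least one C1 sign, or at least two
#' mutually independent C2 signs, within the monitoring year. C3 and
#' discarded signs never contribute.
#'
#' @param classified output of [classify_signs()] (coordinates in km unless
#'   `units = "m"`).
#' @param year monitoring-year label, e.g. `"2015-2016"`.
#' @param units unit of the sign coordinates.
#' @param min_km C2 spatial-independence threshold in km.
#' @return an `occurrence_map`: list with `monitoring_year`, `cells` (data
#'   frame: cell id, indices, `n_C1`, `n_C2`, `confirmed`) and
#'   `evidence` (sign ids per confirmed cell).
#' @export
confirm_cells <- function(classified, year, units = c("km", "m"), min_km = 1) {
  units <- match.arg(units)
  s <- classified[!is.na(classified$monitoring_year) &
                    classified$monitoring_year == year &
                    classified$category %in% c("C1", "C2"), , drop = FALSE]
  empty <- data.frame(cell_id = character(0), easting_index = integer(0),
                      northing_index = integer(0), n_C1 = integer(0),
                      n_C2 = integer(0), confirmed = logical(0),
                      stringsAsFactors = FALSE)
  out <- structure(list(monitoring_year = year, cells = empty,
                        evidence = list()),
                   class = "occurrence_map")
  if (nrow(s) == 0) return(out)

  cc <- cell_of(s$x, s$y, units = units)
  s$cell_id <- cc$cell_id
  cells <- unique(cc)
  n_C1 <- n_C2 <- integer(nrow(cells))
  confirmed <- logical(nrow(cells))
  evidence <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sub <- s[s$cell_id == cells$cell_id[i], , drop = FALSE]
    n_C1[i] <- sum(sub$category == "C1")
    n_C2[i] <- sum(sub$category == "C2")
    ok <- n_C1[i] >= 1
    if (!ok && n_C2[i] >= 2) {
      c2 <- sub[sub$category == "C2", , drop = FALSE]
      for (a in seq_len(nrow(c2) - 1)) {
        for (b in seq((a + 1), nrow(c2))) {
          if (c2_independent(c2[a, , drop = FALSE], c2[b, , drop = FALSE],
                             min_km = min_km)) { ok <- TRUE; break }
        }
        if (ok) break
      }
    }
    confirmed[i] <- ok
    evidence[[i]] <- sub$sign_id
  }
  cells$n_C1 <- n_C1
  cells$n_C2 <- n_C2
  cells$confirmed <- confirmed
  cells <- cells[, c("cell_id", "easting_index", "northing_index",
                     "n_C1", "n_C2", "confirmed")]
  names(evidence) <- cells$cell_id
  out$cells <- cells
  out$evidence <- evidence[confirmed]
  out
}

#' Area of occurrence within the Alpine range
#'
#' 100 km² per confirmed cell whose centre lies inside the Alpine-range
#' polygon. Restricting by the cell centre keeps the count deterministic
#' without partial-intersection bookkeeping.
#'
#' @param map an `occurrence_map` from [confirm_cells()].
#' @param alpine_ring Alpine-range polygon (vertex matrix, km), or a
#'   `wolf_layout` whose `alpine` ring is used.
#' @param cell_km grid cell side (km).
#' @return area in km².
#' @export
area_of_occurrence <- function(map, alpine_ring, cell_km = 10) {
  stopifnot(inherits(map, "occurrence_map"))
  if (inherits(alpine_ring, "wolf_layout")) alpine_ring <- alpine_ring$alpine
  alpine_ring <- as_ring(alpine_ring)
  if (abs(polygon_area(alpine_ring)) < 1e-9) stop("empty Alpine-range polygon")
  cells <- map$cells[map$cells$confirmed, , drop = FALSE]
  if (nrow(cells) == 0) return(0)
  cx <- (cells$easting_index + 0.5) * cell_km
  cy <- (cells$northing_index + 0.5) * cell_km
  inside <- point_in_ring(cx, cy, alpine_ring)
  cell_km^2 * sum(inside)
}

#' Write an occurrence map's confirmed cells as GeoJSON squares
#'
#' @param map an `occurrence_map`.
#' @param path output file.
#' @param cell_km grid cell side (km).
#' @export
write_occurrence_geojson <- function(map, path, cell_km = 10) {
  stopifnot(inherits(map, "occurrence_map"))
  cells <- map$cells[map$cells$confirmed, , drop = FALSE]
  features <- lapply(seq_len(nrow(cells)), function(i) {
    e <- cells$easting_index[i]; n <- cells$northing_index[i]
    ring <- rect_ring(e * cell_km, n * cell_km,
                      (e + 1) * cell_km, (n + 1) * cell_km)
    list(type = "Feature",
         properties = list(cell_id = cells$cell_id[i],
                           monitoring_year = map$monitoring_year,
                           n_C1 = cells$n_C1[i], n_C2 = cells$n_C2[i]),
         geometry = list(type = "Polygon",
                         coordinates = list(ring_to_coords(ring))))
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
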