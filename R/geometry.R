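#' Planar study-region layouts
#'
#' A layout partitions a planar study region (coordinates in km) into
#' labelled country polygons and carries an "Alpine range" polygon used to
#' restrict the area-of-occurrence trend. Polygons are closed rings given as
#' two-column matrices of vertices (km); countries must tile the region
#' without overlap.
#'
#' @param countries named list of two-column vertex matrices (km), one ring
#'   per country.
#' @param alpine two-column vertex matrix: the Alpine-range ring.
#' @param region two-column vertex matrix bounding the whole study region.
#' @return an object of class `wolf_layout`.
#' @export
wolf_layout <- function(countries, alpine, region) {
  stopifnot(is.list(countries), length(countries) >= 1,
            !is.null(names(countries)), all(nzchar(names(countries))))
  countries <- lapply(countries, as_ring)
  structure(list(countries = countries, alpine = as_ring(alpine),
                 region = as_ring(region)),
            class = "wolf_layout")
}

as_ring <- function(m) {
  m <- as.matrix(m)
  stopifnot(ncol(m) == 2, nrow(m) >= 3)
  storage.mode(m) <- "double"
  # drop an explicitly repeated closing vertex; rings are implicitly closed
  if (all(m[1, ] == m[nrow(m), ]) && nrow(m) > 3) m <- m[-nrow(m), , drop = FALSE]
  m
}

#' Axis-aligned rectangular ring
#'
#' @param x0,y0,x1,y1 corners (km).
#' @return four-vertex polygon matrix.
#' @export
rect_ring <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

#' Default four-country Alpine-like layout
#'
#' A stylised west-to-east arc of four countries (FR, CH, IT, SI) on a
#' 640 x 320 km plane, with an interior Alpine-range polygon. Distances are
#' metric so the 10 km occurrence grid and territory circles behave as on a
#' LAEA plane; no real-world CRS is implied.
#'
#' @return a `wolf_layout`.
#' @export
alpine_layout <- function() {
  wolf_layout(
    countries = list(
      FR = rect_ring(0,   0,   220, 320),
      CH = rect_ring(220, 160, 420, 320),
      IT = rect_ring(220, 0,   420, 160),
      SI = rect_ring(420, 0,   640, 320)
    ),
    alpine = rect_ring(40, 40, 600, 280),
    region = rect_ring(0, 0, 640, 320)
  )
}

#' Test whether points fall inside a polygon ring
#'
#' @param x,y point coordinates (km).
#' @param ring two-column vertex matrix.
#' @return logical vector.
#' @export
point_in_ring <- function(x, y, ring) {
  ring <- as_ring(ring)
  bnd <- rbind(ring, ring[1, ])
  mgcv::in.out(bnd, cbind(as.numeric(x), as.numeric(y)))
}

#' Country label at each point
#'
#' Points on a shared border are assigned to the first country in layout
#' order; points outside every country get `NA`.
#'
#' @param x,y coordinates (km).
#' @param layout a `wolf_layout`.
#' @return character vector of country labels.
#' @export
country_of <- function(x, y, layout) {
  stopifnot(inherits(layout, "wolf_layout"))
  out <- rep(NA_character_, length(x))
  for (cn in names(layout$countries)) {
    hit <- is.na(out) & point_in_ring(x, y, layout$countries[[cn]])
    out[hit] <- cn
  }
  out
}

dist_point_segment <- function(px, py, ax, ay, bx, by) {
  vx <- bx - ax; vy <- by - ay
  len2 <- vx * vx + vy * vy
  t <- if (len2 == 0) 0 else pmin(1, pmax(0, ((px - ax) * vx + (py - ay) * vy) / len2))
  sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
}

#' Distance from points to a polygon (0 when inside)
#'
#' @param x,y coordinates (km).
#' @param ring polygon vertex matrix.
#' @return numeric vector of distances in km.
#' @export
dist_to_ring <- function(x, y, ring) {
  ring <- as_ring(ring)
  n <- nrow(ring)
  inside <- point_in_ring(x, y, ring)
  d <- rep(Inf, length(x))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    d <- pmin(d, dist_point_segment(x, y, ring[i, 1], ring[i, 2],
                                    ring[j, 1], ring[j, 2]))
  }
  d[inside] <- 0
  d
}

polygon_area <- function(ring) {
  ring <- as_ring(ring)
  x <- ring[, 1]; y <- ring[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Centroid of a polygon ring
#'
#' Uses the area-weighted polygon centroid; for degenerate rings (zero
#' area) falls back to the vertex mean.
#'
#' @param ring polygon vertex matrix.
#' @return length-2 numeric (x, y).
#' @export
polygon_centroid <- function(ring) {
  ring <- as_ring(ring)
  a <- polygon_area(ring)
  if (abs(a) < 1e-12) return(colMeans(ring))
  x <- ring[, 1]; y <- ring[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  cr <- x * ys - xs * y
  c(sum((x + xs) * cr), sum((y + ys) * cr)) / (6 * a)
}

ring_to_coords <- function(ring) {
  ring <- rbind(ring, ring[1, , drop = FALSE])
  lapply(seq_len(nrow(ring)), function(i) c(ring[i, 1], ring[i, 2]))
}

#' Write a layout as planar GeoJSON
#'
#' Emits a FeatureCollection of the country polygons plus the Alpine-range
#' polygon (property `role`). Coordinates are the layout's planar km; the
#' file is for interchange between the pipeline's own stages, not a
#' geodetic export.
#'
#' @param layout a `wolf_layout`.
#' @param path output file.
#' @export
write_layout_geojson <- function(layout, path) {
  stopifnot(inherits(layout, "wolf_layout"))
  feat <- function(ring, props) {
    list(type = "Feature", properties = props,
         geometry = list(type = "Polygon",
                         coordinates = list(ring_to_coords(ring))))
  }
  features <- c(
    lapply(names(layout$countries), function(cn)
      feat(layout$countries[[cn]], list(role = "country", name = cn))),
    list(feat(layout$alpine, list(role = "alpine_range")),
         feat(layout$region, list(role = "region")))
  )
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a layout written by [write_layout_geojson()]
#'
#' @param path GeoJSON file with `role`/`name` feature properties.
#' @return a `wolf_layout`.
#' @export
read_layout_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  stopifnot(identical(fc$type, "FeatureCollection"))
  countries <- list(); alpine <- NULL; region <- NULL
  for (f in fc$features) {
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(p) c(p[[1]], p[[2]])))
    role <- f$properties$role
    if (identical(role, "country")) countries[[f$properties$name]] <- ring
    else if (identical(role, "alpine_range")) alpine <- ring
    else if (identical(role, "region")) region <- ring
  }
  if (is.null(region)) stop("layout GeoJSON lacks a 'region' feature")
  if (is.null(alpine)) stop("layout GeoJSON lacks an 'alpine_range' feature")
  wolf_layout(countries, alpine, region)
}
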