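#' Convert geographic (azimuth/elevation) coordinates to unit vectors
#'
#' Directions in the fish-centred visual field use an East-North-Up geographic
#' convention: azimuth is the horizontal angle in degrees, zero directly
#' rostral and positive to the animal's right; elevation is the vertical angle
#' in degrees, zero in the horizontal plane and positive above. The Cartesian
#' frame is x = right (East), y = rostral (North), z = up, so
#' `u = (cos(el) sin(az), cos(el) cos(az), sin(el))`.
#'
#' @param azimuth Azimuth in degrees, in `[-180, 180]`.
#' @param elevation Elevation in degrees, in `[-90, 90]`.
#' @return A numeric matrix with one row per input direction and columns
#'   `x`, `y`, `z`; each row has unit norm.
#' @examples
#' geo_to_unit(90, 0)   # right lateral: (1, 0, 0)
#' geo_to_unit(0, 90)   # upper pole: (0, 0, 1)
#' @export
geo_to_unit <- function(azimuth, elevation) {
  if (any(!is.finite(azimuth)) || any(!is.finite(elevation))) {
    stop("azimuth and elevation must be finite", call. = FALSE)
  }
  if (any(azimuth < -180 - 1e-9 | azimuth > 180 + 1e-9)) {
    stop("azimuth must lie in [-180, 180] degrees", call. = FALSE)
  }
  if (any(elevation < -90 - 1e-9 | elevation > 90 + 1e-9)) {
    stop("elevation must lie in [-90, 90] degrees", call. = FALSE)
  }
  a <- azimuth * pi / 180
  b <- elevation * pi / 180
  cbind(x = cos(b) * sin(a), y = cos(b) * cos(a), z = sin(b))
}

#' Convert unit vectors to geographic coordinates
#'
#' Inverse of [geo_to_unit()]. Azimuth `-180` is normalised to `+180`; at the
#' poles (`|z| = 1`), where azimuth is degenerate, it is set to 0 by
#' convention so that round trips are deterministic.
#'
#' @param v A numeric matrix (or length-3 vector) of Cartesian components
#'   `x, y, z`, each row of approximately unit norm.
#' @param tol Tolerance on `|norm - 1|` before an error is raised.
#' @return A tibble with columns `azimuth`, `elevation` (degrees).
#' @export
unit_to_geo <- function(v, tol = 1e-6) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  nrm <- sqrt(rowSums(v^2))
  if (any(nrm < 1e-12)) stop("zero vector has no direction", call. = FALSE)
  if (any(abs(nrm - 1) > tol)) {
    stop("input rows must be unit vectors (within tol)", call. = FALSE)
  }
  v <- v / nrm
  el <- asin(pmin(1, pmax(-1, v[, 3]))) * 180 / pi
  az <- atan2(v[, 1], v[, 2]) * 180 / pi
  at_pole <- abs(abs(v[, 3]) - 1) < 1e-12
  az[at_pole] <- 0
  az[az <= -180 + 1e-12 & !at_pole] <- 180
  tibble::tibble(azimuth = unname(az), elevation = unname(el))
}

#' Great-circle angle between two directions
#'
#' @param az1,el1,az2,el2 Geographic coordinates (degrees) of the two
#'   directions; vectors are recycled.
#' @return Angle(s) in degrees, in `[0, 180]`.
#' @export
great_circle_angle <- function(az1, el1, az2, el2) {
  u <- geo_to_unit(az1, el1)
  w <- geo_to_unit(az2, el2)
  n <- max(nrow(u), nrow(w))
  u <- u[rep_len(seq_len(nrow(u)), n), , drop = FALSE]
  w <- w[rep_len(seq_len(nrow(w)), n), , drop = FALSE]
  d <- rowSums(u * w)
  acos(pmin(1, pmax(-1, d))) * 180 / pi
}

#' Fractional area of a spherical cap
#'
#' A cap of polar half-angle `theta` (the "stimulus diameter" convention of
#' disk-shaped stimuli divides the full planar angle by two to obtain this
#' half-angle) covers `(1 - cos(theta)) / 2` of the sphere: a half-angle of
#' 90 degrees is a hemisphere (50%), 60 degrees covers 25%.
#'
#' @param half_angle Polar half-angle of the cap in degrees, in `[0, 180]`.
#' @return Fraction of the total sphere surface area, in `[0, 1]`.
#' @export
cap_fraction <- function(half_angle) {
  if (any(!is.finite(half_angle)) || any(half_angle < 0 | half_angle > 180)) {
    stop("half_angle must lie in [0, 180] degrees", call. = FALSE)
  }
  (1 - cos(half_angle * pi / 180)) / 2
}

#' Fraction of the sphere between symmetric latitude circles
#'
#' The arena's top and bottom holes for the optical path limit LED coverage to
#' latitudes within +/- `lat_limit`. Removing the two polar caps leaves
#' `1 - 2 * cap_fraction(90 - lat_limit) = cos(90 - lat_limit)` of the sphere;
#' for the arena's 69-degree limit this is cos(21 deg) = 93.36%.
#'
#' @param lat_limit Latitude limit in degrees, in `[0, 90]`.
#' @return Fraction of the sphere surface in the band, in `[0, 1]`.
#' @export
band_fraction <- function(lat_limit) {
  if (any(!is.finite(lat_limit)) || any(lat_limit < 0 | lat_limit > 90)) {
    stop("lat_limit must lie in [0, 90] degrees", call. = FALSE)
  }
  1 - 2 * cap_fraction(90 - lat_limit)
}

#' Effective arena coverage after removing the keel strip
#'
#' The structural keel on the prime meridian spans `keel_span` degrees of
#' azimuth and carries no LEDs, reducing the latitude-band coverage
#' proportionally: `band_fraction(lat_limit) * (360 - keel_span) / 360`.
#'
#' @param lat_limit Latitude limit in degrees, in `[0, 90]`.
#' @param keel_span Azimuthal span of the keel in degrees, in `[0, 360]`.
#' @return Fraction of the sphere surface effectively coverable.
#' @export
effective_coverage <- function(lat_limit, keel_span) {
  if (any(!is.finite(keel_span)) || any(keel_span < 0 | keel_span > 360)) {
    stop("keel_span must lie in [0, 360] degrees", call. = FALSE)
  }
  band_fraction(lat_limit) * (360 - keel_span) / 360
}

#' Solid angle subtended by one square LED tile
#'
#' Projects a flat square tile of edge `D` mounted tangentially at distance
#' `R_S` onto the unit sphere and integrates the projected area numerically:
#' `Omega = int int (1 + x^2 + y^2)^(-3/2) dx dy` over
#' `|x|, |y| <= tan(atan(D / (2 R_S)))`, evaluated by Gauss-Legendre
#' quadrature. Agrees with the closed-form rectangular-pyramid solid angle to
#' better than 1e-6 sr.
#'
#' @param D Tile edge length, mm.
#' @param R_S Sphere radius, mm.
#' @param n_nodes Number of Gauss-Legendre nodes per axis.
#' @return Solid angle in steradian.
#' @export
tile_solid_angle <- function(D, R_S, n_nodes = 64) {
  if (!is.finite(D) || !is.finite(R_S) || D <= 0 || R_S <= 0) {
    stop("D and R_S must be positive", call. = FALSE)
  }
  h <- tan(atan(D / (2 * R_S)))
  gl <- gauss_legendre(n_nodes, -h, h)
  f <- outer(gl$x, gl$x, function(x, y) (1 + x^2 + y^2)^(-1.5))
  as.numeric(gl$w %*% f %*% gl$w)
}

# Gauss-Legendre nodes/weights on [a, b] via the Golub-Welsch eigenproblem.
gauss_legendre <- function(n, a = -1, b = 1) {
  k <- seq_len(n - 1)
  beta <- k / sqrt(4 * k^2 - 1)
  J <- diag(0, n)
  J[cbind(k, k + 1)] <- beta
  J[cbind(k + 1, k)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(x = (b - a) / 2 * x + (a + b) / 2, w = (b - a) / 2 * w)
}

#' Reflect a direction through one of the arena's mirror planes
#'
#' The three planes between the six hemispheres: `sagittal` (left/right,
#' azimuth negated), `horizontal` (up/down, elevation negated) and `coronal`
#' (front/rear, azimuth folded through the lateral meridian). Each reflection
#' is an involution and preserves great-circle angles.
#'
#' @param azimuth,elevation Direction(s) in degrees.
#' @param plane One of `"sagittal"`, `"horizontal"`, `"coronal"`.
#' @return A tibble with reflected `azimuth`, `elevation`.
#' @export
reflect_geo <- function(azimuth, elevation,
                        plane = c("sagittal", "horizontal", "coronal")) {
  plane <- match.arg(plane)
  az <- azimuth
  el <- elevation
  if (plane == "sagittal") {
    az <- -az
    az[az <= -180 + 1e-12] <- 180
  } else if (plane == "horizontal") {
    el <- -el
  } else {
    az <- ifelse(az >= 0, 180 - az, -180 - az)
  }
  tibble::tibble(azimuth = az, elevation = el)
}

#' Build a geometric model of the spherical LED arena
#'
#' Tiles are laid out procedurally on rings of constant latitude whose spacing
#' equals the tile's angular edge, packed without azimuthal overlap and
#' trimmed from the most polar rings inward until exactly `n_tiles` remain.
#' Each tile carries an 8x8 LED grid; LED directions are obtained by central
#' projection of the flat grid onto the sphere through the tile's tangent
#' basis (u_alpha pointing East, u_beta pointing North at the tile centre).
#' The layout reproduces the counts and angular scale of the physical arena,
#' not its exact CAD placement.
#'
#' @param sphere_radius Sphere radius R_S, mm.
#' @param tile_edge Tile edge length D, mm.
#' @param n_tiles Number of LED tiles.
#' @param leds_per_tile LEDs per tile (a perfect square).
#' @param keel_span Azimuthal span (degrees) of the LED-free keel strip,
#'   centred on the prime meridian behind the fish.
#' @return An object of class `okr_arena`: a list with scalar parameters and
#'   tibbles `tiles` (centre azimuth/elevation) and `leds` (per-LED
#'   azimuth/elevation and tile id).
#' @export
arena_model <- function(sphere_radius = 106.5, tile_edge = 21,
                        n_tiles = 232, leds_per_tile = 64,
                        keel_span = 30) {
  stopifnot(sphere_radius > 0, tile_edge > 0, n_tiles >= 0)
  grid_n <- round(sqrt(leds_per_tile))
  if (grid_n^2 != leds_per_tile) {
    stop("leds_per_tile must be a perfect square", call. = FALSE)
  }
  delta <- 2 * atan(tile_edge / (2 * sphere_radius)) * 180 / pi # angular edge
  n_rings <- floor(90 / delta)
  ring_lat <- (seq_len(2 * n_rings) - n_rings - 0.5) * delta
  tiles <- purrr::map_dfr(ring_lat, function(lat) {
    arc <- 360 - keel_span # azimuth degrees available outside the keel
    # each tile spans delta / cos(lat) degrees of azimuth at this latitude
    m <- max(0L, floor(arc * cos(lat * pi / 180) / delta))
    if (m == 0L) return(NULL)
    step <- arc / m
    az <- -arc / 2 + step * (seq_len(m) - 0.5)
    tibble::tibble(azimuth = az, elevation = lat)
  })
  tiles <- tiles[order(abs(tiles$elevation), abs(tiles$azimuth)), ]
  if (nrow(tiles) < n_tiles) {
    stop("ring layout cannot accommodate ", n_tiles, " tiles", call. = FALSE)
  }
  tiles <- tiles[seq_len(n_tiles), ]
  tiles$tile <- seq_len(n_tiles)

  # LED grid offsets in the tile plane, mm from tile centre
  off <- (seq_len(grid_n) - (grid_n + 1) / 2) / grid_n * tile_edge
  grid <- expand.grid(du = off, dv = off)
  leds <- purrr::pmap_dfr(
    tiles[, c("azimuth", "elevation", "tile")],
    function(azimuth, elevation, tile) {
      c0 <- geo_to_unit(azimuth, elevation)[1, ]
      basis <- tile_tangent_basis(azimuth, elevation)
      pts <- sphere_radius * matrix(c0, nrow(grid), 3, byrow = TRUE) +
        outer(grid$du, basis$u_alpha) + outer(grid$dv, basis$u_beta)
      pts <- pts / sqrt(rowSums(pts^2))
      g <- unit_to_geo(pts)
      g$tile <- tile
      g
    }
  )
  structure(
    list(
      sphere_radius = sphere_radius, tile_edge = tile_edge,
      n_tiles = n_tiles, leds_per_tile = leds_per_tile,
      keel_span = keel_span, tiles = tiles, leds = leds
    ),
    class = "okr_arena"
  )
}

# Orthonormal tangent basis at a direction: u_alpha east, u_beta north.
tile_tangent_basis <- function(azimuth, elevation) {
  a <- azimuth * pi / 180
  b <- elevation * pi / 180
  u_alpha <- c(cos(a), -sin(a), 0)
  u_beta <- c(-sin(b) * sin(a), -sin(b) * cos(a), cos(b))
  list(u_alpha = u_alpha, u_beta = u_beta)
}

#' Fraction of the sphere covered by the arena's LED tiles
#'
#' Sums the per-tile projected solid angle over all tiles:
#' `n_tiles * tile_solid_angle(D, R_S) / (4 pi)`. Gaps between tiles count as
#' uncovered, so this is the strict tiled-area estimate.
#'
#' @param arena An `okr_arena` from [arena_model()].
#' @return A tibble with `per_tile_sr` (solid angle of one tile, steradian)
#'   and `coverage` (fraction of the sphere covered by all tiles).
#' @export
arena_coverage <- function(arena) {
  stopifnot(inherits(arena, "okr_arena"))
  per_tile <- if (arena$n_tiles > 0) {
    tile_solid_angle(arena$tile_edge, arena$sphere_radius)
  } else 0
  tibble::tibble(
    per_tile_sr = per_tile,
    coverage = arena$n_tiles * per_tile / (4 * pi)
  )
}

#' @export
print.okr_arena <- function(x, ...) {
  cat("<okr_arena> R_S =", x$sphere_radius, "mm, D =", x$tile_edge, "mm,",
      x$n_tiles, "tiles x", x$leds_per_tile, "LEDs =",
      nrow(x$leds), "LEDs\n")
  invisible(x)
}

#' Serialise an arena model to JSON
#'
#' @param arena An `okr_arena`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly if written to file.
#' @export
arena_to_json <- function(arena, path = NULL) {
  stopifnot(inherits(arena, "okr_arena"))
  obj <- list(
    radius_mm = arena$sphere_radius, tile_edge_mm = arena$tile_edge,
    leds_per_tile = arena$leds_per_tile, keel_span_deg = arena$keel_span,
    tiles = arena$tiles
  )
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = 6)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
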