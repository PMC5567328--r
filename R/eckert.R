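# Eckert IV equal-area projection and 10 km grid indexing.
#
# The projection maps (lat, lon) on a sphere of radius R to
#   x = 2/sqrt(pi(4+pi)) * R * lambda * (1 + cos theta)
#   y = 2*sqrt(pi/(4+pi)) * R * sin theta
# where theta solves  theta + sin(theta)cos(theta) + 2 sin(theta)
#                       = (2 + pi/2) sin(phi).

# Authalic Earth radius (m): the sphere with the ellipsoid's surface area,
# the standard choice for equal-area grids.
#' @export
EARTH_RADIUS_AUTHALIC <- 6371007.181

# Solve the Eckert IV parallel equation for a vector of latitudes (radians).
# Damped Newton from theta0 = phi/2; the derivative 2cos(theta)(1+cos(theta))
# vanishes at the poles, so non-converged entries fall back to bisection.
eck4_theta <- function(phi, tol = 1e-14, max_iter = 50L) {
  rhs <- (2 + pi / 2) * sin(phi)
  theta <- phi / 2
  f <- function(t) t + sin(t) * cos(t) + 2 * sin(t) - rhs
  for (i in seq_len(max_iter)) {
    res <- f(theta)
    if (all(abs(res) < tol)) break
    dfd <- 2 * cos(theta) * (1 + cos(theta))
    step <- res / pmax(dfd, 1e-9)
    step <- pmax(pmin(step, 0.5), -0.5)  # damping
    theta <- theta - step
    theta <- pmax(pmin(theta, pi / 2), -pi / 2)
  }
  # The derivative vanishes at the poles, so the residual criterion is a
  # poor stopping rule there: bisect those entries to full double precision
  # (the bracket, not the residual, is the convergence measure).
  bad <- which(abs(f(theta)) >= tol | abs(phi) > 89 * pi / 180)
  for (k in bad) {
    lo <- -pi / 2; hi <- pi / 2
    flo <- lo + sin(lo) * cos(lo) + 2 * sin(lo) - rhs[k]
    for (i in 1:100) {
      mid <- (lo + hi) / 2
      fm <- mid + sin(mid) * cos(mid) + 2 * sin(mid) - rhs[k]
      if (fm == 0) break
      if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
    }
    theta[k] <- mid
  }
  # poles have the closed-form solution theta = +/- pi/2
  theta[abs(phi) == pi / 2] <- sign(phi[abs(phi) == pi / 2]) * pi / 2
  theta
}

#' Project geographic coordinates with the Eckert IV equal-area projection
#'
#' Pseudocylindrical equal-area projection on a sphere; the parallel
#' parameter is solved by damped Newton iteration (bisection fallback near
#' the poles) to a residual below 1e-12.
#'
#' @param lat,lon numeric vectors, decimal degrees; `lat` in \[-90, 90\],
#'   `lon` normalized internally to \[-180, 180). NA propagates.
#' @param R sphere radius in metres (default: authalic Earth radius
#'   6371007.181 m).
#' @return a `data.table` with columns `x`, `y` in metres.
#' @examples
#' eckert4_project(c(0, 45, 90), c(0, 10, 0))
#' @export
eckert4_project <- function(lat, lon, R = EARTH_RADIUS_AUTHALIC) {
  lat <- as.numeric(lat); lon <- as.numeric(lon)
  if (length(lat) != length(lon)) stop("lat and lon lengths differ")
  if (any(abs(lat) > 90, na.rm = TRUE)) {
    stop("latitude out of [-90, 90]")
  }
  if (any(!is.finite(lon) & !is.na(lon))) stop("non-finite longitude")
  lon <- ((lon + 180) %% 360) - 180
  phi <- lat * pi / 180
  lambda <- lon * pi / 180
  ok <- !is.na(phi) & !is.na(lambda)
  theta <- rep(NA_real_, length(phi))
  theta[ok] <- eck4_theta(phi[ok])
  cx <- 2 / sqrt(pi * (4 + pi))
  cy <- 2 * sqrt(pi / (4 + pi))
  data.table(
    x = cx * R * lambda * (1 + cos(theta)),
    y = cy * R * sin(theta)
  )
}

#' Assign projected points to equal-area grid cells
#'
#' Cells are axis-aligned squares anchored at the projection origin
#' (equator / central meridian); strict floor semantics put boundary points
#' in the cell to their lower left.
#'
#' @param xy a data.frame with columns `x`, `y` in metres (output of
#'   [eckert4_project()]).
#' @param cell_size cell edge in metres (default 10,000 = 10 km).
#' @return `data.table` with integer columns `eck4_i`, `eck4_j`.
#' @export
assign_cell <- function(xy, cell_size = 10000) {
  stopifnot(cell_size > 0)
  data.table(
    eck4_i = as.integer(floor(xy$x / cell_size)),
    eck4_j = as.integer(floor(xy$y / cell_size))
  )
}

#' Count spatially distinct occurrences
#'
#' Two occurrences are spatially distinct when they fall in different cells
#' of the global equal-area grid.  Records without coordinates are excluded
#' before counting.
#'
#' @param lat,lon coordinate vectors in decimal degrees (NA = absent).
#' @param cell_size cell edge in metres (default 10 km).
#' @param R sphere radius in metres.
#' @return integer: the number of distinct occupied grid cells.
#' @export
count_distinct_cells <- function(lat, lon, cell_size = 10000,
                                 R = EARTH_RADIUS_AUTHALIC) {
  keep <- !is.na(lat) & !is.na(lon)
  if (!any(keep)) return(0L)
  cells <- assign_cell(eckert4_project(lat[keep], lon[keep], R), cell_size)
  nrow(unique(cells))
}

# Distinct-cell count per species in one pass; records with empty species or
# missing coordinates are ignored.  Returns a data.table(species, n_cells).
distinct_cells_by_species <- function(dt, cell_size = 10000,
                                      R = EARTH_RADIUS_AUTHALIC) {
  sub <- dt[nzchar(species) & !is.na(lat) & !is.na(lon) & !space_issue]
  if (nrow(sub) == 0L) {
    return(data.table(species = character(), n_cells = integer()))
  }
  xy <- eckert4_project(sub$lat, sub$lon, R)
  cells <- assign_cell(xy, cell_size)
  sub <- data.table(species = sub$species, cells)
  sub[, .(n_cells = nrow(unique(.SD))), by = species,
      .SDcols = c("eck4_i", "eck4_j")]
}
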