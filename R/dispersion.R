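# Hourly unit-emission dispersion kernels.
#
# The plume model is a ground-level Gaussian with full ground reflection,
# lateral/vertical spread from the Briggs (1973) open-country sigma curves,
# and a Pasquill stability class diagnosed from surface sensible heat flux
# and 10 m wind speed. Releases and receptors are at ground level (kerbside
# context; no plume rise for road traffic). A 10 m road source is a
# midpoint-rule quadrature of point sources along its axis.

#' Wind-speed floor applied to calm hours, m s-1
#' @keywords internal
WIND_FLOOR <- 0.5

#' Validate an hourly meteorology table
#'
#' Required columns: `timestamp` (POSIXct, UTC), `u10` (wind speed at 10 m,
#' m s-1), `wdir` (direction the wind comes from, deg from north), `temp`
#' (K), `shf` (surface sensible heat flux, W m-2), `pblh` (boundary-layer
#' height, m).
#'
#' @param met data.frame of hourly meteorology
#' @return the validated data.frame (invisibly unchanged)
#' @export
validate_met <- function(met) {
  need <- c("timestamp", "u10", "wdir", "temp", "shf", "pblh")
  miss <- setdiff(need, names(met))
  if (length(miss)) stop("met table missing columns: ", paste(miss, collapse = ", "))
  if (any(met$u10 < 0, na.rm = TRUE)) stop("u10 must be non-negative")
  if (any(met$pblh <= 0, na.rm = TRUE)) stop("pblh must be positive")
  if (any(met$temp <= 0, na.rm = TRUE)) stop("temp must be positive (kelvin)")
  met
}

# parse ISO-8601 timestamps ("2006-01-02T00:00:00Z" or space-separated), UTC
parse_utc <- function(x) {
  if (inherits(x, "POSIXct")) return(x)
  out <- as.POSIXct(x, tz = "UTC",
                    tryFormats = c("%Y-%m-%dT%H:%M:%SZ", "%Y-%m-%dT%H:%M:%S",
                                   "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M",
                                   "%Y-%m-%d"))
  out
}

#' Read hourly meteorology from CSV
#' @param path CSV with columns timestamp, u10, wdir, temp, shf, pblh
#' @return validated data.frame; timestamps parsed as UTC
#' @export
read_met_csv <- function(path) {
  met <- utils::read.csv(path, stringsAsFactors = FALSE)
  met$timestamp <- parse_utc(met$timestamp)
  validate_met(met)
}

#' Diagnose a Pasquill stability class from surface fluxes
#'
#' A simple lookup in (sensible heat flux, wind speed): strong daytime
#' heating with light wind gives unstable classes (A-C), near-zero flux or
#' strong wind gives neutral (D), and nocturnal negative flux with light
#' wind gives stable classes (E, F).
#'
#' @param shf surface sensible heat flux, W m-2
#' @param u10 wind speed at 10 m, m s-1
#' @return one of "A".."F"
#' @export
stability_class <- function(shf, u10) {
  n <- max(length(shf), length(u10))
  shf <- rep_len(shf, n); u10 <- rep_len(u10, n)
  out <- character(n)
  for (k in seq_len(n)) {
    out[k] <- if (shf[k] > 100) {
      if (u10[k] < 2) "A" else if (u10[k] < 4) "B" else if (u10[k] < 6) "C" else "D"
    } else if (shf[k] > 20) {
      if (u10[k] < 2) "B" else if (u10[k] < 5) "C" else "D"
    } else if (shf[k] >= -5) {
      "D"
    } else if (shf[k] >= -40) {
      if (u10[k] < 5) "E" else "D"
    } else {
      if (u10[k] < 3) "F" else if (u10[k] < 5) "E" else "D"
    }
  }
  out
}

# Briggs (1973) open-country sigma curves, metres, x = downwind distance m
briggs_sigma <- function(x, class) {
  sy <- switch(class,
    A = 0.22 * x / sqrt(1 + 1e-4 * x),
    B = 0.16 * x / sqrt(1 + 1e-4 * x),
    C = 0.11 * x / sqrt(1 + 1e-4 * x),
    D = 0.08 * x / sqrt(1 + 1e-4 * x),
    E = 0.06 * x / sqrt(1 + 1e-4 * x),
    F = 0.04 * x / sqrt(1 + 1e-4 * x),
    stop("unknown stability class: ", class))
  sz <- switch(class,
    A = 0.20 * x,
    B = 0.12 * x,
    C = 0.08 * x / sqrt(1 + 2e-4 * x),
    D = 0.06 * x / sqrt(1 + 1.5e-3 * x),
    E = 0.03 * x / (1 + 3e-4 * x),
    F = 0.016 * x / (1 + 3e-4 * x))
  list(sigma_y = sy, sigma_z = sz)
}

#' Plume spread parameters at a downwind distance
#'
#' Briggs open-country curves for the stability class diagnosed from the
#' met hour; the vertical spread is capped at the boundary-layer height.
#'
#' @param distance downwind distance, m (> 0, vectorised)
#' @param met one met hour (list or single data.frame row; see
#'   [validate_met()])
#' @return list with `sigma_y`, `sigma_z` in metres
#' @export
dispersion_sigmas <- function(distance, met) {
  if (any(distance <= 0)) stop("downwind distance must be positive")
  cls <- stability_class(met$shf[1], met$u10[1])
  s <- briggs_sigma(distance, cls)
  s$sigma_z <- pmin(s$sigma_z, met$pblh[1])
  s
}

# downwind/crosswind components of a receptor offset for wind FROM wdir
wind_frame <- function(dx, dy, wdir) {
  th <- wdir * pi / 180
  ux <- -sin(th); uy <- -cos(th)        # direction the wind blows TOWARD
  list(down = dx * ux + dy * uy, cross = -dx * uy + dy * ux)
}

#' Ground-level Gaussian point-source concentration
#'
#' Concentration at a ground-level receptor from a ground-level point
#' source with full ground reflection:
#' `chi = Q / (pi u sigma_y sigma_z) * exp(-cross^2 / (2 sigma_y^2))`,
#' zero upwind of the source plane. Wind speed is floored at 0.5 m s-1.
#'
#' @param dx,dy receptor offset from the source, m (map frame, vectorised)
#' @param met one met hour
#' @param Q emission rate, g s-1
#' @return concentration, ug m-3
#' @export
point_source_chi <- function(dx, dy, met, Q = 1) {
  if (Q < 0) stop("Q must be non-negative")
  u <- max(met$u10[1], WIND_FLOOR)
  w <- wind_frame(dx, dy, met$wdir[1])
  chi <- numeric(length(w$down))
  ok <- w$down > 0
  if (any(ok)) {
    s <- dispersion_sigmas(w$down[ok], met)
    chi[ok] <- Q / (pi * u * s$sigma_y * s$sigma_z) *
      exp(-w$cross[ok]^2 / (2 * s$sigma_y^2)) * 1e6
  }
  chi
}

# concentration at height z (used by the transect-flux mass check)
point_source_chi_z <- function(dx, dy, z, met, Q = 1) {
  u <- max(met$u10[1], WIND_FLOOR)
  w <- wind_frame(dx, dy, met$wdir[1])
  chi <- numeric(length(w$down))
  ok <- w$down > 0
  if (any(ok)) {
    s <- dispersion_sigmas(w$down[ok], met)
    chi[ok] <- Q / (pi * u * s$sigma_y * s$sigma_z) *
      exp(-w$cross[ok]^2 / (2 * s$sigma_y^2)) *
      exp(-z^2 / (2 * s$sigma_z^2)) * 1e6
  }
  chi
}

#' Street-canyon recirculation enhancement factor
#'
#' Multiplicative enhancement applied inside a canyon footprint when the
#' wind crosses the canyon axis: `1 + c * H / W` for building height H and
#' street width W. Monotone in the aspect ratio H/W.
#'
#' @param height building height, m
#' @param width street width, m
#' @param c enhancement coefficient (default 2)
#' @return factor >= 1
#' @export
recirculation_factor <- function(height, width, c = 2) {
  stopifnot(height > 0, width > 0, c >= 0)
  1 + c * height / width
}

# smallest angle between the wind vector and an axis of given bearing (deg)
wind_axis_angle <- function(wdir, axis_bearing) {
  a <- abs((wdir - axis_bearing) %% 180)
  min(a, 180 - a)
}

#' Unit-rate concentration of one road source at a map-frame offset
#'
#' The canonical plume used both to populate kernels and as the direct
#' (kernel-free) evaluation path. A 10 m line source of `rate` g km-1 s-1
#' lying along the category's nominal axis is integrated by midpoint-rule
#' quadrature of point sources; for canyon categories the recirculation
#' factor is applied at receptors within half a street width of the axis
#' when the wind crosses the axis by more than `canyon_angle` degrees.
#' Concentrations are truncated to zero beyond `cutoff` metres from the
#' source.
#'
#' @param dx,dy receptor offset from the source midpoint, m (vectorised)
#' @param category road category (see [classify_category()])
#' @param met one met hour
#' @param rate line emission rate, g km-1 s-1
#' @param length source length, m
#' @param cutoff radial truncation distance, m (default 225)
#' @param n_quad number of quadrature points along the line
#' @param canyon_width,canyon_height,canyon_c,canyon_angle canyon model
#'   parameters (width/height m, enhancement coefficient, axis-crossing
#'   threshold deg)
#' @param apply_canyon apply the canyon enhancement for canyon categories
#'   (set FALSE to obtain the bare plume, e.g. before [canyon_adjust()])
#' @return concentration, ug m-3
#' @export
source_chi <- function(dx, dy, category, met, rate = 1, length = 10,
                       cutoff = 225, n_quad = 11,
                       canyon_width = 30, canyon_height = 25,
                       canyon_c = 2, canyon_angle = 30, apply_canyon = TRUE) {
  stopifnot(category %in% ROAD_CATEGORIES)
  b <- CATEGORY_AXIS[[category]] * pi / 180
  ax <- sin(b); ay <- cos(b)
  Q_each <- rate * (length / 1000) / n_quad
  s_off <- length * ((seq_len(n_quad) - 0.5) / n_quad - 0.5)
  chi <- 0
  for (s in s_off) {
    chi <- chi + point_source_chi(dx - s * ax, dy - s * ay, met, Q_each)
  }
  if (apply_canyon && startsWith(category, "canyon") &&
      wind_axis_angle(met$wdir[1], CATEGORY_AXIS[[category]]) > canyon_angle) {
    cross_axis <- abs(dx * ay - dy * ax)
    f <- recirculation_factor(canyon_height, canyon_width, canyon_c)
    chi <- chi * ifelse(cross_axis <= canyon_width / 2, f, 1)
  }
  chi[dx^2 + dy^2 > cutoff^2] <- 0
  chi
}

#' Build a unit-emission kernel for one road category and hour
#'
#' Evaluates the unit-rate (1 g km-1 s-1) 10 m road source concentration on
#' a square 5 m lattice of map-frame offsets extending 225 m from the
#' source midpoint (91 x 91 nodes), truncated to zero beyond 225 m radial
#' distance. Canyon categories are post-processed by [canyon_adjust()].
#'
#' @inheritParams source_chi
#' @param spacing kernel lattice spacing, m (default 5)
#' @param half_extent kernel half width, m (default 225; also the radial
#'   truncation distance)
#' @return an object of class `kernel_grid`: offsets vector, chi matrix
#'   (rows index x offsets, columns y offsets), met hour and parameters
#' @export
build_kernel <- function(category, met, spacing = 5, half_extent = 225,
                         length = 10, n_quad = 11,
                         canyon_width = 30, canyon_height = 25,
                         canyon_c = 2, canyon_angle = 30) {
  off <- seq(-half_extent, half_extent, by = spacing)
  g <- expand.grid(dx = off, dy = off)
  chi <- source_chi(g$dx, g$dy, category, met,
                    rate = 1, length = length, cutoff = half_extent,
                    n_quad = n_quad, apply_canyon = FALSE)
  kernel <- structure(
    list(category = category, spacing = spacing,
         half_extent = half_extent, offsets = off,
         chi = matrix(chi, nrow = length(off)), met = met,
         length = length, n_quad = n_quad,
         canyon_width = canyon_width, canyon_height = canyon_height,
         canyon_c = canyon_c, canyon_angle = canyon_angle),
    class = "kernel_grid")
  if (startsWith(category, "canyon")) {
    kernel <- canyon_adjust(kernel, category, met,
                            canyon_width = canyon_width,
                            canyon_height = canyon_height,
                            canyon_c = canyon_c, canyon_angle = canyon_angle)
  }
  kernel
}

#' Apply the street-canyon recirculation adjustment to a kernel
#'
#' Multiplies kernel nodes lying within half a street width of the canyon
#' axis by the recirculation factor when the wind crosses the axis by more
#' than the threshold angle; an along-axis wind leaves the kernel
#' unchanged. Only canyon categories are accepted.
#'
#' @param kernel a `kernel_grid` built without canyon enhancement
#' @param category canyon category (supplies the axis orientation)
#' @param met one met hour
#' @inheritParams source_chi
#' @return the adjusted `kernel_grid`
#' @export
canyon_adjust <- function(kernel, category, met,
                          canyon_width = 30, canyon_height = 25,
                          canyon_c = 2, canyon_angle = 30) {
  if (!startsWith(category, "canyon")) {
    stop("canyon_adjust applies only to canyon categories, got: ", category)
  }
  axis <- CATEGORY_AXIS[[category]]
  if (wind_axis_angle(met$wdir[1], axis) <= canyon_angle) return(kernel)
  b <- axis * pi / 180
  g <- expand.grid(dx = kernel$offsets, dy = kernel$offsets)
  cross_axis <- abs(-g$dx * cos(b) + g$dy * sin(b))
  f <- recirculation_factor(canyon_height, canyon_width, canyon_c)
  mult <- matrix(ifelse(cross_axis <= canyon_width / 2, f, 1),
                 nrow = length(kernel$offsets))
  kernel$chi <- kernel$chi * mult
  kernel
}

#' Sample a kernel at arbitrary map-frame offsets
#'
#' Bilinear interpolation of the 5 m kernel lattice; zero outside the
#' kernel extent. Offsets that land exactly on lattice nodes reproduce the
#' node values exactly.
#'
#' @param kernel a `kernel_grid`
#' @param dx,dy receptor offsets from the source midpoint, m (vectorised)
#' @return concentration, ug m-3
#' @export
kernel_chi <- function(kernel, dx, dy) {
  off <- kernel$offsets
  h <- kernel$spacing
  n <- length(off)
  fx <- (dx - off[1]) / h
  fy <- (dy - off[1]) / h
  out <- numeric(length(dx))
  ok <- fx >= 0 & fx <= n - 1 & fy >= 0 & fy <= n - 1
  if (!any(ok)) return(out)
  i <- pmin(floor(fx[ok]), n - 2)
  j <- pmin(floor(fy[ok]), n - 2)
  tx <- fx[ok] - i
  ty <- fy[ok] - j
  ch <- kernel$chi
  idx <- cbind(i + 1, j + 1)
  v00 <- ch[idx]
  v10 <- ch[idx + cbind(rep(1L, nrow(idx)), 0L)]
  v01 <- ch[idx + cbind(0L, rep(1L, nrow(idx)))]
  v11 <- ch[idx + 1L]
  out[ok] <- (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
  out
}

#' Build the kernel set for one hour
#'
#' One kernel per road category present, shared by every source of that
#' category for the hour.
#'
#' @param categories character vector of categories to build
#' @param met one met hour
#' @param ... passed to [build_kernel()]
#' @return named list of `kernel_grid`
#' @export
build_kernel_set <- function(categories, met, ...) {
  categories <- unique(categories)
  stats::setNames(lapply(categories, build_kernel, met = met, ...), categories)
}

#' Crosswind-integrated mass flux through a downwind transect
#'
#' Numerically integrates `u * chi(y, z)` over a vertical plane at a fixed
#' downwind distance from a unit road source. With no deposition and no
#' truncation the recovered flux equals the emitted mass rate; used as a
#' mass-conservation check on the plume formulation.
#'
#' @param distance downwind distance of the transect, m
#' @param met one met hour
#' @param rate line emission rate, g km-1 s-1
#' @param length source length, m
#' @param ny,nz quadrature resolution
#' @return mass flux through the transect, g s-1
#' @export
transect_mass_flux <- function(distance, met, rate = 1, length = 10,
                               ny = 801, nz = 401) {
  u <- max(met$u10[1], WIND_FLOOR)
  th <- met$wdir[1] * pi / 180
  ux <- -sin(th); uy <- -cos(th)       # downwind unit vector
  nx <- -uy; nyv <- ux                 # crosswind unit vector
  s <- dispersion_sigmas(distance + length, met)
  ymax <- 8 * s$sigma_y + length
  zmax <- min(8 * s$sigma_z, met$pblh[1] * 4)
  yy <- seq(-ymax, ymax, length.out = ny)
  zz <- seq(0, zmax, length.out = nz)
  dyq <- yy[2] - yy[1]; dzq <- zz[2] - zz[1]
  # quadrature over the 10 m line source, matching source_chi
  b <- 0; axx <- sin(b); axy <- cos(b)
  n_quad <- 11
  Q_each <- rate * (length / 1000) / n_quad
  s_off <- length * ((seq_len(n_quad) - 0.5) / n_quad - 0.5)
  flux <- 0
  for (z in zz) {
    dx <- distance * ux + yy * nx
    dy <- distance * uy + yy * nyv
    chi <- 0
    for (so in s_off) {
      chi <- chi + point_source_chi_z(dx - so * axx, dy - so * axy, z, met, Q_each)
    }
    w <- if (z == zz[1] || z == zz[nz]) 0.5 else 1
    flux <- flux + w * sum(chi) * dyq * dzq
  }
  flux * u * 1e-6   # ug m-3 -> g m-3
}
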