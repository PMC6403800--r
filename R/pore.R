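#' Construct a pore geometry from a z-grid of accessible areas
#'
#' A quasi-1D description of a channel: the electrolyte-accessible
#' cross-sectional area `A(z)` on a uniform axial grid, plus the bulk
#' electrolyte conductivity. The axial coordinate is in Angstrom with z = 0
#' at the trans beta-barrel mouth, increasing toward cis.
#'
#' @param z Uniform ascending z-grid, Angstrom.
#' @param area Accessible area at each z, square Angstrom (non-negative;
#'   zero flags a locally blocked pore).
#' @param conductivity Electrolyte conductivity, S/m.
#' @param regions Named list of length-2 z-ranges labelling pore regions.
#' @return A tibble of class `pore_geometry` with columns `z_A`, `area_A2`
#'   and attributes `conductivity_S_m`, `regions`.
#' @export
pore_geometry <- function(z, area, conductivity,
                          regions = alpha_hl_constants$regions) {
  if (length(z) != length(area) || length(z) < 2) {
    abort("`z` and `area` must be equal-length vectors (>= 2 points).")
  }
  dz <- diff(z)
  if (any(dz <= 0) || max(abs(dz - dz[1])) > 1e-8 * dz[1]) {
    abort("`z` must be a uniform ascending grid.")
  }
  if (any(area < 0)) abort("Areas must be non-negative.")
  if (any(area == 0)) warn("Geometry contains zero accessible area (blocked pore).")
  if (conductivity <= 0) abort("`conductivity` must be positive (S/m).")
  out <- tibble(z_A = as.numeric(z), area_A2 = as.numeric(area))
  class(out) <- c("pore_geometry", class(out))
  attr(out, "conductivity_S_m") <- conductivity
  attr(out, "regions") <- regions
  out
}

#' Parametric area profile of the alpha-hemolysin pore
#'
#' Piecewise-cylindrical idealization of alpha-HL: a beta-barrel of radius
#' 10 Angstrom on z in \[0, 44\], a constriction on \[44, 50\] whose area is
#' chosen so that the region volume equals 924 cubic Angstrom (radius about
#' 7.0 Angstrom), and a vestibule of radius 23 Angstrom on \[50, 100\], with
#' 2-Angstrom linear area tapers across the junctions.
#'
#' @param conductivity Electrolyte conductivity, S/m (default 20,
#'   representative of 2 M KCl at room temperature).
#' @param z_step Grid spacing, Angstrom.
#' @param taper Axial width of the linear junction tapers, Angstrom.
#' @return A `pore_geometry` tibble.
#' @examples
#' geom <- parametric_alpha_hl()
#' sqrt(min(geom$area_A2) / pi)  # constriction radius, ~7.0 Angstrom
#' @export
parametric_alpha_hl <- function(conductivity = 20, z_step = 0.5, taper = 2) {
  reg <- alpha_hl_constants$regions
  a_barrel <- pi * (alpha_hl_constants$barrel_diameter_A / 2)^2
  a_constr <- alpha_hl_constants$constriction_volume_A3 / diff(reg$constriction)
  a_vest <- pi * (alpha_hl_constants$vestibule_diameter_A / 2)^2
  h <- taper / 2
  j1 <- reg$constriction[1]; j2 <- reg$constriction[2]
  knots_z <- c(reg$barrel[1], j1 - h, j1 + h, j2 - h, j2 + h, reg$vestibule[2])
  knots_a <- c(a_barrel, a_barrel, a_constr, a_constr, a_vest, a_vest)
  z <- seq(reg$barrel[1], reg$vestibule[2], by = z_step)
  area <- stats::approx(knots_z, knots_a, xout = z, rule = 2)$y
  pore_geometry(z, area, conductivity, regions = reg)
}

#' Accessible area profile from atomic coordinates
#'
#' For each axial slab, the xy plane is rasterized on a square grid; a cell
#' is excluded when its center lies within `atom radius + probe` of any atom
#' whose z coordinate falls within half a slab of the slice. The accessible
#' area is the total area of open cells 4-connected to the pore axis (a
#' flood fill from `axis_xy`), which discards the exterior region and
#' disconnected voids. A slab whose axis cell is blocked reports zero area
#' with a warning.
#'
#' @param atoms Data frame with columns `x`, `y`, `z` (Angstrom) and
#'   `radius` (Angstrom), e.g. from [read_pore_pdb()]. May be empty if
#'   `xy_limits` and `z_range` are given.
#' @param z_step Slab thickness, Angstrom.
#' @param grid_step xy raster cell size, Angstrom.
#' @param probe Probe radius added to every atom radius, Angstrom (default
#'   1.4, a water molecule).
#' @param conductivity Electrolyte conductivity attached to the result, S/m.
#' @param axis_xy Seed point of the flood fill (the pore axis), Angstrom.
#' @param xy_limits Optional `c(xmin, xmax, ymin, ymax)` bounding the
#'   raster; defaults to the dilated atom extent.
#' @param z_range Optional `c(zmin, zmax)` for the slab centers; defaults to
#'   the atom z-extent.
#' @return A `pore_geometry` tibble.
#' @export
area_profile_from_coords <- function(atoms, z_step = 1, grid_step = 0.5,
                                     probe = 1.4, conductivity = 20,
                                     axis_xy = c(0, 0), xy_limits = NULL,
                                     z_range = NULL) {
  if (z_step <= 0 || grid_step <= 0) abort("`z_step` and `grid_step` must be positive.")
  atoms <- as_tibble(atoms)
  if (nrow(atoms) == 0 && (is.null(xy_limits) || is.null(z_range))) {
    abort("With no atoms, `xy_limits` and `z_range` are required.")
  }
  reff <- if (nrow(atoms) > 0) atoms$radius + probe else numeric(0)
  if (is.null(xy_limits)) {
    xy_limits <- c(min(atoms$x - reff), max(atoms$x + reff),
                   min(atoms$y - reff), max(atoms$y + reff))
  }
  if (is.null(z_range)) z_range <- range(atoms$z)
  xs <- seq(xy_limits[1] + grid_step / 2, xy_limits[2], by = grid_step)
  ys <- seq(xy_limits[3] + grid_step / 2, xy_limits[4], by = grid_step)
  zc <- seq(z_range[1], z_range[2], by = z_step)
  if (length(zc) < 2) zc <- c(z_range[1], z_range[1] + z_step)
  ax_i <- which.min(abs(xs - axis_xy[1]))
  ax_j <- which.min(abs(ys - axis_xy[2]))

  area <- vapply(zc, function(z0) {
    sel <- which(abs(atoms$z - z0) <= z_step / 2)
    blocked <- matrix(FALSE, length(xs), length(ys))
    for (k in sel) {
      r <- reff[k]
      ii <- which(abs(xs - atoms$x[k]) <= r)
      jj <- which(abs(ys - atoms$y[k]) <= r)
      if (length(ii) == 0 || length(jj) == 0) next
      d2 <- outer((xs[ii] - atoms$x[k])^2, (ys[jj] - atoms$y[k])^2, `+`)
      blocked[ii, jj] <- blocked[ii, jj] | (d2 <= r^2)
    }
    if (blocked[ax_i, ax_j]) {
      warn(sprintf("Slab at z = %.2f: axis blocked; reporting zero area.", z0))
      return(0)
    }
    n_open <- .flood_fill_count(!blocked, ax_i, ax_j)
    n_open * grid_step^2
  }, numeric(1))

  pore_geometry(zc, area, conductivity)
}

# 4-neighbour flood fill over a logical "open" matrix; returns the number of
# open cells reachable from (i0, j0).
.flood_fill_count <- function(open, i0, j0) {
  nx <- nrow(open); ny <- ncol(open)
  visited <- matrix(FALSE, nx, ny)
  stack <- integer(nx * ny)
  top <- 1L
  stack[1L] <- (j0 - 1L) * nx + i0
  visited[i0, j0] <- TRUE
  count <- 0L
  while (top > 0L) {
    id <- stack[top]; top <- top - 1L
    count <- count + 1L
    i <- ((id - 1L) %% nx) + 1L
    j <- ((id - 1L) %/% nx) + 1L
    if (i > 1L && open[i - 1L, j] && !visited[i - 1L, j]) {
      visited[i - 1L, j] <- TRUE; top <- top + 1L; stack[top] <- id - 1L
    }
    if (i < nx && open[i + 1L, j] && !visited[i + 1L, j]) {
      visited[i + 1L, j] <- TRUE; top <- top + 1L; stack[top] <- id + 1L
    }
    if (j > 1L && open[i, j - 1L] && !visited[i, j - 1L]) {
      visited[i, j - 1L] <- TRUE; top <- top + 1L; stack[top] <- id - nx
    }
    if (j < ny && open[i, j + 1L] && !visited[i, j + 1L]) {
      visited[i, j + 1L] <- TRUE; top <- top + 1L; stack[top] <- id + nx
    }
  }
  count
}

#' Series resistance of a pore from its area profile
#'
#' In the quasi-1D approximation the electric-field flux `E(z) A(z)` is
#' constant along the pore, so resistances of axial slices add in series:
#' `R = (1/sigma) * integral dz / A(z)`, evaluated with the trapezoidal rule
#' on the grid. Access (convergence) resistance at the pore mouths is not
#' included. Any zero area inside the integration range makes the
#' resistance infinite, signalled with a warning.
#'
#' @param geometry A `pore_geometry`.
#' @param z_range Optional `c(zmin, zmax)` restriction, Angstrom.
#' @return Resistance in Ohm.
#' @examples
#' g <- pore_geometry(seq(0, 100, 0.5), rep(pi * 100, 201), conductivity = 20)
#' pore_resistance(g)  # = L / (sigma pi r^2)
#' @export
pore_resistance <- function(geometry, z_range = NULL) {
  z <- geometry$z_A
  a <- geometry$area_A2
  if (!is.null(z_range)) {
    keep <- z >= z_range[1] - 1e-9 & z <= z_range[2] + 1e-9
    z <- z[keep]; a <- a[keep]
  }
  if (length(z) < 2) abort("Integration range covers fewer than 2 grid points.")
  if (any(a <= 0)) {
    warn("Zero accessible area inside the integration range: infinite resistance.")
    return(Inf)
  }
  sigma <- attr(geometry, "conductivity_S_m", exact = TRUE)
  f <- 1 / a
  integral <- sum(diff(z) * (f[-1] + f[-length(f)]) / 2)  # 1/Angstrom
  (integral * 1e10) / sigma                               # Ohm
}

#' Open-pore ionic current predicted by the geometry
#'
#' Ohmic response `I = dV / R` with `R` from [pore_resistance()], converted
#' to pA.
#'
#' @param geometry A `pore_geometry`.
#' @param voltage Transmembrane voltage, mV (signed).
#' @return Current in pA (signed like the voltage). Infinite resistance
#'   yields zero current with a warning.
#' @export
open_pore_current <- function(geometry, voltage) {
  r <- pore_resistance(geometry)
  if (!is.finite(r)) {
    warn("Infinite pore resistance: zero current.")
    return(0)
  }
  (voltage * 1e-3 / r) * 1e12
}

#' Debye screening length of a symmetric electrolyte
#'
#' `kappa^-1 = sqrt(eps_r eps_0 k_B T / (2 e^2 N_A I * 1000))` with the
#' ionic strength `I = (1/2) sum z_i^2 C_i` over both ion species of a
#' symmetric z:z salt at molar concentration `c_salt` (so `I = z^2 c_salt`).
#' The factor 1000 converts mol/L to mol/m^3.
#'
#' @param c_salt Salt concentration, M (positive).
#' @param valence Ion valence of the symmetric salt.
#' @param temperature Absolute temperature, K.
#' @param epsilon_r Relative permittivity of the electrolyte.
#' @return Debye length in Angstrom.
#' @examples
#' debye_length(2, 1, 300, 70)      # ~2 Angstrom at 2 M KCl
#' debye_length(0.1, 1, 298, 78.5)  # ~9.6 Angstrom
#' @export
debye_length <- function(c_salt, valence = 1, temperature = 300,
                         epsilon_r = 70) {
  if (c_salt <= 0 || temperature <= 0 || epsilon_r <= 0) {
    abort("`c_salt`, `temperature` and `epsilon_r` must be positive.")
  }
  ionic_strength <- valence^2 * c_salt  # M, both species of a z:z salt
  num <- epsilon_r * .const$eps0 * .const$k_B * temperature
  den <- 2 * .const$e^2 * .const$N_A * ionic_strength * 1000
  sqrt(num / den) * 1e10
}

#' @export
print.pore_geometry <- function(x, ...) {
  cat(sprintf(
    "<pore_geometry> %d points, z %.4g-%.4g A, area %.4g-%.4g A^2, sigma = %g S/m\n",
    nrow(x), min(x$z_A), max(x$z_A), min(x$area_A2), max(x$area_A2),
    attr(x, "conductivity_S_m")
  ))
  invisible(x)
}
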