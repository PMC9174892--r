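#' Analytic candy-cane aortic geometry
#'
#' Builds a voxelized thoracic-aorta-like tube: a vertical ascending limb, a
#' half-torus arch and a vertical descending limb, with a linearly tapering
#' vessel radius. The centerline is parameterized by arc length
#' `s` in `[0, 1]` from the aortic valve (`s = 0`) to the diaphragm level
#' (`s = 1`); every masked voxel stores the arc length of its nearest
#' centerline point, which later drives regional division and the axial flow
#' direction. Default dimensions give regional volumes close to a healthy
#' adult thoracic aorta (ascending about 35 ml, arch about 11 ml, descending
#' about 37 ml).
#'
#' @param voxel_mm isotropic voxel edge (mm).
#' @param ascending_mm length of the ascending limb (mm).
#' @param arch_radius_mm centerline radius of the half-torus arch (mm); `0`
#'   disables the arch and produces a straight tube of length
#'   `ascending_mm + descending_mm` (degenerate test geometry).
#' @param descending_mm length of the descending limb (mm).
#' @param radius_mm vessel lumen radius (mm): length-2 vector
#'   `c(at valve, at diaphragm)`, linearly interpolated in `s`.
#' @param grid_dim optional integer length-3 grid size; by default the grid
#'   is sized to fit the geometry plus `margin_vox` voxels of background.
#' @param margin_vox background margin (voxels) used when auto-sizing.
#' @return an object of class `aorta_geometry` with elements `mask` (logical
#'   3D array), `voxel_s` (numeric 3D array, `NA` outside the mask),
#'   `tangent` (list of three 3D arrays: unit axial direction), `radial_frac`
#'   (distance from centerline over local radius, in `[0, 1]`),
#'   `inlet` (logical 3D array: first voxel slab of the ascending limb),
#'   `centerline` (matrix of points, mm), `centerline_s`, `voxel_mm`, `dim`.
#' @export
aorta_geometry <- function(voxel_mm = 2.8, ascending_mm = 50,
                           arch_radius_mm = 27, descending_mm = 125,
                           radius_mm = c(11.2, 10.0),
                           grid_dim = NULL, margin_vox = 2L) {
  stopifnot(voxel_mm > 0, ascending_mm > 0, arch_radius_mm >= 0,
            descending_mm > 0, length(radius_mm) %in% c(1L, 2L))
  if (length(radius_mm) == 1L) radius_mm <- rep(radius_mm, 2L)
  if (any(radius_mm <= 0)) stop("vessel radius must be positive")
  r0 <- radius_mm[1]; r1 <- radius_mm[2]
  rmax <- max(radius_mm)
  La <- ascending_mm; Rc <- arch_radius_mm; Ld <- descending_mm
  straight <- Rc == 0
  L <- if (straight) La + Ld else La + pi * Rc + Ld

  # physical extents of the tube (mm), before margin
  if (straight) {
    x_lo <- -rmax; x_hi <- rmax
    z_lo <- 0; z_hi <- L
  } else {
    # ascending axis at x = 0; arch centre at x = -Rc; descending at x = -2*Rc
    x_lo <- -2 * Rc - rmax; x_hi <- rmax
    z_lo <- min(0, La - Ld); z_hi <- La + Rc + rmax
  }
  y_lo <- -rmax; y_hi <- rmax

  m <- margin_vox * voxel_mm
  if (is.null(grid_dim)) {
    grid_dim <- c(ceiling((x_hi - x_lo + 2 * m) / voxel_mm),
                  ceiling((y_hi - y_lo + 2 * m) / voxel_mm),
                  ceiling((z_hi - z_lo + 2 * m) / voxel_mm))
  }
  grid_dim <- as.integer(grid_dim)
  origin <- c(x_lo - m, y_lo - m, z_lo - m)
  # voxel-centre coordinates
  xs <- origin[1] + (seq_len(grid_dim[1]) - 0.5) * voxel_mm
  ys <- origin[2] + (seq_len(grid_dim[2]) - 0.5) * voxel_mm
  zs <- origin[3] + (seq_len(grid_dim[3]) - 0.5) * voxel_mm
  if (xs[length(xs)] < x_hi || zs[length(zs)] < z_hi ||
      xs[1] > x_lo || zs[1] > z_lo || ys[length(ys)] < y_hi) {
    stop("grid too small to contain the aorta geometry")
  }

  X <- array(xs, grid_dim)
  Y <- array(rep(ys, each = grid_dim[1]), grid_dim)
  Z <- array(rep(zs, each = grid_dim[1] * grid_dim[2]), grid_dim)

  big <- Inf
  dist <- array(big, grid_dim)
  arc <- array(NA_real_, grid_dim)
  tx <- array(0, grid_dim); ty <- array(0, grid_dim); tz <- array(0, grid_dim)

  take <- function(cand_d, cand_arc, cand_t) {
    sel <- which(cand_d < dist)
    dist[sel] <<- cand_d[sel]
    arc[sel] <<- cand_arc[sel]
    tx[sel] <<- cand_t[[1]][sel]
    ty[sel] <<- cand_t[[2]][sel]
    tz[sel] <<- cand_t[[3]][sel]
  }

  if (straight) {
    d <- sqrt(X^2 + Y^2)
    d[Z < 0 | Z > L] <- big
    take(d, Z, list(array(0, grid_dim), array(0, grid_dim),
                    array(1, grid_dim)))
  } else {
    # ascending limb: axis x = 0, y = 0, z in [0, La]
    d <- sqrt(X^2 + Y^2)
    d[Z < 0 | Z > La] <- big
    take(d, Z, list(array(0, grid_dim), array(0, grid_dim),
                    array(1, grid_dim)))
    # arch: half torus, centre (-Rc, 0, La), theta in [0, pi]
    u <- sqrt((X + Rc)^2 + (Z - La)^2)
    d <- sqrt((u - Rc)^2 + Y^2)
    d[Z < La] <- big
    theta <- atan2(pmax(Z - La, 0), X + Rc)
    take(d, La + Rc * theta,
         list(-sin(theta), array(0, grid_dim), cos(theta)))
    # descending limb: axis x = -2*Rc, y = 0, z in [La - Ld, La]
    d <- sqrt((X + 2 * Rc)^2 + Y^2)
    d[Z > La | Z < La - Ld] <- big
    take(d, La + pi * Rc + (La - Z),
         list(array(0, grid_dim), array(0, grid_dim), array(-1, grid_dim)))
  }

  s <- arc / L
  radius_at <- r0 + (r1 - r0) * pmin(pmax(s, 0), 1)
  mask <- is.finite(dist) & !is.na(s) & dist <= radius_at
  if (!any(mask)) stop("empty geometry: no voxel falls inside the vessel")

  voxel_s <- array(NA_real_, grid_dim); voxel_s[mask] <- s[mask]
  radial_frac <- array(NA_real_, grid_dim)
  radial_frac[mask] <- pmin(dist[mask] / radius_at[mask], 1)
  tangent <- list(x = array(0, grid_dim), y = array(0, grid_dim),
                  z = array(0, grid_dim))
  tangent$x[mask] <- tx[mask]; tangent$y[mask] <- ty[mask]
  tangent$z[mask] <- tz[mask]
  inlet <- mask & !is.na(arc) & arc <= voxel_mm

  # reference centerline sampled at ~1 mm
  n_cl <- max(2L, ceiling(L))
  s_cl <- seq(0, 1, length.out = n_cl)
  a_cl <- s_cl * L
  if (straight) {
    cl <- cbind(0, 0, a_cl)
  } else {
    cl <- matrix(NA_real_, n_cl, 3)
    i1 <- a_cl <= La
    cl[i1, ] <- cbind(0, 0, a_cl[i1])
    i2 <- a_cl > La & a_cl <= La + pi * Rc
    th <- (a_cl[i2] - La) / Rc
    cl[i2, ] <- cbind(-Rc + Rc * cos(th), 0, La + Rc * sin(th))
    i3 <- a_cl > La + pi * Rc
    cl[i3, ] <- cbind(-2 * Rc, 0, La - (a_cl[i3] - La - pi * Rc))
  }

  structure(list(mask = mask, voxel_s = voxel_s, tangent = tangent,
                 radial_frac = radial_frac, inlet = inlet,
                 centerline = cl, centerline_s = s_cl,
                 radius_mm = radius_mm, voxel_mm = voxel_mm,
                 dim = grid_dim, length_mm = L,
                 params = list(ascending_mm = La, arch_radius_mm = Rc,
                               descending_mm = Ld)),
            class = "aorta_geometry")
}

#' @export
print.aorta_geometry <- function(x, ...) {
  cat(sprintf("aorta geometry: %s grid @ %.1f mm, %d lumen voxels (%.1f ml), centerline %.0f mm\n",
              paste(x$dim, collapse = "x"), x$voxel_mm, sum(x$mask),
              mask_volume_ml(x), x$length_mm))
  invisible(x)
}

#' Volume of a voxel mask in millilitres
#'
#' @param geometry an `aorta_geometry`, or a logical array if `voxel_mm` is
#'   supplied.
#' @param voxel_mm voxel edge (mm), required when `geometry` is a bare array.
#' @return volume (ml).
#' @export
mask_volume_ml <- function(geometry, voxel_mm = NULL) {
  if (inherits(geometry, "aorta_geometry")) {
    sum(geometry$mask) * geometry$voxel_mm^3 / 1000
  } else {
    stopifnot(!is.null(voxel_mm))
    sum(geometry) * voxel_mm^3 / 1000
  }
}

#' Test 6-connectivity of a voxel mask
#'
#' Flood fill from an arbitrary masked voxel by iterative face-neighbour
#' dilation; the mask is connected iff the fill reaches every masked voxel.
#'
#' @param mask logical 3D array.
#' @return `TRUE` if the masked voxels form a single 6-connected component.
#' @export
mask_is_connected <- function(mask) {
  stopifnot(is.logical(mask), length(dim(mask)) == 3L)
  n <- sum(mask)
  if (n == 0L) return(TRUE)
  reach <- array(FALSE, dim(mask))
  reach[which(mask)[1]] <- TRUE
  repeat {
    grown <- reach | shift3(reach, 1, 1) | shift3(reach, -1, 1) |
      shift3(reach, 1, 2) | shift3(reach, -1, 2) |
      shift3(reach, 1, 3) | shift3(reach, -1, 3)
    grown <- grown & mask
    if (sum(grown) == sum(reach)) break
    reach <- grown
  }
  sum(reach) == n
}

# Shift a 3D logical/numeric array by one voxel along an axis, zero/FALSE fill.
shift3 <- function(a, by, axis) {
  d <- dim(a)
  out <- array(if (is.logical(a)) FALSE else 0, d)
  src <- lapply(d, seq_len)
  dst <- src
  if (by == 1) {
    dst[[axis]] <- 2:d[axis]; src[[axis]] <- 1:(d[axis] - 1)
  } else {
    dst[[axis]] <- 1:(d[axis] - 1); src[[axis]] <- 2:d[axis]
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Divide the thoracic aorta into ascending, arch and descending regions
#'
#' Cuts the masked tube at two arc-length positions: voxels with
#' `s < s1` form the ascending aorta (AAo), `s1 <= s < s2` the aortic arch
#' (AoA) and `s >= s2` the descending aorta (DAo); their union is the whole
#' thoracic aorta (TAo). Default cut points are calibrated so the default
#' geometry reproduces typical regional volume proportions
#' (about 35 : 11 : 37 ml).
#'
#' @param geometry an `aorta_geometry`.
#' @param s1,s2 arc-length cut points, `0 < s1 < s2 < 1`.
#' @return an object of class `aorta_regions`: `labels` (integer 3D array,
#'   1 = AAo, 2 = AoA, 3 = DAo, `NA` outside), `volumes_ml` (named, incl.
#'   TAo), `cuts`.
#' @export
divide_regions <- function(geometry, s1 = 0.376, s2 = 0.510) {
  stopifnot(inherits(geometry, "aorta_geometry"))
  if (!(s1 > 0 && s2 < 1 && s1 < s2)) {
    stop("region cuts must satisfy 0 < s1 < s2 < 1")
  }
  labels <- array(NA_integer_, geometry$dim)
  s <- geometry$voxel_s
  m <- geometry$mask
  labels[m & s < s1] <- 1L
  labels[m & s >= s1 & s < s2] <- 2L
  labels[m & s >= s2] <- 3L
  vv <- geometry$voxel_mm^3 / 1000
  counts <- tabulate(labels[m], nbins = 3L)
  volumes <- c(AAo = counts[1] * vv, AoA = counts[2] * vv,
               DAo = counts[3] * vv, TAo = sum(counts) * vv)
  structure(list(labels = labels, volumes_ml = volumes,
                 cuts = c(s1 = s1, s2 = s2), voxel_mm = geometry$voxel_mm),
            class = "aorta_regions")
}

#' @export
print.aorta_regions <- function(x, ...) {
  v <- x$volumes_ml
  cat(sprintf("aortic regions (cuts s1=%.3f, s2=%.3f): AAo %.1f ml | AoA %.1f ml | DAo %.1f ml | TAo %.1f ml\n",
              x$cuts[1], x$cuts[2], v["AAo"], v["AoA"], v["DAo"], v["TAo"]))
  invisible(x)
}

# Region names used throughout; index 4 is the whole thoracic aorta.
region_names <- function() c("AAo", "AoA", "DAo", "TAo")
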