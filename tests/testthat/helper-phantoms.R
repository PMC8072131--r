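# shared fixture builders; everything is generated in code at test time

straight_tube_phantom <- function(radius_um = 3, dim = c(100, 40, 40),
                                  seed = 1) {
  generate_niche_phantom(phantom_spec(
    dim = dim, spacing = c(1, 1, 1),
    vessels = data.frame(kind = "straight", radius_um = radius_um,
                         y_um = floor((dim[2] - 1) / 2),
                         z_um = floor((dim[3] - 1) / 2)),
    seed = seed
  ))
}

arc_tube_phantom <- function(radius_um = 3, seed = 1) {
  # semicircular arc: chord 99 um across x, bulge in y
  generate_niche_phantom(phantom_spec(
    dim = c(100, 62, 20), spacing = c(1, 1, 1),
    vessels = data.frame(kind = "arc", radius_um = radius_um,
                         y_um = 5, z_um = 10),
    seed = seed
  ))
}

sine_tube_phantom <- function(amplitude = 10, wavelength = 50, seed = 1) {
  generate_niche_phantom(phantom_spec(
    dim = c(100, 60, 20), spacing = c(1, 1, 1),
    vessels = data.frame(kind = "sine", radius_um = 3,
                         amplitude_um = amplitude, wavelength_um = wavelength,
                         y_um = 30, z_um = 10),
    seed = seed
  ))
}

# analytic sine-tube tortuosity by dense numerical quadrature, independent
# of make_centerline: arc length of y = A sin(2 pi x / L) over the chord
sine_tortuosity_quadrature <- function(amplitude, wavelength, chord) {
  f <- function(x) sqrt(1 + (amplitude * 2 * pi / wavelength *
                               cos(2 * pi * x / wavelength))^2)
  stats::integrate(f, 0, chord, subdivisions = 2000L,
                   rel.tol = 1e-10)$value / chord
}

# brute-force nearest-feature distance for every voxel of a small grid
brute_force_distance <- function(mask_arr, spacing) {
  d <- dim(mask_arr)
  fg <- which(mask_arr)
  stopifnot(length(fg) > 0)
  idx0 <- fg - 1L
  fx <- (idx0 %% d[1]) * spacing[1]
  fy <- ((idx0 %/% d[1]) %% d[2]) * spacing[2]
  fz <- (idx0 %/% (d[1] * d[2])) * spacing[3]
  all0 <- seq_len(prod(d)) - 1L
  ax <- (all0 %% d[1]) * spacing[1]
  ay <- ((all0 %/% d[1]) %% d[2]) * spacing[2]
  az <- (all0 %/% (d[1] * d[2])) * spacing[3]
  out <- vapply(seq_along(all0), function(i) {
    sqrt(min((fx - ax[i])^2 + (fy - ay[i])^2 + (fz - az[i])^2))
  }, 0)
  array(out, d)
}

# evenly spaced points on a circle of radius r in a rotated 3D plane
circle_points <- function(n = 360, r = 10, seed = 1) {
  rot <- random_rotation(seed)
  th <- 2 * pi * (seq_len(n) - 1) / n
  cbind(r * cos(th), r * sin(th), 0) %*% t(rot)
}

random_rotation <- function(seed = 1) {
  set.seed(seed)
  m <- matrix(rnorm(9), 3)
  qr.Q(qr(m))
}
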