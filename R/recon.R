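#' Gaussian interpolation kernel for the gather reconstruction
#'
#' A truncated Gaussian in reciprocal-space voxels, applied along the
#' distance between a reconstruction grid point and each sphere surface.
#' A deliberately narrow kernel keeps the real-space apodization mild; the
#' predicted-FSC machinery carries a compensating factor for it.
#'
#' @param sigma kernel width, reciprocal-space voxels (> 0).
#' @param support_radius truncation radius, voxels (>= 2 sigma).
#' @return object of class `kernel_spec`.
#' @export
kernel_spec <- function(sigma = 0.75, support_radius = 3 * sigma) {
  if (sigma <= 0) stop("sigma must be positive")
  if (support_radius < 2 * sigma)
    stop("support_radius must be at least 2*sigma")
  structure(list(sigma = sigma, support_radius = support_radius),
            class = "kernel_spec")
}

kernel_eval <- function(kernel, d) {
  ifelse(abs(d) <= kernel$support_radius,
         exp(-d^2 / (2 * kernel$sigma^2)), 0)
}

#' Dual-sphere kernel weights
#'
#' The gather weight at a reconstruction point is the product of the
#' interpolation-kernel term and the sphere-interference amplitude.  For
#' the real (Hermite) component the kernel contributions from the Ewald
#' sphere and its Friedel mate enter with the same sign, and the amplitude
#' is `cos^2(phi)`; for the imaginary (anti-Hermite) component they enter
#' with opposite signs, and the amplitude is `sin^2(phi)`.  A point midway
#' between the spheres therefore gets zero imaginary weight (the planar
#' limit has no imaginary signal) and maximal real weight.
#'
#' @param z_dist_ewald,z_dist_mate signed distances from the point to the
#'   Ewald sphere and to the Friedel mate, in the same units as the kernel
#'   sigma (reciprocal voxels).
#' @param kernel a [kernel_spec()].
#' @param interference_phase wavefront phase `phi` at the in-plane
#'   frequency, radians.
#' @param component `"real"` or `"imaginary"`.
#' @return list with `weight_ewald`, `weight_mate` (signed kernel terms
#'   including the amplitude) and `combined_weight` (their sum).
#' @export
dual_sphere_weights <- function(z_dist_ewald, z_dist_mate, kernel,
                                interference_phase = 0,
                                component = c("real", "imaginary")) {
  component <- match.arg(component)
  ke <- kernel_eval(kernel, z_dist_ewald)
  km <- kernel_eval(kernel, z_dist_mate)
  amp <- if (component == "real") cos(interference_phase)^2
         else sin(interference_phase)^2
  sgn <- if (component == "real") 1 else -1
  list(weight_ewald = amp * ke,
       weight_mate = sgn * amp * km,
       combined_weight = amp * (ke + sgn * km))
}

#' Create an empty volume accumulator
#'
#' Holds the two running sums of the gather reconstruction for one image
#' component: `signal_sum` (sum of weight x sampled value, complex) and
#' `weight_sq_sum` (sum of squared weights).
#'
#' @param box reconstruction box size, voxels (even).
#' @param pixel_size voxel size, Angstrom.
#' @param component `"real"` or `"imaginary"`.
#' @return object of class `volume_accumulator`.
#' @export
new_volume_accumulator <- function(box, pixel_size,
                                   component = c("real", "imaginary")) {
  component <- match.arg(component)
  z <- array(0 + 0i, c(box, box, box))
  structure(list(signal_sum = z,
                 weight_sq_sum = array(0, c(box, box, box)),
                 component = component, n_particles = 0L,
                 box = box, pixel_size = pixel_size),
            class = "volume_accumulator")
}

#' Accumulate factorized particles into real/imaginary reconstructions
#'
#' The gather pass: every reconstruction grid point inside the gathered
#' band of each particle samples the particle's Hermite FT (for the real
#' accumulator) and anti-Hermite FT (for the imaginary accumulator) by
#' bilinear interpolation at the mapped in-plane coordinates, multiplies by
#' the dual-sphere weight, and adds `weight * value` to `signal_sum` and
#' `weight^2` to `weight_sq_sum`.
#'
#' @param acc_real,acc_imag accumulators from [new_volume_accumulator()].
#' @param components a `component_images` object, or a list of them, or a
#'   pair of (box, box, P) complex arrays under names `hermite` /
#'   `antihermite` (centred layout).
#' @param pose an [pose()] object or a data.frame of alpha/beta/gamma rows.
#' @param defocus per-particle defocus, Angstrom.
#' @param optics an [ewald_optics()] (supplies wavelength and pixel size).
#' @param kernel a [kernel_spec()].
#' @param exact_sphere use the exact spherical height instead of the
#'   paraboloid.
#' @param oversample integer Fourier oversampling factor for the in-plane
#'   interpolation (components at box size are padded internally; stacks
#'   already at `box * oversample` are used as-is).
#' @return list with the two updated accumulators.
#' @export
accumulate_particle <- function(acc_real, acc_imag, components, pose, defocus,
                                optics, kernel = kernel_spec(),
                                exact_sphere = FALSE, oversample = 2L) {
  box <- acc_real$box
  if (acc_imag$box != box) stop("accumulator boxes differ")
  if (inherits(components, "component_images")) {
    if (components$box != box) stop("component box does not match accumulator")
    h <- array(components$hermite, c(box, box, 1))
    a <- array(components$antihermite, c(box, box, 1))
  } else {
    h <- components$hermite
    a <- components$antihermite
    if (is.matrix(h)) {
      h <- array(h, c(dim(h), 1))
      a <- array(a, c(dim(a), 1))
    }
  }
  if (dim(h)[1] == box && oversample > 1) {
    osc <- oversample_components(h, a, oversample)
    h <- osc$hermite; a <- osc$antihermite
  }
  if (dim(h)[1] != box * oversample)
    stop("component grids do not match box * oversample")
  poses <- if (inherits(pose, "ewald_pose"))
    data.frame(alpha = pose$alpha, beta = pose$beta, gamma = pose$gamma) else pose
  np <- nrow(poses)
  if (dim(h)[3] != np || length(defocus) != np)
    stop("components, poses and defoci have inconsistent lengths")
  if (!isTRUE(all.equal(optics$pixel_size, acc_real$pixel_size)))
    stop("optics pixel size does not match accumulator")
  res <- cpp_accumulate(as.complex(h), as.complex(a),
                        pose_matrix_rows(poses), as.numeric(defocus),
                        box, optics$pixel_size, optics$wavelength,
                        kernel$sigma, kernel$support_radius,
                        box / 2 - .ewald_const$kmax_margin_vox,
                        exact_sphere, as.integer(oversample))
  acc_real$signal_sum <- acc_real$signal_sum + res$signal_real
  acc_real$weight_sq_sum <- acc_real$weight_sq_sum + res$wsq_real
  acc_real$n_particles <- acc_real$n_particles + np
  acc_imag$signal_sum <- acc_imag$signal_sum + res$signal_imag
  acc_imag$weight_sq_sum <- acc_imag$weight_sq_sum + res$wsq_imag
  acc_imag$n_particles <- acc_imag$n_particles + np
  list(real = acc_real, imag = acc_imag)
}

#' Finalize an accumulator into a real-space map
#'
#' Divides `signal_sum` by the accumulated squared weights with a
#' Wiener-style relative floor (per resolution shell, `weight_floor_rel`
#' times the shell median), zeroes voxels whose weight never rose above the
#' floor, and inverse-transforms to a real-space density.
#'
#' @param acc a `volume_accumulator` with at least one particle.
#' @param weight_floor_rel relative floor for the weight normalizer.
#' @return object of class `ewald_volume` with elements `density`,
#'   `component`, `hand` (`"as_given"`), `pixel_size`, `box`,
#'   `per_shell_snr` (NULL until attached by the pipeline), `n_particles`.
#' @export
finalize_volume <- function(acc, weight_floor_rel = 1e-3) {
  if (acc$n_particles < 1) stop("empty accumulator")
  wsq <- acc$weight_sq_sum
  if (all(wsq == 0)) stop("empty reconstruction: all weights are zero")
  box <- acc$box
  shells <- shell_index_grid(box)
  floor_grid <- array(0, dim(wsq))
  for (s in sort(unique(as.vector(shells)))) {
    sel <- shells == s
    w <- wsq[sel]
    med <- if (any(w > 0)) median(w[w > 0]) else 0
    floor_grid[sel] <- weight_floor_rel * med
  }
  denom <- pmax(wsq, floor_grid)
  fgrid <- acc$signal_sum
  ok <- wsq >= floor_grid & wsq > 0
  fgrid[ok] <- fgrid[ok] / denom[ok]
  fgrid[!ok] <- 0
  structure(list(density = ifft_centered_real(fgrid),
                 component = acc$component, hand = "as_given",
                 pixel_size = acc$pixel_size, box = box,
                 per_shell_snr = NULL,
                 n_particles = acc$n_particles),
            class = "ewald_volume")
}

#' @export
print.ewald_volume <- function(x, ...) {
  cat(sprintf("<ewald_volume> %s component, %d^3 voxels @ %g A, hand %s, %d particles\n",
              x$component, x$box, x$pixel_size, x$hand, x$n_particles))
  invisible(x)
}

# circular inversion through the map centre (0-based voxel box/2)
invert_array <- function(x) {
  n <- dim(x)[1]
  p <- c(1L, n:2L)
  x[p, p, p]
}

#' Invert a reconstructed volume through its centre
#'
#' The real-component map of the inverted solution is the original map with
#' voxel coordinates inverted through the map centre; the
#' imaginary-component map is inverted *and* negated.  Applying the
#' function twice returns the original voxel-exactly.
#'
#' @param vol an `ewald_volume`.
#' @return the inverted-solution volume, with the `hand` flag toggled.
#' @export
invert_volume <- function(vol) {
  stopifnot(inherits(vol, "ewald_volume"))
  d <- invert_array(vol$density)
  if (vol$component == "imaginary") d <- -d
  vol$density <- d
  vol$hand <- if (vol$hand == "as_given") "inverted" else "as_given"
  vol
}
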