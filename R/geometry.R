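#' Particle pose (intrinsic ZYZ Euler triplet)
#'
#' Euler angles in degrees: `alpha` about z, then `beta` about the new y,
#' then `gamma` about the new z (the in-plane rotation).  Angles are stored
#' normalized to `[0, 360)`.  The rotation matrix maps particle-frame
#' vectors into the reconstruction frame.
#'
#' @param alpha,beta,gamma Euler angles in degrees.
#' @return object of class `ewald_pose`.
#' @export
pose <- function(alpha = 0, beta = 0, gamma = 0) {
  structure(list(alpha = alpha %% 360, beta = beta %% 360,
                 gamma = gamma %% 360), class = "ewald_pose")
}

#' @export
print.ewald_pose <- function(x, ...) {
  cat(sprintf("<pose> alpha=%g beta=%g gamma=%g (deg, ZYZ)\n",
              x$alpha, x$beta, x$gamma))
  invisible(x)
}

#' Rotation matrix of a pose
#'
#' `R = Rz(alpha) Ry(beta) Rz(gamma)`; `v_recon = R %*% v_particle`.
#'
#' @param pose an [pose()] object (or list with alpha/beta/gamma degrees).
#' @return 3x3 orthogonal matrix with determinant +1.
#' @export
rotation_matrix <- function(pose) {
  d2r <- pi / 180
  a <- pose$alpha * d2r; b <- pose$beta * d2r; g <- pose$gamma * d2r
  rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0, 0, 0, 1), 3, 3)
  ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0, sin(t), 0, cos(t)), 3, 3)
  rz(a) %*% ry(b) %*% rz(g)
}

# P x 9 row-major pose-matrix table for the C++ kernels
pose_matrix_rows <- function(poses) {
  n <- nrow(poses)
  out <- matrix(0, n, 9)
  for (i in seq_len(n)) {
    out[i, ] <- as.numeric(t(rotation_matrix(
      list(alpha = poses$alpha[i], beta = poses$beta[i], gamma = poses$gamma[i]))))
  }
  out
}

#' Pose of the inverted solution
#'
#' Adding 180 degrees to the in-plane angle `gamma` re-projects every
#' particle so that the reconstruction comes out inverted through the
#' origin.  Conjugating the particle Fourier transform instead is the
#' equivalent alternative; applying both returns the original solution.
#'
#' @param pose an [pose()] object.
#' @return the inverted-solution pose.
#' @export
invert_pose <- function(pose) {
  pose(pose$alpha, pose$beta, pose$gamma + 180)
}

#' Height of the Ewald sphere above its tangent plane
#'
#' `z0(k) = lambda k^2 / 2` (paraboloidal small-angle form; exact spherical
#' form `(1 - sqrt(1 - lambda^2 k^2)) / lambda` behind `exact`).  The
#' Friedel mate sits at `-z0(k)`.
#'
#' @param kx,ky in-plane spatial frequency, reciprocal Angstrom.
#' @param wavelength electron wavelength, Angstrom.
#' @param exact use the exact spherical form.
#' @return sphere height in reciprocal Angstrom (>= 0).
#' @export
ewald_z_offset <- function(kx, ky = 0, wavelength = 0, exact = FALSE) {
  k2 <- kx^2 + ky^2
  if (wavelength == 0) return(k2 * 0)
  if (any(k2 >= 1 / wavelength^2))
    stop("|k| must be below 1/lambda")
  if (exact) (1 - sqrt(1 - wavelength^2 * k2)) / wavelength
  else wavelength * k2 / 2
}

#' Map a reconstruction-grid point onto a particle image
#'
#' The gather step for one grid point: rotates the reconstruction-frame
#' frequency into the particle frame and reports where the image FT is
#' sampled and how far the point lies from the Ewald sphere and from its
#' Friedel mate (the kernel arguments).
#'
#' @param recon_point integer voxel index (3-vector, 0-based, centred grid)
#'   or, with `index = FALSE`, a frequency vector in reciprocal Angstrom.
#' @param pose particle pose.
#' @param wavelength electron wavelength, Angstrom.
#' @param grid_spec list with `box` (voxels) and `pixel_size` (Angstrom).
#' @param index whether `recon_point` is a voxel index.
#' @param exact use the exact spherical form of the sphere height.
#' @return list with `contributes` (FALSE when the point is outside the
#'   gathered band), `k_inplane` (2-vector, 1/A), `image_coord` (1-based
#'   fractional matrix indices for in-plane interpolation), `z_offset`
#'   (sphere height at that in-plane frequency, 1/A), and `z_distances`
#'   (named 2-vector: signed distance to the Ewald sphere and to the mate,
#'   1/A).
#' @export
map_grid_point_to_image <- function(recon_point, pose, wavelength, grid_spec,
                                    index = TRUE, exact = FALSE) {
  box <- grid_spec$box
  dk <- 1 / (box * grid_spec$pixel_size)
  q <- if (index) (as.numeric(recon_point) - box / 2) * dk else as.numeric(recon_point)
  kmax <- (box / 2 - .ewald_const$kmax_margin_vox) * dk
  if (sqrt(sum(q^2)) > kmax) {
    return(list(contributes = FALSE, k_inplane = NULL, image_coord = NULL,
                z_offset = NULL, z_distances = NULL))
  }
  u <- drop(t(rotation_matrix(pose)) %*% q)
  z0 <- ewald_z_offset(u[1], u[2], wavelength, exact = exact)
  list(
    contributes = TRUE,
    k_inplane = u[1:2],
    image_coord = box / 2 + 1 + u[1:2] / dk,
    z_offset = z0,
    z_distances = c(ewald = u[3] - z0, mate = u[3] + z0)
  )
}
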