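#' Specification of a Gaussian-blob phantom
#'
#' Phantoms are sums of isotropic 3D Gaussian blobs.  The chiral variants
#' place blob centres on a helical path whose screw sense sets the hand;
#' the achiral control is an inversion-symmetric blob set that equals its
#' own inversion exactly.
#'
#' @param box phantom box size, voxels (even).
#' @param pixel_size voxel size, Angstrom.
#' @param chirality `"right-helix"`, `"left-helix"` or `"achiral"`.
#' @param blobs optional data.frame with columns `x, y, z` (Angstrom,
#'   relative to the box centre), `sigma` (Angstrom), `amplitude`;
#'   overrides the built-in layouts.
#' @param n_blobs number of blobs on the helical path.
#' @param helix_radius,helix_height helix radius and axial extent,
#'   Angstrom; the defaults scale with the box so the phantom fills it
#'   with clearance.
#' @param turns number of helical turns over the axial extent.
#' @param blob_sigma,amplitude blob width (Angstrom) and amplitude; the
#'   default width puts Fourier power out to about two thirds of Nyquist.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(box = 48, pixel_size = 3,
                         chirality = c("right-helix", "left-helix", "achiral"),
                         blobs = NULL, n_blobs = 16,
                         helix_radius = 0.21 * box * pixel_size,
                         helix_height = 0.55 * box * pixel_size,
                         turns = 1.5,
                         blob_sigma = box * pixel_size / 36, amplitude = 1) {
  chirality <- match.arg(chirality)
  if (box %% 2 != 0) stop("box must be even")
  if (is.null(blobs)) {
    if (chirality == "achiral") {
      # inversion-symmetric: centre blob plus +-p pairs
      p <- helix_radius * cbind(c(1, 0, 0.4), c(0, 1, -0.4), c(0.5, 0.5, 0)) / 1.2
      blobs <- data.frame(
        x = c(0, p[1, ], -p[1, ]), y = c(0, p[2, ], -p[2, ]),
        z = c(0, p[3, ], -p[3, ]),
        sigma = blob_sigma, amplitude = amplitude)
    } else {
      hand <- if (chirality == "right-helix") 1 else -1
      t <- seq(0, 1, length.out = n_blobs)
      th <- hand * 2 * pi * turns * t
      blobs <- data.frame(
        x = helix_radius * cos(th), y = helix_radius * sin(th),
        z = helix_height * (t - 0.5),
        sigma = blob_sigma, amplitude = amplitude)
    }
  }
  structure(list(box = box, pixel_size = pixel_size, chirality = chirality,
                 blobs = blobs), class = "phantom_spec")
}

#' Build a phantom density from its specification
#'
#' @param spec a [phantom_spec()].
#' @param check verify the generation-time invariants (blobs fit inside the
#'   box; chiral phantoms correlate < 0.9 with their own inversion).
#' @return real 3D array (`box^3`) of density values.
#' @export
build_phantom <- function(spec, check = TRUE) {
  box <- spec$box; px <- spec$pixel_size
  b <- spec$blobs
  half <- box / 2 * px
  if (check && any(abs(cbind(b$x, b$y, b$z)) + 3 * b$sigma > half))
    stop("blob outside box (needs 3 sigma clearance)")
  ax <- (seq_len(box) - 1 - box / 2) * px
  vol <- array(0, c(box, box, box))
  gx <- array(rep(ax, times = box * box), c(box, box, box))
  gy <- aperm(gx, c(2, 1, 3))
  gz <- aperm(gx, c(3, 2, 1))
  for (i in seq_len(nrow(b))) {
    d2 <- (gx - b$x[i])^2 + (gy - b$y[i])^2 + (gz - b$z[i])^2
    vol <- vol + b$amplitude[i] * exp(-d2 / (2 * b$sigma[i]^2))
  }
  if (check && spec$chirality != "achiral") {
    cc <- cor(as.vector(vol), as.vector(invert_array(vol)))
    if (cc >= 0.9)
      stop(sprintf("phantom is not chiral enough (inversion correlation %.3f)", cc))
  }
  vol
}

#' Project one particle image through the curved-sphere forward model
#'
#' Samples the 3D FT of the rotated truth on the Ewald sphere (and its
#' complex conjugate on the Friedel mate), applies the defocus phase
#' `exp(-i phi)` to the sphere term, and inverse-transforms to a real
#' image.  The weak-contrast linear model keeps the image a linear
#' function of the density, so reconstructions have an exact ground truth.
#' With zero defocus and zero wavelength the image is the straight
#' projection of the truth along the beam.
#'
#' @param truth real 3D density array (box matching `optics` use).
#' @param pose particle pose.
#' @param defocus defocus, Angstrom.
#' @param optics an [ewald_optics()].
#' @param noise_sigma standard deviation of additive white Gaussian noise
#'   (image units); 0 for noiseless.
#' @param seed RNG seed for the noise draw (ignored when `noise_sigma = 0`).
#' @param exact_sphere use the exact spherical height.
#' @param oversample Fourier oversampling of the truth transform (the truth
#'   is zero-padded by this factor before sampling the sphere).
#' @return real image matrix (box x box).
#' @export
forward_project <- function(truth, pose, defocus, optics, noise_sigma = 0,
                            seed = 1, exact_sphere = FALSE, oversample = 2L) {
  box <- dim(truth)[1]
  f3d <- fft_centered(pad_center(truth, oversample))
  m <- cpp_forward_project(as.complex(f3d), pose_matrix_rows(
         data.frame(alpha = pose$alpha, beta = pose$beta, gamma = pose$gamma)),
         defocus, box, optics$pixel_size, optics$wavelength,
         box / 2 - .ewald_const$kmax_margin_vox, exact_sphere,
         as.integer(oversample))
  img <- ifft_centered_real(array(m, c(box, box)))
  if (noise_sigma > 0)
    img <- img + with_seed(seed, matrix(rnorm(box^2, sd = noise_sigma), box, box))
  img
}

#' Simulate a synthetic single-particle dataset
#'
#' Draws particle poses (uniform over SO(3), or a preferred-orientation
#' mode with fixed viewing direction and random in-plane angle), defoci
#' uniform over a range, projects every particle through the curved-sphere
#' forward model, and adds white Gaussian noise.  The dataset is a
#' deterministic function of the spec and seed.
#'
#' @param spec a [phantom_spec()], or a real 3D array used as the truth.
#' @param n_particles number of particle images (>= 1).
#' @param optics an [ewald_optics()]; its `lambda_scale` is the curvature
#'   exaggeration knob for desk-scale experiments.
#' @param defocus_range length-2 range of defocus values, Angstrom.
#' @param noise_sigma absolute noise standard deviation, or NULL to use
#'   `target_snr`.
#' @param target_snr desired signal variance / noise variance across the
#'   noiseless stack (used when `noise_sigma` is NULL and > 0).
#' @param seed integer seed controlling poses, defoci and noise.
#' @param mode `"uniform"` or `"preferred"` (single viewing direction:
#'   alpha = 0, beta = `beta_preferred`, gamma random).
#' @param beta_preferred fixed tilt for the preferred-orientation mode,
#'   degrees.
#' @param noise_only replace the signal with zeros (pure-noise control
#'   dataset; requires an absolute `noise_sigma`).
#' @param exact_sphere use the exact spherical height.
#' @param oversample Fourier oversampling of the truth transform.
#' @return object of class `ewald_dataset`: list with `images`
#'   (box x box x n array), `poses` (data.frame alpha/beta/gamma),
#'   `defoci`, `optics`, `truth`, `truth_hand = "as_built"`,
#'   `noise_sigma`, `seed`, `mode`.
#' @export
make_dataset <- function(spec, n_particles, optics,
                         defocus_range = c(150, 450),
                         noise_sigma = NULL, target_snr = 0.5,
                         seed = 1, mode = c("uniform", "preferred"),
                         beta_preferred = 45, noise_only = FALSE,
                         exact_sphere = FALSE, oversample = 2L) {
  mode <- match.arg(mode)
  if (n_particles < 1) stop("n_particles must be >= 1")
  truth <- if (inherits(spec, "phantom_spec")) build_phantom(spec) else spec
  box <- dim(truth)[1]
  if (!isTRUE(all.equal(dim(truth), rep(box, 3L))))
    stop("truth volume must be cubic")
  poses <- with_seed(seed, {
    if (mode == "uniform") {
      data.frame(alpha = runif(n_particles, 0, 360),
                 beta = acos(runif(n_particles, -1, 1)) * 180 / pi,
                 gamma = runif(n_particles, 0, 360))
    } else {
      data.frame(alpha = 0, beta = beta_preferred,
                 gamma = runif(n_particles, 0, 360))
    }
  })
  defoci <- with_seed(seed + 1L,
                      runif(n_particles, defocus_range[1], defocus_range[2]))
  f3d <- fft_centered(pad_center(truth, oversample))
  m <- cpp_forward_project(as.complex(f3d), pose_matrix_rows(poses), defoci,
                           box, optics$pixel_size, optics$wavelength,
                           box / 2 - .ewald_const$kmax_margin_vox,
                           exact_sphere, as.integer(oversample))
  m <- array(m, c(box, box, n_particles))
  images <- array(0, c(box, box, n_particles))
  for (p in seq_len(n_particles))
    images[, , p] <- ifft_centered_real(m[, , p])
  if (noise_only) {
    if (is.null(noise_sigma))
      stop("noise_only datasets need an absolute noise_sigma")
    images[] <- 0
  }
  if (is.null(noise_sigma)) {
    noise_sigma <- if (is.null(target_snr) || target_snr <= 0) 0
      else sqrt(mean(apply(images, 3, function(x) mean((x - mean(x))^2))) / target_snr)
  }
  if (noise_sigma > 0)
    images <- images + with_seed(seed + 2L,
      array(rnorm(length(images), sd = noise_sigma), dim(images)))
  structure(list(images = images, poses = poses, defoci = defoci,
                 optics = optics, truth = truth, truth_hand = "as_built",
                 noise_sigma = noise_sigma, seed = seed, mode = mode),
            class = "ewald_dataset")
}

#' @export
print.ewald_dataset <- function(x, ...) {
  cat(sprintf("<ewald_dataset> %d particles, box %d @ %g A/px, noise sd %.4g, %s poses\n",
              dim(x$images)[3], dim(x$images)[1], x$optics$pixel_size,
              x$noise_sigma, x$mode))
  invisible(x)
}
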