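test_that("dual-sphere weights follow the additive/subtractive kernel laws", {
  k <- kernel_spec(0.75, 2.25)
  z0 <- 0.5  # half-separation of the spheres, voxels
  # point exactly midway: imaginary weight cancels, real weight is 2x single
  expect_identical(dual_sphere_weights(-z0, z0, k, 0.3, "imaginary")$combined_weight, 0)
  single <- dual_sphere_weights(-z0, Inf, k, 0.3, "real")
  expect_equal(dual_sphere_weights(-z0, z0, k, 0.3, "real")$combined_weight,
               2 * single$combined_weight)
  # far from both spheres: zero
  expect_identical(dual_sphere_weights(10, 11, k, 0.3, "real")$combined_weight, 0)
  expect_identical(dual_sphere_weights(10, 11, k, 0.3, "imaginary")$combined_weight, 0)
  # |imaginary weight| rises monotonically off the midplane until the
  # kernels separate, then decays: zero at 0, unimodal in |zeta|
  zeta <- seq(0, 4, by = 0.05)
  wi <- vapply(zeta, function(z)
    dual_sphere_weights(z - z0, z + z0, k, pi / 3, "imaginary")$combined_weight, 0)
  expect_identical(wi[1], 0)
  pk <- which.max(abs(wi))
  expect_gt(pk, 5)
  expect_true(all(diff(abs(wi)[1:pk]) > -1e-12))
  expect_true(all(diff(abs(wi)[pk:length(wi)]) < 1e-12))
  # real weight at the midplane is the maximum over zeta (overlapping kernels)
  wr <- vapply(zeta, function(z)
    dual_sphere_weights(z - z0, z + z0, k, pi / 3, "real")$combined_weight, 0)
  expect_equal(which.max(wr), 1)
})

test_that("interference amplitudes are cos^2/sin^2 of the wavefront phase", {
  k <- kernel_spec(0.75, 2.25)
  for (phi in c(0, 0.4, pi / 2, 2)) {
    r <- dual_sphere_weights(0.2, 0.9, k, phi, "real")
    i <- dual_sphere_weights(0.2, 0.9, k, phi, "imaginary")
    ke <- exp(-0.2^2 / (2 * 0.75^2)); km <- exp(-0.9^2 / (2 * 0.75^2))
    expect_equal(r$combined_weight, (ke + km) * cos(phi)^2)
    expect_equal(i$combined_weight, (ke - km) * sin(phi)^2)
  }
})

test_that("gather accumulation matches the naive triple-loop oracle", {
  opt <- desk_optics()
  spec <- phantom_spec(box = 16, pixel_size = 3, chirality = "right-helix",
                       n_blobs = 6, helix_radius = 9, helix_height = 22,
                       blob_sigma = 4)
  ds <- make_dataset(spec, 4, opt, defocus_range = desk_defocus,
                     target_snr = 2, seed = 13)
  # package path: factorize + oversample + accumulate
  ar <- new_volume_accumulator(16, 3, "real")
  ai <- new_volume_accumulator(16, 3, "imaginary")
  comp <- factorize_stack(ds$images, ds$defoci, opt)
  out <- accumulate_particle(ar, ai, comp, ds$poses, ds$defoci, opt,
                             kernel_spec(0.75, 2.25), oversample = 2)
  orc <- oracle_gather(ds$images, ds$poses, ds$defoci, opt)
  relerr <- function(a, b) max(abs(a - b)) / max(abs(b))
  expect_lt(relerr(out$real$signal_sum, orc$signal_real), 1e-10)
  expect_lt(relerr(out$real$weight_sq_sum, orc$wsq_real), 1e-10)
  expect_lt(relerr(out$imag$signal_sum, orc$signal_imag), 1e-10)
  expect_lt(relerr(out$imag$weight_sq_sum, orc$wsq_imag), 1e-10)
})

test_that("accumulation is linear and symmetric", {
  opt <- desk_optics()
  spec <- phantom32()
  ds <- make_dataset(spec, 2, opt, defocus_range = desk_defocus,
                     target_snr = 1, seed = 17)
  comp <- factorize_stack(ds$images, ds$defoci, opt)
  run <- function(sel) {
    ar <- new_volume_accumulator(32, 3, "real")
    ai <- new_volume_accumulator(32, 3, "imaginary")
    accumulate_particle(ar, ai,
                        list(hermite = comp$hermite[, , sel, drop = FALSE],
                             antihermite = comp$antihermite[, , sel, drop = FALSE]),
                        ds$poses[sel, , drop = FALSE], ds$defoci[sel], opt)
  }
  once <- run(1L)
  twice <- run(c(1L, 1L))
  expect_equal(twice$real$signal_sum, 2 * once$real$signal_sum)
  expect_equal(twice$imag$weight_sq_sum, 2 * once$imag$weight_sq_sum)
  # Hermitian symmetry of the accumulated real-component signal
  relerr <- function(a, b) max(abs(a - b)) / max(abs(b))
  both <- run(c(1L, 2L))
  cm <- ewaldhand:::conj_mirror(both$real$signal_sum)
  expect_lt(relerr(both$real$signal_sum, cm), 1e-12)
  # a particle with zero anti-Hermite component contributes no imaginary signal
  zcomp <- list(hermite = comp$hermite[, , 1, drop = FALSE],
                antihermite = comp$antihermite[, , 1, drop = FALSE] * 0)
  z <- accumulate_particle(new_volume_accumulator(32, 3, "real"),
                           new_volume_accumulator(32, 3, "imaginary"),
                           zcomp, ds$poses[1, , drop = FALSE], ds$defoci[1], opt)
  # (only round-off from re-deriving the oversampled component survives)
  expect_lt(max(abs(z$imag$signal_sum)), 1e-12 * max(abs(z$real$signal_sum)))
  expect_gt(max(z$imag$weight_sq_sum), 0)  # weights still accumulate
})

test_that("lambda = 0 reduces the pipeline to planar central-slice insertion", {
  opt0 <- desk_optics(lambda_scale = 0)
  spec <- phantom_spec(box = 16, pixel_size = 3, chirality = "right-helix",
                       n_blobs = 6, helix_radius = 9, helix_height = 22,
                       blob_sigma = 4)
  ds <- make_dataset(spec, 3, opt0, defocus_range = desk_defocus,
                     target_snr = 0, seed = 19)
  ar <- new_volume_accumulator(16, 3, "real")
  ai <- new_volume_accumulator(16, 3, "imaginary")
  comp <- factorize_stack(ds$images, ds$defoci, opt0)
  out <- accumulate_particle(ar, ai, comp, ds$poses, ds$defoci, opt0,
                             kernel_spec(0.75, 2.25))
  orc <- oracle_planar_insertion(ds$images, ds$poses, ds$defoci, opt0)
  relerr <- function(a, b) max(abs(a - b)) / max(abs(b))
  expect_lt(relerr(out$real$signal_sum, orc$signal_real), 1e-10)
  expect_lt(relerr(out$real$weight_sq_sum, orc$wsq_real), 1e-10)
  # no imaginary signal in the planar limit
  expect_true(all(out$imag$signal_sum == 0))
  expect_true(all(out$imag$weight_sq_sum == 0))
})

test_that("finalization recovers a phantom and honours the weight floor", {
  cl <- fixture("clean_recon", function() {
    ds <- make_dataset(phantom32(), 200, desk_optics(),
                       defocus_range = desk_defocus, target_snr = 0, seed = 5)
    list(ds = ds, rec = reconstruct_components(ds))
  })
  f <- fsc(cl$rec$map_real$density, cl$ds$truth, pixel_size = 3)
  expect_gt(max(f$value[1:8]), 0.95)     # low-resolution shells
  expect_true(all(f$value[1:8] > 0.8))
  sr <- small_recon()
  # doubling every particle leaves the density unchanged (ratio invariance)
  ds <- sr$ds
  dbl_idx <- rep(seq_len(dim(ds$images)[3]), each = 2)
  rec2 <- reconstruct_components(
    images = ds$images[, , dbl_idx], poses = ds$poses[dbl_idx, ],
    defoci = ds$defoci[dbl_idx], optics = ds$optics)
  expect_equal(rec2$map_real$density, sr$rec$map_real$density,
               tolerance = 1e-10)
  # weight floor -> infinity zeroes the map
  ar <- new_volume_accumulator(32, 3, "real")
  ai <- new_volume_accumulator(32, 3, "imaginary")
  comp <- factorize_stack(ds$images[, , 1:2], ds$defoci[1:2], ds$optics)
  out <- accumulate_particle(ar, ai, comp, ds$poses[1:2, ], ds$defoci[1:2],
                             ds$optics)
  vol <- finalize_volume(out$real, weight_floor_rel = 1e12)
  expect_true(all(vol$density == 0))
  expect_error(finalize_volume(new_volume_accumulator(8, 1, "real")), "empty")
})

test_that("volume inversion has the Fig-2 algebra", {
  sr <- small_recon()
  vr <- sr$rec$map_real; vi <- sr$rec$map_imag
  # involution, voxel-exact
  expect_identical(invert_volume(invert_volume(vr))$density, vr$density)
  expect_identical(invert_volume(invert_volume(vi))$density, vi$density)
  # real component: map statistics are inversion invariant
  ir <- invert_volume(vr)
  expect_identical(sort(as.vector(ir$density)), sort(as.vector(vr$density)))
  expect_equal(ir$hand, "inverted")
  # imaginary component: inverted AND negated
  ii <- invert_volume(vi)
  expect_equal(mean(ii$density), -mean(vi$density))
  expect_equal(ii$density, -mirror3(vi$density))
})

test_that("reconstructing with inverted poses equals inverting the maps", {
  sr <- small_recon()
  ds <- sr$ds
  pinv <- ds$poses; pinv$gamma <- (pinv$gamma + 180) %% 360
  rec2 <- reconstruct_components(images = ds$images, poses = pinv,
                                 defoci = ds$defoci, optics = ds$optics)
  relerr <- function(a, b) max(abs(a - b)) / max(abs(b))
  expect_lt(relerr(rec2$map_real$density,
                   invert_volume(sr$rec$map_real)$density), 1e-12)
  expect_lt(relerr(rec2$map_imag$density,
                   invert_volume(sr$rec$map_imag)$density), 1e-12)
})

test_that("conjugating the particle transforms also inverts the solution", {
  opt <- desk_optics()
  ds <- make_dataset(phantom32(), 40, opt, defocus_range = desk_defocus,
                     target_snr = 1, seed = 23)
  rec <- reconstruct_components(ds, oversample = 1)
  # conjugating the raw particle FT == inverting each image through the
  # origin; the phase correction then propagates the conjugation so that
  # H -> conj(H) and A -> -conj(A), the inverted solution.  On the
  # critically sampled grid the identity is exact (oversampled grids agree
  # at the sample points but interpolate wrapped edge content differently).
  imgs_conj <- ds$images[c(1, 32:2), c(1, 32:2), , drop = FALSE]
  rec2 <- reconstruct_components(images = imgs_conj, poses = ds$poses,
                                 defoci = ds$defoci, optics = opt,
                                 oversample = 1)
  relerr <- function(a, b) max(abs(a - b)) / max(abs(b))
  expect_lt(relerr(rec2$map_real$density,
                   invert_volume(rec$map_real)$density), 1e-10)
  expect_lt(relerr(rec2$map_imag$density,
                   invert_volume(rec$map_imag)$density), 1e-10)
})

test_that("adding a constant to every alpha rotates the maps without inversion", {
  opt <- desk_optics()
  ds <- make_dataset(phantom32(), 2, opt, defocus_range = desk_defocus,
                     target_snr = 0, seed = 29)
  rec <- reconstruct_components(ds)
  prot <- ds$poses; prot$alpha <- (prot$alpha + 90) %% 360
  rec2 <- reconstruct_components(images = ds$images, poses = prot,
                                 defoci = ds$defoci, optics = opt)
  # rotation by +-90 deg about z permutes grid voxels exactly
  rotz90 <- function(v, sgn) {
    n <- dim(v)[1]; ct <- n / 2
    out <- array(0, dim(v))
    for (i in seq_len(n)) for (j in seq_len(n)) {
      x <- i - 1 - ct; y <- j - 1 - ct
      xs <- sgn * y; ys <- -sgn * x
      out[i, j, ] <- v[((xs + ct) %% n) + 1, ((ys + ct) %% n) + 1, ]
    }
    out
  }
  m2 <- as.vector(rec2$map_real$density)
  cors <- c(cor(m2, as.vector(rotz90(rec$map_real$density, 1))),
            cor(m2, as.vector(rotz90(rec$map_real$density, -1))))
  expect_gt(max(cors), 0.9999)  # rotated, essentially exactly
  expect_lt(cor(m2, as.vector(invert_volume(rec$map_real)$density)),
            max(cors))  # ... and not inverted
})
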