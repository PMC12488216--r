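# Independent brute-force oracles.  Deliberately self-contained: own Euler
# matrices, own FFT shifting, own bilinear interpolation, explicit triple
# loops over grid points — no calls into the package's gather machinery.

oracle_shift <- function(m) {
  n <- nrow(m)
  ix <- c((n / 2 + 1):n, 1:(n / 2))
  if (length(dim(m)) == 2) m[ix, ix] else m[ix, ix, ix]
}

oracle_fft2 <- function(x) oracle_shift(stats::fft(oracle_shift(x)))
oracle_ifft2 <- function(g)
  oracle_shift(stats::fft(oracle_shift(g), inverse = TRUE)) / length(g)

oracle_rotmat <- function(a, b, g) {
  d <- pi / 180
  ca <- cos(a * d); sa <- sin(a * d)
  cb <- cos(b * d); sb <- sin(b * d)
  cg <- cos(g * d); sg <- sin(g * d)
  # Rz(a) Ry(b) Rz(g), written out
  matrix(c(ca * cb * cg - sa * sg, sa * cb * cg + ca * sg, -sb * cg,
           -ca * cb * sg - sa * cg, -sa * cb * sg + ca * cg, sb * sg,
           ca * sb, sa * sb, cb), 3, 3)
}

oracle_bilin <- function(m, x, y) {
  # x, y: 0-based fractional indices
  x0 <- floor(x); y0 <- floor(y)
  tx <- x - x0; ty <- y - y0
  m[x0 + 1, y0 + 1] * (1 - tx) * (1 - ty) +
    m[x0 + 2, y0 + 1] * tx * (1 - ty) +
    m[x0 + 1, y0 + 2] * (1 - tx) * ty +
    m[x0 + 2, y0 + 2] * tx * ty
}

# Factorized, oversampled component transforms of a particle stack
oracle_components <- function(images, defoci, optics, os = 2) {
  box <- dim(images)[1]; np <- dim(images)[3]
  nos <- box * os
  dk <- 1 / (box * optics$pixel_size)
  ax <- (seq_len(box) - 1 - box / 2) * dk
  k2 <- outer(ax^2, ax^2, `+`)
  idx <- (box * (os - 1) / 2 + 1):(box * (os - 1) / 2 + box)
  H <- array(0 + 0i, c(nos, nos, np)); A <- H
  for (p in seq_len(np)) {
    phi <- -pi * defoci[p] * optics$wavelength * k2
    img <- images[, , p]
    cft <- oracle_fft2(img - sum(img) / length(img)) * exp(1i * phi)
    cimg <- oracle_ifft2(cft)
    bigR <- matrix(0, nos, nos); bigI <- matrix(0, nos, nos)
    bigR[idx, idx] <- Re(cimg); bigI[idx, idx] <- Im(cimg)
    H[, , p] <- oracle_fft2(bigR)
    A[, , p] <- 1i * oracle_fft2(bigI)
  }
  list(H = H, A = A)
}

# Naive dual-sphere gather: triple loop over every reconstruction voxel
oracle_gather <- function(images, poses, defoci, optics,
                          sigma = 0.75, support = 2.25, os = 2,
                          wavelength = optics$wavelength) {
  box <- dim(images)[1]; np <- dim(images)[3]
  nos <- box * os
  comp <- oracle_components(images, defoci, optics, os)
  dk <- 1 / (box * optics$pixel_size)
  kmax <- box / 2 - 2
  sr <- array(0 + 0i, c(box, box, box)); si <- sr
  wr <- array(0, c(box, box, box)); wi <- wr
  kern <- function(d) if (abs(d) <= support) exp(-d^2 / (2 * sigma^2)) else 0
  rots <- lapply(seq_len(np), function(p)
    oracle_rotmat(poses$alpha[p], poses$beta[p], poses$gamma[p]))
  for (iz in seq_len(box)) for (iy in seq_len(box)) for (ix in seq_len(box)) {
    v <- c(ix, iy, iz) - 1 - box / 2
    if (sum(v^2) > kmax^2) next
    for (p in seq_len(np)) {
      u <- as.numeric(crossprod(rots[[p]], v))
      k2 <- (u[1]^2 + u[2]^2) * dk^2
      z0 <- wavelength * k2 / 2 / dk
      ke <- kern(u[3] - z0); km <- kern(u[3] + z0)
      if (ke == 0 && km == 0) next
      phi <- -pi * defoci[p] * wavelength * k2
      wR <- (ke + km) * cos(phi)^2
      wI <- (ke - km) * sin(phi)^2
      x <- nos / 2 + os * u[1]; y <- nos / 2 + os * u[2]
      if (wR != 0) {
        sr[ix, iy, iz] <- sr[ix, iy, iz] + wR * oracle_bilin(comp$H[, , p], x, y)
        wr[ix, iy, iz] <- wr[ix, iy, iz] + wR^2
      }
      if (wI != 0) {
        si[ix, iy, iz] <- si[ix, iy, iz] + wI * oracle_bilin(comp$A[, , p], x, y)
        wi[ix, iy, iz] <- wi[ix, iy, iz] + wI^2
      }
    }
  }
  list(signal_real = sr, wsq_real = wr, signal_imag = si, wsq_imag = wi)
}

# Planar central-slice insertion: the lambda = 0 reference for the real
# component (both sphere kernels coincide on the tangent plane)
oracle_planar_insertion <- function(images, poses, defoci, optics,
                                    sigma = 0.75, support = 2.25, os = 2) {
  box <- dim(images)[1]; np <- dim(images)[3]
  nos <- box * os
  comp <- oracle_components(images, defoci, optics, os)
  dk <- 1 / (box * optics$pixel_size)
  kmax <- box / 2 - 2
  sr <- array(0 + 0i, c(box, box, box))
  wr <- array(0, c(box, box, box))
  rots <- lapply(seq_len(np), function(p)
    oracle_rotmat(poses$alpha[p], poses$beta[p], poses$gamma[p]))
  for (iz in seq_len(box)) for (iy in seq_len(box)) for (ix in seq_len(box)) {
    v <- c(ix, iy, iz) - 1 - box / 2
    if (sum(v^2) > kmax^2) next
    for (p in seq_len(np)) {
      u <- as.numeric(crossprod(rots[[p]], v))
      if (abs(u[3]) > support) next
      w <- 2 * exp(-u[3]^2 / (2 * sigma^2))  # cos^2(phi) = 1 at lambda = 0
      val <- oracle_bilin(comp$H[, , p], nos / 2 + os * u[1], nos / 2 + os * u[2])
      sr[ix, iy, iz] <- sr[ix, iy, iz] + w * val
      wr[ix, iy, iz] <- wr[ix, iy, iz] + w^2
    }
  }
  list(signal_real = sr, wsq_real = wr)
}
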