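#' Swap FFT half-spaces (centre the DC term)
#'
#' Circularly shifts every dimension of an even-sized array by half its
#' length, moving the DC term of an unshifted [stats::fft()] result to the
#' centre index `n/2 + 1`.  For even sizes the operation is its own inverse,
#' so the same function converts back.
#'
#' @param x vector, matrix or array with even extents.
#' @return `x` with all dimensions circularly shifted by half their length.
#' @export
fftshift <- function(x) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  if (any(d %% 2L != 0L)) stop("fftshift requires even extents")
  idx <- lapply(d, function(n) c((n / 2 + 1):n, 1:(n / 2)))
  if (length(d) == 1L) return(x[idx[[1L]]])
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Centred forward/inverse transforms (image and volume): centred in BOTH
# domains — the real-space phase origin is the centre voxel n/2 and the DC
# term sits at index n/2.  Keeping the object at the phase origin makes the
# transform's phase slowly varying, which bilinear/trilinear interpolation
# between Fourier samples requires (with the origin at index 0 a centred
# object rides a (-1)^k checkerboard ramp and interpolation is meaningless).
fft_centered <- function(x) fftshift(fft(fftshift(x)))

ifft_centered <- function(g) fftshift(fft(fftshift(g), inverse = TRUE)) / length(g)

ifft_centered_real <- function(g) Re(ifft_centered(g))

#' Index of the Friedel (-k) partner on an even FFT grid
#'
#' On an even grid of size `n` (either layout) the mirror of 1-based index
#' `i` is `(n - (i - 1)) mod n + 1`; the Nyquist row maps to itself.
#'
#' @param i 1-based indices.
#' @param n grid size (even).
#' @return 1-based indices of the `-k` entries.
#' @export
friedel_index <- function(i, n) ((n - (i - 1L)) %% n) + 1L

# conj(F[-k]) for a centred (or unshifted) even square/cubic grid
conj_mirror <- function(f) {
  d <- dim(f)
  idx <- lapply(d, function(n) friedel_index(seq_len(n), n))
  Conj(do.call(`[`, c(list(f), idx, list(drop = FALSE))))
}

# zero-pad an image or volume symmetrically so that the centre voxel n/2
# (0-based) stays the centre of the enlarged grid; Fourier-transforming the
# result oversamples the original transform by `factor`
pad_center <- function(x, factor) {
  if (factor == 1) return(x)
  d <- dim(x)
  n <- d[1]
  off <- n * (factor - 1) / 2
  idx <- (off + 1):(off + n)
  if (length(d) == 2) {
    out <- matrix(0, n * factor, n * factor)
    out[idx, idx] <- x
  } else {
    out <- array(0, rep(n * factor, 3))
    out[idx, idx, idx] <- x
  }
  out
}

# Hermite/anti-Hermite stacks oversampled by zero-padding the corrected
# real-space image: H_os = FT(pad(Re c)), A_os = i FT(pad(Im c)), where c is
# the phase-corrected complex image.
oversample_components <- function(h, a, oversample) {
  box <- dim(h)[1]
  np <- if (length(dim(h)) == 3) dim(h)[3] else 1L
  h <- array(h, c(box, box, np)); a <- array(a, c(box, box, np))
  if (oversample == 1) return(list(hermite = h, antihermite = a))
  nos <- box * oversample
  ho <- array(0 + 0i, c(nos, nos, np)); ao <- ho
  for (p in seq_len(np)) {
    cimg <- ifft_centered(h[, , p] + a[, , p])
    ho[, , p] <- fft_centered(pad_center(Re(cimg), oversample))
    ao[, , p] <- 1i * fft_centered(pad_center(Im(cimg), oversample))
  }
  list(hermite = ho, antihermite = ao)
}

# voxel radius array (distance from centre index, voxel units), cached
.radius_cache <- new.env(parent = emptyenv())

radius_grid <- function(box, ndim = 3L) {
  key <- paste0(ndim, "d", box)
  if (!is.null(.radius_cache[[key]])) return(.radius_cache[[key]])
  ax <- seq_len(box) - 1 - box / 2
  r <- if (ndim == 3L) {
    sqrt(outer(outer(ax^2, ax^2, `+`), ax^2, `+`))
  } else {
    sqrt(outer(ax^2, ax^2, `+`))
  }
  .radius_cache[[key]] <- r
  r
}

# shell index per voxel (round-half-up of voxel radius); 0 = DC shell
shell_index_grid <- function(box, ndim = 3L) {
  key <- paste0("s", ndim, "d", box)
  if (!is.null(.radius_cache[[key]])) return(.radius_cache[[key]])
  s <- as.integer(floor(radius_grid(box, ndim) + 0.5))
  .radius_cache[[key]] <- s
  s
}

# run expr with a local RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}
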