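# Shared fixtures, built once per test run and cached.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

# desk-scale optics: exaggerated curvature, defocus range chosen so that
# z * lambda (hence the CTF ring count) stays in the physical range
desk_optics <- function(lambda_scale = 50, pixel_size = 3)
  ewald_optics(300, pixel_size, lambda_scale = lambda_scale)

desk_defocus <- c(150, 450)

phantom32 <- function(chirality = "right-helix")
  phantom_spec(box = 32, pixel_size = 3, chirality = chirality,
               helix_radius = 20, helix_height = 52)

# small noisy reconstruction reused across validation tests
small_recon <- function() fixture("small_recon", function() {
  ds <- make_dataset(phantom32(), 150, desk_optics(),
                     defocus_range = desk_defocus, target_snr = 0.7, seed = 7)
  list(ds = ds, rec = reconstruct_components(ds))
})

mirror3 <- function(x) {
  n <- dim(x)[1]; p <- c(1L, n:2L)
  x[p, p, p]
}
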