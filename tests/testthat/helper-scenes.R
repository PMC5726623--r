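# Shared scene fixtures, cached so expensive renders happen once per run.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, expr, envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

test_sphere_mesh <- function(resolution = 5) {
  cached(paste0("sphere", resolution),
         glossim::make_shape_mesh("sphere", resolution = resolution))
}

test_blob_mesh <- function(which = 1, resolution = 4, seed = 7) {
  cached(sprintf("blob%d_%d_%d", which, resolution, seed),
         glossim::make_shape_mesh(paste0("blob", which), seed = seed,
                                  resolution = resolution))
}

# single central light sphere render across material smoothness
single_light_render <- function(s, size = 128, intensity = 1.5, fov = 10) {
  cached(sprintf("sl_%g_%d_%g_%g", s, size, intensity, fov), {
    sc <- glossim::scene(test_sphere_mesh(), glossim::material(s),
                         list(glossim::point_light(c(0, -5, 0),
                                                   intensity = intensity)))
    glossim::render(sc, glossim::default_camera(size = c(size, size),
                                                fov = fov),
                    clip = FALSE)
  })
}

# full three-light stimulus render
stimulus_render <- function(shape, s, alpha, intensity, size = 128,
                            clip = FALSE) {
  cached(sprintf("st_%s_%g_%g_%g_%d_%d", shape, s, alpha, intensity, size,
                 clip), {
    mesh <- if (shape == "sphere") test_sphere_mesh() else
      glossim::make_shape_mesh(shape, seed = 7, resolution = 4)
    glossim::render_condition(shape, s, alpha, intensity, size = c(size, size),
                              clip = clip, mesh = mesh)
  })
}

# tiny rendered_image built from raw matrices
toy_image <- function(lum, fg = NULL, ...) {
  glossim::as_rendered_image(lum, fg, ...)
}
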