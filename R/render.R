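# Scene construction and ray-cast rendering.
#
# The scene layout places the object at the origin, three point lights on a
# radius-5 arc in the horizontal plane (z = 0), and the camera(s) about one
# unit in front of the object at y = -1. The material is a GGX microfacet
# model driven by a "smoothness" parameter via roughness = (1 - s)^2.

REC709 <- c(0.2126, 0.7152, 0.0722)

#' Point light source
#'
#' @param position length-3 position in scene units.
#' @param intensity non-negative scalar intensity (the stimuli use 0.5 or 1.5).
#' @param color rgb triple in [0,1].
#' @param range distance at which the light's contribution reaches zero
#'   (10 units in the stimuli).
#' @return object of class `point_light`.
#' @export
point_light <- function(position, intensity = 1, color = c(1, 1, 1), range = 10) {
  if (range <= 0) stop("range must be positive")
  if (intensity < 0) stop("intensity must be non-negative")
  structure(list(position = as.numeric(position), intensity = intensity,
                 color = as.numeric(color), range = range),
            class = "point_light")
}

#' Surface material
#'
#' Dielectric microfacet material: diffuse albedo plus a GGX specular lobe
#' with Schlick Fresnel. `smoothness` is the user-facing gloss parameter;
#' roughness is always derived as `(1 - smoothness)^2` and never stored.
#'
#' @param smoothness scalar in [0,1].
#' @param albedo rgb triple (stimulus default mid-gray 0.5).
#' @param metallic kept at 0 (dielectric highlights in the light color).
#' @param F0 base dielectric reflectance for the Fresnel term (linear scale).
#' @param shading `"engine_gamma"` (default) emulates a gamma-color-space
#'   game-engine pipeline: the specular lobe `pi * D * Vis` is square-rooted
#'   and the Fresnel base reflectance is expressed in gamma space
#'   (`F0^(1/2.2)`, i.e. 0.04 -> ~0.23), which is the regime in which broad
#'   low-smoothness highlights remain brighter than the diffuse shading
#'   gradient. `"physical"` is the plain radiometric Cook-Torrance term
#'   `pi * D * F * Vis`. Both are linear in light intensity.
#' @param diffuse `"lambert"` or `"disney"` (roughness-dependent
#'   retro-reflective diffuse); defaults to `"disney"` under
#'   `"engine_gamma"` shading and `"lambert"` under `"physical"`.
#' @return object of class `material`.
#' @export
material <- function(smoothness, albedo = c(0.5, 0.5, 0.5), metallic = 0,
                     F0 = 0.04, shading = c("engine_gamma", "physical"),
                     diffuse = NULL) {
  if (smoothness < 0 || smoothness > 1) stop("smoothness must lie in [0,1]")
  shading <- match.arg(shading)
  if (is.null(diffuse))
    diffuse <- if (shading == "engine_gamma") "disney" else "lambert"
  diffuse <- match.arg(diffuse, c("lambert", "disney"))
  structure(list(smoothness = smoothness, albedo = as.numeric(albedo),
                 metallic = metallic, F0 = F0, shading = shading,
                 diffuse = diffuse),
            class = "material")
}

# specular factor for one light sample set, per the material's shading mode
specular_term <- function(mat, D, Vis, v_h) {
  if (mat$shading == "engine_gamma") {
    sqrt(pmax(pi * D * Vis, 1e-12)) * fresnel_schlick(v_h, mat$F0^(1 / 2.2))
  } else {
    pi * D * fresnel_schlick(v_h, mat$F0) * Vis
  }
}

#' Pinhole camera
#'
#' @param position,target length-3 vectors; the camera looks from `position`
#'   towards `target` with vertical up = +z.
#' @param fov vertical field of view in degrees.
#' @param size image size as `c(rows, cols)`.
#' @return object of class `camera`.
#' @export
camera <- function(position, target = c(0, 0, 0), fov = 10,
                   size = c(256, 256)) {
  if (fov <= 0 || fov >= 180) stop("fov must lie in (0, 180)")
  if (any(size < 1)) stop("image size must be positive")
  structure(list(position = as.numeric(position), target = as.numeric(target),
                 fov = fov, size = as.integer(size)),
            class = "camera")
}

#' Stereo eye cameras
#'
#' The two half-image cameras sit at x = -eye_sep/2 and +eye_sep/2, one unit
#' in front of the object, both aimed at the origin.
#'
#' @param eye `"left"`, `"right"` or `"center"`.
#' @param eye_sep inter-camera separation in scene units (default 0.06, i.e.
#'   positions x = -0.03 and +0.03).
#' @param distance camera distance from the object centre.
#' @param fov,size passed to [camera()]. The default fov (10 degrees) frames
#'   the ~4.2-degree object with some margin; it is an analysis view, not the
#'   full display geometry.
#' @return a `camera`.
#' @export
default_camera <- function(eye = c("center", "left", "right"), eye_sep = 0.06,
                           distance = 1, fov = 10, size = c(256, 256)) {
  eye <- match.arg(eye)
  x <- switch(eye, center = 0, left = -eye_sep / 2, right = eye_sep / 2)
  camera(position = c(x, -distance, 0), target = c(0, 0, 0),
         fov = fov, size = size)
}

#' Place the three point lights for a given light spread
#'
#' The central light is fixed at (0, -5, 0); the two lateral lights sit on the
#' same radius-5 arc in the horizontal plane, at angles of +/- alpha * 90
#' degrees from the central direction. alpha = 0 stacks all three lights at
#' the central position; alpha = 1 puts the lateral lights at (+/-5, 0, 0),
#' i.e. 90 degrees away.
#'
#' @param alpha light spread in [0,1].
#' @param intensity per-light intensity.
#' @param color rgb triple, or a list of three rgb triples (central, left,
#'   right) for the colored-light conditions.
#' @param distance arc radius (5 units).
#' @param range light range passed to [point_light()].
#' @return list of three `point_light`s: central, left, right.
#' @export
place_lights <- function(alpha, intensity = 1.5, color = c(1, 1, 1),
                         distance = 5, range = 10) {
  if (length(alpha) != 1 || is.na(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0,1]")
  th <- alpha * pi / 2
  pos <- list(central = c(0, -distance, 0),
              left = c(-distance * sin(th), -distance * cos(th), 0),
              right = c(distance * sin(th), -distance * cos(th), 0))
  cols <- if (is.list(color)) color else list(color, color, color)
  mapply(function(p, cl) point_light(p, intensity = intensity, color = cl,
                                     range = range),
         pos, cols, SIMPLIFY = FALSE)
}

#' Scene container
#'
#' @param mesh a `triangle_mesh`.
#' @param material a `material`.
#' @param lights list of `point_light`s (usually from [place_lights()]).
#' @param ambient_intensity scalar ambient level (stimulus default 0.6).
#' @param ambient_color rgb triple.
#' @param spread_alpha the light spread used to place the lights (metadata).
#' @return object of class `scene`.
#' @export
scene <- function(mesh, material, lights, ambient_intensity = 0.6,
                  ambient_color = c(1, 1, 1), spread_alpha = NA_real_) {
  structure(list(mesh = mesh, material = material, lights = lights,
                 ambient_intensity = ambient_intensity,
                 ambient_color = as.numeric(ambient_color),
                 spread_alpha = spread_alpha),
            class = "scene")
}

#' Smoothness to roughness mapping
#'
#' @param s smoothness in [0,1].
#' @return roughness `(1 - s)^2`.
#' @export
smoothness_to_roughness <- function(s) {
  if (any(s < 0 | s > 1)) stop("smoothness must lie in [0,1]")
  (1 - s)^2
}

#' GGX normal distribution function
#'
#' `D(n.h) = a^2 / (pi * ((n.h)^2 (a^2 - 1) + 1)^2)` with shape parameter
#' `a = roughness`. Normalized so the projected hemispherical integral
#' `int D (n.h) dw = 1`; maximal at `n_dot_h = 1`. A roughness of exactly 0
#' is floored at 1e-4 to keep the lobe finite.
#'
#' @param n_dot_h cosine between normal and half vector, in [0,1].
#' @param roughness GGX shape parameter in (0,1].
#' @return density value(s) >= 0.
#' @export
ggx_ndf <- function(n_dot_h, roughness) {
  a <- pmax(roughness, 1e-4)
  a2 <- a * a
  d <- n_dot_h * n_dot_h * (a2 - 1) + 1
  a2 / (pi * d * d)
}

#' Schlick Fresnel approximation
#'
#' @param v_dot_h cosine between view and half vector, in [0,1].
#' @param F0 base reflectance at normal incidence.
#' @return reflectance in [F0, 1].
#' @export
fresnel_schlick <- function(v_dot_h, F0 = 0.04) {
  F0 + (1 - F0) * (1 - v_dot_h)^5
}

#' Range-limited light attenuation
#'
#' Inverse-square falloff windowed so the contribution reaches exactly zero
#' at `distance = range`: `min(1, 1/d^2) * max(0, 1 - (d/range)^4)^2`. The
#' `min(1, .)` caps the near-field blow-up so `attenuation(0) = 1`.
#'
#' @param distance distance(s) from the light, >= 0.
#' @param range light range, > 0.
#' @return attenuation factor(s) in [0,1], monotone non-increasing.
#' @export
attenuation <- function(distance, range = 10) {
  if (range <= 0) stop("range must be positive")
  w <- pmax(0, 1 - (distance / range)^4)
  pmin(1, 1 / pmax(distance, .Machine$double.eps)^2) * w * w
}

# Smith height-correlated visibility for GGX: V = G / (4 (n.l)(n.v))
smith_vis <- function(n_l, n_v, a) {
  a2 <- a * a
  gv <- n_l * sqrt(n_v * n_v * (1 - a2) + a2)
  gl <- n_v * sqrt(n_l * n_l * (1 - a2) + a2)
  0.5 / pmax(gv + gl, 1e-12)
}

disney_diffuse_factor <- function(n_l, n_v, v_h, roughness) {
  fd90 <- 0.5 + 2 * roughness * v_h * v_h
  (1 + (fd90 - 1) * (1 - n_l)^5) * (1 + (fd90 - 1) * (1 - n_v)^5)
}

#' Shade surface points
#'
#' Evaluates, per point and per light, diffuse (Lambert or Disney) plus a
#' Cook-Torrance GGX specular term `D * F * G / (4 (n.l)(n.v))` (transformed
#' per the material's shading mode, see [material()]), weighted by
#' light intensity, range attenuation and the clamped cosine `(n.l)+`, and
#' adds the ambient term `ambient_intensity * ambient_color * albedo`.
#' Following the game-engine convention the punctual-light BRDF is scaled by
#' pi (light intensities are in surface-response units, not radiometric
#' watts), so a Lambert surface under a single unattenuated unit light at
#' normal incidence returns exactly its albedo. Points facing away from the
#' camera (n.v <= 0) receive the ambient term only.
#'
#' @param points,normals,view_dirs `n x 3` matrices (normals and view
#'   directions unit length; view_dirs point from the surface towards the
#'   camera).
#' @param lights list of `point_light`s.
#' @param mat a `material`.
#' @param ambient_intensity,ambient_color ambient term parameters.
#' @return `n x 3` matrix of rgb radiance values (non-negative).
#' @export
shade <- function(points, normals, view_dirs, lights, mat,
                  ambient_intensity = 0.6, ambient_color = c(1, 1, 1)) {
  as_m <- function(x) if (is.null(dim(x))) matrix(x, ncol = 3) else as.matrix(x)
  p <- as_m(points); n <- as_m(normals); v <- as_m(view_dirs)
  npts <- nrow(p)
  rough <- smoothness_to_roughness(mat$smoothness)
  a <- max(rough, 1e-4)
  n_v <- rowSums(n * v)
  front <- n_v > 0
  out <- matrix(rep(ambient_intensity * ambient_color * mat$albedo,
                    each = npts), npts, 3)
  for (L in lights) {
    lv <- -sweep(p, 2, L$position)          # point -> light
    dist <- row_norms(lv)
    lv <- lv / pmax(dist, 1e-12)
    n_l <- rowSums(n * lv)
    lit <- front & n_l > 0
    if (!any(lit)) next
    h <- normalize_rows(lv + v)
    n_h <- pmin(1, pmax(0, rowSums(n * h)))
    v_h <- pmin(1, pmax(0, rowSums(v * h)))
    D <- ggx_ndf(n_h, a)
    Vis <- smith_vis(pmax(n_l, 1e-6), pmax(n_v, 1e-6), a)
    diff_fac <- if (mat$diffuse == "disney")
      disney_diffuse_factor(pmax(n_l, 0), pmax(n_v, 0), v_h, rough) else 1
    spec <- specular_term(mat, D, Vis, v_h)
    wt <- L$intensity * attenuation(dist, L$range) * pmax(n_l, 0) * lit
    for (k in 1:3)
      out[, k] <- out[, k] +
        wt * L$color[k] * (mat$albedo[k] * diff_fac + spec)
  }
  pmax(out, 0)
}

camera_rays <- function(cam) {
  rows <- cam$size[1]; cols <- cam$size[2]
  fwd <- cam$target - cam$position
  fwd <- fwd / sqrt(sum(fwd^2))
  up0 <- c(0, 0, 1)
  right <- c(fwd[2] * up0[3] - fwd[3] * up0[2],
             fwd[3] * up0[1] - fwd[1] * up0[3],
             fwd[1] * up0[2] - fwd[2] * up0[1])
  right <- right / sqrt(sum(right^2))
  upv <- c(right[2] * fwd[3] - right[3] * fwd[2],
           right[3] * fwd[1] - right[1] * fwd[3],
           right[1] * fwd[2] - right[2] * fwd[1])
  tanh <- tan(cam$fov / 2 * pi / 180)
  aspect <- cols / rows
  # pixel centres; row 1 is the top of the image
  xs <- ((seq_len(cols) - 0.5) / cols * 2 - 1) * tanh * aspect
  ys <- (1 - (seq_len(rows) - 0.5) / rows * 2) * tanh
  gx <- rep(xs, each = rows)       # column-major order of an R matrix
  gy <- rep(ys, times = cols)
  dirs <- cbind(fwd[1] + gx * right[1] + gy * upv[1],
                fwd[2] + gx * right[2] + gy * upv[2],
                fwd[3] + gx * right[3] + gy * upv[3])
  normalize_rows(dirs)
}

#' Render a scene
#'
#' Casts one primary ray per pixel, shades the nearest hit with [shade()],
#' and returns linear-luminance and rgb images plus the foreground mask.
#' Luminance is the Rec. 709 weighted sum of the linear rgb channels.
#'
#' @param sc a `scene`.
#' @param cam a `camera`.
#' @param clip if `TRUE`, rgb channels are limited to `clip_ceiling`
#'   (hard clipping, no tone mapping) and the number of clipped foreground
#'   pixels is recorded.
#' @param clip_ceiling the clipping ceiling (display maximum, 1.0).
#' @return object of class `rendered_image` with elements `luminance`
#'   (rows x cols matrix), `foreground_mask`, `rgb` (rows x cols x 3 array),
#'   `clipped_count`, `n_views`, `clip`, `clip_ceiling`.
#' @export
render <- function(sc, cam = default_camera(), clip = TRUE, clip_ceiling = 1) {
  if (nrow(sc$mesh$faces) == 0) stop("empty mesh")
  rows <- cam$size[1]; cols <- cam$size[2]
  dirs <- camera_rays(cam)
  origins <- matrix(cam$position, nrow(dirs), 3, byrow = TRUE)
  hit <- cpp_raycast(sc$mesh$vertices, sc$mesh$faces, origins, dirs)
  fg <- hit$face > 0
  rgb <- matrix(0, nrow(dirs), 3)
  clipped <- 0L
  if (any(fg)) {
    f <- sc$mesh$faces[hit$face[fg], , drop = FALSE]
    u <- hit$u[fg]; v <- hit$v[fg]; w <- 1 - u - v
    pts <- origins[fg, , drop = FALSE] + dirs[fg, , drop = FALSE] * hit$t[fg]
    nrm <- normalize_rows(
      sc$mesh$normals[f[, 1], , drop = FALSE] * w +
      sc$mesh$normals[f[, 2], , drop = FALSE] * u +
      sc$mesh$normals[f[, 3], , drop = FALSE] * v)
    shaded <- shade(pts, nrm, -dirs[fg, , drop = FALSE], sc$lights,
                    sc$material, sc$ambient_intensity, sc$ambient_color)
    if (clip) {
      clipped <- sum(pmax(shaded[, 1], shaded[, 2], shaded[, 3]) >= clip_ceiling)
      shaded <- pmin(shaded, clip_ceiling)
    }
    rgb[fg, ] <- shaded
  }
  lum <- matrix(rgb %*% REC709, rows, cols)
  mask <- matrix(fg, rows, cols)
  arr <- array(rgb, c(rows, cols, 3))
  structure(list(luminance = lum, foreground_mask = mask, rgb = arr,
                 clipped_count = as.integer(clipped), n_views = 1L,
                 clip = clip, clip_ceiling = clip_ceiling),
            class = "rendered_image")
}

#' @export
print.rendered_image <- function(x, ...) {
  cat(sprintf(
    "rendered_image: %d x %d, %d view(s), %d foreground px, %d clipped\n",
    nrow(x$luminance), ncol(x$luminance), x$n_views,
    sum(x$foreground_mask), x$clipped_count))
  invisible(x)
}

#' Render a stereo pair
#'
#' Renders the scene from two cameras that differ only in position and
#' concatenates the half-images side by side (left half first), as the
#' stimuli were displayed.
#'
#' @param sc a `scene`.
#' @param left_cam,right_cam `camera`s with identical size, fov and target.
#' @param clip,clip_ceiling as in [render()].
#' @return a `rendered_image` with `n_views = 2` and width `2 * cols`.
#' @export
render_stereo <- function(sc, left_cam, right_cam, clip = TRUE,
                          clip_ceiling = 1) {
  if (!identical(left_cam$size, right_cam$size))
    stop("stereo cameras must share the same image size")
  if (!isTRUE(all.equal(left_cam$fov, right_cam$fov)) ||
      !isTRUE(all.equal(left_cam$target, right_cam$target)))
    stop("stereo cameras may differ only in position")
  li <- render(sc, left_cam, clip = clip, clip_ceiling = clip_ceiling)
  ri <- render(sc, right_cam, clip = clip, clip_ceiling = clip_ceiling)
  rows <- nrow(li$luminance); cols <- ncol(li$luminance)
  rgb <- array(0, c(rows, 2 * cols, 3))
  rgb[, seq_len(cols), ] <- li$rgb
  rgb[, cols + seq_len(cols), ] <- ri$rgb
  structure(list(luminance = cbind(li$luminance, ri$luminance),
                 foreground_mask = cbind(li$foreground_mask, ri$foreground_mask),
                 rgb = rgb,
                 clipped_count = li$clipped_count + ri$clipped_count,
                 n_views = 2L, clip = clip, clip_ceiling = clip_ceiling),
            class = "rendered_image")
}

#' Build a rendered_image from raw matrices
#'
#' Wraps an externally produced luminance matrix (e.g. read back from disk,
#' or a pluggable segmentation mask source) in the container the statistics
#' functions expect.
#'
#' @param luminance numeric matrix of linear luminance.
#' @param foreground_mask logical matrix of the same shape.
#' @param n_views 1 or 2.
#' @param clip,clip_ceiling clipping metadata.
#' @param clipped_count clipped-pixel count if known.
#' @return a `rendered_image`.
#' @export
as_rendered_image <- function(luminance, foreground_mask = NULL, n_views = 1L,
                              clip = FALSE, clip_ceiling = 1,
                              clipped_count = NA_integer_) {
  luminance <- as.matrix(luminance)
  if (is.null(foreground_mask))
    foreground_mask <- matrix(TRUE, nrow(luminance), ncol(luminance))
  stopifnot(identical(dim(luminance), dim(foreground_mask)))
  if (is.na(clipped_count))
    clipped_count <- if (clip) sum(foreground_mask & luminance >= clip_ceiling) else 0L
  structure(list(luminance = luminance,
                 foreground_mask = foreground_mask, rgb = NULL,
                 clipped_count = as.integer(clipped_count),
                 n_views = as.integer(n_views), clip = clip,
                 clip_ceiling = clip_ceiling),
            class = "rendered_image")
}
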