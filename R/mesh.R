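# Mesh generation: subdivided icospheres, seeded Perlin "clouds" displacement,
# and analytic sphere / cylinder primitives.
#
# Coordinate convention used throughout the package: x lateral, y depth
# (the camera looks along +y from negative y), z vertical. Lights and cameras
# all lie in the horizontal plane z = 0.

#' Triangle mesh container
#'
#' A minimal indexed triangle mesh: an `n x 3` matrix of vertex positions, an
#' `m x 3` integer matrix of 1-based vertex indices (counter-clockwise when
#' seen from outside), and per-vertex unit normals.
#'
#' @param vertices numeric matrix, one row per vertex.
#' @param faces integer matrix, one row per triangle, 1-based indices.
#' @param normals optional numeric matrix of per-vertex unit normals; computed
#'   from the faces (area-weighted) when omitted.
#' @return object of class `triangle_mesh` with elements `vertices`, `faces`,
#'   `normals`.
#' @export
triangle_mesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3)
  if (nrow(faces) > 0 && (min(faces) < 1 || max(faces) > nrow(vertices)))
    stop("face indices out of range")
  mesh <- structure(list(vertices = vertices, faces = faces, normals = NULL),
                    class = "triangle_mesh")
  mesh$normals <- if (is.null(normals)) vertex_normals(mesh) else as.matrix(normals)
  mesh
}

#' @export
print.triangle_mesh <- function(x, ...) {
  cat(sprintf("triangle_mesh: %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

row_norms <- function(m) sqrt(rowSums(m * m))

normalize_rows <- function(m) {
  n <- row_norms(m)
  n[n == 0] <- 1
  m / n
}

#' Area-weighted per-vertex normals
#'
#' Face normals (cross products, whose length is twice the triangle area) are
#' accumulated onto each incident vertex and normalized, so large faces weigh
#' more -- the usual smooth-shading normal.
#'
#' @param mesh a `triangle_mesh`.
#' @return numeric matrix of unit normals, one row per vertex.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices
  f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  e1 <- v[f[, 2], , drop = FALSE] - a
  e2 <- v[f[, 3], , drop = FALSE] - a
  fn <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  acc <- matrix(0, nrow(v), 3)
  for (k in 1:3) {
    s <- rowsum(fn, group = f[, k], reorder = FALSE)
    idx <- as.integer(rownames(s))
    acc[idx, ] <- acc[idx, ] + s
  }
  normalize_rows(acc)
}

icosahedron <- function() {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c( phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(1 + phi^2)
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  list(vertices = v, faces = f)
}

#' Subdivided icosphere
#'
#' `resolution = 1` is the raw icosahedron (20 faces); each further level
#' splits every triangle into four and projects the new edge-midpoint vertices
#' onto the unit sphere, so the face count is `20 * 4^(resolution - 1)`.
#' Resolution 6 gives the 20,480-triangle sphere used as the base shape of the
#' blob stimuli.
#'
#' @param resolution integer >= 1 subdivision level.
#' @return a unit-radius `triangle_mesh` centred on the origin.
#' @export
make_icosphere <- function(resolution) {
  if (length(resolution) != 1 || is.na(resolution) || resolution < 1 ||
      resolution != round(resolution))
    stop("resolution must be a positive integer")
  base <- icosahedron()
  v <- base$vertices
  f <- base$faces
  if (resolution > 1) {
    for (lvl in seq_len(resolution - 1)) {
      nv <- nrow(v)
      # unique undirected edges, midpoints shared between adjacent faces
      e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
      e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
      key <- (e[, 1] - 1) * nv + e[, 2]
      ukey <- unique(key)
      mid_of <- match(key, ukey)
      ue <- e[match(ukey, key), , drop = FALSE]
      mids <- normalize_rows((v[ue[, 1], , drop = FALSE] +
                              v[ue[, 2], , drop = FALSE]) / 2)
      m12 <- nv + mid_of[seq_len(nrow(f))]
      m23 <- nv + mid_of[nrow(f) + seq_len(nrow(f))]
      m31 <- nv + mid_of[2 * nrow(f) + seq_len(nrow(f))]
      v <- rbind(v, mids)
      f <- rbind(cbind(f[, 1], m12, m31),
                 cbind(f[, 2], m23, m12),
                 cbind(f[, 3], m31, m23),
                 cbind(m12, m23, m31))
    }
  }
  # for a sphere the exact normals are the radial directions
  triangle_mesh(v, f, normals = normalize_rows(v))
}

#' Tessellated sphere of given radius
#'
#' @param radius positive radius.
#' @param resolution icosphere subdivision level (see [make_icosphere()]).
#' @return a `triangle_mesh`.
#' @export
make_sphere <- function(radius, resolution = 4) {
  if (radius <= 0) stop("radius must be positive")
  s <- make_icosphere(resolution)
  triangle_mesh(s$vertices * radius, s$faces, normals = s$normals)
}

#' Open cylinder (lateral surface only)
#'
#' Axis along z, centred on the origin. Normals are exactly radial (zero
#' axial component). Used for the highlight-separability analyses where a
#' surface with a single curvature direction is convenient.
#'
#' @param radius,height positive dimensions.
#' @param segments number of angular segments (>= 3).
#' @return a `triangle_mesh`.
#' @export
make_cylinder <- function(radius, height, segments = 64) {
  if (radius <= 0 || height <= 0) stop("radius and height must be positive")
  if (segments < 3) stop("segments must be >= 3")
  th <- 2 * pi * (seq_len(segments) - 1) / segments
  ring <- cbind(radius * cos(th), radius * sin(th))
  v <- rbind(cbind(ring, -height / 2), cbind(ring, height / 2))
  n <- cbind(cos(th), sin(th), 0)
  nxt <- c(seq_len(segments)[-1], 1)
  bot <- seq_len(segments); top <- segments + seq_len(segments)
  f <- rbind(cbind(bot, nxt, top),
             cbind(nxt, segments + nxt, top))
  triangle_mesh(v, f, normals = rbind(n, n))
}

# ---- Perlin noise ----------------------------------------------------------

perlin_perm <- function(seed) {
  # seeded permutation table without touching the caller's RNG stream
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  sample(0L:255L)
}

perlin_fade <- function(t) t * t * t * (t * (t * 6 - 15) + 10)

perlin_grad <- function(h, x, y, z) {
  h <- h %% 16L
  u <- ifelse(h < 8L, x, y)
  v <- ifelse(h < 4L, y, ifelse(h == 12L | h == 14L, x, z))
  ifelse(h %% 2L == 0L, u, -u) + ifelse((h %/% 2L) %% 2L == 0L, v, -v)
}

#' Improved Perlin noise in 3D
#'
#' Classic gradient noise on the integer lattice with the quintic fade curve;
#' zero at every lattice point, continuous, deterministic for a fixed seed.
#' Values fall in roughly [-1, 1].
#'
#' @param points length-3 vector or `n x 3` matrix of sample positions.
#' @param seed integer seed for the gradient permutation table.
#' @return numeric vector of noise values.
#' @export
perlin3 <- function(points, seed = 0L) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  perm <- perlin_perm(seed)
  pp <- c(perm, perm)  # wrap-around, index with +1
  xi <- floor(p[, 1]); yi <- floor(p[, 2]); zi <- floor(p[, 3])
  xf <- p[, 1] - xi; yf <- p[, 2] - yi; zf <- p[, 3] - zi
  X <- as.integer(xi %% 256); Y <- as.integer(yi %% 256); Z <- as.integer(zi %% 256)
  u <- perlin_fade(xf); v <- perlin_fade(yf); w <- perlin_fade(zf)
  h <- function(ix, iy, iz) pp[pp[pp[ix + 1L] + iy + 1L] + iz + 1L]
  lerp <- function(a, b, t) a + t * (b - a)
  g <- function(ix, iy, iz, dx, dy, dz)
    perlin_grad(h(ix, iy, iz), xf - dx, yf - dy, zf - dz)
  X1 <- (X + 1L) %% 256L; Y1 <- (Y + 1L) %% 256L; Z1 <- (Z + 1L) %% 256L
  x00 <- lerp(g(X, Y, Z, 0, 0, 0),  g(X1, Y, Z, 1, 0, 0),  u)
  x10 <- lerp(g(X, Y1, Z, 0, 1, 0), g(X1, Y1, Z, 1, 1, 0), u)
  x01 <- lerp(g(X, Y, Z1, 0, 0, 1), g(X1, Y, Z1, 1, 0, 1), u)
  x11 <- lerp(g(X, Y1, Z1, 0, 1, 1), g(X1, Y1, Z1, 1, 1, 1), u)
  lerp(lerp(x00, x10, v), lerp(x01, x11, v), w)
}

#' Displacement-texture parameter set
#'
#' Parameters of the "clouds" displacement applied to the icosphere: `strength`
#' scales the displacement along the vertex normal, `size` is the spatial
#' scale of the noise (larger = lower frequency), `depth` the number of extra
#' noise octaves (0 = single octave), `midlevel` the texture value mapped to
#' zero displacement. `nabla` (the texture's gradient step) is retained for
#' config fidelity but has no effect on scalar displacement.
#'
#' @param strength,size,depth,nabla,midlevel,seed see description.
#' @return object of class `displacement_params`.
#' @export
displacement_params <- function(strength = 1, size = 1, depth = 0L,
                                nabla = 0.03, midlevel = 0.5, seed = 0L) {
  if (size <= 0) stop("size must be positive")
  if (depth < 0) stop("depth must be >= 0")
  if (midlevel < 0 || midlevel > 1) stop("midlevel must lie in [0,1]")
  structure(list(strength = strength, size = size, depth = as.integer(depth),
                 nabla = nabla, midlevel = midlevel, seed = as.integer(seed)),
            class = "displacement_params")
}

#' Blob displacement presets
#'
#' The three blob stimuli share one recipe and differ only in displacement
#' strength and texture size: blob 1 (1.0, 1.0), blob 2 (1.0, 0.7),
#' blob 3 (0.5, 0.4); depth 0 and nabla 0.03 throughout.
#'
#' @param which blob number 1, 2 or 3.
#' @param seed noise seed.
#' @return a `displacement_params` object.
#' @export
blob_params <- function(which, seed = 0L) {
  stopifnot(which %in% 1:3)
  strength <- c(1, 1, 0.5)[which]
  size <- c(1, 0.7, 0.4)[which]
  displacement_params(strength = strength, size = size, depth = 0L,
                      nabla = 0.03, midlevel = 0.5, seed = seed)
}

#' Clouds texture value
#'
#' Perlin octaves at `point / size`, averaged with weights `2^-i` over
#' `depth + 1` octaves and affinely remapped from [-1, 1] to [0, 1] (clamped).
#' With `depth = 0` this is a single octave.
#'
#' @param points positions (vector or matrix as in [perlin3()]).
#' @param params a `displacement_params`.
#' @return numeric vector of values in [0, 1].
#' @export
clouds_value <- function(points, params) {
  p <- if (is.null(dim(points))) matrix(points, ncol = 3) else as.matrix(points)
  acc <- 0; wsum <- 0
  for (i in 0:params$depth) {
    w <- 2^-i
    acc <- acc + w * perlin3(p * 2^i / params$size, seed = params$seed + i)
    wsum <- wsum + w
  }
  pmin(1, pmax(0, (acc / wsum + 1) / 2))
}

#' Displace a mesh along its normals
#'
#' Each vertex moves along its (incoming) normal by
#' `strength * (clouds_value(v) - midlevel)`; normals are recomputed from the
#' displaced geometry afterwards.
#'
#' @param mesh a `triangle_mesh` with valid normals.
#' @param params a `displacement_params`.
#' @return the displaced `triangle_mesh`.
#' @export
displace_mesh <- function(mesh, params) {
  d <- params$strength * (clouds_value(mesh$vertices, params) - params$midlevel)
  v <- mesh$vertices + mesh$normals * d
  triangle_mesh(v, mesh$faces)
}

#' Build one of the blob test objects
#'
#' Icosphere at the given resolution, displaced by the blob's clouds preset,
#' then uniformly rescaled so its maximum vertical extent subtends
#' `target_deg` degrees at `view_distance` scene units.
#'
#' @param which blob number 1, 2 or 3.
#' @param seed noise seed.
#' @param resolution icosphere subdivision level (6 for the full-resolution
#'   stimulus; lower is handy in tests).
#' @param target_deg angular size of the vertical extent (degrees).
#' @param view_distance viewing distance in scene units.
#' @return a `triangle_mesh`.
#' @export
make_blob <- function(which, seed = 0L, resolution = 6L, target_deg = 4.2,
                      view_distance = 1) {
  mesh <- displace_mesh(make_icosphere(resolution), blob_params(which, seed))
  scale_mesh_to_extent(mesh, target_deg, view_distance)
}

#' Rescale a mesh to a target angular size
#'
#' @param mesh a `triangle_mesh`.
#' @param target_deg desired angular subtense of the vertical (z) extent.
#' @param view_distance distance at which the subtense is measured.
#' @return the rescaled `triangle_mesh` (normals unchanged by uniform scaling).
#' @export
scale_mesh_to_extent <- function(mesh, target_deg = 4.2, view_distance = 1) {
  ext <- diff(range(mesh$vertices[, 3]))
  target <- 2 * view_distance * tan(target_deg / 2 * pi / 180)
  triangle_mesh(mesh$vertices * (target / ext), mesh$faces,
                normals = mesh$normals)
}

# ---- OBJ I/O ---------------------------------------------------------------

#' Write a mesh as Wavefront OBJ
#'
#' Emits `v`, `vn` and `f` records (faces as `i//i`, sharing vertex and
#' normal indices).
#'
#' @param mesh a `triangle_mesh`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("vn %.9g %.9g %.9g",
                     mesh$normals[, 1], mesh$normals[, 2], mesh$normals[, 3]), con)
  writeLines(sprintf("f %d//%d %d//%d %d//%d",
                     mesh$faces[, 1], mesh$faces[, 1],
                     mesh$faces[, 2], mesh$faces[, 2],
                     mesh$faces[, 3], mesh$faces[, 3]), con)
  invisible(path)
}

#' Read a Wavefront OBJ mesh
#'
#' Supports the subset written by [write_obj()]: `v`, `vn` and triangular `f`
#' records (with `i`, `i/j`, `i//k` or `i/j/k` face syntax).
#'
#' @param path OBJ file path.
#' @return a `triangle_mesh`.
#' @export
read_obj <- function(path) {
  ln <- readLines(path)
  parse3 <- function(prefix) {
    rows <- ln[startsWith(ln, prefix)]
    if (!length(rows)) return(NULL)
    matrix(as.numeric(unlist(strsplit(trimws(sub(prefix, "", rows)), "\\s+"))),
           ncol = 3, byrow = TRUE)
  }
  v <- parse3("v ")
  vn <- parse3("vn ")
  frows <- ln[startsWith(ln, "f ")]
  fidx <- vapply(strsplit(trimws(sub("^f ", "", frows)), "\\s+"), function(parts) {
    as.integer(vapply(strsplit(parts, "/"), `[[`, "", 1))
  }, integer(3))
  triangle_mesh(v, t(fidx), normals = vn)
}
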