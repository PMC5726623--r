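# Pipeline orchestration, configuration and file formats.
#
# One call runs meshes -> renders -> statistics -> split curves -> model fits
# from a single config and seed, writing plain-format outputs (OBJ, PGM, CSV,
# JSON) plus a hashed manifest so runs can be compared byte for byte.

# fixed per-stage seed offsets so stages are independently reproducible
SEED_OFFSETS <- c(mesh = 11L, observer = 23L, fixtures = 37L)

#' Shape meshes of the stimulus set
#'
#' The three blob shapes are displaced icospheres (see [make_blob()]); the
#' sphere and cylinder primitives stand in for the remaining shapes. Each
#' mesh is scaled to its stimulus angular size (blobs 4.2 / 4.0 / 4.3
#' degrees of visual angle; sphere and cylinder 4.2).
#'
#' @param shape one of `"blob1"`, `"blob2"`, `"blob3"`, `"sphere"`,
#'   `"cylinder"`.
#' @param seed noise seed for the blob displacement.
#' @param resolution icosphere subdivision level for blobs and sphere.
#' @return a `triangle_mesh`.
#' @export
make_shape_mesh <- function(shape, seed = 0L, resolution = 5L) {
  ext <- c(blob1 = 4.2, blob2 = 4.0, blob3 = 4.3, sphere = 4.2,
           cylinder = 4.2)
  if (!shape %in% names(ext)) stop("unknown shape: ", shape)
  mesh <- switch(shape,
    blob1 = make_blob(1, seed = seed, resolution = resolution,
                      target_deg = ext[["blob1"]]),
    blob2 = make_blob(2, seed = seed, resolution = resolution,
                      target_deg = ext[["blob2"]]),
    blob3 = make_blob(3, seed = seed, resolution = resolution,
                      target_deg = ext[["blob3"]]),
    sphere = scale_mesh_to_extent(make_sphere(1, resolution = resolution),
                                  ext[["sphere"]]),
    cylinder = scale_mesh_to_extent(make_cylinder(0.3, 1, segments = 96),
                                    ext[["cylinder"]]))
  mesh
}

#' Render one stimulus condition
#'
#' Convenience wrapper: build (or reuse) the shape mesh, place the lights at
#' the given spread and intensity, and render from the standard camera (or
#' the stereo pair).
#'
#' @param shape,smoothness,alpha,intensity condition factors.
#' @param seed mesh noise seed.
#' @param size per-half-image size `c(rows, cols)`.
#' @param resolution mesh subdivision level.
#' @param stereo render the side-by-side stereo pair.
#' @param clip clip channels at 1.0.
#' @param ambient_intensity ambient level (0.6 in the stimuli).
#' @param fov camera vertical field of view, degrees.
#' @param mesh optional prebuilt `triangle_mesh` (overrides `shape`).
#' @return a `rendered_image`.
#' @export
render_condition <- function(shape, smoothness, alpha, intensity,
                             seed = 0L, size = c(128, 128), resolution = 5L,
                             stereo = FALSE, clip = TRUE,
                             ambient_intensity = 0.6, fov = 10,
                             mesh = NULL) {
  if (is.null(mesh)) mesh <- make_shape_mesh(shape, seed, resolution)
  sc <- scene(mesh, material(smoothness), place_lights(alpha, intensity),
              ambient_intensity = ambient_intensity, spread_alpha = alpha)
  if (stereo) {
    render_stereo(sc,
                  default_camera("left", fov = fov, size = size),
                  default_camera("right", fov = fov, size = size),
                  clip = clip)
  } else {
    render(sc, default_camera("center", fov = fov, size = size), clip = clip)
  }
}

#' Pipeline run configuration
#'
#' All knobs of a pipeline run in one serializable object; a run is
#' reproducible from its config plus seed.
#'
#' @param seed global integer seed (fans out to fixed per-stage seeds).
#' @param shapes,smoothness,alpha,intensity design factor levels.
#' @param size per-half-image render size.
#' @param resolution mesh subdivision level.
#' @param stereo render stereo pairs.
#' @param clip clip at the display ceiling.
#' @param curvature_radius cross-section radius for the alpha* curves.
#' @param observer an `observer_params` for the synthetic responses.
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       shapes = c("blob1", "sphere"),
                       smoothness = c(0.2, 0.4, 0.6),
                       alpha = c(0, 0.32),
                       intensity = c(0.5, 1.5),
                       size = c(64, 64), resolution = 4L, stereo = FALSE,
                       clip = TRUE, curvature_radius = 0.0367,
                       observer = observer_params(seed = seed + SEED_OFFSETS[["observer"]]),
                       out_dir = tempfile("glossim_run_")) {
  structure(list(seed = as.integer(seed), shapes = shapes,
                 smoothness = smoothness, alpha = alpha,
                 intensity = intensity, size = as.integer(size),
                 resolution = as.integer(resolution), stereo = stereo,
                 clip = clip, curvature_radius = curvature_radius,
                 observer = observer, out_dir = out_dir),
            class = "run_config")
}

#' Serialize / restore a run config
#'
#' @param config a `run_config`.
#' @param path JSON file path.
#' @return `write_run_config` returns `path`; `read_run_config` the config.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  x$observer <- unclass(x$observer)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  obs <- observer_params(intercept = x$observer$intercept,
                         weights = unlist(x$observer$weights),
                         noise_sd = x$observer$noise_sd,
                         seed = x$observer$seed)
  run_config(seed = x$seed, shapes = x$shapes, smoothness = x$smoothness,
             alpha = x$alpha, intensity = x$intensity, size = x$size,
             resolution = x$resolution, stereo = x$stereo, clip = x$clip,
             curvature_radius = x$curvature_radius, observer = obs,
             out_dir = x$out_dir)
}

# ---- image files -----------------------------------------------------------

#' Write a luminance matrix as 16-bit binary PGM
#'
#' Values are clamped to `[0, white]` and scaled to the 16-bit range.
#'
#' @param mat numeric matrix.
#' @param path output path.
#' @param white luminance value mapped to the PGM maximum.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(mat, path, white = 1) {
  maxval <- 65535L
  q <- round(pmin(pmax(mat / white, 0), 1) * maxval)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P5\n%d %d\n%d\n", ncol(mat), nrow(mat), maxval), con,
            eos = NULL)
  # PGM is row-major, big-endian; write the two bytes by hand so values
  # above 32767 are safe
  v <- as.integer(t(q))
  writeBin(as.raw(rbind(v %/% 256L, v %% 256L)), con)
  invisible(path)
}

#' Read a binary PGM file
#'
#' @param path PGM (P5) file path.
#' @param white luminance value of the PGM maximum (inverse of the scaling
#'   used by [write_pgm()]).
#' @return numeric matrix.
#' @export
read_pgm <- function(path, white = 1) {
  bytes <- readBin(path, "raw", n = file.size(path))
  # header: magic, width, height, maxval as whitespace-separated tokens
  # (comment lines not supported; we never write them)
  ws <- bytes %in% as.raw(c(0x20, 0x09, 0x0a, 0x0d))
  tok_end <- 0L; tokens <- character(4)
  pos <- 1L
  for (k in 1:4) {
    while (ws[pos]) pos <- pos + 1L
    start <- pos
    while (pos <= length(bytes) && !ws[pos]) pos <- pos + 1L
    tokens[k] <- rawToChar(bytes[start:(pos - 1L)])
  }
  pos <- pos + 1L  # single whitespace after maxval
  if (!identical(tokens[1], "P5")) stop("only binary PGM (P5) is supported")
  nc <- as.integer(tokens[2]); nr <- as.integer(tokens[3])
  maxval <- as.integer(tokens[4])
  sz <- if (maxval > 255) 2 else 1
  raw <- readBin(bytes[pos:length(bytes)], "integer", n = nr * nc, size = sz,
                 signed = FALSE, endian = "big")
  matrix(raw, nr, nc, byrow = TRUE) / maxval * white
}

#' Write an rgb image as binary PPM (gamma-encoded for viewing)
#'
#' @param rgb rows x cols x 3 array of linear values in [0, 1+].
#' @param path output path.
#' @param gamma display gamma used for encoding.
#' @return `path`, invisibly.
#' @export
write_ppm <- function(rgb, path, gamma = 2.2) {
  q <- round(pmin(pmax(rgb, 0), 1)^(1 / gamma) * 255)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(sprintf("P6\n%d %d\n255\n", dim(rgb)[2], dim(rgb)[1]), con,
            eos = NULL)
  px <- aperm(q, c(3, 2, 1))  # channel fastest, then column, then row
  writeBin(as.raw(px), con)
  invisible(path)
}

# ---- CSV -------------------------------------------------------------------

#' Write a records table as CSV
#'
#' Comma separated, UTF-8, header row, "." decimal; numeric columns
#' serialized with 9 significant digits.
#'
#' @param df data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_records_csv <- function(df, path) {
  for (j in seq_along(df)) if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 9)
  utils::write.csv(df, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_records_csv <- function(path) {
  utils::read.csv(path, fileEncoding = "UTF-8", stringsAsFactors = FALSE)
}

# ---- pipeline --------------------------------------------------------------

#' Run the full pipeline
#'
#' Executes every stage from one config: builds and writes the shape meshes,
#' renders every condition of the design grid, computes the highlight
#' statistics table, the alpha* split curves, synthetic-observer responses
#' and the model fits, and writes a manifest with an md5 hash of every
#' output file plus a log of versions, seed and timings.
#'
#' @param config a `run_config`.
#' @return the manifest (data frame of `file`, `md5`), invisibly; all outputs
#'   under `config$out_dir`.
#' @export
run_pipeline <- function(config = run_config()) {
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  for (d in c("meshes", "renders")) dir.create(file.path(out, d),
                                               showWarnings = FALSE)
  t0 <- Sys.time()
  timings <- list()
  stage <- function(name, expr) {
    ts <- Sys.time()
    r <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), ts, units = "secs"))
    r
  }
  files <- character(0)
  add <- function(p) files <<- c(files, p)

  add(write_run_config(config, file.path(out, "config.json")))

  mesh_seed <- config$seed + SEED_OFFSETS[["mesh"]]
  meshes <- stage("meshes", {
    ms <- lapply(config$shapes, make_shape_mesh, seed = mesh_seed,
                 resolution = config$resolution)
    names(ms) <- config$shapes
    for (s in config$shapes)
      add(write_obj(ms[[s]], file.path(out, "meshes", paste0(s, ".obj"))))
    ms
  })

  design <- enumerate_design(smoothness = config$smoothness,
                             alpha = config$alpha, shapes = config$shapes,
                             intensity = config$intensity)
  stats_df <- stage("renders_and_stats", {
    rows <- vector("list", nrow(design))
    for (i in seq_len(nrow(design))) {
      cond <- design[i, ]
      img <- tryCatch(
        render_condition(cond$shape, cond$smoothness, cond$alpha,
                         cond$intensity, size = config$size,
                         stereo = config$stereo, clip = config$clip,
                         mesh = meshes[[cond$shape]]),
        error = function(e)
          stop(sprintf("condition (%s, s=%g, a=%g, i=%g): %s", cond$shape,
                       cond$smoothness, cond$alpha, cond$intensity,
                       conditionMessage(e)), call. = FALSE))
      base <- sprintf("%s_s%03d_a%03d_i%02d", cond$shape,
                      round(cond$smoothness * 100), round(cond$alpha * 100),
                      round(cond$intensity * 10))
      add(write_pgm(img$luminance, file.path(out, "renders",
                                             paste0(base, ".pgm"))))
      add(write_pgm(img$foreground_mask * 1,
                    file.path(out, "renders", paste0(base, "_mask.pgm"))))
      rows[[i]] <- stimulus_record(img, meta = as.list(cond))
    }
    df <- do.call(rbind, rows)
    add(write_records_csv(df, file.path(out, "stats.csv")))
    df
  })

  stage("split_curves", {
    curves <- alpha_star_curve(config$smoothness,
                               curvature_radius = config$curvature_radius)
    add(write_records_csv(curves, file.path(out, "split_curves.csv")))
  })

  stage("model_fits", {
    recs <- synth_observer(stats_df, config$observer)
    add(write_records_csv(recs, file.path(out, "records.csv")))
    fits <- subset_analysis(recs)
    if (length(unique(recs$intensity)) > 1) {
      fi <- subset_analysis(recs, "intensity")
      fi$subset <- paste0("intensity=", fi$intensity)
      fi$intensity <- NULL
      fits <- rbind(fits, fi[, names(fits)])
    }
    add(write_records_csv(fits, file.path(out, "fits.csv")))
  })

  log <- list(r_version = as.character(getRversion()),
              package_version = as.character(utils::packageVersion("glossim")),
              seed = config$seed,
              started = format(t0, "%Y-%m-%dT%H:%M:%S"),
              timings_sec = timings)
  jsonlite::write_json(log, file.path(out, "log.json"), auto_unbox = TRUE,
                       digits = 6, pretty = TRUE)
  add(file.path(out, "log.json"))

  manifest <- data.frame(file = sub(paste0("^", out, "/?"), "", files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Write the deterministic test fixtures
#'
#' Small plain-text inputs used by the test suite: a 5x5 toy luminance
#' matrix whose two bright pixels touch only diagonally, a two-lobe 1D
#' profile, a 3-point regression set with y = 2x, and a 64x64 sphere render
#' (PGM luminance + mask).
#'
#' @param seed integer seed (fans out from the global seed).
#' @param dir output directory.
#' @return data frame of `file`, `md5`, invisibly.
#' @export
make_fixtures <- function(seed = 1L, dir = tempfile("glossim_fixtures_")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)

  toy <- matrix(0.1, 5, 5)
  toy[2, 2] <- 0.9
  toy[3, 3] <- 0.8   # touches (2,2) only diagonally
  p <- file.path(dir, "toy5x5.csv")
  utils::write.csv(as.data.frame(toy), p, row.names = FALSE)
  files <- c(files, p)

  th <- seq(-1, 1, length.out = 401)
  prof <- exp(-(th - 0.4)^2 / (2 * 0.05^2)) + exp(-(th + 0.4)^2 / (2 * 0.05^2))
  p <- file.path(dir, "two_lobe_profile.csv")
  write_records_csv(data.frame(angle = th, intensity = prof), p)
  files <- c(files, p)

  p <- file.path(dir, "regression3.csv")
  utils::write.csv(data.frame(x = c(1, 2, 3), y = c(2, 4, 6)), p,
                   row.names = FALSE)
  files <- c(files, p)

  img <- render_condition("sphere", smoothness = 0.5, alpha = 0.32,
                          intensity = 1.5, seed = seed + SEED_OFFSETS[["fixtures"]],
                          size = c(64, 64), resolution = 3L)
  p <- file.path(dir, "render64.pgm")
  write_pgm(img$luminance, p)
  files <- c(files, p)
  p <- file.path(dir, "render64_mask.pgm")
  write_pgm(img$foreground_mask * 1, p)
  files <- c(files, p)

  invisible(data.frame(file = basename(files),
                       md5 = unname(tools::md5sum(files)),
                       stringsAsFactors = FALSE))
}
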