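# Superposition and split-up of specular lobes.
#
# Three point lights project three specular lobes onto a curved surface; at
# small light spreads the lobes merge into one broad highlight, and as the
# spread grows they separate. This module evaluates the specular intensity
# profile along an equatorial cross-section analytically (all lights, cameras
# and the object centre are coplanar in the stimulus layout), detects whether
# the profile is resolved into separate peaks under a Rayleigh-style
# dip-depth criterion, and finds the critical spread alpha* per smoothness.

#' Resolvability criterion
#'
#' Two adjacent peaks count as resolved when the dip between them is deep
#' enough: `dip_depth = 1 - min_between / lower_adjacent_peak` must reach
#' `dip_fraction`. The default 0.26 is the classical Rayleigh-style dip for
#' two equal narrow lines. `min_peak_prominence` (as a fraction of the
#' profile maximum) suppresses numerical micro-peaks.
#'
#' @param dip_fraction required dip depth in (0,1).
#' @param min_peak_prominence minimum relative dip separating two maxima for
#'   them to count as distinct peaks at all; shallower pairs are merged into
#'   the higher peak (suppresses numerical and Fresnel micro-structure).
#' @param min_peaks minimum number of peaks for "resolved" (2 for generic
#'   two-lobe profiles; use 3 when asking whether all three light highlights
#'   are individually discernible).
#' @param min_peak_height peaks lower than this fraction of the profile
#'   maximum are ignored entirely (suppresses grazing-angle Fresnel rim
#'   glints at the profile boundary).
#' @return object of class `split_criterion`.
#' @export
split_criterion <- function(dip_fraction = 0.26, min_peak_prominence = 0.02,
                            min_peaks = 2L, min_peak_height = 0.02) {
  if (dip_fraction <= 0 || dip_fraction >= 1)
    stop("dip_fraction must lie in (0,1)")
  structure(list(dip_fraction = dip_fraction,
                 min_peak_prominence = min_peak_prominence,
                 min_peaks = as.integer(min_peaks),
                 min_peak_height = min_peak_height),
            class = "split_criterion")
}

#' Specular intensity profile along an equatorial cross-section
#'
#' Evaluates the renderer's specular term (GGX x Fresnel x visibility,
#' weighted by intensity, attenuation and the clamped cosine) on a circular
#' cross-section of radius `curvature_radius` centred at the origin in the
#' horizontal plane, under the standard three-light arrangement at spread
#' `alpha`, viewed from the default camera position. Points facing away from
#' the camera contribute zero.
#'
#' @param curvature_radius local curvature radius of the cross-section
#'   (scene units).
#' @param smoothness material smoothness in [0,1].
#' @param alpha light spread in [0,1].
#' @param n_samples number of samples of the tangent angle.
#' @param intensity light intensity.
#' @param span half-range of the surface angle sampled, radians (measured
#'   from the point nearest the camera). The default 1.1 rad (~63 deg)
#'   covers the mirror reflections of all three lights at every spread
#'   (the lateral mirror points reach ~50 deg at spread 1) while excluding
#'   the grazing limb, whose thin Fresnel rim glints are not part of the
#'   highlight group under study.
#' @param cam_distance camera distance from the object centre.
#' @param F0 Fresnel base reflectance.
#' @param shading shading mode, as in [material()]; must match the renders
#'   the profile is compared against.
#' @return object of class `lobe_profile`: `angles` (radians), `intensity`,
#'   `degenerate` flag and a `geometry` record.
#' @export
lobe_profile <- function(curvature_radius, smoothness, alpha,
                         n_samples = 2048, intensity = 1.5, span = 1.1,
                         cam_distance = 1, F0 = 0.04,
                         shading = c("engine_gamma", "physical")) {
  if (curvature_radius <= 0) stop("curvature_radius must be positive")
  if (curvature_radius >= cam_distance)
    stop("curvature_radius must be smaller than cam_distance ",
         "(the camera must sit outside the surface)")
  if (smoothness < 0 || smoothness > 1) stop("smoothness must lie in [0,1]")
  mat <- material(smoothness, F0 = F0, shading = match.arg(shading))
  th <- seq(-span, span, length.out = n_samples)
  # surface points and outward normals on the circle; theta = 0 faces the camera
  pts <- cbind(curvature_radius * sin(th), -curvature_radius * cos(th), 0)
  nrm <- cbind(sin(th), -cos(th), 0)
  campos <- c(0, -cam_distance, 0)
  vdir <- normalize_rows(-sweep(pts, 2, campos, check.margin = FALSE))
  lights <- place_lights(alpha, intensity = intensity)
  a <- max(smoothness_to_roughness(smoothness), 1e-4)
  n_v <- rowSums(nrm * vdir)
  y <- numeric(n_samples)
  for (L in lights) {
    lv <- -sweep(pts, 2, L$position, check.margin = FALSE)
    dist <- row_norms(lv)
    lv <- lv / dist
    n_l <- rowSums(nrm * lv)
    ok <- n_v > 0 & n_l > 0
    h <- normalize_rows(lv + vdir)
    n_h <- pmin(1, pmax(0, rowSums(nrm * h)))
    v_h <- pmin(1, pmax(0, rowSums(vdir * h)))
    term <- specular_term(mat, ggx_ndf(n_h, a),
                          smith_vis(pmax(n_l, 1e-6), pmax(n_v, 1e-6), a),
                          v_h) *
      L$intensity * attenuation(dist, L$range) * pmax(n_l, 0)
    y <- y + term * ok
  }
  structure(list(angles = th, intensity = y,
                 degenerate = all(y <= 0),
                 geometry = list(curvature_radius = curvature_radius,
                                 smoothness = smoothness, alpha = alpha,
                                 cam_distance = cam_distance)),
            class = "lobe_profile")
}

# strict local maxima of a 1D profile after collapsing exact plateaus
find_local_maxima <- function(y) {
  n <- length(y)
  if (n < 3) return(integer(0))
  keep <- c(TRUE, diff(y) != 0)
  map <- which(keep)
  z <- y[keep]
  m <- length(z)
  if (m < 3) return(integer(0))
  core <- 2:(m - 1)
  map[core[z[core] > z[core - 1] & z[core] > z[core + 1]]]
}

# relative dip between adjacent peaks: 1 - valley / lower_peak
pairwise_dips <- function(y, idx) {
  if (length(idx) < 2) return(numeric(0))
  vapply(seq_len(length(idx) - 1), function(k) {
    lo <- min(y[idx[k]:idx[k + 1]])
    1 - lo / min(y[idx[k]], y[idx[k + 1]])
  }, 0)
}

# iteratively merge adjacent peak pairs whose relative dip is below the
# threshold, dropping the lower (second, on ties) peak of the shallowest pair
merge_shallow_peaks <- function(y, idx, min_dip) {
  while (length(idx) >= 2) {
    dips <- pairwise_dips(y, idx)
    k <- which.min(dips)
    if (dips[k] >= min_dip) break
    drop <- if (y[idx[k]] < y[idx[k + 1]]) k else k + 1
    idx <- idx[-drop]
  }
  idx
}

#' Detect whether a profile is split into separate highlights
#'
#' Finds strict local maxima, merges adjacent maxima separated by a relative
#' dip below `min_peak_prominence` into the higher one, computes the dip
#' depth between each surviving adjacent pair
#' (`1 - min_between / lower_peak`), and declares the profile resolved when
#' there are at least `min_peaks` peaks and every dip reaches
#' `dip_fraction`.
#'
#' @param profile a `lobe_profile` (or any list with `angles`/`intensity`).
#' @param criterion a `split_criterion`.
#' @return object of class `split_result`: `n_peaks`, `peak_angles`,
#'   `dip_depths`, `resolved`.
#' @export
detect_split <- function(profile, criterion = split_criterion()) {
  y <- profile$intensity
  if (all(y <= 0)) stop("all-zero profile: nothing to detect")
  idx <- find_local_maxima(y)
  idx <- idx[y[idx] >= criterion$min_peak_height * max(y)]
  idx <- merge_shallow_peaks(y, idx, criterion$min_peak_prominence)
  dips <- pairwise_dips(y, idx)
  resolved <- length(idx) >= max(2L, criterion$min_peaks) &&
    length(dips) > 0 && min(dips) >= criterion$dip_fraction
  structure(list(n_peaks = length(idx),
                 peak_angles = profile$angles[idx],
                 dip_depths = dips, resolved = resolved),
            class = "split_result")
}

#' Critical light spread for highlight separation
#'
#' Smallest spread alpha at which the equatorial profile is resolved into
#' separate highlights under the criterion, found by a coarse scan followed
#' by bisection to `tol`. Returns `NA` with attribute `feasible = FALSE`
#' when even `alpha = 1` leaves the highlights merged (the "not feasible"
#' outcome).
#'
#' @param curvature_radius,smoothness passed to [lobe_profile()].
#' @param criterion a `split_criterion`; the default demands all three
#'   light highlights be individually discernible (`min_peaks = 3`), which
#'   is the three-light separation task.
#' @param tol bisection tolerance on alpha.
#' @param n_samples profile resolution.
#' @param intensity light intensity.
#' @return alpha* in [0,1], or `NA_real_` (attr `feasible = FALSE`).
#' @export
find_alpha_star <- function(curvature_radius, smoothness,
                            criterion = split_criterion(min_peaks = 3L),
                            tol = 1e-3,
                            n_samples = 2048, intensity = 1.5) {
  is_res <- function(a) {
    pr <- lobe_profile(curvature_radius, smoothness, a, n_samples = n_samples,
                       intensity = intensity)
    if (pr$degenerate) return(FALSE)
    detect_split(pr, criterion)$resolved
  }
  grid <- seq(0, 1, length.out = 33)
  res <- vapply(grid, is_res, FALSE)
  if (!any(res)) {
    out <- NA_real_
    attr(out, "feasible") <- FALSE
    return(out)
  }
  first <- which(res)[1]
  if (first == 1) {
    out <- 0
    attr(out, "feasible") <- TRUE
    return(out)
  }
  lo <- grid[first - 1]; hi <- grid[first]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (is_res(mid)) hi <- mid else lo <- mid
  }
  out <- hi
  attr(out, "feasible") <- TRUE
  out
}

#' Alpha* curve over a smoothness grid
#'
#' @param smoothness_grid numeric vector of smoothness values.
#' @param curvature_radius surface curvature radius.
#' @param criterion a `split_criterion`.
#' @param ... passed to [find_alpha_star()].
#' @return `data.frame` with columns `smoothness`, `alpha_star`, `feasible`.
#' @export
alpha_star_curve <- function(smoothness_grid, curvature_radius = 0.0367,
                             criterion = split_criterion(min_peaks = 3L),
                             ...) {
  rows <- lapply(smoothness_grid, function(s) {
    a <- find_alpha_star(curvature_radius, s, criterion, ...)
    data.frame(smoothness = s,
               alpha_star = as.numeric(a),
               feasible = isTRUE(attr(a, "feasible")))
  })
  do.call(rbind, rows)
}

#' Split detection on a rendered image
#'
#' Bridges the analytic and rendered paths: takes the maximum luminance
#' projection of a rectangular region of interest across its short axis and
#' runs [detect_split()] on the resulting 1D profile.
#'
#' @param image a `rendered_image`.
#' @param roi list with integer ranges `rows = c(r0, r1)`,
#'   `cols = c(c0, c1)` (1-based, inclusive).
#' @param criterion a `split_criterion`.
#' @return a `split_result` (with `peak_angles` holding pixel indices along
#'   the long axis).
#' @export
image_split_detect <- function(image, roi, criterion = split_criterion()) {
  ri <- roi$rows[1]:roi$rows[2]
  ci <- roi$cols[1]:roi$cols[2]
  sub <- image$luminance[ri, ci, drop = FALSE]
  subm <- image$foreground_mask[ri, ci, drop = FALSE]
  if (!any(subm)) stop("roi covers no foreground pixels")
  sub[!subm] <- 0
  prof <- if (nrow(sub) <= ncol(sub)) apply(sub, 2, max) else apply(sub, 1, max)
  detect_split(list(angles = seq_along(prof), intensity = prof), criterion)
}
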