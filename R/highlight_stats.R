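# Gloss-layer segmentation and global highlight image statistics.
#
# The gloss layer is the set of foreground pixels whose luminance exceeds the
# foreground mean by more than two standard deviations; connected highlight
# regions are counted under 8-connectivity. Background pixels are ignored in
# every calculation.

#' Label connected regions of a binary mask
#'
#' 8-connectivity (all eight neighbouring pixels, including diagonals), as
#' used for counting highlight regions.
#'
#' @param mask logical matrix.
#' @return integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  cpp_label8(mask)
}

#' Segment the gloss layer of a rendered image
#'
#' Threshold = mean + 2 * SD of the foreground luminance distribution
#' (population SD); pixels strictly greater than the threshold form the
#' highlight mask, which is then labelled into connected components using
#' 8-connectivity.
#'
#' @param image a `rendered_image` with non-empty foreground.
#' @param k SD multiplier (2 in the standard procedure).
#' @return object of class `gloss_layer` with elements `binary_mask`,
#'   `labels` (0 = background), `n_components`, `threshold`.
#' @export
segment_gloss_layer <- function(image, k = 2) {
  fg <- image$foreground_mask
  if (!any(fg)) stop("empty foreground: nothing to segment")
  vals <- image$luminance[fg]
  thr <- mean(vals) + k * sqrt(mean((vals - mean(vals))^2))
  mask <- fg & (image$luminance > thr)
  labels <- cpp_label8(mask)
  structure(list(binary_mask = mask, labels = labels,
                 n_components = max(labels), threshold = thr),
            class = "gloss_layer")
}

#' @export
print.gloss_layer <- function(x, ...) {
  cat(sprintf("gloss_layer: %d component(s), %d px, threshold %.6g\n",
              x$n_components, sum(x$binary_mask), x$threshold))
  invisible(x)
}

#' Global highlight statistics
#'
#' The four image statistics of the gloss layer: `number` of connected
#' highlights (components divided by the number of half-images), `mean_size`
#' in pixels per component, `pct_area` (highlight pixels over foreground
#' pixels, in [0,1]) and `strength` (mean luminance of highlight pixels).
#' An empty gloss layer yields `NA` statistics flagged invalid.
#'
#' @param layer a `gloss_layer` derived from `image`.
#' @param image the `rendered_image` the layer came from.
#' @return object of class `highlight_statistics` with fields `number`,
#'   `mean_size`, `pct_area`, `strength`, and `valid`.
#' @export
compute_statistics <- function(layer, image) {
  nc <- layer$n_components
  npx <- sum(layer$binary_mask)
  nfg <- sum(image$foreground_mask)
  if (nc == 0) {
    out <- list(number = NA_real_, mean_size = NA_real_, pct_area = NA_real_,
                strength = NA_real_, valid = FALSE)
  } else {
    out <- list(number = nc / image$n_views,
                mean_size = npx / nc,
                pct_area = npx / nfg,
                strength = mean(image$luminance[layer$binary_mask]),
                valid = TRUE)
  }
  structure(out, class = "highlight_statistics")
}

# separable sliding min/max with out-of-mask values neutralized
window_extrema <- function(lum, fg, w) {
  h <- w %/% 2
  shift_mat <- function(m, di, dj, fill) {
    nr <- nrow(m); nc <- ncol(m)
    out <- matrix(fill, nr, nc)
    ri <- seq_len(nr) + di; ci <- seq_len(nc) + dj
    ok_r <- ri >= 1 & ri <= nr; ok_c <- ci >= 1 & ci <= nc
    out[ok_r, ok_c] <- m[ri[ok_r], ci[ok_c]]
    out
  }
  run1 <- function(m, along, fill, fun) {
    acc <- m
    for (d in seq_len(h)) {
      if (along == "row") {
        acc <- fun(acc, shift_mat(m, d, 0, fill), shift_mat(m, -d, 0, fill))
      } else {
        acc <- fun(acc, shift_mat(m, 0, d, fill), shift_mat(m, 0, -d, fill))
      }
    }
    acc
  }
  lo <- lum; lo[!fg] <- Inf
  hi <- lum; hi[!fg] <- -Inf
  lo <- run1(run1(lo, "row", Inf, pmin), "col", Inf, pmin)
  hi <- run1(run1(hi, "row", -Inf, pmax), "col", -Inf, pmax)
  list(min = lo, max = hi)
}

#' Foreground contrast measures
#'
#' Three luminance contrasts over the object (background ignored):
#' the global Michelson contrast `(Lmax - Lmin) / (Lmax + Lmin)`, and
#' space-averaged Michelson and Whittle contrasts obtained by evaluating the
#' respective contrast in a sliding square window (side `window`, restricted
#' to foreground pixels) centred on every foreground pixel and averaging.
#' The Whittle contrast per window is `(Lmax - Lmin) / max(Lmin, eps)`.
#'
#' @param image a `rendered_image` with non-empty foreground.
#' @param window side length of the square window in pixels (odd).
#' @param eps floor on the Whittle denominator.
#' @return object of class `contrast_measures` with fields `michelson`,
#'   `space_avg_michelson`, `space_avg_whittle`.
#' @export
contrasts <- function(image, window = 15, eps = 1e-4) {
  fg <- image$foreground_mask
  if (!any(fg)) stop("empty foreground")
  vals <- image$luminance[fg]
  lmax <- max(vals); lmin <- min(vals)
  mich <- if (lmax + lmin == 0) 0 else (lmax - lmin) / (lmax + lmin)
  ext <- window_extrema(image$luminance, fg, window)
  wmin <- ext$min[fg]; wmax <- ext$max[fg]
  den <- wmax + wmin
  m_w <- ifelse(den == 0, 0, (wmax - wmin) / den)
  wh_w <- (wmax - wmin) / pmax(wmin, eps)
  structure(list(michelson = mich,
                 space_avg_michelson = mean(m_w),
                 space_avg_whittle = mean(wh_w)),
            class = "contrast_measures")
}

#' Validity flags for a stimulus
#'
#' A stimulus is invalid when its gloss layer is empty (no pixel exceeds the
#' threshold) or when any foreground pixel sits at the clipping ceiling.
#'
#' @param image a `rendered_image`.
#' @param layer the corresponding `gloss_layer` (computed if omitted).
#' @return object of class `validity_flags` with fields `empty_gloss_layer`,
#'   `clipped`, `invalid`.
#' @export
validity <- function(image, layer = NULL) {
  if (is.null(layer)) layer <- segment_gloss_layer(image)
  empty <- layer$n_components == 0
  clipped <- image$clipped_count > 0 ||
    (isTRUE(image$clip) &&
     any(image$foreground_mask & image$luminance >= image$clip_ceiling))
  structure(list(empty_gloss_layer = empty, clipped = clipped,
                 invalid = empty || clipped),
            class = "validity_flags")
}

#' One CSV-ready record of image statistics for a stimulus
#'
#' Convenience wrapper running segmentation, statistics, contrasts and
#' validity on one rendered image and returning a single-row data frame.
#'
#' @param image a `rendered_image`.
#' @param meta named list of condition descriptors (shape, smoothness, alpha,
#'   intensity, ...) prepended as columns.
#' @param window,eps passed to [contrasts()].
#' @return one-row `data.frame`.
#' @export
stimulus_record <- function(image, meta = list(), window = 15, eps = 1e-4) {
  layer <- segment_gloss_layer(image)
  st <- compute_statistics(layer, image)
  ct <- contrasts(image, window = window, eps = eps)
  vf <- validity(image, layer)
  cbind(as.data.frame(meta),
        data.frame(number = st$number, mean_size = st$mean_size,
                   pct_area = st$pct_area, strength = st$strength,
                   michelson = ct$michelson,
                   sa_michelson = ct$space_avg_michelson,
                   sa_whittle = ct$space_avg_whittle,
                   invalid = vf$invalid, clipped_count = image$clipped_count))
}
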