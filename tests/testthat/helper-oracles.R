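# Independent brute-force oracles used to cross-check the implementation.

# Recursive-free flood fill labelling of a binary mask.
# connectivity: 8 (default) or 4.
flood_fill_label <- function(mask, connectivity = 8) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  offs <- if (connectivity == 8) {
    expand.grid(di = -1:1, dj = -1:1)
  } else {
    data.frame(di = c(-1, 1, 0, 0), dj = c(0, 0, -1, 1))
  }
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    stack <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(stack) > 0) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (k in seq_len(nrow(offs))) {
        ni <- cur[1] + offs$di[k]; nj <- cur[2] + offs$dj[k]
        if (ni >= 1 && nj >= 1 && ni <= nr && nj <= nc &&
            mask[ni, nj] && lab[ni, nj] == 0L) {
          lab[ni, nj] <- nxt
          stack[[length(stack) + 1]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}

# canonical relabelling by first occurrence (column-major), so two labelings
# can be compared independently of label order
canonical_labels <- function(lab) {
  ids <- unique(lab[lab != 0])
  out <- lab
  for (k in seq_along(ids)) out[lab == ids[k]] <- k
  out
}

# naive O(n^2)-ish peak/dip oracle implementing the same definition as
# detect_split with explicit loops: strict local maxima (plateaus collapsed),
# height floor, iterative merging of shallow pairs, dip-depth test
oracle_split <- function(y, dip_fraction = 0.26, min_prom = 0.02,
                         min_peaks = 2, min_height = 0.02) {
  # plateau-collapsed strict maxima
  keep <- c(TRUE, diff(y) != 0)
  z <- y[keep]; map <- which(keep)
  idx <- integer(0)
  if (length(z) >= 3) {
    for (i in 2:(length(z) - 1))
      if (z[i] > z[i - 1] && z[i] > z[i + 1]) idx <- c(idx, map[i])
  }
  idx <- idx[y[idx] >= min_height * max(y)]
  dips_of <- function(idx) {
    if (length(idx) < 2) return(numeric(0))
    d <- numeric(length(idx) - 1)
    for (k in seq_len(length(idx) - 1)) {
      lo <- min(y[idx[k]:idx[k + 1]])
      d[k] <- 1 - lo / min(y[idx[k]], y[idx[k + 1]])
    }
    d
  }
  repeat {
    if (length(idx) < 2) break
    d <- dips_of(idx)
    k <- which.min(d)
    if (d[k] >= min_prom) break
    idx <- idx[-(if (y[idx[k]] < y[idx[k + 1]]) k else k + 1)]
  }
  d <- dips_of(idx)
  list(n_peaks = length(idx),
       resolved = length(idx) >= max(2, min_peaks) && length(d) > 0 &&
         min(d) >= dip_fraction)
}

# random Gaussian-mixture profile on a fixed grid
random_mixture_profile <- function(n_lobes, grid = seq(0, 1, length.out = 600)) {
  y <- rep(0, length(grid))
  for (k in seq_len(n_lobes)) {
    mu <- stats::runif(1, 0.1, 0.9)
    sdv <- stats::runif(1, 0.01, 0.15)
    amp <- stats::runif(1, 0.2, 1)
    y <- y + amp * exp(-(grid - mu)^2 / (2 * sdv^2))
  }
  list(angles = grid, intensity = y)
}
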