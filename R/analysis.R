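# Place-field quantification: occupancy-normalized rate maps, field centroid
# and size, rotation and remapping statistics.

#' Occupancy-normalized firing rate map
#'
#' Bins the arena into an `n_bins x n_bins` grid, attributes each somatic
#' spike to the trajectory sample nearest in time, and divides per-bin spike
#' counts by per-bin dwell time. Bins with occupancy below `min_occupancy`
#' are masked (rate set to NA).
#'
#' @param session a `pc_session`, or a list with `trajectory` (tibble
#'   `time_s`, `x`, `y`), `somatic_spikes` (tibble with `x`, `y`), `arena`
#'   and `config` (`dt_env`).
#' @param n_bins bins per side.
#' @param min_occupancy s.
#' @return a `pc_ratemap`: list with matrices `rate_hz`, `occupancy_s`,
#'   `spike_counts` (rows = x bins, cols = y bins), bin `breaks`, and the
#'   arena side.
#' @export
rate_map <- function(session, n_bins = 20, min_occupancy = 0.2) {
  side <- session$arena$side_length
  dt_env <- session$config$dt_env
  breaks <- seq(0, side, length.out = n_bins + 1)
  bin_of <- function(v) pmin(pmax(findInterval(v, breaks, rightmost.closed = TRUE), 1), n_bins)
  traj <- session$trajectory
  occ <- matrix(0, n_bins, n_bins)
  tb <- table(factor(bin_of(traj$x), levels = 1:n_bins),
              factor(bin_of(traj$y), levels = 1:n_bins))
  occ <- occ + as.numeric(tb) * dt_env
  dim(occ) <- c(n_bins, n_bins)
  cnt <- matrix(0, n_bins, n_bins)
  sp <- session$somatic_spikes
  if (nrow(sp) > 0) {
    tb2 <- table(factor(bin_of(sp$x), levels = 1:n_bins),
                 factor(bin_of(sp$y), levels = 1:n_bins))
    cnt <- matrix(as.numeric(tb2), n_bins, n_bins)
  }
  rate <- ifelse(occ >= min_occupancy & occ > 0, cnt / occ, NA_real_)
  structure(list(rate_hz = rate, occupancy_s = occ, spike_counts = cnt,
                 breaks = breaks, side_length = side,
                 min_occupancy = min_occupancy), class = "pc_ratemap")
}

bin_centers <- function(map) {
  b <- map$breaks
  (b[-1] + b[-length(b)]) / 2
}

#' Place-field centroid and size
#'
#' The field is the connected region (4-neighborhood) of bins with rate at
#' least `threshold_fraction` of the map maximum that contains the maximum
#' bin; the centroid is its rate-weighted center of mass.
#'
#' @param map a `pc_ratemap` with a nonzero maximum.
#' @param threshold_fraction fraction of the peak rate defining the field.
#' @return list: `centroid` (x, y), `area_bins`, `peak_rate_hz`,
#'   `field_bins` (logical matrix).
#' @export
field_centroid_and_size <- function(map, threshold_fraction = 0.5) {
  r <- map$rate_hz
  if (all(is.na(r)) || max(r, na.rm = TRUE) <= 0) {
    abort("rate map has no positive rates; no place field to measure")
  }
  peak <- max(r, na.rm = TRUE)
  n <- nrow(r)
  above <- !is.na(r) & r >= threshold_fraction * peak
  start <- which(r == peak)[1]
  # flood fill over the 4-neighborhood
  in_field <- matrix(FALSE, n, n)
  stack <- start
  while (length(stack) > 0) {
    i <- stack[[1]]; stack <- stack[-1]
    if (in_field[i] || !above[i]) next
    in_field[i] <- TRUE
    row <- (i - 1) %% n + 1; col <- (i - 1) %/% n + 1
    nb <- c(if (row > 1) i - 1, if (row < n) i + 1,
            if (col > 1) i - n, if (col < n) i + n)
    stack <- c(stack, nb)
  }
  cx <- bin_centers(map)
  w <- ifelse(in_field, r, 0); w[is.na(w)] <- 0
  centroid <- c(x = sum(outer(cx, rep(1, n)) * w) / sum(w),
                y = sum(outer(rep(1, n), cx) * w) / sum(w))
  list(centroid = centroid, area_bins = sum(in_field), peak_rate_hz = peak,
       field_bins = in_field)
}

# rotate a rate map's matrix by `angle` degrees about the arena center
# (nearest-bin mapping; exact for multiples of 90)
rotate_map_matrix <- function(m, breaks, angle) {
  n <- nrow(m)
  cx <- (breaks[-1] + breaks[-length(breaks)]) / 2
  c0 <- (breaks[1] + breaks[length(breaks)]) / 2
  th <- angle * pi / 180
  out <- matrix(NA_real_, n, n)
  for (i in 1:n) for (j in 1:n) {
    # source location that lands in bin (i, j) after rotation
    x <- c0 + cos(-th) * (cx[i] - c0) - sin(-th) * (cx[j] - c0)
    y <- c0 + sin(-th) * (cx[i] - c0) + cos(-th) * (cx[j] - c0)
    si <- findInterval(x, breaks, rightmost.closed = TRUE)
    sj <- findInterval(y, breaks, rightmost.closed = TRUE)
    if (si >= 1 && si <= n && sj >= 1 && sj <= n) out[i, j] <- m[si, sj]
  }
  out
}

#' Rate-map correlation under arena rotation
#'
#' Pearson correlation between `map_after` and `map_before` rotated by
#' `angle`, over bins unmasked in both. A place field that follows the
#' arena's rotation yields a higher correlation at the true angle than at 0.
#'
#' @param map_before,map_after `pc_ratemap`s on the same bin grid.
#' @param angle degrees.
#' @return Pearson correlation coefficient.
#' @export
rotation_test <- function(map_before, map_after, angle) {
  if (!identical(dim(map_before$rate_hz), dim(map_after$rate_hz))) {
    abort("rate maps must share the same bin grid")
  }
  rot <- rotate_map_matrix(map_before$rate_hz, map_before$breaks, angle)
  ok <- !is.na(rot) & !is.na(map_after$rate_hz)
  if (sum(ok) < 3) abort("too few jointly unmasked bins")
  a <- rot[ok]; b <- map_after$rate_hz[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(a, b)
}

#' Distance between two place-field centroids
#'
#' Remapping statistic: Euclidean distance between the field centroids of
#' two rate maps recorded in the same arena. A distance exceeding the field
#' radius indicates remapping.
#'
#' @param map_a,map_b `pc_ratemap`s.
#' @param threshold_fraction passed to [field_centroid_and_size()].
#' @return distance in arena length units.
#' @export
remap_test <- function(map_a, map_b, threshold_fraction = 0.5) {
  ca <- field_centroid_and_size(map_a, threshold_fraction)$centroid
  cb <- field_centroid_and_size(map_b, threshold_fraction)$centroid
  sqrt(sum((ca - cb)^2))
}
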