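# Virtual square arena: bar-shaped objects decomposed into features, a random
# agent trajectory with a 90-degree visual field, and cue-dependent Poisson
# presynaptic rates.

#' Square arena with feature-decomposed objects
#'
#' Objects are bars decomposed into `n_features` point features evenly spaced
#' along their long axis; each feature will be mapped to one oblique
#' dendrite's synapse by [place_cue_synapses()]. The default arena holds a
#' red and a blue bar in opposite quadrants.
#'
#' @param side_length arena side, length units.
#' @param objects data frame with columns `object_id`, `x`, `y` (center),
#'   `width`, `height`, `n_features`; defaults to two bars.
#' @param rotation rigid rotation of all objects about the arena center,
#'   degrees.
#' @return an `arena` object with `objects` and `features` tibbles.
#' @export
arena <- function(side_length = 1, objects = NULL, rotation = 0) {
  if (is.null(objects)) {
    objects <- tibble::tibble(
      object_id = c("red", "blue"),
      x = side_length * c(0.25, 0.75),
      y = side_length * c(0.80, 0.20),
      width = side_length * c(0.40, 0.40),
      height = side_length * c(0.05, 0.05),
      n_features = 7L)
  }
  if (any(objects$x < 0 | objects$x > side_length |
            objects$y < 0 | objects$y > side_length)) {
    abort("object centers must lie inside the arena")
  }
  features <- purrr::pmap_dfr(objects, function(object_id, x, y, width, height,
                                                n_features) {
    u <- if (n_features == 1) 0 else seq(-0.5, 0.5, length.out = n_features)
    along_x <- width >= height
    tibble::tibble(
      feature_id = paste0(object_id, "_", seq_len(n_features)),
      object_id = object_id,
      fx = x + if (along_x) u * width else 0,
      fy = y + if (along_x) 0 else u * height)
  })
  a <- structure(list(side_length = side_length, objects = objects,
                      features = features, rotation = 0), class = "arena")
  if (rotation != 0) a <- rotate_arena(a, rotation) else a
}

#' Rigidly rotate the arena's objects about its center
#'
#' Feature-to-synapse identities are untouched; only positions move.
#'
#' @param arena an [arena()].
#' @param angle degrees, counterclockwise.
#' @return the rotated arena (cumulative `rotation` recorded).
#' @export
rotate_arena <- function(arena, angle) {
  c0 <- arena$side_length / 2
  th <- angle * pi / 180
  rot <- function(x, y) {
    list(x = c0 + cos(th) * (x - c0) - sin(th) * (y - c0),
         y = c0 + sin(th) * (x - c0) + cos(th) * (y - c0))
  }
  o <- rot(arena$objects$x, arena$objects$y)
  arena$objects$x <- o$x; arena$objects$y <- o$y
  f <- rot(arena$features$fx, arena$features$fy)
  arena$features$fx <- f$x; arena$features$fy <- f$y
  arena$rotation <- (arena$rotation + angle) %% 360
  arena
}

#' Visual-field parameters
#'
#' Resolution is full out to `full_range` (the foveal range at which every
#' feature of an object can be made out) and then falls off linearly,
#' reaching zero at `max_range`: at object distance `r`, only the first
#' `ceiling(resolution_decay(r) * n_features)` features are resolvable
#' (deterministic feature order).
#'
#' @param fov field of view, degrees (default 90).
#' @param max_range distance at which resolution reaches zero.
#' @param full_range distance out to which all features are resolvable.
#' @return a `visual_field` list.
#' @export
visual_field <- function(fov = 90, max_range = 1.2, full_range = 0.35) {
  if (fov <= 0 || fov > 360) abort("fov must be in (0, 360]")
  if (full_range >= max_range) abort("full_range must be below max_range")
  structure(list(fov = fov, max_range = max_range, full_range = full_range),
            class = "visual_field")
}

resolution_decay <- function(r, vf) {
  r0 <- vf$full_range %||% 0
  pmin(1, pmax(0, (vf$max_range - r) / (vf$max_range - r0)))
}

#' Features visible from an agent state
#'
#' A feature is visible iff its bearing lies within +/- fov/2 of the heading,
#' its distance is at most `max_range`, and its within-object index does not
#' exceed the number of features resolvable at the object's distance.
#'
#' @param x,y agent position.
#' @param heading degrees.
#' @param arena an [arena()].
#' @param vf a [visual_field()].
#' @return character vector of visible feature ids.
#' @export
visible_features <- function(x, y, heading, arena, vf = visual_field()) {
  vis <- visibility_matrix(tibble::tibble(x = x, y = y, heading = heading),
                           arena, vf)
  colnames(vis)[vis[1, ]]
}

# logical matrix (steps x features) of per-feature visibility along a
# trajectory; fully vectorized
visibility_matrix <- function(traj, arena, vf = visual_field()) {
  f <- arena$features
  n <- nrow(traj)
  dx <- outer(-traj$x, f$fx, `+`)
  dy <- outer(-traj$y, f$fy, `+`)
  dist <- sqrt(dx^2 + dy^2)
  bearing <- atan2(dy, dx) * 180 / pi
  rel <- (bearing - traj$heading + 180) %% 360 - 180
  in_view <- abs(rel) <= vf$fov / 2 & dist <= vf$max_range
  # per-object resolvable count from object-center distance
  feat_rank <- stats::ave(seq_len(nrow(f)), f$object_id, FUN = seq_along)
  for (k in seq_len(nrow(arena$objects))) {
    o <- arena$objects[k, ]
    r <- sqrt((traj$x - o$x)^2 + (traj$y - o$y)^2)
    n_res <- ceiling(resolution_decay(r, vf) * o$n_features)
    cols <- which(f$object_id == o$object_id)
    in_view[, cols] <- in_view[, cols] & outer(n_res, feat_rank[cols], `>=`)
  }
  dimnames(in_view) <- list(NULL, f$feature_id)
  in_view
}

#' Step or generate the agent's random-walk trajectory
#'
#' Fixed speed, Gaussian heading increments, reflection at walls; fully
#' reproducible from the seed.
#'
#' @param arena an [arena()].
#' @param duration_s seconds.
#' @param dt_env environment step, s.
#' @param speed length units per second.
#' @param turn_sd_deg standard deviation of the per-step heading increment.
#' @param seed RNG seed.
#' @param start optional c(x, y, heading); defaults to the arena center with
#'   a seeded random heading.
#' @return tibble: `time_s`, `x`, `y`, `heading`.
#' @export
make_trajectory <- function(arena, duration_s, dt_env = 0.1, speed = 0.08,
                            turn_sd_deg = 4, seed = 1, start = NULL) {
  n <- ceiling(duration_s / dt_env)
  set.seed(seed)
  side <- arena$side_length
  x <- numeric(n); y <- numeric(n); h <- numeric(n)
  if (is.null(start)) {
    x[1] <- side / 2; y[1] <- side / 2; h[1] <- runif(1, 0, 360)
  } else {
    x[1] <- start[1]; y[1] <- start[2]; h[1] <- start[3] %% 360
  }
  turns <- rnorm(n, 0, turn_sd_deg)
  for (i in seq_len(n - 1)) {
    hh <- (h[i] + turns[i]) %% 360
    nx <- x[i] + speed * dt_env * cos(hh * pi / 180)
    ny <- y[i] + speed * dt_env * sin(hh * pi / 180)
    if (nx < 0) { nx <- -nx; hh <- (180 - hh) %% 360 }
    if (nx > side) { nx <- 2 * side - nx; hh <- (180 - hh) %% 360 }
    if (ny < 0) { ny <- -ny; hh <- (-hh) %% 360 }
    if (ny > side) { ny <- 2 * side - ny; hh <- (-hh) %% 360 }
    x[i + 1] <- nx; y[i + 1] <- ny; h[i + 1] <- hh
  }
  tibble::tibble(time_s = (seq_len(n) - 1) * dt_env, x = x, y = y, heading = h)
}

#' Presynaptic rates given the visible feature set
#'
#' Cue synapses whose feature is currently visible fire at the gamma-range
#' cue rate; all others at the theta-range background rate. A pure function
#' of the visible set.
#'
#' @param visible character vector of visible feature ids.
#' @param synapse_map synapse table from [place_cue_synapses()] (bijective
#'   feature -> synapse mapping).
#' @param cue_rate,background_rate Hz.
#' @return tibble: `synapse_id`, `rate_hz`.
#' @export
presynaptic_rates <- function(visible, synapse_map, cue_rate = 80,
                              background_rate = 3) {
  if (anyDuplicated(synapse_map$feature_id)) {
    abort("feature -> synapse mapping must be bijective")
  }
  tibble::tibble(
    synapse_id = synapse_map$synapse_id,
    rate_hz = ifelse(synapse_map$feature_id %in% visible, cue_rate,
                     background_rate))
}

#' Sample an inhomogeneous Poisson spike train
#'
#' The rate is piecewise constant (it changes only at environment steps);
#' each interval is sampled as a homogeneous Poisson process. Uses the
#' current RNG state; seed outside for reproducibility.
#'
#' @param rate_segments data frame with columns `t0_ms`, `t1_ms`, `rate_hz`.
#' @return sorted numeric vector of spike times, ms.
#' @export
poisson_spike_train <- function(rate_segments) {
  if (any(rate_segments$t1_ms <= rate_segments$t0_ms)) {
    abort("rate segments must have t1 > t0")
  }
  len_s <- (rate_segments$t1_ms - rate_segments$t0_ms) / 1000
  counts <- rpois(nrow(rate_segments), rate_segments$rate_hz * len_s)
  if (sum(counts) == 0) return(numeric(0))
  t0 <- rep(rate_segments$t0_ms, counts)
  t1 <- rep(rate_segments$t1_ms, counts)
  sort(runif(sum(counts), t0, t1))
}
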