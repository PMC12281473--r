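#' Synthetic phantom scenes with known ground truth
#'
#' A `phantom_scene` describes a single-slice digital phantom: a pixel
#' grid and a list of disjoint labelled regions, each with a geometric
#' mask (disc or box), a baseline intensity M0, per-gas ground-truth T1
#' values, and TOLD kinetic parameters (plateau `s_max` in %, rise time
#' constant `t_ox` in min, decay rate `k_oc` in 1/min). Scenes are the
#' ground truth against which every downstream fit can be checked.
#'
#' @param shape integer grid shape `c(ny, nx)`; default 64 x 64.
#' @param regions list of regions from [phantom_region()].
#' @param noise_sigma additive Gaussian noise sd as a fraction of M0.
#' @return An object of class `phantom_scene`.
#' @seealso [brain_phantom()], [simulate_variable_tr()],
#'   [simulate_told()]
#' @export
phantom_scene <- function(shape = c(64, 64), regions, noise_sigma = 0) {
  stopifnot(length(shape) == 2, all(shape >= 1), noise_sigma >= 0)
  shape <- as.integer(shape)
  masks <- lapply(regions, region_mask, shape = shape)
  cover <- Reduce(`+`, lapply(masks, function(m) array(as.integer(m), shape)))
  if (any(cover > 1L)) stop("region masks must be disjoint")
  for (r in regions) {
    if (any(r$t1 <= 0))
      stop(sprintf("region '%s' has a non-positive T1", r$name))
  }
  structure(list(shape = shape, regions = regions,
                 noise_sigma = noise_sigma),
            class = "phantom_scene")
}

#' Define a phantom region
#'
#' @param name region label.
#' @param geometry `"disc"` (`center = c(y, x)`, `radius`) or `"box"`
#'   (`center`, `halfwidth = c(hy, hx)`).
#' @param center,radius,halfwidth geometry parameters in pixels.
#' @param t1 named numeric vector of ground-truth T1 (s) per gas, e.g.
#'   `c(air = 1.85, carbogen = 1.72)`.
#' @param m0 baseline intensity (arbitrary units).
#' @param s_max TOLD plateau amplitude in percent (sign gives direction).
#' @param t_ox rise time constant in minutes.
#' @param k_oc post-challenge decay rate in 1/min.
#' @return A region description used by [phantom_scene()].
#' @export
phantom_region <- function(name, geometry = c("disc", "box"), center,
                           radius = NULL, halfwidth = NULL,
                           t1, m0 = 100,
                           s_max = 5, t_ox = 0.5, k_oc = 1.5) {
  geometry <- match.arg(geometry)
  if (geometry == "disc" && is.null(radius))
    stop("disc regions need a radius")
  if (geometry == "box" && is.null(halfwidth))
    stop("box regions need a halfwidth")
  if (is.null(names(t1))) stop("`t1` must be a named per-gas vector")
  list(name = name, geometry = geometry, center = center, radius = radius,
       halfwidth = halfwidth, t1 = t1, m0 = m0,
       s_max = s_max, t_ox = t_ox, k_oc = k_oc)
}

#' Logical mask of a phantom region on a grid
#' @param region a region from [phantom_region()].
#' @param shape grid shape `c(ny, nx)`.
#' @return Logical matrix.
#' @export
region_mask <- function(region, shape) {
  yy <- matrix(seq_len(shape[1]), shape[1], shape[2])
  xx <- matrix(seq_len(shape[2]), shape[1], shape[2], byrow = TRUE)
  if (region$geometry == "disc") {
    (yy - region$center[1])^2 + (xx - region$center[2])^2 <=
      region$radius^2
  } else {
    abs(yy - region$center[1]) <= region$halfwidth[1] &
      abs(xx - region$center[2]) <= region$halfwidth[2]
  }
}

#' Integer label image of a scene (0 = background)
#' @param scene a `phantom_scene`.
#' @return Integer matrix; region i carries label i, in scene order.
#' @export
scene_labels <- function(scene) {
  lab <- array(0L, scene$shape)
  for (i in seq_along(scene$regions))
    lab[region_mask(scene$regions[[i]], scene$shape)] <- i
  lab
}

#' Ground-truth T1 map of a scene under a given gas
#' @param scene a `phantom_scene`.
#' @param gas gas name matched against each region's `t1` names.
#' @return A `scalar_map` in seconds; background is invalid.
#' @export
scene_t1_map <- function(scene, gas = "air") {
  t1 <- array(NA_real_, scene$shape)
  for (r in scene$regions) {
    if (!gas %in% names(r$t1))
      stop(sprintf("region '%s' has no T1 for gas '%s'", r$name, gas))
    t1[region_mask(r, scene$shape)] <- r$t1[[gas]]
  }
  scalar_map(t1, unit = "s")
}

#' Ground-truth M0 map of a scene
#' @param scene a `phantom_scene`.
#' @return A `scalar_map` of baseline intensities; background invalid.
#' @export
scene_m0_map <- function(scene) {
  m0 <- array(NA_real_, scene$shape)
  for (r in scene$regions)
    m0[region_mask(r, scene$shape)] <- r$m0
  scalar_map(m0, unit = "intensity")
}

#' @export
print.phantom_scene <- function(x, ...) {
  cat(sprintf("<phantom_scene> %d x %d grid, %d region(s), noise sigma %g\n",
              x$shape[1], x$shape[2], length(x$regions), x$noise_sigma))
  for (r in x$regions)
    cat(sprintf("  %-16s %s  T1[%s]  s_max %.3g%%  t_ox %.3g min  k_oc %.3g /min\n",
                r$name, r$geometry,
                paste(sprintf("%s=%.3g", names(r$t1), r$t1), collapse = ", "),
                r$s_max, r$t_ox, r$k_oc))
  invisible(x)
}

#' Three-region mouse brain phantom
#'
#' A 64 x 64 single-slice phantom with cortex, ventricles, and caudate
#' nucleus regions. Per-gas ground-truth T1 values default to the group
#' means measured at 7 T in mouse brain (cortex 1.85 s under air, 1.72 s
#' under carbogen, 1.73 s under 100% O2; ventricles 2.84/2.75/2.79 s;
#' caudate 1.70/1.60/1.62 s). Kinetic defaults are the carbogen-challenge
#' group means (cortex s_max 5.08%, t_ox 0.60 min; ventricles 4.05%,
#' 0.97 min; caudate 3.08%, 0.66 min) with the cortical consumption rate
#' 1.55 1/min used for all regions (the only region with a measured
#' decay rate).
#'
#' @param noise_sigma noise sd as a fraction of M0; default 0.
#' @return A `phantom_scene`.
#' @examples
#' scene <- brain_phantom()
#' scene_t1_map(scene, "air")
#' @export
brain_phantom <- function(noise_sigma = 0) {
  phantom_scene(
    shape = c(64, 64),
    regions = list(
      phantom_region("cortex", "disc", center = c(20, 32), radius = 9,
                     t1 = c(air = 1.85, carbogen = 1.72, oxygen = 1.73),
                     m0 = 100, s_max = 5.08, t_ox = 0.60, k_oc = 1.55),
      phantom_region("ventricles", "disc", center = c(40, 20), radius = 7,
                     t1 = c(air = 2.84, carbogen = 2.75, oxygen = 2.79),
                     m0 = 100, s_max = 4.05, t_ox = 0.97, k_oc = 1.55),
      phantom_region("caudate", "disc", center = c(40, 44), radius = 7,
                     t1 = c(air = 1.70, carbogen = 1.60, oxygen = 1.62),
                     m0 = 100, s_max = 3.08, t_ox = 0.66, k_oc = 1.55)),
    noise_sigma = noise_sigma)
}

#' Two-compartment tube phantom (water and corn oil)
#'
#' Cross-section of two tubes, one of water and one of corn oil,
#' equilibrated with N2, air, carbogen, or 100% O2 at ~30 degrees C.
#' Ground-truth T1 values are the tabulated phantom means at 7 T.
#'
#' @param noise_sigma noise sd as a fraction of M0.
#' @return A `phantom_scene` with regions "water" and "corn_oil".
#' @export
tube_phantom <- function(noise_sigma = 0) {
  phantom_scene(
    shape = c(64, 64),
    regions = list(
      phantom_region("water", "disc", center = c(32, 20), radius = 10,
                     t1 = c(nitrogen = 4.61, air = 4.25,
                            carbogen = 2.97, oxygen = 2.91),
                     m0 = 100, s_max = 12, t_ox = 1 / 1.06, k_oc = 0.63),
      phantom_region("corn_oil", "disc", center = c(32, 46), radius = 10,
                     t1 = c(nitrogen = 0.67, air = 0.60,
                            carbogen = 0.48, oxygen = 0.47),
                     m0 = 100, s_max = 4, t_ox = 1 / 0.41, k_oc = 0.26)),
    noise_sigma = noise_sigma)
}

## The 12 repetition times (s) of the variable-TR T1-mapping protocol,
## in acquisition order.
#' Default variable-TR protocol
#' @return The 12 repetition times in seconds, longest first.
#' @export
default_tr_s <- function()
  c(15000, 8000, 5500, 4000, 3000, 2000, 1600, 1200, 800, 500, 200, 100) / 1000

#' Simulate a variable-TR saturation-recovery series
#'
#' Forward model: per pixel, `signal(TR) = M0 * (1 - exp(-TR / T1))`,
#' plus zero-mean Gaussian noise with sd `noise_sigma * M0` (additive
#' noise on magnitude images; an optional Rician mode is available since
#' the pipeline is intended to run far above the noise floor).
#'
#' @param t1_map `scalar_map` of ground-truth T1 (s), or numeric array.
#' @param m0_map `scalar_map` or array of baseline intensities.
#' @param tr_s repetition times in seconds, acquisition order.
#' @param noise_sigma Gaussian noise sd as a fraction of M0.
#' @param seed integer RNG seed; identical inputs and seed give
#'   bit-identical output.
#' @param rician if `TRUE`, take the magnitude of the complex-valued
#'   noisy signal (Rician noise) instead of adding real Gaussian noise.
#' @return A `variable_tr_series`: list with `data` (ny x nx x nTR
#'   array), `tr_s`, and the validity mask of the input maps.
#' @examples
#' scene <- brain_phantom()
#' ser <- simulate_variable_tr(scene_t1_map(scene, "air"),
#'                             scene_m0_map(scene), default_tr_s())
#' @export
simulate_variable_tr <- function(t1_map, m0_map, tr_s = default_tr_s(),
                                 noise_sigma = 0, seed = NULL,
                                 rician = FALSE) {
  t1 <- if (inherits(t1_map, "scalar_map")) t1_map$values else
    as.array(t1_map)
  m0 <- if (inherits(m0_map, "scalar_map")) m0_map$values else
    as.array(m0_map)
  if (!identical(dim(t1), dim(m0)))
    stop("T1 and M0 maps must have the same shape")
  if (length(tr_s) == 0) stop("`tr_s` must be non-empty")
  if (any(tr_s <= 0))
    stop(sprintf("non-positive TR rejected: %g s", min(tr_s)))
  bad <- which(is.finite(t1) & t1 <= 0)
  if (length(bad))
    stop(sprintf("non-positive T1 rejected: %g s", t1[bad[1]]))
  valid <- is.finite(t1) & is.finite(m0)
  ny <- dim(t1)[1]; nx <- dim(t1)[2]
  data <- array(0, c(ny, nx, length(tr_s)))
  if (!is.null(seed)) set.seed(as.integer(seed))
  for (k in seq_along(tr_s)) {
    sig <- m0 * (1 - exp(-tr_s[k] / t1))
    sig[!valid] <- 0
    if (noise_sigma > 0) {
      sd_px <- noise_sigma * ifelse(valid, m0, 0)
      if (rician) {
        re <- sig + stats::rnorm(length(sig), 0, sd_px)
        im <- stats::rnorm(length(sig), 0, sd_px)
        sig <- sqrt(re^2 + im^2)
      } else {
        sig <- sig + stats::rnorm(length(sig), 0, sd_px)
      }
    }
    data[, , k] <- sig
  }
  structure(list(data = data, tr_s = as.numeric(tr_s), valid = valid),
            class = "variable_tr_series")
}

#' @export
print.variable_tr_series <- function(x, ...) {
  cat(sprintf("<variable_tr_series> %d x %d pixels, %d TR steps (%.3g-%.3g s)\n",
              dim(x$data)[1], dim(x$data)[2], length(x$tr_s),
              min(x$tr_s), max(x$tr_s)))
  invisible(x)
}

## Noiseless TOLD trajectory (percent enhancement) for one region over a
## schedule. Challenge intervals (O2 fraction differing from the first
## interval's) relax toward s_max with time constant t_ox; return
## intervals decay exponentially toward the pre-challenge baseline (0%)
## at rate k_oc. Starting each interval from the level reached at its
## start makes the single-cycle case exactly
## S(t) = s_max * (1 - exp(-(t - t_on)/t_ox)) on the rise and
## S(t) = S_off * exp(-k_oc (t - t_off)) on the decay.
told_truth_curve <- function(time_min, schedule, s_max, t_ox, k_oc) {
  base_frac <- schedule$o2_fraction[1]
  s <- numeric(length(time_min))
  level <- 0
  for (i in seq_len(nrow(schedule))) {
    t0 <- schedule$start_min[i]
    sel <- interval_at(schedule, time_min) == i
    dt <- time_min[sel] - t0
    if (abs(schedule$o2_fraction[i] - base_frac) > 1e-12) {
      s[sel] <- s_max + (level - s_max) * exp(-dt / t_ox)
      level <- s_max + (level - s_max) *
        exp(-(schedule$end_min[i] - t0) / t_ox)
    } else {
      s[sel] <- level * exp(-k_oc * dt)
      level <- level * exp(-k_oc * (schedule$end_min[i] - t0))
    }
  }
  s
}

#' Simulate a TOLD T1-weighted time series
#'
#' Each region's percent enhancement follows an exponential wash-in
#' toward its plateau `s_max` with time constant `t_ox` from each
#' challenge onset, and an exponential return toward the pre-challenge
#' baseline at rate `k_oc` after each offset. Frame intensity is
#' `M0 * (1 + S(t)/100)` plus per-frame Gaussian noise of sd
#' `noise_sigma * M0`. Frame times follow the frame-start convention
#' (`(k-1) * frame_interval`), and the frame containing a gas switch is
#' assigned the gas active at its start time.
#'
#' @param scene a `phantom_scene`.
#' @param schedule a `gas_schedule` spanning the scan duration.
#' @param frame_interval_s frame duration in seconds (> 0).
#' @param n_frames number of frames.
#' @param seed integer RNG seed.
#' @return A `told_series`: list with `data` (ny x nx x frames),
#'   `time_min`, `schedule`, `baseline_frames` (all frames of the
#'   initial interval), `labels`, `roi_names`, and `truth` (data.frame of
#'   generating parameters per region, with `k_ox = 1/t_ox`).
#' @examples
#' scene <- brain_phantom()
#' sched <- gas_schedule(c(0, 5, 10), c(5, 10, 15),
#'                       c("air", "carbogen", "air"), c(0.21, 0.95, 0.21))
#' ser <- simulate_told(scene, sched, frame_interval_s = 20, n_frames = 45)
#' @export
simulate_told <- function(scene, schedule, frame_interval_s, n_frames,
                          seed = NULL) {
  stopifnot(inherits(scene, "phantom_scene"),
            inherits(schedule, "gas_schedule"))
  if (frame_interval_s <= 0) stop("frame interval must be positive")
  time_min <- (seq_len(n_frames) - 1) * frame_interval_s / 60
  if (max(time_min) > max(schedule$end_min) + 1e-9)
    stop("gas schedule does not span the scan duration")
  ny <- scene$shape[1]; nx <- scene$shape[2]
  data <- array(0, c(ny, nx, n_frames))
  truth <- data.frame(region = character(), m0 = numeric(),
                      s_max = numeric(), t_ox = numeric(),
                      k_ox = numeric(), k_oc = numeric(),
                      stringsAsFactors = FALSE)
  curves <- list()
  for (r in scene$regions) {
    curves[[r$name]] <- told_truth_curve(time_min, schedule,
                                         r$s_max, r$t_ox, r$k_oc)
    truth <- rbind(truth, data.frame(
      region = r$name, m0 = r$m0, s_max = r$s_max, t_ox = r$t_ox,
      k_ox = 1 / r$t_ox, k_oc = r$k_oc, stringsAsFactors = FALSE))
  }
  masks <- lapply(scene$regions, region_mask, shape = scene$shape)
  if (!is.null(seed)) set.seed(as.integer(seed))
  for (k in seq_len(n_frames)) {
    frame <- array(0, c(ny, nx))
    for (i in seq_along(scene$regions)) {
      r <- scene$regions[[i]]
      frame[masks[[i]]] <- r$m0 * (1 + curves[[r$name]][k] / 100)
    }
    if (scene$noise_sigma > 0) {
      sd_px <- array(0, c(ny, nx))
      for (i in seq_along(scene$regions))
        sd_px[masks[[i]]] <- scene$noise_sigma * scene$regions[[i]]$m0
      frame <- frame + stats::rnorm(length(frame), 0, sd_px)
    }
    data[, , k] <- frame
  }
  baseline_frames <- which(interval_at(schedule, time_min) == 1L)
  structure(list(data = data, time_min = time_min, schedule = schedule,
                 baseline_frames = baseline_frames,
                 labels = scene_labels(scene),
                 roi_names = vapply(scene$regions, `[[`, "", "name"),
                 truth = truth, truth_curves = curves),
            class = "told_series")
}

#' @export
print.told_series <- function(x, ...) {
  cat(sprintf("<told_series> %d x %d pixels, %d frames over %.3g min\n",
              dim(x$data)[1], dim(x$data)[2], length(x$time_min),
              max(x$time_min)))
  print(x$schedule)
  invisible(x)
}
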