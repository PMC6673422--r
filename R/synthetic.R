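# Synthetic-data generators. These define the ground-truth study conditions
# for the whole test suite: textured frame pairs under known camera motion
# (flow oracle), degraded frames (informative-filter classes), hue-separable
# flow-color images (CNN classes), and direction-label signals with a known
# cecum time (locator battery). Every generator is a pure function of its
# parameters and seed.

#' Parameters for a synthetic motion scene
#'
#' The texture is a band-limited random field: a sum of sinusoids with
#' frequencies drawn from `freq_band` (cycles/pixel). The default band
#' (0.02-0.08, i.e. wavelengths of roughly 12-50 px) gives the smooth,
#' large-structure appearance of endoscopic scenes and keeps displacements
#' of a pixel or two within the validity of flow linearization. Motion is
#' radial about the image center (forward = expansion, backward =
#' contraction, emulating the zoom-like appearance of scope insertion and
#' withdrawal) or pure translation for unit tests; `magnitude` is the flow
#' magnitude in pixels at the reference radius `min(frame_size)/4` for
#' radial motion, or the shift length for translation.
#'
#' @param motion_type One of `"forward"`, `"backward"`, `"static"`,
#'   `"translate"`.
#' @param magnitude Pixels per frame step (>= 0; forced to 0 for static).
#' @param direction Translation direction `c(dx, dy)` (only for
#'   `"translate"`).
#' @param frame_size `c(height, width)` in pixels.
#' @param freq_band Frequency band `c(low, high)` in cycles/pixel.
#' @param n_waves Number of sinusoidal components.
#' @param noise_sigma Additive i.i.d. Gaussian intensity noise.
#' @param seed Integer seed.
#' @return A `motion_scene_params` object.
#' @export
motion_scene_params <- function(motion_type = c("forward", "backward", "static",
                                                "translate"),
                                magnitude = 1, direction = c(1, 0),
                                frame_size = c(96L, 96L),
                                freq_band = c(0.02, 0.08), n_waves = 12L,
                                noise_sigma = 0, seed = 1L) {
  motion_type <- match.arg(motion_type)
  if (magnitude < 0) stop("magnitude must be >= 0")
  if (motion_type == "static") magnitude <- 0
  structure(list(motion_type = motion_type, magnitude = magnitude,
                 direction = direction / sqrt(sum(direction^2) + (sum(direction^2) == 0)),
                 frame_size = as.integer(frame_size), freq_band = freq_band,
                 n_waves = as.integer(n_waves), noise_sigma = noise_sigma,
                 seed = as.integer(seed)),
            class = "motion_scene_params")
}

# continuous band-limited texture: amplitude-weighted sum of sinusoids,
# evaluated at arbitrary (row, col) coordinates; range mapped into [0.15, 0.85]
make_texture_fun <- function(freq_band, n_waves) {
  fr <- stats::runif(n_waves, freq_band[1], freq_band[2])
  th <- stats::runif(n_waves, 0, 2 * pi)
  ph <- stats::runif(n_waves, 0, 2 * pi)
  am <- stats::runif(n_waves, 0.5, 1)
  am <- am / sum(am)                  # |sum| <= 1, so the range bound is fixed
  fy <- fr * sin(th); fx <- fr * cos(th)
  function(r, c) {
    s <- 0
    for (k in seq_len(n_waves))
      s <- s + am[k] * sin(2 * pi * (fx[k] * c + fy[k] * r) + ph[k])
    0.5 + 0.35 * s
  }
}

#' Generate a textured frame pair under known motion
#'
#' The second frame is the first warped by an analytic motion field; because
#' the texture is a closed-form function, the warp is evaluated exactly (no
#' interpolation). The analytic field is returned as ground truth for flow
#' validation.
#'
#' @param params A [motion_scene_params].
#' @return List with `frame1`, `frame2` ([frame_image]s) and `truth`
#'   (a [flow_field]).
#' @export
generate_frame_pair <- function(params = motion_scene_params()) {
  stopifnot(inherits(params, "motion_scene_params"))
  H <- params$frame_size[1]; W <- params$frame_size[2]
  withr::with_seed(params$seed, {
    tex <- make_texture_fun(params$freq_band, params$n_waves)
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    if (params$motion_type %in% c("static", "translate")) {
      d <- if (params$motion_type == "static") c(0, 0)
           else params$magnitude * params$direction        # (dx, dy)
      u <- matrix(d[1], H, W); v <- matrix(d[2], H, W)
    } else {
      c0 <- c((H + 1) / 2, (W + 1) / 2)
      r0 <- min(H, W) / 4
      gain <- params$magnitude / r0
      if (params$motion_type == "backward") gain <- -gain
      u <- gain * (cc - c0[2]); v <- gain * (rr - c0[1])
    }
    f1 <- tex(rr, cc)
    f2 <- tex(rr - v, cc - u)   # content at p moved from p - flow
    if (params$noise_sigma > 0) {
      f1 <- f1 + stats::rnorm(H * W, 0, params$noise_sigma)
      f2 <- f2 + stats::rnorm(H * W, 0, params$noise_sigma)
      f1 <- pmin(pmax(f1, 0), 1); f2 <- pmin(pmax(f2, 0), 1)
    }
  })
  list(frame1 = frame_image(f1, timestamp = 0, index = 0L),
       frame2 = frame_image(f2, timestamp = 0.5, index = 1L),
       truth = flow_field(u, v))
}

# small separable Gaussian blur with replicate edges
gaussian_blur <- function(px, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  conv1 <- function(m) {
    out <- m * k[half + 1]
    for (d in seq_len(half)) {
      out <- out + k[half + 1 + d] * shift_mat(m, d, 0) +
                   k[half + 1 - d] * shift_mat(m, -d, 0)
    }
    out
  }
  t(conv1(t(conv1(px))))
}

#' Generate a clean or degraded frame for the informative filter
#'
#' Emulates the visual defects that make a frame non-informative: motion
#' blur, excessive darkness or brightness, and directional motion streaks.
#' Degradation strengths are drawn from fixed documented ranges.
#'
#' @param kind One of `"clean"`, `"blur"`, `"dark"`, `"bright"`, `"streak"`.
#' @param seed Integer seed.
#' @param frame_size `c(height, width)` in pixels.
#' @return List with `frame` (a [frame_image]) and `informative` (logical:
#'   `TRUE` only for `"clean"`).
#' @export
generate_degraded_frame <- function(kind = c("clean", "blur", "dark", "bright",
                                             "streak"),
                                    seed = 1L, frame_size = c(128L, 128L)) {
  kind <- match.arg(kind)
  H <- frame_size[1]; W <- frame_size[2]
  withr::with_seed(seed, {
    tex <- make_texture_fun(c(0.03, 0.25), 16L)   # sharp texture: high band
    rr <- matrix(seq_len(H), H, W)
    cc <- matrix(seq_len(W), H, W, byrow = TRUE)
    px <- tex(rr, cc) + matrix(stats::rnorm(H * W, 0, 0.02), H, W)
    px <- pmin(pmax(px, 0), 1)
    px <- switch(kind,
      clean = px,
      blur = gaussian_blur(px, stats::runif(1, 3, 6)),
      dark = px * stats::runif(1, 0.02, 0.08),
      bright = 1 - (1 - px) * stats::runif(1, 0.02, 0.08),
      streak = {
        len <- as.integer(stats::runif(1, 15, 30))
        out <- px
        for (d in seq_len(len)) out <- out + shift_mat(px, 0, d)
        out / (len + 1)
      })
  })
  list(frame = frame_image(pmin(pmax(px, 0), 1)),
       informative = kind == "clean")
}

#' Parameters for a synthetic direction-label scenario
#'
#' A single true phase change at `insertion_duration` (the ground-truth
#' cecum time) separates an insertion phase from a withdrawal phase.
#' Oscillations inject short opposite-sign runs (emulating the light
#' insertion-withdrawal repeat movements common during colonoscopy, which
#' rarely exceed 10 s); `stop_prob` zeroes samples and `label_noise_prob`
#' flips signs, emulating stop frames and classifier errors.
#'
#' @param insertion_duration,withdrawal_duration Phase lengths in seconds.
#' @param sample_interval Seconds between samples.
#' @param oscillation_spec List of `c(time, half_length)` pairs (seconds):
#'   each flips the phase sign over `[time, time + half_length)`.
#' @param stop_prob Per-sample probability of a stop (0) sample.
#' @param label_noise_prob Per-sample probability of a sign flip.
#' @param t_max Largest window width the locator will use; oscillations
#'   closer than `t_max / 2` to the true change are rejected.
#' @param seed Integer seed.
#' @return A `signal_scenario_params` object with derived `true_cecum_time`.
#' @export
signal_scenario_params <- function(insertion_duration = 600,
                                   withdrawal_duration = 400,
                                   sample_interval = 0.5,
                                   oscillation_spec = list(),
                                   stop_prob = 0, label_noise_prob = 0,
                                   t_max = 30, seed = 1L) {
  if (insertion_duration <= 0 || withdrawal_duration <= 0)
    stop("phase durations must be > 0")
  if (stop_prob < 0 || stop_prob > 1 || label_noise_prob < 0 || label_noise_prob > 1)
    stop("probabilities must lie in [0, 1]")
  for (o in oscillation_spec) {
    if (length(o) != 2 || o[2] <= 0) stop("oscillation entries are c(time, half_length)")
    if (o[1] + o[2] > insertion_duration - t_max / 2 &&
        o[1] < insertion_duration + t_max / 2)
      stop("oscillation overlaps the true phase change within t_max/2")
  }
  structure(list(insertion_duration = insertion_duration,
                 withdrawal_duration = withdrawal_duration,
                 sample_interval = sample_interval,
                 oscillation_spec = oscillation_spec,
                 stop_prob = stop_prob, label_noise_prob = label_noise_prob,
                 t_max = t_max, seed = as.integer(seed),
                 true_cecum_time = insertion_duration),
            class = "signal_scenario_params")
}

#' Generate a direction signal with a known cecum time
#'
#' @param params A [signal_scenario_params].
#' @return List with `signal` (a [direction_signal]) and `truth_time`
#'   (seconds, equal to `params$true_cecum_time`).
#' @export
generate_direction_signal <- function(params = signal_scenario_params()) {
  stopifnot(inherits(params, "signal_scenario_params"))
  dt <- params$sample_interval
  n <- round((params$insertion_duration + params$withdrawal_duration) / dt)
  times <- (seq_len(n) - 1) * dt
  vals <- ifelse(times < params$insertion_duration, 1, -1)
  for (o in params$oscillation_spec) {
    inw <- times >= o[1] & times < o[1] + o[2]
    vals[inw] <- -vals[inw]
  }
  withr::with_seed(params$seed, {
    if (params$stop_prob > 0)
      vals[stats::runif(n) < params$stop_prob] <- 0
    if (params$label_noise_prob > 0) {
      flip <- stats::runif(n) < params$label_noise_prob
      vals[flip] <- -vals[flip]
    }
  })
  list(signal = direction_signal(vals, sample_interval = dt, times = times),
       truth_time = params$true_cecum_time)
}

#' Generate a hue-separable flow-color image dataset
#'
#' Builds labeled flow-color images whose dominant hue family identifies
#' the class: insertion images encode flow around a base direction of 0
#' degrees, withdrawal around 180 degrees (each with smooth per-image and
#' per-pixel angular jitter), and stop images encode near-zero magnitude
#' (neutral coloring). This is the separable-by-construction training set
#' for the direction CNN.
#'
#' @param n_per_class Images per class.
#' @param width,height Image size in pixels.
#' @param magnitude_scale Encoder saturation scale (px/frame-step).
#' @param angle_jitter Per-image standard deviation of the base direction
#'   (degrees).
#' @param seed Integer seed.
#' @return List with `images` (list of `flow_color_image`) and `labels`
#'   (character vector).
#' @export
generate_flow_color_dataset <- function(n_per_class = 300L, width = 170L,
                                        height = 150L, magnitude_scale = 2,
                                        angle_jitter = 15, seed = 1L) {
  images <- list()
  labels <- character(0)
  withr::with_seed(seed, {
    for (cls in DIRECTION_LEVELS) {
      for (i in seq_len(n_per_class)) {
        if (cls == "stop") {
          mag <- matrix(stats::runif(height * width, 0, 0.05 * magnitude_scale),
                        height, width)
          ang <- matrix(stats::runif(height * width, 0, 2 * pi), height, width)
        } else {
          base <- if (cls == "insertion") 0 else pi
          base <- base + stats::rnorm(1, 0, angle_jitter * pi / 180)
          ang <- base + matrix(stats::rnorm(height * width, 0, 10 * pi / 180),
                               height, width)
          mag <- matrix(stats::runif(1, 0.5, 1) * magnitude_scale *
                          stats::runif(height * width, 0.7, 1), height, width)
        }
        fl <- flow_field(mag * cos(ang), -mag * sin(ang))
        images[[length(images) + 1]] <- flow_to_color(fl, magnitude_scale)
        labels <- c(labels, cls)
      }
    }
  })
  list(images = images, labels = labels)
}
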