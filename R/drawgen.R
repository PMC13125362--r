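#' Drawing task kinds
#'
#' The closed set of structured drawing tasks used for Parkinsonian
#' handwriting assessment: an Archimedean spiral, a square-wave meander,
#' and a sinusoidal wave.
#'
#' @return Character vector `c("spiral", "meander", "wave")`.
#' @export
task_kinds <- function() c("spiral", "meander", "wave")

#' Motor profile of a simulated writer
#'
#' Bundles the distortion parameters of one (class of) writer. The three
#' distortion channels map onto the cardinal Parkinsonian drawing signs:
#' a radial/perpendicular sinusoidal tremor (oscillatory jaggedness), white
#' positional jitter (loss of smooth motor control), and a per-revolution
#' geometric radius shrink (micrographia). A slow Brownian drift models
#' low-frequency hand wander common to all writers.
#'
#' @param tremor_amplitude Tremor amplitude in pixels (>= 0).
#' @param tremor_frequency Tremor frequency in cycles per radian of the
#'   task's parameter sweep (> 0). Clinical rest/action tremor at 4-6 Hz
#'   over a 15-25 s spiral corresponds to roughly 2-2.5 cycles/radian.
#' @param jitter_sd White positional jitter SD in pixels (>= 0).
#' @param micrographia_factor Per-revolution radial shrink multiplier in
#'   (0, 1]; 1 means no shrink.
#' @param drift_sd Total Brownian drift SD in pixels over the whole
#'   trajectory (>= 0).
#' @param label Class label: 0 = control, 1 = PD.
#' @return A `motor_profile` list.
#' @export
motor_profile <- function(tremor_amplitude = 0, tremor_frequency = 2,
                          jitter_sd = 0, micrographia_factor = 1,
                          drift_sd = 0, label = 0L) {
  p <- list(tremor_amplitude = tremor_amplitude,
            tremor_frequency = tremor_frequency,
            jitter_sd = jitter_sd,
            micrographia_factor = micrographia_factor,
            drift_sd = drift_sd, label = as.integer(label))
  num <- unlist(p[1:5])
  if (!all(is.finite(num))) stopf("motor profile fields must be finite")
  if (tremor_amplitude < 0 || jitter_sd < 0 || drift_sd < 0)
    stopf("noise magnitudes must be non-negative")
  if (tremor_frequency <= 0) stopf("tremor_frequency must be > 0")
  if (micrographia_factor <= 0 || micrographia_factor > 1)
    stopf("micrographia_factor must be in (0, 1]")
  if (!label %in% c(0L, 1L)) stopf("label must be 0 or 1")
  structure(p, class = "motor_profile")
}

#' Class-level profiles for a given effect strength
#'
#' Presets pairing a smooth control writer with a Parkinsonian writer at
#' three distortion strengths. Amplitudes are in canvas pixels (512 px
#' default canvas).
#'
#' @param effect One of `"mild"`, `"moderate"`, `"strong"`.
#' @return List with elements `control` and `pd` (motor profiles).
#' @export
effect_profiles <- function(effect = c("moderate", "mild", "strong")) {
  effect <- match.arg(effect)
  pd <- switch(effect,
    mild     = motor_profile(1.5, 2.0, 0.5, 0.97, 1.2, label = 1L),
    moderate = motor_profile(3.0, 2.0, 0.8, 0.93, 1.6, label = 1L),
    strong   = motor_profile(5.0, 2.5, 1.2, 0.88, 2.0, label = 1L))
  list(control = motor_profile(0, 2.0, 0.3, 1.0, 0.8, label = 0L), pd = pd)
}

# Piecewise-linear base polyline of the square-wave meander, resampled
# uniformly by arc length.
meander_base <- function(n_points, folds = 6, width = 420, height = 340,
                         center = c(256, 256)) {
  x0 <- center[1] - width / 2
  dx <- width / folds
  y_top <- center[2] - height / 2
  y_bot <- center[2] + height / 2
  vx <- x0; vy <- y_bot
  for (k in seq_len(folds)) {
    up <- k %% 2 == 1
    vy <- c(vy, if (up) y_top else y_bot)
    vx <- c(vx, vx[length(vx)])
    if (k < folds) {
      vx <- c(vx, x0 + k * dx)
      vy <- c(vy, vy[length(vy)])
    }
  }
  seg <- sqrt(diff(vx)^2 + diff(vy)^2)
  s <- c(0, cumsum(seg))
  t <- seq(0, s[length(s)], length.out = n_points)
  list(x = stats::approx(s, vx, t)$y, y = stats::approx(s, vy, t)$y,
       progress = t / s[length(s)])
}

#' Generate a simulated drawing trajectory
#'
#' Produces an ordered pen-down point sequence for one task under a motor
#' profile. The spiral base curve is the Archimedean spiral r(theta) =
#' a * theta; the meander is a square-wave folded path; the wave is a
#' sinusoid. Parkinsonian distortions are applied on top of the base
#' curve: a sinusoidal tremor of the stated amplitude and frequency
#' (radial for the spiral, perpendicular to the path otherwise), white
#' positional jitter, per-revolution radial multiplication by the
#' micrographia factor, and Brownian drift. Identical arguments always
#' yield identical output.
#'
#' @param task One of [task_kinds()].
#' @param profile A [motor_profile()].
#' @param n_points Number of points (>= 2).
#' @param seed Integer seed.
#' @param center Canvas-coordinate center of the figure.
#' @param r_max Outer radius (spiral) / half-extent scale in pixels.
#' @param turns Spiral revolutions (also wave/meander fold count scale).
#' @return Data frame with columns `x`, `y`, `pen` plus attributes `task`
#'   and, for spirals, `theta` and `a` (the base-curve parameters).
#' @export
generate_trajectory <- function(task, profile, n_points = 1200L, seed = 0L,
                                center = c(256, 256), r_max = 210,
                                turns = 4) {
  task <- match.arg(task, task_kinds())
  if (!inherits(profile, "motor_profile")) profile <- do.call(motor_profile, profile)
  if (n_points < 2) stopf("n_points must be >= 2")
  with_seed(seed, {
    A <- profile$tremor_amplitude
    f <- profile$tremor_frequency
    phase <- stats::runif(1, 0, 2 * pi)
    if (task == "spiral") {
      theta <- seq(0, turns * 2 * pi, length.out = n_points)
      a <- r_max / (turns * 2 * pi)
      r <- a * theta * profile$micrographia_factor^(theta / (2 * pi))
      r <- r + A * sin(2 * pi * f * theta + phase)
      x <- center[1] + r * cos(theta)
      y <- center[2] + r * sin(theta)
      sweep <- theta
    } else if (task == "meander") {
      base <- meander_base(n_points, center = center)
      sweep <- base$progress * 2 * pi * 6
      shrink <- profile$micrographia_factor^(sweep / (2 * pi))
      x <- base$x
      y <- center[2] + (base$y - center[2]) * shrink
    } else {
      cycles <- turns
      prog <- seq(0, 1, length.out = n_points)
      sweep <- 2 * pi * cycles * prog
      amp <- 0.55 * r_max * profile$micrographia_factor^(sweep / (2 * pi))
      x <- center[1] - r_max + 2 * r_max * prog
      y <- center[2] + amp * sin(sweep)
    }
    if (task != "spiral" && A > 0) {
      tx <- c(diff(x), x[length(x)] - x[length(x) - 1])
      ty <- c(diff(y), y[length(y)] - y[length(y) - 1])
      nrm <- pmax(sqrt(tx^2 + ty^2), 1e-12)
      off <- A * sin(f * sweep + phase)
      x <- x - ty / nrm * off
      y <- y + tx / nrm * off
    }
    if (profile$jitter_sd > 0) {
      x <- x + stats::rnorm(n_points, 0, profile$jitter_sd)
      y <- y + stats::rnorm(n_points, 0, profile$jitter_sd)
    }
    if (profile$drift_sd > 0) {
      step <- profile$drift_sd / sqrt(n_points)
      x <- x + cumsum(stats::rnorm(n_points, 0, step))
      y <- y + cumsum(stats::rnorm(n_points, 0, step))
    }
    check_finite(c(x, y), "trajectory coordinates")
    traj <- data.frame(x = x, y = y, pen = TRUE)
    attr(traj, "task") <- task
    attr(traj, "center") <- center
    if (task == "spiral") { attr(traj, "theta") <- theta; attr(traj, "a") <- a }
    traj
  })
}

#' Radial deviation of a spiral trajectory from its base curve
#'
#' @param traj A spiral trajectory from [generate_trajectory()].
#' @return Numeric vector of signed radial deviations r_i - a * theta_i.
#' @export
radial_deviation <- function(traj) {
  if (is.null(attr(traj, "theta"))) stopf("not a spiral trajectory")
  ctr <- attr(traj, "center")
  r <- sqrt((traj$x - ctr[1])^2 + (traj$y - ctr[2])^2)
  r - attr(traj, "a") * attr(traj, "theta")
}

#' High-frequency stroke energy
#'
#' Sum of squared second differences of the pen coordinates along the
#' stroke; tremor and jitter raise it, smooth drawing keeps it low.
#'
#' @param traj Trajectory data frame.
#' @return Scalar energy.
#' @export
stroke_roughness <- function(traj) {
  sum(diff(traj$x, differences = 2)^2 + diff(traj$y, differences = 2)^2)
}

#' Rasterize a trajectory onto a canvas
#'
#' Pen-down runs are drawn as connected Bresenham strokes stamped with a
#' `stroke_width` x `stroke_width` square; pen-up gaps leave no ink.
#' Rendering is binary (ink = 1, background = 0) so pixel-count oracles
#' are exact; coordinates outside the canvas are clipped.
#'
#' @param traj Trajectory data frame (`x`, `y`, `pen`); may be empty.
#' @param height,width Canvas dimensions in pixels (>= 8).
#' @param stroke_width Positive integer stroke width.
#' @return `height` x `width` intensity matrix in \[0, 1\].
#' @export
rasterize <- function(traj, height = 512L, width = 512L, stroke_width = 3L) {
  if (height < 8 || width < 8) stopf("canvas dimensions must be >= 8")
  if (stroke_width < 1) stopf("stroke_width must be a positive integer")
  if (nrow(traj) == 0 || !any(traj$pen))
    return(matrix(0, height, width))
  r <- as.integer(round(traj$y)); c <- as.integer(round(traj$x))
  pen <- traj$pen
  seg <- which(pen[-length(pen)] & pen[-1])
  if (length(seg) == 0) seg <- integer(0)
  i0 <- c(seg, which(pen))        # lone pen-down points drawn as dots
  i1 <- c(seg + 1L, which(pen))
  img <- cpp_draw_segments(r[i0], c[i0], r[i1], c[i1],
                           as.integer(height), as.integer(width),
                           as.integer(stroke_width))
  img
}

write_drawing_png <- function(img, path) {
  EBImage::writeImage(EBImage::Image(t(img)), path)
}

read_drawing_png <- function(path) {
  im <- EBImage::readImage(path)
  a <- EBImage::imageData(im)
  if (length(dim(a)) == 3) {                       # RGB -> luminance
    a <- 0.2126 * a[, , 1] + 0.7152 * a[, , 2] + 0.0722 * a[, , 3]
  }
  t(a)
}

perturb_profile <- function(profile, variation) {
  f <- function(mu, lower = 0, upper = Inf) {
    if (mu == 0 || variation == 0) return(mu)
    min(max(stats::rnorm(1, mu, variation * abs(mu)), lower), upper)
  }
  motor_profile(
    tremor_amplitude = f(profile$tremor_amplitude),
    tremor_frequency = f(profile$tremor_frequency, lower = 1e-3),
    jitter_sd = f(profile$jitter_sd),
    micrographia_factor = f(profile$micrographia_factor, lower = 0.5, upper = 1),
    drift_sd = f(profile$drift_sd),
    label = profile$label)
}

#' Synthesize a drawing cohort
#'
#' Generates one drawing per subject per task. Each subject's motor
#' profile is drawn around its class profile by seeded Gaussian
#' perturbation (relative SD `variation`), truncated to valid ranges, so
#' subject-independent splits are meaningful. Images are written as 8-bit
#' greyscale PNG when `out_dir` is given (with a JSON sidecar echoing the
#' cohort parameters), otherwise kept in memory.
#'
#' @param n_control,n_pd Subjects per class (>= 0).
#' @param tasks Non-empty subset of [task_kinds()].
#' @param control_profile,pd_profile Class-level [motor_profile()]s.
#' @param variation Relative SD of per-subject profile perturbation.
#' @param seed Integer cohort seed.
#' @param out_dir Output directory or `NULL` for in-memory images.
#' @param n_points,canvas,stroke_width Rendering parameters.
#' @return Manifest data frame (`subject_id`, `label`, `task`, `path`)
#'   with attributes `seed` and, when `out_dir` is `NULL`, `images`
#'   (named list of intensity matrices).
#' @export
synthesize_cohort <- function(n_control, n_pd, tasks = task_kinds(),
                              control_profile = effect_profiles("moderate")$control,
                              pd_profile = effect_profiles("moderate")$pd,
                              variation = 0.15, seed = 1L, out_dir = NULL,
                              n_points = 1200L, canvas = 512L,
                              stroke_width = 3L) {
  if (n_control < 0 || n_pd < 0) stopf("subject counts must be >= 0")
  tasks <- match.arg(tasks, task_kinds(), several.ok = TRUE)
  if (length(tasks) == 0) stopf("tasks must be non-empty")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stopf("cannot create output directory '%s'", out_dir)
  }
  n <- n_control + n_pd
  labels <- c(rep(0L, n_control), rep(1L, n_pd))
  ids <- sprintf("S%03d", seq_len(n))
  seeds <- derive_seeds(seed, n * length(tasks) + n)
  profiles <- lapply(seq_len(n), function(i) {
    cls <- if (labels[i] == 0L) control_profile else pd_profile
    with_seed(seeds[n * length(tasks) + i], perturb_profile(cls, variation))
  })
  rows <- list(); images <- list(); k <- 0L
  for (i in seq_len(n)) {
    for (task in tasks) {
      k <- k + 1L
      traj <- generate_trajectory(task, profiles[[i]], n_points = n_points,
                                  seed = seeds[k],
                                  center = c(canvas / 2, canvas / 2),
                                  r_max = 0.41 * canvas)
      img <- rasterize(traj, canvas, canvas, stroke_width)
      key <- paste0(ids[i], "_", task)
      path <- if (is.null(out_dir)) NA_character_ else
        file.path(out_dir, paste0(key, ".png"))
      if (!is.null(out_dir)) write_drawing_png(img, path)
      else images[[key]] <- img
      rows[[k]] <- data.frame(subject_id = ids[i], label = labels[i],
                              task = task, path = path,
                              stringsAsFactors = FALSE)
    }
  }
  manifest <- do.call(rbind, rows)
  attr(manifest, "seed") <- seed
  if (is.null(out_dir)) attr(manifest, "images") <- images
  if (!is.null(out_dir)) {
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(n_control = n_control, n_pd = n_pd, tasks = tasks,
           variation = variation, seed = seed, canvas = canvas,
           n_points = n_points, stroke_width = stroke_width,
           control_profile = unclass(control_profile),
           pd_profile = unclass(pd_profile)),
      file.path(out_dir, "cohort.json"), auto_unbox = TRUE)
  }
  manifest
}
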