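#' Neutral 68-point face template
#'
#' A fixed, embedded landmark layout in the dlib/iBUG convention (x right,
#' y down, nominal 200 x 200 px image): jaw arc 0-16, right eyebrow 17-21,
#' left eyebrow 22-26, nose 27-35, right eye 36-41, left eye 42-47, mouth
#' 48-67. "Right" is the subject's right, so the right eye lies at smaller x.
#' Identical across calls; used as the base geometry by the synthetic
#' generator.
#'
#' @return a `landmark_frame` labelled `"Neutral"`.
#' @export
neutral_template <- function() {
  t_jaw <- seq(0, pi, length.out = 17)
  jaw <- cbind(100 - 60 * cos(t_jaw), 80 + 90 * sin(t_jaw))
  reb <- cbind(seq(55, 90, length.out = 5),
               60 - 5 * sin(seq(0, pi, length.out = 5)))
  leb <- cbind(seq(110, 145, length.out = 5),
               60 - 5 * sin(seq(pi, 0, length.out = 5)))
  nose <- rbind(cbind(100, c(70, 80, 90, 100)),          # bridge 27-30
                cbind(c(88, 94, 100, 106, 112), 110))    # base   31-35
  eye <- function(cx) cbind(cx + c(-12, -4, 6, 14, 6, -4),
                            75 + c(0, -4, -4, 0, 4, 4))
  re <- eye(72)
  le <- eye(128)
  a_out <- seq(pi, -pi, length.out = 13)[1:12]           # corner-first loop
  outer <- cbind(100 + 25 * cos(a_out), 135 - 10 * sin(a_out))
  # inner lips 60-67: corner, 3 upper, corner, 3 lower
  inner <- cbind(100 + 18 * cos(c(pi, 3 * pi / 4, pi / 2, pi / 4, 0,
                                  -pi / 4, -pi / 2, -3 * pi / 4)),
                 135 - 5 * sin(c(pi, 3 * pi / 4, pi / 2, pi / 4, 0,
                                 -pi / 4, -pi / 2, -3 * pi / 4)))
  pts <- rbind(jaw, reb, leb, nose, re, le, outer, inner)
  landmark_frame(round(pts, 3), subject_id = "template",
                 video_id = "template", frame_index = 0L, label = "Neutral")
}

# Per-AU displacement fields at unit intensity: 68 x 2 matrices of pixel
# offsets encoding the FACS muscle action (y down, so raising = negative dy).
# Each AU touches only landmarks inside its own facial-region grouping.
au_displacement_field <- function(code) {
  d <- matrix(0, 68L, 2L)
  set <- function(idx0, dx, dy) {
    d[idx0 + 1L, 1] <<- d[idx0 + 1L, 1] + dx
    d[idx0 + 1L, 2] <<- d[idx0 + 1L, 2] + dy
  }
  switch(as.character(code),
    `1` = { set(c(20, 21, 22, 23), 0, c(-0.6, -1, -1, -0.6)) },     # inner brow raiser
    `2` = { set(c(17, 18, 25, 26), 0, c(-1, -0.6, -0.6, -1)) },     # outer brow raiser
    `4` = { set(17:26, 0, 0.8); set(c(20, 21), 0.2, 0); set(c(22, 23), -0.2, 0) }, # brow lowerer
    `5` = { set(c(37, 38, 43, 44), 0, -0.6) },                      # upper lid raiser
    `6` = { set(c(40, 41, 46, 47), 0, -0.4); set(c(31, 35), 0, -0.2) }, # cheek raiser
    `7` = { set(c(37, 38, 43, 44), 0, 0.3); set(c(40, 41, 46, 47), 0, -0.3) }, # lid tightener
    `9` = { set(27:35, 0, -0.5); set(c(31, 32), 0.3, 0); set(c(34, 35), -0.3, 0) }, # nose wrinkler
    `12` = { set(48, -0.7, -0.7); set(54, 0.7, -0.7)
             set(c(49, 59), -0.35, -0.35); set(c(53, 55), 0.35, -0.35) }, # lip corner puller
    `14` = { set(48, 0.5, 0); set(54, -0.5, 0) },                   # dimpler
    `15` = { set(48, -0.3, 0.8); set(54, 0.3, 0.8)
             set(c(49, 59), -0.15, 0.4); set(c(53, 55), 0.15, 0.4) }, # lip corner depressor
    `16` = { set(c(55:59, 65:67), 0, 0.7) },                        # lower lip depressor
    `20` = { set(48, -1, 0); set(54, 1, 0)
             set(c(49, 59), -0.5, 0); set(c(53, 55), 0.5, 0) },     # lip stretcher
    `23` = { mouth <- 48:67
             ctr <- c(100, 135)
             tpl <- neutral_template()$points[mouth + 1L, ]
             v <- sweep(tpl, 2L, ctr, "-")
             nrm <- sqrt(rowSums(v^2)); nrm[nrm == 0] <- 1
             d[mouth + 1L, ] <- -0.4 * v / nrm },                   # lip tightener
    `26` = { set(5:11, 0, 1); set(c(55:59), 0, 0.6); set(65:67, 0, 0.9) }, # jaw drop
    stop("unknown AU code: ", code))
  d
}

#' Emotion displacement field
#'
#' Sum of the AU displacement fields of the emotion's Action Units, scaled by
#' intensity. Landmarks outside the emotion's AU regions are untouched;
#' intensity 0 gives the zero field.
#'
#' @param emotion emotion name (see [emotion_registry()]).
#' @param intensity expression intensity in [0, 1] (0 = neutral, 1 = apex).
#' @param displacement_scale apex displacement magnitude in pixels applied to
#'   the unit fields.
#' @return 68 x 2 matrix of (dx, dy) pixel offsets.
#' @export
emotion_displacement <- function(emotion, intensity = 1,
                                 displacement_scale = 1) {
  reg <- emotion_registry()
  if (!emotion %in% names(reg)) stop("unknown emotion: ", emotion)
  d <- Reduce(`+`, lapply(reg[[emotion]], au_displacement_field))
  d * intensity * displacement_scale
}

#' Onset-apex-offset intensity ramp
#'
#' Piecewise-linear intensity over an N-frame clip: 0 at the first frame,
#' 1 at the mid (apex) frame ceil(N/2), back to 0 at the last frame. The apex
#' frame is the strict maximum, matching the mid-frame-as-apex premise of the
#' sampling schemes.
#'
#' @param n_frames clip length N.
#' @return numeric vector of length N in [0, 1].
#' @export
intensity_ramp <- function(n_frames) {
  if (n_frames == 1L) return(1)
  chi <- ceiling(n_frames / 2)
  t <- seq_len(n_frames)
  up <- if (chi > 1) (t - 1) / (chi - 1) else rep(1, n_frames)
  down <- (n_frames - t) / (n_frames - chi)
  ifelse(t <= chi, up, down)
}

#' Synthetic dataset configuration
#'
#' @param n_subjects number of synthetic subjects.
#' @param videos_per_class videos per emotion class per subject.
#' @param frames_per_video frames per clip.
#' @param classes emotion classes to generate (subset of the seven emotions).
#' @param displacement_scale apex landmark displacement in pixels.
#' @param noise_sd i.i.d. Gaussian landmark noise per frame, in pixels.
#' @param subject_variation magnitude of the per-subject affine jitter
#'   (rotation/scale/translation) of the template.
#' @param seed integer RNG seed; identical seeds give bit-identical datasets.
#' @return list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 8L, videos_per_class = 2L,
                         frames_per_video = 12L,
                         classes = c("Happy", "Surprise", "Disgust"),
                         displacement_scale = 10, noise_sd = 0.5,
                         subject_variation = 1, seed = 42L) {
  stopifnot(n_subjects >= 1, videos_per_class >= 1, frames_per_video >= 1,
            noise_sd >= 0, displacement_scale >= 0,
            all(classes %in% names(emotion_registry())))
  structure(list(n_subjects = as.integer(n_subjects),
                 videos_per_class = as.integer(videos_per_class),
                 frames_per_video = as.integer(frames_per_video),
                 classes = classes,
                 displacement_scale = displacement_scale,
                 noise_sd = noise_sd,
                 subject_variation = subject_variation,
                 seed = as.integer(seed)),
            class = "synth_config")
}

affine_transform <- function(points, angle, scale, shift) {
  ctr <- colMeans(points)
  rot <- matrix(c(cos(angle), sin(angle), -sin(angle), cos(angle)), 2L)
  sweep(scale * sweep(points, 2L, ctr, "-") %*% t(rot), 2L, ctr + shift, "+")
}

#' Generate a synthetic labelled landmark dataset
#'
#' Emulates what the recognition pipeline assumes about real data: every clip
#' starts near a subject-specific neutral face, deforms along its emotion's
#' AU directions with a 0 -> 1 -> 0 onset-apex-offset intensity ramp peaking
#' at the mid frame, and carries per-frame Gaussian landmark jitter. Each
#' subject gets a fixed random affine variant of the neutral template, drawn
#' before any frame noise so adding videos never perturbs earlier subjects'
#' geometry. Deterministic under `config$seed`.
#'
#' @param config a [synth_config()].
#' @return list with `table` (landmark table of all frames) and `manifest`
#'   (`data.frame`: subject_id, video_id, label, frame_count).
#' @export
generate_synthetic <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  template <- neutral_template()$points
  v <- config$subject_variation
  subjects <- sprintf("s%02d", seq_len(config$n_subjects))
  jitter <- lapply(subjects, function(s)
    list(angle = stats::rnorm(1, 0, 0.02 * v),
         scale = exp(stats::rnorm(1, 0, 0.02 * v)),
         shift = stats::rnorm(2, 0, 2 * v)))
  names(jitter) <- subjects

  ramp <- intensity_ramp(config$frames_per_video)
  disp <- lapply(config$classes, emotion_displacement,
                 intensity = 1, displacement_scale = config$displacement_scale)
  names(disp) <- config$classes

  frames <- list()
  manifest <- list()
  for (s in subjects) {
    base <- affine_transform(template, jitter[[s]]$angle,
                             jitter[[s]]$scale, jitter[[s]]$shift)
    for (cls in config$classes) {
      for (vnum in seq_len(config$videos_per_class)) {
        vid <- sprintf("%s_%s_v%02d", s, tolower(cls), vnum)
        for (t in seq_len(config$frames_per_video)) {
          noise <- matrix(stats::rnorm(136, 0, config$noise_sd), 68L, 2L)
          pts <- base + ramp[t] * disp[[cls]] + noise
          frames[[length(frames) + 1L]] <-
            landmark_frame(pts, subject_id = s, video_id = vid,
                           frame_index = t, label = cls)
        }
        manifest[[length(manifest) + 1L]] <-
          data.frame(subject_id = s, video_id = vid, label = cls,
                     frame_count = config$frames_per_video,
                     stringsAsFactors = FALSE)
      }
    }
  }
  list(table = frames_to_table(frames),
       manifest = do.call(rbind, manifest))
}
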