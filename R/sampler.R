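#' Single-frame sampling positions within a video sequence
#'
#' Turns an N-frame expression clip into single-frame samples without
#' onset/apex/offset detection, on the premise that frames near the middle of
#' a short expression clip carry the apex. Three schemes are supported, all in
#' 1-based frame positions:
#'
#' * `mid`: the single mid frame at position ceil(N/2) (N = 12 -> 6).
#' * `mid3`: the three frames centred on the mid frame (N = 12 -> 5, 6, 7).
#' * `midhalf`: a centred contiguous block of floor(N/2) frames
#'   (N = 12 -> 4..9).
#'
#' @param n_frames number of frames N in the video.
#' @return integer vector of 1-based frame positions.
#' @export
mid_positions <- function(n_frames) {
  if (n_frames < 1L) stop("video must have at least 1 frame")
  as.integer(ceiling(n_frames / 2))
}

#' @rdname mid_positions
#' @export
mid_three_positions <- function(n_frames) {
  if (n_frames < 3L) stop("mid-three sampling requires at least 3 frames")
  chi <- ceiling(n_frames / 2)
  as.integer((chi - 1L):(chi + 1L))
}

#' @rdname mid_positions
#' @export
mid_half_positions <- function(n_frames) {
  if (n_frames < 2L) stop("mid-half sampling requires at least 2 frames")
  chi <- n_frames %/% 2L
  start <- (n_frames - chi) %/% 2L + 1L
  as.integer(start:(start + chi - 1L))
}

#' Construct a video sequence
#'
#' An ordered, labelled list of landmark frames from one subject's video.
#'
#' @param frames list of `landmark_frame` with strictly increasing
#'   `frame_index` and shared subject/video ids.
#' @return object of class `video_sequence`.
#' @export
video_sequence <- function(frames) {
  if (!length(frames)) stop("video sequence must contain at least one frame")
  idx <- vapply(frames, `[[`, integer(1), "frame_index")
  if (any(diff(idx) <= 0))
    stop("frame_index must be strictly increasing within a video")
  structure(list(frames = frames,
                 subject_id = frames[[1]]$subject_id,
                 video_id = frames[[1]]$video_id,
                 label = frames[[1]]$label),
            class = "video_sequence")
}

sample_positions <- function(n_frames, scheme = c("mid", "mid3", "midhalf")) {
  scheme <- match.arg(scheme)
  switch(scheme,
         mid = mid_positions(n_frames),
         mid3 = mid_three_positions(n_frames),
         midhalf = mid_half_positions(n_frames))
}

#' Sample frames from a video sequence
#'
#' @param video a `video_sequence`.
#' @return list of selected `landmark_frame`s (length 1, 3 or floor(N/2)).
#' @export
sample_mid <- function(video) video$frames[mid_positions(length(video$frames))]

#' @rdname sample_mid
#' @export
sample_mid_three <- function(video) {
  n <- length(video$frames)
  if (n < 3L) stop("video ", video$video_id, ": mid-three requires >= 3 frames")
  video$frames[mid_three_positions(n)]
}

#' @rdname sample_mid
#' @export
sample_mid_half <- function(video) {
  n <- length(video$frames)
  if (n < 2L) stop("video ", video$video_id, ": mid-half requires >= 2 frames")
  video$frames[mid_half_positions(n)]
}

#' Group a landmark table into video sequences
#'
#' @param tab landmark table; frames of a video share `subject_id` and
#'   `video_id` and are ordered by `frame_index`.
#' @return list of `video_sequence`.
#' @export
table_to_videos <- function(tab) {
  validate_landmark_table(tab)
  key <- interaction(tab$subject_id, tab$video_id, drop = TRUE)
  lapply(split(seq_len(nrow(tab)), key), function(rows) {
    sub <- tab[rows[order(tab$frame_index[rows])], , drop = FALSE]
    video_sequence(table_to_frames(sub))
  })
}

#' Restructure a labelled video dataset into single-frame samples
#'
#' Applies one sampling scheme to every video and concatenates the selected
#' frames into a flat labelled sample table; each sample keeps its source
#' video's subject and label.
#'
#' @param tab landmark table covering all videos.
#' @param scheme `"mid"`, `"mid3"` or `"midhalf"`.
#' @return object of class `sample_set`: list with `samples` (landmark table
#'   of selected frames), `per_class` and `per_video` counts.
#' @export
restructure <- function(tab, scheme = c("mid", "mid3", "midhalf")) {
  scheme <- match.arg(scheme)
  videos <- table_to_videos(tab)
  picked <- lapply(videos, function(v) {
    pos <- tryCatch(sample_positions(length(v$frames), scheme),
                    error = function(e) stop("video ", v$video_id, ": ",
                                             conditionMessage(e), call. = FALSE))
    frames_to_table(v$frames[pos])
  })
  samples <- do.call(rbind, picked)
  rownames(samples) <- NULL
  structure(list(samples = samples,
                 scheme = scheme,
                 per_class = table(samples$label),
                 per_video = vapply(picked, nrow, integer(1)),
                 n_videos = length(videos),
                 n_samples = nrow(samples)),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set> scheme=%s: %d samples from %d videos\n",
              x$scheme, x$n_samples, x$n_videos))
  print(x$per_class)
  invisible(x)
}

#' Read or write a dataset manifest
#'
#' JSON manifest listing per-video metadata:
#' `subject_id, video_id, label, frame_count`.
#'
#' @param videos list of `video_sequence`, or a landmark table.
#' @param path file path.
#' @export
write_manifest <- function(videos, path) {
  if (is.data.frame(videos)) videos <- table_to_videos(videos)
  rows <- lapply(videos, function(v)
    list(subject_id = v$subject_id, video_id = v$video_id,
         label = v$label, frame_count = length(v$frames)))
  jsonlite::write_json(unname(rows), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
}
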