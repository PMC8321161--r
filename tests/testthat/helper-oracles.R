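# Independent brute-force oracles, kept free of the package's incremental
# graph-construction path.

# all unordered 0-based pairs whose endpoints both lie inside at least one of
# the maximal AU part regions
brute_force_facs_segments <- function(units = default_unit_map()) {
  regions <- list(c("LEB", "LE", "N"), c("REB", "RE", "N"),
                  c("LE", "N", "M"), c("RE", "N", "M"),
                  c("N", "M", "LJ"))
  region_idx <- lapply(regions, function(r) sort(unique(unlist(units[r]))))
  keep <- list()
  for (i in 0:66) for (j in (i + 1):67) {
    inside <- any(vapply(region_idx,
                         function(r) (i %in% r) && (j %in% r), logical(1)))
    if (inside) keep[[length(keep) + 1L]] <- c(i, j)
  }
  m <- do.call(rbind, keep)
  colnames(m) <- c("i", "j")
  m
}

# naive per-segment loop with scalar arithmetic
naive_features <- function(frame, segments, g_cap = 1e4) {
  out <- numeric(0)
  for (r in seq_len(nrow(segments))) {
    p <- frame$points[segments[r, 1] + 1L, ]
    q <- frame$points[segments[r, 2] + 1L, ]
    d <- sqrt((p[1] - q[1])^2 + (p[2] - q[2])^2)
    dx <- q[1] - p[1]; dy <- q[2] - p[2]
    g <- if (dx == 0) { if (dy == 0) 0 else sign(dy) * g_cap } else dy / dx
    out <- c(out, d, g)
  }
  unname(out)
}

# brute-force confusion tally
naive_confusion <- function(truth, predicted, classes) {
  m <- matrix(0L, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (k in seq_along(truth)) m[truth[k], predicted[k]] <- m[truth[k], predicted[k]] + 1L
  m
}

random_frame <- function(seed = 1) {
  set.seed(seed)
  landmark_frame(matrix(stats::runif(136, 0, 200), 68L, 2L))
}

# minimal labelled landmark table: n_videos videos of n_frames frames each,
# cycling over subjects/labels; geometry irrelevant
toy_video_table <- function(n_videos, n_frames, n_subjects = 4L,
                            labels = c("A", "B")) {
  frames <- list()
  for (v in seq_len(n_videos)) {
    subj <- sprintf("s%02d", (v - 1L) %% n_subjects + 1L)
    lab <- labels[(v - 1L) %% length(labels) + 1L]
    for (t in seq_len(n_frames)) {
      frames[[length(frames) + 1L]] <- landmark_frame(
        matrix(as.numeric(v * 100 + t), 68L, 2L) + matrix(seq_len(136), 68L, 2L),
        subject_id = subj, video_id = sprintf("v%03d", v),
        frame_index = t, label = lab)
    }
  }
  frames_to_table(frames)
}
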