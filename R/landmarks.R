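#' Construct a landmark frame
#'
#' A landmark frame is one face observation: 68 indexed 2-D points in image
#' pixel coordinates (x to the right, y down, as produced by dlib-style
#' detectors) plus subject/video/frame metadata and an optional emotion label.
#'
#' @param points numeric 68 x 2 matrix of (x, y) coordinates; all finite.
#' @param subject_id,video_id opaque identifier strings.
#' @param frame_index non-negative integer position of the frame in its video.
#' @param label emotion-class string, or `NA` when unlabelled.
#' @return an object of class `landmark_frame`.
#' @export
landmark_frame <- function(points, subject_id = "s0", video_id = "v0",
                           frame_index = 0L, label = NA_character_) {
  points <- as.matrix(points)
  if (nrow(points) != 68L || ncol(points) != 2L)
    stop("landmark frame requires exactly 68 (x, y) points, got ",
         nrow(points), " x ", ncol(points))
  if (!all(is.finite(points)))
    stop("landmark coordinates must all be finite")
  if (frame_index < 0) stop("frame_index must be non-negative")
  storage.mode(points) <- "double"
  dimnames(points) <- list(NULL, c("x", "y"))
  structure(
    list(points = points,
         subject_id = as.character(subject_id),
         video_id = as.character(video_id),
         frame_index = as.integer(frame_index),
         label = as.character(label)),
    class = "landmark_frame")
}

#' @export
print.landmark_frame <- function(x, ...) {
  cat(sprintf("<landmark_frame> subject=%s video=%s frame=%d label=%s\n",
              x$subject_id, x$video_id, x$frame_index, x$label))
  invisible(x)
}

#' Seven-unit map of the 68-point landmark model
#'
#' Partitions (a subset of) the dlib/iBUG 68-point model into the seven facial
#' units used by the AU graphs: lower-jaw (LJ), right eyebrow (REB), left
#' eyebrow (LEB), nose (N), right eye (RE), left eye (LE) and mouth (M).
#' Indices are 0-based, matching the detector convention. LJ is the 7 central
#' chin indices 5..11 of the 17-point jaw line; the remaining six units cover
#' 51 indices.
#'
#' @return named list of integer vectors of 0-based landmark indices.
#' @export
default_unit_map <- function() {
  list(LJ  = 5:11,
       REB = 17:21,
       LEB = 22:26,
       N   = 27:35,
       RE  = 36:41,
       LE  = 42:47,
       M   = 48:67)
}

validate_unit_map <- function(units) {
  need <- c("LJ", "REB", "LEB", "N", "RE", "LE", "M")
  if (!all(need %in% names(units)))
    stop("unit map must define units: ", paste(need, collapse = ", "))
  idx <- unlist(units[need])
  if (any(idx < 0 | idx > 67)) stop("unit-map indices must lie in [0, 67]")
  nonjaw <- unlist(units[setdiff(need, "LJ")])
  if (anyDuplicated(nonjaw))
    stop("non-jaw units must be pairwise disjoint")
  invisible(units)
}

landmark_table_columns <- function() {
  c("subject_id", "video_id", "frame_index", "label",
    as.vector(rbind(paste0("x", 0:67), paste0("y", 0:67))))
}

#' Load landmark frames from file
#'
#' Two dialects are supported: the iBUG `.pts` single-frame format
#' (`version: 1`, `n_points: 68`, brace-delimited coordinate lines) and a
#' delimited landmark table with a header row and columns
#' `subject_id, video_id, frame_index, label, x0, y0, ..., x67, y67`.
#' For `.pts` files, metadata defaults from the file name
#' (`<subject>_<video>_<frame>.pts` when it parses that way).
#'
#' @param path file path.
#' @param dialect `"pts"` or `"table"`.
#' @return list of `landmark_frame` objects, in file order.
#' @export
load_landmarks <- function(path, dialect = c("pts", "table")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  switch(dialect,
         pts = list(read_pts(path)),
         table = table_to_frames(read_landmark_table(path)))
}

#' @rdname load_landmarks
#' @export
read_pts <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  np_line <- grep("^n_points:", lines, value = TRUE)
  if (length(np_line) != 1L)
    stop("parse error in ", path, ": expected one 'n_points:' line")
  n <- as.integer(sub("^n_points:\\s*", "", np_line))
  open <- match("{", lines)
  close <- match("}", lines)
  if (is.na(open) || is.na(close) || close <= open)
    stop("parse error in ", path, ": missing brace-delimited point block")
  coord_lines <- lines[(open + 1L):(close - 1L)]
  coord_lines <- coord_lines[nzchar(coord_lines)]
  if (length(coord_lines) != n)
    stop("parse error in ", path, ": n_points is ", n, " but ",
         length(coord_lines), " coordinate lines found (line ", open + 1L, ")")
  if (n != 68L)
    stop("validation error in ", path, ": expected 68 points, file declares ", n)
  xy <- do.call(rbind, lapply(coord_lines, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(l, "\\s+")[[1]]))
    if (length(v) != 2L || anyNA(v))
      stop("parse error in ", path, ": bad coordinate line '", l, "'")
    v
  }))
  meta <- sub("\\.pts$", "", basename(path))
  parts <- strsplit(meta, "_")[[1]]
  if (length(parts) >= 3L && !is.na(suppressWarnings(as.integer(parts[length(parts)])))) {
    fr <- as.integer(parts[length(parts)])
    landmark_frame(xy, subject_id = parts[1L],
                   video_id = paste(parts[-c(1L, length(parts))], collapse = "_"),
                   frame_index = fr)
  } else {
    landmark_frame(xy, subject_id = meta, video_id = meta, frame_index = 0L)
  }
}

#' Read or write a delimited landmark table
#'
#' @param path file path of a comma-delimited table with header
#'   `subject_id, video_id, frame_index, label, x0, y0, ..., x67, y67`.
#' @return `read_landmark_table`: a `data.frame` with those columns, one row
#'   per frame.
#' @export
read_landmark_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_landmark_table(tab, where = path)
  tab
}

#' @rdname read_landmark_table
#' @param tab landmark table (`data.frame`) as produced by
#'   [frames_to_table()] or [generate_synthetic()].
#' @export
write_landmark_table <- function(tab, path) {
  validate_landmark_table(tab)
  utils::write.csv(tab, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

validate_landmark_table <- function(tab, where = "landmark table") {
  cols <- landmark_table_columns()
  missing <- setdiff(cols, names(tab))
  if (length(missing))
    stop("malformed ", where, ": missing columns ",
         paste(utils::head(missing, 4L), collapse = ", "),
         if (length(missing) > 4L) ", ...")
  xy <- as.matrix(tab[, cols[-(1:4)]])
  if (length(xy) && !all(is.finite(xy)))
    stop("validation error in ", where, ": non-finite coordinates")
  invisible(tab)
}

#' Convert between landmark tables and frame lists
#'
#' @param frames list of `landmark_frame`.
#' @return `frames_to_table`: one-row-per-frame `data.frame`;
#'   `table_to_frames`: list of `landmark_frame`.
#' @export
frames_to_table <- function(frames) {
  rows <- lapply(frames, function(f) {
    xy <- as.vector(t(f$points))  # x0 y0 x1 y1 ...
    c(list(subject_id = f$subject_id, video_id = f$video_id,
           frame_index = f$frame_index, label = f$label),
      as.list(xy))
  })
  tab <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  names(tab) <- landmark_table_columns()
  tab
}

#' @rdname frames_to_table
#' @param tab landmark table.
#' @export
table_to_frames <- function(tab) {
  validate_landmark_table(tab)
  cols <- landmark_table_columns()
  lapply(seq_len(nrow(tab)), function(r) {
    xy <- matrix(as.numeric(tab[r, cols[-(1:4)]]), ncol = 2L, byrow = TRUE)
    landmark_frame(xy,
                   subject_id = tab$subject_id[r],
                   video_id = tab$video_id[r],
                   frame_index = tab$frame_index[r],
                   label = tab$label[r])
  })
}

#' Write a single frame in iBUG .pts format
#'
#' @param frame a `landmark_frame`.
#' @param path output path.
#' @export
write_pts <- function(frame, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("version: 1", "n_points: 68", "{"), con)
  writeLines(sprintf("%.6f %.6f", frame$points[, 1], frame$points[, 2]), con)
  writeLines("}", con)
  invisible(path)
}
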