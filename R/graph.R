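#' Action-Unit facial-region registry
#'
#' Maps each FACS Action Unit used by the emotion graphs to its facial-region
#' grouping, expressed as one or two "parts", each a set of facial units.
#' Single-part AUs (12, 14, 15, 16, 23, 26) act on one contiguous region;
#' two-part AUs (1, 2, 4, 5, 6, 7, 9, 20) act symmetrically on a left and a
#' right region that may share the nose and mouth units.
#'
#' @return named list keyed by AU code; each element a list of character
#'   vectors of unit names.
#' @export
au_registry <- function() {
  bilateral_brow_eye <- list(c("LEB", "LE"), c("REB", "RE"))
  list(
    `1`  = bilateral_brow_eye,
    `2`  = bilateral_brow_eye,
    `4`  = bilateral_brow_eye,
    `5`  = list("LE", "RE"),
    `6`  = list(c("LE", "N"), c("RE", "N")),
    `7`  = list(c("LEB", "LE", "N"), c("REB", "RE", "N")),
    `9`  = list(c("LEB", "N"), c("REB", "N")),
    `12` = list(c("N", "M", "LJ")),
    `14` = list(c("N", "M", "LJ")),
    `15` = list(c("N", "M", "LJ")),
    `16` = list(c("M", "LJ")),
    `20` = list(c("LE", "N", "M"), c("RE", "N", "M")),
    `23` = list(c("M", "LJ")),
    `26` = list(c("M", "LJ")))
}

#' Emotion-to-AU registry
#'
#' The AU combination defining each of the seven emotion graphs.
#'
#' @return named list: emotion -> integer vector of AU codes.
#' @export
emotion_registry <- function() {
  list(Happy    = c(6L, 12L),
       Anger    = c(1L, 4L, 15L),
       Sad      = c(1L, 2L, 5L, 26L),
       Fear     = c(1L, 2L, 4L, 5L, 7L, 20L, 26L),
       Surprise = c(4L, 5L, 7L, 23L),
       Disgust  = c(9L, 15L, 16L),
       Contempt = c(12L, 14L))
}

segment_graph <- function(segments, provenance = list(), deduped = TRUE) {
  segments <- as.matrix(segments)
  storage.mode(segments) <- "integer"
  dimnames(segments) <- list(NULL, c("i", "j"))
  if (nrow(segments) && any(segments[, 1] >= segments[, 2]))
    stop("segments must be canonical pairs with i < j")
  if (nrow(segments) && (any(segments < 0) || any(segments > 67)))
    stop("segment indices must lie in [0, 67]")
  structure(list(segments = segments, provenance = provenance,
                 deduped = deduped),
            class = "segment_graph")
}

#' @export
print.segment_graph <- function(x, ...) {
  cat(sprintf("<segment_graph> %d segments%s\n", nrow(x$segments),
              if (isTRUE(x$deduped)) "" else " (per-part, duplicates retained)"))
  if (length(x$provenance))
    cat("  provenance:", paste(names(x$provenance), collapse = ", "), "\n")
  invisible(x)
}

#' Number of segments in a graph
#' @param graph a `segment_graph`.
#' @return integer segment count (rows of the segment list).
#' @export
n_segments <- function(graph) nrow(graph$segments)

# complete graph over a sorted 0-based index set, lexicographic (i, j) order
complete_pairs <- function(idx) {
  idx <- sort(unique(as.integer(idx)))
  n <- length(idx)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  pairs <- t(utils::combn(idx, 2L))
  pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
}

canonical_sort <- function(segments) {
  if (!nrow(segments)) return(segments)
  segments <- unique(segments)
  segments[order(segments[, 1], segments[, 2]), , drop = FALSE]
}

part_indices <- function(part, units) {
  unknown <- setdiff(part, names(units))
  if (length(unknown))
    stop("unknown facial units: ", paste(unknown, collapse = ", "))
  sort(unique(unlist(units[part])))
}

#' Build the segment graph of one Action Unit
#'
#' Forms the complete graph over the landmark indices of each facial-region
#' part, then concatenates the parts' segment lists. Two-part AUs that share
#' units (nose/mouth) therefore list the shared segments once per part — this
#' is the per-AU segment accounting the region-grouping table uses (e.g.,
#' AU 20 has 2 x C(35,2) = 1190 segments); deduplication across parts and AUs
#' happens when emotion graphs are combined.
#'
#' @param code AU code (one of 1, 2, 4, 5, 6, 7, 9, 12, 14, 15, 16, 20, 23, 26).
#' @param units facial-unit map, see [default_unit_map()].
#' @return a `segment_graph` with `deduped = FALSE` when parts overlap.
#' @export
build_au_graph <- function(code, units = default_unit_map()) {
  validate_unit_map(units)
  reg <- au_registry()
  key <- as.character(code)
  if (!key %in% names(reg))
    stop("unknown AU code: ", code)
  parts <- reg[[key]]
  seg_parts <- lapply(parts, function(p) complete_pairs(part_indices(p, units)))
  segments <- do.call(rbind, seg_parts)
  dup <- anyDuplicated(segments) > 0L
  g <- structure(list(segments = segments,
                      provenance = list(au = as.integer(code)),
                      deduped = !dup),
                 class = "segment_graph")
  g
}

#' Build the segment graph of one emotion
#'
#' Deduplicated union of the emotion's AU graphs, in canonical (i, j) order.
#'
#' @param emotion one of Happy, Anger, Sad, Fear, Surprise, Disgust, Contempt.
#' @inheritParams build_au_graph
#' @return a deduplicated `segment_graph`; provenance records contributing AUs.
#' @export
build_emotion_graph <- function(emotion, units = default_unit_map()) {
  reg <- emotion_registry()
  if (!emotion %in% names(reg))
    stop("unknown emotion: ", emotion,
         " (expected one of ", paste(names(reg), collapse = ", "), ")")
  codes <- reg[[emotion]]
  segs <- do.call(rbind, lapply(codes, function(c) build_au_graph(c, units)$segments))
  segment_graph(canonical_sort(segs),
                provenance = list(emotion = emotion, au = codes))
}

#' Build the combined FACS-based graph
#'
#' Unions the seven emotion graphs and deletes repeated segments, yielding the
#' 1178 unique segments of the combined FACS-based graph under the default
#' unit map. The pre-dedupe multiset size (concatenation of the seven
#' deduplicated emotion graphs) is recorded in the provenance for
#' transparency.
#'
#' @inheritParams build_au_graph
#' @return a deduplicated, canonically sorted `segment_graph`.
#' @export
build_facs_graph <- function(units = default_unit_map()) {
  emos <- names(emotion_registry())
  per_emotion <- lapply(emos, function(e) build_emotion_graph(e, units)$segments)
  segs <- do.call(rbind, per_emotion)
  segment_graph(canonical_sort(segs),
                provenance = list(emotions = emos,
                                  n_pre_dedupe = nrow(segs)))
}

#' Build the full-face one-to-all graph
#'
#' All C(n, 2) unordered landmark pairs — 2278 segments for the 68-point model.
#'
#' @param n_points number of landmark points (default 68).
#' @return a `segment_graph` in canonical order.
#' @export
build_full_face_graph <- function(n_points = 68L) {
  segment_graph(complete_pairs(seq_len(n_points) - 1L),
                provenance = list(mode = "full"))
}

#' Render a segment graph over a landmark frame
#'
#' Draws the graph's segments as lines over the frame's landmark points and
#' writes a PNG, for visual inspection of graph coverage.
#'
#' @param frame a `landmark_frame`.
#' @param graph a `segment_graph`.
#' @param path output PNG path.
#' @param width,height image size in pixels.
#' @export
graph_overlay <- function(frame, graph, path, width = 600, height = 600) {
  grDevices::png(path, width = width, height = height)
  on.exit(grDevices::dev.off())
  pts <- frame$points
  graphics::plot(pts[, 1], -pts[, 2], asp = 1, pch = 16, cex = 0.6,
                 xlab = "x", ylab = "-y",
                 main = sprintf("%d segments", n_segments(graph)))
  if (n_segments(graph)) {
    i <- graph$segments[, 1] + 1L
    j <- graph$segments[, 2] + 1L
    graphics::segments(pts[i, 1], -pts[i, 2], pts[j, 1], -pts[j, 2],
                       col = grDevices::adjustcolor("steelblue", 0.3))
  }
  graphics::points(pts[, 1], -pts[, 2], pch = 16, cex = 0.6, col = "red3")
  invisible(path)
}

#' Export or import a segment graph as a delimited edge list
#'
#' Tab-separated two-column file `i<TAB>j` with `#`-prefixed header comments
#' recording the unit-map convention.
#'
#' @param graph a `segment_graph`.
#' @param path file path.
#' @export
write_edge_list <- function(graph, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# facsgraph edge list",
               "# unit-map: dlib-68 0-based; LJ=5..11",
               "i\tj"), con)
  utils::write.table(graph$segments, con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path) {
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           header = TRUE)
  segment_graph(as.matrix(tab[, c("i", "j")]))
}
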