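#' Segment distance and gradient
#'
#' Each graph segment contributes two geometric features: the Euclidean
#' distance between its two landmark points, and the gradient (slope)
#' (y_j - y_i) / (x_j - x_i). The slope is undefined for vertical segments;
#' it is capped at `sign(dy) * g_cap` when dx is exactly zero, and defined as
#' 0 for coincident points. Both features are invariant to translating the
#' face, and the generic slope is invariant to swapping endpoints (the capped
#' vertical value carries the sign of dy, so feature extraction always
#' evaluates segments in canonical i < j orientation); isotropic scaling
#' scales distances and leaves gradients unchanged.
#'
#' @param frame a `landmark_frame`.
#' @param i,j 0-based landmark indices of the segment endpoints.
#' @param g_cap finite slope assigned to vertical segments (default 1e4).
#' @return scalar feature value.
#' @export
segment_distance <- function(frame, i, j) {
  p <- frame$points[i + 1L, ]
  q <- frame$points[j + 1L, ]
  sqrt(sum((p - q)^2))
}

#' @rdname segment_distance
#' @export
segment_gradient <- function(frame, i, j, g_cap = 1e4) {
  p <- frame$points[i + 1L, ]
  q <- frame$points[j + 1L, ]
  dx <- q[[1]] - p[[1]]
  dy <- q[[2]] - p[[2]]
  if (dx == 0) {
    if (dy == 0) return(0)
    return(sign(dy) * g_cap)
  }
  dy / dx
}

# vectorised core over one frame's coordinate matrix (68 x 2)
feature_values <- function(points, segments, g_cap = 1e4) {
  i <- segments[, 1] + 1L
  j <- segments[, 2] + 1L
  dx <- points[j, 1] - points[i, 1]
  dy <- points[j, 2] - points[i, 2]
  d <- sqrt(dx^2 + dy^2)
  g <- ifelse(dx == 0, ifelse(dy == 0, 0, sign(dy) * g_cap), dy / dx)
  as.vector(rbind(d, g))  # interleaved: d, g per segment
}

feature_names <- function(n_seg) {
  idx <- sprintf("%04d", seq_len(n_seg) - 1L)
  as.vector(rbind(paste0("d_", idx), paste0("g_", idx)))
}

#' Extract the feature vector of a frame on a graph
#'
#' For each segment in the graph's canonical order, emits the (distance,
#' gradient) pair, interleaved, giving 2 x |segments| features — 4556 for the
#' full-face graph and 2356 for the FACS-based graph.
#'
#' @param frame a `landmark_frame`.
#' @param graph a `segment_graph`.
#' @param g_cap vertical-segment slope cap, see [segment_gradient()].
#' @return named numeric vector of length `2 * n_segments(graph)`.
#' @export
extract_features <- function(frame, graph, g_cap = 1e4) {
  if (!n_segments(graph)) stop("graph has no segments")
  v <- feature_values(frame$points, graph$segments, g_cap)
  names(v) <- feature_names(n_segments(graph))
  v
}

#' Extract a feature matrix from a landmark table
#'
#' Applies [extract_features()] to every row of a landmark table, carrying
#' the metadata columns through.
#'
#' @param tab landmark table (`data.frame` in the
#'   `subject_id, video_id, frame_index, label, x0, y0, ...` dialect).
#' @param graph a `segment_graph`.
#' @param g_cap vertical-segment slope cap.
#' @return `data.frame`: metadata columns then `d_0000, g_0000, d_0001, ...`.
#' @export
extract_feature_matrix <- function(tab, graph, g_cap = 1e4) {
  validate_landmark_table(tab)
  cols <- landmark_table_columns()
  xy <- as.matrix(tab[, cols[-(1:4)]])
  feats <- t(apply(xy, 1L, function(row) {
    feature_values(matrix(row, ncol = 2L, byrow = TRUE), graph$segments, g_cap)
  }))
  colnames(feats) <- feature_names(n_segments(graph))
  cbind(tab[, cols[1:4]], as.data.frame(feats), stringsAsFactors = FALSE)
}

#' Fit a per-feature normalizer on training rows
#'
#' Min-max scaling to [0, 1] per feature by default (z-score selectable).
#' Features constant in training map to 0. The normalizer must be fitted on
#' training folds only and applied to held-out folds, so held-out values may
#' fall outside [0, 1]; no clipping is applied.
#'
#' @param x numeric training matrix (rows = samples, columns = features).
#' @param method `"minmax"` or `"zscore"`.
#' @return object of class `feature_normalizer`.
#' @export
fit_normalizer <- function(x, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  x <- as.matrix(x)
  if (!nrow(x)) stop("cannot fit a normalizer on an empty training matrix")
  if (method == "minmax") {
    lo <- apply(x, 2L, min)
    hi <- apply(x, 2L, max)
    structure(list(method = method, center = lo, scale = hi - lo),
              class = "feature_normalizer")
  } else {
    mu <- colMeans(x)
    sd <- apply(x, 2L, stats::sd)
    structure(list(method = method, center = mu, scale = sd),
              class = "feature_normalizer")
  }
}

#' @rdname fit_normalizer
#' @param object fitted `feature_normalizer`.
#' @param ... unused.
#' @export
predict.feature_normalizer <- function(object, x, ...) {
  x <- as.matrix(x)
  scl <- object$scale
  constant <- scl == 0 | !is.finite(scl)
  scl[constant] <- 1
  out <- sweep(sweep(x, 2L, object$center, "-"), 2L, scl, "/")
  out[, constant] <- 0  # constant-in-training features carry no signal
  out
}

#' @rdname fit_normalizer
#' @export
apply_normalizer <- function(object, x) predict(object, x)
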