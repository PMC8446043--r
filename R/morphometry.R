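#' Granule morphometry
#'
#' Segmentation of bright granules from a frozen threshold, boundary-polygon
#' measurement of area, perimeter and the shape factor `4 pi A / P^2`
#' (1 for a circle, smaller for elongated or irregular outlines), greedy
#' mutual nearest-neighbour track linking, and size-distribution comparison
#' by a two-sided Mann-Whitney test.
#'
#' @name morphometry
NULL

#' Shoelace area of a polygon
#' @param poly n x 2 matrix of vertices (closed implicitly).
#' @return Signed area (positive for counter-clockwise).
#' @keywords internal
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  sum(x * ys - xs * y) / 2
}

#' Perimeter of a polygon (sum of segment lengths)
#' @inheritParams polygon_area
#' @keywords internal
polygon_perimeter <- function(poly) {
  d <- rbind(poly[-1, , drop = FALSE], poly[1, , drop = FALSE]) - poly
  sum(sqrt(rowSums(d^2)))
}

#' Shape factor of a simple polygon
#'
#' `4 pi A / P^2` with `A` the shoelace area and `P` the segment-sum
#' perimeter.  By the isoperimetric inequality the value is at most 1 for any
#' simple polygon, reaching 1 only in the circular limit.
#'
#' @param boundary n x 2 matrix of polygon vertices (>= 3), in order.
#' @return Value in (0, 1].
#' @export
shape_factor <- function(boundary) {
  if (!is.matrix(boundary) || nrow(boundary) < 3L)
    stop("boundary must be a polygon with at least 3 vertices")
  A <- abs(polygon_area(boundary))
  P <- polygon_perimeter(boundary)
  if (A <= 0 || P <= 0) stop("degenerate (zero-area) polygon")
  4 * pi * A / P^2
}

#' Otsu threshold of an intensity image
#' @param img Numeric matrix.
#' @param n_bins Histogram resolution.
#' @return Threshold value.
#' @keywords internal
otsu_threshold <- function(img, n_bins = 256L) {
  v <- as.numeric(img)
  rng <- range(v)
  if (diff(rng) == 0) return(rng[1])
  h <- tabulate(pmin(pmax(floor((v - rng[1]) / diff(rng) * n_bins) + 1L, 1L),
                     n_bins), n_bins)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- rng[1] + (seq_len(n_bins) - 0.5) / n_bins * diff(rng)
  mu <- cumsum(p * mids)
  mu_t <- mu[n_bins]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# connected components of a logical matrix under 4-connectivity,
# two-pass union-find; returns an integer label matrix (0 = background)
label_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) { i <- parent[i] }; i }
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j]) next
    up <- if (i > 1L) labels[i - 1L, j] else 0L
    left <- if (j > 1L) labels[i, j - 1L] else 0L
    if (up == 0L && left == 0L) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      labels[i, j] <- nxt
    } else if (up != 0L && left != 0L) {
      ru <- find(up); rl <- find(left)
      labels[i, j] <- min(ru, rl)
      parent[max(ru, rl)] <- min(ru, rl)
    } else {
      labels[i, j] <- max(up, left)
    }
  }
  if (nxt > 0L) {
    roots <- vapply(seq_len(nxt), find, integer(1))
    relab <- match(roots, sort(unique(roots)))
    pos <- labels > 0L
    labels[pos] <- relab[labels[pos]]
  }
  labels
}

# fill holes: background components (4-connectivity) not touching the border
fill_holes <- function(mask) {
  bg <- label_components(!mask)
  border_labels <- unique(c(bg[1, ], bg[nrow(bg), ], bg[, 1], bg[, ncol(bg)]))
  border_labels <- border_labels[border_labels > 0L]
  mask | (bg > 0L & !(bg %in% border_labels))
}

# Moore-neighbour boundary tracing; returns the ordered outer boundary as
# 0-based pixel-center (x, y) coordinates.  The start pixel must be the
# uppermost pixel of the leftmost occupied column (its W neighbour is then
# guaranteed background, the canonical backtrack).
trace_boundary <- function(mask, start_rc) {
  nr <- nrow(mask); nc <- ncol(mask)
  inside <- function(r, c) r >= 1L && r <= nr && c >= 1L && c <= nc &&
    mask[r, c]
  # Moore neighbourhood enumerated clockwise starting at W (screen coords)
  moves <- rbind(W = c(0L, -1L), NW = c(-1L, -1L), N = c(-1L, 0L),
                 NE = c(-1L, 1L), E = c(0L, 1L), SE = c(1L, 1L),
                 S = c(1L, 0L), SW = c(1L, -1L))
  b <- as.integer(start_rc)
  scan_from <- 1L  # begin scanning at the backtrack (W of the start pixel)
  path <- matrix(b, 1L, 2L)
  max_steps <- 4L * sum(mask) + 8L
  repeat {
    found_dir <- 0L
    for (k in 0:7) {
      d <- ((scan_from - 1L + k) %% 8L) + 1L
      cand <- b + moves[d, ]
      if (inside(cand[1], cand[2])) { found_dir <- d; break }
    }
    if (found_dir == 0L) break  # isolated pixel
    b <- b + moves[found_dir, ]
    if (all(b == path[1, ])) break
    path <- rbind(path, b)
    # resume scanning two steps counter-clockwise of the entry direction,
    # i.e. from the background cell just before the one we moved into
    scan_from <- ((found_dir - 1L + 6L) %% 8L) + 1L
    if (nrow(path) > max_steps) break  # safety net
  }
  cbind(x = path[, 2] - 1L, y = path[, 1] - 1L)
}

#' Segment granules in one or more frames
#'
#' Thresholds the image(s) into a binary mask, labels connected components
#' with 4-connectivity, fills interior holes (projected area), traces each
#' component's outer boundary as an ordered pixel-center polygon, and
#' measures area, perimeter and shape factor in physical units.  With
#' `threshold = NULL` the Otsu threshold of the first frame is computed once
#' and reused for every frame, so time-lapse measurements share one
#' threshold.  Raster areas use the lattice-point count enclosed by the
#' boundary (Pick-corrected shoelace, the projected pixel area); raster shape
#' factors may slightly exceed 1 for small objects — exact statements hold
#' for polygon inputs only.
#'
#' @param seq An [image_sequence()], a numeric matrix (single frame) or a
#'   3-D array.
#' @param threshold Fixed intensity threshold, or `NULL` for
#'   Otsu-on-first-frame-then-frozen.
#' @param min_area_px Components below this pixel count are dropped
#'   (default 9).
#' @param pixel_size_um Pixel size; taken from the sequence when available.
#' @return Data frame with one row per granule: `frame, label, area_um2,
#'   perimeter_um, shape_factor, x_um, y_um, n_px`, with the boundary
#'   polygons in `attr(, "boundaries")` (list of n x 2 pixel-coordinate
#'   matrices, named `frame.label`) and the threshold in
#'   `attr(, "threshold")`.
#' @export
segment_granules <- function(seq, threshold = NULL, min_area_px = 9L,
                             pixel_size_um = NULL) {
  if (inherits(seq, "ImageSequence")) {
    frames <- seq$frames
    pixel_size_um <- pixel_size_um %||% seq$pixel_size_um
  } else if (is.matrix(seq)) {
    frames <- array(seq, c(1L, nrow(seq), ncol(seq)))
  } else frames <- seq
  pixel_size_um <- pixel_size_um %||% 1
  if (is.null(threshold)) threshold <- otsu_threshold(frames[1, , ])
  px <- pixel_size_um
  out <- list(); boundaries <- list()
  for (t in seq_len(dim(frames)[1])) {
    mask <- frames[t, , ] > threshold
    if (!any(mask)) next
    mask <- fill_holes(mask)
    labels <- label_components(mask)
    for (lb in seq_len(max(labels))) {
      idx <- which(labels == lb, arr.ind = TRUE)
      if (nrow(idx) < min_area_px) next
      comp <- labels == lb
      # start pixel: first in column-major scan (uppermost of leftmost column)
      start <- idx[order(idx[, 2], idx[, 1]), , drop = FALSE][1, ]
      poly <- trace_boundary(comp, start)
      n_b <- nrow(poly)
      if (n_b >= 3L) {
        shoelace <- abs(polygon_area(poly))
        # Pick: lattice points enclosed incl. boundary = A + B/2 + 1
        area_px2 <- shoelace + n_b / 2 + 1
        perim_px <- polygon_perimeter(poly)
        sf <- 4 * pi * area_px2 / perim_px^2
      } else {
        area_px2 <- nrow(idx); perim_px <- max(n_b, 1) * 1; sf <- NA_real_
      }
      cx <- mean(idx[, 2] - 1L); cy <- mean(idx[, 1] - 1L)
      key <- sprintf("%d.%d", t, lb)
      boundaries[[key]] <- poly
      out[[length(out) + 1L]] <- data.frame(
        frame = t, label = lb, area_um2 = area_px2 * px^2,
        perimeter_um = perim_px * px, shape_factor = sf,
        x_um = cx * px, y_um = cy * px, n_px = nrow(idx))
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(frame = integer(), label = integer(),
                         area_um2 = numeric(), perimeter_um = numeric(),
                         shape_factor = numeric(), x_um = numeric(),
                         y_um = numeric(), n_px = integer())
  attr(res, "boundaries") <- boundaries
  attr(res, "threshold") <- threshold
  res
}

#' Compare two granule size distributions
#'
#' Standard reporting plumbing for before/after (e.g. hexanediol) or
#' genotype comparisons: per-group mean +/- SD of areas and a two-sided
#' Mann-Whitney (Wilcoxon rank-sum) test.
#'
#' @param sizes_a,sizes_b Numeric vectors of granule areas (n >= 3 each).
#' @param labels Group names.
#' @return List `summary` (data frame), `U`, `p_value`.
#' @export
size_distribution <- function(sizes_a, sizes_b,
                              labels = c("group_a", "group_b")) {
  if (length(sizes_a) < 3L || length(sizes_b) < 3L)
    stop("each group needs at least 3 granules")
  wt <- stats::wilcox.test(sizes_a, sizes_b, alternative = "two.sided",
                           exact = length(sizes_a) < 50 &&
                             length(sizes_b) < 50)
  list(summary = data.frame(
         group = labels,
         n = c(length(sizes_a), length(sizes_b)),
         mean = c(mean(sizes_a), mean(sizes_b)),
         sd = c(stats::sd(sizes_a), stats::sd(sizes_b))),
       U = unname(wt$statistic), p_value = wt$p.value)
}

#' Link per-frame granules into tracks
#'
#' Greedy mutual nearest-neighbour linking between consecutive frames within
#' `max_link_distance_um`; unmatched granules start or terminate tracks, and
#' isolated detections form length-1 tracks.  (The original measurements were
#' tracked manually; any automated linker is an extrapolation and this one is
#' deliberately the simplest defensible choice.)
#'
#' @param granules A [segment_granules()] data frame spanning >= 2 frames.
#' @param max_link_distance_um Maximum per-step displacement.
#' @param frame_interval_s Frame interval used for speeds (default 1).
#' @return A `TrackSet`: `tracks` data frame (`track, frame, label, x_um,
#'   y_um, area_um2, shape_factor`), `steps` data frame (`track, frame,
#'   displacement_um, speed_um_s`).
#' @export
link_tracks <- function(granules, max_link_distance_um,
                        frame_interval_s = 1) {
  frames <- sort(unique(granules$frame))
  granules$track <- NA_integer_
  next_track <- 0L
  rows_of <- function(fr) which(granules$frame == fr)
  prev <- rows_of(frames[1])
  granules$track[prev] <- seq_along(prev)
  next_track <- length(prev)
  if (length(frames) >= 2L) for (fi in 2:length(frames)) {
    cur <- rows_of(frames[fi])
    if (length(prev) && length(cur)) {
      dmat <- outer(seq_along(prev), seq_along(cur), function(i, j)
        sqrt((granules$x_um[prev[i]] - granules$x_um[cur[j]])^2 +
             (granules$y_um[prev[i]] - granules$y_um[cur[j]])^2))
      # mutual nearest neighbours within range, greedy by distance
      repeat {
        if (!length(dmat) || all(!is.finite(dmat))) break
        m <- which.min(dmat)
        if (!length(m) || dmat[m] > max_link_distance_um) break
        ij <- arrayInd(m, dim(dmat))
        i <- ij[1]; j <- ij[2]
        if (dmat[i, j] == min(dmat[i, ], na.rm = TRUE) &&
            dmat[i, j] == min(dmat[, j], na.rm = TRUE)) {
          granules$track[cur[j]] <- granules$track[prev[i]]
        }
        dmat[i, ] <- Inf; dmat[, j] <- Inf
      }
    }
    un <- cur[is.na(granules$track[cur])]
    if (length(un)) {
      granules$track[un] <- next_track + seq_along(un)
      next_track <- next_track + length(un)
    }
    prev <- cur
  }
  tracks <- granules[order(granules$track, granules$frame),
                     c("track", "frame", "label", "x_um", "y_um",
                       "area_um2", "shape_factor")]
  steps <- do.call(rbind, lapply(split(tracks, tracks$track), function(tr) {
    if (nrow(tr) < 2L) return(NULL)
    disp <- sqrt(diff(tr$x_um)^2 + diff(tr$y_um)^2)
    dfr <- diff(tr$frame)
    data.frame(track = tr$track[-1], frame = tr$frame[-1],
               displacement_um = disp,
               speed_um_s = disp / (dfr * frame_interval_s))
  }))
  if (is.null(steps))
    steps <- data.frame(track = integer(), frame = integer(),
                        displacement_um = numeric(), speed_um_s = numeric())
  structure(list(tracks = tracks, steps = steps,
                 frame_interval_s = frame_interval_s), class = "TrackSet")
}

#' Per-track shape-factor time course
#'
#' Requires shapes measured with one frozen threshold across frames (as
#' [segment_granules()] does), so the series reflects morphology, not
#' thresholding.
#'
#' @param track_set A [link_tracks()] result.
#' @return Data frame `track, frame, shape_factor, area_um2`.
#' @export
circularity_timecourse <- function(track_set) {
  stopifnot(inherits(track_set, "TrackSet"))
  track_set$tracks[, c("track", "frame", "shape_factor", "area_um2")]
}
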