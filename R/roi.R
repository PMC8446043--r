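#' Regions of interest
#'
#' ROIs are rectangles or discs in 0-based, pixel-centered coordinates.
#' For a rectangle `(x, y)` is the corner pixel (column, row) and
#' `(w, h)` its extent in pixels; for a disc `(x, y)` is the center and `w`
#' the radius in pixels (`h` is ignored and stored equal to `w`).  The `role`
#' tags how a pipeline uses the ROI: `bleach`, `granule`, `cytoplasm`,
#' `background` or `reference`.
#'
#' @param kind `"rectangle"` or `"disc"`.
#' @param x,y Corner (rectangle) or center (disc) coordinates in pixels.
#' @param w,h Extent in pixels (disc: `w` = radius).
#' @param label Free-text identifier.
#' @param role One of `bleach`, `granule`, `cytoplasm`, `background`,
#'   `reference`.
#' @return An object of class `RoiSpec`.
#' @export
roi_spec <- function(kind, x, y, w, h = w, label = "", role = "granule") {
  kind <- match.arg(kind, c("rectangle", "disc"))
  role <- match.arg(role, c("bleach", "granule", "cytoplasm", "background",
                            "reference"))
  if (kind == "disc") h <- w
  if (w <= 0 || (kind == "rectangle" && h <= 0))
    stop("ROI must have positive area")
  structure(list(kind = kind, x = as.numeric(x), y = as.numeric(y),
                 w = as.numeric(w), h = as.numeric(h),
                 label = as.character(label), role = role),
            class = "RoiSpec")
}

#' @export
print.RoiSpec <- function(x, ...) {
  cat(sprintf("RoiSpec[%s] %s (%g,%g) extent (%g,%g) role=%s\n",
              x$kind, x$label, x$x, x$y, x$w, x$h, x$role))
  invisible(x)
}

# validate that an ROI fits a frame of `nrow` x `ncol` pixels
.roi_check_bounds <- function(roi, nrow, ncol, where = "") {
  ok <- if (roi$kind == "rectangle") {
    roi$x >= 0 && roi$y >= 0 &&
      roi$x + roi$w <= ncol && roi$y + roi$h <= nrow
  } else {
    roi$x - roi$w >= -0.5 && roi$y - roi$w >= -0.5 &&
      roi$x + roi$w <= ncol - 0.5 && roi$y + roi$w <= nrow - 0.5
  }
  if (!ok) stop("ROI out of frame bounds", where)
  invisible(TRUE)
}

#' Logical pixel mask of an ROI
#'
#' @param roi A [roi_spec()].
#' @param nrow,ncol Frame dimensions in pixels.
#' @param center Optional `(x, y)` overriding the stored position (used when a
#'   granule ROI is tracked frame to frame).
#' @return Logical `nrow` x `ncol` matrix.
#' @export
roi_mask <- function(roi, nrow, ncol, center = NULL) {
  m <- matrix(FALSE, nrow, ncol)
  if (roi$kind == "rectangle") {
    x0 <- roi$x; y0 <- roi$y
    if (!is.null(center)) { x0 <- center[1] - roi$w / 2; y0 <- center[2] - roi$h / 2 }
    rows <- seq.int(floor(y0), ceiling(y0 + roi$h) - 1L)
    cols <- seq.int(floor(x0), ceiling(x0 + roi$w) - 1L)
    rows <- rows[rows >= 0 & rows < nrow]; cols <- cols[cols >= 0 & cols < ncol]
    m[rows + 1L, cols + 1L] <- TRUE
  } else {
    cx <- roi$x; cy <- roi$y
    if (!is.null(center)) { cx <- center[1]; cy <- center[2] }
    xs <- matrix(rep(0:(ncol - 1L), each = nrow), nrow)
    ys <- matrix(rep(0:(nrow - 1L), times = ncol), nrow)
    m <- (xs - cx)^2 + (ys - cy)^2 <= roi$w^2
  }
  m
}

#' Read ROIs from a CSV table
#'
#' Expected columns: `kind, x, y, w, h, label, role` (header optional when the
#' first field of the first row is `rectangle` or `disc`).
#'
#' @param path CSV file path.
#' @param frame_shape Optional `(nrow, ncol)`; when given, every ROI is
#'   validated against the frame bounds and an out-of-bounds row raises an
#'   error naming the row.
#' @return List of [roi_spec()] objects.
#' @export
read_rois <- function(path, frame_shape = NULL) {
  if (!file.exists(path)) stop("ROI file not found: ", path)
  first <- strsplit(readLines(path, n = 1L), ",")[[1]][1]
  header <- !(first %in% c("rectangle", "disc"))
  df <- utils::read.csv(path, header = header, stringsAsFactors = FALSE)
  if (!header)
    names(df) <- c("kind", "x", "y", "w", "h", "label", "role")[seq_len(ncol(df))]
  rois <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    rois[[i]] <- tryCatch(
      roi_spec(df$kind[i], df$x[i], df$y[i], df$w[i],
               if ("h" %in% names(df)) df$h[i] else df$w[i],
               label = if ("label" %in% names(df)) df$label[i] else "",
               role = if ("role" %in% names(df)) df$role[i] else "granule"),
      error = function(e) stop("ROI row ", i, ": ", conditionMessage(e)))
    if (!is.null(frame_shape))
      tryCatch(.roi_check_bounds(rois[[i]], frame_shape[1], frame_shape[2]),
               error = function(e) stop("ROI row ", i, ": ", conditionMessage(e)))
  }
  rois
}

#' Write ROIs to CSV
#'
#' @param rois List of [roi_spec()] objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rois <- function(rois, path) {
  df <- do.call(rbind, lapply(rois, function(r)
    data.frame(kind = r$kind, x = r$x, y = r$y, w = r$w, h = r$h,
               label = r$label, role = r$role)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
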