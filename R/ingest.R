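# Frame ingestion: sampling frames from a video source at a fixed interval,
# cropping to the endoscopic region of interest, and reading/writing frame
# sequences on disk.
#
# Coordinate convention used throughout the package: 0-based (row, column)
# with the origin at the top-left pixel and half-open index ranges. Crop
# regions are given as (left, top, width, height) in that convention.

#' A single video frame with timing metadata
#'
#' Wraps a pixel grid together with its timestamp and ordinal position in the
#' sampled sequence. Pixels are stored as doubles in `[0, 1]`: a `height x
#' width` matrix for grayscale frames or a `height x width x 3` array for RGB.
#'
#' @param pixels Numeric matrix (grayscale) or `H x W x 3` array (RGB) with
#'   values in `[0, 1]`.
#' @param timestamp Seconds from the start of the video.
#' @param index 0-based ordinal position in the sampled sequence.
#' @return A `frame_image` object.
#' @export
frame_image <- function(pixels, timestamp = 0, index = 0L) {
  if (!(is.matrix(pixels) || (is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3)))
    stop("pixels must be a matrix or an H x W x 3 array")
  if (!all(is.finite(pixels))) stop("pixels contain non-finite values")
  if (min(pixels) < 0 || max(pixels) > 1)
    stop("pixel intensities must lie in [0, 1]")
  d <- dim(pixels)
  structure(
    list(pixels = pixels, width = d[2], height = d[1],
         timestamp = as.numeric(timestamp), index = as.integer(index)),
    class = "frame_image")
}

#' @export
print.frame_image <- function(x, ...) {
  kind <- if (is.matrix(x$pixels)) "grayscale" else "RGB"
  cat(sprintf("<frame_image %dx%d %s  t=%.3fs  index=%d>\n",
              x$width, x$height, kind, x$timestamp, x$index))
  invisible(x)
}

#' Frame-sampling configuration
#'
#' Controls how frames are sampled from a video source. The defaults mirror a
#' common acquisition protocol for colonoscopy footage: one frame every 0.5 s
#' from a 1920x1080 source, cropped to the 850x750 endoscopic viewing area.
#' The crop offset within the source frame depends on the endoscope UI layout
#' and is therefore configurable; the default centers the region horizontally
#' and aligns it to the top.
#'
#' @param sampling_interval Seconds between sampled frames (> 0).
#' @param crop_region Integer vector `c(left, top, width, height)` in 0-based
#'   pixel coordinates, or `NULL` to skip cropping. Defaults to an 850x750
#'   region centered horizontally at the top of a 1920x1080 frame.
#' @param grayscale Convert frames to grayscale luminance on ingest?
#' @return An `ingest_config` object.
#' @export
ingest_config <- function(sampling_interval = 0.5,
                          crop_region = c(left = 535L, top = 0L, width = 850L, height = 750L),
                          grayscale = FALSE) {
  if (sampling_interval <= 0) stop("sampling_interval must be > 0")
  if (!is.null(crop_region)) {
    if (length(crop_region) != 4) stop("crop_region must be c(left, top, width, height)")
    crop_region <- as.integer(crop_region)
    names(crop_region) <- c("left", "top", "width", "height")
    if (any(crop_region[c("width", "height")] <= 0) || any(crop_region[c("left", "top")] < 0))
      stop("crop_region must have non-negative offsets and positive size")
  }
  structure(list(sampling_interval = sampling_interval,
                 crop_region = crop_region, grayscale = grayscale),
            class = "ingest_config")
}

#' In-memory video object
#'
#' A stack of frames with a frame rate, used for synthetic videos and for
#' sources whose frames are already decoded. `frames` is a list of pixel
#' grids (all the same size) or a `H x W x T` / `H x W x 3 x T` array.
#'
#' @param frames List of matrices/arrays, or a 3-D/4-D array with time last.
#' @param fps Frames per second of the source (> 0).
#' @return A `video_frames` object.
#' @export
video_frames <- function(frames, fps = 30) {
  if (fps <= 0) stop("fps must be > 0")
  if (is.array(frames) && !is.list(frames)) {
    nd <- length(dim(frames))
    if (!nd %in% c(3, 4)) stop("frame array must be H x W x T or H x W x 3 x T")
    tdim <- dim(frames)[nd]
    frames <- lapply(seq_len(tdim), function(k)
      if (nd == 3) frames[, , k] else frames[, , , k])
  }
  if (length(frames) == 0) stop("video has no frames")
  d1 <- dim(frames[[1]])
  for (f in frames) if (!identical(dim(f)[1:2], d1[1:2]))
    stop("all frames must share dimensions")
  structure(list(frames = frames, fps = fps), class = "video_frames")
}

rgb_to_gray <- function(pixels) {
  if (is.matrix(pixels)) return(pixels)
  # ITU-R BT.601 luminance
  0.299 * pixels[, , 1] + 0.587 * pixels[, , 2] + 0.114 * pixels[, , 3]
}

#' Crop a frame to a rectangular region
#'
#' Extracts an exact sub-grid copy. The region is `(left, top, width, height)`
#' in 0-based coordinates with the origin at the top-left pixel, so a source
#' pixel at 0-based `(r, c)` lands at `(r - top, c - left)` in the output.
#'
#' @param frame A [frame_image].
#' @param region `c(left, top, width, height)`, 0-based.
#' @return A [frame_image] of the region's dimensions, same timestamp/index.
#' @export
crop_frame <- function(frame, region) {
  stopifnot(inherits(frame, "frame_image"))
  region <- as.integer(region)
  left <- region[1]; top <- region[2]; w <- region[3]; h <- region[4]
  if (left < 0 || top < 0 || w <= 0 || h <= 0 ||
      left + w > frame$width || top + h > frame$height)
    stop("crop region lies outside the frame bounds")
  rows <- (top + 1):(top + h)
  cols <- (left + 1):(left + w)
  px <- if (is.matrix(frame$pixels)) frame$pixels[rows, cols, drop = FALSE]
        else frame$pixels[rows, cols, , drop = FALSE]
  frame_image(px, timestamp = frame$timestamp, index = frame$index)
}

#' Sample frames from a video source at a fixed interval
#'
#' Produces frames at times `k * sampling_interval` for `k = 0, 1, ...` up to
#' the video duration (timestamp of the last source frame); a trailing partial
#' interval yields no frame. Each sampled time is mapped to the nearest source
#' frame (no interpolation), then cropped per the configuration.
#'
#' Accepted sources: a [video_frames] object, or a path to a directory of PNG
#' frames named with zero-padded indices (interpreted as consecutive source
#' frames at `fps`). Compressed video containers are not decoded; decompose
#' the video to PNG frames first.
#'
#' @param video A [video_frames] object or a directory path of PNG frames.
#' @param config An [ingest_config].
#' @param fps Source frame rate, used when `video` is a directory path.
#' @return List of [frame_image] objects with strictly increasing timestamps.
#' @export
extract_frames <- function(video, config = ingest_config(), fps = 30) {
  stopifnot(inherits(config, "ingest_config"))
  if (is.character(video)) {
    if (grepl("\\.(mp4|avi|mov|mkv)$", video, ignore.case = TRUE))
      stop("compressed video containers are not decoded; extract PNG frames first ",
           "and pass the frame directory")
    if (!dir.exists(video)) stop("unreadable video source: ", video)
    files <- sort(list.files(video, pattern = "\\.png$", full.names = TRUE))
    if (length(files) == 0) stop("no PNG frames found in ", video)
    src <- lapply(files, function(f) read_frame_png(f)$pixels)
    video <- video_frames(src, fps = fps)
  }
  stopifnot(inherits(video, "video_frames"))
  n_src <- length(video$frames)
  duration <- (n_src - 1) / video$fps
  if (config$sampling_interval < 1 / video$fps)
    stop("sampling interval must be at least one source-frame duration")
  times <- seq(0, duration + 1e-9, by = config$sampling_interval)
  times <- times[times <= duration + 1e-9]
  out <- vector("list", length(times))
  for (k in seq_along(times)) {
    src_idx <- round(times[k] * video$fps) + 1
    src_idx <- min(max(src_idx, 1), n_src)
    px <- video$frames[[src_idx]]
    if (config$grayscale) px <- rgb_to_gray(px)
    fr <- frame_image(px, timestamp = times[k], index = k - 1L)
    if (!is.null(config$crop_region)) fr <- crop_frame(fr, config$crop_region)
    out[[k]] <- fr
  }
  out
}

#' Read a PNG file as a frame
#'
#' @param path PNG file path.
#' @param timestamp,index Metadata attached to the returned frame.
#' @return A [frame_image].
#' @export
read_frame_png <- function(path, timestamp = 0, index = 0L) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 3) {
    if (dim(px)[3] == 4) px <- px[, , 1:3]      # drop alpha
    else if (dim(px)[3] == 1) px <- px[, , 1]
  }
  frame_image(px, timestamp = timestamp, index = index)
}

#' Write a frame sequence as PNG files plus a CSV manifest
#'
#' Files are named `frame_<index>.png` with zero-padded indices; the manifest
#' lists `index`, `timestamp_s` and `filename`.
#'
#' @param frames List of [frame_image] objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data frame.
#' @export
write_frames <- function(frames, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pad <- max(4, nchar(as.character(max(vapply(frames, `[[`, 0L, "index")))))
  manifest <- data.frame(index = integer(0), timestamp_s = numeric(0),
                         filename = character(0))
  for (fr in frames) {
    fn <- sprintf(paste0("frame_%0", pad, "d.png"), fr$index)
    png::writePNG(fr$pixels, file.path(dir, fn))
    manifest <- rbind(manifest, data.frame(index = fr$index,
                                           timestamp_s = fr$timestamp,
                                           filename = fn))
  }
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Read a frame sequence written by [write_frames()]
#'
#' @param dir Directory containing PNG frames and `manifest.csv`.
#' @return List of [frame_image] objects in manifest order.
#' @export
read_frames <- function(dir) {
  mf <- utils::read.csv(file.path(dir, "manifest.csv"))
  lapply(seq_len(nrow(mf)), function(i)
    read_frame_png(file.path(dir, mf$filename[i]),
                   timestamp = mf$timestamp_s[i], index = mf$index[i]))
}
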