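# Color-coded timeline summary (SRCV): the direction signal rendered as rows
# of colored squares at several time scales (1 s / 10 s / 30 s per square)
# with the cecum estimate marked. Coarser scales aggregate each bin to its
# majority label, which removes small outliers and makes the insertion /
# withdrawal phase boundary visually obvious.

#' Default timeline colors
#'
#' Three maximally distinct colors for insertion (red), withdrawal (blue)
#' and stop (light gray), plus black for the cecum marker.
#' @export
timeline_colors <- function() {
  c(insertion = "#D7263D", withdrawal = "#1B6CA8", stop = "#C8C8C8",
    cecum = "#000000")
}

#' Aggregate a direction signal into timeline squares
#'
#' Partitions time from the signal start into consecutive half-open bins
#' `[k*scale, (k+1)*scale)` and labels each bin with the modal label of the
#' samples inside it; a trailing partial bin is kept if it contains at least
#' one sample. A tie between labels is resolved in favor of the tied label
#' that occurs first in time within the bin.
#'
#' @param signal A [direction_signal].
#' @param scale Seconds per square (> 0).
#' @return Data frame with columns `start_time`, `scale`, `label`, `value`;
#'   zero rows for an empty signal.
#' @export
aggregate_timeline <- function(signal, scale) {
  stopifnot(inherits(signal, "direction_signal"))
  if (scale <= 0) stop("scale must be > 0")
  rel <- signal$times - signal$times[1]
  bin <- floor(rel / scale + 1e-9)
  labs_by_value <- c(`1` = "insertion", `-1` = "withdrawal", `0` = "stop")
  rows <- lapply(sort(unique(bin)), function(k) {
    vals <- signal$values[bin == k]
    counts <- table(vals)
    top <- max(counts)
    tied <- as.numeric(names(counts)[counts == top])
    v <- if (length(tied) == 1) tied else vals[vals %in% tied][1]
    data.frame(start_time = signal$times[1] + k * scale, scale = scale,
               label = unname(labs_by_value[as.character(v)]), value = v)
  })
  do.call(rbind, rows)
}

#' Compose the summary report of a colonoscopy video (SRCV)
#'
#' Bundles the aggregated timelines at the requested scales with the cecum
#' estimate and the video metadata.
#'
#' @param signal A [direction_signal].
#' @param estimate A `cecum_estimate` from [locate_cecum()] (or `NULL`).
#' @param scales Seconds per square for each timeline row.
#' @return An `srcv_report` object.
#' @export
srcv_report <- function(signal, estimate = NULL, scales = c(1, 10, 30)) {
  stopifnot(inherits(signal, "direction_signal"))
  if (length(scales) == 0) stop("need at least one scale")
  timelines <- lapply(scales, function(s) aggregate_timeline(signal, s))
  names(timelines) <- paste0("scale_", scales)
  duration <- signal$times[length(signal$times)] - signal$times[1]
  structure(list(timelines = timelines, scales = scales,
                 cecum_marker = if (!is.null(estimate) && !is.na(estimate$time))
                   list(time = estimate$time, window_t = estimate$window_t)
                 else NULL,
                 metadata = list(duration = duration,
                                 sampling_interval = signal$sample_interval,
                                 start_time = signal$times[1])),
            class = "srcv_report")
}

#' @export
print.srcv_report <- function(x, ...) {
  cat(sprintf("<srcv_report %.1fs at scales {%s}s%s>\n", x$metadata$duration,
              paste(x$scales, collapse = ", "),
              if (!is.null(x$cecum_marker))
                sprintf(", cecum at %.1fs", x$cecum_marker$time) else ""))
  invisible(x)
}

hex_to_rgb01 <- function(hex) as.vector(grDevices::col2rgb(hex)) / 255

#' Render an SRCV report to a PNG image
#'
#' Draws one row of colored squares per scale (temporal order left to
#' right), a black cecum tick across every row at the marker time, and a
#' three-entry legend strip. Pixel output is a pure function of the report
#' and settings, so repeated renders are byte-identical.
#'
#' @param report An [srcv_report].
#' @param out_path Output PNG path.
#' @param colormap Named colors as from [timeline_colors()].
#' @param square_px Pixel height of a timeline square.
#' @param row_gap_px Vertical gap between rows, in pixels.
#' @return Invisibly, `out_path`.
#' @export
render_report <- function(report, out_path, colormap = timeline_colors(),
                          square_px = 12L, row_gap_px = 4L) {
  stopifnot(inherits(report, "srcv_report"))
  if (length(report$timelines) == 0) stop("report has no timelines")
  duration <- max(report$metadata$duration, max(report$scales))
  margin <- 6L
  width <- margin * 2L + as.integer(ceiling(duration))  # 1 px per second
  n_rows <- length(report$timelines)
  legend_h <- square_px + row_gap_px
  height <- margin * 2L + n_rows * (square_px + row_gap_px) + legend_h
  img <- array(1, c(height, width, 3))
  t0 <- report$metadata$start_time
  px_of <- function(tt) margin + as.integer(floor(tt - t0)) + 1L
  for (r in seq_len(n_rows)) {
    tl <- report$timelines[[r]]
    y0 <- margin + (r - 1L) * (square_px + row_gap_px)
    rows_px <- (y0 + 1L):(y0 + square_px)
    for (i in seq_len(nrow(tl))) {
      xa <- px_of(tl$start_time[i])
      xb <- min(px_of(tl$start_time[i] + tl$scale[i]) - 1L, width - margin)
      if (xb < xa) next
      col3 <- hex_to_rgb01(colormap[[tl$label[i]]])
      for (ch in 1:3) img[rows_px, xa:xb, ch] <- col3[ch]
    }
    # thin white separators between squares of this row
    sep <- px_of(tl$start_time) - 1L
    sep <- sep[sep > margin & sep <= width - margin]
    img[rows_px, sep, ] <- 1
  }
  if (!is.null(report$cecum_marker)) {
    xc <- min(max(px_of(report$cecum_marker$time), margin + 1L), width - margin)
    yr <- (margin + 1L):(margin + n_rows * (square_px + row_gap_px) - row_gap_px)
    col3 <- hex_to_rgb01(colormap[["cecum"]])
    for (ch in 1:3) img[yr, xc, ch] <- col3[ch]
  }
  # legend: three swatches at the bottom-left
  ly <- height - margin - square_px
  for (j in seq_along(DIRECTION_LEVELS)) {
    xa <- margin + (j - 1L) * (square_px * 2L) + 1L
    col3 <- hex_to_rgb01(colormap[[DIRECTION_LEVELS[j]]])
    for (ch in 1:3)
      img[(ly + 1L):(ly + square_px), xa:(xa + square_px - 1L), ch] <- col3[ch]
  }
  png::writePNG(img, out_path)
  invisible(out_path)
}
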