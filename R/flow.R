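# Horn-Schunck optical flow and its color encoding.
#
# The flow between two grayscale frames is the minimizer of the global energy
#   E(u, v) = sum (Ex*u + Ey*v + Et)^2 + alpha^2 * (|grad u|^2 + |grad v|^2),
# i.e. a brightness-constancy data term plus a smoothness regularizer. The
# classical fixed-point iteration updates each pixel from the local flow
# average:  u <- ubar - Ex*(Ex*ubar + Ey*vbar + Et) / (alpha^2 + Ex^2 + Ey^2),
# and likewise for v. Only small displacements (a pixel or two) are within the
# linearization's validity, which is why upstream sampling keeps consecutive
# frames 0.5 s apart; no coarse-to-fine pyramid is used.

#' Parameters for Horn-Schunck flow estimation
#'
#' @param alpha Smoothness weight (> 0), expressed relative to the root-mean-
#'   square spatial intensity gradient of the frame pair: the effective
#'   weight used in the energy is `alpha` times that RMS gradient. This
#'   makes the estimator exactly invariant to scaling both frames'
#'   intensities by a constant (both energy terms then scale together) and
#'   keeps one default sensible across 8-bit and normalized data. For a
#'   frame pair with no spatial gradient at all the data term vanishes and
#'   the flow stays identically zero regardless of `alpha`.
#' @param n_iterations Maximum fixed-point iterations. The update is a
#'   Jacobi-type relaxation and needs a few hundred sweeps to propagate
#'   motion evidence across texture-poor regions.
#' @param convergence_tol Stop when the mean absolute update of (u, v) falls
#'   below this threshold (0 disables early stopping).
#' @return A `flow_params` object.
#' @export
flow_params <- function(alpha = 2, n_iterations = 400L, convergence_tol = 1e-5) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (convergence_tol < 0) stop("convergence_tol must be >= 0")
  structure(list(alpha = alpha, n_iterations = as.integer(n_iterations),
                 convergence_tol = convergence_tol), class = "flow_params")
}

#' Per-pixel motion field between two frames
#'
#' @param u,v Matrices of horizontal (+u = rightward, increasing column) and
#'   vertical (+v = downward, increasing row) velocity in pixels per frame
#'   step.
#' @return A `flow_field` object.
#' @export
flow_field <- function(u, v) {
  if (!identical(dim(u), dim(v))) stop("u and v must have identical dimensions")
  if (!all(is.finite(u)) || !all(is.finite(v))) stop("flow values must be finite")
  structure(list(u = u, v = v, width = ncol(u), height = nrow(u)),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field %dx%d  mean |flow| = %.4f px>\n", x$width, x$height,
              mean(sqrt(x$u^2 + x$v^2))))
  invisible(x)
}

# shift a matrix by (dr, dc) with replicate-edge padding
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1), nc)
  m[ri, ci, drop = FALSE]
}

# Horn's derivative estimates: averages of forward differences over the
# 2x2x2 cube spanning the two frames, evaluated with replicate-edge padding
# so the derivative grids keep the image size. Stencil choice shifts values
# slightly; this is the classical one.
hs_derivatives <- function(e1, e2) {
  dxs <- function(m) shift_mat(m, 0, 1) - m   # column (x) forward difference
  dys <- function(m) shift_mat(m, 1, 0) - m   # row (y) forward difference
  ex <- (dxs(e1) + shift_mat(dxs(e1), 1, 0) + dxs(e2) + shift_mat(dxs(e2), 1, 0)) / 4
  ey <- (dys(e1) + shift_mat(dys(e1), 0, 1) + dys(e2) + shift_mat(dys(e2), 0, 1)) / 4
  dt <- e2 - e1
  et <- (dt + shift_mat(dt, 1, 0) + shift_mat(dt, 0, 1) + shift_mat(dt, 1, 1)) / 4
  list(ex = ex, ey = ey, et = et)
}

# weighted 8-neighbor local average (1/6 edge, 1/12 diagonal), replicate edges
hs_local_avg <- function(m) {
  (shift_mat(m, -1, 0) + shift_mat(m, 1, 0) +
   shift_mat(m, 0, -1) + shift_mat(m, 0, 1)) / 6 +
  (shift_mat(m, -1, -1) + shift_mat(m, -1, 1) +
   shift_mat(m, 1, -1) + shift_mat(m, 1, 1)) / 12
}

hs_energy <- function(u, v, ex, ey, et, alpha) {
  gx <- function(m) shift_mat(m, 0, 1) - m
  gy <- function(m) shift_mat(m, 1, 0) - m
  sum((ex * u + ey * v + et)^2) +
    alpha^2 * sum(gx(u)^2 + gy(u)^2 + gx(v)^2 + gy(v)^2)
}

#' Compute Horn-Schunck optical flow between two consecutive frames
#'
#' Runs the fixed-point iteration from a zero field for at most
#' `params$n_iterations`, stopping early when the mean absolute update drops
#' below `params$convergence_tol`. RGB frames are converted to luminance
#' first. The per-iteration energy trace is attached for diagnostics.
#'
#' @param prev,curr [frame_image] objects (or plain matrices) of identical
#'   dimensions.
#' @param params A [flow_params].
#' @return A [flow_field] with attribute `energy` (numeric vector, one entry
#'   per completed iteration).
#' @export
compute_flow <- function(prev, curr, params = flow_params()) {
  e1 <- if (inherits(prev, "frame_image")) rgb_to_gray(prev$pixels) else prev
  e2 <- if (inherits(curr, "frame_image")) rgb_to_gray(curr$pixels) else curr
  if (!identical(dim(e1), dim(e2))) stop("frames must have identical dimensions")
  if (!all(is.finite(e1)) || !all(is.finite(e2))) stop("frames contain non-finite values")
  d <- hs_derivatives(e1, e2)
  # smoothness weight relative to the data's gradient scale (see flow_params)
  grms <- sqrt(mean(d$ex^2 + d$ey^2))
  alpha_eff <- if (grms > 0) params$alpha * grms else params$alpha
  a2 <- alpha_eff^2
  denom <- a2 + d$ex^2 + d$ey^2
  u <- matrix(0, nrow(e1), ncol(e1))
  v <- u
  energy <- numeric(0)
  for (it in seq_len(params$n_iterations)) {
    ubar <- hs_local_avg(u); vbar <- hs_local_avg(v)
    common <- (d$ex * ubar + d$ey * vbar + d$et) / denom
    u_new <- ubar - d$ex * common
    v_new <- vbar - d$ey * common
    upd <- mean(abs(u_new - u)) + mean(abs(v_new - v))
    u <- u_new; v <- v_new
    energy <- c(energy, hs_energy(u, v, d$ex, d$ey, d$et, alpha_eff))
    if (params$convergence_tol > 0 && upd < params$convergence_tol) break
  }
  fl <- flow_field(u, v)
  attr(fl, "energy") <- energy
  fl
}

#' Encode a flow field as a color image
#'
#' Direction maps to hue on a fixed color wheel (0 deg = rightward, angles
#' increase counter-clockwise on screen, i.e. upward motion is 90 deg) and
#' magnitude maps to saturation, clipped at `magnitude_scale`; value is held
#' at 1, so zero motion renders as white (achromatic). The mapping is
#' bijective up to the 8-bit quantization of the PNG representation and is
#' inverted by [color_to_flow()].
#'
#' @param field A [flow_field].
#' @param magnitude_scale Flow magnitude (px/frame-step) mapped to full
#'   saturation (> 0).
#' @return A `flow_color_image`: `H x W x 3` RGB array in `[0, 1]` with
#'   fields `width`, `height`, `magnitude_scale`.
#' @export
flow_to_color <- function(field, magnitude_scale = 2) {
  stopifnot(inherits(field, "flow_field"))
  if (magnitude_scale <= 0) stop("magnitude_scale must be > 0")
  mag <- sqrt(field$u^2 + field$v^2)
  # +v points down rows; negate so hue runs counter-clockwise on screen
  ang <- atan2(-field$v, field$u)
  hue <- (ang / (2 * pi)) %% 1
  sat <- pmin(mag / magnitude_scale, 1)
  cols <- grDevices::hsv(h = hue, s = sat, v = 1)
  rgbm <- grDevices::col2rgb(cols) / 255
  px <- array(0, c(field$height, field$width, 3))
  px[, , 1] <- rgbm[1, ]; px[, , 2] <- rgbm[2, ]; px[, , 3] <- rgbm[3, ]
  # quantize to 8 bits so in-memory images equal their PNG round-trip
  px <- round(px * 255) / 255
  structure(list(pixels = px, width = field$width, height = field$height,
                 magnitude_scale = magnitude_scale),
            class = "flow_color_image")
}

#' Decode a flow color image back to a flow field
#'
#' Inverse of [flow_to_color()] up to 8-bit quantization and magnitude
#' clipping.
#'
#' @param img A `flow_color_image`, or an `H x W x 3` array plus
#'   `magnitude_scale`.
#' @param magnitude_scale Required when `img` is a plain array.
#' @return A [flow_field].
#' @export
color_to_flow <- function(img, magnitude_scale = NULL) {
  if (inherits(img, "flow_color_image")) {
    px <- img$pixels; scale <- img$magnitude_scale
  } else {
    px <- img; scale <- magnitude_scale
    if (is.null(scale)) stop("magnitude_scale required for a plain array")
  }
  h <- dim(px)[1]; w <- dim(px)[2]
  hsvm <- grDevices::rgb2hsv(rbind(as.vector(px[, , 1]), as.vector(px[, , 2]),
                                   as.vector(px[, , 3])), maxColorValue = 1)
  ang <- hsvm["h", ] * 2 * pi
  mag <- hsvm["s", ] * scale
  u <- matrix(mag * cos(ang), h, w)
  v <- matrix(-mag * sin(ang), h, w)
  flow_field(u, v)
}

#' Compute flow-color images for a frame sequence
#'
#' Applies [compute_flow()] + [flow_to_color()] to each consecutive pair; the
#' result for pair (k-1, k) carries the later frame's timestamp.
#'
#' @param frames List of [frame_image] objects.
#' @param params A [flow_params].
#' @param magnitude_scale Passed to [flow_to_color()].
#' @return List of `flow_color_image` objects (length `length(frames) - 1`),
#'   each with a `timestamp` field.
#' @export
flow_color_sequence <- function(frames, params = flow_params(), magnitude_scale = 2) {
  if (length(frames) < 2) stop("need at least two frames")
  out <- vector("list", length(frames) - 1)
  for (k in 2:length(frames)) {
    fl <- compute_flow(frames[[k - 1]], frames[[k]], params)
    ci <- flow_to_color(fl, magnitude_scale)
    ci$timestamp <- frames[[k]]$timestamp
    out[[k - 1]] <- ci
  }
  out
}
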