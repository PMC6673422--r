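# Informative-frame filtering. Colonoscopy footage contains stretches that
# carry no usable visual content (motion blur, over-dark or over-bright
# screens, wash-out); these frames are removed before flow computation and
# direction classification. A frame is summarized by seven statistics --
# mean, variance, skewness, gray-level co-occurrence correlation and
# contrast, energy of Laplacian, energy of gradient -- and classified
# informative / non-informative by a support-vector machine.

GLCM_LEVELS <- 32L          # gray-level quantization for co-occurrence stats
GLCM_OFFSET <- c(0L, 1L)    # (row, col) displacement: horizontally adjacent

# Symmetric normalized gray-level co-occurrence matrix at the configured
# offset. Intensities in [0,1] are quantized to GLCM_LEVELS bins.
glcm_matrix <- function(px, levels = GLCM_LEVELS, offset = GLCM_OFFSET) {
  q <- pmin(floor(px * levels), levels - 1) + 1L   # 1..levels
  nr <- nrow(q); nc <- ncol(q)
  dr <- offset[1]; dc <- offset[2]
  r1 <- 1:(nr - dr); c1 <- 1:(nc - dc)
  a <- q[r1, c1, drop = FALSE]
  b <- q[r1 + dr, c1 + dc, drop = FALSE]
  counts <- matrix(0, levels, levels)
  tab <- table(factor(a, levels = 1:levels), factor(b, levels = 1:levels))
  counts <- counts + tab + t(tab)                   # symmetric counts
  counts / sum(counts)
}

glcm_stats <- function(P) {
  lv <- seq_len(nrow(P))
  pi_ <- rowSums(P)
  mu_i <- sum(lv * pi_)
  sd_i <- sqrt(sum((lv - mu_i)^2 * pi_))
  ii <- matrix(lv, nrow(P), ncol(P))
  jj <- t(ii)
  contrast <- sum(P * (ii - jj)^2)
  correlation <- if (sd_i > 0) sum(P * (ii - mu_i) * (jj - mu_i)) / sd_i^2 else 0
  list(contrast = contrast, correlation = correlation)
}

#' Compute the seven informative-frame features
#'
#' Over all pixels of a grayscale frame: intensity mean, variance and
#' skewness; correlation and contrast of the symmetric gray-level
#' co-occurrence matrix (32 levels, horizontally adjacent pixel pairs);
#' energy of the 4-neighbor Laplacian; and energy of the first-difference
#' gradient. The two energies are normalized per pixel so frame size does not
#' dominate. Skewness and correlation of a constant frame are 0 by
#' convention.
#'
#' @param frame A [frame_image] (RGB frames are converted to luminance) or a
#'   numeric matrix in `[0, 1]`.
#' @return Named numeric vector with elements `mean`, `variance`, `skewness`,
#'   `correlation`, `contrast`, `energy_of_laplacian`, `energy_of_gradient`.
#' @export
compute_features <- function(frame) {
  px <- if (inherits(frame, "frame_image")) rgb_to_gray(frame$pixels) else frame
  n <- length(px)
  m <- mean(px)
  v <- sum((px - m)^2) / n
  skew <- if (v > 0) (sum((px - m)^3) / n) / v^1.5 else 0
  g <- glcm_stats(glcm_matrix(px))
  lap <- shift_mat(px, -1, 0) + shift_mat(px, 1, 0) +
         shift_mat(px, 0, -1) + shift_mat(px, 0, 1) - 4 * px
  eol <- sum(lap^2) / n
  gx <- shift_mat(px, 0, 1) - px
  gy <- shift_mat(px, 1, 0) - px
  eog <- sum(gx^2 + gy^2) / n
  c(mean = m, variance = v, skewness = skew,
    correlation = g$correlation, contrast = g$contrast,
    energy_of_laplacian = eol, energy_of_gradient = eog)
}

#' Train the informative-frame SVM
#'
#' Standardizes the seven features, grid-searches RBF-kernel hyperparameters
#' (cost, gamma) by 5-fold cross-validation, and refits the best model on all
#' data. The returned model stores the normalization parameters so
#' classification is self-contained and deterministic.
#'
#' @param features Matrix or data frame of feature rows (columns as returned
#'   by [compute_features()]).
#' @param labels Logical (or 0/1) vector: `TRUE` = informative.
#' @param cost_grid,gamma_grid Hyperparameter candidates.
#' @param k Cross-validation folds.
#' @param seed Integer seed for the fold shuffle.
#' @return An `informative_model` with element `cv_accuracy` (best
#'   cross-validated accuracy).
#' @export
train_informative <- function(features, labels,
                              cost_grid = c(0.1, 1, 10, 100),
                              gamma_grid = c(0.01, 0.1, 1),
                              k = 5L, seed = 1L) {
  X <- as.matrix(features)
  y <- as.logical(labels)
  if (length(unique(y)) < 2) stop("training labels contain a single class")
  if (min(table(y)) < 2) stop("need at least 2 samples per class")
  mu <- colMeans(X)
  sdv <- apply(X, 2, stats::sd)
  sdv[sdv == 0] <- 1
  Xs <- scale(X, center = mu, scale = sdv)
  yf <- factor(y, levels = c(FALSE, TRUE))
  folds <- withr::with_seed(seed, make_folds(y, k))
  best <- list(acc = -1)
  for (cost in cost_grid) for (gamma in gamma_grid) {
    correct <- 0
    for (f in seq_len(k)) {
      tr <- folds != f
      fit <- e1071::svm(Xs[tr, , drop = FALSE], yf[tr], kernel = "radial",
                        cost = cost, gamma = gamma, scale = FALSE)
      pred <- stats::predict(fit, Xs[!tr, , drop = FALSE])
      correct <- correct + sum(pred == yf[!tr])
    }
    acc <- correct / length(y)
    if (acc > best$acc) best <- list(acc = acc, cost = cost, gamma = gamma)
  }
  fit <- e1071::svm(Xs, yf, kernel = "radial", cost = best$cost,
                    gamma = best$gamma, scale = FALSE)
  structure(list(svm = fit, center = mu, scale = sdv,
                 cost = best$cost, gamma = best$gamma,
                 cv_accuracy = best$acc, version = "1"),
            class = "informative_model")
}

# stratified fold assignment: shuffled within each class, folds 1..k
make_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- sample(which(y == cl))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

#' Classify a frame as informative or not
#'
#' @param frame A [frame_image], a feature vector, or a feature matrix.
#' @param model A trained `informative_model`.
#' @return Logical: `TRUE` if informative (vector if a matrix was given).
#' @export
classify_informative <- function(frame, model) {
  if (!inherits(model, "informative_model")) stop("model is not a trained informative_model")
  X <- if (inherits(frame, "frame_image")) matrix(compute_features(frame), nrow = 1)
       else if (is.null(dim(frame))) matrix(frame, nrow = 1)
       else as.matrix(frame)
  Xs <- scale(X, center = model$center, scale = model$scale)
  as.logical(stats::predict(model$svm, Xs) == "TRUE")
}
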