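#' Localised histograms of gradients
#'
#' Slides a square window over an x-gradient field and summarises each
#' window by an L1-normalised histogram of its p values over fixed,
#' symmetric bin edges. These per-window descriptors are the features
#' used to train and apply a meristem scorer on two-source gradient
#' maps, where only the x-gradient is available.
#'
#' Values outside `[-p_range, p_range]` are clamped into the end bins,
#' so every histogram sums to exactly 1.
#'
#' @param p x-gradient raster.
#' @param window_px window side in pixels (>= 4).
#' @param n_bins number of histogram bins (>= 4).
#' @param stride window step in pixels (default `window_px / 2`).
#' @param p_range half-width of the symmetric bin range (default 1).
#' @return a `gradient_histograms` object: `features` array
#'   (windows_down x windows_across x n_bins), window `centers_row` /
#'   `centers_col` (fractional pixels), bin `edges`, and the geometry
#'   parameters.
#' @export
gradient_histogram_features <- function(p, window_px, n_bins,
                                        stride = max(1L, window_px %/% 2L),
                                        p_range = 1) {
  .assert(.is_raster(p), "p must be a numeric matrix")
  .assert(window_px >= 4, "window_px must be >= 4")
  .assert(n_bins >= 4, "n_bins must be >= 4")
  .assert(stride >= 1, "stride must be >= 1")
  nr <- nrow(p); nc <- ncol(p)
  .assert(window_px <= nr && window_px <= nc,
          "window (%d px) larger than image (%d x %d)", window_px, nr, nc)
  r0 <- seq(1L, nr - window_px + 1L, by = stride)
  c0 <- seq(1L, nc - window_px + 1L, by = stride)
  edges <- seq(-p_range, p_range, length.out = n_bins + 1)
  feat <- array(0, c(length(r0), length(c0), n_bins))
  for (i in seq_along(r0)) {
    for (j in seq_along(c0)) {
      v <- p[r0[i]:(r0[i] + window_px - 1L), c0[j]:(c0[j] + window_px - 1L)]
      v <- pmin(pmax(v, -p_range), p_range)
      b <- pmin(pmax(findInterval(v, edges, rightmost.closed = TRUE), 1L),
                n_bins)
      feat[i, j, ] <- tabulate(b, n_bins) / length(v)
    }
  }
  structure(list(features = feat,
                 centers_row = r0 + (window_px - 1) / 2,
                 centers_col = c0 + (window_px - 1) / 2,
                 edges = edges, window_px = window_px, stride = stride,
                 n_bins = n_bins, p_range = p_range),
            class = "gradient_histograms")
}

#' Train a minimal linear window scorer
#'
#' Reference trainer for the pluggable window-scoring contract used by
#' [scan_meristem_classifier()]: a regularised linear discriminant
#' direction between meristem-window and background-window histogram
#' features. Any function mapping one feature vector to a scalar score
#' can replace it (the field system used an SVM; heavy ML frameworks
#' are deliberately out of scope here).
#'
#' @param pos matrix of positive (meristem) feature vectors, one per row.
#' @param neg matrix of negative (background) feature vectors.
#' @param lambda ridge regularisation added to the pooled covariance.
#' @return a scoring function `f(v) -> scalar` (class `window_scorer`);
#'   larger means more meristem-like.
#' @export
train_window_scorer <- function(pos, neg, lambda = 1e-3) {
  pos <- as.matrix(pos); neg <- as.matrix(neg)
  .assert(nrow(pos) >= 1 && nrow(neg) >= 1 && ncol(pos) == ncol(neg),
          "pos and neg must be non-empty matrices with equal columns")
  mu_p <- colMeans(pos); mu_n <- colMeans(neg)
  X <- rbind(sweep(pos, 2, mu_p), sweep(neg, 2, mu_n))
  S <- crossprod(X) / max(1, nrow(X) - 2) + diag(lambda, ncol(pos))
  w <- solve(S, mu_p - mu_n)
  b <- -sum(w * (mu_p + mu_n)) / 2
  f <- function(v) sum(w * v) + b
  class(f) <- c("window_scorer", class(f))
  attr(f, "w") <- w; attr(f, "b") <- b
  f
}

#' Scan a gradient map for meristem-like windows
#'
#' Applies a window scorer to localised gradient histograms over the
#' whole field, producing a match-strength heat map and the best
#' candidate (the arg-max window). Ties are broken by scan order:
#' the window with the smallest (row, col) wins.
#'
#' @param p x-gradient raster (e.g. from [two_source_gradient()]).
#' @param scorer function mapping one feature vector to a scalar score.
#' @param window_px window side in pixels.
#' @param n_bins,stride,p_range histogram geometry, as in
#'   [gradient_histogram_features()].
#' @return list with `heat` (raster upsampled to image size by
#'   nearest-window assignment, NA outside window coverage), `candidate`
#'   (one-row data.frame: row, col, score, method), and the per-window
#'   `scores` matrix.
#' @export
scan_meristem_classifier <- function(p, scorer, window_px, n_bins = 16,
                                     stride = max(1L, window_px %/% 2L),
                                     p_range = 1) {
  .assert(is.function(scorer), "scorer must be a function")
  gh <- gradient_histogram_features(p, window_px, n_bins, stride, p_range)
  nwr <- length(gh$centers_row); nwc <- length(gh$centers_col)
  scores <- matrix(NA_real_, nwr, nwc)
  for (i in seq_len(nwr))
    for (j in seq_len(nwc))
      scores[i, j] <- scorer(gh$features[i, j, ])
  # arg-max with documented scan-order tie-break (row-major)
  best <- which(scores == max(scores), arr.ind = TRUE)
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  candidate <- data.frame(row = gh$centers_row[best[1]],
                          col = gh$centers_col[best[2]],
                          score = scores[best[1], best[2]],
                          method = "gradient_hist")
  # nearest-window upsample to image size
  heat <- matrix(NA_real_, nrow(p), ncol(p))
  ridx <- pmin(pmax(round((seq_len(nrow(p)) - gh$centers_row[1]) / stride) + 1, 1), nwr)
  cidx <- pmin(pmax(round((seq_len(ncol(p)) - gh$centers_col[1]) / stride) + 1, 1), nwc)
  heat <- scores[ridx, cidx, drop = FALSE]
  list(heat = heat, candidate = candidate, scores = scores,
       centers_row = gh$centers_row, centers_col = gh$centers_col)
}
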