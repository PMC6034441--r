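#' Virtual sieve size of a tuber
#'
#' Side of the smallest square aperture through which the tuber's
#' minimal cross-section — modelled as the ellipse with diameters
#' (width, height), the two smaller ellipsoid axes — can pass. Grading
#' rigs sieve potatoes through square grids, and the major axis never
#' constrains passage, so only width and height enter the size grade.
#'
#' For aperture rotation theta, the rotated ellipse's axis-aligned
#' extents are `2 sqrt(A^2 cos^2 + B^2 sin^2)` and
#' `2 sqrt(A^2 sin^2 + B^2 cos^2)` (A = width/2, B = height/2); the
#' square must cover the larger of the two, and the sieve size is the
#' minimum of that requirement over rotation, found by 1-D numerical
#' minimisation.
#'
#' @param width ellipse major diameter, mm (tuber width, >= height).
#' @param height ellipse minor diameter, mm (> 0).
#' @return minimal square aperture side, mm. Vectorised over
#'   (width, height) pairs.
#' @export
#' @examples
#' sieve_size(60, 60)  # a circle needs a square of its own diameter
#' sieve_size(60, 40)
sieve_size <- function(width, height) {
  .assert(all(height > 0) && all(width >= height),
          "need width >= height > 0")
  one <- function(w, h) {
    A <- w / 2; B <- h / 2
    f <- function(th) {
      e1 <- 2 * sqrt(A^2 * cos(th)^2 + B^2 * sin(th)^2)
      e2 <- 2 * sqrt(A^2 * sin(th)^2 + B^2 * cos(th)^2)
      pmax(e1, e2)
    }
    optimize(f, c(0, pi / 2), tol = 1e-10)$objective
  }
  mapply(one, width, height)
}

#' Commercial size band of a sieve size
#'
#' Half-open binning `[lo, hi)` of sieve sizes into grading bands. The
#' default edges (45, 65, 80) give the four standard ranges `<45`,
#' `45-65`, `65-80` and `80+` mm; a value exactly on an edge falls in
#' the upper band.
#'
#' @param sieve sieve size(s), mm (> 0).
#' @param edges strictly increasing band edges, mm.
#' @param labels optional band labels (length = `length(edges) + 1`).
#' @return character vector of band labels.
#' @export
#' @examples
#' size_band(c(44.9, 45, 64.9, 65, 92))
size_band <- function(sieve, edges = c(45, 65, 80), labels = NULL) {
  .assert(all(sieve > 0), "sieve sizes must be positive")
  .assert(all(diff(edges) > 0), "band edges must be strictly increasing")
  if (is.null(labels)) labels <- band_labels(edges)
  .assert(length(labels) == length(edges) + 1,
          "need %d labels for %d edges", length(edges) + 1, length(edges))
  labels[findInterval(sieve, edges) + 1L]
}

#' Standard labels for a set of band edges
#'
#' @param edges strictly increasing band edges, mm.
#' @return character vector like `c("<45", "45-65", "65-80", "80+")`.
#' @export
band_labels <- function(edges = c(45, 65, 80)) {
  n <- length(edges)
  c(sprintf("<%g", edges[1]),
    if (n > 1) sprintf("%g-%g", edges[-n], edges[-1]),
    sprintf("%g+", edges[n]))
}
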