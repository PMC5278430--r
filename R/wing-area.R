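## Planform wing-area estimation from a top-down photograph: edge-preserving
## bilateral smoothing, two-class k-means++ binarisation, pixel-fraction area.

#' Two-class wing/background segmentation
#'
#' @slot mask binary matrix (wing = 1, background = 0)
#' @slot Nw wing pixel count
#' @slot N total pixel count
#' @export
setClass("SegmentationResult",
         representation(mask = "matrix", Nw = "numeric", N = "numeric"))

setValidity("SegmentationResult", function(object) {
  if (object@Nw != sum(object@mask)) return("Nw must equal the 1-pixels in mask")
  if (object@Nw > object@N) return("Nw must not exceed N")
  TRUE
})

#' Edge-preserving bilateral filter
#'
#' Gaussian smoothing whose weights combine spatial distance (sigma
#' `sigmaS`, pixels) and intensity difference (sigma `sigmaR`, intensity
#' units), so flat regions are denoised while step edges between wings and
#' background are preserved.
#'
#' @param img numeric intensity matrix
#' @param sigmaS spatial standard deviation (pixels)
#' @param sigmaR range standard deviation (intensity); default 10% of the
#'   image's intensity range
#' @return smoothed matrix of the same size
#' @export
bilateralFilter <- function(img, sigmaS = 3,
                            sigmaR = 0.1 * diff(range(img))) {
  stopifnot(is.matrix(img), length(img) > 0)
  if (sigmaR <= 0) sigmaR <- 1e-6
  half <- max(1L, ceiling(2 * sigmaS))
  nr <- nrow(img); nc <- ncol(img)
  num <- matrix(0, nr, nc); den <- matrix(0, nr, nc)
  shift <- function(m, dr, dc) {
    ## replicate-padded shift
    r <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
    c <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
    m[r, c, drop = FALSE]
  }
  for (dr in -half:half) for (dc in -half:half) {
    ws <- exp(-(dr^2 + dc^2) / (2 * sigmaS^2))
    sh <- shift(img, dr, dc)
    w <- ws * exp(-((sh - img)^2) / (2 * sigmaR^2))
    num <- num + w * sh
    den <- den + w
  }
  num / den
}

## k-means++ seeding on a numeric vector, then Lloyd iterations via
## stats::kmeans; nRestarts independent seedings, best inertia kept.
kmeansPlusPlus <- function(x, k = 2, nRestarts = 5, seed = 1L) {
  ux <- unique(x)
  if (length(ux) < k) stop("no contrast: fewer than ", k, " distinct intensities")
  best <- NULL
  withSeed(seed, {
    for (r in seq_len(nRestarts)) {
      centres <- numeric(k)
      centres[1] <- x[sample.int(length(x), 1)]
      for (j in 2:k) {
        d2 <- Reduce(pmin, lapply(centres[1:(j - 1)], function(cc) (x - cc)^2))
        if (all(d2 == 0)) centres[j] <- sample(ux, 1)
        else centres[j] <- x[sample.int(length(x), 1, prob = d2)]
      }
      centres <- sort(unique(centres))
      while (length(centres) < k) centres <- c(centres, max(x) + seq_len(k))
      fit <- suppressWarnings(stats::kmeans(x, centers = matrix(centres, ncol = 1)))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
  })
  best
}

#' Segment wings from background
#'
#' Bilateral smoothing followed by two-class k-means++ clustering of pixel
#' intensities; the cluster with the lower mean intensity is labelled wing
#' (dark wings on a white background) unless `wingsBright = TRUE`.
#' Deterministic for a fixed seed.
#'
#' @param image numeric intensity matrix (single channel; convert colour
#'   images with luminance weights 0.2126 R + 0.7152 G + 0.0722 B first)
#' @param sigmaS,sigmaR bilateral filter parameters, see [bilateralFilter()]
#' @param wingsBright set if the wings are brighter than the background
#' @param nRestarts k-means++ restarts; best within-cluster inertia kept
#' @param seed RNG seed for the k-means++ seeding
#' @return a [SegmentationResult-class]
#' @export
segmentWings <- function(image, sigmaS = 3, sigmaR = 0.1 * diff(range(image)),
                         wingsBright = FALSE, nRestarts = 5, seed = 1L) {
  stopifnot(is.matrix(image), length(image) > 0)
  if (diff(range(image)) == 0) stop("no contrast: image is constant")
  sm <- bilateralFilter(image, sigmaS, sigmaR)
  km <- kmeansPlusPlus(as.vector(sm), k = 2, nRestarts = nRestarts, seed = seed)
  wingCluster <- if (wingsBright) which.max(km$centers) else which.min(km$centers)
  mask <- matrix(as.integer(km$cluster == wingCluster),
                 nrow(image), ncol(image))
  new("SegmentationResult", mask = mask, Nw = sum(mask), N = length(mask))
}

#' Planform area from a segmentation
#'
#' Pixel-fraction estimate `Sw = (Nw / N) * Sb`, with `Sb` the known area of
#' the white background sheet.
#'
#' @param seg a [SegmentationResult-class]
#' @param Sb background reference area (m^2)
#' @return a [WingSetGeometry-class]
#' @export
estimateArea <- function(seg, Sb) {
  stopifnot(is(seg, "SegmentationResult"))
  if (Sb <= 0) stop("Sb must be positive")
  if (seg@N == 0) stop("empty segmentation")
  WingSetGeometry(Sw = seg@Nw / seg@N * Sb, Sb = Sb, Nw = seg@Nw, N = seg@N)
}
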