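#' Green-minus-red colour index of an RGB image
#'
#' Computes the per-pixel signed difference between the green and red
#' channels of an 8-bit RGB image. Positive values indicate green
#' (vegetation) dominance; the result is not clamped, so values span
#' \eqn{[-255, 255]}.
#'
#' @param image An RGB image: a numeric array of dimension
#'   \code{c(height, width, channels)} with integer channel values in
#'   \code{[0, 255]}. An alpha channel (4th channel), if present, is dropped.
#' @return An integer matrix (\code{height x width}) of G\eqn{-}R values.
#' @examples
#' img <- array(0L, c(2, 2, 3))
#' img[, , 2] <- 200L  # pure green
#' gr_index(img)
#' @seealso [segment_canopy()], [auto_threshold()], [canopy_cover()]
#' @export
gr_index <- function(image) {
  image <- validate_rgb(image)
  gr <- image[, , 2, drop = TRUE] - image[, , 1, drop = TRUE]
  storage.mode(gr) <- "integer"
  if (is.null(dim(gr))) dim(gr) <- dim(image)[1:2]
  gr
}

# Checks an array is an 8-bit RGB image; drops alpha; names the offending
# mode in errors so callers can diagnose grayscale/palette input.
validate_rgb <- function(image) {
  if (is.matrix(image) || (is.array(image) && length(dim(image)) == 2L))
    stop("expected an RGB image, got a single-channel (grayscale) image",
         call. = FALSE)
  if (!is.array(image) || length(dim(image)) != 3L)
    stop("expected an RGB image array of dimension height x width x channels",
         call. = FALSE)
  nc <- dim(image)[3]
  if (nc == 1L)
    stop("expected an RGB image, got a single-channel (grayscale) image",
         call. = FALSE)
  if (nc == 2L)
    stop("expected an RGB image, got a 2-channel (gray+alpha) image",
         call. = FALSE)
  if (nc == 4L) image <- image[, , 1:3, drop = FALSE]  # drop alpha
  if (dim(image)[3] != 3L)
    stop("expected an RGB image, got ", nc, " channels", call. = FALSE)
  if (anyNA(image) || min(image) < 0 || max(image) > 255)
    stop("channel values must lie in [0, 255]", call. = FALSE)
  image
}

#' Segment canopy from background by thresholding a G-R map
#'
#' A pixel is classified as canopy when its G\eqn{-}R value is strictly
#' greater than the threshold; boundary pixels are background. Canopy
#' cover (CC) is the fraction of canopy pixels among all pixels.
#'
#' @param gr An integer matrix of G\eqn{-}R values, as returned by
#'   [gr_index()].
#' @param threshold Integer threshold in \code{[-255, 255]}. Default 0
#'   (green dominance).
#' @return An object of class \code{"canopy_segmentation"}: a list with
#'   \code{mask} (logical matrix, \code{TRUE} = canopy), \code{threshold},
#'   \code{n_canopy}, \code{n_total} and \code{cc}.
#' @examples
#' gr <- matrix(c(-10L, 5L, 30L, 0L), 2, 2)
#' segment_canopy(gr, threshold = 0)
#' @export
segment_canopy <- function(gr, threshold = 0) {
  if (!is.matrix(gr) || !is.numeric(gr))
    stop("'gr' must be a numeric matrix of G-R values", call. = FALSE)
  if (length(threshold) != 1L || is.na(threshold) ||
      threshold < -255 || threshold > 255)
    stop("'threshold' must be a single value in [-255, 255]", call. = FALSE)
  mask <- gr > threshold
  n_canopy <- sum(mask)
  n_total <- length(mask)
  structure(
    list(mask = mask, threshold = threshold,
         n_canopy = n_canopy, n_total = n_total,
         cc = n_canopy / n_total),
    class = "canopy_segmentation")
}

#' @export
print.canopy_segmentation <- function(x, ...) {
  cat("Canopy segmentation\n")
  cat(sprintf("  image: %d x %d pixels\n", nrow(x$mask), ncol(x$mask)))
  cat(sprintf("  threshold (G-R): %d\n", as.integer(x$threshold)))
  cat(sprintf("  canopy pixels: %d / %d\n", x$n_canopy, x$n_total))
  cat(sprintf("  canopy cover: %.4f\n", x$cc))
  invisible(x)
}

#' Automatic G-R threshold by Otsu's criterion
#'
#' Selects the threshold maximizing the between-class variance of the
#' 511-bin G\eqn{-}R histogram over \eqn{[-255, 255]}, with pixels above the
#' threshold forming the foreground class (strict inequality, matching
#' [segment_canopy()]). Ties are broken toward the lower threshold. The
#' result is deterministic.
#'
#' @param gr An integer matrix of G\eqn{-}R values.
#' @return A single integer threshold in \code{[-255, 254]}.
#' @examples
#' gr <- matrix(rep(c(-80L, 120L), each = 50), 10, 10)
#' auto_threshold(gr)
#' @export
auto_threshold <- function(gr) {
  if (!is.matrix(gr) || !is.numeric(gr))
    stop("'gr' must be a numeric matrix of G-R values", call. = FALSE)
  v <- as.integer(gr)
  if (min(v) == max(v))
    stop("constant G-R map: no bimodality to exploit for thresholding",
         call. = FALSE)
  # histogram over the 511 possible values -255..255
  counts <- tabulate(v + 256L, nbins = 511L)
  n <- length(v)
  levels <- -255:255
  p <- counts / n
  omega0 <- cumsum(p)              # P(value <= t), t = -255..255
  mu_t <- cumsum(p * levels)
  mu_total <- mu_t[511L]
  # candidate thresholds t = -255..254 (index 1..510); background: value <= t
  w0 <- omega0[1:510]
  w1 <- 1 - w0
  m0t <- mu_t[1:510]
  valid <- w0 > 0 & w1 > 0
  sigma_b <- rep(-Inf, 510)
  sigma_b[valid] <- (mu_total * w0[valid] - m0t[valid])^2 /
    (w0[valid] * w1[valid])
  levels[which.max(sigma_b)]      # which.max keeps the first (lowest) tie
}

#' Read an image file as an 8-bit RGB array
#'
#' Reads a PNG or JPEG file (detected by file signature, not extension)
#' and returns an integer array of dimension \code{height x width x 3}
#' with values in \code{[0, 255]}. An alpha channel is dropped; grayscale
#' or palette images raise a format error.
#'
#' @param path Path to a readable PNG or JPEG file.
#' @return Integer array \code{c(height, width, 3)}.
#' @export
read_rgb_image <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("cannot read image file: ", path, call. = FALSE)
  sig <- readBin(path, "raw", n = 3L)
  img <- if (length(sig) >= 3L &&
             identical(sig[1:2], as.raw(c(0xff, 0xd8)))) {
    jpeg::readJPEG(path)
  } else if (length(sig) >= 3L &&
             identical(sig, as.raw(c(0x89, 0x50, 0x4e)))) {
    png::readPNG(path)
  } else {
    stop("not a PNG or JPEG file: ", path, call. = FALSE)
  }
  if (is.matrix(img))
    stop("expected an RGB image, got a single-channel (grayscale) image: ",
         path, call. = FALSE)
  img <- round(img * 255)
  storage.mode(img) <- "integer"
  validate_rgb(img)
}

#' Canopy cover from an image file
#'
#' Reads a nadir RGB canopy image, computes the G\eqn{-}R index, thresholds
#' it (fixed value or Otsu), and returns the segmentation with pixel counts
#' and canopy cover. The result is a pure pixel ratio, so it is independent
#' of image resolution for a scale-invariant scene.
#'
#' @param path Path to a PNG or JPEG image file.
#' @param threshold Either a single integer in \code{[-255, 255]} (fixed
#'   threshold; default 0) or the string \code{"auto"} for Otsu selection.
#' @return A \code{"canopy_segmentation"} object; the image path is recorded
#'   in its \code{path} element.
#' @examples
#' \dontrun{
#' seg <- canopy_cover("plot_001.jpg", threshold = "auto")
#' seg$cc
#' }
#' @export
canopy_cover <- function(path, threshold = 0) {
  img <- read_rgb_image(path)
  gr <- gr_index(img)
  thr <- if (identical(threshold, "auto")) auto_threshold(gr) else threshold
  seg <- segment_canopy(gr, thr)
  seg$path <- path
  seg
}

#' Batch canopy cover for a set of images
#'
#' Applies [canopy_cover()] to each file and, optionally, joins the results
#' to a plot-metadata table keyed by \code{image_path}.
#'
#' @param paths Character vector of image file paths, or a directory whose
#'   PNG/JPEG files are processed in sorted order.
#' @param meta Optional data frame with an \code{image_path} column plus
#'   plot identifiers (site, season, cultivar, n_rate_kg_ha, replicate,
#'   stage); joined by file name.
#' @param threshold Passed to [canopy_cover()].
#' @return A data frame with columns \code{image_path}, \code{threshold},
#'   \code{n_canopy}, \code{n_total}, \code{cc}, plus any metadata columns.
#' @export
canopy_cover_table <- function(paths, meta = NULL, threshold = 0) {
  if (length(paths) == 1L && dir.exists(paths))
    paths <- sort(list.files(paths, pattern = "\\.(png|jpe?g)$",
                             ignore.case = TRUE, full.names = TRUE))
  if (length(paths) == 0L)
    stop("no image files to process", call. = FALSE)
  rows <- lapply(paths, function(p) {
    seg <- canopy_cover(p, threshold = threshold)
    data.frame(image_path = p, threshold = seg$threshold,
               n_canopy = seg$n_canopy, n_total = seg$n_total,
               cc = seg$cc, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(meta)) {
    if (!"image_path" %in% names(meta))
      stop("'meta' must contain an 'image_path' column", call. = FALSE)
    meta <- as.data.frame(meta)
    out$.key <- basename(out$image_path)
    meta$.key <- basename(meta$image_path)
    meta$image_path <- NULL
    out <- merge(out, meta, by = ".key", all.x = TRUE, sort = FALSE)
    out$.key <- NULL
  }
  out
}
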