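# OCT volume container and TIFF round-trip I/O.
#
# A volume is stored as a 3-D array indexed [b-scan, a-scan, sample]:
# the first axis runs superior -> inferior across B-scans, the second
# temporal -> nasal across A-scans (for a right eye; left eyes are rendered
# mirrored), and the third is depth into the retina.

#' OCT volume
#'
#' Wraps a 3-D intensity array of shape `n_bscans x n_ascans x n_samples`
#' together with acquisition metadata. The default murine acquisition is 512
#' B-scans of 512 A-scans with 1024 depth samples each. Intensities must be
#' finite and non-negative; integer-valued intensities survive a
#' [write_volume()] / [read_volume()] round trip bit-exactly.
#'
#' @param intensities 3-D numeric array `[n_bscans, n_ascans, n_samples]`.
#' @param eye `"OS"` (left) or `"OD"` (right).
#' @param age_months Age at acquisition, months.
#' @param group Group label, e.g. `"WT"` or `"3xTg-AD"`.
#' @param animal_id Animal identifier.
#' @return An object of class `oct_volume`: a list with elements
#'   `intensities` and `meta`.
#' @examples
#' v <- oct_volume(array(0, c(2, 16, 32)), eye = "OD", age_months = 1)
#' dim(v$intensities)
#' @export
oct_volume <- function(intensities, eye = NA_character_,
                       age_months = NA_integer_, group = NA_character_,
                       animal_id = NA_character_) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L) {
    stop("`intensities` must be a 3-D array [n_bscans, n_ascans, n_samples]",
         call. = FALSE)
  }
  d <- dim(intensities)
  if (d[1] < 1L || d[2] < 16L || d[3] < 16L) {
    stop("volume too small: need >= 1 B-scan and >= 16 A-scans/samples",
         call. = FALSE)
  }
  if (!all(is.finite(intensities)) || any(intensities < 0)) {
    stop("intensities must be finite and non-negative", call. = FALSE)
  }
  if (!is.na(eye) && !eye %in% c("OS", "OD")) {
    stop('`eye` must be "OS" or "OD"', call. = FALSE)
  }
  structure(
    list(
      intensities = intensities,
      meta = list(eye = eye, age_months = age_months, group = group,
                  animal_id = as.character(animal_id))
    ),
    class = "oct_volume"
  )
}

#' @export
print.oct_volume <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf("<oct_volume> %d B-scans x %d A-scans x %d samples\n",
              d[1], d[2], d[3]))
  cat(sprintf("  eye: %s  age: %s mo  group: %s  animal: %s\n",
              x$meta$eye, x$meta$age_months, x$meta$group, x$meta$animal_id))
  invisible(x)
}

#' Axial sampling scale
#'
#' Converts axial sample indices to micrometres. The imaging depth of the
#' acquisition system is 1.4 mm over 1024 samples, i.e.
#' `1000 * 1.4 / 1024 = 1.3672` um per sample.
#'
#' @param depth_mm Imaging depth in millimetres.
#' @param n_samples Number of axial samples spanning that depth.
#' @return An object of class `axial_scale` with fields `depth_mm`,
#'   `n_samples`, `microns_per_sample`.
#' @examples
#' axial_scale()$microns_per_sample
#' @export
axial_scale <- function(depth_mm = 1.4, n_samples = 1024L) {
  stopifnot(depth_mm > 0, n_samples >= 1)
  structure(
    list(depth_mm = depth_mm, n_samples = as.integer(n_samples),
         microns_per_sample = 1000 * depth_mm / n_samples),
    class = "axial_scale"
  )
}

.meta_sidecar_path <- function(path) {
  if (dir.exists(path)) file.path(path, "meta.yaml") else paste0(path, ".yaml")
}

#' Read an OCT volume from TIFF files
#'
#' Reads either a directory of single-page grayscale TIFFs (one per B-scan,
#' stacked in lexicographic filename order, which defines the
#' superior-to-inferior axis) or one multi-page TIFF. Each page holds one
#' B-scan with depth samples as rows and A-scans as columns. Pixel values are
#' read as stored (integer for 8/16-bit files). A metadata sidecar
#' (`meta.yaml` in the directory, or `<file>.yaml` next to a multi-page
#' file) written by [write_volume()] is honoured when present.
#'
#' @param path Directory of `.tif`/`.tiff` files or a single multi-page TIFF.
#' @return An [oct_volume()].
#' @export
read_volume <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                             full.names = TRUE))
    if (length(files) == 0L) stop("no TIFF images found in ", path, call. = FALSE)
    pages <- lapply(files, function(f) tiff::readTIFF(f, as.is = TRUE))
  } else {
    if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (is.array(pages)) pages <- list(pages)
    if (length(pages) == 0L) stop("empty TIFF: ", path, call. = FALSE)
  }
  ok <- vapply(pages, function(p) is.matrix(p), logical(1))
  if (!all(ok)) stop("all pages must be single-channel grayscale images",
                     call. = FALSE)
  shapes <- vapply(pages, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1])) {
    stop("mixed B-scan shapes in ", path, call. = FALSE)
  }
  n_samples <- shapes[1, 1]
  n_ascans <- shapes[2, 1]
  arr <- array(0, c(length(pages), n_ascans, n_samples))
  for (b in seq_along(pages)) arr[b, , ] <- t(pages[[b]])
  meta <- list(eye = NA_character_, age_months = NA_integer_,
               group = NA_character_, animal_id = NA_character_)
  sidecar <- .meta_sidecar_path(path)
  if (file.exists(sidecar)) {
    m <- yaml::read_yaml(sidecar)
    meta[names(m)] <- m
  }
  oct_volume(arr, eye = meta$eye, age_months = meta$age_months,
             group = meta$group, animal_id = meta$animal_id)
}

#' Write an OCT volume as TIFF files
#'
#' Writes one grayscale TIFF page per B-scan (rows = depth samples,
#' columns = A-scans) plus a YAML metadata sidecar. Integer-valued
#' intensities within the bit depth are written verbatim and round-trip
#' bit-exactly through [read_volume()]; other non-negative values are
#' rescaled to the full integer range of `bits` and rounded.
#'
#' @param volume An [oct_volume()].
#' @param path Output directory (one file per B-scan, `bscan_0001.tif`, ...)
#'   or a `.tif`/`.tiff` filename for a multi-page file.
#' @param bits Bits per sample, 8 or 16.
#' @return `path`, invisibly.
#' @export
write_volume <- function(volume, path, bits = 16L) {
  stopifnot(inherits(volume, "oct_volume"), bits %in% c(8L, 16L))
  x <- volume$intensities
  maxint <- 2^bits - 1
  integral <- all(x == round(x)) && max(x) <= maxint
  if (!integral) {
    hi <- max(x)
    x <- if (hi > 0) round(x / hi * maxint) else x
  }
  # tiff::writeTIFF expects [0,1] floats; exact for integers / maxint
  x <- x / maxint
  d <- dim(x)
  pages <- lapply(seq_len(d[1]), function(b) t(matrix(x[b, , ], d[2], d[3])))
  as_dir <- !grepl("\\.tiff?$", path, ignore.case = TRUE)
  if (as_dir) {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (b in seq_along(pages)) {
      tiff::writeTIFF(pages[[b]],
                      file.path(path, sprintf("bscan_%04d.tif", b)),
                      bits.per.sample = bits, compression = "none")
    }
  } else {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none")
  }
  yaml::write_yaml(volume$meta, .meta_sidecar_path(path))
  invisible(path)
}
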