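# Imaging layer: read patch photographs, segment seedling foreground from
# the frame/soil background by colour range, and summarize foreground
# pixels into channel means.
#
# Images are H x W x 3 integer arrays (8-bit, 0-255), row-major with the
# origin at the top-left, 0-based in all serialized coordinates. The
# proprietary "colour range" selection of the original workflow is
# emulated by nearest-seed Euclidean thresholding in RGB space.

#' Construct a patch image
#'
#' @param pixels numeric H x W x 3 array of 8-bit channel values.
#' @param patchId identifier carried through to summaries and errors.
#' @param metadata optional list of capture descriptors (flash, frame
#'   colour, patch size class); stored as an attribute.
#' @return The integer array with class `"patch_image"`.
#' @export
patch_image <- function(pixels, patchId = "patch001", metadata = list()) {
  if (length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    hb_stop("pixels must be an H x W x 3 array", class = "hb_domain_error")
  if (anyNA(pixels) || any(pixels < 0) || any(pixels > 255))
    hb_stop("pixel values must lie in [0, 255]", class = "hb_domain_error")
  img <- array(as.integer(round(pixels)), dim = dim(pixels))
  attr(img, "patchId") <- as.character(patchId)
  attr(img, "metadata") <- metadata
  class(img) <- c("patch_image", class(img))
  img
}

#' Read one patch image from disk
#'
#' Supports 8-bit RGB PNG and plain-text P3 PPM (the latter is handy for
#' text-only fixtures). Greyscale or RGBA PNGs are rejected: the pipeline
#' is defined on 3-channel colour images.
#'
#' @param path file path ending in `.png` or `.ppm`.
#' @param patchId identifier; defaults to the file stem.
#' @return A [patch_image].
#' @export
read_patch_image <- function(path, patchId = NULL) {
  if (!file.exists(path))
    hb_stop("file not found: ", path, class = "hb_io_error")
  patchId <- patchId %||% sub("\\.[^.]+$", "", basename(path))
  ext <- tolower(sub(".*\\.", "", path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) != 3L || dim(a)[3] < 3L)
      hb_stop("not an RGB image: ", path, class = "hb_io_error")
    px <- round(a[, , 1:3] * 255)
  } else if (ext == "ppm") {
    px <- read_ppm(path)
  } else {
    hb_stop("unsupported image format: ", path, class = "hb_io_error")
  }
  patch_image(px, patchId = patchId)
}

# plain-text (P3) portable pixmap reader; enough for fixtures
#' @keywords internal
#' @noRd
read_ppm <- function(path) {
  toks <- scan(path, what = character(), quiet = TRUE,
               comment.char = "#")
  if (toks[1] != "P3")
    hb_stop("only plain-text P3 PPM supported: ", path,
            class = "hb_io_error")
  w <- as.integer(toks[2]); h <- as.integer(toks[3])
  maxval <- as.integer(toks[4])
  vals <- as.numeric(toks[-(1:4)]) * (255 / maxval)
  if (length(vals) != 3L * w * h)
    hb_stop("truncated PPM: ", path, class = "hb_io_error")
  # PPM is row-major, pixel-interleaved
  px <- array(NA_real_, c(h, w, 3))
  m <- matrix(vals, ncol = 3, byrow = TRUE)
  for (k in 1:3) px[, , k] <- matrix(m[, k], nrow = h, byrow = TRUE)
  px
}

#' Write a patch image (PNG or text PPM)
#' @param img a [patch_image] or H x W x 3 array.
#' @param path destination ending in `.png` or `.ppm`.
#' @return `path`, invisibly.
#' @export
write_patch_image <- function(img, path) {
  ext <- tolower(sub(".*\\.", "", path))
  a <- array(as.numeric(img), dim = dim(img))
  if (ext == "png") {
    png::writePNG(a / 255, path)
  } else if (ext == "ppm") {
    h <- dim(a)[1]; w <- dim(a)[2]
    m <- cbind(as.vector(t(a[, , 1])), as.vector(t(a[, , 2])),
               as.vector(t(a[, , 3])))
    writeLines(c("P3", paste(w, h), "255",
                 paste(apply(round(m), 1, paste, collapse = " "),
                       collapse = " ")), path)
  } else hb_stop("unsupported image format: ", path, class = "hb_io_error")
  invisible(path)
}

#' Load a batch of patch images from a manifest
#'
#' @param manifest either a directory containing `.png`/`.ppm` files or a
#'   `data.frame` with columns `path` and `patchId` (extra plate-map
#'   columns such as variety, tray, row, col, treatment, day are carried
#'   into each image's metadata).
#' @return A list with `images` (list of [patch_image]) and `errors`
#'   (`data.frame` of per-file failures: unreadable files are reported,
#'   not fatal). An empty manifest is an error.
#' @export
load_patch_images <- function(manifest) {
  if (is.character(manifest) && length(manifest) == 1L) {
    files <- list.files(manifest, pattern = "\\.(png|ppm)$",
                        full.names = TRUE, ignore.case = TRUE)
    if (length(files) == 0L)
      hb_stop("no images found in ", manifest, class = "hb_config_error")
    manifest <- data.frame(path = files,
                           patchId = sub("\\.[^.]+$", "", basename(files)),
                           stringsAsFactors = FALSE)
  }
  if (!is.data.frame(manifest) || nrow(manifest) == 0L)
    hb_stop("empty image manifest", class = "hb_config_error")
  if (!all(c("path", "patchId") %in% names(manifest)))
    hb_stop("manifest needs columns path, patchId",
            class = "hb_config_error")
  meta_cols <- setdiff(names(manifest), c("path", "patchId"))
  images <- list()
  errors <- data.frame(path = character(), patchId = character(),
                       message = character(), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch(
      read_patch_image(manifest$path[i], patchId = manifest$patchId[i]),
      error = function(e) e)
    if (inherits(res, "error")) {
      errors <- rbind(errors, data.frame(
        path = manifest$path[i], patchId = manifest$patchId[i],
        message = conditionMessage(res), stringsAsFactors = FALSE))
    } else {
      if (length(meta_cols))
        attr(res, "metadata") <- c(attr(res, "metadata"),
                                   as.list(manifest[i, meta_cols,
                                                    drop = FALSE]))
      images[[manifest$patchId[i]]] <- res
    }
  }
  list(images = images, errors = errors)
}

#' Default seed-colour palette for foreground selection
#'
#' Colours sampled along the damage gradient the screens produce: healthy
#' and aged leaf green, the yellow-green of early chlorosis, straw and
#' brown of dead whitebacked-planthopper kill, and the elevated-red,
#' elevated-blue tones of hopperburn. Dead seedlings must stay foreground
#' — dropping the senescent colours would bias indices toward survivors.
#'
#' @return Integer matrix with one seed colour per row (R, G, B).
#' @export
default_seed_palette <- function() {
  pal <- rbind(
    healthy      = c(62, 108, 48),
    aged         = c(76, 116, 58),
    chlorotic1   = c(85, 95, 66),
    chlorotic2   = c(97, 88, 75),
    straw        = c(108, 92, 85),
    wbph_kill    = c(102, 83, 98),
    bph_mid      = c(97, 88, 76),
    bph_late     = c(115, 78, 90),
    hopperburn   = c(132, 68, 103))
  colnames(pal) <- c("R", "G", "B")
  pal
}

#' Segment seedling foreground by colour range
#'
#' A pixel is foreground iff its minimum Euclidean distance in RGB space
#' to any seed colour is at most `threshold` — a deterministic, auditable
#' stand-in for interactive colour-range selection. An `hsb` mode measures
#' the distance in (hue/360-scaled, saturation, brightness) space instead.
#'
#' @param img a [patch_image].
#' @param seeds matrix of reference colours, one per row (0-255 RGB);
#'   defaults to [default_seed_palette()].
#' @param threshold positive selection radius in 0-255 RGB units
#'   (default 60; the original tool's fuzziness is unknown, this is a free
#'   parameter, not a reconstruction).
#' @param space `"rgb"` (default) or `"hsb"`; for `"hsb"` the threshold
#'   is interpreted on the 0-1 scale.
#' @param coverage_floor emit a warning when the foreground fraction falls
#'   below this (default 0.01).
#' @return Logical H x W matrix of class `"foreground_mask"` with a
#'   `coverage` attribute.
#' @export
segment_foreground <- function(img, seeds = default_seed_palette(),
                               threshold = 60, space = c("rgb", "hsb"),
                               coverage_floor = 0.01) {
  space <- match.arg(space)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    hb_stop("threshold must be > 0", class = "hb_config_error")
  seeds <- rbind(seeds)
  if (nrow(seeds) < 1L)
    hb_stop("need at least one seed colour", class = "hb_config_error")
  d <- dim(img)
  px <- cbind(as.vector(img[, , 1]), as.vector(img[, , 2]),
              as.vector(img[, , 3]))
  if (space == "hsb") {
    hsb <- rgb_to_hsb(px)
    px <- cbind(hsb$hue / 360, hsb$saturation, hsb$brightness)
    sh <- rgb_to_hsb(seeds)
    seeds <- cbind(sh$hue / 360, sh$saturation, sh$brightness)
  }
  d2min <- rep(Inf, nrow(px))
  for (i in seq_len(nrow(seeds))) {
    d2 <- (px[, 1] - seeds[i, 1])^2 + (px[, 2] - seeds[i, 2])^2 +
      (px[, 3] - seeds[i, 3])^2
    d2min <- pmin(d2min, d2)
  }
  mask <- matrix(d2min <= threshold^2, nrow = d[1], ncol = d[2])
  coverage <- mean(mask)
  if (coverage < coverage_floor)
    warning(sprintf("foreground coverage %.4f below floor %.4f for %s",
                    coverage, coverage_floor,
                    attr(img, "patchId") %||% "patch"), call. = FALSE)
  attr(mask, "coverage") <- coverage
  class(mask) <- c("foreground_mask", class(mask))
  mask
}

#' Summarize masked pixels into channel means
#'
#' Arithmetic mean of each channel over foreground pixels — the histogram
#' means the screening workflow records per patch.
#'
#' @param img a [patch_image].
#' @param mask logical matrix congruent with `img` (e.g. from
#'   [segment_foreground()]).
#' @return A one-row [channel_means] with `nPixels` = masked pixel count.
#' @export
summarize_patch <- function(img, mask) {
  d <- dim(img)
  if (!identical(dim(mask)[1:2], d[1:2]))
    hb_stop("mask dimensions do not match image", class = "hb_domain_error")
  n <- sum(mask)
  if (n < 1L)
    hb_stop("empty foreground mask for patch ",
            attr(img, "patchId") %||% "(unnamed)",
            class = "hb_degenerate_error")
  channel_means(mean(img[, , 1][mask]), mean(img[, , 2][mask]),
                mean(img[, , 3][mask]), nPixels = n,
                patchId = attr(img, "patchId") %||% "patch001")
}

#' Mean per-pixel index over a mask (sensitivity mode)
#'
#' The default pipeline is means-first: indices are computed from the
#' patch's mean colour. This helper computes the mean of the per-pixel
#' index instead, for sensitivity checks; outputs that use it should be
#' labelled `mode = "per-pixel"`.
#'
#' @inheritParams summarize_patch
#' @param name index name as in [compute_index()].
#' @param literal see [compute_index()].
#' @return Mean per-pixel index value (pixels with undefined index are
#'   dropped).
#' @export
per_pixel_index <- function(img, mask, name, literal = FALSE) {
  if (sum(mask) < 1L)
    hb_stop("empty foreground mask", class = "hb_degenerate_error")
  px <- cbind(img[, , 1][mask], img[, , 2][mask], img[, , 3][mask])
  mean(suppressWarnings(compute_index(name, px, literal = literal)),
       na.rm = TRUE)
}

#' Write a mask as an 8-bit PNG (0 background / 255 foreground)
#' @param mask logical matrix.
#' @param path destination `.png` path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(matrix(as.numeric(mask), nrow = nrow(mask)), path)
  invisible(path)
}
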