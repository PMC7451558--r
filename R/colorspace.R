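# Colour-space layer: per-patch channel means and their pure conversions.
#
# All conversions operate on proportions (value / 255); the raw 0-255 means
# are kept unchanged in the channel_means record. Ratio quantities (hue,
# saturation, normalized rgb) are unaffected by the rescaling; additive ones
# (chroma, brightness, TGI downstream) are reported on the 0-1 scale.

#' Per-patch mean channel intensities
#'
#' Construct a validated table of mean red, green and blue intensities on
#' the 0-255 histogram scale, one row per patch observation. This is the
#' fundamental record produced by image summarization and consumed by the
#' colour conversions and vegetation indices.
#'
#' @param meanR,meanG,meanB numeric vectors of mean channel intensity,
#'   each in `[0, 255]`.
#' @param nPixels integer vector, count of foreground pixels behind each
#'   mean (>= 1).
#' @param patchId optional character vector of patch identifiers.
#' @return A `data.frame` of class `"channel_means"` with columns
#'   `patchId`, `meanR`, `meanG`, `meanB`, `nPixels`.
#' @examples
#' channel_means(100, 150, 50)
#' @export
channel_means <- function(meanR, meanG, meanB, nPixels = 1L,
                          patchId = NULL) {
  n <- max(length(meanR), length(meanG), length(meanB))
  meanR <- rep_len(as.numeric(meanR), n)
  meanG <- rep_len(as.numeric(meanG), n)
  meanB <- rep_len(as.numeric(meanB), n)
  nPixels <- rep_len(as.integer(nPixels), n)
  if (is.null(patchId)) patchId <- sprintf("patch%03d", seq_len(n))
  patchId <- rep_len(as.character(patchId), n)
  vals <- c(meanR, meanG, meanB)
  if (anyNA(vals) || any(vals < 0) || any(vals > 255))
    hb_stop("channel means must lie in [0, 255]",
            class = "hb_domain_error")
  if (any(is.na(nPixels)) || any(nPixels < 1L))
    hb_stop("nPixels must be >= 1", class = "hb_domain_error")
  out <- data.frame(patchId = patchId, meanR = meanR, meanG = meanG,
                    meanB = meanB, nPixels = nPixels,
                    stringsAsFactors = FALSE)
  class(out) <- c("channel_means", "data.frame")
  out
}

# Coerce channel_means / data.frame with meanR-meanB columns / length-3
# vector / n x 3 matrix into an n x 3 numeric matrix plus ids.
#' @keywords internal
#' @noRd
cm_matrix <- function(x) {
  if (is.data.frame(x)) {
    need <- c("meanR", "meanG", "meanB")
    if (!all(need %in% names(x)))
      hb_stop("expected columns meanR, meanG, meanB",
              class = "hb_domain_error")
    m <- as.matrix(x[, need])
    ids <- if ("patchId" %in% names(x)) as.character(x$patchId)
           else sprintf("patch%03d", seq_len(nrow(m)))
  } else if (is.matrix(x)) {
    if (ncol(x) != 3L)
      hb_stop("channel matrix must have 3 columns", class = "hb_domain_error")
    m <- x
    ids <- rownames(x) %||% sprintf("patch%03d", seq_len(nrow(m)))
  } else if (is.numeric(x) && length(x) == 3L) {
    m <- matrix(x, nrow = 1L)
    ids <- "patch001"
  } else {
    hb_stop("cannot interpret input as channel means",
            class = "hb_domain_error")
  }
  colnames(m) <- c("R", "G", "B")
  if (anyNA(m) || any(m < 0) || any(m > 255))
    hb_stop("channel values must lie in [0, 255]", class = "hb_domain_error")
  list(m = m, ids = ids)
}

#' Normalized RGB (brightness ratios)
#'
#' Convert channel means to the brightness ratios r = R/(R+G+B),
#' g = G/(R+G+B), b = B/(R+G+B). The result is scale invariant: multiplying
#' all channels by a constant leaves it unchanged.
#'
#' @param x a [channel_means] table, a numeric length-3 vector, or an
#'   n x 3 matrix of 0-255 channel values.
#' @return A `data.frame` with columns `r`, `g`, `b`, each row summing
#'   to one.
#' @examples
#' normalize_rgb(c(100, 150, 50))
#' @export
normalize_rgb <- function(x) {
  cm <- cm_matrix(x)
  s <- unname(rowSums(cm$m))
  if (any(s <= 0)) {
    bad <- cm$ids[s <= 0]
    hb_stop("all-zero channel means (pure black) for patch(es): ",
            paste(bad, collapse = ", "), class = "hb_degenerate_error")
  }
  data.frame(r = unname(cm$m[, "R"]) / s, g = unname(cm$m[, "G"]) / s,
             b = unname(cm$m[, "B"]) / s)
}

#' Hue, saturation, brightness and chroma from channel means
#'
#' Channels are first divided by 255; brightness is the channel maximum,
#' chroma the max-min range, saturation chroma/max, and hue the standard
#' piecewise 60-degree formula keyed on which channel is largest, with
#' negative values wrapped into `[0, 360)`. Achromatic inputs (max = min)
#' have no defined hue; they are reported with hue 0 and saturation 0 and
#' flagged so downstream code can drop rather than misuse them.
#'
#' @inheritParams normalize_rgb
#' @return A `data.frame` with columns `hue` (degrees in `[0, 360)`),
#'   `saturation`, `brightness`, `chroma` (all fractions in `[0, 1]`) and
#'   logical `achromatic`.
#' @examples
#' rgb_to_hsb(c(255, 0, 0))   # hue 0, saturation 1, brightness 1
#' rgb_to_hsb(c(50, 100, 150))
#' @export
rgb_to_hsb <- function(x) {
  cm <- cm_matrix(x)
  p <- cm$m / 255
  R <- unname(p[, "R"]); G <- unname(p[, "G"]); B <- unname(p[, "B"])
  mx <- pmax(R, G, B)
  mn <- pmin(R, G, B)
  chroma <- mx - mn
  achromatic <- chroma == 0
  hue <- numeric(length(mx))
  # first-maximum tie-break in the order R, G, B (matches the usual
  # hexcone convention)
  isR <- !achromatic & mx == R
  isG <- !achromatic & !isR & mx == G
  isB <- !achromatic & !isR & !isG
  hue[isR] <- 60 * ((G[isR] - B[isR]) / chroma[isR])
  hue[isG] <- 60 * (2 + (B[isG] - R[isG]) / chroma[isG])
  hue[isB] <- 60 * (4 + (R[isB] - G[isB]) / chroma[isB])
  hue <- hue %% 360
  hue[achromatic] <- 0
  saturation <- ifelse(mx > 0, chroma / mx, 0)
  data.frame(hue = hue, saturation = saturation, brightness = mx,
             chroma = chroma, achromatic = achromatic)
}

#' Weighted luma of channel means
#'
#' Rec.601 luma, 0.299 R + 0.587 G + 0.114 B, on the 0-255 scale. Carried
#' as capture metadata only; no vegetation index consumes it.
#'
#' @inheritParams normalize_rgb
#' @return Numeric vector in `[0, 255]`.
#' @examples
#' luminosity(c(100, 150, 50))  # 123.65
#' @export
luminosity <- function(x) {
  cm <- cm_matrix(x)
  as.numeric(cm$m %*% c(0.299, 0.587, 0.114))
}
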