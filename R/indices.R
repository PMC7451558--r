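# Vegetation / colour indices computed from per-patch channel MEANS
# (means-first convention: the index of the mean colour, not the mean of
# per-pixel indices — matching a histogram-mean workflow).

hb_index_names <- c("gmr", "gdr", "ngrdi", "vari", "gli", "tgi", "dgci")

#' Compute one vegetation or colour index
#'
#' All indices are evaluated on channel proportions (mean / 255):
#' \describe{
#'   \item{gmr}{green minus red, `G - R`}
#'   \item{gdr}{green over red, `G / R`}
#'   \item{ngrdi}{`(G - R) / (G + R)`}
#'   \item{vari}{`(G - R) / (G + R - B)`}
#'   \item{gli}{`(2G - R - B) / (2G + R + B)`}
#'   \item{tgi}{`-0.5 * (190 (R - G) - 120 (R - B))`}
#'   \item{dgci}{`((H - 60)/60 + (1 - S) + (1 - V)) / 3` from
#'     hue-saturation-brightness}
#' }
#' Degenerate denominators (e.g. GDR at R = 0, VARI at G + R = B) and DGCI
#' on achromatic input yield `NA` with a warning, never an error: a
#' screening run must not abort on one black patch.
#'
#' Some published tabulations of GLI and TGI circulate with typographic
#' variants; `literal = TRUE` evaluates those variant strings
#' (`2 (G - R - B) / (2G + R + B)` and `-95 (R - G) - 120 (R - B)`) instead
#' of the canonical forms, for side-by-side auditing. Indices without a
#' parseable variant are unaffected by the flag.
#'
#' @param name index identifier, one of `"gmr"`, `"gdr"`, `"ngrdi"`,
#'   `"vari"`, `"gli"`, `"tgi"`, `"dgci"` (case-insensitive).
#' @inheritParams normalize_rgb
#' @param literal logical; evaluate the literal variant forms (see above).
#' @return Numeric vector, one value per row of `x`; `NA` where degenerate.
#' @examples
#' compute_index("gli", c(0, 255, 0))    # 1
#' compute_index("dgci", c(0, 255, 0))   # 1/3
#' @export
compute_index <- function(name, x, literal = FALSE) {
  name <- tolower(as.character(name))
  if (length(name) != 1L || !name %in% hb_index_names)
    hb_stop("unknown index name: ", name, " (expected one of ",
            paste(hb_index_names, collapse = ", "), ")",
            class = "hb_config_error")
  cm <- cm_matrix(x)
  p <- cm$m / 255
  R <- unname(p[, "R"]); G <- unname(p[, "G"]); B <- unname(p[, "B"])
  na_if_degenerate <- function(num, den, what) {
    bad <- den == 0
    if (any(bad)) {
      warning(sprintf("%s undefined (zero denominator) for patch(es): %s",
                      what, paste(cm$ids[bad], collapse = ", ")),
              call. = FALSE)
    }
    out <- rep(NA_real_, length(num))
    out[!bad] <- num[!bad] / den[!bad]
    out
  }
  switch(name,
    gmr = G - R,
    gdr = na_if_degenerate(G, R, "GDR"),
    ngrdi = na_if_degenerate(G - R, G + R, "NGRDI"),
    vari = na_if_degenerate(G - R, G + R - B, "VARI"),
    gli = if (literal) na_if_degenerate(2 * (G - R - B), 2 * G + R + B, "GLI")
          else na_if_degenerate(2 * G - R - B, 2 * G + R + B, "GLI"),
    tgi = if (literal) -0.5 * 190 * (R - G) - 120 * (R - B)
          else -0.5 * (190 * (R - G) - 120 * (R - B)),
    dgci = {
      hsb <- rgb_to_hsb(cm$m)
      out <- ((hsb$hue - 60) / 60 + (1 - hsb$saturation) +
                (1 - hsb$brightness)) / 3
      out[hsb$achromatic] <- NA_real_
      out
    })
}

#' Compute every index plus carried colour quantities for each patch
#'
#' One row per patch observation with all indices (from a single
#' hue-saturation-brightness conversion) and the carried colour
#' descriptors: normalized r, g, b; hue; saturation; brightness; chroma;
#' luminosity. `dgci` is `NA` for achromatic patches.
#'
#' @inheritParams compute_index
#' @return A `data.frame` with columns `patchId`, `gmr`, `gdr`, `ngrdi`,
#'   `vari`, `gli`, `tgi`, `dgci`, `r`, `g`, `b`, `hue`, `saturation`,
#'   `brightness`, `chroma`, `luminosity`.
#' @examples
#' compute_indices(channel_means(62, 108, 48))
#' @export
compute_indices <- function(x, literal = FALSE) {
  cm <- cm_matrix(x)
  idx <- lapply(setNames(hb_index_names, hb_index_names), function(nm)
    suppressWarnings(compute_index(nm, cm$m, literal = literal)))
  hsb <- rgb_to_hsb(cm$m)
  s <- rowSums(cm$m)
  norm <- data.frame(r = ifelse(s > 0, cm$m[, "R"] / s, NA_real_),
                     g = ifelse(s > 0, cm$m[, "G"] / s, NA_real_),
                     b = ifelse(s > 0, cm$m[, "B"] / s, NA_real_))
  cbind(data.frame(patchId = cm$ids, stringsAsFactors = FALSE),
        as.data.frame(idx), norm,
        hsb[, c("hue", "saturation", "brightness", "chroma")],
        data.frame(luminosity = luminosity(cm$m)))
}
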