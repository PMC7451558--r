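# internal helpers shared across modules

#' @keywords internal
#' @noRd
hb_stop <- function(..., class = "hb_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Deterministic 32-bit sub-seeds from one root seed, one per named stream,
# so that trajectory / render / damage / permutation randomness can be
# reproduced independently. Values stay below 2^31 - 1.
#' @keywords internal
#' @noRd
derive_seed <- function(root_seed, stream) {
  offsets <- c(trajectory = 1013904223, render = 1664525,
               damage = 22695477, perm = 69069, noise = 377003613,
               design = 134775813)
  if (!stream %in% names(offsets))
    hb_stop("unknown random substream: ", stream, class = "hb_config_error")
  ((as.double(root_seed) %% 2147483647) * 48271 + offsets[[stream]]) %%
    2147483647
}

# Polynomial rolling hash (mod 2^31 - 1) of a deparsed object, for
# provenance headers. Not cryptographic; only has to be stable.
#' @keywords internal
#' @noRd
config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "\n")
  bytes <- utf8ToInt(s)
  h <- 5381
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

# round-half-up at a given number of decimals (base round() is half-even)
#' @keywords internal
#' @noRd
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5 + 1e-9) / p
}

#' @keywords internal
#' @noRd
clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a
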