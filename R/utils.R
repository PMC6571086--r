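# internal helpers shared across modules

# deterministic per-measurement substream seed; stays below 2^31 so it is a
# valid set.seed() argument
substream_seed <- function(base_seed, sample_index, replicate) {
  (abs(base_seed) * 2654435 + sample_index * 97561 + replicate * 1013) %% 2147483647
}

# canonical text key for a concentration class, used in metadata and file names
class_key <- function(concentration_class) {
  sprintf("%.0e", concentration_class)
}

# polynomial rolling hash (mod 2^31 - 1) of a config serialised to JSON;
# cheap content digest for the run manifest
config_digest <- function(x) {
  s <- as.character(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                     null = "null", force = TRUE))
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# trapezoid weights for a (possibly non-uniform) grid restricted to a window;
# returns the index set and matching weights so frame-wise integrals can be
# computed as a single matrix product
trapz_weights <- function(wavelengths, window) {
  if (window[1] > window[2]) stop("window must be [lower, upper] with lower < upper")
  if (window[1] < min(wavelengths) || window[2] > max(wavelengths)) {
    stop("integration window [", window[1], ", ", window[2],
         "] lies outside the wavelength grid")
  }
  idx <- which(wavelengths >= window[1] & wavelengths <= window[2])
  if (length(idx) < 2) stop("integration window contains fewer than 2 grid points")
  wl <- wavelengths[idx]
  d <- diff(wl)
  w <- c(d / 2, 0) + c(0, d / 2)
  list(idx = idx, weights = w)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    stop(name, " must be a single positive finite number")
  }
  invisible(TRUE)
}
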