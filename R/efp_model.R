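# EFP weight models: a time-lag x frequency-band weight table that turns a
# binned time-frequency representation of one EEG segment into a single
# predicted BOLD value.  The published Amyg-EFP / VS-EFP weights are not
# public, so models are pluggable; a documented synthetic demo model ships
# with the package.

#' Construct an EFP weight model
#'
#' @param weights numeric matrix, `(segment_s / time_bin_s)` rows (time-lag
#'   bins, oldest first) by `nrow(band_edges)` columns (frequency bands).
#' @param intercept scalar added to the weighted sum.
#' @param segment_s EEG segment length in seconds (default 12).
#' @param time_bin_s temporal bin width in seconds (default 0.25).
#' @param band_edges two-column matrix of `[f_lo, f_hi)` band edges in Hz,
#'   ascending and non-overlapping (default: 10 log-spaced bands, 1-40 Hz).
#' @param derivation character vector `c(active, reference)` channel labels
#'   (default `c("Pz", "FCz")`).
#' @param name model label.
#' @return an object of class `EFPModel`.
#' @export
efp_model <- function(weights, intercept = 0, segment_s = 12,
                      time_bin_s = 0.25, band_edges = default_band_edges(),
                      derivation = c("Pz", "FCz"), name = "efp") {
  band_edges <- .check_band_edges(band_edges)
  n_t <- segment_s / time_bin_s
  if (abs(n_t - round(n_t)) > 1e-9) {
    stopf("segment_s (%g) must be an integer multiple of time_bin_s (%g)",
          segment_s, time_bin_s)
  }
  weights <- as.matrix(weights)
  if (!all(is.finite(weights))) stopf("model weights must all be finite")
  if (nrow(weights) != round(n_t) || ncol(weights) != nrow(band_edges)) {
    stopf("weights must be %d x %d (time-lag bins x bands), got %d x %d",
          round(n_t), nrow(band_edges), nrow(weights), ncol(weights))
  }
  if (!is_scalar_num(intercept)) stopf("intercept must be a finite scalar")
  structure(list(weights = weights, intercept = intercept,
                 segment_s = segment_s, time_bin_s = time_bin_s,
                 band_edges = band_edges,
                 derivation = as.character(derivation), name = name),
            class = "EFPModel")
}

.check_band_edges <- function(band_edges) {
  band_edges <- as.matrix(band_edges)
  if (ncol(band_edges) != 2L) stopf("band_edges must have two columns")
  if (any(band_edges[, 2] <= band_edges[, 1])) {
    stopf("each band must have f_hi > f_lo")
  }
  if (nrow(band_edges) > 1L &&
      any(band_edges[-1, 1] < band_edges[-nrow(band_edges), 2] - 1e-12)) {
    stopf("bands must be ascending and non-overlapping")
  }
  if (any(band_edges <= 0)) stopf("band edges must be positive frequencies")
  colnames(band_edges) <- c("f_lo", "f_hi")
  band_edges
}

#' Default frequency bands for EFP models
#'
#' The study reduces the frequency axis to 10 bands but does not publish
#' their edges; the package default is `n_bands` contiguous log-spaced
#' bands spanning `f_lo`-`f_hi` Hz, stored inside each model so results
#' are always read relative to a declared model.
#'
#' @param n_bands number of bands (default 10).
#' @param f_lo,f_hi overall span in Hz (defaults 1 and 40).
#' @return a two-column matrix of band edges.
#' @export
default_band_edges <- function(n_bands = 10, f_lo = 1, f_hi = 40) {
  e <- exp(seq(log(f_lo), log(f_hi), length.out = n_bands + 1))
  cbind(f_lo = e[-length(e)], f_hi = e[-1])
}

#' Synthetic demonstration EFP model
#'
#' A stand-in for the proprietary trained EFP weights: uniform positive
#' weights on every frequency band overlapping `carrier_band` (the band
#' whose power envelope tracks the latent drive in the synthetic cohort),
#' zero elsewhere, zero intercept.  Its output is the mean power in the
#' carrier band over the trailing segment, which is what a trained model
#' would recover on data whose target signal lives in that band.
#'
#' @param carrier_band `[f_lo, f_hi]` Hz band carrying signal (default 4-8).
#' @param band_edges frequency bands (default [default_band_edges()]).
#' @param segment_s,time_bin_s segment geometry (defaults 12 and 0.25 s).
#' @return an `EFPModel` named `"demo-synthetic"`.
#' @export
demo_efp_model <- function(carrier_band = c(4, 8),
                           band_edges = default_band_edges(),
                           segment_s = 12, time_bin_s = 0.25) {
  band_edges <- .check_band_edges(band_edges)
  active <- band_edges[, 1] < carrier_band[2] & band_edges[, 2] > carrier_band[1]
  if (!any(active)) stopf("no band overlaps the carrier band")
  n_t <- round(segment_s / time_bin_s)
  w <- matrix(0, n_t, nrow(band_edges))
  w[, active] <- 1 / (n_t * sum(active))
  efp_model(w, intercept = 0, segment_s = segment_s, time_bin_s = time_bin_s,
            band_edges = band_edges, name = "demo-synthetic")
}

#' Serialize / load an EFP model as JSON
#'
#' @param model an `EFPModel`.
#' @param path file path.
#' @return `write_efp_model` returns `path` invisibly; `read_efp_model`
#'   returns the `EFPModel`.
#' @export
write_efp_model <- function(model, path) {
  stopifnot(inherits(model, "EFPModel"))
  obj <- list(format = "efpcouple-model-v1",
              name = model$name,
              intercept = model$intercept,
              segment_s = model$segment_s,
              time_bin_s = model$time_bin_s,
              derivation = model$derivation,
              band_edges = unname(model$band_edges),
              weights = unname(model$weights))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_efp_model
#' @export
read_efp_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "efpcouple-model-v1") {
    stopf("'%s' is not an efpcouple model file (format tag missing/unknown)",
          path)
  }
  efp_model(weights = obj$weights, intercept = obj$intercept,
            segment_s = obj$segment_s, time_bin_s = obj$time_bin_s,
            band_edges = obj$band_edges, derivation = obj$derivation,
            name = obj$name)
}

#' @export
print.EFPModel <- function(x, ...) {
  cat(sprintf(
    "EFPModel '%s': %d lag bins x %d bands (%g s segment, %g s bins), %s-%s\n",
    x$name, nrow(x$weights), ncol(x$weights), x$segment_s, x$time_bin_s,
    x$derivation[1], x$derivation[2]))
  invisible(x)
}
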