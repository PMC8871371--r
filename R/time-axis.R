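#' TCSPC time axis
#'
#' A time axis describes the discretisation of the photon arrival-time
#' histogram: `n_bins` equal bins spanning a total measurement `window`
#' (one laser repetition period). The default matches common two-photon
#' TCSPC acquisition: 256 bins over a 12.5 ns window (80 MHz repetition),
#' i.e. ~48.8 ps per bin.
#'
#' @param n_bins Number of histogram time bins (integer, >= 8).
#' @param window Total measurement window in ns. Exactly one of `window`
#'   and `bin_width` must be given; the other is derived.
#' @param bin_width Width of one bin in ns.
#'
#' @return An object of class `time_axis`: a list with `n_bins`,
#'   `bin_width` (ns), `window` (ns) and `centers` (bin-centre times, ns).
#' @examples
#' ta <- time_axis()
#' ta$n_bins
#' ta$bin_width * ta$n_bins # == ta$window
#' @export
time_axis <- function(n_bins = 256L, window = 12.5, bin_width = NULL) {
  n_bins <- as.integer(n_bins)
  if (is.na(n_bins) || n_bins < 8L) {
    stop("`n_bins` must be an integer >= 8", call. = FALSE)
  }
  if (!is.null(bin_width)) {
    if (bin_width <= 0) stop("`bin_width` must be positive", call. = FALSE)
    window <- n_bins * bin_width
  } else {
    if (is.null(window) || window <= 0) {
      stop("`window` must be positive", call. = FALSE)
    }
    bin_width <- window / n_bins
  }
  stopifnot(abs(n_bins * bin_width - window) <= 1e-6 * window)
  structure(
    list(
      n_bins = n_bins,
      bin_width = bin_width,
      window = window,
      centers = (seq_len(n_bins) - 0.5) * bin_width
    ),
    class = "time_axis"
  )
}

#' @export
print.time_axis <- function(x, ...) {
  cat(sprintf(
    "<time_axis> %d bins x %.4f ns = %.4f ns window\n",
    x$n_bins, x$bin_width, x$window
  ))
  invisible(x)
}

is_time_axis <- function(x) inherits(x, "time_axis")

assert_time_axis <- function(x) {
  if (!is_time_axis(x)) stop("expected a `time_axis` object", call. = FALSE)
  invisible(x)
}
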