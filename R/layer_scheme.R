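#' Construct a layer scheme
#'
#' A layer scheme records the cumulative sizes of the nested layers of an
#' egocentric network, ordered from the innermost layer outward (e.g. the
#' canonical 5, 15, 50, 150, 500, 1500, 5000).  Each value counts all
#' alters up to and including that layer, so the sequence must be
#' strictly increasing and positive.
#'
#' @param cumulative_sizes numeric vector of strictly increasing positive
#'   cumulative layer sizes, innermost first.
#' @param label optional free-text label for the scheme.
#' @return an object of class `layer_scheme`.
#' @examples
#' sc <- layer_scheme(c(5, 15, 50, 150))
#' annuli(sc)
#' scaling_ratios(sc)
#' @seealso [dunbar_scheme()], [annuli()], [scaling_ratios()]
#' @export
layer_scheme <- function(cumulative_sizes, label = "") {
  cumulative_sizes <- as.numeric(cumulative_sizes)
  if (length(cumulative_sizes) < 1L || anyNA(cumulative_sizes) ||
      any(!is.finite(cumulative_sizes))) {
    stop("`cumulative_sizes` must be a non-empty vector of finite numbers",
         call. = FALSE)
  }
  if (any(cumulative_sizes <= 0)) {
    stop("cumulative layer sizes must be positive", call. = FALSE)
  }
  if (length(cumulative_sizes) > 1L && any(diff(cumulative_sizes) <= 0)) {
    stop("cumulative layer sizes must be strictly increasing (innermost first)",
         call. = FALSE)
  }
  structure(
    list(cumulative_sizes = cumulative_sizes, label = as.character(label)[1L]),
    class = "layer_scheme"
  )
}

#' The canonical layer scheme
#'
#' Cumulative layer sizes 5, 15, 50, 150, 500, 1500, 5000 — the default
#' nested structure of human egocentric networks, in which each layer is
#' approximately three times the size of the layer immediately inside it.
#'
#' @param n_layers number of layers to keep, from the innermost outward
#'   (default all 7).
#' @return a [layer_scheme()].
#' @export
dunbar_scheme <- function(n_layers = 7L) {
  sizes <- c(5, 15, 50, 150, 500, 1500, 5000)
  n_layers <- as.integer(n_layers)
  if (is.na(n_layers) || n_layers < 1L || n_layers > length(sizes)) {
    stop("`n_layers` must be between 1 and 7", call. = FALSE)
  }
  layer_scheme(sizes[seq_len(n_layers)], label = "canonical")
}

## coerce numeric vectors for convenience in the stat helpers
as_layer_scheme <- function(x) {
  if (inherits(x, "layer_scheme")) x else layer_scheme(x)
}

#' @export
print.layer_scheme <- function(x, ...) {
  cat("Layer scheme", if (nzchar(x$label)) paste0("(", x$label, ")"), "\n")
  cat("  cumulative sizes:", paste(x$cumulative_sizes, collapse = ", "), "\n")
  cat("  annuli:          ", paste(annuli(x), collapse = ", "), "\n")
  if (length(x$cumulative_sizes) > 1L) {
    cat("  mean scaling ratio:", format(mean_scaling_ratio(x), digits = 4), "\n")
  }
  invisible(x)
}

#' Annulus sizes of a layer scheme
#'
#' The *i*-th annulus holds the members of layer *i* excluding all inner
#' layers: element *i* is the difference between consecutive cumulative
#' sizes (the first annulus equals the innermost cumulative size).  The
#' annuli always sum back to the outermost cumulative size.
#'
#' @param scheme a [layer_scheme()] or numeric vector of cumulative sizes.
#' @return numeric vector of annulus sizes, same length as the scheme.
#' @examples
#' annuli(c(5, 15, 50, 150))  # 5 10 35 100
#' @export
annuli <- function(scheme) {
  scheme <- as_layer_scheme(scheme)
  diff(c(0, scheme$cumulative_sizes))
}

#' Successive scaling ratios of a layer scheme
#'
#' Ratio of each cumulative layer size to the one inside it; empirically
#' these cluster around 3 across human and animal grouping data.
#'
#' @inheritParams annuli
#' @return numeric vector of length `n_layers - 1`.
#' @examples
#' scaling_ratios(c(3, 9, 27))  # 3 3
#' @export
scaling_ratios <- function(scheme) {
  scheme <- as_layer_scheme(scheme)
  sizes <- scheme$cumulative_sizes
  if (length(sizes) < 2L) {
    stop("at least two layers are needed to form scaling ratios", call. = FALSE)
  }
  sizes[-1L] / sizes[-length(sizes)]
}

#' Mean scaling ratio
#'
#' Arithmetic mean of the successive [scaling_ratios()]; the summary
#' statistic reported for layered grouping data (about 3.0 for personal
#' networks, 3.11 for human community structure, 2.49 for multilevel
#' mammal societies and 2.23 for primate group sizes).
#'
#' @inheritParams annuli
#' @return a single number.
#' @export
mean_scaling_ratio <- function(scheme) {
  mean(scaling_ratios(scheme))
}
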