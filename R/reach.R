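#' Construct an annulus profile
#'
#' Inputs to the layered information-reach model: for each annulus of an
#' egocentric network, its member count `n_i`, the per-dyad probability
#' `c_i` of contacting any given member face-to-face (per unit time),
#' and the common prevalence `r_K` of the trait (innovation, piece of
#' information, infection) among community members.
#'
#' @param n_i members per annulus (nonnegative).
#' @param c_i per-dyad contact probability per annulus, each in \[0, 1\].
#' @param r_K trait prevalence in \[0, 1\] (default 0.01: 1% of the
#'   community seeded).
#' @return an object of class `annulus_profile`.
#' @seealso [reach()], [reach_curve()]
#' @export
annulus_profile <- function(n_i, c_i, r_K = 0.01) {
  n_i <- as.numeric(n_i); c_i <- as.numeric(c_i); r_K <- as.numeric(r_K)
  if (length(n_i) != length(c_i)) {
    stop("`n_i` and `c_i` must have the same length", call. = FALSE)
  }
  if (length(n_i) == 0L) stop("empty annulus profile", call. = FALSE)
  if (anyNA(c(n_i, c_i, r_K)) || any(!is.finite(c(n_i, c_i, r_K)))) {
    stop("profile entries must be finite", call. = FALSE)
  }
  if (any(n_i < 0)) stop("`n_i` must be nonnegative", call. = FALSE)
  if (any(c_i < 0 | c_i > 1)) stop("`c_i` must lie in [0, 1]", call. = FALSE)
  if (length(r_K) != 1L || r_K < 0 || r_K > 1) {
    stop("`r_K` must be a single probability", call. = FALSE)
  }
  structure(list(n_i = n_i, c_i = c_i, r_K = r_K),
            class = "annulus_profile")
}

#' Expected information reach out to a layer
#'
#' The layered-reach statistic: the expected number of trait-carrying
#' alters contacted, summed over annuli 1..`upto_layer`,
#' \deqn{P_i = \sum_{j=1}^{i} n_j \, r_K \, c_j.}
#' This is the model's literal additive form: it is an expected count,
#' linear (homogeneous of degree 1) in `r_K`, and may exceed 1.  For a
#' strict probability of hearing at least once, see
#' [reach_complement()].
#'
#' @param profile an [annulus_profile()].
#' @param upto_layer outermost layer included (default all).
#' @return a nonnegative number.
#' @examples
#' p <- annulus_profile(n_i = c(5, 10), c_i = c(0.5, 0.1), r_K = 0.01)
#' reach(p)  # 0.035
#' @export
reach <- function(profile, upto_layer = length(profile$n_i)) {
  stopifnot(inherits(profile, "annulus_profile"))
  i <- check_layer_index(profile, upto_layer)
  idx <- seq_len(i)
  sum(profile$n_i[idx] * profile$r_K * profile$c_i[idx])
}

#' Probability-of-hearing variant of the reach model
#'
#' Strict-probability counterpart of [reach()]: the chance that at
#' least one contacted alter carries the trait, treating dyads as
#' independent,
#' \deqn{1 - \prod_{j \le i} (1 - r_K c_j)^{n_j}.}
#' Always in \[0, 1\], never exceeds the additive reach, and agrees
#' with it to first order as \eqn{r_K c_j \to 0}.
#'
#' @inheritParams reach
#' @return a probability in \[0, 1\].
#' @export
reach_complement <- function(profile, upto_layer = length(profile$n_i)) {
  stopifnot(inherits(profile, "annulus_profile"))
  i <- check_layer_index(profile, upto_layer)
  idx <- seq_len(i)
  ## log1p for accuracy at small r_K * c
  -expm1(sum(profile$n_i[idx] * log1p(-profile$r_K * profile$c_i[idx])))
}

check_layer_index <- function(profile, upto_layer) {
  i <- as.integer(upto_layer)
  if (is.na(i) || i < 1L || i > length(profile$n_i)) {
    stop("`upto_layer` out of range 1..", length(profile$n_i), call. = FALSE)
  }
  i
}

#' Default per-dyad contact probabilities for a layer scheme
#'
#' Calibrates the contact-probability vector `c_i` of the reach model
#' from a social-effort profile: per-capita effort (share divided by
#' annulus size) is taken as proportional to per-dyad contact
#' probability and scaled so the innermost annulus has `c = 1`.  With
#' the default 40%/20% effort profile, per-capita contact decays
#' roughly 4-fold per layer.  This is a calibration choice, not an
#' observed quantity; pass your own `c_i` to [reach_curve()] to
#' override it.
#'
#' @param scheme a [layer_scheme()] or numeric cumulative sizes.
#' @param profile an [effort_profile()] over the scheme's annuli
#'   (default [default_effort_profile()]).
#' @return numeric vector of contact probabilities, one per annulus,
#'   with `c[1] == 1`.
#' @export
default_contact_probs <- function(scheme,
                                  profile = default_effort_profile(scheme)) {
  scheme <- as_layer_scheme(scheme)
  ann <- annuli(scheme)
  shares <- if (inherits(profile, "effort_profile")) {
    profile$annulus_shares
  } else {
    as.numeric(profile)
  }
  if (length(shares) != length(ann)) {
    stop("effort profile length does not match the scheme's annuli",
         call. = FALSE)
  }
  percap <- shares / ann
  percap / percap[1L]
}

#' Cumulative reach curve over community sizes
#'
#' Evaluates the layered reach model cumulatively, layer by layer, for
#' communities of different size (by default the scheme's own cumulative
#' layer sizes, e.g. 5, 15, 50, 150, 500, 1500, 5000).  Each requested
#' community size must coincide with a cumulative layer boundary.
#'
#' @param scheme a [layer_scheme()] or numeric cumulative sizes.
#' @param c_i per-dyad contact probabilities per annulus (default
#'   [default_contact_probs()]).
#' @param r_K trait prevalence (default 0.01).
#' @param community_sizes community sizes at which to evaluate
#'   (default: all cumulative layer sizes).
#' @return an object of class `reach_curve`: a data frame with columns
#'   `community_size`, `reach_literal` (additive expected count) and
#'   `reach_probability` (strict probability variant).
#' @examples
#' rc <- reach_curve(dunbar_scheme())
#' rc
#' inflection_point(rc)
#' @export
reach_curve <- function(scheme, c_i = default_contact_probs(scheme),
                        r_K = 0.01,
                        community_sizes = NULL) {
  scheme <- as_layer_scheme(scheme)
  sizes <- scheme$cumulative_sizes
  profile <- annulus_profile(annuli(scheme), c_i, r_K)
  if (is.null(community_sizes)) community_sizes <- sizes
  if (any(community_sizes < sizes[1L])) {
    stop("community size below the innermost layer (", sizes[1L], ")",
         call. = FALSE)
  }
  idx <- match(community_sizes, sizes)
  if (anyNA(idx)) {
    stop("community sizes must coincide with cumulative layer sizes; ",
         "offending: ",
         paste(community_sizes[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- data.frame(
    community_size = as.numeric(community_sizes),
    reach_literal = vapply(idx, function(i) reach(profile, i), 0),
    reach_probability = vapply(idx, function(i) reach_complement(profile, i), 0)
  )
  out <- out[order(out$community_size), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("reach_curve", "data.frame")
  out
}

#' 1/e inflection point of a saturating curve
#'
#' For a curve that saturates to an asymptote, the optimal community
#' size for information transmission is defined as the point where the
#' curve has closed all but 1/e of the gap between its baseline and its
#' asymptote: the smallest x with
#' \deqn{y \ge y_0 + (1 - e^{-1}) (A - y_0),}
#' where the asymptote A is estimated by the final curve value and the
#' baseline \eqn{y_0} defaults to the first.  Positions between samples
#' are linearly interpolated.  For the canonical exponential
#' \eqn{y = A(1 - e^{-x/\lambda})} with baseline 0, the criterion point
#' is exactly \eqn{x = \lambda}.  A curve that is still rising at its
#' end — final-segment slope above `tol` times the steepest segment
#' slope — has no usable asymptote and is rejected (a strictly linear
#' curve has relative end slope 1).
#'
#' @param curve a `reach_curve`, or a numeric vector `x` (with `y`).
#' @param ... passed to methods.
#' @return the interpolated x position (community size) of the 1/e
#'   point.
#' @export
inflection_point <- function(curve, ...) UseMethod("inflection_point")

#' @rdname inflection_point
#' @param value which reach column to use, `"literal"` (default) or
#'   `"probability"`.
#' @export
inflection_point.reach_curve <- function(curve,
                                         value = c("literal", "probability"),
                                         ...) {
  value <- match.arg(value)
  col <- paste0("reach_", value)
  inflection_point(curve$community_size, curve[[col]], ...)
}

#' @rdname inflection_point
#' @param y curve values at `curve` (when `curve` is a numeric x
#'   vector).
#' @param baseline baseline value \eqn{y_0}; default the first curve
#'   value.
#' @param tol saturation tolerance: maximal allowed ratio of the final
#'   segment's slope to the steepest segment slope (default 1e-3).
#' @export
inflection_point.default <- function(curve, y, baseline = NULL,
                                     tol = 1e-3, ...) {
  x <- as.numeric(curve)
  y <- as.numeric(y)
  if (length(x) != length(y) || length(x) < 3L) {
    stop("need matched x and y with at least 3 points", call. = FALSE)
  }
  if (is.unsorted(x, strictly = TRUE)) {
    stop("x must be strictly increasing", call. = FALSE)
  }
  asymptote <- y[length(y)]
  y0 <- if (is.null(baseline)) y[1L] else as.numeric(baseline)
  gap <- asymptote - y0
  if (gap <= 0) stop("curve does not rise above its baseline", call. = FALSE)
  slopes <- diff(y) / diff(x)
  end_slope <- slopes[length(slopes)]
  ref_slope <- max(slopes)
  if (ref_slope > 0 && end_slope / ref_slope > tol) {
    stop("curve has not saturated (relative end slope ",
         format(end_slope / ref_slope, digits = 3), " > tol ", tol,
         "): no asymptote", call. = FALSE)
  }
  target <- y0 + (1 - exp(-1)) * gap
  above <- which(y >= target)
  if (!length(above)) stop("curve never attains the 1/e level", call. = FALSE)
  j <- above[1L]
  if (j == 1L) return(x[1L])
  x[j - 1L] + (target - y[j - 1L]) / (y[j] - y[j - 1L]) * (x[j] - x[j - 1L])
}

#' Optimal community size for information transmission
#'
#' Maps the interpolated [inflection_point()] of a reach curve to the
#' nearest layer boundary on the log scale (layer sizes are
#' geometrically spaced, so distances are compared in log community
#' size).  With the canonical scheme and default contact calibration
#' this lands on the 50-layer.
#'
#' @param curve a `reach_curve`.
#' @param ... passed to [inflection_point()].
#' @return a single layer-boundary community size.
#' @export
optimal_community_size <- function(curve, ...) {
  stopifnot(inherits(curve, "reach_curve"))
  xi <- inflection_point(curve, ...)
  sizes <- curve$community_size
  sizes[which.min(abs(log(sizes) - log(xi)))]
}
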