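#' Construct a layer-allocation (urn) model
#'
#' One-parameter Bayesian urn model of how an individual distributes a
#' limited budget of social effort over relationship layers.  Each of
#' the `L` relationships is assigned independently to layer `k` with
#' probability proportional to \eqn{e^{-\mu s_k}}, where `s_k` is the
#' cost (time investment) of a relationship in layer `k` and \eqn{\mu}
#' is the Lagrange multiplier enforcing the total-resource constraint.
#' Conditionally on the network size `L`, the layer occupancy vector is
#' multinomial; the prior factor over `L` itself (a function of `L`,
#' `L/N`, `N`) is never evaluated — all operations condition on `L`.
#' The total resource `S` enters only through \eqn{\mu} and is recorded
#' for bookkeeping.
#'
#' @param costs per-relationship cost `s_k` of each layer, `k = 1..r`
#'   (finite reals; empirically cost declines from the inner layers
#'   outward).
#' @param mu Lagrange multiplier \eqn{\mu}.  \eqn{\mu > 0} gives
#'   conventional networks, \eqn{\mu < 0} inverted ones; the phase
#'   transition sits exactly at \eqn{\mu = 0}.
#' @param L total network size (nonnegative integer), if occupancy-level
#'   quantities are wanted.
#' @param N community (population) size, `N >= L`, informational.
#' @param S total resource budget, informational.
#' @return an object of class `allocation_model`.
#' @examples
#' m <- allocation_model(costs = c(4, 3, 2, 1), mu = 0.5, L = 150)
#' layer_probs(m)
#' expected_occupancy(m)
#' classify_shape(m)
#' @export
allocation_model <- function(costs, mu, L = NULL, N = NULL, S = NULL) {
  costs <- as.numeric(costs)
  if (length(costs) < 1L || anyNA(costs) || any(!is.finite(costs))) {
    stop("`costs` must be a non-empty vector of finite values", call. = FALSE)
  }
  mu <- as.numeric(mu)
  if (length(mu) != 1L || !is.finite(mu)) {
    stop("`mu` must be a single finite number", call. = FALSE)
  }
  if (!is.null(L)) {
    L <- as.integer(L)
    if (is.na(L) || L < 0L) stop("`L` must be a nonnegative integer",
                                 call. = FALSE)
  }
  if (!is.null(N) && !is.null(L) && N < L) {
    stop("population size `N` must be at least the network size `L`",
         call. = FALSE)
  }
  structure(list(costs = costs, mu = mu, L = L, N = N, S = S),
            class = "allocation_model")
}

#' Layer membership probabilities
#'
#' \eqn{p_k = e^{-\mu s_k} / \sum_j e^{-\mu s_j}}, computed in log
#' space with a max-shifted exponent so large \eqn{|\mu s_k|} cannot
#' overflow.  At \eqn{\mu = 0} the distribution is uniform; the
#' ordering of the \eqn{p_k} follows the cost ordering for
#' \eqn{\mu > 0} (cheaper layers more probable) and reverses for
#' \eqn{\mu < 0}.
#'
#' @param model an [allocation_model()].
#' @return probability vector over layers, summing to 1.
#' @export
layer_probs <- function(model) {
  stopifnot(inherits(model, "allocation_model"))
  z <- -model$mu * model$costs
  z <- z - max(z)
  exp(z) / sum(exp(z))
}

#' Probability of a layer occupancy vector
#'
#' Conditional-on-`L` probability mass of an occupancy vector
#' \eqn{\ell} with \eqn{\sum_k \ell_k = L}: the multinomial
#' \eqn{\binom{L}{\ell} \prod_k p_k^{\ell_k}} with \eqn{p} from
#' [layer_probs()], evaluated in log space via `lgamma`.
#'
#' @param model an [allocation_model()].
#' @param occupancy integer vector \eqn{\ell}, one entry per layer,
#'   summing to `model$L` (or to any L if `model$L` is `NULL`).
#' @param log return the log probability?
#' @return the (log) probability.
#' @examples
#' m <- allocation_model(c(1, 2), mu = 0, L = 2)
#' allocation_pmf(m, c(1, 1))  # 0.5
#' @export
allocation_pmf <- function(model, occupancy, log = FALSE) {
  stopifnot(inherits(model, "allocation_model"))
  occupancy <- as.numeric(occupancy)
  if (length(occupancy) != length(model$costs)) {
    stop("`occupancy` must have one entry per layer", call. = FALSE)
  }
  if (any(occupancy < 0) || any(occupancy != round(occupancy))) {
    stop("`occupancy` must be nonnegative integers", call. = FALSE)
  }
  L <- sum(occupancy)
  if (!is.null(model$L) && L != model$L) {
    stop("occupancy sums to ", L, " but the model has L = ", model$L,
         call. = FALSE)
  }
  if (L == 0) return(if (log) 0 else 1)
  lp <- log(layer_probs(model))
  ll <- lgamma(L + 1) - sum(lgamma(occupancy + 1)) +
    sum(ifelse(occupancy > 0, occupancy * lp, 0))
  if (log) ll else exp(ll)
}

#' Expected layer occupancies
#'
#' \eqn{\bar\ell_k = L p_k}: the mean number of the `L` network members
#' allocated to each layer.
#'
#' @param model an [allocation_model()] with `L` set.
#' @return numeric vector of expected occupancies.
#' @export
expected_occupancy <- function(model) {
  stopifnot(inherits(model, "allocation_model"))
  if (is.null(model$L)) stop("model has no network size `L`", call. = FALSE)
  model$L * layer_probs(model)
}

#' Classify the shape of the allocation curve
#'
#' Shape of the cumulative proportional occupancy curve (cumulative
#' \eqn{\sum_{j \le k} p_j} against layer rank `k`): its second
#' differences are \eqn{p_{k+1} - p_k}, so the curve is *convex* when
#' the occupancies increase with rank, *concave* when they decrease,
#' and *degenerate* (linear) when they are uniform.  For any strictly
#' monotone cost schedule the classification flips exactly at
#' \eqn{\mu = 0}: with costs declining outward (the empirical pattern —
#' inner ties cost more time), \eqn{\mu > 0} gives a convex curve, the
#' conventional few-close-ties/many-weak-ties network, and
#' \eqn{\mu < 0} gives a concave curve, the inverted network observed
#' e.g. in migrant communities with few social opportunities.
#'
#' @param model an [allocation_model()] with at least 3 layers and
#'   strictly monotone costs.
#' @param tol tolerance on second differences for the degenerate label.
#' @return `"concave"`, `"convex"` or `"degenerate"`.
#' @seealso [network_regime()]
#' @export
classify_shape <- function(model, tol = 1e-12) {
  stopifnot(inherits(model, "allocation_model"))
  s <- model$costs
  if (length(s) < 3L) stop("shape needs at least 3 layers", call. = FALSE)
  ds <- diff(s)
  if (!(all(ds > 0) || all(ds < 0))) {
    stop("`costs` must be strictly monotone to classify network shape",
         call. = FALSE)
  }
  p <- layer_probs(model)
  second <- diff(p)  # second differences of cumsum(p)
  if (all(abs(second) <= tol)) return("degenerate")
  if (all(second >= -tol)) return("convex")
  if (all(second <= tol)) return("concave")
  ## cannot happen for monotone costs: p is monotone in k
  stop("occupancy curve is neither convex nor concave", call. = FALSE)
}

#' Conventional or inverted network regime
#'
#' Labels the allocation by where the weight sits: `"conventional"`
#' when outer (cheaper-by-convention) layers hold more members than
#' inner ones — few close ties, many weak ones — and `"inverted"` when
#' the inner layers dominate.  Orientation is taken from the cost
#' schedule: the innermost layer is the costliest end.
#'
#' @inheritParams classify_shape
#' @return `"conventional"`, `"inverted"` or `"uniform"`.
#' @export
network_regime <- function(model, tol = 1e-12) {
  stopifnot(inherits(model, "allocation_model"))
  s <- model$costs
  if (length(s) < 2L) stop("regime needs at least 2 layers", call. = FALSE)
  ds <- diff(s)
  if (!(all(ds > 0) || all(ds < 0))) {
    stop("`costs` must be strictly monotone", call. = FALSE)
  }
  ## rank layers from the costly (inner) end outward
  p <- layer_probs(model)
  if (all(ds > 0)) p <- rev(p)  # make index 1 = costliest = innermost
  if (all(abs(diff(p)) <= tol)) return("uniform")
  if (all(diff(p) >= -tol)) return("conventional")  # grows outward
  if (all(diff(p) <= tol)) return("inverted")
  stop("occupancy is not monotone across layers", call. = FALSE)
}
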