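#' Optimal 1-D partition (Jenks natural breaks / exact 1-D k-means)
#'
#' Partitions scalar values into `k` contiguous classes minimising the
#' total within-class sum of squared deviations, by dynamic programming
#' over the sorted values.  The optimum of this contiguous-partition
#' problem is also the global optimum of 1-D k-means (an optimal k-means
#' solution is always contiguous in sorted order), so a single exact
#' routine serves both the "Jenks"/"natural breaks" and "k-means"
#' labels used across layer-detection studies.  Complexity O(k n^2);
#' deterministic, globally optimal.
#'
#' @param values numeric vector of finite values (any order; ties are
#'   kept in stable sorted order and identical values are never split
#'   across classes unless forced by `k > #distinct`).
#' @param k number of classes, `1 <= k <= length(values)`.
#' @return an object of class `layer_fit` with elements:
#'   \describe{
#'     \item{k}{number of classes.}
#'     \item{assignment}{class index (1 = lowest values) per element of
#'       `sort(values)`.}
#'     \item{breaks}{`k - 1` thresholds on the value scale (midpoints
#'       between adjacent class extremes).}
#'     \item{class_sizes}{elements per class, ascending value order.}
#'     \item{within_class_ssd}{total within-class sum of squared
#'       deviations of the returned partition.}
#'     \item{values}{the sorted input.}
#'   }
#' @examples
#' optimal_breaks(c(1, 2, 3, 10, 11, 12, 100, 101), k = 3)
#' @seealso [select_num_layers()], [detect_layers()]
#' @export
optimal_breaks <- function(values, k) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("`values` is empty", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite and non-missing", call. = FALSE)
  }
  k <- as.integer(k)
  n <- length(values)
  if (is.na(k) || k < 1L) stop("`k` must be a positive integer", call. = FALSE)
  if (k > n) stop("`k` (", k, ") exceeds the number of values (", n, ")",
                  call. = FALSE)
  x <- sort(values)
  dp <- jenks_dp(x, k)
  part <- jenks_backtrack(dp, k)
  build_layer_fit(x, part, dp$D[k, n])
}

## DP tables for all class counts 1..kmax on sorted x.
## D[k, j] = minimal SSD of x[1..j] split into k contiguous classes;
## B[k, j] = start index of the last class in that optimum (smallest
## optimal start, which keeps ties co-clustered as far as possible).
jenks_dp <- function(x, kmax) {
  n <- length(x)
  x <- x - mean(x)  # SSD is shift invariant; centring conditions the sums
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x * x))
  cost <- function(i, j) {  # SSD of class x[i..j], vectorised over i
    s <- cs[j + 1L] - cs[i]
    s2 <- cs2[j + 1L] - cs2[i]
    pmax(s2 - s * s / (j - i + 1L), 0)
  }
  D <- matrix(Inf, kmax, n)
  B <- matrix(1L, kmax, n)
  D[1L, ] <- cost(1L, seq_len(n))
  if (kmax > 1L) {
    for (k in 2L:kmax) {
      for (j in k:n) {
        starts <- k:j
        cand <- D[k - 1L, starts - 1L] + cost(starts, j)
        m <- which.min(cand)   # first minimum -> smallest start
        D[k, j] <- cand[m]
        B[k, j] <- starts[m]
      }
    }
  }
  list(D = D, B = B, x = x)
}

## class assignment (1 = lowest) for the optimal k-partition
jenks_backtrack <- function(dp, k) {
  n <- length(dp$x)
  ends <- integer(k)
  j <- n
  for (kk in k:1) {
    ends[kk] <- j
    j <- dp$B[kk, j] - 1L
  }
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  rep(seq_len(k), ends - starts + 1L)
}

build_layer_fit <- function(x, assignment, ssd,
                            selection_scores = NULL, k_candidates = NULL) {
  k <- max(assignment)
  sizes <- tabulate(assignment, nbins = k)
  breaks <- if (k > 1L) {
    uppers <- x[cumsum(sizes)[-k]]
    lowers <- x[cumsum(sizes)[-k] + 1L]
    (uppers + lowers) / 2
  } else {
    numeric(0)
  }
  structure(
    list(k = k, assignment = assignment, breaks = breaks,
         class_sizes = sizes, within_class_ssd = ssd, values = x,
         selection_scores = selection_scores, k_candidates = k_candidates),
    class = "layer_fit"
  )
}

#' @export
print.layer_fit <- function(x, ...) {
  cat("Optimal 1-D partition: k =", x$k, "classes over", length(x$values),
      "values\n")
  cat("  class sizes (ascending value):",
      paste(x$class_sizes, collapse = ", "), "\n")
  if (length(x$breaks)) {
    cat("  breaks:", paste(format(x$breaks, digits = 4), collapse = ", "), "\n")
  }
  cat("  within-class SSD:", format(x$within_class_ssd, digits = 6), "\n")
  if (!is.null(x$cumulative_sizes)) {
    cat("  cumulative layer sizes (inner->outer):",
        paste(x$cumulative_sizes, collapse = ", "), "\n")
    if (!is.null(x$mean_scaling_ratio) && !is.na(x$mean_scaling_ratio)) {
      cat("  mean scaling ratio:",
          format(x$mean_scaling_ratio, digits = 4), "\n")
    }
  }
  invisible(x)
}

## mean silhouette width of a 1-D partition; O(n^2), agrees with
## cluster::silhouette on |x_i - x_j| distances. Singletons score 0.
mean_silhouette_1d <- function(x, cl) {
  n <- length(x)
  k <- max(cl)
  if (k < 2L) stop("silhouette needs at least two classes", call. = FALSE)
  d <- abs(outer(x, x, "-"))
  sizes <- tabulate(cl, nbins = k)
  ## mean distance from each point to each class
  md <- vapply(seq_len(k), function(g) rowSums(d[, cl == g, drop = FALSE]),
               numeric(n))
  md <- sweep(md, 2L, sizes, "/")
  s <- numeric(n)
  for (i in seq_len(n)) {
    g <- cl[i]
    if (sizes[g] == 1L) { s[i] <- 0; next }
    a <- (md[i, g] * sizes[g]) / (sizes[g] - 1L)  # exclude self
    b <- min(md[i, -g])
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Select the number of layers
#'
#' Chooses the layer count by maximising the mean silhouette width of
#' the optimal contiguous partition, computed by default on log10-scale
#' values (contact rates are multiplicative: layers are equally spaced
#' in log rate, not in rate).  Ties break toward the smaller `k`.  If
#' all values are identical, silhouette is undefined and `1` is
#' returned with a warning.
#'
#' @param values numeric vector of positive values (rates) — or any
#'   reals when `transform = "identity"`.
#' @param k_range candidate class counts (default `2:8`).
#' @param transform `"log10"` (default) or `"identity"`.
#' @return the selected `k` (integer), with the per-candidate mean
#'   silhouette widths attached as attribute `"scores"`.
#' @examples
#' select_num_layers(c(rep(1, 10), rep(100, 10)))  # 2
#' @export
select_num_layers <- function(values, k_range = 2:8,
                              transform = c("log10", "identity")) {
  transform <- match.arg(transform)
  values <- as.numeric(values)
  if (anyNA(values) || any(!is.finite(values))) {
    stop("`values` must be finite and non-missing", call. = FALSE)
  }
  if (transform == "log10") {
    if (any(values <= 0)) {
      stop("log10 transform requires strictly positive values", call. = FALSE)
    }
    values <- log10(values)
  }
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2L)) stop("`k_range` must be >= 2", call. = FALSE)
  n <- length(values)
  if (n < max(k_range)) {
    stop("need at least ", max(k_range), " values for k_range up to ",
         max(k_range), call. = FALSE)
  }
  if (length(unique(values)) == 1L) {
    warning("all values identical; returning a single layer")
    return(structure(1L, scores = NULL))
  }
  x <- sort(values)
  dp <- jenks_dp(x, max(k_range))
  scores <- vapply(k_range, function(k) {
    mean_silhouette_1d(x, jenks_backtrack(dp, k))
  }, 0)
  best <- k_range[which.max(scores)]  # which.max: first max -> smallest k
  structure(as.integer(best), scores = stats::setNames(scores, k_range))
}

#' Detect layers in an egocentric contact table
#'
#' End-to-end layer detection for one ego: selects the number of layers
#' by silhouette ([select_num_layers()]), computes the optimal partition
#' of the contact rates ([optimal_breaks()]), and reports cumulative
#' layer sizes ordered from the highest-contact-rate (innermost) layer
#' outward, together with the mean scaling ratio of those cumulative
#' sizes.
#'
#' @param table a contact table: data frame with columns `alter_id` and
#'   `contact_rate_per_day` (or `contact_rate`), one row per alter —
#'   e.g. from [gen_ego_contacts()] or [load_contacts()]; a bare numeric
#'   vector of rates is also accepted.
#' @param k_range candidate layer counts (default `2:8`, capped at the
#'   number of alters).
#' @param transform rate transform for layer-count selection, `"log10"`
#'   (default) or `"identity"`.
#' @return a `layer_fit` (see [optimal_breaks()]) with additional
#'   elements `cumulative_sizes` (inner layer outward),
#'   `mean_scaling_ratio` (`NA` for a single layer) and `transform`.
#'   `breaks` are reported on the original rate scale (back-transformed
#'   when clustering was done on log10 rates); `values` and
#'   `within_class_ssd` are on the clustering scale.
#' @examples
#' tab <- gen_ego_contacts(seed = 1, log10_noise_sd = 0.1)
#' detect_layers(tab)
#' @export
detect_layers <- function(table, k_range = 2:8,
                          transform = c("log10", "identity")) {
  transform <- match.arg(transform)
  rates <- contact_rates(table)
  n <- length(rates)
  if (n < 4L) stop("need at least 4 alters to detect layers", call. = FALSE)
  k_range <- k_range[k_range <= n]
  if (length(unique(rates)) == 1L) {
    ## degenerate: a single undifferentiated layer
    fit <- optimal_breaks(rates, 1L)
    fit$cumulative_sizes <- n
    fit$mean_scaling_ratio <- NA_real_
    warning("all contact rates identical; returning a single layer")
    return(fit)
  }
  k <- select_num_layers(rates, k_range = k_range, transform = transform)
  ## partition on the same scale used for selection (rates are
  ## multiplicative, so layers are contiguous in log rate)
  v <- if (transform == "log10") log10(rates) else rates
  fit <- optimal_breaks(v, as.integer(k))
  if (transform == "log10") fit$breaks <- 10^fit$breaks  # back to rate scale
  fit$transform <- transform
  fit$selection_scores <- attr(k, "scores")
  fit$k_candidates <- as.integer(names(attr(k, "scores")))
  ## classes are in ascending rate order; innermost layer = highest rates
  fit$cumulative_sizes <- cumsum(rev(fit$class_sizes))
  fit$mean_scaling_ratio <- if (fit$k > 1L) {
    mean_scaling_ratio(fit$cumulative_sizes)
  } else {
    NA_real_
  }
  fit
}

## accept a contact data frame or a bare rate vector
contact_rates <- function(table) {
  if (is.numeric(table)) {
    rates <- as.numeric(table)
  } else if (is.data.frame(table)) {
    col <- intersect(c("contact_rate_per_day", "contact_rate"), names(table))
    if (!length(col)) {
      stop("contact table needs a `contact_rate_per_day` column",
           call. = FALSE)
    }
    rates <- as.numeric(table[[col[1L]]])
    if ("alter_id" %in% names(table) && anyDuplicated(table$alter_id)) {
      stop("duplicated alter_id in contact table", call. = FALSE)
    }
  } else {
    stop("`table` must be a data frame or numeric vector", call. = FALSE)
  }
  if (length(rates) == 0L) stop("empty contact table", call. = FALSE)
  if (anyNA(rates) || any(!is.finite(rates))) {
    stop("contact rates must be finite and non-missing", call. = FALSE)
  }
  if (any(rates <= 0)) stop("contact rates must be positive", call. = FALSE)
  rates
}
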