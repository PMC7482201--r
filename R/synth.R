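#' Generate a synthetic egocentric contact table
#'
#' Emulates the layered contact-rate structure of real egocentric
#' networks: each layer's alters share a base contact rate that decays
#' geometrically from the innermost layer outward (factor
#' `layer_rate_ratio` per layer, mirroring the ~3-fold layer scaling),
#' multiplied by log-normal noise with the given log10 standard
#' deviation.  Deterministic under a fixed seed.
#'
#' @param cumulative_sizes cumulative layer sizes of the true structure
#'   (default `c(5, 15, 50, 150)`: the four layers found in personal
#'   networks).
#' @param rate_innermost base contact rate (events/day) of the
#'   innermost layer (default 1: near-daily contact).
#' @param layer_rate_ratio per-layer decay factor of the base rate,
#'   `>= 1` (default 3).
#' @param log10_noise_sd standard deviation of the log10-normal
#'   multiplicative noise (default 0.3).
#' @param ego_id identifier for the ego column (default `"ego1"`).
#' @param seed optional integer seed.
#' @return a data frame with columns `ego_id`, `alter_id`,
#'   `contact_rate_per_day` and `true_layer` (1 = innermost).
#' @examples
#' tab <- gen_ego_contacts(seed = 42)
#' nrow(tab)  # 150
#' @seealso [detect_layers()]
#' @export
gen_ego_contacts <- function(cumulative_sizes = c(5, 15, 50, 150),
                             rate_innermost = 1,
                             layer_rate_ratio = 3,
                             log10_noise_sd = 0.3,
                             ego_id = "ego1",
                             seed = NULL) {
  scheme <- layer_scheme(cumulative_sizes)
  if (any(annuli(scheme) != round(annuli(scheme)))) {
    stop("cumulative sizes must yield integer annuli", call. = FALSE)
  }
  if (rate_innermost <= 0) stop("`rate_innermost` must be positive",
                                call. = FALSE)
  if (layer_rate_ratio < 1) stop("`layer_rate_ratio` must be >= 1",
                                 call. = FALSE)
  if (log10_noise_sd < 0) stop("`log10_noise_sd` must be nonnegative",
                               call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ann <- as.integer(annuli(scheme))
  layer <- rep(seq_along(ann), ann)
  base <- rate_innermost / layer_rate_ratio^(layer - 1)
  noise <- 10^stats::rnorm(length(layer), mean = 0, sd = log10_noise_sd)
  data.frame(
    ego_id = ego_id,
    alter_id = sprintf("alter%03d", seq_along(layer)),
    contact_rate_per_day = base * noise,
    true_layer = layer,
    stringsAsFactors = FALSE
  )
}

#' Generate a small weighted community graph
#'
#' Builds a connected, symmetric, weighted community graph in which
#' every node has the same nested ego-layer structure: nodes are placed
#' on a ring and each node's nearest ring neighbours fill its layers
#' from the inside out.  A cumulative layer size `L` corresponds to the
#' `L - 1` nearest neighbours (the group of `L` includes ego), i.e.
#' ring distance up to `floor((L - 1) / 2)` on each side.  Edge weights
#' are the per-capita effort shares of the tie's layer, so the weight
#' profile follows the supplied effort profile; weights are symmetric
#' because a pair's ring distance is.  The ring construction guarantees
#' connectivity.
#'
#' @param n number of nodes (default 150); must be at least the
#'   innermost layer size.
#' @param scheme cumulative layer sizes (default `c(5, 15, 50, 150)`,
#'   truncated to layers smaller than `n`).
#' @param tie_weight_profile an [effort_profile()] over the scheme's
#'   annuli (default [default_effort_profile()]).
#' @param seed unused at present (the construction is deterministic);
#'   accepted for interface stability.
#' @return a data frame of undirected edges with columns `source`,
#'   `target` (1-based node ids, `source < target`) and `weight`.
#' @examples
#' g <- gen_community_graph(n = 15, scheme = c(5, 15))
#' nrow(g)  # 15 * 14 / 2: every pair connected, two weight levels
#' @export
gen_community_graph <- function(n = 150, scheme = c(5, 15, 50, 150),
                                tie_weight_profile = NULL,
                                seed = NULL) {
  n <- as.integer(n)
  scheme <- as_layer_scheme(scheme)
  sizes <- scheme$cumulative_sizes
  if (n < sizes[1L]) {
    stop("`n` must be at least the innermost layer size (", sizes[1L], ")",
         call. = FALSE)
  }
  ## keep the layers that fit in the community
  sizes <- sizes[sizes <= n]
  scheme <- layer_scheme(sizes)
  if (is.null(tie_weight_profile)) {
    tie_weight_profile <- default_effort_profile(scheme)
  }
  shares <- tie_weight_profile$annulus_shares
  if (length(shares) != length(sizes)) {
    stop("tie weight profile length must match the number of layers",
         call. = FALSE)
  }
  percap <- shares / annuli(scheme)
  ## ring distance d belongs to the innermost layer whose half-width
  ## floor((L-1)/2) covers it
  half <- pmin(floor((sizes - 1) / 2), floor((n - 1) / 2))
  dmax <- max(half, 1)  # ring distance >= 1 keeps the graph connected
  edges <- list()
  for (d in seq_len(dmax)) {
    lay <- which(half >= d)[1L]
    if (is.na(lay)) lay <- length(sizes)
    i <- seq_len(n)
    j <- ((i + d - 1L) %% n) + 1L  # dmax < n/2, so each pair appears once
    edges[[d]] <- data.frame(source = pmin(i, j),
                             target = pmax(i, j),
                             weight = percap[lay])
  }
  out <- do.call(rbind, edges)
  out <- out[order(out$source, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}
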