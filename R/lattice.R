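#' Configuration of the lattice transmission model
#'
#' Agents sit on the nodes of a `width` x `height` lattice wrapped on a
#' torus (no edges) and carry one of two cultural variants (wild or
#' mutant).  Each interacts only with its eight closest neighbours,
#' split into two classes: the four orthogonally adjacent nodes
#' ("friends", direct contacts) and the four diagonal nodes
#' ("friends-of-friends", reachable only through the direct ones).  The
#' default 100 x 100 torus holds 10,000 agents; the mutant variant is
#' seeded at a single node (frequency 1e-4).
#'
#' @param width,height lattice dimensions; each at least 3 so the two
#'   neighbour classes are distinct (default 100 x 100).
#' @param n_parents number of cultural parents sampled per agent in the
#'   mean-field variant (default 8, matching the lattice neighbourhood).
#' @param max_generations generation cap after which a run is censored
#'   (default 500).
#' @param seed_count number of initially mutant nodes (default 1).
#' @return an object of class `lattice_config`.
#' @seealso [run_lattice()], [run_mean_field()], [run_ensemble()]
#' @export
lattice_config <- function(width = 100L, height = 100L, n_parents = 8L,
                           max_generations = 500L, seed_count = 1L) {
  width <- as.integer(width); height <- as.integer(height)
  if (anyNA(c(width, height)) || width < 3L || height < 3L) {
    stop("lattice must be at least 3x3: smaller tori collapse the ",
         "friend and friend-of-friend classes", call. = FALSE)
  }
  n_parents <- as.integer(n_parents)
  if (is.na(n_parents) || n_parents < 1L) {
    stop("`n_parents` must be a positive integer", call. = FALSE)
  }
  max_generations <- as.integer(max_generations)
  if (is.na(max_generations) || max_generations < 1L) {
    stop("`max_generations` must be a positive integer", call. = FALSE)
  }
  seed_count <- as.integer(seed_count)
  n <- width * height
  if (is.na(seed_count) || seed_count < 1L || seed_count > n) {
    stop("`seed_count` must be between 1 and the number of agents (", n, ")",
         call. = FALSE)
  }
  structure(list(width = width, height = height, n_agents = n,
                 n_parents = n_parents, max_generations = max_generations,
                 seed_count = seed_count),
            class = "lattice_config")
}

#' Cultural-inheritance bias vector
#'
#' Three-element vector of inheritance biases: the probability that an
#' agent retains its own variant (`b_self`), copies one of its four
#' direct neighbours (`b_direct`) or copies one of its four indirect
#' neighbours (`b_indirect`).  The three must sum to 1 (tolerance
#' 1e-12).
#'
#' @param b_self,b_direct,b_indirect probabilities summing to 1.
#' @return an object of class `bias_vector`.
#' @export
bias_vector <- function(b_self, b_direct, b_indirect) {
  b <- c(b_self, b_direct, b_indirect)
  if (length(b) != 3L || anyNA(b) || any(b < 0) || any(b > 1)) {
    stop("bias components must be probabilities", call. = FALSE)
  }
  if (abs(sum(b) - 1) > 1e-12) {
    stop("bias components must sum to 1 (tolerance 1e-12); got ",
         format(sum(b), digits = 15), call. = FALSE)
  }
  structure(list(b_self = b[1L], b_direct = b[2L], b_indirect = b[3L]),
            class = "bias_vector")
}

as_bias_vector <- function(b) {
  if (inherits(b, "bias_vector")) return(b)
  if (is.numeric(b) && length(b) == 3L) return(bias_vector(b[1], b[2], b[3]))
  stop("bias must be a bias_vector or numeric triple", call. = FALSE)
}

#' Neighbour classes of a lattice cell
#'
#' Torus-wrapped Moore neighbourhood of cell `(x, y)`, split into the
#' four orthogonal (direct, "friends") and four diagonal (indirect,
#' "friends-of-friends") neighbours.  All eight cells are distinct on
#' any lattice of at least 3 x 3.
#'
#' @param config a [lattice_config()].
#' @param x,y 1-based cell coordinates (`1 <= x <= width`).
#' @return a list with `direct` and `indirect`, each a 4 x 2 matrix of
#'   `(x, y)` coordinates.
#' @examples
#' nb <- lattice_neighbours(lattice_config(100, 100), 1, 1)
#' nb$indirect  # wraps to (100, 100) etc.
#' @export
lattice_neighbours <- function(config, x, y) {
  stopifnot(inherits(config, "lattice_config"))
  x <- as.integer(x); y <- as.integer(y)
  if (is.na(x) || is.na(y) || x < 1L || x > config$width ||
      y < 1L || y > config$height) {
    stop("coordinates off the lattice", call. = FALSE)
  }
  wrap <- function(v, m) ((v - 1L) %% m) + 1L
  dxy_direct <- rbind(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))
  dxy_indirect <- rbind(c(-1L, -1L), c(-1L, 1L), c(1L, -1L), c(1L, 1L))
  mk <- function(d) {
    cbind(x = wrap(x + d[, 1L], config$width),
          y = wrap(y + d[, 2L], config$height))
  }
  list(direct = mk(dxy_direct), indirect = mk(dxy_indirect))
}

## linear-index neighbour tables for the whole lattice: n x 4 integer
## matrices (column-major linear indices, x = row, y = column)
neighbour_index <- function(config) {
  w <- config$width; h <- config$height
  xs <- rep(seq_len(w), times = h)
  ys <- rep(seq_len(h), each = w)
  wrap <- function(v, m) ((v - 1L) %% m) + 1L
  lin <- function(x, y) (y - 1L) * w + x
  shift <- function(dx, dy) lin(wrap(xs + dx, w), wrap(ys + dy, h))
  list(
    direct = cbind(shift(-1L, 0L), shift(1L, 0L),
                   shift(0L, -1L), shift(0L, 1L)),
    indirect = cbind(shift(-1L, -1L), shift(-1L, 1L),
                     shift(1L, -1L), shift(1L, 1L))
  )
}

#' One synchronous generation of the lattice dynamics
#'
#' Every node, independently and reading the previous generation's
#' states: with probability `b_self` retains its variant; with
#' probability `b_direct` copies from its direct-neighbour class; with
#' probability `b_indirect` from its indirect class.  Within the chosen
#' class the source is drawn with weight 1 for wild carriers and
#' `1 + beta` for mutant carriers, so given `m` mutant neighbours in
#' the class the node becomes mutant with probability
#' \eqn{(1+\beta) m / (4 + \beta m)}; `beta = 0` (the default) is
#' unbiased neutral copying, `beta > 0` is a directional transmission
#' bias favouring the mutant variant.
#'
#' @param state logical or 0/1 matrix (width x height), `TRUE` = mutant.
#' @param bias a [bias_vector()] or numeric triple.
#' @param beta directional-bias parameter, `>= 0` (default 0).
#' @param config optional [lattice_config()] (defaults to the state's
#'   dimensions).
#' @return the next state, same shape as `state`.
#' @export
lattice_step <- function(state, bias, beta = 0, config = NULL) {
  state <- as.matrix(state)
  if (is.null(config)) {
    config <- lattice_config(nrow(state), ncol(state))
  }
  if (nrow(state) != config$width || ncol(state) != config$height) {
    stop("state dimensions do not match the configuration", call. = FALSE)
  }
  nb <- neighbour_index(config)
  matrix(step_engine(as.logical(state), as_bias_vector(bias), beta, nb),
         nrow = config$width)
}

## core synchronous update on a logical vector of states
step_engine <- function(s, bias, beta, nb) {
  n <- length(s)
  u <- stats::runif(n)
  copy_direct <- u >= bias$b_self & u < bias$b_self + bias$b_direct
  copy_indirect <- u >= bias$b_self + bias$b_direct
  out <- s
  for (cls in c("direct", "indirect")) {
    sel <- if (cls == "direct") copy_direct else copy_indirect
    if (!any(sel)) next
    idx <- nb[[cls]][sel, , drop = FALSE]
    m <- rowSums(matrix(s[idx], nrow = sum(sel)))
    p <- (1 + beta) * m / (4 + beta * m)
    out[sel] <- stats::runif(sum(sel)) < p
  }
  out
}

#' Run one realisation of the lattice transmission model
#'
#' Seeds `seed_count` mutant nodes uniformly at random, then iterates
#' synchronous generations ([lattice_step()]) until the mutant variant
#' either fixes in the whole population (*penetrant*), is lost from
#' every node (*extinct*), or `max_generations` is reached
#' (*censored*).  Mutation occurs only at seeding; afterwards the
#' dynamics are pure imitation, so the all-wild and all-mutant states
#' are absorbing.
#'
#' @param config a [lattice_config()].
#' @param bias a [bias_vector()] or numeric triple.
#' @param beta directional transmission bias (default 0, neutral).
#' @param seed optional integer seed for this run.
#' @param record_trajectory keep the mutant count per generation?
#' @return an object of class `sim_result`: list with `outcome`
#'   (`"extinct"`, `"penetrant"` or `"censored"`), `generations`,
#'   `final_mutants`, `n_agents`, and optionally `trajectory` (mutant
#'   count at generations `0..generations`).
#' @examples
#' run_lattice(lattice_config(10, 10, max_generations = 50),
#'             bias_vector(0.2, 0.6, 0.2), seed = 1)
#' @export
run_lattice <- function(config, bias, beta = 0, seed = NULL,
                        record_trajectory = FALSE) {
  stopifnot(inherits(config, "lattice_config"))
  bias <- as_bias_vector(bias)
  if (!is.null(seed)) set.seed(seed)
  nb <- neighbour_index(config)
  n <- config$n_agents
  s <- logical(n)
  s[sample.int(n, config$seed_count)] <- TRUE
  run_loop(s, config, function(st) step_engine(st, bias, beta, nb),
           record_trajectory)
}

#' Run one realisation of the mean-field variant
#'
#' Identical dynamics to [run_lattice()] but with the spatial
#' constraint dropped: a copying agent samples `n_parents` cultural
#' parents uniformly (with replacement) from the whole population and
#' adopts the variant of one of them, mutant parents being weighted
#' `1 + beta` against 1 for wild ones.  Since the direct/indirect
#' distinction has no meaning without space, the copy probability is
#' `b_direct + b_indirect = 1 - b_self`.
#'
#' @inheritParams run_lattice
#' @return a `sim_result`, as for [run_lattice()].
#' @export
run_mean_field <- function(config, bias, beta = 0, seed = NULL,
                           record_trajectory = FALSE) {
  stopifnot(inherits(config, "lattice_config"))
  bias <- as_bias_vector(bias)
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_agents
  np <- config$n_parents
  s <- logical(n)
  s[sample.int(n, config$seed_count)] <- TRUE
  stepper <- function(st) {
    u <- stats::runif(n)
    copying <- u >= bias$b_self
    out <- st
    nc <- sum(copying)
    if (nc) {
      m <- stats::rbinom(nc, np, mean(st))
      p <- (1 + beta) * m / (np + beta * m)
      out[copying] <- stats::runif(nc) < p
    }
    out
  }
  run_loop(s, config, stepper, record_trajectory)
}

run_loop <- function(s, config, stepper, record_trajectory) {
  n <- length(s)
  counts <- if (record_trajectory) integer(config$max_generations + 1L)
  gen <- 0L
  cnt <- sum(s)
  if (record_trajectory) counts[1L] <- cnt
  while (cnt > 0L && cnt < n && gen < config$max_generations) {
    s <- stepper(s)
    gen <- gen + 1L
    cnt <- sum(s)
    if (record_trajectory) counts[gen + 1L] <- cnt
  }
  outcome <- if (cnt == 0L) "extinct" else if (cnt == n) "penetrant"
             else "censored"
  structure(
    list(outcome = outcome, generations = gen, final_mutants = cnt,
         n_agents = n,
         trajectory = if (record_trajectory) counts[seq_len(gen + 1L)]),
    class = "sim_result"
  )
}

#' @export
print.sim_result <- function(x, ...) {
  cat("Transmission run:", x$outcome, "after", x$generations,
      "generations (", x$final_mutants, "/", x$n_agents, "mutants )\n")
  invisible(x)
}

#' Ensemble of transmission runs
#'
#' Aggregates `n_reps` independent realisations of [run_lattice()] (or
#' [run_mean_field()] with `mean_field = TRUE`) into extinction,
#' penetrance and censoring fractions plus quantiles of the time to
#' penetrance.  Each replicate runs on its own sub-seed derived from
#' `seed`, so the whole ensemble is bit-reproducible and replicates are
#' independent.
#'
#' @inheritParams run_lattice
#' @param n_reps number of replicates (`>= 1`).
#' @param mean_field use the mean-field dynamics instead of the
#'   lattice?
#' @param seed master seed for the ensemble (default 1).
#' @return a list of class `sim_ensemble`: `extinction_fraction`,
#'   `penetrance_fraction`, `censored_fraction`,
#'   `penetrance_time_quantiles` (2.5/25/50/75/97.5%), `runs` (a data
#'   frame with columns `rep`, `seed`, `outcome`, `generations`,
#'   `final_mutants`), and the call parameters.
#' @export
run_ensemble <- function(config, bias, n_reps, beta = 0, seed = 1L,
                         mean_field = FALSE) {
  stopifnot(inherits(config, "lattice_config"))
  n_reps <- as.integer(n_reps)
  if (is.na(n_reps) || n_reps < 1L) stop("`n_reps` must be >= 1",
                                         call. = FALSE)
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n_reps)
  runner <- if (mean_field) run_mean_field else run_lattice
  runs <- lapply(seq_len(n_reps), function(i) {
    r <- runner(config, bias, beta = beta, seed = sub_seeds[i])
    data.frame(rep = i, seed = sub_seeds[i], outcome = r$outcome,
               generations = r$generations, final_mutants = r$final_mutants)
  })
  runs <- do.call(rbind, runs)
  pen <- runs$generations[runs$outcome == "penetrant"]
  qs <- c(0.025, 0.25, 0.5, 0.75, 0.975)
  structure(
    list(
      extinction_fraction = mean(runs$outcome == "extinct"),
      penetrance_fraction = mean(runs$outcome == "penetrant"),
      censored_fraction = mean(runs$outcome == "censored"),
      penetrance_time_quantiles =
        if (length(pen)) stats::quantile(pen, qs) else
          stats::setNames(rep(NA_real_, length(qs)), paste0(qs * 100, "%")),
      runs = runs,
      config = config, bias = as_bias_vector(bias), beta = beta,
      mean_field = mean_field, seed = seed
    ),
    class = "sim_ensemble"
  )
}

#' @export
print.sim_ensemble <- function(x, ...) {
  cat("Ensemble of", nrow(x$runs), if (x$mean_field) "mean-field" else
      "lattice", "runs:\n")
  cat(sprintf("  extinct %.1f%%  penetrant %.1f%%  censored %.1f%%\n",
              100 * x$extinction_fraction, 100 * x$penetrance_fraction,
              100 * x$censored_fraction))
  if (!all(is.na(x$penetrance_time_quantiles))) {
    cat("  penetrance time (median):",
        x$penetrance_time_quantiles[["50%"]], "generations\n")
  }
  invisible(x)
}
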