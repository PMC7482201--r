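## Independent oracles used across the suite.  These are deliberately
## naive (enumeration, linear algebra, closed forms) and share no code
## with the package implementation.

## --- exhaustive contiguous-partition search -------------------------------

## all ways to split 1..n into k contiguous blocks, as lists of end indices
all_contiguous_partitions <- function(n, k) {
  if (k == 1L) return(list(n))
  cuts <- utils::combn(n - 1L, k - 1L, simplify = FALSE)
  lapply(cuts, function(cc) c(cc, n))
}

partition_ssd <- function(x, ends) {
  starts <- c(1L, head(ends, -1L) + 1L)
  sum(vapply(seq_along(ends), function(i) {
    seg <- x[starts[i]:ends[i]]
    sum((seg - mean(seg))^2)
  }, 0))
}

## minimal SSD over every contiguous k-partition of sorted x
brute_force_min_ssd <- function(x, k) {
  x <- sort(x)
  min(vapply(all_contiguous_partitions(length(x), k),
             function(ends) partition_ssd(x, ends), 0))
}

## --- compositions of L into r nonnegative parts ---------------------------

compositions <- function(L, r) {
  if (r == 1L) return(list(L))
  out <- list()
  for (first in 0:L) {
    for (rest in compositions(L - first, r - 1L)) {
      out[[length(out) + 1L]] <- c(first, rest)
    }
  }
  out
}

## --- exact Markov chain for the 3x3 torus dynamics ------------------------

## neighbour lists written from scratch for the 3x3 torus: cell id
## 1..9 maps to (x, y) = ((id-1) %% 3 + 1, (id-1) %/% 3 + 1)
torus3_neighbours <- function() {
  wrap <- function(v) ((v - 1L) %% 3L) + 1L
  id <- function(x, y) (wrap(y) - 1L) * 3L + wrap(x)
  direct <- indirect <- matrix(0L, 9L, 4L)
  for (i in 1:9) {
    x <- (i - 1L) %% 3L + 1L
    y <- (i - 1L) %/% 3L + 1L
    direct[i, ] <- c(id(x - 1L, y), id(x + 1L, y), id(x, y - 1L),
                     id(x, y + 1L))
    indirect[i, ] <- c(id(x - 1L, y - 1L), id(x - 1L, y + 1L),
                       id(x + 1L, y - 1L), id(x + 1L, y + 1L))
  }
  list(direct = direct, indirect = indirect)
}

## per-node probability of being mutant next generation, given state s
## (logical length 9) under bias (self, direct, indirect) and beta
torus3_node_probs <- function(s, bias, beta = 0) {
  nb <- torus3_neighbours()
  md <- rowSums(matrix(s[nb$direct], 9L))
  mi <- rowSums(matrix(s[nb$indirect], 9L))
  bias[1] * s +
    bias[2] * (1 + beta) * md / (4 + beta * md) +
    bias[3] * (1 + beta) * mi / (4 + beta * mi)
}

## 512 x 512 transition matrix of the synchronous dynamics
torus3_transition_matrix <- function(bias, beta = 0) {
  states <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), 9L)))
  n_states <- nrow(states)  # 512, row 1 = all wild, row 512 = all mutant
  P <- matrix(0, n_states, n_states)
  for (a in seq_len(n_states)) {
    p <- torus3_node_probs(states[a, ], bias, beta)
    ## successor probability: independent Bernoulli product
    lp1 <- log(p); lp0 <- log1p(-p)
    lp1[p == 0] <- -Inf; lp0[p == 1] <- -Inf
    loglik <- states %*% ifelse(is.finite(lp1), lp1, -1e30) +
      (1 - states) %*% ifelse(is.finite(lp0), lp0, -1e30)
    P[a, ] <- exp(loglik)
  }
  list(P = P, states = states)
}

## extinction probability and expected absorption time starting from a
## single mutant (all single-mutant states are equivalent by symmetry)
torus3_absorption <- function(bias, beta = 0) {
  tm <- torus3_transition_matrix(bias, beta)
  counts <- rowSums(tm$states)
  absorbing <- counts == 0L | counts == 9L
  trans <- which(!absorbing)
  Q <- tm$P[trans, trans]
  b_ext <- tm$P[trans, which(counts == 0L)]
  h <- solve(diag(length(trans)) - Q, b_ext)       # P(absorb at all-wild)
  t_abs <- solve(diag(length(trans)) - Q, rep(1, length(trans)))
  start <- which(counts[trans] == 1L)
  list(extinction_prob = mean(h[start]),
       mean_absorption_time = mean(t_abs[start]))
}

## --- mean-field one-step expectation oracle -------------------------------

## E[mutant fraction after one generation | current fraction x], for a
## population where each copying agent samples n_parents uniformly with
## replacement and adopts with mutant weight 1 + beta
mean_field_expectation <- function(x, b_self, n_parents, beta = 0) {
  m <- 0:n_parents
  adopt <- sum(stats::dbinom(m, n_parents, x) *
                 (1 + beta) * m / (n_parents + beta * m))
  b_self * x + (1 - b_self) * adopt
}

## --- misc -----------------------------------------------------------------

## silhouette reference via the cluster package (independent code path)
ref_mean_silhouette <- function(x, cl) {
  mean(cluster::silhouette(cl, stats::dist(x))[, "sil_width"])
}
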