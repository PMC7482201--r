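test_that("neighbour classes split the Moore neighbourhood four and four", {
  cfg <- lattice_config(100, 100)
  nb <- lattice_neighbours(cfg, 50, 50)
  all8 <- rbind(nb$direct, nb$indirect)
  expect_equal(nrow(nb$direct), 4)
  expect_equal(nrow(nb$indirect), 4)
  expect_equal(nrow(unique(all8)), 8)

  ## torus wrap at the corner
  nbc <- lattice_neighbours(cfg, 1, 1)
  expect_true(any(nbc$indirect[, 1] == 100 & nbc$indirect[, 2] == 100))
  expect_true(any(nbc$direct[, 1] == 100 & nbc$direct[, 2] == 1))

  ## 3x3 torus: the eight neighbours are all eight other cells
  nb3 <- lattice_neighbours(lattice_config(3, 3), 2, 2)
  cells <- rbind(nb3$direct, nb3$indirect)
  ids <- sort((cells[, 2] - 1) * 3 + cells[, 1])
  expect_equal(ids, setdiff(1:9, 5))

  expect_error(lattice_config(2, 5), "3x3")
  expect_error(lattice_neighbours(cfg, 0, 1), "off the lattice")
})

test_that("bias vectors validate", {
  expect_error(bias_vector(0.5, 0.5, 0.5), "sum to 1")
  expect_error(bias_vector(-0.1, 0.6, 0.5), "probabilities")
  b <- bias_vector(0.2, 0.6, 0.2)
  expect_equal(b$b_direct, 0.6)
})

test_that("pure retention and consensus states are fixed points", {
  set.seed(1)
  st <- matrix(runif(25) < 0.4, 5, 5)
  expect_equal(lattice_step(st, c(1, 0, 0)), st)

  ones <- matrix(TRUE, 5, 5)
  expect_equal(lattice_step(ones, c(0.1, 0.6, 0.3)), ones)
  zeros <- matrix(FALSE, 5, 5)
  expect_equal(lattice_step(zeros, c(0.1, 0.6, 0.3)), zeros)
})

test_that("one-step node probabilities match the exact enumeration", {
  ## fixed 3x3 state, bias (0, 1, 0): every node copies a direct
  ## neighbour; empirical per-node mutant frequencies must match the
  ## oracle's independent per-node probabilities
  s <- c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE)
  p_exact <- torus3_node_probs(s, c(0, 1, 0))
  st <- matrix(s, 3, 3)
  set.seed(202)
  reps <- 4000
  freq <- rowMeans(vapply(seq_len(reps), function(i) {
    as.vector(lattice_step(st, c(0, 1, 0)))
  }, logical(9)))
  se <- sqrt(p_exact * (1 - p_exact) / reps)
  expect_true(all(abs(freq - p_exact) <= 4 * se + 1e-9))

  ## and with a mixed bias vector including indirect copying
  p_exact2 <- torus3_node_probs(s, c(0.2, 0.3, 0.5))
  set.seed(203)
  freq2 <- rowMeans(vapply(seq_len(reps), function(i) {
    as.vector(lattice_step(st, c(0.2, 0.3, 0.5)))
  }, logical(9)))
  se2 <- sqrt(p_exact2 * (1 - p_exact2) / reps)
  expect_true(all(abs(freq2 - p_exact2) <= 4 * se2 + 1e-9))
})

test_that("runs terminate correctly at the absorbing states", {
  cfg_full <- lattice_config(4, 4, seed_count = 16, max_generations = 10)
  r <- run_lattice(cfg_full, c(0.2, 0.6, 0.2), seed = 1)
  expect_equal(r$outcome, "penetrant")
  expect_equal(r$generations, 0)

  cfg1 <- lattice_config(4, 4, seed_count = 1, max_generations = 25)
  r2 <- run_lattice(cfg1, c(1, 0, 0), seed = 1)
  expect_equal(r2$outcome, "censored")
  expect_equal(r2$final_mutants, 1)
  expect_equal(r2$generations, 25)
})

test_that("runs are bit-reproducible under a fixed seed", {
  cfg <- lattice_config(6, 6, max_generations = 60)
  a <- run_lattice(cfg, c(0.2, 0.5, 0.3), seed = 77, record_trajectory = TRUE)
  b <- run_lattice(cfg, c(0.2, 0.5, 0.3), seed = 77, record_trajectory = TRUE)
  expect_identical(a, b)
  e1 <- run_ensemble(cfg, c(0.2, 0.5, 0.3), n_reps = 5, seed = 9)
  e2 <- run_ensemble(cfg, c(0.2, 0.5, 0.3), n_reps = 5, seed = 9)
  expect_identical(e1$runs, e2$runs)
  tab <- gen_ego_contacts(seed = 4)
  expect_identical(tab, gen_ego_contacts(seed = 4))
})

test_that("mean-field copying is a martingale when unbiased", {
  ## from a fixed 10% mutant start, the expected one-step fraction is
  ## unchanged under neutral copying (exact identity, checked by MC)
  cfg <- lattice_config(10, 10, n_parents = 5, seed_count = 10,
                        max_generations = 1)
  set.seed(55)
  fr <- replicate(800, {
    r <- run_mean_field(cfg, c(0.3, 0.4, 0.3), record_trajectory = TRUE)
    r$trajectory[2] / 100
  })
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.10), 3 * se)
})

test_that("mean-field first step matches the binomial expectation oracle", {
  cfg <- lattice_config(10, 10, n_parents = 6, seed_count = 10,
                        max_generations = 1)
  beta <- 0.8
  expected <- mean_field_expectation(0.10, b_self = 0.3, n_parents = 6,
                                     beta = beta)
  set.seed(56)
  fr <- replicate(800, {
    r <- run_mean_field(cfg, c(0.3, 0.4, 0.3), beta = beta,
                        record_trajectory = TRUE)
    r$trajectory[2] / 100
  })
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - expected), 3 * se)
  expect_gt(expected, 0.10)  # positive bias pushes the mutant up
})

test_that("lattice extinction probability matches the 512-state oracle", {
  ## light version (the acceptance suite runs 10^4 replicates)
  bias <- c(0, 0.5, 0.5)
  oracle <- torus3_absorption(bias)
  cfg <- lattice_config(3, 3, seed_count = 1, max_generations = 400)
  ens <- run_ensemble(cfg, bias, n_reps = 1500, seed = 31)
  expect_equal(ens$censored_fraction, 0)
  se <- sqrt(oracle$extinction_prob * (1 - oracle$extinction_prob) / 1500)
  expect_lt(abs(ens$extinction_fraction - oracle$extinction_prob), 4 * se)
})

test_that("ensembles aggregate outcomes and quantiles correctly", {
  cfg <- lattice_config(4, 4, seed_count = 16, max_generations = 5)
  ens <- run_ensemble(cfg, c(0.2, 0.6, 0.2), n_reps = 10, seed = 3)
  expect_equal(ens$penetrance_fraction, 1)
  expect_true(all(ens$penetrance_time_quantiles == 0))

  cfg1 <- lattice_config(4, 4, seed_count = 1, max_generations = 5)
  ens1 <- run_ensemble(cfg1, c(1, 0, 0), n_reps = 10, seed = 3)
  expect_equal(ens1$extinction_fraction, 0)
  expect_equal(ens1$censored_fraction, 1)
})

test_that("spatial structure slows penetrance relative to mean field", {
  ## small paired comparison (the acceptance suite runs the full one);
  ## favourable bias so penetrant runs are common
  cfg <- lattice_config(10, 10, n_parents = 8, seed_count = 10,
                        max_generations = 300)
  bias <- c(0.2, 0.6, 0.2)
  lat <- run_ensemble(cfg, bias, n_reps = 40, beta = 1, seed = 17)
  mf <- run_ensemble(cfg, bias, n_reps = 40, beta = 1, seed = 17,
                     mean_field = TRUE)
  expect_gt(lat$penetrance_fraction, 0.5)
  expect_gt(mf$penetrance_fraction, 0.5)
  expect_gt(lat$penetrance_time_quantiles[["50%"]],
            mf$penetrance_time_quantiles[["50%"]])
})
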