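test_that("well-separated values partition into their natural classes", {
  fit <- optimal_breaks(c(1, 2, 3, 10, 11, 12, 100, 101), k = 3)
  expect_equal(fit$class_sizes, c(3, 3, 2))
  expect_equal(fit$assignment, rep(1:3, c(3, 3, 2)))
  expect_true(all(fit$breaks > c(3, 12) & fit$breaks < c(10, 100)))
})

test_that("dynamic programme matches the exhaustive-partition oracle", {
  set.seed(101)
  for (rep in 1:8) {
    n <- sample(5:12, 1)
    x <- sort(runif(n, 0, 10))
    for (k in 1:n) {
      fit <- optimal_breaks(x, k)
      expect_equal(fit$within_class_ssd, brute_force_min_ssd(x, k),
                   tolerance = 1e-10)
      ## returned SSD matches a recomputation of the returned partition
      recomputed <- sum(tapply(x, fit$assignment,
                               function(v) sum((v - mean(v))^2)))
      expect_equal(fit$within_class_ssd, recomputed, tolerance = 1e-10)
    }
  }
})

test_that("k = 1 gives the total sum of squares; SSD is nonincreasing in k", {
  set.seed(7)
  x <- runif(30)
  fit1 <- optimal_breaks(x, 1)
  expect_equal(fit1$within_class_ssd, sum((x - mean(x))^2))
  ssds <- vapply(1:10, function(k) optimal_breaks(x, k)$within_class_ssd, 0)
  expect_true(all(diff(ssds) <= 1e-12))
})

test_that("degenerate and invalid inputs are rejected", {
  expect_error(optimal_breaks(1:3, 4), "exceeds")
  expect_error(optimal_breaks(c(1, NaN, 3), 2), "finite")
  expect_error(optimal_breaks(numeric(0), 1), "empty")
})

test_that("tied values are never split across classes", {
  fit <- optimal_breaks(c(10, 10, 10, 0.1, 0.1, 0.1), k = 2)
  expect_equal(fit$class_sizes, c(3, 3))
  tab <- data.frame(alter_id = letters[1:6],
                    contact_rate_per_day = c(10, 10, 10, 0.1, 0.1, 0.1))
  det <- detect_layers(tab, k_range = 2:5)
  expect_equal(det$cumulative_sizes, c(3, 6))
})

test_that("package silhouette agrees with the cluster package", {
  skip_if_not_installed("cluster")
  set.seed(42)
  for (rep in 1:5) {
    x <- sort(rnorm(40))
    for (k in 2:5) {
      fit <- optimal_breaks(x, k)
      expect_equal(dunbargraph:::mean_silhouette_1d(x, fit$assignment),
                   ref_mean_silhouette(x, fit$assignment),
                   tolerance = 1e-12)
    }
  }
})

test_that("layer-count selection finds clean geometric structure", {
  ## two point masses -> 2
  expect_equal(as.integer(select_num_layers(rep(c(1, 100), each = 10))), 2L)

  ## three well-separated log-spaced levels -> 3, and the silhouette
  ## scores really are maximal at 3 (independent recomputation)
  set.seed(5)
  x <- c(1, 30, 900)[rep(1:3, each = 12)] * 10^rnorm(36, 0, 0.05)
  k <- select_num_layers(x, k_range = 2:6)
  expect_equal(as.integer(k), 3L)
  skip_if_not_installed("cluster")
  lx <- sort(log10(x))
  ref <- vapply(2:6, function(kk) {
    ref_mean_silhouette(lx, optimal_breaks(lx, kk)$assignment)
  }, 0)
  expect_equal(which.max(ref) + 1L, 3L)
})

test_that("identical rates collapse to a single layer with a warning", {
  expect_warning(k <- select_num_layers(rep(2, 10)), "identical")
  expect_equal(as.integer(k), 1L)
  tab <- data.frame(alter_id = 1:6, contact_rate_per_day = rep(1, 6))
  expect_warning(fit <- detect_layers(tab), "identical")
  expect_equal(fit$k, 1L)
  expect_equal(fit$cumulative_sizes, 6)
  expect_true(is.na(fit$mean_scaling_ratio))
})

test_that("detection recovers planted four-layer structure at moderate noise", {
  ## log10 noise 0.1 keeps adjacent layers ~4.8 sigma apart: the
  ## identifiable regime (at the default 0.3 the layers genuinely
  ## blur together; see the acceptance suite)
  ks <- integer(30)
  errs <- matrix(NA_real_, 30, 4)
  for (s in 1:30) {
    tab <- gen_ego_contacts(seed = s, log10_noise_sd = 0.1)
    fit <- detect_layers(tab)
    ks[s] <- fit$k
    if (fit$k == 4) {
      errs[s, ] <- abs(fit$cumulative_sizes - c(5, 15, 50, 150)) /
        c(5, 15, 50, 150)
    }
  }
  modal <- as.integer(names(which.max(table(ks))))
  expect_equal(modal, 4L)
  ## median per-layer relative error within 20%
  expect_true(all(apply(errs, 2, stats::median, na.rm = TRUE) <= 0.20))
})

test_that("contact-table validation catches malformed input", {
  expect_error(detect_layers(data.frame(alter_id = 1:3,
                                        contact_rate_per_day = c(1, 2, 3))),
               "at least 4")
  expect_error(detect_layers(data.frame(alter_id = c(1, 1, 2, 3),
                                        contact_rate_per_day = 1:4)),
               "duplicated")
  expect_error(detect_layers(data.frame(alter_id = 1:4,
                                        contact_rate_per_day = c(1, -1, 2, 3))),
               "positive")
})
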