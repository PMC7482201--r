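test_that("annuli are cumulative differences and conserve the total", {
  expect_equal(annuli(c(5, 15, 50, 150)), c(5, 10, 35, 100))
  expect_equal(annuli(c(2.9, 7.4, 17.7, 43.0, 134.3)),
               c(2.9, 4.5, 10.3, 25.3, 91.3))
  expect_equal(annuli(7), 7)

  set.seed(11)
  for (i in 1:20) {
    sizes <- cumsum(runif(sample(1:8, 1), 0.5, 50))
    expect_equal(sum(annuli(sizes)), sizes[length(sizes)])
    expect_length(annuli(sizes), length(sizes))
  }
})

test_that("invalid layer schemes are rejected", {
  expect_error(layer_scheme(c(5, 5, 15)), "strictly increasing")
  expect_error(layer_scheme(c(15, 5)), "strictly increasing")
  expect_error(layer_scheme(c(-1, 5)), "positive")
  expect_error(layer_scheme(numeric(0)))
  expect_error(layer_scheme(c(1, NA)))
})

test_that("scaling ratios are successive cumulative quotients", {
  expect_equal(scaling_ratios(c(3, 9, 27)), c(3, 3))
  expect_error(scaling_ratios(5), "at least two")
  ## exact geometric schemes give back the ratio everywhere
  for (r in c(2, 3, 3.5)) {
    sizes <- 4 * r^(0:5)
    expect_equal(scaling_ratios(sizes), rep(r, 5))
    expect_equal(mean_scaling_ratio(sizes), r)
  }
})

test_that("published layer-size rows reproduce their printed scaling ratios", {
  d <- dunbar_layer_datasets()
  row <- function(id) d$cumulative_size[d$dataset == id]
  expect_equal(round(mean_scaling_ratio(row("personal_average")), 1), 3.0)
  expect_equal(round(mean_scaling_ratio(row("community_average")), 2), 3.11)
  expect_equal(round(mean_scaling_ratio(row("multilevel_mammals")), 2), 2.49)
  expect_equal(round(mean_scaling_ratio(row("primate_groups")), 2), 2.23)
  ## every stored row is a valid strictly increasing scheme
  for (id in unique(d$dataset)) {
    expect_silent(layer_scheme(row(id)))
  }
})

test_that("effort profiles validate and the default is anchored at 40/20", {
  expect_error(effort_profile(c(0.5, 0.4)), "sum to 1")
  expect_error(effort_profile(c(1.2, -0.2)), "\\[0, 1\\]")

  p <- default_effort_profile(dunbar_scheme())
  expect_s3_class(p, "effort_profile")
  expect_equal(sum(p$annulus_shares), 1, tolerance = 1e-12)
  expect_equal(p$annulus_shares[1:2], c(0.40, 0.20))
  ## outer per-capita effort decays geometrically
  percap <- p$annulus_shares / annuli(dunbar_scheme())
  decay <- percap[-1] / percap[-7]
  expect_true(all(diff(decay[2:6]) < 1e-9))  # constant factor beyond layer 2
  expect_true(all(percap[-1] < percap[-7]))  # strictly decreasing per capita
})

test_that("cumulative effort accumulates to one and hits 60% at 15 alters", {
  p <- default_effort_profile(dunbar_scheme())
  expect_equal(cumulative_effort(p, 2), 0.60)
  expect_equal(cumulative_effort(p, 7), 1)
  vals <- vapply(1:7, function(i) cumulative_effort(p, i), 0)
  expect_true(all(diff(vals) >= 0))
  expect_equal(cumulative_effort(rep(0.25, 4), 1), 0.25)
  expect_error(cumulative_effort(p, 8), "out of range")
  expect_error(cumulative_effort(p, 0), "out of range")
  expect_error(cumulative_effort(p, 3, scheme = c(5, 15)), "does not match")
})

test_that("group-size tables parse ranges and summarise under each policy", {
  tab <- group_size_table(data.frame(
    label = c("a", "b", "c"),
    size = c("100-200", "150", "50")
  ))
  expect_equal(tab$low, c(100, 150, 50))
  expect_equal(tab$high, c(200, 150, 50))

  s_mid <- summarize_group_sizes(tab, "midpoint")
  s_low <- summarize_group_sizes(tab, "low")
  s_high <- summarize_group_sizes(tab, "high")
  expect_equal(s_mid$mean, mean(c(150, 150, 50)))
  expect_equal(s_low$mean, mean(c(100, 150, 50)))
  expect_equal(s_high$mean, mean(c(200, 150, 50)))
  ## sample (n-1) sd, hand value
  expect_equal(s_mid$sd, sd(c(150, 150, 50)))

  expect_equal(summarize_group_sizes(group_size_table(c(7, 7, 7)))$sd, 0)
  expect_error(group_size_table(data.frame(label = "x", size = "200-100")),
               "low > high")
  expect_error(group_size_table(data.frame(label = "x", size = "abc")),
               "unparseable")
  expect_error(summarize_group_sizes(group_size_table(data.frame(
    label = character(), size = character()))), "empty")
})

test_that("bundled community table round-trips through CSV reading", {
  tab <- dunbar_community_sizes()
  expect_equal(nrow(tab), 12)
  expect_true(all(tab$low > 0))
  ## two rows are ranges, the rest are point estimates
  expect_equal(sum(tab$low != tab$high), 2)
})
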