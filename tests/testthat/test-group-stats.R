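# quick synthetic CS table: one channel/interval cell per subject
cell_table <- function(values, groups) {
  tibble::tibble(
    subject = sprintf("S%03d", seq_along(values)), group = groups,
    channel = 1, interval = "III", sigma = values
  )
}

test_that("the channel-region map validates its shape", {
  map <- channel_region_map()
  expect_equal(nrow(map), 24)
  expect_equal(length(unique(map$region)), 6)
  expect_true(all(table(map$region) == 4))
  expect_error(
    channel_region_map(data.frame(channel = c(1, 1), region = c("LPFC", "RPFC"))),
    class = "cacoupling_invalid_parameter"
  )
  expect_error(
    channel_region_map(data.frame(channel = 1:24, region = "FRONT")),
    class = "cacoupling_invalid_parameter"
  )
})

test_that("Bonferroni thresholds divide alpha by the family size", {
  b <- bonferroni_threshold(0.05, 8)
  expect_equal(b$threshold, 0.00625)
  expect_equal(b$threshold_reported, 0.006)
  expect_equal(bonferroni_threshold(0.05, 1)$threshold, 0.05)
  expect_equal(bonferroni_threshold(0.05, 10)$threshold, 0.005)
  expect_error(bonferroni_threshold(0.05, 0),
               class = "cacoupling_invalid_parameter")
})

test_that("two-group ANOVA equals the squared t statistic", {
  withr::with_seed(1, {
    x <- stats::rnorm(17, 0.3, 0.1)
    y <- stats::rnorm(9, 0.4, 0.1)
  })
  p_aov <- stats::oneway.test(c(x, y) ~ rep(c("a", "b"), c(17, 9)),
                              var.equal = TRUE)$p.value
  p_t <- stats::t.test(x, y, var.equal = TRUE)$p.value
  expect_lt(abs(p_aov - p_t), 1e-9)
  tab <- channelwise_anova(cell_table(c(x, y), rep(c("healthy", "L-H"), c(17, 9))),
                           m = 8)
  expect_equal(tab$p_value, p_t, tolerance = 1e-12)
  expect_equal(tab$mean_ref, mean(x))
  expect_equal(tab$n_grp, 9)
})

test_that("the ANOVA null is calibrated and the power case detects", {
  null_p <- sapply(1:100, function(r) {
    v <- withr::with_seed(r, stats::rnorm(26, 0.4, 0.1))
    channelwise_anova(cell_table(v, rep(c("healthy", "L-H"), c(17, 9))),
                      m = 8)$p_value
  })
  expect_lt(abs(mean(null_p < 0.05) - 0.05), 0.05)
  pow_p <- sapply(1:100, function(r) {
    v <- withr::with_seed(1000 + r,
      c(stats::rnorm(17, 0.3, 0.1), stats::rnorm(9, 0.6, 0.1)))
    channelwise_anova(cell_table(v, rep(c("healthy", "L-H"), c(17, 9))),
                      m = 8)$p_value
  })
  expect_gte(mean(pow_p < 0.006), 0.9)
})

test_that("degenerate and missing ANOVA cells are handled", {
  tab <- channelwise_anova(cell_table(rep(0.4, 26),
                                      rep(c("healthy", "L-H"), c(17, 9))))
  expect_equal(tab$p_value, 1)
  expect_false(tab$significant)
  bad <- cell_table(stats::rnorm(26), rep(c("healthy", "L-H"), c(17, 9)))
  bad$interval[bad$group == "L-H"] <- "IV" # healthy-only cell appears
  expect_error(channelwise_anova(bad), class = "cacoupling_missing_data")
  tiny <- cell_table(stats::rnorm(4), rep(c("healthy", "L-H"), c(2, 2)))
  expect_error(channelwise_anova(tiny), class = "cacoupling_insufficient_data")
})

test_that("hemispheric paired tests: identity, power, degenerate n", {
  regions <- c("LPFC", "RPFC")
  mk <- function(delta, sd, n = 9, seed = 1) {
    withr::with_seed(seed, {
      base <- stats::rnorm(n, 0.4, 0.05)
      tibble::tibble(
        subject = rep(sprintf("P%02d", 1:n), each = 2),
        region = rep(regions, n), interval = "III",
        sigma = as.vector(rbind(base + delta + stats::rnorm(n, 0, sd), base))
      )
    })
  }
  affected <- stats::setNames(rep("L", 9), sprintf("P%02d", 1:9))
  ident <- mk(0, 0)
  ident$sigma <- rep(ident$sigma[1], nrow(ident))
  expect_equal(hemispheric_paired_test(ident, affected)$p_value, 1)
  pow <- sapply(1:100, function(r) {
    hemispheric_paired_test(mk(0.3, 0.05, seed = r), affected)$p_value
  })
  expect_gte(mean(pow < 0.05), 0.95)
  one <- mk(0.1, 0.05)[1:2, ]
  expect_error(hemispheric_paired_test(one, affected),
               class = "cacoupling_insufficient_data")
})

test_that("region averaging is the element-wise mean over channel surfaces", {
  m <- build_basis(2)
  surf <- function(val) {
    structure(list(q = matrix(val, 10, 10), phi_target = seq(0, 2 * pi, length.out = 10),
                   phi_source = seq(0, 2 * pi, length.out = 10),
                   direction = "1->2", labels = c("map", "hbo2")),
              class = "coupling_surface")
  }
  same <- replicate(24, surf(1.5), simplify = FALSE)
  out <- region_average_surfaces(same)
  expect_length(out, 6)
  expect_true(all(sapply(out, function(s) all(s$q == 1.5))))
  # linearity: doubling every channel surface doubles each region average
  doubled <- replicate(24, surf(3.0), simplify = FALSE)
  out2 <- region_average_surfaces(doubled)
  expect_equal(out2$LPFC$q, 2 * out$LPFC$q)
  expect_error(region_average_surfaces(same[1:20]),
               class = "cacoupling_missing_data")
})
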