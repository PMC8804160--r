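test_that("mean ranks and U match hand-computable cases", {
  r <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(r$mr1, 1.5)
  expect_equal(r$mr2, 3.5)
  expect_equal(r$U, 0)
  expect_equal(r$U1 + r$U2, r$n1 * r$n2)
  # identical samples: symmetric mean ranks
  r2 <- mann_whitney(c(5, 7, 9), c(5, 7, 9))
  expect_equal(r2$mr1, r2$mr2)
})

test_that("small-sample p equals the exact enumeration oracle", {
  # no ties: base wilcox.test computes the exact distribution independently
  cases <- list(list(a = c(1, 3), b = c(2, 4)),
                list(a = c(1, 2, 5, 9), b = c(3, 4, 8, 10)),
                list(a = c(0.5, 2.2, 6.1), b = c(1.1, 3.3, 4.4, 7.7)))
  for (cs in cases) {
    mine <- mann_whitney(cs$a, cs$b)
    ref <- wilcox.test(cs$a, cs$b, exact = TRUE)
    expect_equal(mine$method, "exact")
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("rank conservation and U bounds hold across random inputs", {
  for (s in 1:25) {
    xy <- withr::with_seed(s, list(a = round(rnorm(sample(2:30, 1)), 1),
                                   b = round(rnorm(sample(2:30, 1)), 1)))
    r <- mann_whitney(xy$a, xy$b)
    N <- r$n1 + r$n2
    expect_equal(r$n1 * r$mr1 + r$n2 * r$mr2, N * (N + 1) / 2)
    expect_gte(r$U, 0); expect_lte(r$U, r$n1 * r$n2)
    expect_equal(r$U1 + r$U2, r$n1 * r$n2)
  }
})

test_that("normal approximation tracks the exact p for N of 8 to 12", {
  # exhaustive over every no-tie configuration and achievable U:
  # the continuity-corrected normal p stays within 0.05 of the exact p
  # everywhere, and within 0.02 wherever the exact p is at most 0.1
  worst_all <- 0; worst_tail <- 0
  for (N in 8:12) for (n1 in 2:(N - 2)) {
    n2 <- N - n1
    r <- seq_len(N)
    combos <- utils::combn(N, n1)
    U1 <- n1 * n2 + n1 * (n1 + 1) / 2 - colSums(matrix(r[combos], nrow = n1))
    mu <- n1 * n2 / 2
    for (u in unique(U1)) {
      pe <- mean(abs(U1 - mu) >= abs(u - mu) - 1e-9)
      umin <- min(u, n1 * n2 - u)
      pn <- min(1, 2 * pnorm((umin - mu + 0.5) / sqrt(n1 * n2 * (N + 1) / 12)))
      worst_all <- max(worst_all, abs(pe - pn))
      if (pe <= 0.1) worst_tail <- max(worst_tail, abs(pe - pn))
    }
  }
  expect_lt(worst_all, 0.05)
  expect_lt(worst_tail, 0.02)
})

test_that("empty samples are rejected", {
  expect_error(mann_whitney(numeric(0), 1:3), "nonempty")
  expect_error(mann_whitney(1:3, NA_real_), "nonempty")
})

test_that("signed-rank midranks and Z match the direct formula", {
  # d = {+1, -1}: tied midranks, perfectly symmetric
  r <- wilcoxon_signed_rank(c(2, 1), c(1, 2))
  expect_equal(r$mr_pos, 1.5); expect_equal(r$mr_neg, 1.5)
  expect_equal(r$Z, 0)
  # all positive differences: negative side absent
  r2 <- wilcoxon_signed_rank(c(5, 6, 7), c(1, 2, 3))
  expect_true(is.na(r2$mr_neg))
  expect_equal(r2$w_neg, 0)
  # hand-evaluated case d = {3, -1, 2, 5, -2, 4}
  a <- c(3, -1, 2, 5, -2, 4); b <- rep(0, 6)
  r3 <- wilcoxon_signed_rank(a, b)
  # oracle: ranks of |d| = 4, 1, 2.5, 6, 2.5, 5 -> W+ = 17.5, W- = 3.5
  expect_equal(r3$w_pos, 17.5); expect_equal(r3$w_neg, 3.5)
  s2 <- 6 * 7 * 13 / 24 - (2^3 - 2) / 48
  expect_equal(r3$Z, (17.5 - 10.5 - 0.5) / sqrt(s2))
  expect_equal(r3$p, 2 * pnorm(-abs(r3$Z)))
})

test_that("swapping the paired arguments swaps MR+/MR- and negates Z", {
  for (s in 1:10) {
    ab <- withr::with_seed(200 + s,
      list(a = rnorm(15), b = rnorm(15)))
    f <- wilcoxon_signed_rank(ab$a, ab$b)
    g <- wilcoxon_signed_rank(ab$b, ab$a)
    expect_equal(f$mr_pos, g$mr_neg)
    expect_equal(f$mr_neg, g$mr_pos)
    expect_equal(f$Z, -g$Z)
    expect_equal(f$p, g$p)
  }
})

test_that("zero differences are dropped; all-zero input is degenerate", {
  r <- wilcoxon_signed_rank(c(1, 2, 3, 4), c(1, 2, 1, 2))
  expect_equal(r$n_zero, 2)
  expect_equal(r$n_pos, 2)
  expect_error(wilcoxon_signed_rank(1:3, 1:3), "zero")
})

test_that("proportion sample-size formula matches its closed form", {
  # rare-condition case: raw value far below one person
  r <- required_sample_size(0.00042)
  expect_lt(r$n_raw, 1)
  expect_identical(r$n, 1L)
  # p = 0.5 worst case at 95%/5%
  r2 <- required_sample_size(0.5)
  expect_identical(r2$n, 385L)
  expect_equal(r2$n_raw, qnorm(0.975)^2 * 0.25 / 0.0025)
  # monotone in the margin of error
  margins <- c(0.01, 0.02, 0.05, 0.1)
  ns <- vapply(margins, function(e) required_sample_size(0.3, margin = e)$n,
               integer(1))
  expect_true(all(diff(ns) <= 0))
  expect_error(required_sample_size(0.5, margin = 0), "margin")
})

test_that("cohort report covers 8 metrics x 3 comparisons with stars", {
  tr <- generate_cohort(cohort_spec(n_per_group = 12, seed = 3),
                        render = FALSE)$truth
  # build a metrics-shaped table from truth parameters (statistics layer
  # does not care how the metric values were obtained)
  mk <- function(ids, region, shift = 0) {
    withr::with_seed(42 + shift * 100, {
      n <- length(ids)
      data.frame(image_id = ids, group = if (region == "HC-cover") "HC"
                 else "RRD", region = region,
                 density = runif(n) + shift, caliber_avg = rnorm(n, 6 + shift),
                 caliber_median = rnorm(n, 6 + shift),
                 tort_unweighted = rnorm(n, 20), tort_area = rnorm(n, 20),
                 tort_length = rnorm(n, 20), tort_width = rnorm(n, 20),
                 tort_width_inv = rnorm(n, 20))
    })
  }
  hc_ids <- tr$image_id[tr$group == "HC"]
  rrd_ids <- tr$image_id[tr$group == "RRD"]
  metrics <- rbind(mk(hc_ids, "HC-cover", 1), mk(rrd_ids, "RRD", 2),
                   mk(rrd_ids, "non-RRD", 3))
  rep <- compare_cohort(metrics)
  expect_equal(nrow(rep$table), 24)
  expect_setequal(unique(rep$table$test), c("Mann-Whitney", "Wilcoxon"))
  expect_true(all(rep$table$stars[rep$table$p < 0.001] == "***"))
  expect_true(all(rep$table$stars[rep$table$p >= 0.05] == ""))
  expect_s3_class(rep$radar, "ggplot")
  # Bonferroni column only on request
  expect_false("p_bonferroni" %in% names(rep$table))
  expect_true("p_bonferroni" %in%
                names(compare_cohort(metrics, bonferroni = TRUE)$table))
})
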