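#' Mann-Whitney U test with mean ranks
#'
#' Nonparametric independent two-sample comparison reporting the group mean
#' ranks — the effect summary used in ophthalmic cohort reports — together
#' with both U statistics. Ties receive midranks; the two-sided p-value
#' comes from exact enumeration of all group assignments when
#' `n1 + n2 <= 12`, otherwise from the normal approximation with
#' tie-corrected variance and continuity correction.
#'
#' @param a,b numeric samples (missing values dropped).
#' @param metric optional label carried into the result.
#' @return A `mann_whitney_result`: list with `mr1`, `mr2` (mean ranks),
#'   `n1`, `n2`, `U` (= min(U1, U2)), `U1`, `U2`, `p`, `method`
#'   (`"exact"` or `"normal"`), `metric`.
#' @export
mann_whitney <- function(a, b, metric = NA_character_) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 1 || length(b) < 1)
    stop("both samples must be nonempty")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  pooled <- c(a, b)
  r <- rank(pooled)
  stopifnot(abs(sum(r) - N * (N + 1) / 2) < 1e-8)   # rank conservation
  R1 <- sum(r[seq_len(n1)])
  mr1 <- R1 / n1
  mr2 <- (N * (N + 1) / 2 - R1) / n2
  U1 <- n1 * n2 + n1 * (n1 + 1) / 2 - R1
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  mu <- n1 * n2 / 2
  if (N <= 12) {
    method <- "exact"
    combos <- utils::combn(N, n1)
    Rperm <- colSums(matrix(r[combos], nrow = n1))
    U1perm <- n1 * n2 + n1 * (n1 + 1) / 2 - Rperm
    p <- mean(abs(U1perm - mu) >= abs(U1 - mu) - 1e-9)
  } else {
    method <- "normal"
    tt <- table(pooled)
    s2 <- n1 * n2 / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    if (s2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu + 0.5) / sqrt(s2)   # U <= mu by construction
      p <- min(1, 2 * pnorm(z))
    }
  }
  structure(list(mr1 = mr1, mr2 = mr2, n1 = n1, n2 = n2,
                 U = U, U1 = U1, U2 = U2, p = p, method = method,
                 metric = metric),
            class = "mann_whitney_result")
}

#' @export
print.mann_whitney_result <- function(x, ...) {
  cat(sprintf(
    "Mann-Whitney U: MR1 = %.2f (n1 = %d), MR2 = %.2f (n2 = %d)\n",
    x$mr1, x$n1, x$mr2, x$n2))
  cat(sprintf("  U = %.2f (U1 = %.2f, U2 = %.2f), p = %.4g [%s]\n",
              x$U, x$U1, x$U2, x$p, x$method))
  invisible(x)
}

#' Wilcoxon signed-rank test (two-tailed) with positive/negative mean ranks
#'
#' Paired nonparametric comparison. Zero differences are dropped; absolute
#' differences receive midranks; the reported mean ranks are the mean rank
#' within the positive differences (first argument larger) and within the
#' negative differences. Z uses the normal approximation with tie
#' correction and continuity correction.
#'
#' @param a,b paired numeric samples of equal length (pairs with a missing
#'   value are dropped).
#' @param metric optional label carried into the result.
#' @return A `wilcoxon_result`: list with `mr_pos`, `mr_neg`, `n_pos`,
#'   `n_neg`, `n_zero`, `w_pos`, `w_neg`, `Z`, `p`, `n` (pairs used).
#' @export
wilcoxon_signed_rank <- function(a, b, metric = NA_character_) {
  stopifnot(length(a) == length(b))
  keep <- !(is.na(a) | is.na(b))
  d <- a[keep] - b[keep]
  n <- length(d)
  n_zero <- sum(d == 0)
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) stop("all paired differences are zero; test degenerate")
  r <- rank(abs(d))
  pos <- d > 0
  w_pos <- sum(r[pos]); w_neg <- sum(r[!pos])
  stopifnot(abs(w_pos + w_neg - m * (m + 1) / 2) < 1e-8)
  mr_pos <- if (any(pos)) mean(r[pos]) else NA_real_
  mr_neg <- if (any(!pos)) mean(r[!pos]) else NA_real_
  mu <- m * (m + 1) / 4
  tt <- table(abs(d))
  s2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(tt^3 - tt) / 48
  if (s2 <= 0) {
    Z <- 0; p <- 1
  } else {
    dev <- w_pos - mu
    Z <- if (dev == 0) 0 else (dev - 0.5 * sign(dev)) / sqrt(s2)
    p <- min(1, 2 * pnorm(-abs(Z)))
  }
  structure(list(mr_pos = mr_pos, mr_neg = mr_neg,
                 n_pos = sum(pos), n_neg = sum(!pos), n_zero = n_zero,
                 w_pos = w_pos, w_neg = w_neg, Z = Z, p = p, n = n,
                 metric = metric),
            class = "wilcoxon_result")
}

#' @export
print.wilcoxon_result <- function(x, ...) {
  cat(sprintf(
    "Wilcoxon signed-rank: MR+ = %.2f (n+ = %d), MR- = %.2f (n- = %d), zeros = %d\n",
    x$mr_pos, x$n_pos, x$mr_neg, x$n_neg, x$n_zero))
  cat(sprintf("  Z = %.3f, p = %.4g (n = %d pairs)\n", x$Z, x$p, x$n))
  invisible(x)
}

#' Minimum sample size for estimating a proportion
#'
#' `n = z^2 * p * (1 - p) / eps^2`, where `z` is the two-sided
#' standard-normal quantile of the confidence level, `p` the population
#' proportion, and `eps` the margin of error; the returned count is the
#' ceiling. With a rare condition (e.g. an incidence of 0.042%) at 95%
#' confidence and a 5% margin, the requirement collapses to 1.
#'
#' @param proportion population proportion `p` in `(0, 1)`.
#' @param confidence confidence level in `(0, 1)` (default 0.95).
#' @param margin margin of error `eps > 0` (default 0.05).
#' @return A `sample_size_result`: list with `n` (integer), `n_raw`, `z`,
#'   and the inputs.
#' @export
required_sample_size <- function(proportion, confidence = 0.95,
                                 margin = 0.05) {
  stopifnot(proportion > 0, proportion < 1, confidence > 0, confidence < 1)
  if (margin <= 0) stop("margin of error must be > 0")
  z <- qnorm(1 - (1 - confidence) / 2)
  n_raw <- z^2 * proportion * (1 - proportion) / margin^2
  structure(list(n = as.integer(ceiling(n_raw)), n_raw = n_raw, z = z,
                 proportion = proportion, confidence = confidence,
                 margin = margin),
            class = "sample_size_result")
}

#' @export
print.sample_size_result <- function(x, ...) {
  cat(sprintf(
    "required n = %d (raw %.3f; z = %.4f, p = %g, margin = %g)\n",
    x$n, x$n_raw, x$z, x$proportion, x$margin))
  invisible(x)
}

.p_stars <- function(p) {
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

.metric_cols <- c("density", "caliber_avg", "caliber_median",
                  "tort_unweighted", "tort_area", "tort_length",
                  "tort_width", "tort_width_inv")

#' Cohort-level group comparisons with radar summary
#'
#' Runs, per metric, the three comparisons of the study design:
#' HC vs RRD and HC vs non-RRD by Mann-Whitney U (independent samples,
#' mean ranks reported) and paired RRD vs non-RRD by the two-tailed
#' Wilcoxon signed-rank test (pairing on `image_id`). Emits a results table
#' with mean ranks, statistics, unadjusted p-values, and significance stars
#' at 0.05 / 0.01 / 0.001, plus a radar plot of mean ranks with the eight
#' metric axes arranged anti-clockwise from density.
#'
#' @param metrics metrics table (rows from [compute_all_metrics()]), with
#'   regions `HC-cover`, `RRD`, `non-RRD`.
#' @param bonferroni add a Bonferroni-adjusted p column (off by default;
#'   the primary report carries unadjusted p with stars).
#' @return A `cohort_report`: list with `table` (data.frame) and `radar`
#'   (a ggplot object).
#' @export
compare_cohort <- function(metrics, bonferroni = FALSE) {
  stopifnot(is.data.frame(metrics))
  need <- c("image_id", "region", .metric_cols)
  if (!all(need %in% names(metrics)))
    stop("metrics table lacks columns: ",
         paste(setdiff(need, names(metrics)), collapse = ", "))
  hc <- metrics[metrics$region == "HC-cover", ]
  rrd <- metrics[metrics$region == "RRD", ]
  nonr <- metrics[metrics$region == "non-RRD", ]
  if (nrow(hc) == 0 || nrow(rrd) == 0 || nrow(nonr) == 0)
    stop("metrics table must contain regions HC-cover, RRD, and non-RRD")
  pair_ids <- intersect(rrd$image_id, nonr$image_id)
  rrd_p <- rrd[match(pair_ids, rrd$image_id), ]
  nonr_p <- nonr[match(pair_ids, nonr$image_id), ]

  rows <- list()
  for (mcol in .metric_cols) {
    mw1 <- mann_whitney(hc[[mcol]], rrd[[mcol]], metric = mcol)
    mw2 <- mann_whitney(hc[[mcol]], nonr[[mcol]], metric = mcol)
    wx <- wilcoxon_signed_rank(rrd_p[[mcol]], nonr_p[[mcol]], metric = mcol)
    rows[[length(rows) + 1]] <- data.frame(
      metric = mcol, comparison = "HC vs RRD", test = "Mann-Whitney",
      mr1 = mw1$mr1, mr2 = mw1$mr2, n1 = mw1$n1, n2 = mw1$n2,
      U = mw1$U, Z = NA_real_, p = mw1$p, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      metric = mcol, comparison = "HC vs non-RRD", test = "Mann-Whitney",
      mr1 = mw2$mr1, mr2 = mw2$mr2, n1 = mw2$n1, n2 = mw2$n2,
      U = mw2$U, Z = NA_real_, p = mw2$p, stringsAsFactors = FALSE)
    rows[[length(rows) + 1]] <- data.frame(
      metric = mcol, comparison = "RRD vs non-RRD", test = "Wilcoxon",
      mr1 = wx$mr_pos, mr2 = wx$mr_neg, n1 = wx$n, n2 = wx$n,
      U = NA_real_, Z = wx$Z, p = wx$p, stringsAsFactors = FALSE)
  }
  tab <- do.call(rbind, rows)
  tab$stars <- .p_stars(tab$p)
  if (bonferroni) tab$p_bonferroni <- pmin(1, tab$p * nrow(tab))
  structure(list(table = tab, radar = plot_rank_radar(tab)),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report> ", nrow(x$table), " comparison rows\n", sep = "")
  print(utils::head(x$table, 12))
  invisible(x)
}

#' Radar plot of mean ranks per comparison
#'
#' One panel per comparison; the eight metric axes run anti-clockwise from
#' density, mirroring the usual radar-plot summary of rank-based vascular
#' comparisons.
#'
#' @param tab the `table` element of a [compare_cohort()] report.
#' @return A ggplot object.
#' @export
plot_rank_radar <- function(tab) {
  long <- do.call(rbind, lapply(c("mr1", "mr2"), function(side) {
    data.frame(metric = tab$metric, comparison = tab$comparison,
               side = ifelse(rep(side == "mr1", nrow(tab)),
                             sub(" vs.*", "", tab$comparison),
                             sub(".*vs ", "", tab$comparison)),
               mean_rank = tab[[side]], stringsAsFactors = FALSE)
  }))
  long$metric <- factor(long$metric, levels = .metric_cols)
  long <- long[!is.na(long$mean_rank), ]
  ggplot2::ggplot(long,
                  ggplot2::aes(x = .data$metric, y = .data$mean_rank,
                               group = .data$side, colour = .data$side)) +
    ggplot2::geom_polygon(fill = NA, linewidth = 0.8) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::coord_polar(direction = -1) +
    ggplot2::facet_wrap(~comparison, nrow = 1) +
    ggplot2::labs(x = NULL, y = "mean rank", colour = NULL) +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(size = 6))
}
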