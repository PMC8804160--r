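test_that("absolute density is an exact pixel-count ratio", {
  roi <- matrix(FALSE, 10, 10); roi[1:10, 1:10] <- TRUE
  vm <- matrix(FALSE, 10, 10); vm[1:5, 1:5] <- TRUE
  expect_equal(absolute_density(vm, roi), 0.25)
  expect_equal(absolute_density(matrix(FALSE, 10, 10), roi), 0)
  expect_equal(absolute_density(roi, roi), 1)
  expect_error(absolute_density(vm, matrix(FALSE, 10, 10)), "empty|outside")
  # oracle equivalence on random maps
  for (s in 1:50) {
    mk <- withr::with_seed(s, {
      roi <- matrix(runif(400) < 0.7, 20, 20)
      vm <- matrix(runif(400) < 0.3, 20, 20) & roi
      list(roi = roi, vm = vm)
    })
    if (!any(mk$roi)) next
    num <- 0L
    for (i in 1:20) for (j in 1:20) if (mk$vm[i, j]) num <- num + 1L
    expect_identical(absolute_density(mk$vm, mk$roi), num / sum(mk$roi))
  }
})

test_that("caliber statistics follow their definitions", {
  fake_graph <- function(widths, ok = TRUE) {
    segs <- lapply(seq_along(widths), function(i)
      list(id = i, rect = min_rect(c(0, 0), max(widths[i], 10), widths[i], 0),
           caliber_ok = ok, tortuosity_ok = FALSE, seg_type = "II",
           neighbors = integer(0), pixels = cbind(1, 1)))
    structure(list(segments = segs), class = "segment_graph")
  }
  cs <- caliber_stats(fake_graph(c(4, 6)))
  expect_equal(cs$caliber_avg, 5); expect_equal(cs$caliber_median, 5)
  cs2 <- caliber_stats(fake_graph(c(3, 3, 9)))
  expect_equal(cs2$caliber_avg, 5); expect_equal(cs2$caliber_median, 3)
  # no qualified segment: missing, not zero
  cs3 <- caliber_stats(fake_graph(c(4, 6), ok = FALSE))
  expect_true(is.na(cs3$caliber_avg) && is.na(cs3$caliber_median))
})

test_that("inter-segment angles follow the type II / III rules", {
  g <- make_chain_graph(c(10, 40))
  th <- inter_segment_angles(g)
  expect_equal(unname(th), c(30, 30))        # type II on both ends
  # type III: mean of the two neighbor angles
  g3 <- make_chain_graph(c(10, 30, 70))
  th3 <- inter_segment_angles(g3)
  expect_equal(unname(th3[["2"]]), (20 + 40) / 2)
  # wraparound acute angle: orientations 170 and 10 differ by 20
  gw <- make_chain_graph(c(170, 10))
  expect_equal(unname(inter_segment_angles(gw)), c(20, 20))
  # brute-force oracle over direction representatives
  a <- 170; b <- 10
  brute <- min(abs(outer(c(a, a + 180), c(b, b + 180), "-")) %% 360)
  expect_equal(acute_line_angle(a, b), brute)
})

test_that("tortuosity schemes are the stated weighted means", {
  n <- 3
  g <- make_chain_graph(c(0, 30, 0))
  th <- inter_segment_angles(g)
  expect_equal(tortuosity(th, g, "unweighted"), mean(th))
  # straight chain: zero under every scheme
  gs <- make_chain_graph(c(45, 45, 45, 45))
  ths <- inter_segment_angles(gs)
  for (sch in c("unweighted", "area", "length", "width", "width_inv"))
    expect_equal(tortuosity(ths, gs, sch), 0)
  # hand-computed weighted cases: angles {10, 30}, widths {1, 3}
  segs <- list(
    list(id = 1, rect = min_rect(c(0, 0), 10, 1, 0), neighbors = 2L,
         seg_type = "II", caliber_ok = TRUE, tortuosity_ok = TRUE),
    list(id = 2, rect = min_rect(c(0, 0), 10, 3, 10), neighbors = 1L,
         seg_type = "II", caliber_ok = TRUE, tortuosity_ok = TRUE))
  gg <- structure(list(segments = segs), class = "segment_graph")
  ang <- c(`1` = 10, `2` = 30)
  expect_equal(tortuosity(ang, gg, "width"), (10 * 1 + 30 * 3) / 4)
  expect_equal(tortuosity(ang, gg, "width_inv"),
               (10 * 1 + 30 / 3) / (1 + 1 / 3))
  expect_equal(tortuosity(ang, gg, "length"), 20)   # equal lengths
  expect_equal(tortuosity(ang, gg, "area"), (10 * 10 + 30 * 30) / 40)
  # no angles: missing value
  expect_true(is.na(tortuosity(numeric(0), gg, "unweighted")))
})

test_that("identical rectangles collapse all five schemes to one value", {
  g <- make_chain_graph(c(0, 20, 50, 85, 110), L = 17, W = 4)
  th <- inter_segment_angles(g)
  vals <- vapply(c("unweighted", "area", "length", "width", "width_inv"),
                 function(s) tortuosity(th, g, s), numeric(1))
  expect_lt(max(vals) - min(vals), 1e-9)
  # weighted means stay inside the angle range
  expect_gte(min(vals), min(th)); expect_lte(max(vals), max(th))
})

test_that("the full metric pipeline is deterministic and NA-safe", {
  tr <- grow_vessel_tree(21, image_size = c(200, 200))
  rend <- render_fundus(tr, noise_sd = 5)
  roi <- make_general_cover(200, 200)
  m1 <- compute_all_metrics(rend$image, roi)
  m2 <- compute_all_metrics(rend$image, roi)
  expect_identical(m1, m2)
  expect_true(all(c("density", "caliber_avg", "tort_width_inv") %in%
                    names(m1)))
  # blank image: zero density, missing caliber and tortuosity
  blank <- compute_all_metrics(flat_image(), make_general_cover(64, 64))
  expect_equal(blank$density, 0)
  expect_true(is.na(blank$caliber_avg))
  expect_true(is.na(blank$tort_unweighted))
})

test_that("density and caliber scale correctly under a x2 upscale", {
  # metric layer on ground-truth maps: rasterizing the same tree geometry
  # at doubled resolution preserves density and doubles the fitted caliber.
  # qualification criteria are expressed in pixels, so they scale with the
  # resolution alongside the run length.
  scale_tree <- function(tr, s) {
    tr$polylines <- lapply(tr$polylines, function(p) p * s)
    tr$widths <- tr$widths * s
    tr$disc_center <- tr$disc_center * s
    tr$disc_radius <- tr$disc_radius * s
    tr$image_size <- tr$image_size * s
    tr
  }
  measure <- function(tr, s) {
    vm <- rasterize_tree(tr)
    g <- qualify_segments(partition_segments(vm, 20 * s),
                          optic_disc(tr$disc_center, tr$disc_radius),
                          qualify_params(min_L = 8 * s, max_L = 40 * s))
    c(density = absolute_density(
        vm, matrix(TRUE, tr$image_size[1], tr$image_size[2])),
      caliber = caliber_stats(g)$caliber_avg)
  }
  for (sd_i in c(31, 41)) {
    tr <- grow_vessel_tree(sd_i, n_roots = 4, bend_amplitude = 8,
                           width_root = 5, image_size = c(128, 128))
    m1 <- measure(tr, 1)
    m2 <- measure(scale_tree(tr, 2), 2)
    expect_lt(abs(m2["density"] - m1["density"]), 0.02)
    expect_lt(abs(m2["caliber"] - 2 * m1["caliber"]), 1.5)
  }
})

test_that("a reduced-caliber group is recovered with the correct sign", {
  correct <- 0L
  for (rep_i in 1:20) {
    sp <- cohort_spec(n_per_group = 20, effect_caliber = 0.7,
                      image_size = c(144, 144), seed = 1000 + rep_i,
                      base_width = 6)
    co <- generate_cohort(sp)
    roi <- make_general_cover(144, 144)
    cal <- vapply(names(co$images), function(id) {
      compute_all_metrics(co$images[[id]], roi)$caliber_avg
    }, numeric(1))
    grp <- co$truth$group[match(names(co$images), co$truth$image_id)]
    d <- mean(cal[grp == "HC"], na.rm = TRUE) -
      mean(cal[grp == "RRD"], na.rm = TRUE)
    if (is.finite(d) && d > 0) correct <- correct + 1L
  }
  expect_gte(correct, 18)
})
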