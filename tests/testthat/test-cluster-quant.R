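test_that("single-order entropy threshold equals the brute-force search", {
  set.seed(101)
  for (i in 1:60) {
    counts <- stats::rpois(256, lambda = stats::rexp(256, 0.2))
    if (sum(counts > 0) < 2) next
    for (rho in c(0.5, 1, 2)) {
      expect_identical(renyi_threshold(counts, "single_order", rho = rho),
                       oracle_renyi_single(counts, rho))
    }
  }
  ## uniform histogram: agreement including the documented low tie-break
  uni <- rep(10L, 256)
  expect_identical(renyi_threshold(uni, "single_order", rho = 1),
                   oracle_renyi_single(uni, 1))
})

test_that("two well-separated modes are split between them", {
  counts <- integer(256); counts[11] <- 100; counts[201] <- 100
  for (m in list(c("single_order", 1), c("single_order", 0.5),
                 c("single_order", 2))) {
    t <- renyi_threshold(counts, m[1], rho = as.numeric(m[2]))
    expect_gte(t, 11); expect_lt(t, 201)
  }
  t <- renyi_threshold(counts, "sahoo_combined")
  expect_gte(t, 11); expect_lt(t, 201)
})

test_that("degenerate histograms are rejected", {
  counts <- integer(256); counts[5] <- 50
  expect_error(renyi_threshold(counts), "degenerate")
  expect_error(renyi_threshold(integer(256)), "degenerate")
})

test_that("auto threshold is covariant under integer intensity shifts", {
  set.seed(7)
  frame <- matrix(stats::rpois(64 * 64, 40) +
                    200 * (stats::runif(64 * 64) < 0.1), 64, 64)
  t0 <- auto_threshold(frame)
  for (shift in c(5L, 137L)) {
    expect_equal(auto_threshold(frame + shift), t0 + shift)
  }
  ## constant frame: empty foreground, not an error
  expect_equal(auto_threshold(matrix(7, 8, 8)), 7)
})

test_that("maximum-intensity projection matches the element-wise oracle", {
  a <- matrix(1:6, 2, 3)
  expect_identical(project_stack(list(a)), a)
  expect_identical(project_stack(list(a, 2 * a)), 2 * a)
  set.seed(11)
  z <- array(stats::rnorm(4 * 5 * 6), dim = c(4, 5, 6))
  want <- pmax(z[1, , ], z[2, , ], z[3, , ], z[4, , ])
  expect_equal(project_stack(z), want)
  expect_error(project_stack(list()), "empty")
})

test_that("component labelling is 8-connected and matches a flood fill", {
  m <- matrix(0, 6, 6); m[2, 2] <- 1; m[3, 3] <- 1   # diagonal touch
  expect_equal(max(label_components(m)), 1L)
  set.seed(13)
  for (i in 1:5) {
    mask <- matrix(stats::runif(30 * 30) < 0.35, 30, 30)
    got <- label_components(mask)
    want <- oracle_label8(mask)
    ## same partition (labels may be numbered differently)
    expect_equal(max(got), max(want))
    key <- paste(got[mask], want[mask])
    expect_equal(length(unique(key)), max(want))
  }
})

test_that("cluster extraction enforces the physical size window", {
  px <- 0.16
  blank <- matrix(100, 128, 128)
  expect_equal(nrow(segment_clusters(blank, px, threshold = 150)), 0L)

  frame <- matrix(100, 128, 128)
  frame <- paint_disk(frame, 30, 30, 2.0, px, 500)    # in window
  frame <- paint_disk(frame, 90, 90, 20.0, px, 500)   # too large
  frame <- paint_disk(frame, 30, 96, 0.5, px, 500)    # too small
  cl <- segment_clusters(frame, px, threshold = 300)
  expect_equal(nrow(cl), 1L)
  ## the reported area equals the painted pixel count exactly
  r_px <- sqrt(2.0 / pi) / px
  yy <- matrix(1:128, 128, 128); xx <- t(yy)
  painted <- sum((yy - 30)^2 + (xx - 30)^2 <= r_px^2)
  expect_equal(cl$area, painted * px^2)
  expect_lt(abs(cl$cx - 29), 1)   # 0-based centroid of the painted disk
  expect_lt(abs(cl$cy - 29), 1)
  expect_equal(cl$mean_intensity, 500)

  ## property: never a record outside the window
  set.seed(17)
  for (i in 1:5) {
    f <- matrix(stats::rpois(128 * 128, 50), 128, 128)
    n_disks <- sample(3:8, 1)
    for (k in seq_len(n_disks))
      f <- paint_disk(f, stats::runif(1, 15, 110), stats::runif(1, 15, 110),
                      stats::runif(1, 0.2, 25), px, 400)
    cl <- segment_clusters(f, px, threshold = 200)
    if (nrow(cl)) {
      expect_true(all(cl$area >= 0.8 & cl$area <= 10.0))
    }
  }
})

test_that("frame metrics are exact and order-invariant", {
  empty <- segment_clusters(matrix(0, 8, 8), 0.16, threshold = 10)
  m <- frame_metrics(empty, 0)
  expect_equal(m$n_clusters, 0L)
  expect_equal(m$total_area, 0)
  expect_true(is.nan(m$mean_area))

  cl <- data.frame(label = 1:2, area = c(1, 3), cx = c(0, 1), cy = c(0, 1),
                   mean_intensity = c(10, 20))
  m <- frame_metrics(cl, 5)
  expect_equal(m$total_area, 4); expect_equal(m$mean_area, 2)
  expect_equal(m$n_clusters, 2L)
  m_rev <- frame_metrics(cl[2:1, ], 5)
  expect_equal(m_rev$total_area, m$total_area)
  expect_equal(m_rev$mean_area, m$mean_area)

  set.seed(19)
  areas <- stats::runif(12, 0.8, 10)
  cl <- data.frame(label = 1:12, area = areas, cx = 0, cy = 0,
                   mean_intensity = stats::runif(12, 50, 500))
  m <- frame_metrics(cl, 1)
  expect_equal(m$total_area, sum(areas))
  expect_equal(m$mean_area, mean(areas))
})

test_that("growth rates recover planted linear trends exactly", {
  t <- seq(0, 180, by = 20)
  mk <- function(n) data.frame(frame_time = t, n_clusters = n,
                               total_area = 2 * n, mean_area = 2,
                               mean_intensity = 100)
  ## constant metric: slope 0
  s <- cluster_time_series(mk(rep(4, 10)), addition_time = 90)
  r <- growth_rates(s)
  expect_equal(r$slope[r$metric == "n_clusters" & r$segment == "post"], 0)
  ## exact linear: count = 2 + 1.5 t
  s <- cluster_time_series(mk(2 + 1.5 * t), addition_time = 90)
  r <- growth_rates(s)
  expect_equal(r$slope[r$metric == "n_clusters" & r$segment == "post"], 1.5,
               tolerance = 1e-10)
  expect_equal(r$slope[r$metric == "total_area" & r$segment == "post"], 3,
               tolerance = 1e-10)
  ## fewer than two post frames is an error
  expect_error(growth_rates(cluster_time_series(mk(rep(1, 10)),
                                                addition_time = 175)),
               "post-addition")
})

test_that("the full stack pipeline recovers planted dynamics and is deterministic", {
  sim <- synth_cluster_timelapse(n_pre = 4, n_post = 12, count_slope = 1.0,
                                 frame_interval = 20, initial_count = 5,
                                 dim_yx = c(160L, 160L), seed = 31)
  q1 <- quantify_stack(sim$stack, sim$truth$addition_time)
  q2 <- quantify_stack(sim$stack, sim$truth$addition_time)
  expect_identical(q1$series$metrics, q2$series$metrics)  # re-run identical

  planted <- 1.0 / 20   # clusters per second
  got <- q1$rates$slope[q1$rates$metric == "n_clusters" &
                        q1$rates$segment == "post"]
  expect_lt(abs(got - planted) / planted, 0.15)

  sc <- score_detections(sim$truth$clusters, q1$clusters)
  expect_gte(sc[["recall"]], 0.9)
  expect_gte(sc[["precision"]], 0.9)

  ## zero planted slopes: post slopes near zero
  sim0 <- synth_cluster_timelapse(n_pre = 3, n_post = 8, count_slope = 0,
                                  mean_area_slope = 0, initial_count = 6,
                                  dim_yx = c(160L, 160L), seed = 32)
  q0 <- quantify_stack(sim0$stack, sim0$truth$addition_time)
  post <- q0$rates[q0$rates$segment == "post", ]
  sl <- post$slope[post$metric == "n_clusters"]
  se <- post$se[post$metric == "n_clusters"]
  expect_lt(abs(sl), 4 * max(se, 1e-3))

  expect_error(quantify_stack(sim$stack, sim$truth$addition_time,
                              channel = "SV2A"),
               "channel")
})
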