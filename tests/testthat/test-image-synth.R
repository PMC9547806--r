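test_that("time-lapse ground truth follows the planted rates", {
  ## zero slopes: constant planted count
  sim0 <- synth_cluster_timelapse(n_pre = 2, n_post = 6, count_slope = 0,
                                  mean_area_slope = 0, initial_count = 5,
                                  dim_yx = c(96L, 96L), noise = FALSE, seed = 2)
  post <- sim0$truth$per_frame[-(1:2), ]
  expect_true(all(post$planted_count == 5L))
  expect_true(all(sim0$truth$per_frame$planted_count[1:2] == 0L))

  ## fractional slope: count follows round(initial + slope * k)
  sim <- synth_cluster_timelapse(n_pre = 2, n_post = 10, count_slope = 1.5,
                                 initial_count = 4, dim_yx = c(160L, 160L),
                                 noise = FALSE, seed = 3)
  post <- sim$truth$per_frame[-(1:2), ]
  expect_equal(post$planted_count, as.integer(round(4 + 1.5 * (0:9))))

  ## truth areas respect the configured window
  expect_true(all(sim$truth$clusters$area_um2 >= 0.5))  # pixelation slack
  expect_true(all(sim$truth$clusters$area_um2 <= 10.5))
})

test_that("rendered signal matches the planted photon budget", {
  sim_nf <- synth_cluster_timelapse(n_pre = 2, n_post = 3, count_slope = 0,
                                    initial_count = 4, dim_yx = c(96L, 96L),
                                    noise = FALSE, seed = 5)
  sim_n <- synth_cluster_timelapse(n_pre = 2, n_post = 3, count_slope = 0,
                                   initial_count = 4, dim_yx = c(96L, 96L),
                                   noise = TRUE, seed = 5)
  for (f in 1:5) {
    expected_total <- sum(sim_nf$stack$data[f, 1, , ])
    observed_total <- sum(sim_n$stack$data[f, 1, , ])
    ## Poisson: sd of the frame total is sqrt(total expectation)
    expect_lt(abs(observed_total - expected_total),
              3 * sqrt(expected_total) +
                3 * sqrt(prod(dim(sim_n$stack$data)[3:4])) * 2)
  }
})

test_that("generators are bit-deterministic given the seed", {
  a <- synth_cluster_timelapse(n_pre = 2, n_post = 3, dim_yx = c(64L, 64L),
                               seed = 9)
  b <- synth_cluster_timelapse(n_pre = 2, n_post = 3, dim_yx = c(64L, 64L),
                               seed = 9)
  expect_identical(a$stack$data, b$stack$data)
  expect_identical(a$truth$clusters, b$truth$clusters)

  n1 <- synth_nmj_image(seed = 4); n2 <- synth_nmj_image(seed = 4)
  expect_identical(n1$stack$data, n2$stack$data)

  f1 <- synth_flow_events(500, seed = 7); f2 <- synth_flow_events(500, seed = 7)
  expect_identical(f1$igg, f2$igg)

  t1 <- synth_calcium_traces(seed = 3); t2 <- synth_calcium_traces(seed = 3)
  expect_identical(t1$traces, t2$traces)
})

test_that("NMJ renders encode the planted retention, complement and fragments", {
  for (nf in c(0L, 1L, 4L)) {
    sim <- synth_nmj_image(n_fragments = nf, achr_retention = 0.5,
                           c3_level = 300, noise = FALSE, seed = nf + 1L)
    tr <- sim$truth
    btx <- sim$stack$data[1, 1, , ]
    sv2a <- sim$stack$data[1, 2, , ]
    c3 <- sim$stack$data[1, 3, , ]
    bg <- 100   # default optics background
    expect_equal(max(tr$fragment_label), nf)
    if (nf == 0L) {
      expect_true(all(btx == bg))   # blank receptor channel
    } else {
      ## mask-mean BTX over mask-mean SV2A equals retention exactly
      ratio <- (mean(btx[tr$mask]) - bg) / (mean(sv2a[tr$mask]) - bg)
      expect_equal(ratio, 0.5, tolerance = 1e-12)
    }
    expect_equal(mean(c3[tr$mask]) - bg, 300, tolerance = 1e-12)
    ## fragments are disjoint and inside the junction mask
    expect_true(all(tr$mask[tr$fragment_label > 0]))
  }
  ## retention = 1, one fragment covering content: ratio 1 inside mask
  sim1 <- synth_nmj_image(n_fragments = 1, achr_retention = 1,
                          noise = FALSE, seed = 2)
  tr <- sim1$truth
  btx <- sim1$stack$data[1, 1, , ]; sv2a <- sim1$stack$data[1, 2, , ]
  expect_equal((mean(btx[tr$mask]) - 100) / (mean(sv2a[tr$mask]) - 100), 1,
               tolerance = 1e-12)
  expect_error(synth_nmj_image(achr_retention = 1.2), "retention")
  expect_error(synth_nmj_image(n_fragments = -1), "n_fragments")
})

test_that("flow event tables carry the planted populations and ratios", {
  expect_error(synth_flow_events(100, frac_transfected = 0), "strictly")
  expect_error(synth_flow_events(100, binding_ratio = 0), "> 0")

  ev <- synth_flow_events(1000, frac_transfected = 0.5, seed = 21)
  n_pos <- sum(ev$population == "pos")
  expect_lt(abs(n_pos - 500), 3 * sqrt(250))   # binomial bound

  ## planted geometric-mean ratio is encoded in the channel populations
  ev10 <- synth_flow_events(10000, binding_ratio = 10, seed = 22)
  gm <- function(x) exp(mean(log(x)))
  recovered <- gm(ev10$igg[ev10$population == "pos"]) /
    gm(ev10$igg[ev10$population == "neg"])
  expect_lt(abs(recovered - 10) / 10, 0.05)

  ev1 <- synth_flow_events(10000, binding_ratio = 1, seed = 23)
  recovered1 <- gm(ev1$igg[ev1$population == "pos"]) /
    gm(ev1$igg[ev1$population == "neg"])
  expect_lt(abs(recovered1 - 1), 0.05)
})

test_that("calcium traces peak at the planted amplitude", {
  tr0 <- synth_calcium_traces(n_wells = 4, peak_amplitude = 0, noise_sd = 3,
                              seed = 5)
  for (w in 1:4)
    expect_lt(abs(trace_peak(tr0$traces[w, ], tr0$stim_index)), 4 * 3)

  tre <- synth_calcium_traces(n_wells = 3, peak_amplitude = 80, noise_sd = 0,
                              seed = 6)
  for (w in 1:3)
    expect_equal(trace_peak(tre$traces[w, ], tre$stim_index), 80)

  trn <- synth_calcium_traces(n_wells = 20, peak_amplitude = 100,
                              noise_sd = 4, seed = 7)
  peaks <- vapply(seq_len(20), function(w)
    trace_peak(trn$traces[w, ], trn$stim_index), 0)
  expect_lt(abs(mean(peaks) - 100), 3 * 4)
  expect_error(synth_calcium_traces(stim_index = 0), "stim_index")
})

test_that("image stacks round-trip through TIFF + JSON bit-identically", {
  sim <- synth_nmj_image(n_fragments = 2, dim_yx = c(64L, 64L), seed = 8)
  path <- file.path(tempdir(), "roundtrip.tif")
  write_image_stack(sim$stack, path)
  back <- read_image_stack(path)
  expect_identical(back$data, sim$stack$data)
  expect_identical(back$channel_names, sim$stack$channel_names)
  expect_equal(back$pixel_size, sim$stack$pixel_size)
  expect_equal(back$frame_times, sim$stack$frame_times)
  unlink(c(path, paste0(path, ".json")))
})

test_that("rendered crosslink fields place aggregates at one bright spot", {
  ## empty graph: background only
  g0 <- simulate_binding(make_receptor_pool(5), list(), seed = 1)
  pos <- cbind(runif(5, 1, 4), runif(5, 1, 4))
  r0 <- render_simulated_field(g0, noise = FALSE, field_um = 5, seed = 2,
                               positions = pos)
  expect_equal(max(r0$frame) > 100, TRUE)      # emitters present
  expect_equal(nrow(r0$truth), 5L)
  expect_true(all(r0$truth$component_size == 1L))

  ## photon budget: integrated intensity above background ~ emitters x scale
  opt <- optics_params()
  total_sig <- sum(r0$frame - opt$background_level)
  expect_equal(total_sig, 5 * opt$photon_scale, tolerance = 0.05)

  ## aggregate members are rendered condensed around a common centroid
  pool <- make_receptor_pool(10, c(alpha = 2L, delta = 1L))
  g <- simulate_binding(pool, list(antibody_species("a", "alpha", 10),
                                   antibody_species("d", "delta", 10)),
                        binding_params(k_cross = 50), seed = 3)
  pos10 <- cbind(runif(10, 1, 7), runif(10, 1, 7))
  r <- render_simulated_field(g, noise = FALSE, field_um = 8,
                              jitter_um = 0.15, seed = 4, positions = pos10)
  px <- optics_params()$pixel_size
  for (comp in unique(r$truth$component)) {
    mem <- r$truth[r$truth$component == comp, ]
    if (nrow(mem) > 1) {
      spread <- sqrt((mem$x_px - mean(mem$x_px))^2 +
                     (mem$y_px - mean(mem$y_px))^2) * px
      expect_true(all(spread < 5 * 0.15))   # within the jitter scale
    }
  }
  expect_error(render_simulated_field(g, noise = FALSE, seed = 4),
               "positions")
})
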