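test_that("receptor pools carry the pentamer stoichiometry", {
  pool <- make_receptor_pool(3)
  expect_equal(pool$n, 3L)
  expect_equal(sum(pool$stoichiometry), 5L)
  expect_equal(pool$stoichiometry[["alpha"]], 2L)
  expect_equal(unname(pool$stoichiometry[c("beta", "delta", "epsilon")]),
               c(1L, 1L, 1L))

  small <- make_receptor_pool(1, c(alpha = 2L))
  expect_equal(small$stoichiometry, c(alpha = 2L))

  expect_error(make_receptor_pool(0), "n")
  expect_error(make_receptor_pool(5, c(alpha = -1L)), "non-negative")
  expect_error(make_receptor_pool(5, c(alpha = 0L)), "at least one epitope")
})

test_that("binding simulation handles edge cases and rejects bad input", {
  pool <- make_receptor_pool(5)
  g <- simulate_binding(pool, list(), seed = 1)
  expect_equal(nrow(g$antibodies), 0L)
  expect_equal(component_stats(g)$component_sizes, rep(1L, 5))

  expect_error(
    simulate_binding(pool, list(antibody_species("x", "gamma", 5)), seed = 1),
    "unknown target")
})

test_that("simulation is deterministic given the seed", {
  pool <- make_receptor_pool(40)
  sp <- list(antibody_species("a", "alpha", 30),
             antibody_species("b", "beta", 30))
  g1 <- simulate_binding(pool, sp, seed = 11)
  g2 <- simulate_binding(pool, sp, seed = 11)
  expect_identical(g1$antibodies, g2$antibodies)
  expect_identical(g1$occupancy, g2$occupancy)
  g3 <- simulate_binding(pool, sp, seed = 12)
  expect_false(identical(g1$antibodies, g3$antibodies))
})

test_that("structural invariants hold after simulation, any parameters", {
  pool <- make_receptor_pool(30)
  cases <- list(
    list(sp = list(antibody_species("b", "beta", 60)), p = binding_params()),
    list(sp = list(antibody_species("a", "alpha", 20),
                   antibody_species("d", "delta", 20)),
         p = binding_params(k_cross = 5)),
    list(sp = list(antibody_species("a", "alpha", 40)),
         p = binding_params(allow_intra_receptor = TRUE)),
    list(sp = list(antibody_species("a", "alpha", 15)),
         p = binding_params(allow_cycles = FALSE)),
    list(sp = list(antibody_species("e", "epsilon", 25)),
         p = binding_params(max_events = 17))
  )
  for (cs in cases) for (s in 1:5) {
    g <- simulate_binding(pool, cs$sp, cs$p, seed = s)
    expect_true(validate_crosslink_graph(g))
  }
})

test_that("a single non-alpha species mediates dimerization only", {
  pool <- make_receptor_pool(25)
  for (target in c("beta", "delta", "epsilon")) {
    for (s in 1:10) {
      g <- simulate_binding(pool,
                            list(antibody_species("x", target, 50)),
                            binding_params(k_cross = s %% 3 + 0.5), seed = s)
      expect_lte(component_stats(g)$max_size, 2L)
    }
  }
})

test_that("a single anti-alpha species yields chains: receptor degree <= 2", {
  pool <- make_receptor_pool(30)
  for (s in 1:15) {
    g <- simulate_binding(pool, list(antibody_species("a", "alpha", 30)),
                          seed = s)
    expect_lte(max(receptor_degrees(g)), 2L)
  }
})

test_that("cycle ban yields acyclic aggregates (edges < receptors per component)", {
  pool <- make_receptor_pool(20)
  for (s in 1:5) {
    g <- simulate_binding(pool, list(antibody_species("a", "alpha", 20)),
                          binding_params(allow_cycles = FALSE), seed = s)
    linked <- g$antibodies[!is.na(g$antibodies$receptor2), ]
    sizes <- oracle_component_sizes(g)
    ## a forest has exactly n - (number of components) edges
    expect_equal(nrow(linked), g$n_receptors - length(sizes))
  }
})

test_that("intra-receptor binding is off by default and works when enabled", {
  pool <- make_receptor_pool(1)   # one receptor: only intra binding possible
  sp <- list(antibody_species("a", "alpha", 3))
  g_off <- simulate_binding(pool, sp, seed = 1)
  expect_true(all(is.na(g_off$antibodies$receptor2)))
  intra_seen <- FALSE
  for (s in 1:10) {
    g_on <- simulate_binding(pool, sp,
                             binding_params(allow_intra_receptor = TRUE),
                             seed = s)
    expect_true(validate_crosslink_graph(g_on))
    if (any(stats::na.omit(g_on$antibodies$receptor2) == 1)) intra_seen <- TRUE
  }
  expect_true(intra_seen)
})

test_that("component statistics match an independent union-find oracle", {
  pool <- make_receptor_pool(50)
  for (s in 1:8) {
    g <- simulate_binding(pool,
                          list(antibody_species("a", "alpha", 30),
                               antibody_species("e", "epsilon", 30)),
                          seed = s)
    st <- component_stats(g)
    expect_equal(st$component_sizes, oracle_component_sizes(g))
    expect_equal(sum(st$component_sizes), 50L)
    expect_gte(st$max_size, st$mean_size)
    expect_gte(st$mean_size, 1)
  }
})

test_that("complement proxy equals the direct recount and handles extremes", {
  singleton_stats <- component_stats(
    simulate_binding(make_receptor_pool(4), list(), seed = 1))
  expect_equal(complement_proxy(singleton_stats, 2), 0)

  pool <- make_receptor_pool(4)
  g <- simulate_binding(pool, list(antibody_species("b", "beta", 1)),
                        binding_params(max_events = 2), seed = 3)
  st <- component_stats(g)
  if (st$max_size == 2) expect_equal(complement_proxy(st, 2), 0.5)

  for (s in 1:5) {
    st <- component_stats(simulate_binding(
      make_receptor_pool(60),
      list(antibody_species("a", "alpha", 30),
           antibody_species("d", "delta", 30)), seed = s))
    for (k in c(1, 2, 4, 8)) {
      direct <- sum(st$component_sizes[st$component_sizes >= k]) /
        sum(st$component_sizes)
      expect_equal(complement_proxy(st, k), direct)
    }
    fr <- receptor_fraction_ge(st, 1:10)
    expect_true(all(diff(fr) <= 1e-12))
    expect_true(all(fr >= 0 & fr <= 1))
  }
  expect_error(complement_proxy(singleton_stats, 0), "s_min")
})

test_that("small-system outcome distribution matches exact enumeration", {
  pool <- make_receptor_pool(4)
  sp <- list(antibody_species("a", "alpha", 2))
  enum <- enumerate_binding_outcomes(pool, sp)
  expect_equal(sum(enum$probability), 1, tolerance = 1e-12)
  n_sim <- 1500
  set.seed(91)
  run_seeds <- sample.int(2^31 - 2, n_sim)   # scattered, not consecutive
  obs <- table(vapply(run_seeds, function(s)
    paste(component_stats(simulate_binding(pool, sp, seed = s))$component_sizes,
          collapse = "+"), ""))
  counts <- as.integer(obs[enum$outcome])
  counts[is.na(counts)] <- 0L
  expect_equal(sum(counts), n_sim)   # no outcomes outside the enumeration
  p <- stats::chisq.test(counts, p = enum$probability)$p.value
  expect_gt(p, 0.01)
})

test_that("mixed-specificity enumeration also matches the simulator", {
  pool <- make_receptor_pool(3)
  sp <- list(antibody_species("a", "alpha", 1),
             antibody_species("d", "delta", 1))
  enum <- enumerate_binding_outcomes(pool, sp, binding_params(k_cross = 2))
  expect_equal(sum(enum$probability), 1, tolerance = 1e-12)
  n_sim <- 1200
  set.seed(92)
  run_seeds <- sample.int(2^31 - 2, n_sim)
  obs <- table(vapply(run_seeds, function(s)
    paste(component_stats(simulate_binding(pool, sp,
                                           binding_params(k_cross = 2),
                                           seed = s))$component_sizes,
          collapse = "+"), ""))
  counts <- as.integer(obs[enum$outcome])
  counts[is.na(counts)] <- 0L
  expect_equal(sum(counts), n_sim)
  p <- stats::chisq.test(counts, p = enum$probability)$p.value
  expect_gt(p, 0.01)
})

test_that("combination sweep has the expected shape and synergy ordering", {
  single <- sweep_combinations(
    60L, list(antibody_species("b", "beta", 0)), seeds = 1:3)
  expect_equal(nrow(single), 1L)
  expect_equal(single$species_a, single$species_b)

  panel <- list(antibody_species("anti-beta", "beta", 0),
                antibody_species("anti-beta2", "beta", 0),
                antibody_species("anti-delta", "delta", 0))
  sw <- sweep_combinations(80L, panel, seeds = 1:6)
  expect_equal(nrow(sw), 6L)   # 3 singles + 3 pairs
  get <- function(a, b) sw[(sw$species_a == a & sw$species_b == b) |
                           (sw$species_a == b & sw$species_b == a), ]
  bb <- get("anti-beta", "anti-beta2")
  best_single <- max(get("anti-beta", "anti-beta")$proxy_mean,
                     get("anti-beta2", "anti-beta2")$proxy_mean)
  ## same-subunit pair: no enhancement beyond seed noise
  expect_lte(bb$proxy_mean,
             best_single + 2 * bb$proxy_sd / sqrt(bb$n_seeds) + 1e-9)
  ## different-subunit pair: exceeds both singles
  bd <- get("anti-beta", "anti-delta")
  expect_gt(bd$proxy_mean, get("anti-beta", "anti-beta")$proxy_mean)
  expect_gt(bd$proxy_mean, get("anti-delta", "anti-delta")$proxy_mean)
  expect_gt(bd$mean_size_mean, 2)   # beyond the dimer ceiling of the singles
})

test_that("geometric mode restricts crosslinks to the capture radius", {
  pool <- make_receptor_pool(12, c(beta = 1L))
  ## two tight clusters of 6 receptors, 2 um apart: crosslinks never bridge
  pos <- rbind(cbind(runif(6, 0, 0.05), runif(6, 0, 0.05)),
               cbind(2 + runif(6, 0, 0.05), runif(6, 0, 0.05)))
  for (s in 1:5) {
    g <- simulate_binding(pool, list(antibody_species("b", "beta", 24)),
                          binding_params(mode = "geometric",
                                         capture_radius = 100),
                          seed = s, positions = pos)
    linked <- g$antibodies[!is.na(g$antibodies$receptor2), ]
    if (nrow(linked)) {
      same_side <- (linked$receptor1 <= 6) == (linked$receptor2 <= 6)
      expect_true(all(same_side))
    }
  }
})
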