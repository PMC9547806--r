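## ---------------------------------------------------------------------------
## Orchestration: per-stage seed derivation, fixture-suite generation, and
## the end-to-end run simulate -> render -> quantify -> synergy statistics.
## ---------------------------------------------------------------------------

#' Derive a per-stage seed from a global seed
#'
#' Deterministic counter scheme: stage `k` of global seed `s` uses
#' `(s * 1000 + k) mod 2^31`, so any stage can be re-run independently of
#' the others with the same stream.
#'
#' @param seed Global integer seed.
#' @param stage Stage counter (0, 1, 2, ...).
#' @return Integer seed.
#' @export
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) * 1000 + stage) %% 2^31)
}

#' Generate the documented synthetic fixture suite
#'
#' Writes a self-describing set of synthetic datasets with ground-truth
#' sidecars: clustering time-lapses at three signal-to-noise levels,
#' NMJ images at fragment counts 1, 2, 4 and 8, flow event tables at
#' planted GMFI ratios 1, 2, 5 and 10, a calcium trace set, and a
#' simulator combination sweep.  The same seed reproduces the same files
#' byte for byte.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Global seed; expanded per stage with [stage_seed()].
#' @return Data frame manifest (`file`, `kind`) of everything written,
#'   invisibly; also saved as `manifest.csv`.
#' @export
generate_fixture_suite <- function(outdir, seed = 1L) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(outdir)) stop("cannot create ", outdir, call. = FALSE)
  manifest <- list()
  note <- function(file, kind)
    manifest[[length(manifest) + 1L]] <<- data.frame(file = file, kind = kind)

  ## clustering time-lapses at three cluster amplitudes (SNR levels)
  amps <- c(low = 150, mid = 400, high = 800)
  for (i in seq_along(amps)) {
    sim <- synth_cluster_timelapse(n_pre = 3, n_post = 8,
                                   cluster_amplitude = amps[[i]],
                                   dim_yx = c(128L, 128L),
                                   seed = stage_seed(seed, i))
    f <- file.path(outdir, sprintf("timelapse_%s.tif", names(amps)[i]))
    write_image_stack(sim$stack, f)
    utils::write.csv(sim$truth$clusters,
                     sub("\\.tif$", "_truth.csv", f), row.names = FALSE)
    note(f, "timelapse"); note(sub("\\.tif$", "_truth.csv", f), "truth")
  }

  ## NMJ images across fragment counts
  for (nf in c(1L, 2L, 4L, 8L)) {
    sim <- synth_nmj_image(n_fragments = nf, achr_retention = 0.6,
                           c3_level = 250, dim_yx = c(128L, 128L),
                           seed = stage_seed(seed, 10L + nf))
    f <- file.path(outdir, sprintf("nmj_frag%d.tif", nf))
    write_image_stack(sim$stack, f)
    jsonlite::write_json(
      sim$truth[c("n_fragments", "achr_retention", "c3_level")],
      sub("\\.tif$", "_truth.json", f), auto_unbox = TRUE, digits = NA)
    note(f, "nmj"); note(sub("\\.tif$", "_truth.json", f), "truth")
  }

  ## flow event tables across planted ratios
  for (r in c(1, 2, 5, 10)) {
    ev <- synth_flow_events(n_events = 5000L, binding_ratio = r,
                            seed = stage_seed(seed, 20L + r))
    f <- file.path(outdir, sprintf("flow_ratio%g.csv", r))
    utils::write.csv(ev, f, row.names = FALSE)
    note(f, "flow")
  }

  ## calcium traces
  tr <- synth_calcium_traces(seed = stage_seed(seed, 30L))
  f <- file.path(outdir, "calcium_traces.csv")
  utils::write.csv(as.data.frame(tr$traces), f, row.names = FALSE)
  jsonlite::write_json(tr[c("stim_index", "baseline", "peak_amplitude",
                            "noise_sd")],
                       file.path(outdir, "calcium_traces_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  note(f, "traces")
  note(file.path(outdir, "calcium_traces_truth.json"), "truth")

  ## simulator combination sweep
  panel <- list(antibody_species("anti-alpha", "alpha", 0),
                antibody_species("anti-beta", "beta", 0),
                antibody_species("anti-delta", "delta", 0))
  sw <- sweep_combinations(n_receptors = 100L, panel,
                           seeds = stage_seed(seed, 40L) + 0:4)
  f <- file.path(outdir, "simulator_sweep.csv")
  utils::write.csv(sw, f, row.names = FALSE)
  note(f, "simulation")

  man <- do.call(rbind, manifest)
  utils::write.csv(man, file.path(outdir, "manifest.csv"), row.names = FALSE)
  invisible(man)
}

#' Default configuration for [run_end_to_end()]
#'
#' @return Nested list mirroring the pipeline stages; edit and pass to
#'   [run_end_to_end()], or serialize to YAML.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    out_dir = NULL,
    simulate = list(
      n_receptors = 150L,
      count_total = 600L,
      k_on = 1, k_cross = 1,
      panel = list(list(id = "anti-alpha", target = "alpha"),
                   list(id = "anti-beta", target = "beta")),
      pairs = list(c("anti-alpha", "anti-beta")),
      n_seeds = 3L
    ),
    render = list(
      n_pre = 3L, n_post = 8L, frame_interval = 20,
      field_um = 20,
      pixel_size = 0.16, psf_sigma = 0.2,
      background_level = 100, photon_scale = 400,
      jitter_um = 0.35
    ),
    quantify = list(area_min = 0.8, area_max = 10.0),
    proxy_s_min = 4L
  )
}

#' Load a run configuration from YAML
#'
#' @param path YAML file with the structure of [default_run_config()];
#'   missing fields fall back to the defaults.
#' @return Configuration list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_cfg <- function(base, upd) {
    for (nm in names(upd)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(upd[[nm]]) &&
                        !is.null(names(upd[[nm]])))
        merge_cfg(base[[nm]], upd[[nm]]) else upd[[nm]]
    }
    base
  }
  merge_cfg(default_run_config(), user)
}

## Simulate one antibody condition as a time series of crosslink graphs by
## capping the event count per frame: with a fixed seed the event sequence
## is reproducible, so later frames extend earlier ones.
condition_series <- function(pool, species, params, seed, events_per_frame,
                             n_frames) {
  lapply(seq_len(n_frames), function(k) {
    p <- params
    p$max_events <- events_per_frame * k
    simulate_binding(pool, species, p, seed = seed)
  })
}

#' End-to-end run: simulate, render, quantify, compare conditions
#'
#' For each antibody condition (each single species and each configured
#' pair at matched total count), simulates progressive crosslinking
#' (well-mixed kinetics, the event budget growing frame by frame), lays the
#' receptors out on a sparse visual field, renders the receptor
#' distribution before and after antibody addition as a fluorescence time
#' series (aggregates condense at their centroids), quantifies each frame
#' with the cluster pipeline, and assembles a condition-by-growth-rate
#' table together with the simulator's aggregate-size synergy sweep.
#'
#' @param config Configuration list ([default_run_config()]) or the path of
#'   a YAML file ([read_run_config()]).
#' @return An object of class `run_manifest`: `config` (fully resolved),
#'   `growth` (data frame: condition, seed, metric slopes), `sweep`
#'   (aggregate-size sweep from [sweep_combinations()]), `files` (written
#'   outputs, when `out_dir` is set), `timestamp`.
#' @export
run_end_to_end <- function(config = default_run_config()) {
  if (is.character(config)) config <- read_run_config(config)
  cfg <- config
  sim <- cfg$simulate; ren <- cfg$render
  optics <- optics_params(pixel_size = ren$pixel_size,
                          psf_sigma = ren$psf_sigma,
                          background_level = ren$background_level,
                          photon_scale = ren$photon_scale)
  pool <- make_receptor_pool(sim$n_receptors)
  params <- binding_params(k_on = sim$k_on, k_cross = sim$k_cross)
  ids <- vapply(sim$panel, `[[`, "", "id")
  conditions <- lapply(sim$panel, function(p)
    list(label = p$id,
         species = list(antibody_species(p$id, p$target, sim$count_total))))
  for (pr in sim$pairs) {
    ia <- match(pr[1], ids); ib <- match(pr[2], ids)
    if (is.na(ia) || is.na(ib)) stop("pair references unknown species", call. = FALSE)
    conditions[[length(conditions) + 1L]] <- list(
      label = paste(pr[1], pr[2], sep = "+"),
      species = list(
        antibody_species(pr[1], sim$panel[[ia]]$target, sim$count_total %/% 2L),
        antibody_species(pr[2], sim$panel[[ib]]$target,
                         sim$count_total - sim$count_total %/% 2L)))
  }

  total_arms <- 2L * sim$count_total
  events_per_frame <- max(1L, total_arms %/% ren$n_post)
  field_um <- ren$field_um
  growth <- list()
  for (cond in conditions) {
    for (sd_i in seq_len(sim$n_seeds)) {
      seed_c <- stage_seed(cfg$seed, 100L * sd_i)
      graphs <- condition_series(pool, cond$species, params, seed_c,
                                 events_per_frame, ren$n_post)
      empty <- simulate_binding(pool, list(), params, seed = seed_c)
      pos <- with_seed(seed_c, cbind(runif(sim$n_receptors, 1, field_um - 1),
                                     runif(sim$n_receptors, 1, field_um - 1)))
      frames <- vector("list", ren$n_pre + ren$n_post)
      for (f in seq_len(ren$n_pre))
        frames[[f]] <- render_simulated_field(
          empty, optics, field_um = field_um, jitter_um = ren$jitter_um,
          seed = stage_seed(cfg$seed, 100L * sd_i + f), positions = pos)$frame
      for (f in seq_len(ren$n_post))
        frames[[ren$n_pre + f]] <- render_simulated_field(
          graphs[[f]], optics, field_um = field_um, jitter_um = ren$jitter_um,
          seed = stage_seed(cfg$seed, 100L * sd_i + ren$n_pre + f),
          positions = pos)$frame
      npix <- nrow(frames[[1]])
      data <- array(0, dim = c(length(frames), 1L, npix, npix))
      for (f in seq_along(frames)) data[f, 1, , ] <- frames[[f]]
      times <- (seq_along(frames) - 1L) * ren$frame_interval
      stack <- image_stack(data, times, "BTX", optics$pixel_size)
      q <- quantify_stack(stack,
                          addition_time = (ren$n_pre - 0.5) * ren$frame_interval,
                          area_min = cfg$quantify$area_min,
                          area_max = cfg$quantify$area_max)
      post <- q$rates[q$rates$segment == "post", ]
      growth[[length(growth) + 1L]] <- data.frame(
        condition = cond$label, seed = sd_i,
        metric = post$metric, slope = post$slope, se = post$se)
    }
  }
  growth <- do.call(rbind, growth)

  sweep <- sweep_combinations(
    n_receptors = sim$n_receptors,
    panel = lapply(sim$panel, function(p) antibody_species(p$id, p$target, 0L)),
    params = binding_params(k_on = sim$k_on, k_cross = sim$k_cross),
    count_total = sim$count_total,
    seeds = stage_seed(cfg$seed, 7L) + seq_len(max(3L, sim$n_seeds)) - 1L,
    s_min = cfg$proxy_s_min)

  files <- character(0)
  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    gf <- file.path(cfg$out_dir, "growth_rates.csv")
    sf <- file.path(cfg$out_dir, "synergy_sweep.csv")
    mf <- file.path(cfg$out_dir, "run_manifest.json")
    utils::write.csv(growth, gf, row.names = FALSE)
    utils::write.csv(sweep, sf, row.names = FALSE)
    jsonlite::write_json(list(package_version = as.character(
                                utils::packageVersion("clusterlab")),
                              config = cfg,
                              outputs = c(gf, sf)),
                         mf, auto_unbox = TRUE, digits = NA)
    files <- c(gf, sf, mf)
  }
  structure(
    list(config = cfg, growth = growth, sweep = sweep, files = files,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")),
    class = "run_manifest"
  )
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("End-to-end run over", length(unique(x$growth$condition)),
      "conditions x", max(x$growth$seed), "seed(s)\n")
  agg <- stats::aggregate(slope ~ condition + metric, x$growth, mean)
  print(agg, row.names = FALSE)
  invisible(x)
}
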