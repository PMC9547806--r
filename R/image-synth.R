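## ---------------------------------------------------------------------------
## Synthetic-data generators with ground truth
##
## Every downstream stage of the package (thresholding, segmentation, NMJ
## morphometry, flow statistics) is exercised against data produced here, so
## each generator records exactly what it planted.
## ---------------------------------------------------------------------------

#' Optical/camera parameters for synthetic image rendering
#'
#' @param pixel_size Pixel size in micrometres (default 0.16, a 40x confocal
#'   configuration).
#' @param psf_sigma Gaussian point-spread-function sigma in micrometres
#'   (default 0.2).
#' @param background_level Constant camera/cell background in counts.
#' @param photon_scale Expected counts contributed by one labelled receptor.
#' @param read_noise_sd Gaussian read-noise standard deviation in counts.
#' @param bit_depth 8 or 16; rendered images are clipped to this range.
#' @return An object of class `optics_params`.
#' @export
optics_params <- function(pixel_size = 0.16, psf_sigma = 0.2,
                          background_level = 100, photon_scale = 200,
                          read_noise_sd = 2, bit_depth = 16L) {
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  if (psf_sigma < 0) stop("psf_sigma must be >= 0", call. = FALSE)
  if (background_level < 0) stop("background_level must be >= 0", call. = FALSE)
  if (!bit_depth %in% c(8L, 16L)) stop("bit_depth must be 8 or 16", call. = FALSE)
  structure(
    list(pixel_size = pixel_size, psf_sigma = psf_sigma,
         background_level = background_level, photon_scale = photon_scale,
         read_noise_sd = read_noise_sd, bit_depth = as.integer(bit_depth)),
    class = "optics_params"
  )
}

#' Construct a multichannel time-lapse image stack
#'
#' Container for T x C x Y x X unsigned-integer image data with acquisition
#' metadata.  Z is assumed already projected (see [project_stack()]).
#'
#' @param data Numeric array ordered T x C x Y x X.
#' @param frame_times Strictly increasing acquisition times in seconds, one
#'   per frame.
#' @param channel_names Character vector, one name per channel.
#' @param pixel_size Pixel size in micrometres.
#' @return An object of class `image_stack`.
#' @export
image_stack <- function(data, frame_times, channel_names, pixel_size) {
  if (length(dim(data)) != 4L)
    stop("`data` must be a 4-D array ordered T x C x Y x X", call. = FALSE)
  if (length(frame_times) != dim(data)[1])
    stop("one frame time per frame is required", call. = FALSE)
  if (any(diff(frame_times) <= 0))
    stop("frame_times must be strictly increasing", call. = FALSE)
  if (length(channel_names) != dim(data)[2])
    stop("one name per channel is required", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  structure(
    list(data = data, frame_times = as.numeric(frame_times),
         channel_names = as.character(channel_names),
         pixel_size = pixel_size),
    class = "image_stack"
  )
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Image stack: %d frame(s) x %d channel(s) x %d x %d px; %.3g um/px\n",
              d[1], d[2], d[3], d[4], x$pixel_size))
  cat("  channels:", paste(x$channel_names, collapse = ", "), "\n")
  invisible(x)
}

## Gaussian blur that tolerates sigma = 0 and keeps matrix orientation.
blur_frame <- function(frame, sigma_px) {
  if (sigma_px <= 0) return(frame)
  EBImage::gblur(frame, sigma = sigma_px)
}

## Shot + read noise, quantized and clipped to the camera bit depth.
## Noise-free renders keep the exact (unquantized) expectation so that
## planted quantities are recoverable exactly.
apply_camera_noise <- function(expected, optics, noise = TRUE) {
  maxval <- 2^optics$bit_depth - 1
  if (!noise) return(matrix(pmin(pmax(expected, 0), maxval),
                            nrow = nrow(expected)))
  img <- matrix(stats::rpois(length(expected), lambda = pmax(expected, 0)),
                nrow = nrow(expected))
  if (optics$read_noise_sd > 0)
    img <- img + matrix(stats::rnorm(length(img), 0, optics$read_noise_sd),
                        nrow = nrow(img))
  matrix(pmin(pmax(round(img), 0), maxval), nrow = nrow(expected))
}

## Paint a filled disk into a matrix; returns logical mask of painted pixels.
disk_mask <- function(dim_yx, cy, cx, radius_px) {
  yy <- matrix(seq_len(dim_yx[1]), dim_yx[1], dim_yx[2])
  xx <- matrix(seq_len(dim_yx[2]), dim_yx[1], dim_yx[2], byrow = TRUE)
  (yy - cy)^2 + (xx - cx)^2 <= radius_px^2
}

## Rejection-sample k disk centres with no overlap and a safety margin.
place_disks <- function(k, dim_yx, radii_px, margin_px = 3, max_tries = 4000) {
  cy <- numeric(0); cx <- numeric(0)
  tries <- 0
  while (length(cy) < k && tries < max_tries) {
    tries <- tries + 1
    i <- length(cy) + 1L
    r <- radii_px[i]
    y <- stats::runif(1, r + margin_px, dim_yx[1] - r - margin_px)
    x <- stats::runif(1, r + margin_px, dim_yx[2] - r - margin_px)
    if (i == 1L ||
        all(sqrt((cy - y)^2 + (cx - x)^2) >
            (radii_px[seq_len(i - 1L)] + r + margin_px))) {
      cy <- c(cy, y); cx <- c(cx, x)
    }
  }
  if (length(cy) < k)
    warning("could not place all clusters without overlap; field too crowded")
  list(cy = cy, cx = cx, n = length(cy))
}

#' Synthesize a receptor-clustering time-lapse with known ground truth
#'
#' Emulates live-cell imaging of fluorescently labelled surface receptors:
#' pre-addition frames show diffuse membrane signal only; after antibody
#' addition, disk-shaped clusters are planted whose number and mean area
#' grow linearly at the requested rates.  The returned ground truth records
#' every planted cluster, so segmentation recall/precision and recovered
#' growth slopes can be scored exactly.
#'
#' @param n_pre,n_post Number of frames before/after antibody addition
#'   (each >= 2).
#' @param frame_interval Seconds between frames (default 20, i.e. three
#'   frames per minute).
#' @param count_slope Planted growth in cluster count per frame.
#' @param mean_area_slope Planted growth in mean cluster area (um^2/frame).
#' @param initial_count Cluster count in the first post-addition frame.
#' @param initial_mean_area Mean cluster area in the first post-addition
#'   frame (um^2).
#' @param cluster_area_range Allowed cluster areas in um^2 (default
#'   `c(0.8, 10)`, the size window used to define clusters downstream).
#' @param cluster_amplitude Cluster signal above the diffuse level, counts.
#' @param diffuse_level Diffuse membrane signal above camera background,
#'   counts.
#' @param dim_yx Image size in pixels, `c(y, x)`.
#' @param optics An [optics_params()] object.
#' @param noise Apply Poisson + Gaussian camera noise (default `TRUE`);
#'   `FALSE` renders the noise-free expectation.
#' @param seed Integer seed; output is fully reproducible.
#' @return A list with `stack` (an [image_stack()] with one `BTX` channel)
#'   and `truth`: a list with `clusters` (data frame: `frame`, `id`, `cy`,
#'   `cx` in 1-based pixels, `radius_px`, `area_um2`), `per_frame` (data
#'   frame of planted counts and mean areas), `addition_time`, and the
#'   planted slopes.
#' @export
synth_cluster_timelapse <- function(n_pre = 5L, n_post = 15L,
                                    frame_interval = 20,
                                    count_slope = 1.0,
                                    mean_area_slope = 0.0,
                                    initial_count = 6L,
                                    initial_mean_area = 2.0,
                                    cluster_area_range = c(0.8, 10),
                                    cluster_amplitude = 600,
                                    diffuse_level = 60,
                                    dim_yx = c(192L, 192L),
                                    optics = optics_params(),
                                    noise = TRUE, seed = 1L) {
  if (n_pre < 2 || n_post < 2)
    stop("at least two frames are required on each side of the addition",
         call. = FALSE)
  n_frames <- n_pre + n_post
  px <- optics$pixel_size
  with_seed(seed, {
    ## geometry is drawn for all frames before any noise, so the planted
    ## truth is identical between noisy and noise-free renders of a seed
    expected_frames <- vector("list", n_frames)
    truth_rows <- list()
    per_frame <- data.frame(frame = seq_len(n_frames),
                            time = (seq_len(n_frames) - 1L) * frame_interval,
                            planted_count = 0L, planted_mean_area = NA_real_)
    for (f in seq_len(n_frames)) {
      expected <- matrix(optics$background_level + diffuse_level,
                         dim_yx[1], dim_yx[2])
      if (f > n_pre) {
        k_post <- f - n_pre - 1L                  # 0-based post frame index
        n_k <- max(0L, as.integer(round(initial_count + count_slope * k_post)))
        if (initial_count + count_slope * k_post < 0)
          warning("planted count clipped at 0")
        if (n_k > 0) {
          target_mean <- min(max(initial_mean_area + mean_area_slope * k_post,
                                 cluster_area_range[1]), cluster_area_range[2])
          areas <- stats::runif(n_k, 0.85 * target_mean, 1.15 * target_mean)
          areas <- areas - mean(areas) + target_mean   # exact planted mean
          areas <- pmin(pmax(areas, cluster_area_range[1]),
                        cluster_area_range[2])
          radii <- sqrt(areas / pi) / px
          pos <- place_disks(n_k, dim_yx, radii)
          n_k <- pos$n
          signal <- matrix(0, dim_yx[1], dim_yx[2])
          for (i in seq_len(n_k)) {
            m <- disk_mask(dim_yx, pos$cy[i], pos$cx[i], radii[i])
            signal[m] <- signal[m] + cluster_amplitude
            truth_rows[[length(truth_rows) + 1L]] <- data.frame(
              frame = f, id = i, cy = pos$cy[i], cx = pos$cx[i],
              radius_px = radii[i], area_um2 = sum(m) * px^2)
          }
          expected <- expected + blur_frame(signal, optics$psf_sigma / px)
          per_frame$planted_count[f] <- n_k
          per_frame$planted_mean_area[f] <- mean(areas[seq_len(n_k)])
        }
      }
      expected_frames[[f]] <- expected
    }
    data <- array(0, dim = c(n_frames, 1L, dim_yx[1], dim_yx[2]))
    for (f in seq_len(n_frames))
      data[f, 1, , ] <- apply_camera_noise(expected_frames[[f]], optics, noise)
    stack <- image_stack(data, per_frame$time, "BTX", px)
    truth <- list(
      clusters = if (length(truth_rows)) do.call(rbind, truth_rows)
                 else data.frame(frame = integer(0), id = integer(0),
                                 cy = numeric(0), cx = numeric(0),
                                 radius_px = numeric(0), area_um2 = numeric(0)),
      per_frame = per_frame,
      addition_time = (n_pre - 0.5) * frame_interval,
      count_slope = count_slope, mean_area_slope = mean_area_slope,
      n_pre = n_pre, n_post = n_post, seed = seed)
    list(stack = stack, truth = truth)
  })
}

#' Render a crosslink graph as a synthetic fluorescence field
#'
#' Receptors are point emitters at their simulated 2-D positions; members of
#' an antibody-linked aggregate are drawn together at the aggregate centroid
#' with a small jitter, emulating the condensation of receptor label into
#' bright patches as crosslinking proceeds.
#'
#' @param graph A `crosslink_graph`; positions come from the graph
#'   (geometric mode) or from the `positions` argument.
#' @param positions Optional n x 2 matrix of receptor positions in
#'   micrometres, overriding `graph$positions` (lets well-mixed simulations
#'   be laid out on a visual field for rendering).
#' @param optics An [optics_params()] object.
#' @param field_um Field of view in micrometres (square); defaults to the
#'   bounding box of the positions plus a margin.
#' @param jitter_um Positional jitter (sd, um) of emitters around their
#'   aggregate centroid (default 0.25).
#' @param noise Apply camera noise (default `TRUE`).
#' @param seed Integer seed.
#' @return A list with `frame` (Y x X integer matrix), `truth` (data frame:
#'   emitter positions in pixels and their component id/size), and
#'   `pixel_size`.
#' @export
render_simulated_field <- function(graph, optics = optics_params(),
                                   field_um = NULL, jitter_um = 0.25,
                                   noise = TRUE, seed = 1L,
                                   positions = NULL) {
  stopifnot(inherits(graph, "crosslink_graph"))
  pos <- if (!is.null(positions)) positions else graph$positions
  if (is.null(pos))
    stop("no receptor positions: simulate in geometric mode or supply `positions`",
         call. = FALSE)
  if (nrow(pos) != graph$n_receptors)
    stop("one position per receptor is required", call. = FALSE)
  px <- optics$pixel_size
  if (is.null(field_um)) field_um <- max(pos) + 2
  npix <- max(16L, ceiling(field_um / px))
  ab <- graph$antibodies
  linked <- ab[!is.na(ab$receptor2), , drop = FALSE]
  g <- igraph::make_empty_graph(n = graph$n_receptors, directed = FALSE)
  if (nrow(linked)) g <- igraph::add_edges(g, rbind(linked$receptor1, linked$receptor2))
  comp <- igraph::components(g)
  with_seed(seed, {
    cx_um <- tapply(pos[, 1], comp$membership, mean)[comp$membership]
    cy_um <- tapply(pos[, 2], comp$membership, mean)[comp$membership]
    ex <- cx_um + stats::rnorm(length(cx_um), 0, jitter_um)
    ey <- cy_um + stats::rnorm(length(cy_um), 0, jitter_um)
    ix <- pmin(pmax(ceiling(ex / px), 1L), npix)
    iy <- pmin(pmax(ceiling(ey / px), 1L), npix)
    expected <- matrix(0, npix, npix)
    for (i in seq_along(ix))
      expected[iy[i], ix[i]] <- expected[iy[i], ix[i]] + optics$photon_scale
    expected <- blur_frame(expected, optics$psf_sigma / px) +
      optics$background_level
    frame <- apply_camera_noise(expected, optics, noise)
    truth <- data.frame(receptor = seq_len(graph$n_receptors),
                        x_px = ex / px, y_px = ey / px,
                        component = comp$membership,
                        component_size = comp$csize[comp$membership])
    list(frame = frame, truth = truth, pixel_size = px)
  })
}

## Pretzel-shaped junction mask: a band around a perturbed closed curve.
nmj_outline_mask <- function(dim_yx, centre_yx, radius_px, band_px,
                             lobes = 3, lobe_depth = 0.25, phase = 0) {
  yy <- matrix(seq_len(dim_yx[1]), dim_yx[1], dim_yx[2])
  xx <- matrix(seq_len(dim_yx[2]), dim_yx[1], dim_yx[2], byrow = TRUE)
  dy <- yy - centre_yx[1]; dx <- xx - centre_yx[2]
  r <- sqrt(dy^2 + dx^2)
  theta <- atan2(dy, dx)
  r0 <- radius_px * (1 + lobe_depth * sin(lobes * theta + phase))
  abs(r - r0) <= band_px
}

#' Synthesize a three-channel neuromuscular-junction image
#'
#' Renders a pretzel-shaped junction in three co-registered channels: a
#' presynaptic marker (`SV2A`) filling the whole junction outline, a
#' receptor label (`BTX`) whose total content within the junction equals
#' `achr_retention` times the SV2A content but is concentrated into exactly
#' `n_fragments` disjoint blobs, and a complement channel (`C3`) at
#' `c3_level` counts above background within the junction.  Channels are
#' rendered crisp (no PSF blur) so that noise-free renders recover the
#' planted values exactly.
#'
#' @param n_fragments Number of disjoint receptor blobs (>= 0; 0 gives a
#'   blank receptor channel).
#' @param achr_retention Fraction in `[0, 1]` of receptor content retained
#'   relative to the presynaptic marker.
#' @param c3_level Complement signal in counts above background.
#' @param sv2a_level Presynaptic marker signal in counts above background.
#' @param dim_yx Image size in pixels.
#' @param optics An [optics_params()] object.
#' @param noise Apply camera noise (default `TRUE`).
#' @param seed Integer seed.
#' @return A list with `stack` (single-frame [image_stack()], channels
#'   `BTX`, `SV2A`, `C3`) and `truth` (mask matrix, fragment label matrix,
#'   `n_fragments`, `achr_retention`, `c3_level`, per-fragment pixel areas).
#' @export
synth_nmj_image <- function(n_fragments = 4L, achr_retention = 0.7,
                            c3_level = 300, sv2a_level = 800,
                            dim_yx = c(160L, 160L),
                            optics = optics_params(),
                            noise = TRUE, seed = 1L) {
  if (n_fragments < 0) stop("n_fragments must be >= 0", call. = FALSE)
  if (achr_retention < 0 || achr_retention > 1)
    stop("achr_retention must be in [0, 1]", call. = FALSE)
  px <- optics$pixel_size
  with_seed(seed, {
    centre <- dim_yx / 2
    radius_px <- min(dim_yx) * 0.28
    band_px <- min(dim_yx) * 0.07
    phase <- stats::runif(1, 0, 2 * pi)
    mask <- nmj_outline_mask(dim_yx, centre, radius_px, band_px,
                             phase = phase)
    ## fragment blobs: disks centred on the outline, pruned to the mask
    frag_label <- matrix(0L, dim_yx[1], dim_yx[2])
    frag_areas <- numeric(0)
    if (n_fragments > 0) {
      angles <- phase / 3 + 2 * pi * (seq_len(n_fragments) - 1) / n_fragments +
        stats::runif(n_fragments, -0.1, 0.1)
      r0 <- radius_px * (1 + 0.25 * sin(3 * angles + phase))
      fy <- centre[1] + r0 * sin(angles)
      fx <- centre[2] + r0 * cos(angles)
      frad <- band_px * 0.75
      for (i in seq_len(n_fragments)) {
        m <- disk_mask(dim_yx, fy[i], fx[i], frad) & mask & frag_label == 0L
        frag_label[m] <- i
        frag_areas <- c(frag_areas, sum(m) * px^2)
      }
    }
    mask_area_px <- sum(mask)
    frag_area_px <- sum(frag_label > 0L)
    ## receptor content scaled so the mask-mean BTX / mask-mean SV2A ratio
    ## equals the planted retention exactly (content, not coverage)
    btx_level <- if (frag_area_px > 0)
      achr_retention * sv2a_level * mask_area_px / frag_area_px else 0
    bg <- optics$background_level
    sv2a <- matrix(bg, dim_yx[1], dim_yx[2]); sv2a[mask] <- bg + sv2a_level
    btx <- matrix(bg, dim_yx[1], dim_yx[2]); btx[frag_label > 0L] <- bg + btx_level
    c3 <- matrix(bg, dim_yx[1], dim_yx[2]); c3[mask] <- bg + c3_level
    data <- array(0, dim = c(1L, 3L, dim_yx[1], dim_yx[2]))
    data[1, 1, , ] <- apply_camera_noise(btx, optics, noise)
    data[1, 2, , ] <- apply_camera_noise(sv2a, optics, noise)
    data[1, 3, , ] <- apply_camera_noise(c3, optics, noise)
    stack <- image_stack(data, 0, c("BTX", "SV2A", "C3"), px)
    truth <- list(mask = mask, fragment_label = frag_label,
                  n_fragments = n_fragments, achr_retention = achr_retention,
                  c3_level = c3_level, sv2a_level = sv2a_level,
                  btx_level = btx_level,
                  fragment_areas_um2 = frag_areas,
                  mask_area_um2 = mask_area_px * px^2, seed = seed)
    list(stack = stack, truth = truth)
  })
}

#' Synthesize a two-population flow-cytometry event table
#'
#' Emulates a binding/complement assay on a mixed culture of transfected
#' (antigen-expressing, GFP-positive) and untransfected cells.  GFP is
#' log-normal in both populations with well-separated geometric means; the
#' readout channels (`igg`, `c3`) are log-normal with geometric means
#' differing between populations by exactly the planted ratios.
#'
#' @param n_events Total number of events (>= 1).
#' @param frac_transfected Fraction of events in the GFP-positive
#'   population, strictly between 0 and 1.
#' @param binding_ratio Planted geometric-mean ratio of the `igg` channel
#'   (positive / negative population).
#' @param c3_ratio Planted geometric-mean ratio of the `c3` channel.
#' @param gfp_meanlog Named list/vector with `neg` and `pos` log-scale GFP
#'   means (natural log).
#' @param sdlog Log-scale standard deviation shared by all channels.
#' @param base_gm Geometric mean of `igg` and `c3` in the negative
#'   population.
#' @param seed Integer seed.
#' @return A data frame of class `flow_events` with columns `gfp`, `igg`,
#'   `c3` and the ground-truth `population` (`"neg"`/`"pos"`); planted
#'   parameters are stored in attributes.
#' @export
synth_flow_events <- function(n_events = 10000L, frac_transfected = 0.4,
                              binding_ratio = 5, c3_ratio = 1,
                              gfp_meanlog = c(neg = log(50), pos = log(5000)),
                              sdlog = 0.5, base_gm = 100, seed = 1L) {
  if (n_events < 1) stop("n_events must be >= 1", call. = FALSE)
  if (frac_transfected <= 0 || frac_transfected >= 1)
    stop("frac_transfected must be strictly between 0 and 1", call. = FALSE)
  if (binding_ratio <= 0 || c3_ratio <= 0)
    stop("planted ratios must be > 0", call. = FALSE)
  with_seed(seed, {
    pop <- ifelse(stats::runif(n_events) < frac_transfected, "pos", "neg")
    mus <- ifelse(pop == "pos", gfp_meanlog[["pos"]], gfp_meanlog[["neg"]])
    gfp <- stats::rlnorm(n_events, meanlog = mus, sdlog = sdlog)
    igg <- stats::rlnorm(n_events,
                         meanlog = log(base_gm) +
                           ifelse(pop == "pos", log(binding_ratio), 0),
                         sdlog = sdlog)
    c3 <- stats::rlnorm(n_events,
                        meanlog = log(base_gm) +
                          ifelse(pop == "pos", log(c3_ratio), 0),
                        sdlog = sdlog)
    out <- data.frame(gfp = gfp, igg = igg, c3 = c3, population = pop,
                      stringsAsFactors = FALSE)
    class(out) <- c("flow_events", "data.frame")
    attr(out, "planted") <- list(binding_ratio = binding_ratio,
                                 c3_ratio = c3_ratio,
                                 frac_transfected = frac_transfected,
                                 gfp_meanlog = gfp_meanlog, sdlog = sdlog,
                                 seed = seed)
    out
  })
}

#' Synthesize stimulus-evoked calcium indicator traces
#'
#' Each trace is a flat baseline with Gaussian noise, plus an exponentially
#' decaying transient of the given amplitude starting at the stimulus frame
#' (the peak equals the amplitude exactly at `stim_index`), emulating the
#' population calcium response of myotubes to a presynaptic stimulus.
#'
#' @param n_wells Number of traces.
#' @param n_frames Trace length in frames.
#' @param stim_index Stimulus frame (1-based; `0 < stim_index <= n_frames`).
#' @param peak_amplitude Transient amplitude above baseline (recycled across
#'   wells).
#' @param baseline Baseline fluorescence level.
#' @param noise_sd Gaussian noise standard deviation.
#' @param decay_tau Transient decay constant in frames.
#' @param seed Integer seed.
#' @return A list of class `trace_set`: `traces` (n_wells x n_frames
#'   matrix), `stim_index`, and the planted `peak_amplitude` per well.
#' @export
synth_calcium_traces <- function(n_wells = 12L, n_frames = 200L,
                                 stim_index = 50L, peak_amplitude = 100,
                                 baseline = 500, noise_sd = 5,
                                 decay_tau = 15, seed = 1L) {
  if (stim_index <= 0 || stim_index > n_frames)
    stop("stim_index must lie within the trace", call. = FALSE)
  amp <- rep_len(peak_amplitude, n_wells)
  with_seed(seed, {
    t <- seq_len(n_frames)
    transient <- ifelse(t >= stim_index,
                        exp(-(t - stim_index) / decay_tau), 0)
    traces <- matrix(0, n_wells, n_frames)
    for (w in seq_len(n_wells)) {
      traces[w, ] <- baseline + amp[w] * transient +
        if (noise_sd > 0) stats::rnorm(n_frames, 0, noise_sd) else 0
    }
    structure(
      list(traces = traces, stim_index = as.integer(stim_index),
           baseline = baseline, peak_amplitude = amp,
           noise_sd = noise_sd, seed = seed),
      class = "trace_set"
    )
  })
}

## ---------------------------------------------------------------------------
## Image stack IO: multi-page TIFF + JSON metadata sidecar
## ---------------------------------------------------------------------------

#' Write an image stack to a multi-page TIFF with a JSON metadata sidecar
#'
#' Pages are ordered frame-major (frame 1 channel 1, frame 1 channel 2, ...).
#' Pixel size, channel names and frame times travel in `<path>.json`; both
#' files together round-trip bit-identically through [read_image_stack()].
#'
#' @param stack An [image_stack()].
#' @param path Output TIFF path.
#' @param bits 8 or 16 bits per sample.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path, bits = 16L) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$data)
  maxval <- 2^bits - 1
  if (max(stack$data) > maxval)
    stop("image data exceed the requested bit depth", call. = FALSE)
  pages <- list()
  for (f in seq_len(d[1])) for (ch in seq_len(d[2]))
    pages[[length(pages) + 1L]] <- stack$data[f, ch, , ] / maxval
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  meta <- list(pixel_size_um = stack$pixel_size,
               channel_names = stack$channel_names,
               frame_times_s = stack$frame_times,
               n_frames = d[1], n_channels = d[2],
               dim_yx = c(d[3], d[4]), bits = bits)
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an image stack written by [write_image_stack()]
#'
#' @param path TIFF path; `<path>.json` must exist alongside.
#' @return An [image_stack()].
#' @export
read_image_stack <- function(path) {
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path))
    stop("metadata sidecar not found: ", meta_path, call. = FALSE)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  maxval <- 2^meta$bits - 1
  data <- array(0, dim = c(meta$n_frames, meta$n_channels,
                           meta$dim_yx[1], meta$dim_yx[2]))
  k <- 0L
  for (f in seq_len(meta$n_frames)) for (ch in seq_len(meta$n_channels)) {
    k <- k + 1L
    data[f, ch, , ] <- round(pages[[k]] * maxval)
  }
  image_stack(data, meta$frame_times_s, meta$channel_names,
              meta$pixel_size_um)
}
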