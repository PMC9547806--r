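## ---------------------------------------------------------------------------
## Live-cell cluster quantification:
## entropy-based auto-thresholding -> size-filtered connected components ->
## per-frame metrics -> pre/post antibody growth-rate slopes.
## ---------------------------------------------------------------------------

#' Intensity histogram specification for threshold selection
#'
#' Bins a frame into 256 equal-width intensity bins spanning its observed
#' range (8-bit convention; higher-depth images are rescaled to 256 levels
#' for threshold selection and the chosen bin is mapped back to native
#' intensity by [auto_threshold()]).
#'
#' @param frame Numeric matrix of pixel intensities.
#' @param n_bins Number of bins (default 256).
#' @return A list of class `hist_spec`: `counts` (length `n_bins`),
#'   `breaks` (length `n_bins + 1`), `total`.
#' @export
hist_spec <- function(frame, n_bins = 256L) {
  lo <- min(frame); hi <- max(frame)
  if (!is.finite(lo) || !is.finite(hi))
    stop("frame contains non-finite values", call. = FALSE)
  if (hi == lo) {
    counts <- integer(n_bins); counts[1] <- length(frame)
    breaks <- seq(lo, lo + n_bins, length.out = n_bins + 1L)
  } else {
    breaks <- seq(lo, hi, length.out = n_bins + 1L)
    bin <- findInterval(frame, breaks, rightmost.closed = TRUE)
    counts <- tabulate(bin, nbins = n_bins)
  }
  structure(list(counts = counts, breaks = breaks, total = length(frame)),
            class = "hist_spec")
}

## Renyi entropy of order rho for a renormalized class distribution.
## rho = 1 is the Shannon/Kapur limit.
renyi_entropy <- function(p, rho) {
  p <- p[p > 0]
  if (length(p) == 0) return(-Inf)
  p <- p / sum(p)
  if (abs(rho - 1) < 1e-12) {
    -sum(p * log(p))
  } else {
    log(sum(p^rho)) / (1 - rho)
  }
}

## Best split for one entropy order: argmax_t H_rho(bins <= t) +
## H_rho(bins > t); ties broken toward the lower threshold.
renyi_single_order <- function(counts, rho) {
  n <- length(counts)
  p <- counts / sum(counts)
  nonzero <- which(counts > 0)
  if (length(nonzero) < 2)
    stop("degenerate histogram: fewer than two nonempty bins", call. = FALSE)
  lo <- nonzero[1]; hi <- nonzero[length(nonzero)]
  cand <- lo:(hi - 1L)
  crit <- vapply(cand, function(t)
    renyi_entropy(p[1:t], rho) + renyi_entropy(p[(t + 1L):n], rho), 0)
  cand[which.max(crit)]   # which.max takes the first (lowest) maximiser
}

#' Renyi-entropy automatic threshold selection
#'
#' Histogram-based automatic thresholding that maximises the sum of the
#' order-`rho` Renyi entropies of the background (bins `<= t`) and
#' foreground (bins `> t`) class distributions.  The default
#' `"sahoo_combined"` method computes the optimal split for three entropy
#' orders (0.5, 1, 2 -- order 1 being the Shannon/Kapur maximum-entropy
#' threshold) and combines the three thresholds with the published
#' weighting rule, matching the behaviour of the widely used ImageJ-style
#' open-source implementation.  `"single_order"` returns the plain maximiser
#' for one order and serves as the brute-force-verifiable reference.
#'
#' @param hist A [hist_spec()] object, or a bare vector of bin counts.
#' @param method `"sahoo_combined"` (default) or `"single_order"`.
#' @param rho Entropy order for `"single_order"` (default 1).
#' @return Threshold bin index `t` (1-based): background is bins `1..t`,
#'   foreground is bins `t+1 ..`.
#' @export
#' @examples
#' counts <- integer(256); counts[11] <- 100; counts[201] <- 100
#' renyi_threshold(counts)                   # splits between the two modes
renyi_threshold <- function(hist, method = c("sahoo_combined", "single_order"),
                            rho = 1) {
  method <- match.arg(method)
  counts <- if (inherits(hist, "hist_spec")) hist$counts else hist
  if (sum(counts > 0) < 2)
    stop("degenerate histogram: fewer than two nonempty bins", call. = FALSE)
  if (method == "single_order") return(renyi_single_order(counts, rho))

  t1 <- renyi_single_order(counts, 1)     # Shannon / Kapur
  t2 <- renyi_single_order(counts, 0.5)
  t3 <- renyi_single_order(counts, 2)
  ts <- sort(c(t1, t2, t3))
  t_star1 <- ts[1]; t_star2 <- ts[2]; t_star3 <- ts[3]

  ## weighting between the three candidate thresholds depends on how close
  ## together they fall (within 5 of the 256 levels)
  if (abs(t_star1 - t_star2) <= 5) {
    if (abs(t_star2 - t_star3) <= 5) {
      beta <- c(1, 2, 1)
    } else {
      beta <- c(0, 1, 3)
    }
  } else {
    if (abs(t_star2 - t_star3) <= 5) {
      beta <- c(3, 1, 0)
    } else {
      beta <- c(1, 2, 1)
    }
  }
  p <- counts / sum(counts)
  cum <- cumsum(p)
  p1 <- cum[t_star1]          # background mass at the lowest threshold
  p3 <- 1 - cum[t_star3]      # foreground mass at the highest threshold
  omega <- cum[t_star3] - cum[t_star1]
  ## combine on the 0-based level scale used by the published rule
  t0 <- (t_star1 - 1L) * (p1 + 0.25 * omega * beta[1]) +
    0.25 * (t_star2 - 1L) * omega * beta[2] +
    (t_star3 - 1L) * (p3 + 0.25 * omega * beta[3])
  as.integer(floor(t0)) + 1L
}

#' Automatic intensity threshold for a frame
#'
#' Builds the 256-bin histogram, selects the Renyi-entropy threshold bin,
#' and maps it back to a native-intensity cutoff.  Foreground is
#' `frame > cutoff`.  For integer-valued images the cutoff is an integer,
#' which makes thresholding exactly covariant under integer intensity
#' shifts.  A constant frame returns its own value (empty foreground)
#' rather than an error, so blank fields segment to zero clusters.
#'
#' @param frame Numeric matrix.
#' @param method,rho Passed to [renyi_threshold()].
#' @return Scalar intensity cutoff.
#' @export
auto_threshold <- function(frame, method = "sahoo_combined", rho = 1) {
  h <- hist_spec(frame)
  if (sum(h$counts > 0) < 2) return(max(frame))
  t <- renyi_threshold(h, method = method, rho = rho)
  edge <- h$breaks[t + 1L]
  if (all(frame == round(frame))) ceiling(edge) - 1 else edge
}

#' Maximum-intensity projection of a Z-stack
#'
#' @param zstack 3-D array (Z x Y x X) or list of matrices.
#' @return Matrix of per-pixel maxima across planes.
#' @export
project_stack <- function(zstack) {
  if (is.list(zstack)) {
    if (length(zstack) == 0) stop("empty stack", call. = FALSE)
    return(Reduce(pmax, zstack))
  }
  d <- dim(zstack)
  if (is.null(d) || length(d) != 3L || d[1] < 1)
    stop("zstack must be a Z x Y x X array or list of planes", call. = FALSE)
  apply(zstack, c(2, 3), max)
}

#' Label connected foreground components (8-connectivity)
#'
#' ImageJ-style particle labelling: components are connected through edges
#' and diagonals.
#'
#' @param mask Logical or 0/1 matrix.
#' @return Integer matrix of component labels (0 = background).
#' @export
label_components <- function(mask) {
  m <- matrix(as.numeric(mask > 0), nrow = nrow(mask))
  lab <- EBImage::bwlabel(m)          # 4-connected
  nlab <- max(lab)
  if (nlab == 0) return(matrix(0L, nrow(m), ncol(m)))
  ## merge labels touching diagonally
  a <- lab[-nrow(lab), -ncol(lab)]; b <- lab[-1, -1]
  c_ <- lab[-nrow(lab), -1]; d_ <- lab[-1, -ncol(lab)]
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c_), as.vector(d_)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                 pairs[, 1] != pairs[, 2], , drop = FALSE]
  parent <- seq_len(nlab)
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  if (nrow(pairs)) {
    for (k in seq_len(nrow(pairs))) {
      ra <- find(pairs[k, 1]); rb <- find(pairs[k, 2])
      if (ra != rb) parent[ra] <- rb
    }
  }
  roots <- vapply(seq_len(nlab), find, 0L)
  remap <- match(roots, sort(unique(roots)))
  out <- matrix(0L, nrow(m), ncol(m))
  fg <- lab > 0
  out[fg] <- remap[lab[fg]]
  out
}

#' Morphological background subtraction
#'
#' Estimates the smooth background of a frame by grayscale opening with a
#' disc structuring element (a rolling-ball-style estimate) and subtracts
#' it, clipping at zero.
#'
#' @param frame Numeric matrix.
#' @param radius Disc radius in pixels (default 50).
#' @return Background-reduced matrix.
#' @export
subtract_background <- function(frame, radius = 50) {
  if (radius <= 0) return(frame)
  kern <- EBImage::makeBrush(2 * round(radius) + 1, shape = "disc")
  bg <- EBImage::opening(frame, kern)
  pmax(frame - bg, 0)
}

#' Extract size-filtered clusters from a thresholded frame
#'
#' Pixels above the threshold are grouped into 8-connected components;
#' components whose physical area falls inside `[area_min, area_max]`
#' square micrometres are reported as clusters, everything else (specks and
#' large confluent patches alike) is discarded.
#'
#' @param frame Numeric matrix.
#' @param pixel_size Pixel size in micrometres.
#' @param threshold Intensity cutoff; foreground is `frame > threshold`.
#'   `NULL` (default) selects it with [auto_threshold()].
#' @param area_min,area_max Cluster area window in um^2 (defaults 0.8 and
#'   10.0).
#' @param background_radius Radius for [subtract_background()] applied
#'   before thresholding; `NULL` disables background reduction.
#' @param method Threshold method when `threshold` is `NULL`.
#' @return Data frame with one row per cluster: `label`, `area` (um^2),
#'   `cx`, `cy` (0-based pixel centroid), `mean_intensity`.
#' @export
segment_clusters <- function(frame, pixel_size, threshold = NULL,
                             area_min = 0.8, area_max = 10.0,
                             background_radius = NULL,
                             method = "sahoo_combined") {
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  if (area_min >= area_max) stop("area_min must be < area_max", call. = FALSE)
  work <- frame
  if (!is.null(background_radius))
    work <- subtract_background(work, background_radius)
  if (is.null(threshold)) threshold <- auto_threshold(work, method = method)
  mask <- work > threshold
  empty <- data.frame(label = integer(0), area = numeric(0),
                      cx = numeric(0), cy = numeric(0),
                      mean_intensity = numeric(0))
  if (!any(mask)) return(empty)
  lab <- label_components(mask)
  nlab <- max(lab)
  idx <- which(lab > 0)
  labs <- lab[idx]
  npx <- tabulate(labs, nlab)
  areas <- npx * pixel_size^2
  keep <- which(areas >= area_min & areas <= area_max)
  if (length(keep) == 0) return(empty)
  rows <- (idx - 1L) %% nrow(lab) + 1L
  cols <- (idx - 1L) %/% nrow(lab) + 1L
  ## intensities measured on the original frame
  vals <- frame[idx]
  sum_y <- tapply(rows, labs, sum)[as.character(keep)]
  sum_x <- tapply(cols, labs, sum)[as.character(keep)]
  sum_i <- tapply(vals, labs, sum)[as.character(keep)]
  data.frame(label = seq_along(keep),
             area = areas[keep],
             cx = as.numeric(sum_x) / npx[keep] - 1,
             cy = as.numeric(sum_y) / npx[keep] - 1,
             mean_intensity = as.numeric(sum_i) / npx[keep])
}

#' Per-frame summary of a cluster set
#'
#' @param clusters Data frame from [segment_clusters()] (possibly empty).
#' @param frame_time Acquisition time of the frame in seconds.
#' @return One-row data frame: `frame_time`, `n_clusters`, `total_area`,
#'   `mean_area` (`NaN` when no clusters), `mean_intensity`.
#' @export
frame_metrics <- function(clusters, frame_time = NA_real_) {
  n <- nrow(clusters)
  data.frame(frame_time = frame_time,
             n_clusters = n,
             total_area = if (n) sum(clusters$area) else 0,
             mean_area = if (n) mean(clusters$area) else NaN,
             mean_intensity = if (n) mean(clusters$mean_intensity) else NaN)
}

#' Assemble a cluster time series
#'
#' @param metrics Data frame of per-frame metrics ([frame_metrics()] rows).
#' @param addition_time Antibody addition time in seconds; the boundary
#'   between the pre segment (`frame_time < addition_time`) and the post
#'   segment (`frame_time >= addition_time`).
#' @return An object of class `cluster_time_series`.
#' @export
cluster_time_series <- function(metrics, addition_time) {
  if (any(diff(metrics$frame_time) <= 0))
    stop("frame times must be strictly increasing", call. = FALSE)
  if (addition_time < min(metrics$frame_time) ||
      addition_time > max(metrics$frame_time))
    stop("addition_time must fall within the observed time range", call. = FALSE)
  structure(list(metrics = metrics, addition_time = addition_time),
            class = "cluster_time_series")
}

ols_slope <- function(t, y) {
  ok <- is.finite(y)
  if (sum(ok) < 2) return(c(slope = NA_real_, se = NA_real_, n = sum(ok)))
  fit <- stats::lm(y[ok] ~ t[ok])
  co <- suppressWarnings(summary(fit)$coefficients)  # constant y: SE is 0
  se <- if (nrow(co) >= 2 && ncol(co) >= 2) co[2, 2] else NA_real_
  c(slope = unname(stats::coef(fit)[2]), se = unname(se), n = sum(ok))
}

#' Growth rates of cluster metrics after antibody addition
#'
#' Ordinary-least-squares slope of each metric (`n_clusters`, `mean_area`,
#' `total_area`) against time on the post-addition segment, with the
#' pre-addition slopes reported alongside as a no-antibody baseline.
#'
#' @param series A [cluster_time_series()].
#' @return Data frame with columns `metric`, `segment` (`"pre"`/`"post"`),
#'   `slope` (units per second), `se`, `n_frames`.
#' @export
growth_rates <- function(series) {
  stopifnot(inherits(series, "cluster_time_series"))
  m <- series$metrics
  post <- m$frame_time >= series$addition_time
  if (sum(post) < 2)
    stop("at least two post-addition frames are required", call. = FALSE)
  out <- list()
  for (metric in c("n_clusters", "mean_area", "total_area")) {
    for (seg in c("pre", "post")) {
      sel <- if (seg == "post") post else !post
      est <- if (sum(sel) >= 2) ols_slope(m$frame_time[sel], m[[metric]][sel])
             else c(slope = NA_real_, se = NA_real_, n = sum(sel))
      out[[length(out) + 1L]] <- data.frame(
        metric = metric, segment = seg,
        slope = est[["slope"]], se = est[["se"]], n_frames = est[["n"]])
    }
  }
  do.call(rbind, out)
}

#' Quantify a clustering time-lapse end to end
#'
#' For each frame of the receptor channel: optional background reduction,
#' per-frame Renyi-entropy threshold (or one fixed threshold for the whole
#' series), 8-connected size-filtered cluster extraction, and per-frame
#' metrics; then growth-rate slopes on the post-addition segment.
#'
#' @param stack An [image_stack()].
#' @param addition_time Antibody addition time (s).
#' @param channel Name or index of the receptor channel (default `"BTX"`
#'   falling back to channel 1).
#' @param area_min,area_max Cluster area window in um^2.
#' @param background_radius Background-reduction radius in px, `NULL` to
#'   disable (default).
#' @param method Threshold method (see [renyi_threshold()]).
#' @param per_frame_threshold Compute the threshold per frame (default
#'   `TRUE`, one threshold per image) or once on the first post-addition
#'   frame and reuse it.
#' @return List with `series` (a [cluster_time_series()]), `rates`
#'   ([growth_rates()] table), `clusters` (all cluster records with a
#'   `frame` column), and `bubble` (frame_time, n_clusters, mean_area --
#'   the bubble-chart table).
#' @export
quantify_stack <- function(stack, addition_time, channel = "BTX",
                           area_min = 0.8, area_max = 10.0,
                           background_radius = NULL,
                           method = "sahoo_combined",
                           per_frame_threshold = TRUE) {
  stopifnot(inherits(stack, "image_stack"))
  ch <- if (is.character(channel)) match(channel, stack$channel_names)
        else as.integer(channel)
  if (is.na(ch)) {
    ## the default channel name falls back to a sole unnamed channel
    if (identical(channel, "BTX") && dim(stack$data)[2] == 1L) ch <- 1L
    else stop("channel '", channel, "' not found in stack", call. = FALSE)
  }
  n_frames <- dim(stack$data)[1]
  fixed_thr <- NULL
  if (!per_frame_threshold) {
    ref <- which(stack$frame_times >= addition_time)[1]
    if (is.na(ref)) ref <- n_frames
    f0 <- stack$data[ref, ch, , ]
    if (!is.null(background_radius)) f0 <- subtract_background(f0, background_radius)
    fixed_thr <- auto_threshold(f0, method = method)
  }
  metrics <- list(); clusters <- list()
  for (f in seq_len(n_frames)) {
    frame <- stack$data[f, ch, , ]
    cl <- segment_clusters(frame, stack$pixel_size, threshold = fixed_thr,
                           area_min = area_min, area_max = area_max,
                           background_radius = background_radius,
                           method = method)
    if (nrow(cl)) cl$frame <- f
    clusters[[f]] <- cl
    metrics[[f]] <- frame_metrics(cl, stack$frame_times[f])
  }
  m <- do.call(rbind, metrics)
  series <- cluster_time_series(m, addition_time)
  list(series = series,
       rates = growth_rates(series),
       clusters = do.call(rbind, clusters[vapply(clusters, nrow, 0L) > 0]),
       bubble = m[, c("frame_time", "n_clusters", "mean_area")])
}
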