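## ---------------------------------------------------------------------------
## NMJ morphometry from multichannel muscle-section images: presynaptic-mask
## delineation, receptor/presynaptic content ratio, complement deposition,
## fragmentation analysis, per-animal summaries.
## ---------------------------------------------------------------------------

#' Delineate neuromuscular junctions from the presynaptic channel
#'
#' Thresholds the presynaptic marker (SV2A) with the same Renyi-entropy
#' method used for cluster extraction, closes small gaps morphologically,
#' and keeps 8-connected regions of at least `min_area` square micrometres
#' as junction masks.
#'
#' @param sv2a_frame Numeric matrix (presynaptic channel).
#' @param pixel_size Pixel size in micrometres.
#' @param min_area Minimum junction area in um^2 (default 20).
#' @param closing_radius Disc radius in px for morphological closing
#'   (default 3; 0 disables).
#' @param threshold Intensity cutoff; `NULL` (default) uses
#'   [auto_threshold()].
#' @return List: `labels` (integer matrix, 0 = background) and `regions`
#'   (data frame: `nmj_id`, `area` um^2); a blank image yields zero regions.
#' @export
delineate_nmj <- function(sv2a_frame, pixel_size, min_area = 20,
                          closing_radius = 3, threshold = NULL) {
  if (pixel_size <= 0) stop("pixel_size must be > 0", call. = FALSE)
  if (is.null(threshold)) threshold <- auto_threshold(sv2a_frame)
  mask <- sv2a_frame > threshold
  if (closing_radius > 0 && any(mask)) {
    kern <- EBImage::makeBrush(2 * round(closing_radius) + 1, shape = "disc")
    mask <- EBImage::closing(matrix(as.numeric(mask), nrow(mask)), kern) > 0.5
  }
  empty <- list(labels = matrix(0L, nrow(sv2a_frame), ncol(sv2a_frame)),
                regions = data.frame(nmj_id = integer(0), area = numeric(0)))
  if (!any(mask)) return(empty)
  lab <- label_components(mask)
  npx <- tabulate(lab[lab > 0], max(lab))
  areas <- npx * pixel_size^2
  keep <- which(areas >= min_area)
  if (length(keep) == 0) return(empty)
  remap <- integer(max(lab))
  remap[keep] <- seq_along(keep)
  out <- matrix(0L, nrow(lab), ncol(lab))
  fg <- lab > 0
  out[fg] <- remap[lab[fg]]
  list(labels = out,
       regions = data.frame(nmj_id = seq_along(keep), area = areas[keep]))
}

## per-channel background: median intensity outside all junction masks
mask_background <- function(frame, labels) {
  outside <- frame[labels == 0L]
  if (length(outside) == 0) return(0)
  stats::median(outside)
}

#' Receptor content of each junction relative to the presynaptic marker
#'
#' For each labelled junction, the ratio of mean receptor-label (BTX)
#' intensity to mean presynaptic (SV2A) intensity within the mask, after
#' subtracting each channel's background (median intensity outside all
#' masks).  Means rather than sums make the ratio independent of mask area,
#' and the ratio is invariant under common intensity scaling of both
#' channels.
#'
#' @param btx_frame,sv2a_frame Co-registered numeric matrices of equal
#'   dimensions.
#' @param labels Junction label matrix from [delineate_nmj()].
#' @param background_subtract Subtract per-channel background medians
#'   (default `TRUE`).
#' @return Data frame: `nmj_id`, `btx_sv2a_ratio` (`NaN` with a warning
#'   when a junction has no SV2A signal above background).
#' @export
achr_content <- function(btx_frame, sv2a_frame, labels,
                         background_subtract = TRUE) {
  if (!all(dim(btx_frame) == dim(sv2a_frame)) ||
      !all(dim(btx_frame) == dim(labels)))
    stop("frames and labels must have identical dimensions", call. = FALSE)
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  bg_btx <- if (background_subtract) mask_background(btx_frame, labels) else 0
  bg_sv2a <- if (background_subtract) mask_background(sv2a_frame, labels) else 0
  ratio <- vapply(ids, function(id) {
    sel <- labels == id
    denom <- mean(sv2a_frame[sel]) - bg_sv2a
    num <- mean(btx_frame[sel]) - bg_btx
    if (denom <= 0) {
      warning("junction ", id, " has no SV2A signal above background; ratio is NaN")
      return(NaN)
    }
    num / denom
  }, 0)
  data.frame(nmj_id = ids, btx_sv2a_ratio = ratio)
}

#' Complement (C3) deposition intensity at each junction
#'
#' @param c3_frame Numeric matrix, co-registered with the label matrix.
#' @param labels Junction label matrix from [delineate_nmj()].
#' @param background_subtract Subtract the background median (default
#'   `TRUE`).
#' @return Data frame: `nmj_id`, `c3_mean_intensity`.
#' @export
c3_at_nmj <- function(c3_frame, labels, background_subtract = TRUE) {
  if (!all(dim(c3_frame) == dim(labels)))
    stop("frame and labels must have identical dimensions", call. = FALSE)
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  bg <- if (background_subtract) mask_background(c3_frame, labels) else 0
  data.frame(
    nmj_id = ids,
    c3_mean_intensity = vapply(ids, function(id)
      mean(c3_frame[labels == id]) - bg, 0))
}

#' Fragmentation analysis of the receptor channel
#'
#' Reproduces the structural workflow for single-junction image stacks:
#' maximum-intensity projection, optional background reduction,
#' Renyi-entropy threshold, and 8-connected object extraction; reports the
#' number of receptor fragments, their areas, and the mean fluorescence of
#' the thresholded objects.
#'
#' @param btx_stack 3-D array (Z x Y x X), list of planes, or a single
#'   matrix (already projected).
#' @param pixel_size Pixel size in micrometres.
#' @param background_radius Radius for [subtract_background()]; `NULL`
#'   disables (default).
#' @param threshold Intensity cutoff; `NULL` uses [auto_threshold()].
#' @param min_area Ignore specks below this area in um^2 (default 0.1).
#' @param region Optional logical matrix restricting the analysis to one
#'   junction's bounding region.
#' @return List of class `fragmentation_result`: `n_fragments`,
#'   `fragment_areas` (um^2), `total_area`, `mean_fluorescence`.
#' @export
fragmentation_analysis <- function(btx_stack, pixel_size,
                                   background_radius = NULL,
                                   threshold = NULL, min_area = 0.1,
                                   region = NULL) {
  frame <- if (is.matrix(btx_stack)) btx_stack else project_stack(btx_stack)
  work <- frame
  if (!is.null(background_radius))
    work <- subtract_background(work, background_radius)
  if (!is.null(region)) work[!region] <- min(work)
  if (is.null(threshold)) threshold <- auto_threshold(work)
  mask <- work > threshold
  if (!any(mask)) {
    return(structure(list(n_fragments = 0L, fragment_areas = numeric(0),
                          total_area = 0, mean_fluorescence = NaN),
                     class = "fragmentation_result"))
  }
  lab <- label_components(mask)
  npx <- tabulate(lab[lab > 0], max(lab))
  areas <- npx * pixel_size^2
  keep <- which(areas >= min_area)
  structure(
    list(n_fragments = length(keep),
         fragment_areas = unname(areas[keep]),
         total_area = sum(areas[keep]),
         mean_fluorescence = if (length(keep))
           mean(frame[lab %in% keep]) else NaN),
    class = "fragmentation_result"
  )
}

#' @export
print.fragmentation_result <- function(x, ...) {
  cat("Fragmentation:", x$n_fragments, "fragment(s), total area",
      round(x$total_area, 2), "um^2\n")
  invisible(x)
}

#' Per-animal means of junction metrics
#'
#' Collapses per-junction records to per-animal means, the unit of analysis
#' for group statistics (one value per animal avoids pseudo-replication
#' across junctions of the same muscle).
#'
#' @param records Data frame of per-junction measurements; must contain
#'   `animal_id`, and optionally `group`.
#' @param metrics Character vector of numeric columns to average; defaults
#'   to all numeric columns except identifiers.
#' @return Long-format data frame: `animal_id`, (`group`,) `metric`,
#'   `mean_value`, `n_nmj`.
#' @export
summarize_per_animal <- function(records, metrics = NULL) {
  if (!"animal_id" %in% names(records) || anyNA(records$animal_id))
    stop("every record needs an `animal_id`", call. = FALSE)
  if (is.null(metrics)) {
    metrics <- names(records)[vapply(records, is.numeric, TRUE)]
    metrics <- setdiff(metrics, c("nmj_id"))
  }
  has_group <- "group" %in% names(records)
  split_keys <- if (has_group)
    interaction(records$animal_id, records$group, drop = TRUE)
  else factor(records$animal_id)
  rows <- lapply(levels(split_keys), function(k) {
    sub <- records[split_keys == k, , drop = FALSE]
    do.call(rbind, lapply(metrics, function(mname) {
      data.frame(animal_id = sub$animal_id[1],
                 group = if (has_group) sub$group[1] else NA_character_,
                 metric = mname,
                 mean_value = mean(sub[[mname]], na.rm = TRUE),
                 n_nmj = nrow(sub))
    }))
  })
  out <- do.call(rbind, rows)
  if (!has_group) out$group <- NULL
  out
}
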