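## Independent oracles used across the suite.  These deliberately share no
## code with the implementation paths they check.

## Brute-force single-order Renyi threshold: plain loop over every split.
oracle_renyi_single <- function(counts, rho = 1) {
  p <- counts / sum(counts)
  n <- length(counts)
  H <- function(q) {
    q <- q[q > 0]
    if (!length(q)) return(-Inf)
    q <- q / sum(q)
    if (abs(rho - 1) < 1e-12) -sum(q * log(q)) else log(sum(q^rho)) / (1 - rho)
  }
  best <- -Inf; bt <- NA_integer_
  for (t in 1:(n - 1)) {
    if (sum(counts[1:t]) == 0 || sum(counts[(t + 1):n]) == 0) next
    v <- H(p[1:t]) + H(p[(t + 1):n])
    if (v > best + 1e-12) { best <- v; bt <- t }
  }
  bt
}

## Union-find component sizes of a crosslink graph (no igraph).
oracle_component_sizes <- function(graph) {
  n <- graph$n_receptors
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  ab <- graph$antibodies
  linked <- ab[!is.na(ab$receptor2), , drop = FALSE]
  for (k in seq_len(nrow(linked))) {
    a <- find(linked$receptor1[k]); b <- find(linked$receptor2[k])
    if (a != b) parent[a] <- b
  }
  roots <- vapply(seq_len(n), find, 0L)
  sort(as.integer(table(roots)))
}

## Receptor degrees (number of crosslinks touching each receptor).
receptor_degrees <- function(graph) {
  ab <- graph$antibodies
  linked <- ab[!is.na(ab$receptor2), , drop = FALSE]
  tabulate(c(linked$receptor1, linked$receptor2), graph$n_receptors)
}

## Queue-based flood fill with 8-connectivity (independent of EBImage).
oracle_label8 <- function(mask) {
  ny <- nrow(mask); nx <- ncol(mask)
  lab <- matrix(0L, ny, nx)
  cur <- 0L
  for (j in seq_len(nx)) for (i in seq_len(ny)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (di in -1:1) for (dj in -1:1) {
        y <- p[1] + di; x <- p[2] + dj
        if (y >= 1 && y <= ny && x >= 1 && x <= nx &&
            mask[y, x] && lab[y, x] == 0L) {
          lab[y, x] <- cur
          queue[[length(queue) + 1L]] <- c(y, x)
        }
      }
    }
  }
  lab
}

## Exhaustive Spearman permutation p-value via explicit recursion
## (independent of the package's permutation matrix construction).
oracle_spearman_exact_p <- function(x, y) {
  n <- length(x)
  rho <- function(a, b) stats::cor(rank(a), rank(b))
  r_obs <- abs(rho(x, y))
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  hits <- 0L; total <- 0L
  for (p in perms(seq_len(n))) {
    total <- total + 1L
    if (abs(rho(x, y[p])) >= r_obs - 1e-12) hits <- hits + 1L
  }
  hits / total
}

## Match detected clusters to planted disks by centroid distance; returns
## recall and precision over the frames present in the truth table.
score_detections <- function(truth, clusters) {
  tp <- 0L; fn <- 0L; fp <- 0L
  for (f in unique(truth$frame)) {
    t_f <- truth[truth$frame == f, , drop = FALSE]
    c_f <- if (is.null(clusters)) clusters[0, ] else
      clusters[clusters$frame == f, , drop = FALSE]
    used <- rep(FALSE, nrow(c_f))
    for (i in seq_len(nrow(t_f))) {
      d <- sqrt((c_f$cx + 1 - t_f$cx[i])^2 + (c_f$cy + 1 - t_f$cy[i])^2)
      j <- which(!used & d < t_f$radius_px[i] + 2)[1]
      if (!is.na(j)) { tp <- tp + 1L; used[j] <- TRUE } else fn <- fn + 1L
    }
    fp <- fp + sum(!used)
  }
  c(recall = tp / (tp + fn), precision = tp / (tp + fp))
}

## Paint a disk of a given physical area onto a frame (for filter tests).
paint_disk <- function(frame, cy, cx, area_um2, pixel_size, value) {
  r <- sqrt(area_um2 / pi) / pixel_size
  yy <- matrix(seq_len(nrow(frame)), nrow(frame), ncol(frame))
  xx <- matrix(seq_len(ncol(frame)), nrow(frame), ncol(frame), byrow = TRUE)
  m <- (yy - cy)^2 + (xx - cx)^2 <= r^2
  frame[m] <- value
  frame
}
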