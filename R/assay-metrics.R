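## ---------------------------------------------------------------------------
## Flow-style and functional assay statistics: GMFI ratios, 4PL
## dose-response / EC50, combination synergy indices, calcium-trace peaks,
## and the Spearman-with-permutation correlation test.
## ---------------------------------------------------------------------------

#' Rectangular gate on one channel
#'
#' @param channel Column name the gate applies to (e.g. `"gfp"`).
#' @param lower,upper Linear-intensity bounds, `lower < upper`.
#' @return An object of class `gate_spec`.
#' @export
gate_spec <- function(channel, lower, upper = Inf) {
  if (!is.character(channel) || length(channel) != 1L)
    stop("`channel` must be a single column name", call. = FALSE)
  if (lower >= upper) stop("gate requires lower < upper", call. = FALSE)
  structure(list(channel = channel, lower = lower, upper = upper),
            class = "gate_spec")
}

#' Default GFP gates from an untransfected control
#'
#' The negative gate keeps events below the 99.5th percentile of the
#' control's GFP distribution, the positive gate keeps events above it.
#'
#' @param control_gfp Numeric vector of GFP intensities from an
#'   untransfected control sample.
#' @param channel Gated channel name (default `"gfp"`).
#' @param q Percentile splitting the gates (default 0.995).
#' @return List with elements `neg` and `pos`, each a [gate_spec()].
#' @export
default_gfp_gates <- function(control_gfp, channel = "gfp", q = 0.995) {
  cut <- stats::quantile(control_gfp, q, names = FALSE)
  list(neg = gate_spec(channel, -Inf, cut),
       pos = gate_spec(channel, cut, Inf))
}

apply_gate <- function(events, gate) {
  x <- events[[gate$channel]]
  if (is.null(x)) stop("channel '", gate$channel, "' not found", call. = FALSE)
  x > gate$lower & x <= gate$upper
}

geometric_mean_positive <- function(x) {
  pos <- x[is.finite(x) & x > 0]
  list(gm = if (length(pos)) exp(mean(log(pos))) else NaN,
       n = length(pos), n_excluded = length(x) - length(pos))
}

#' Geometric-mean fluorescence intensity ratio between two gates
#'
#' The specific-binding (or complement-deposition) metric: the geometric
#' mean of the measured channel on antigen-expressing (positive-gate)
#' events divided by the geometric mean on non-expressing (negative-gate)
#' events.  Geometric means are computed as `exp(mean(log(x)))` over
#' strictly positive values; non-positive events (possible in compensated
#' flow exports) are excluded and counted.
#'
#' @param events Data frame of per-event channel intensities.
#' @param pos_gate,neg_gate [gate_spec()] objects defining the two
#'   populations.
#' @param channel Measured channel column (e.g. `"igg"` or `"c3"`).
#' @param min_events Minimum events required in each gate (default 100).
#' @param arithmetic Use arithmetic instead of geometric means (default
#'   `FALSE`).
#' @return An object of class `gmfi_result`: `gm_pos`, `gm_neg`, `ratio`,
#'   `n_pos`, `n_neg`, `n_excluded`.
#' @export
#' @examples
#' ev <- data.frame(gfp = c(1, 1, 1000, 1000), igg = c(10, 10, 10, 1000))
#' r <- gmfi_ratio(ev, gate_spec("gfp", 100), gate_spec("gfp", -Inf, 100),
#'                 channel = "igg", min_events = 1)
#' r$ratio   # gm(10, 1000) / gm(10, 10) = 10
gmfi_ratio <- function(events, pos_gate, neg_gate, channel = "igg",
                       min_events = 100L, arithmetic = FALSE) {
  if (is.null(events[[channel]]))
    stop("channel '", channel, "' not found", call. = FALSE)
  in_pos <- apply_gate(events, pos_gate)
  in_neg <- apply_gate(events, neg_gate)
  if (sum(in_pos) < min_events || sum(in_neg) < min_events)
    stop("insufficient events in gate (need >= ", min_events,
         " in each)", call. = FALSE)
  xp <- events[[channel]][in_pos]
  xn <- events[[channel]][in_neg]
  if (arithmetic) {
    gp <- list(gm = mean(xp), n = length(xp), n_excluded = 0L)
    gn <- list(gm = mean(xn), n = length(xn), n_excluded = 0L)
  } else {
    gp <- geometric_mean_positive(xp)
    gn <- geometric_mean_positive(xn)
  }
  if (!is.finite(gp$gm) || !is.finite(gn$gm))
    stop("all gated values non-positive; cannot form a geometric mean",
         call. = FALSE)
  structure(
    list(gm_pos = gp$gm, gm_neg = gn$gm, ratio = gp$gm / gn$gm,
         n_pos = gp$n, n_neg = gn$n,
         n_excluded = gp$n_excluded + gn$n_excluded),
    class = "gmfi_result"
  )
}

#' @export
print.gmfi_result <- function(x, ...) {
  cat(sprintf("GMFI ratio %.3g  (gm+ %.3g over %d events / gm- %.3g over %d)\n",
              x$ratio, x$gm_pos, x$n_pos, x$gm_neg, x$n_neg))
  invisible(x)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `R(c) = bottom + (top - bottom) / (1 + (ec50/c)^h)`
#' in log-concentration space, with multiple Hill-slope starts for
#' robustness.  EC50 is the concentration of half-maximal specific
#' response.
#'
#' @param conc Concentrations (positive, same units as the reported EC50,
#'   e.g. ng/ml); at least 5 values spanning at least two decades.
#' @param response Responses (e.g. GMFI ratios), same length.
#' @param hill_starts Hill-slope starting values (default `c(0.5, 1, 2)`).
#' @param flat_tol Minimum response span; flatter data raise a fit-failure
#'   error.
#' @return An object of class `fourpl_fit`: `bottom`, `top`, `ec50`,
#'   `hill`, `residual_norm`, `fitted`, and the input data.
#' @export
#' @examples
#' conc <- 10^seq(0, 4, length.out = 9)
#' resp <- 1 + (20 - 1) / (1 + (100 / conc)^1)
#' fit_4pl(conc, resp)$ec50
fit_4pl <- function(conc, response, hill_starts = c(0.5, 1, 2),
                    flat_tol = 1e-6) {
  if (length(conc) != length(response))
    stop("conc and response must have the same length", call. = FALSE)
  if (any(conc <= 0)) stop("concentrations must be positive", call. = FALSE)
  if (length(conc) < 5)
    stop("at least 5 concentrations are required", call. = FALSE)
  if (diff(range(log10(conc))) < 2)
    stop("concentrations must span at least two decades", call. = FALSE)
  span <- diff(range(response))
  if (span < flat_tol)
    stop("fit-failure: response is flat (span ", signif(span, 3),
         "); no dose dependence to fit", call. = FALSE)
  lc <- log10(conc)
  best <- NULL
  for (h0 in hill_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        response ~ bottom + (top - bottom) / (1 + 10^(hill * (lec50 - lc))),
        start = list(bottom = min(response), top = max(response),
                     lec50 = stats::median(lc), hill = h0),
        lower = c(-Inf, -Inf, min(lc) - 3, 1e-3),
        upper = c(Inf, Inf, max(lc) + 3, 100),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rn <- sqrt(sum(stats::residuals(fit)^2))
      if (is.null(best) || rn < best$rn) best <- list(fit = fit, rn = rn)
    }
  }
  if (is.null(best))
    stop("fit-failure: no 4PL start converged", call. = FALSE)
  cf <- stats::coef(best$fit)
  structure(
    list(bottom = unname(cf["bottom"]), top = unname(cf["top"]),
         ec50 = unname(10^cf["lec50"]), hill = unname(cf["hill"]),
         residual_norm = best$rn,
         fitted = unname(stats::fitted(best$fit)),
         conc = conc, response = response),
    class = "fourpl_fit"
  )
}

#' @export
print.fourpl_fit <- function(x, ...) {
  cat(sprintf("4PL fit: bottom %.3g, top %.3g, EC50 %.4g, hill %.3g (||r|| %.3g)\n",
              x$bottom, x$top, x$ec50, x$hill, x$residual_norm))
  invisible(x)
}

#' Fold enhancement of a combination over its best single antibody
#'
#' Combination assays are run at matched total antibody concentration (each
#' constituent at half), so a combination that merely pools independent
#' activities scores about 1; values well above 1 indicate synergy.
#'
#' @param single_a,single_b Responses (e.g. GMFI ratios) of the single
#'   antibodies at the full concentration.
#' @param combo Response of the combination at the same total
#'   concentration.
#' @return Scalar fold enhancement `combo / max(single_a, single_b)`.
#' @export
synergy_index <- function(single_a, single_b, combo) {
  if (any(c(single_a, single_b, combo) <= 0))
    stop("all inputs must be positive", call. = FALSE)
  combo / max(single_a, single_b)
}

#' Assemble a symmetric synergy matrix over an antibody panel
#'
#' @param singles Named numeric vector of single-antibody responses.
#' @param pairs Data frame with columns `a`, `b`, `response` for each
#'   measured pair (unordered).
#' @return List: `response` (symmetric matrix; diagonal = singles) and
#'   `fold` (fold enhancement over the best constituent single; diagonal
#'   1).
#' @export
synergy_matrix <- function(singles, pairs) {
  ids <- names(singles)
  if (is.null(ids)) stop("`singles` must be named", call. = FALSE)
  resp <- matrix(NA_real_, length(ids), length(ids),
                 dimnames = list(ids, ids))
  diag(resp) <- singles
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$a[k]; b <- pairs$b[k]
    resp[a, b] <- resp[b, a] <- pairs$response[k]
  }
  fold <- resp
  for (a in ids) for (b in ids)
    if (!is.na(resp[a, b]))
      fold[a, b] <- synergy_index(singles[[a]], singles[[b]], resp[a, b])
  list(response = resp, fold = fold)
}

#' Stimulus-evoked peak height of a fluorescence trace
#'
#' @param trace Numeric vector.
#' @param stim_index Stimulus frame (1-based, within the trace).
#' @param baseline_window Indices used for the baseline statistic; default
#'   is every frame before the stimulus.
#' @return Peak height: maximum over the post-stimulus window minus the
#'   median of the baseline window.
#' @export
trace_peak <- function(trace, stim_index,
                       baseline_window = seq_len(stim_index - 1L)) {
  if (stim_index < 1 || stim_index > length(trace))
    stop("stim_index out of range", call. = FALSE)
  if (length(baseline_window) < 1 || max(baseline_window) >= stim_index)
    stop("baseline window must precede the stimulus", call. = FALSE)
  max(trace[stim_index:length(trace)]) -
    stats::median(trace[baseline_window])
}

#' Normalize evoked peaks to the untreated-well mean
#'
#' @param peaks Peak heights of treated wells.
#' @param untreated_peaks Peak heights of untreated control wells.
#' @return `peaks / mean(untreated_peaks)`.
#' @export
normalize_transmission <- function(peaks, untreated_peaks) {
  m <- mean(untreated_peaks)
  if (!is.finite(m) || m <= 0)
    stop("untreated-well mean must be positive", call. = FALSE)
  peaks / m
}

## all permutations of 1..n (n <= 8 or so)
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Spearman correlation with a two-tailed permutation test
#'
#' Spearman's rho on mid-ranks (ties averaged), with significance from the
#' permutation distribution of rho under random re-pairing of `y`.  When
#' `n!` does not exceed `n_perm`, all `n!` permutations are enumerated and
#' the p-value is exact: the fraction of permutations (including the
#' identity) with `|rho*| >= |rho_obs|`.  Otherwise `n_perm` random
#' permutations are drawn and `p = (1 + #extreme) / (1 + n_perm)`.
#'
#' @param x,y Numeric vectors of equal length `n >= 3`.
#' @param n_perm Permutation budget (default 10000).
#' @param seed Integer seed for the Monte-Carlo branch.
#' @return An object of class `correlation_result`: `rho`, `p_two_tailed`,
#'   `n_perm` (permutations actually used), `exact`.
#' @export
#' @examples
#' r <- spearman_permutation(1:5, c(2, 1, 4, 3, 5), seed = 1)
#' c(r$rho, r$p_two_tailed)
spearman_permutation <- function(x, y, n_perm = 10000L, seed = 1L) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length", call. = FALSE)
  if (n < 3) stop("at least 3 pairs are required", call. = FALSE)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("correlation undefined: constant input", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  rx_c <- rx - mean(rx); ry_c <- ry - mean(ry)
  denom <- sqrt(sum(rx_c^2) * sum(ry_c^2))
  rho_obs <- sum(rx_c * ry_c) / denom
  eps <- 1e-12
  exact <- factorial(n) <= n_perm
  if (exact) {
    perms <- all_permutations(n)
    rho_perm <- as.vector((matrix(ry_c[t(perms)], nrow(perms), n,
                                  byrow = TRUE) %*% rx_c) / denom)
    p <- mean(abs(rho_perm) >= abs(rho_obs) - eps)
    used <- nrow(perms)
  } else {
    p <- with_seed(seed, {
      hits <- 0L
      block <- 500L
      done <- 0L
      while (done < n_perm) {
        b <- min(block, n_perm - done)
        pm <- matrix(0, b, n)
        for (i in seq_len(b)) pm[i, ] <- ry_c[sample.int(n)]
        rho_perm <- as.vector((pm %*% rx_c) / denom)
        hits <- hits + sum(abs(rho_perm) >= abs(rho_obs) - eps)
        done <- done + b
      }
      (1 + hits) / (1 + n_perm)
    })
    used <- n_perm
  }
  structure(
    list(rho = rho_obs, p_two_tailed = p, n_perm = used, exact = exact),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, two-tailed permutation p = %.4g (%s, %d perms)\n",
              x$rho, x$p_two_tailed,
              if (x$exact) "exact" else "Monte Carlo", x$n_perm))
  invisible(x)
}
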