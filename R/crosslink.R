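## ---------------------------------------------------------------------------
## Receptor-antibody crosslinking model
##
## Receptors are multi-epitope particles (the adult muscle AChR pentamer
## carries two alpha epitopes and one each of beta, delta, epsilon).  IgG
## antibodies are bivalent; each arm can occupy one free epitope of the
## antibody's target subunit.  Binding is modelled as random sequential
## attachment with two rate constants and no unbinding: a solution antibody
## attaches a first arm (rate k_on per arm-epitope pair), a singly bound
## antibody attaches its second arm to a free compatible epitope on another
## receptor (rate k_cross per pair), crosslinking the two receptors.
## ---------------------------------------------------------------------------

#' Default AChR subunit stoichiometry
#'
#' The adult muscle acetylcholine receptor is a pentamer of two alpha
#' subunits and one each of beta, delta and epsilon, so an antibody against
#' a non-alpha subunit sees one epitope per receptor while an anti-alpha
#' antibody sees two.
#'
#' @return Named integer vector of epitope copies per receptor.
#' @export
#' @examples
#' achr_stoichiometry()
achr_stoichiometry <- function() {
  c(alpha = 2L, beta = 1L, delta = 1L, epsilon = 1L)
}

#' Create a pool of free receptors
#'
#' @param n Number of receptors (>= 1).
#' @param stoichiometry Named integer vector mapping subunit name to epitope
#'   copies per receptor; defaults to [achr_stoichiometry()].
#' @return An object of class `receptor_pool`.
#' @export
#' @examples
#' make_receptor_pool(10)
make_receptor_pool <- function(n, stoichiometry = achr_stoichiometry()) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 1)
    stop("`n` must be a single integer >= 1", call. = FALSE)
  stoichiometry <- validate_stoichiometry(stoichiometry)
  structure(
    list(n = as.integer(n), stoichiometry = stoichiometry),
    class = "receptor_pool"
  )
}

validate_stoichiometry <- function(stoichiometry) {
  if (is.null(names(stoichiometry)) || any(!nzchar(names(stoichiometry))))
    stop("stoichiometry must be a named vector", call. = FALSE)
  s <- as.integer(stoichiometry)
  names(s) <- names(stoichiometry)
  if (any(is.na(s)) || any(s < 0))
    stop("stoichiometry counts must be non-negative integers", call. = FALSE)
  if (sum(s) < 1)
    stop("stoichiometry must provide at least one epitope", call. = FALSE)
  s
}

#' @export
print.receptor_pool <- function(x, ...) {
  cat("Receptor pool:", x$n, "receptors;",
      "epitopes per receptor:",
      paste(sprintf("%s=%d", names(x$stoichiometry), x$stoichiometry),
            collapse = ", "), "\n")
  invisible(x)
}

#' Define a bivalent antibody species
#'
#' @param id Label for the species (e.g. `"aG1_01"`).
#' @param target Name of the targeted subunit; must match a stoichiometry key
#'   at simulation time.
#' @param count Number of antibody molecules supplied in solution.
#' @param subclass Optional free-text subclass annotation (e.g. IgG1, IgG4);
#'   metadata only, the binding model does not use it.
#' @return An object of class `antibody_species`.
#' @export
#' @examples
#' antibody_species("bG4_02", "beta", 100)
antibody_species <- function(id, target, count, subclass = NA_character_) {
  if (!is.character(id) || length(id) != 1L)
    stop("`id` must be a single string", call. = FALSE)
  if (!is.character(target) || length(target) != 1L)
    stop("`target` must be a single subunit name", call. = FALSE)
  if (!is.numeric(count) || length(count) != 1L || is.na(count) || count < 0)
    stop("`count` must be a non-negative integer", call. = FALSE)
  structure(
    list(id = id, target = target, count = as.integer(count),
         valence = 2L, subclass = as.character(subclass)),
    class = "antibody_species"
  )
}

#' Kinetic parameters for the crosslinking simulation
#'
#' @param k_on Rate constant for a solution antibody arm binding a free
#'   compatible epitope (per arm-epitope pair; arbitrary units -- only the
#'   ratio `k_cross / k_on` matters for the final graph).
#' @param k_cross Rate constant for the free arm of a singly bound antibody
#'   binding a free compatible epitope on another receptor.
#' @param allow_intra_receptor May an antibody bridge the two alpha epitopes
#'   of one receptor?  Default `FALSE`: crosslinks must join two receptors.
#' @param allow_cycles May a crosslink close a cycle (join two receptors
#'   already in the same aggregate)?  Default `TRUE`.
#' @param max_events Hard cap on the number of binding events; `Inf` runs to
#'   exhaustion.
#' @param mode `"well_mixed"` (default; any receptor reachable) or
#'   `"geometric"` (receptors carry 2-D positions and the second arm reaches
#'   only receptors within `capture_radius`).
#' @param capture_radius Reach of the second arm in nm, geometric mode only.
#'   Default 15 nm, matching the span of an IgG binding epitopes roughly
#'   10 nm apart at synaptic receptor densities.
#' @param density Receptor surface density for geometric mode, receptors per
#'   square micrometre.  Default 1000.
#' @return An object of class `binding_params`.
#' @export
binding_params <- function(k_on = 1, k_cross = 1,
                           allow_intra_receptor = FALSE,
                           allow_cycles = TRUE,
                           max_events = Inf,
                           mode = c("well_mixed", "geometric"),
                           capture_radius = 15,
                           density = 1000) {
  mode <- match.arg(mode)
  if (k_on < 0 || k_cross < 0) stop("rates must be >= 0", call. = FALSE)
  if (max_events < 0) stop("max_events must be >= 0", call. = FALSE)
  if (capture_radius <= 0) stop("capture_radius must be > 0", call. = FALSE)
  structure(
    list(k_on = k_on, k_cross = k_cross,
         allow_intra_receptor = isTRUE(allow_intra_receptor),
         allow_cycles = isTRUE(allow_cycles),
         max_events = max_events, mode = mode,
         capture_radius = capture_radius, density = density),
    class = "binding_params"
  )
}

## Evaluate `expr` under a private RNG stream seeded by `seed`, restoring the
## caller's RNG state afterwards (relies on lazy evaluation of `expr`).
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

## Weighted draw of one index; returns 0 when all weights are zero.
draw_index <- function(w) {
  tot <- sum(w)
  if (tot <= 0) return(0L)
  cs <- cumsum(w)
  u <- stats::runif(1) * tot
  idx <- findInterval(u, cs, left.open = TRUE) + 1L
  min(idx, length(w))
}

#' Simulate antibody binding and crosslinking
#'
#' Random-sequential-attachment (Gillespie-style, no unbinding) simulation of
#' bivalent antibodies binding a pool of multi-epitope receptors.  At each
#' step the possible events are: a solution antibody of species `s` binds a
#' random free epitope of its target subunit (weight `k_on` per arm-epitope
#' pair), or a singly bound antibody's free arm binds a free compatible
#' epitope on a different receptor (weight `k_cross` per pair; same-receptor
#' binding only if `allow_intra_receptor`).  The loop ends when no event is
#' possible or `max_events` is reached.  Identical seeds give identical
#' graphs.
#'
#' @param pool A [make_receptor_pool()] object.
#' @param species List of [antibody_species()] (may be empty).
#' @param params A [binding_params()] object.
#' @param seed Integer seed; the simulation is deterministic given the seed.
#' @param positions Optional n x 2 matrix of receptor positions in
#'   micrometres (geometric mode).  If `NULL` in geometric mode, positions
#'   are drawn uniformly on a square field sized so the receptor density
#'   equals `params$density`.
#' @return An object of class `crosslink_graph` with elements
#'   `n_receptors`, `stoichiometry`, `occupancy` (receptor x subunit count of
#'   bound epitopes), `antibodies` (data frame of attachments; `receptor2`
#'   is `NA` for singly bound molecules), `free_in_solution` (named count of
#'   unbound molecules per species), `positions` and `params`.
#' @export
#' @examples
#' pool <- make_receptor_pool(20)
#' abs <- list(antibody_species("anti-beta", "beta", 20))
#' g <- simulate_binding(pool, abs, binding_params(), seed = 1)
#' component_stats(g)$max_size   # single non-alpha species: dimers at most
simulate_binding <- function(pool, species, params = binding_params(),
                             seed = 1L, positions = NULL) {
  stopifnot(inherits(pool, "receptor_pool"), inherits(params, "binding_params"))
  if (length(species) > 0 && inherits(species, "antibody_species"))
    species <- list(species)
  stoich <- pool$stoichiometry
  subunits <- names(stoich)
  for (sp in species) {
    if (!inherits(sp, "antibody_species"))
      stop("`species` must be a list of antibody_species objects", call. = FALSE)
    if (!sp$target %in% subunits)
      stop(sprintf("unknown target subunit '%s'", sp$target), call. = FALSE)
  }
  n <- pool$n
  nsub <- length(subunits)
  nsp <- length(species)
  tgt <- if (nsp) match(vapply(species, `[[`, "", "target"), subunits) else integer(0)
  sol <- if (nsp) vapply(species, `[[`, 0L, "count") else integer(0)
  sp_ids <- if (nsp) vapply(species, `[[`, "", "id") else character(0)

  geometric <- params$mode == "geometric"

  with_seed(seed, {
    if (geometric && is.null(positions)) {
      side <- sqrt(n / params$density)           # um
      positions <- cbind(stats::runif(n, 0, side), stats::runif(n, 0, side))
    }
    neighbours <- NULL
    if (geometric) {
      r_um <- params$capture_radius / 1000
      d2 <- as.matrix(stats::dist(positions))^2
      neighbours <- lapply(seq_len(n), function(i)
        setdiff(which(d2[i, ] <= r_um^2), i))
    }

    ## free epitope counts, receptor x subunit
    free <- matrix(rep(stoich, each = n), nrow = n, ncol = nsub,
                   dimnames = list(NULL, subunits))
    total_free <- colSums(free)
    ## bound antibody records (grown in blocks)
    cap <- max(16L, sum(sol) + 8L)
    ab_sp <- integer(cap); ab_r1 <- integer(cap); ab_r2 <- integer(cap)
    n_ab <- 0L
    singly <- integer(0)          # indices into ab_* of singly bound abs
    parent <- seq_len(n)          # union-find over receptors (for cycle ban)
    uf_find <- function(x) {
      while (parent[x] != x) {
        parent[x] <<- parent[parent[x]]
        x <- parent[x]
      }
      x
    }

    ## In the default well-mixed, cycles-allowed regime the number of
    ## second-arm candidates for a singly bound antibody reduces to
    ## total_free[target] minus (unless intra-receptor binding is allowed)
    ## the free epitopes on its own receptor, so cross weights need no
    ## per-antibody scan.
    fast <- !geometric && params$allow_cycles

    ## candidate second-arm epitope counts per receptor (general path)
    cross_avail <- function(i) {
      u <- tgt[ab_sp[i]]
      r1 <- ab_r1[i]
      f <- free[, u]
      if (geometric) {
        keep <- logical(n)
        keep[neighbours[[r1]]] <- TRUE
        if (params$allow_intra_receptor) keep[r1] <- TRUE
        f[!keep] <- 0L
      } else if (!params$allow_intra_receptor) {
        f[r1] <- 0L
      }
      if (!params$allow_cycles && any(f > 0)) {
        c1 <- uf_find(r1)
        same <- vapply(which(f > 0), function(r) uf_find(r) == c1, FALSE)
        f[which(f > 0)[same]] <- 0L
      }
      f
    }

    events <- 0L
    repeat {
      if (events >= params$max_events) break
      w_on <- if (nsp) params$k_on * sol * total_free[tgt] else numeric(0)
      if (length(singly)) {
        if (fast) {
          su <- tgt[ab_sp[singly]]
          avail_n <- total_free[su]
          if (!params$allow_intra_receptor)
            avail_n <- avail_n - free[cbind(ab_r1[singly], su)]
          w_cross <- params$k_cross * avail_n
        } else {
          w_cross <- params$k_cross *
            vapply(singly, function(i) sum(cross_avail(i)), 0)
        }
      } else w_cross <- numeric(0)
      k <- draw_index(c(w_on, w_cross))
      if (k == 0L) break
      if (k <= nsp) {
        ## first-arm attachment from solution
        s <- k
        u <- tgt[s]
        r <- draw_index(free[, u])
        free[r, u] <- free[r, u] - 1L
        total_free[u] <- total_free[u] - 1L
        sol[s] <- sol[s] - 1L
        n_ab <- n_ab + 1L
        if (n_ab > cap) {
          cap <- cap * 2L
          length(ab_sp) <- cap; length(ab_r1) <- cap; length(ab_r2) <- cap
        }
        ab_sp[n_ab] <- s; ab_r1[n_ab] <- r; ab_r2[n_ab] <- NA_integer_
        singly <- c(singly, n_ab)
      } else {
        ## second-arm crosslink
        i <- singly[k - nsp]
        u <- tgt[ab_sp[i]]
        f <- if (fast) {
          fv <- free[, u]
          if (!params$allow_intra_receptor) fv[ab_r1[i]] <- 0L
          fv
        } else cross_avail(i)
        r <- draw_index(f)
        free[r, u] <- free[r, u] - 1L
        total_free[u] <- total_free[u] - 1L
        ab_r2[i] <- r
        singly <- singly[singly != i]
        ra <- uf_find(ab_r1[i]); rb <- uf_find(r)
        if (ra != rb) parent[ra] <- rb
      }
      events <- events + 1L
    }

    antibodies <- data.frame(
      species = if (n_ab) sp_ids[ab_sp[seq_len(n_ab)]] else character(0),
      target = if (n_ab) subunits[tgt[ab_sp[seq_len(n_ab)]]] else character(0),
      receptor1 = ab_r1[seq_len(n_ab)],
      receptor2 = ab_r2[seq_len(n_ab)],
      stringsAsFactors = FALSE
    )
    occupancy <- matrix(rep(stoich, each = n), nrow = n) - free
    colnames(occupancy) <- subunits
    structure(
      list(n_receptors = n, stoichiometry = stoich,
           occupancy = occupancy, antibodies = antibodies,
           free_in_solution = stats::setNames(sol, sp_ids),
           positions = positions, params = params, seed = seed,
           n_events = events),
      class = "crosslink_graph"
    )
  })
}

#' Validate the structural invariants of a crosslink graph
#'
#' Checks that no epitope is bound twice (occupancy never exceeds the
#' stoichiometry), every antibody has at most two attachments referencing
#' existing receptors, and the occupancy matrix agrees with the attachment
#' records.  Called by the simulator's tests; useful for externally
#' constructed graphs.
#'
#' @param graph A `crosslink_graph`.
#' @return `TRUE` invisibly, or an error describing the violated invariant.
#' @export
validate_crosslink_graph <- function(graph) {
  stopifnot(inherits(graph, "crosslink_graph"))
  n <- graph$n_receptors
  stoich <- graph$stoichiometry
  occ <- graph$occupancy
  if (any(occ < 0) || any(sweep(occ, 2, stoich[colnames(occ)], `>`)))
    stop("occupancy exceeds stoichiometry (an epitope bound twice)")
  ab <- graph$antibodies
  if (any(ab$receptor1 < 1 | ab$receptor1 > n, na.rm = TRUE) ||
      any(ab$receptor2 < 1 | ab$receptor2 > n, na.rm = TRUE))
    stop("attachment references a non-existent receptor")
  ## recompute occupancy from attachments
  expect <- matrix(0L, n, ncol(occ), dimnames = dimnames(occ))
  for (k in seq_len(nrow(ab))) {
    u <- ab$target[k]
    expect[ab$receptor1[k], u] <- expect[ab$receptor1[k], u] + 1L
    if (!is.na(ab$receptor2[k]))
      expect[ab$receptor2[k], u] <- expect[ab$receptor2[k], u] + 1L
  }
  if (!identical(unname(expect), unname(occ)))
    stop("occupancy matrix inconsistent with attachment records")
  invisible(TRUE)
}

#' @export
print.crosslink_graph <- function(x, ...) {
  nb <- nrow(x$antibodies)
  nd <- sum(!is.na(x$antibodies$receptor2))
  cat("Crosslink graph:", x$n_receptors, "receptors;",
      nb, "bound antibodies (", nd, "crosslinking );",
      sum(x$free_in_solution), "left in solution\n")
  invisible(x)
}

#' Aggregate-size statistics of a crosslink graph
#'
#' Receptors are connected when they share a (doubly bound) antibody; the
#' connected components of that receptor projection are the antibody-driven
#' aggregates.  Aggregate size distributions distinguish the binding
#' regimes: one non-alpha species yields dimers at most, one anti-alpha
#' species yields linear chains, and mixed-subunit combinations yield large
#' branched lattices.
#'
#' @param graph A `crosslink_graph`.
#' @return An object of class `aggregate_stats`: `component_sizes` (sorted
#'   receptor counts, one per component), `max_size`, `mean_size`, and
#'   `n_receptors`.
#' @export
component_stats <- function(graph) {
  stopifnot(inherits(graph, "crosslink_graph"))
  ab <- graph$antibodies
  linked <- ab[!is.na(ab$receptor2), , drop = FALSE]
  g <- igraph::make_empty_graph(n = graph$n_receptors, directed = FALSE)
  if (nrow(linked) > 0) {
    g <- igraph::add_edges(g, rbind(linked$receptor1, linked$receptor2))
  }
  comp <- igraph::components(g)
  sizes <- sort(as.integer(comp$csize))
  structure(
    list(component_sizes = sizes,
         max_size = max(sizes),
         mean_size = mean(sizes),
         n_receptors = graph$n_receptors),
    class = "aggregate_stats"
  )
}

#' @export
print.aggregate_stats <- function(x, ...) {
  cat("Aggregates over", x$n_receptors, "receptors:",
      length(x$component_sizes), "components; max",
      x$max_size, "; mean", round(x$mean_size, 2), "\n")
  invisible(x)
}

#' Fraction of receptors in aggregates of at least a given size
#'
#' @param stats An `aggregate_stats` object.
#' @param k Integer size threshold(s).
#' @return Numeric vector: for each `k`, the fraction of receptors residing
#'   in components of `>= k` receptors (non-increasing in `k`).
#' @export
receptor_fraction_ge <- function(stats, k) {
  stopifnot(inherits(stats, "aggregate_stats"))
  vapply(k, function(kk) {
    sum(stats$component_sizes[stats$component_sizes >= kk]) /
      sum(stats$component_sizes)
  }, 0)
}

#' Complement-activation proxy from aggregate sizes
#'
#' Complement initiation requires stable supramolecular antigen-antibody
#' platforms; as a monotone stand-in this proxy reports the fraction of
#' receptors residing in aggregates of at least `s_min` receptors.  It is a
#' qualitative surrogate: no quantitative mapping from aggregate size to C3
#' deposition is implied.
#'
#' @param stats An `aggregate_stats` object.
#' @param s_min Minimum aggregate size counted as a platform (default 4).
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' g <- simulate_binding(make_receptor_pool(50),
#'                       list(antibody_species("d", "delta", 25),
#'                            antibody_species("e", "epsilon", 25)),
#'                       seed = 7)
#' complement_proxy(component_stats(g))
complement_proxy <- function(stats, s_min = 4L) {
  if (!is.numeric(s_min) || length(s_min) != 1L || is.na(s_min) || s_min < 1)
    stop("`s_min` must be a single integer >= 1", call. = FALSE)
  receptor_fraction_ge(stats, as.integer(s_min))
}

#' Sweep single antibodies and pairwise combinations
#'
#' Runs the crosslinking simulation for every species alone and for every
#' (unordered) pair of species at matched total antibody count: singles use
#' `count_total` molecules, pairs use `count_total / 2` of each, mirroring
#' combination assays performed at half the concentration of each antibody
#' so the total stays constant.
#'
#' @param n_receptors Receptors per simulation (default 200).
#' @param panel List of [antibody_species()]; the `count` fields are ignored
#'   in favour of `count_total`.
#' @param params [binding_params()].
#' @param count_total Total antibody molecules per condition.  The default,
#'   two molecules per receptor, is a saturating dose: each single species
#'   supplies at least as many molecules as it has target epitopes.  In this
#'   antibody-excess regime free antibody caps epitopes faster than singly
#'   bound antibody can crosslink them, so single species stay in the
#'   dimer/short-chain regime while mixed-subunit pairs, with more epitope
#'   classes per receptor, still assemble large branched lattices.
#' @param seeds Integer vector of seeds; entries are means over seeds.
#' @param s_min Aggregate-size cutoff for [complement_proxy()].
#' @param stoichiometry Subunit stoichiometry for the receptor pool.
#' @return A long-format data frame with one row per condition:
#'   `species_a`, `species_b` (equal for singles), `proxy_mean`, `proxy_sd`,
#'   `mean_size_mean`, `mean_size_sd`, `n_seeds`.
#' @export
sweep_combinations <- function(n_receptors = 200L, panel,
                               params = binding_params(),
                               count_total = 2L * n_receptors,
                               seeds = 1:10, s_min = 4L,
                               stoichiometry = achr_stoichiometry()) {
  if (length(panel) < 1) stop("`panel` must contain at least one species", call. = FALSE)
  if (length(seeds) < 1) stop("at least one seed is required", call. = FALSE)
  pool <- make_receptor_pool(n_receptors, stoichiometry)
  ids <- vapply(panel, `[[`, "", "id")
  conditions <- list()
  for (i in seq_along(panel)) {
    for (j in i:length(panel)) {
      if (i == j) {
        sp <- list(antibody_species(ids[i], panel[[i]]$target, count_total,
                                    panel[[i]]$subclass))
      } else {
        sp <- list(
          antibody_species(ids[i], panel[[i]]$target, count_total %/% 2L,
                           panel[[i]]$subclass),
          antibody_species(ids[j], panel[[j]]$target,
                           count_total - count_total %/% 2L,
                           panel[[j]]$subclass))
      }
      conditions[[length(conditions) + 1L]] <- list(a = ids[i], b = ids[j], sp = sp)
    }
  }
  rows <- lapply(conditions, function(cond) {
    prox <- numeric(length(seeds))
    msize <- numeric(length(seeds))
    for (k in seq_along(seeds)) {
      g <- simulate_binding(pool, cond$sp, params, seed = seeds[k])
      st <- component_stats(g)
      prox[k] <- complement_proxy(st, s_min)
      msize[k] <- st$mean_size
    }
    data.frame(species_a = cond$a, species_b = cond$b,
               proxy_mean = mean(prox), proxy_sd = stats::sd(prox),
               mean_size_mean = mean(msize), mean_size_sd = stats::sd(msize),
               n_seeds = length(seeds), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "s_min") <- s_min
  attr(out, "count_total") <- count_total
  out
}

#' Exact outcome distribution for small crosslinking systems
#'
#' Exhaustively enumerates every possible sequence of binding events for a
#' small receptor pool and antibody load, propagating the exact probability
#' of each branch (event weights as in [simulate_binding()]), and aggregates
#' the terminal states by their aggregate-size multiset.  Feasible only for
#' a handful of receptors and antibodies; serves as the exact reference
#' distribution that the stochastic simulator must reproduce.
#'
#' @param pool A [make_receptor_pool()] object (keep `n` at 4 or less).
#' @param species List of [antibody_species()] (3 molecules or fewer in
#'   total, or enumeration explodes).
#' @param params [binding_params()]; `well_mixed` mode only.
#' @return Data frame with `outcome` (component sizes as a sorted
#'   `+`-separated string, e.g. `"1+1+2"`) and `probability` (sums to 1).
#' @export
#' @examples
#' pool <- make_receptor_pool(3)
#' sp <- list(antibody_species("a", "alpha", 1))
#' enumerate_binding_outcomes(pool, sp)
enumerate_binding_outcomes <- function(pool, species, params = binding_params()) {
  stopifnot(inherits(pool, "receptor_pool"))
  if (params$mode != "well_mixed")
    stop("enumeration supports well_mixed mode only", call. = FALSE)
  stoich <- pool$stoichiometry
  subunits <- names(stoich)
  n <- pool$n
  nsp <- length(species)
  tgt <- if (nsp) match(vapply(species, `[[`, "", "target"), subunits) else integer(0)
  if (any(is.na(tgt))) stop("unknown target subunit", call. = FALSE)

  acc <- new.env(parent = emptyenv())
  add_outcome <- function(key, p) {
    assign(key, p + (if (exists(key, acc)) get(key, acc) else 0), envir = acc)
  }
  comp_key <- function(edges) {
    g <- igraph::make_empty_graph(n = n, directed = FALSE)
    if (length(edges)) g <- igraph::add_edges(g, unlist(edges))
    paste(sort(igraph::components(g)$csize), collapse = "+")
  }

  recurse <- function(free, sol, singly, edges, p, depth) {
    ## singly: list of (sp, r1)
    total_free <- colSums(free)
    w_on <- if (nsp) params$k_on * sol * total_free[tgt] else numeric(0)
    avail <- lapply(singly, function(b) {
      f <- free[, tgt[b$sp]]
      if (!params$allow_intra_receptor) f[b$r1] <- 0L
      f
    })
    w_cross <- params$k_cross * vapply(avail, sum, 0)
    tot <- sum(w_on) + sum(w_cross)
    if (tot <= 0 || depth >= params$max_events) {
      add_outcome(comp_key(edges), p)
      return(invisible(NULL))
    }
    for (s in seq_len(nsp)) {
      if (w_on[s] <= 0) next
      for (r in which(free[, tgt[s]] > 0)) {
        p_ev <- (params$k_on * sol[s] * free[r, tgt[s]]) / tot
        free2 <- free; free2[r, tgt[s]] <- free2[r, tgt[s]] - 1L
        sol2 <- sol; sol2[s] <- sol2[s] - 1L
        recurse(free2, sol2, c(singly, list(list(sp = s, r1 = r))),
                edges, p * p_ev, depth + 1L)
      }
    }
    for (bi in seq_along(singly)) {
      if (w_cross[bi] <= 0) next
      b <- singly[[bi]]
      f <- avail[[bi]]
      for (r in which(f > 0)) {
        p_ev <- (params$k_cross * f[r]) / tot
        free2 <- free; free2[r, tgt[b$sp]] <- free2[r, tgt[b$sp]] - 1L
        recurse(free2, sol, singly[-bi],
                c(edges, list(c(b$r1, r))), p * p_ev, depth + 1L)
      }
    }
  }

  free0 <- matrix(rep(stoich, each = n), nrow = n, dimnames = list(NULL, subunits))
  sol0 <- if (nsp) vapply(species, `[[`, 0L, "count") else integer(0)
  recurse(free0, sol0, list(), list(), 1, 0L)

  keys <- ls(acc)
  out <- data.frame(outcome = keys,
                    probability = vapply(keys, get, 0, envir = acc),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(out$outcome), , drop = FALSE]
}
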