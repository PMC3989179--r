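# Barcode-gap discovery: detect a significant discontinuity in the ranked
# pairwise distances above a prior maximum intraspecific divergence, cut the
# single-linkage graph there, recurse within groups, and sweep the prior
# over a geometric series.

# a dataset whose largest pairwise distance sits below this carries too
# little variation for any gap scan (treated as a single species, flagged)
DEGENERATE_MAX_DIST <- 0.005

#' Configuration for the barcode-gap prior sweep
#'
#' @param pmin,pmax Smallest/largest prior maximum intraspecific divergence
#'   (K2P substitutions/site). Defaults 0.001 and 0.2.
#' @param steps Number of priors in the sweep (geometrically spaced),
#'   default 20. At least 4, since the stability rule downstream needs runs
#'   of three successive priors.
#' @param X Relative gap width: a gap is significant when it exceeds `X`
#'   times the local mean gap. Default 1.5.
#' @param bins Bin count for the diagnostic distance histogram (display
#'   only; plays no part in gap detection). Default 20.
#' @param window Number of preceding gaps over which the local mean gap is
#'   taken. Default 10.
#' @return A list of class `sweep_config`.
#' @export
sweep_config <- function(pmin = 0.001, pmax = 0.2, steps = 20, X = 1.5,
                         bins = 20, window = 10) {
  stopifnot(pmin > 0, pmin < pmax, pmax < 1, steps >= 4, X > 0,
            window >= 1, bins >= 1)
  structure(list(pmin = pmin, pmax = pmax, steps = as.integer(steps),
                 X = X, bins = as.integer(bins), window = as.integer(window)),
            class = "sweep_config")
}

#' The geometric series of priors used by a sweep
#' @param config A [sweep_config()].
#' @return Numeric vector of length `config$steps`, strictly increasing from
#'   `pmin` to `pmax`.
#' @export
sweep_priors <- function(config = sweep_config()) {
  k <- seq(0L, config$steps - 1L)
  config$pmin * (config$pmax / config$pmin)^(k / (config$steps - 1L))
}

#' Locate the first significant gap in ranked pairwise distances
#'
#' The distinct distances are sorted; the gap after rank `i`,
#' `g(i) = d(i+1) - d(i)`, is a candidate when it reaches the prior (its
#' upper edge `d(i+1) >= prior`; distances wholly below the prior are
#' assumed intraspecific and never separated), and is significant when
#' `g(i) > X * w(i)`, where `w(i)` is the mean of the up-to-`window`
#' preceding gaps. The run of gaps starts at the baseline gap from zero
#' divergence up to the smallest distance, which supplies the intraspecific
#' scale but can never itself be significant. The first (lowest-rank)
#' significant gap wins; its lower edge `d(i)`, the last pre-gap distance,
#' is the single-linkage threshold (pairs at or below it stay connected).
#'
#' @param distances Numeric vector of pairwise distances (need not be
#'   sorted or unique).
#' @param prior Prior maximum intraspecific divergence `P`.
#' @param config A [sweep_config()] (supplies `X` and `window`).
#' @return A list of class `gap_scan`: `values` (sorted distinct distances),
#'   `gaps`, `prior`, `significant_index` (rank into `values`, or `NA`),
#'   `threshold` (the distance at that rank, or `NA`), `insufficient`
#'   (`TRUE` when fewer than 2 distinct distances were available).
#' @export
find_significant_gap <- function(distances, prior, config = sweep_config()) {
  v <- sort(unique(distances))
  if (length(v) < 2L) {
    return(structure(list(values = v, gaps = numeric(0), prior = prior,
                          significant_index = NA_integer_,
                          threshold = NA_real_, insufficient = TRUE),
                     class = "gap_scan"))
  }
  # g[1] is the baseline gap 0 -> d(1); g[i+1] is the gap after rank i
  g <- diff(c(0, v))
  sig <- NA_integer_
  for (i in seq_len(length(v) - 1L)) {
    if (v[i + 1L] < prior) next
    lo <- max(1L, i + 1L - config$window)
    w <- mean(g[lo:i])
    if (g[i + 1L] > config$X * w) { sig <- i; break }
  }
  structure(list(values = v, gaps = g[-1L], prior = prior,
                 significant_index = sig,
                 threshold = if (is.na(sig)) NA_real_ else v[sig],
                 insufficient = FALSE),
            class = "gap_scan")
}

#' Partition haplotypes by single linkage at a distance threshold
#'
#' Groups are the connected components of the graph joining every pair of
#' haplotypes at K2P distance `<= threshold` (single-linkage clusters cut at
#' that height). Group ids are contiguous integers from 1, assigned in order
#' of each group's smallest haplotype index, so the labelling is
#' deterministic under input permutation.
#'
#' @param dm A [k2p_matrix()] result (must not carry saturation flags).
#' @param threshold Distance at or below which pairs stay connected.
#' @return Named integer vector: haplotype id -> group id.
#' @export
partition_once <- function(dm, threshold) {
  stopifnot(inherits(dm, "k2p_dist"), threshold >= 0)
  if (is_flagged(dm)) stop("matrix has saturated (flagged) pairs; refusing")
  n <- length(dm$labels)
  if (n == 1L) return(stats::setNames(1L, dm$labels))
  hc <- stats::hclust(stats::as.dist(dm$d), method = "single")
  grp <- stats::cutree(hc, h = threshold)
  renumber_partition(grp[dm$labels])
}

# contiguous ids in order of first occurrence (= smallest member index)
renumber_partition <- function(grp) {
  stats::setNames(match(grp, unique(grp)), names(grp))
}

#' One barcode-gap partition at a single prior (initial + recursive)
#'
#' The initial partition is one gap-search over the whole matrix followed by
#' a single-linkage cut (the identity partition when no gap is significant).
#' The recursive partition repeats the gap-search/cut inside every resulting
#' group with at least 3 members and at least 2 distinct within-group
#' distances, until no group splits further. Insufficient within-group
#' variation is a no-split outcome, not an error.
#'
#' @param dm A [k2p_matrix()] result.
#' @param prior Prior maximum intraspecific divergence.
#' @param config A [sweep_config()].
#' @return List with `initial` and `recursive` partitions (named integer
#'   vectors); the recursive partition always refines the initial one.
#' @export
abgd_partition <- function(dm, prior, config = sweep_config()) {
  scan <- find_significant_gap(pairwise_distances(dm), prior, config)
  initial <- if (scan$insufficient || is.na(scan$significant_index)) {
    stats::setNames(rep(1L, length(dm$labels)), dm$labels)
  } else {
    partition_once(dm, scan$threshold)
  }
  recursive <- recurse_partition(dm, initial, prior, config)
  list(initial = initial, recursive = recursive)
}

recurse_partition <- function(dm, partition, prior, config) {
  grp <- partition
  queue <- unique(grp)
  next_id <- max(grp)
  while (length(queue)) {
    g <- queue[1L]; queue <- queue[-1L]
    members <- names(grp)[grp == g]
    if (length(members) < 3L) next
    sub_d <- dm$d[members, members, drop = FALSE]
    vals <- sub_d[upper.tri(sub_d)]
    if (length(unique(vals)) < 2L) next
    scan <- find_significant_gap(vals, prior, config)
    if (is.na(scan$significant_index)) next
    sub_dm <- structure(list(d = sub_d,
                             sites_used = dm$sites_used[members, members, drop = FALSE],
                             labels = members,
                             flagged = matrix(character(0), ncol = 2L)),
                        class = "k2p_dist")
    sub_grp <- partition_once(sub_dm, scan$threshold)
    if (max(sub_grp) == 1L) next
    for (sg in unique(sub_grp)) {
      sub_members <- names(sub_grp)[sub_grp == sg]
      if (sg == 1L) {
        # keep the first subgroup under the old id
        new_id <- g
      } else {
        next_id <- next_id + 1L
        new_id <- next_id
        grp[sub_members] <- new_id
      }
      queue <- c(queue, new_id)
    }
  }
  renumber_partition(grp)
}

#' Sweep barcode-gap partitions over the full series of priors
#'
#' Runs [abgd_partition()] at every prior of the geometric series from
#' `pmin` to `pmax`. A dataset whose distances carry too little variation
#' to scan -- fewer than two distinct values, or a maximum pairwise
#' distance below half a percent (0.005 substitutions/site, below any
#' plausible barcode gap) -- is flagged degenerate: it contributes a
#' single-group partition at every prior and is treated as one species
#' downstream.
#'
#' @param dm A [k2p_matrix()] result.
#' @param config A [sweep_config()].
#' @return An object of class `abgd_sweep`: list with `table` (data frame:
#'   `prior`, `n_initial`, `n_recursive`), `partitions` (per prior, list
#'   with `initial` and `recursive`), `degenerate`, `config`, `labels`.
#' @export
prior_sweep <- function(dm, config = sweep_config()) {
  stopifnot(inherits(dm, "k2p_dist"))
  if (is_flagged(dm)) stop("matrix has saturated (flagged) pairs; refusing")
  priors <- sweep_priors(config)
  vals <- pairwise_distances(dm)
  degenerate <- length(unique(vals)) < 2L || max(vals) < DEGENERATE_MAX_DIST
  one <- stats::setNames(rep(1L, length(dm$labels)), dm$labels)
  partitions <- vector("list", length(priors))
  tab <- data.frame(prior = priors, n_initial = NA_integer_,
                    n_recursive = NA_integer_)
  for (k in seq_along(priors)) {
    if (degenerate) {
      partitions[[k]] <- list(initial = one, recursive = one)
    } else {
      partitions[[k]] <- abgd_partition(dm, priors[k], config)
    }
    tab$n_initial[k] <- max(partitions[[k]]$initial)
    tab$n_recursive[k] <- max(partitions[[k]]$recursive)
  }
  structure(list(table = tab, partitions = partitions,
                 degenerate = degenerate, config = config,
                 labels = dm$labels),
            class = "abgd_sweep")
}

#' @export
print.abgd_sweep <- function(x, ...) {
  cat("Barcode-gap sweep over", nrow(x$table), "priors [",
      format(min(x$table$prior)), ",", format(max(x$table$prior)), "]\n")
  if (x$degenerate) {
    cat("  degenerate: variation too limited to scan; single group\n")
  } else {
    cat("  group counts (initial):",
        paste(x$table$n_initial, collapse = " "), "\n")
    cat("  group counts (recursive):",
        paste(x$table$n_recursive, collapse = " "), "\n")
  }
  invisible(x)
}

#' Export a sweep as JSON
#' @param sweep An [prior_sweep()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(sweep, path) {
  stopifnot(inherits(sweep, "abgd_sweep"))
  obj <- list(degenerate = sweep$degenerate,
              priors = sweep$table$prior,
              n_initial = sweep$table$n_initial,
              n_recursive = sweep$table$n_recursive)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Diagnostic histogram of pairwise distances
#'
#' Plots the distribution of pairwise K2P distances with the configured bin
#' count; a clear barcode gap shows as an empty stretch between the
#' intraspecific mass near zero and the interspecific mass.
#'
#' @param dm A [k2p_matrix()] result.
#' @param config A [sweep_config()] (supplies `bins`).
#' @param ... Passed to [graphics::hist()].
#' @return The histogram object, invisibly.
#' @export
plot_distance_histogram <- function(dm, config = sweep_config(), ...) {
  vals <- pairwise_distances(dm)
  h <- graphics::hist(vals, breaks = config$bins,
                      main = "Pairwise K2P distances",
                      xlab = "K2P distance", ...)
  invisible(h)
}
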