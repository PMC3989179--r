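# Primary species hypothesis selection: reduce a prior sweep to one
# partition via a conservative stability rule.

#' Group count retained at each prior of a sweep
#'
#' When the initial and recursive partitions disagree at a prior, the
#' smaller of the two group counts is retained (the conservative choice),
#' along with the matching partition.
#'
#' @param sweep An [prior_sweep()] result.
#' @return Data frame with one row per prior: `prior`, `count`, `which`
#'   (`"initial"` or `"recursive"`, the partition the count came from).
#' @export
per_prior_count <- function(sweep) {
  stopifnot(inherits(sweep, "abgd_sweep"))
  tab <- sweep$table
  use_initial <- tab$n_initial <= tab$n_recursive
  data.frame(prior = tab$prior,
             count = ifelse(use_initial, tab$n_initial, tab$n_recursive),
             which = ifelse(use_initial, "initial", "recursive"),
             stringsAsFactors = FALSE)
}

#' Select the primary species hypothesis from a sweep
#'
#' Finds maximal runs of successive priors over which the retained group
#' count is constant. Among counts whose run spans at least `min_run`
#' priors, the smallest is chosen; the trivial all-in-one count of 1 is
#' excluded as a candidate whenever any other count qualifies (at large
#' priors every dataset collapses to one group, so count 1 is almost always
#' "stable" but uninformative). Ties between equal counts go to the run
#' starting at the lower prior. The reported partition is the one at the
#' smallest prior of the chosen run.
#'
#' @param sweep An [prior_sweep()] result.
#' @param min_run Minimum number of successive priors a count must persist
#'   over to qualify as stable. Default 3.
#' @return An object of class `psh_selection`: list with `chosen_count`,
#'   `stable_prior_max` (largest prior of the chosen run),
#'   `stable_prior_min`, `chosen_partition` (named integer vector),
#'   `degenerate`, `trivial_excluded` (`TRUE` when the count-1 exclusion
#'   fired), and `alternatives` (data frame of every stable run).
#' @export
select_psh <- function(sweep, min_run = 3) {
  stopifnot(inherits(sweep, "abgd_sweep"))
  counts <- per_prior_count(sweep)
  if (sweep$degenerate) {
    return(structure(list(chosen_count = 1L,
                          stable_prior_max = NA_real_,
                          stable_prior_min = NA_real_,
                          chosen_partition = sweep$partitions[[1L]]$initial,
                          degenerate = TRUE, trivial_excluded = FALSE,
                          alternatives = NULL),
                     class = "psh_selection"))
  }
  if (nrow(counts) < min_run) stop("sweep has fewer priors than min_run")
  runs <- count_runs(counts)
  stable <- runs[runs$length >= min_run, , drop = FALSE]
  if (nrow(stable) == 0L) stop("no stable PSH: no count persists over ",
                               min_run, " successive priors")
  trivial_excluded <- FALSE
  candidates <- stable
  if (any(stable$count != 1L) && any(stable$count == 1L)) {
    candidates <- stable[stable$count != 1L, , drop = FALSE]
    trivial_excluded <- TRUE
  }
  best_count <- min(candidates$count)
  best <- candidates[candidates$count == best_count, , drop = FALSE]
  best <- best[which.min(best$prior_min), ]
  k <- best$start
  part <- if (counts$which[k] == "initial") {
    sweep$partitions[[k]]$initial
  } else {
    sweep$partitions[[k]]$recursive
  }
  structure(list(chosen_count = as.integer(best$count),
                 stable_prior_max = best$prior_max,
                 stable_prior_min = best$prior_min,
                 chosen_partition = part,
                 degenerate = FALSE,
                 trivial_excluded = trivial_excluded,
                 alternatives = stable),
            class = "psh_selection")
}

count_runs <- function(counts) {
  r <- rle(counts$count)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  data.frame(count = r$values, start = starts, end = ends,
             length = r$lengths,
             prior_min = counts$prior[starts],
             prior_max = counts$prior[ends])
}

#' @export
print.psh_selection <- function(x, ...) {
  if (x$degenerate) {
    cat("PSH: degenerate dataset (variation too limited); 1 species\n")
  } else {
    cat("PSH:", x$chosen_count, "putative species, stable over priors [",
        format(x$stable_prior_min, digits = 3), ",",
        format(x$stable_prior_max, digits = 3), "]\n")
    if (x$trivial_excluded)
      cat("  (trivial single-group plateau excluded from candidates)\n")
  }
  invisible(x)
}

#' Export a PSH selection as JSON
#' @param psh A [select_psh()] result.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_psh <- function(psh, path) {
  stopifnot(inherits(psh, "psh_selection"))
  obj <- list(chosen_count = psh$chosen_count,
              stable_prior_max = psh$stable_prior_max,
              stable_prior_min = psh$stable_prior_min,
              degenerate = psh$degenerate,
              trivial_excluded = psh$trivial_excluded,
              partition = as.list(psh$chosen_partition),
              alternatives = psh$alternatives)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
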