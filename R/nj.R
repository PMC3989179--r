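# Neighbour-joining trees from K2P distances, midpoint rooting, monophyly
# assessment, and column-resampling bootstrap support for putative species.

#' Neighbour-joining tree from a K2P distance matrix
#'
#' Standard Saitou-Nei agglomeration via [ape::nj()]. Negative branch
#' lengths, an occasional artefact of NJ on noisy matrices, are set to zero
#' with the deficit transferred onto the adjacent descendant branches so
#' that root-to-tip path lengths through the node are preserved.
#'
#' @param dm A [k2p_matrix()] result; must be free of saturation flags and
#'   have at least 3 labels.
#' @return An unrooted `phylo` tree with tip labels equal to `dm$labels`.
#' @export
nj_tree <- function(dm) {
  stopifnot(inherits(dm, "k2p_dist"))
  if (is_flagged(dm)) stop("matrix has saturated (flagged) pairs; refusing")
  if (length(dm$labels) < 3L) stop("need at least 3 haplotypes for a tree")
  tr <- ape::nj(stats::as.dist(dm$d))
  fix_negative_branches(tr)
}

fix_negative_branches <- function(tr) {
  repeat {
    neg <- which(tr$edge.length < 0)
    if (!length(neg)) break
    e <- neg[1L]
    deficit <- tr$edge.length[e]
    tr$edge.length[e] <- 0
    child <- tr$edge[e, 2L]
    down <- which(tr$edge[, 1L] == child)
    if (length(down)) tr$edge.length[down] <- tr$edge.length[down] + deficit
    # at a tip there is nothing to transfer to; clamp only
    if (!length(down)) next
  }
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Midpoint-root a tree
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path
#' (via [phangorn::midpoint()]). A tree whose diameter is zero has no
#' defined midpoint; it is rooted arbitrarily and flagged with the
#' attribute `midpoint_arbitrary`.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  dm <- ape::cophenetic.phylo(tree)
  if (max(dm) == 0) {
    rooted <- ape::root(tree, outgroup = tree$tip.label[1L],
                        resolve.root = TRUE)
    attr(rooted, "midpoint_arbitrary") <- TRUE
    return(rooted)
  }
  phangorn::midpoint(tree)
}

#' Is a set of leaves monophyletic (an unrooted clan)?
#'
#' True when the group is exactly one side of some bipartition of the
#' unrooted tree, i.e. a clade under rooting at any leaf outside the group.
#' By unrooted symmetry the complement of a monophyletic group is also
#' monophyletic. Singleton groups are monophyletic by convention and carry
#' the attribute `trivial`.
#'
#' @param tree A `phylo` tree (rooted or not; the test is rooting-invariant).
#' @param group Character vector of tip labels; must be a proper non-empty
#'   subset of the tree's tips.
#' @return Logical scalar.
#' @export
is_monophyletic <- function(tree, group) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  group <- unique(group)
  if (!all(group %in% tips)) {
    stop("group contains labels absent from the tree: ",
         paste(setdiff(group, tips), collapse = ", "))
  }
  if (length(group) >= length(tips)) stop("group must be a proper subset of tips")
  if (length(group) == 0L) stop("group is empty")
  if (length(group) == 1L) return(structure(TRUE, trivial = TRUE))
  out <- setdiff(tips, group)[1L]
  rooted <- ape::root(ape::unroot(tree), outgroup = out, resolve.root = TRUE)
  ape::is.monophyletic(rooted, group)
}

#' Bootstrap support for the monophyly of putative species
#'
#' Resamples alignment columns with replacement; for each pseudoreplicate
#' recomputes the K2P matrix (with pairwise deletion of the resampled
#' columns), rebuilds the NJ tree, and tests each group for monophyly.
#' Support is the percentage of usable replicates in which the group is
#' monophyletic. Replicates in which any pairwise distance is undefined
#' (no comparable sites, or K2P saturation) are dropped and counted.
#'
#' @param haps A [collapse_haplotypes()] result or [alignment()] object
#'   whose rows are the tree's tips.
#' @param groups Named list of character vectors of row labels (one per
#'   putative species).
#' @param reps Number of bootstrap pseudoreplicates, default 1000.
#' @param seed Integer seed; the run is reproducible given it.
#' @return Data frame of class `support_table`: `group`, `support`
#'   (percent of usable replicates), `n_replicates_used`,
#'   `n_replicates_dropped`.
#' @export
bootstrap_support <- function(haps, groups, reps = 1000, seed = NULL) {
  seq_mat <- sequence_rows(haps)
  if (is.null(names(groups))) names(groups) <- seq_along(groups)
  lapply(groups, function(g) {
    if (!all(g %in% rownames(seq_mat)))
      stop("group member absent from sequences: ",
           paste(setdiff(g, rownames(seq_mat)), collapse = ", "))
  })
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  L <- ncol(seq_mat)
  hits <- stats::setNames(numeric(length(groups)), names(groups))
  used <- 0L
  dropped <- 0L
  for (r in seq_len(reps)) {
    cols <- sample.int(L, L, replace = TRUE)
    rep_mat <- seq_mat[, cols, drop = FALSE]
    dm <- tryCatch(k2p_matrix(rep_mat), error = function(e) NULL)
    if (is.null(dm)) { dropped <- dropped + 1L; next }
    tr <- ape::nj(stats::as.dist(dm$d))
    used <- used + 1L
    for (gn in names(groups)) {
      g <- groups[[gn]]
      if (length(g) >= length(tr$tip.label)) next
      if (isTRUE(as.logical(is_monophyletic(tr, g)))) hits[gn] <- hits[gn] + 1
    }
  }
  if (used == 0L) stop("every bootstrap replicate was dropped")
  structure(data.frame(group = names(groups),
                       support = 100 * unname(hits) / used,
                       n_replicates_used = used,
                       n_replicates_dropped = dropped,
                       stringsAsFactors = FALSE),
            class = c("support_table", "data.frame"))
}

#' Write a Newick tree (support values as internal node labels)
#' @param tree A `phylo` tree.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return A `phylo` tree.
#' @export
read_tree <- function(path) {
  ape::read.tree(path)
}
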