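# Kimura two-parameter distances with pairwise deletion.
# Sites carrying a gap or any IUPAC ambiguity in either member of a pair are
# excluded for that pair only. Transitions are A<->G and C<->T; every other
# difference between unambiguous bases is a transversion.

BASE_CODE <- c(A = 1L, C = 2L, G = 3L, T = 4L)
# purine/pyrimidine class: transition = same class, different base
BASE_CLASS <- c(1L, 2L, 1L, 2L)

encode_sequences <- function(seq_mat) {
  m <- matrix(BASE_CODE[seq_mat], nrow = nrow(seq_mat))
  rownames(m) <- rownames(seq_mat)
  m
}

k2p_from_pq <- function(P, Q) {
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(NA_real_)
  -0.5 * log(arg1 * sqrt(arg2))
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' Computes the K2P (Kimura 1980) distance
#' \eqn{d = -\tfrac{1}{2}\ln[(1-2P-Q)\sqrt{1-2Q}]} where `P` and `Q` are the
#' proportions of transition and transversion differences over the sites
#' comparable in both sequences (pairwise deletion: a site with a gap or
#' ambiguity code in either sequence is skipped).
#'
#' @param a,b Character vectors of single bases, or single strings, of equal
#'   aligned length.
#' @return A list of class `k2p_pair` with `d` (distance, `NA` when the
#'   correction is undefined), `P`, `Q`, `sites_used`, and `saturated`
#'   (`TRUE` when a logarithm argument was non-positive, i.e. the distance
#'   is beyond the reach of the correction).
#' @examples
#' k2p_pair("ACGTACGTACGTACGTACGT", "GCGTACGTACGAACGTACGT")
#' @export
k2p_pair <- function(a, b) {
  if (length(a) == 1L && nchar(a) > 1L) a <- strsplit(a, "")[[1]]
  if (length(b) == 1L && nchar(b) > 1L) b <- strsplit(b, "")[[1]]
  if (length(a) != length(b)) stop("sequences have different aligned lengths")
  ca <- BASE_CODE[toupper(a)]
  cb <- BASE_CODE[toupper(b)]
  ok <- !is.na(ca) & !is.na(cb)
  n <- sum(ok)
  if (n == 0L) stop("no comparable sites: every column has a gap/ambiguity")
  ca <- ca[ok]; cb <- cb[ok]
  diff <- ca != cb
  ts <- diff & (BASE_CLASS[ca] == BASE_CLASS[cb])
  P <- sum(ts) / n
  Q <- (sum(diff) - sum(ts)) / n
  d <- k2p_from_pq(P, Q)
  structure(list(d = d, P = P, Q = Q, sites_used = n,
                 saturated = is.na(d)),
            class = "k2p_pair")
}

#' Pairwise K2P distance matrix over a haplotype set
#'
#' @param x A [collapse_haplotypes()] result, a [alignment()] object (each
#'   specimen kept as its own row), or a character matrix of aligned rows.
#' @param on_saturation What to do when a pair's K2P correction is undefined
#'   (logarithm argument non-positive, "saturation"): `"error"` (default)
#'   aborts listing the offending pairs; `"flag"` records them and stores
#'   `NA` distances. Downstream gap/tree code refuses flagged matrices.
#' @return An object of class `k2p_dist`: list with `d` (symmetric numeric
#'   matrix, zero diagonal), `sites_used` (integer matrix), `labels`, and
#'   `flagged` (2-column matrix of saturated pairs, zero rows when clean).
#' @export
k2p_matrix <- function(x, on_saturation = c("error", "flag")) {
  on_saturation <- match.arg(on_saturation)
  seq_mat <- sequence_rows(x)
  n <- nrow(seq_mat)
  if (n < 2L) stop("need at least 2 sequences for a distance matrix")
  labels <- rownames(seq_mat)
  enc <- encode_sequences(seq_mat)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  su <- matrix(ncol(seq_mat), n, n, dimnames = list(labels, labels))
  flagged <- matrix(character(0), ncol = 2L)
  for (i in seq_len(n - 1L)) {
    ai <- enc[i, ]
    for (j in (i + 1L):n) {
      bj <- enc[j, ]
      ok <- !is.na(ai) & !is.na(bj)
      ns <- sum(ok)
      if (ns == 0L) {
        stop("no comparable sites between ", labels[i], " and ", labels[j])
      }
      ca <- ai[ok]; cb <- bj[ok]
      diffs <- ca != cb
      nts <- sum(diffs & (BASE_CLASS[ca] == BASE_CLASS[cb]))
      P <- nts / ns
      Q <- (sum(diffs) - nts) / ns
      dij <- k2p_from_pq(P, Q)
      if (is.na(dij)) flagged <- rbind(flagged, c(labels[i], labels[j]))
      d[i, j] <- d[j, i] <- dij
      su[i, j] <- su[j, i] <- ns
    }
  }
  if (nrow(flagged) > 0L && on_saturation == "error") {
    stop("K2P undefined (saturation) for pairs: ",
         paste(apply(flagged, 1L, paste, collapse = "/"), collapse = ", "))
  }
  structure(list(d = d, sites_used = su, labels = labels, flagged = flagged),
            class = "k2p_dist")
}

sequence_rows <- function(x) {
  if (inherits(x, "haplotype_set") || inherits(x, "barcode_alignment")) {
    x$seq
  } else if (is.matrix(x) && is.character(x)) {
    x
  } else {
    stop("expected a haplotype_set, barcode_alignment or character matrix")
  }
}

is_flagged <- function(dm) nrow(dm$flagged) > 0L

#' @export
print.k2p_dist <- function(x, ...) {
  cat("K2P distance matrix:", length(x$labels), "haplotypes; max distance",
      format(max(x$d, na.rm = TRUE), digits = 4), "\n")
  if (is_flagged(x)) cat("  ", nrow(x$flagged), "saturated pair(s) flagged\n")
  invisible(x)
}

#' Off-diagonal distances of a K2P matrix
#' @param dm A [k2p_matrix()] result.
#' @return Numeric vector of the upper-triangle distances.
#' @export
pairwise_distances <- function(dm) {
  dm$d[upper.tri(dm$d)]
}

#' Per-group distance summary (mean intra, minimum mean inter)
#'
#' For each group of a partition: the mean K2P distance over within-group
#' haplotype pairs, the mean distance to every other group, the minimum of
#' those between-group means, and the ratio minimum-inter / intra. Singleton
#' groups have no within-group pairs; their intraspecific mean is `NA`
#' (explicitly "n/a", not zero).
#'
#' @param dm A [k2p_matrix()] result.
#' @param partition Named integer vector (haplotype id -> group id) as
#'   produced by [partition_once()], or any vector coercible to one covering
#'   `dm$labels`.
#' @return Data frame with one row per group: `group`, `n`, `mean_intra`,
#'   `min_inter`, `nearest_group`, `ratio`.
#' @export
group_distance_summary <- function(dm, partition) {
  stopifnot(inherits(dm, "k2p_dist"))
  partition <- partition[dm$labels]
  if (anyNA(partition)) stop("partition does not cover all matrix labels")
  groups <- sort(unique(partition))
  out <- lapply(groups, function(g) {
    in_g <- which(partition == g)
    mean_intra <- if (length(in_g) >= 2L) {
      sub <- dm$d[in_g, in_g, drop = FALSE]
      mean(sub[upper.tri(sub)])
    } else NA_real_
    others <- setdiff(groups, g)
    if (length(others)) {
      inter_means <- vapply(others, function(h) {
        mean(dm$d[in_g, which(partition == h), drop = FALSE])
      }, numeric(1))
      k <- which.min(inter_means)
      min_inter <- inter_means[k]
      nearest <- others[k]
    } else {
      min_inter <- NA_real_
      nearest <- NA
    }
    data.frame(group = g, n = length(in_g), mean_intra = mean_intra,
               min_inter = min_inter, nearest_group = nearest,
               ratio = min_inter / mean_intra)
  })
  do.call(rbind, out)
}

#' Export a K2P matrix as tab-delimited text
#'
#' @param dm A [k2p_matrix()] result.
#' @param path Output path.
#' @param lower_triangle If `TRUE`, write a PHYLIP-style lower-triangular
#'   matrix (taxon count header, one labelled row per taxon); otherwise a
#'   full square tab-delimited table with a header row.
#' @return `path`, invisibly.
#' @export
write_k2p_matrix <- function(dm, path, lower_triangle = FALSE) {
  stopifnot(inherits(dm, "k2p_dist"))
  if (lower_triangle) {
    n <- length(dm$labels)
    lines <- as.character(n)
    for (i in seq_len(n)) {
      vals <- if (i > 1L) format(dm$d[i, seq_len(i - 1L)], digits = 8) else character(0)
      lines <- c(lines, paste(c(dm$labels[i], vals), collapse = "\t"))
    }
    writeLines(lines, path)
  } else {
    utils::write.table(dm$d, path, sep = "\t", quote = FALSE,
                       col.names = NA)
  }
  invisible(path)
}
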