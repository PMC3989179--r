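#' Construct an aligned barcode dataset
#'
#' Bundles equal-length DNA sequences with per-specimen metadata. This is the
#' entry container for the whole pipeline: haplotype collapsing, distance
#' computation, gap partitioning and tree building all start from it.
#'
#' @param sequences Character vector of aligned sequences (one string per
#'   specimen, all the same length), or a character matrix with one row per
#'   specimen and one column per site. Names/rownames must be specimen ids.
#' @param meta Data frame of specimen metadata with columns `specimen_id`,
#'   `morphospecies_label`, `locality`, `in_britain_or_ireland`, `source`,
#'   `locus`. Rows are matched to sequences by `specimen_id`.
#'
#' @return An object of class `barcode_alignment`: a list with elements
#'   `seq` (character matrix, upper case, rownames = specimen ids),
#'   `meta` (data frame, one row per specimen, same order) and
#'   `length` (number of aligned sites).
#'
#' @details Sequences are upper-cased on construction. Any IUPAC ambiguity
#'   code or gap character is kept literally; downstream distance code treats
#'   non-ACGT symbols as missing for the pair (pairwise deletion).
#' @export
alignment <- function(sequences, meta) {
  if (is.character(sequences) && !is.matrix(sequences)) {
    if (length(sequences) == 0L) stop("empty alignment: no sequences")
    ids <- names(sequences)
    if (is.null(ids)) stop("sequences must be named by specimen id")
    lens <- nchar(sequences)
    if (length(unique(lens)) != 1L) {
      stop("unaligned input: sequence lengths differ (",
           paste(unique(lens), collapse = ", "), ")")
    }
    seq_mat <- do.call(rbind, strsplit(toupper(sequences), ""))
    rownames(seq_mat) <- ids
  } else if (is.matrix(sequences)) {
    if (nrow(sequences) == 0L) stop("empty alignment: no sequences")
    if (is.null(rownames(sequences))) stop("sequence matrix must have rownames")
    seq_mat <- toupper(sequences)
    dim(seq_mat) <- dim(sequences)
    dimnames(seq_mat) <- dimnames(sequences)
  } else {
    stop("sequences must be a character vector or matrix")
  }
  ids <- rownames(seq_mat)
  if (anyDuplicated(ids)) {
    stop("duplicate specimen ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  meta <- validate_metadata(meta)
  missing_meta <- setdiff(ids, meta$specimen_id)
  if (length(missing_meta)) {
    stop("specimens missing from metadata: ",
         paste(missing_meta, collapse = ", "))
  }
  meta <- meta[match(ids, meta$specimen_id), , drop = FALSE]
  rownames(meta) <- NULL
  if (length(unique(meta$locus)) > 1L) {
    stop("all specimens in one alignment must share a locus; found: ",
         paste(unique(meta$locus), collapse = ", "))
  }
  structure(
    list(seq = seq_mat, meta = meta, length = ncol(seq_mat)),
    class = "barcode_alignment"
  )
}

REQUIRED_META_COLS <- c("specimen_id", "morphospecies_label", "locality",
                        "in_britain_or_ireland", "source", "locus")

validate_metadata <- function(meta) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  missing <- setdiff(REQUIRED_META_COLS, names(meta))
  if (length(missing)) {
    stop("metadata lacks required columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(meta$specimen_id)) {
    stop("duplicate specimen ids in metadata: ",
         paste(unique(meta$specimen_id[duplicated(meta$specimen_id)]),
               collapse = ", "))
  }
  meta$in_britain_or_ireland <- as.logical(meta$in_britain_or_ireland)
  meta
}

#' Read an aligned FASTA file plus specimen metadata
#'
#' @param path Path to a FASTA file of aligned (equal-length) sequences.
#' @param metadata_path Path to a delimited text file (comma- or
#'   tab-separated, chosen by extension) with a header row and the columns
#'   documented in [alignment()]. FASTA identifiers must appear in its
#'   `specimen_id` column.
#' @return A [alignment()] object.
#' @export
read_alignment <- function(path, metadata_path) {
  if (!file.exists(path) || file.size(path) == 0)
    stop("empty file: no FASTA records in ", path)
  dna <- ape::read.FASTA(path)
  if (length(dna) == 0L) stop("empty file: no FASTA records in ", path)
  seqs <- vapply(as.character(dna), paste, character(1), collapse = "")
  names(seqs) <- names(dna)
  meta <- read_metadata(metadata_path)
  alignment(seqs, meta)
}

read_metadata <- function(path) {
  sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep,
                    stringsAsFactors = FALSE, comment.char = "")
}

#' Write an alignment back to FASTA (+ optional metadata CSV)
#'
#' @param aln A [alignment()] object.
#' @param path Output FASTA path.
#' @param metadata_path Optional path for a metadata CSV.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, metadata_path = NULL) {
  stopifnot(inherits(aln, "barcode_alignment"))
  lines <- character(2L * nrow(aln$seq))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(aln$seq))
  lines[c(FALSE, TRUE)] <- apply(aln$seq, 1L, paste, collapse = "")
  writeLines(lines, path)
  if (!is.null(metadata_path)) {
    utils::write.csv(aln$meta, metadata_path, row.names = FALSE)
  }
  invisible(path)
}

#' @export
print.barcode_alignment <- function(x, ...) {
  cat("Aligned barcode dataset:", nrow(x$seq), "specimens x", x$length,
      "sites (", x$meta$locus[1], ")\n", sep = " ")
  invisible(x)
}

#' Collapse identical sequences to haplotypes
#'
#' Identical rows (exact string identity after upper-casing; ambiguity codes
#' and gaps compared literally, so an `N` never matches an `A`) are merged
#' into one haplotype. Haplotypes are labelled `H1, H2, ...` in order of
#' first occurrence, which makes the collapse deterministic and idempotent.
#'
#' @param aln A [alignment()] object.
#' @return An object of class `haplotype_set`: list with `seq` (character
#'   matrix of unique rows, rownames `H1...`), `multiplicity` (integer vector,
#'   specimens per haplotype), `members` (list of specimen id vectors) and
#'   `meta` (the alignment metadata, for provenance).
#' @export
collapse_haplotypes <- function(aln) {
  stopifnot(inherits(aln, "barcode_alignment"))
  keys <- apply(aln$seq, 1L, paste, collapse = "")
  first <- !duplicated(keys)
  hap_keys <- keys[first]
  idx <- match(keys, hap_keys)
  hap_ids <- paste0("H", seq_along(hap_keys))
  members <- split(rownames(aln$seq), factor(idx, levels = seq_along(hap_keys)))
  names(members) <- hap_ids
  seq_mat <- aln$seq[first, , drop = FALSE]
  rownames(seq_mat) <- hap_ids
  structure(
    list(seq = seq_mat,
         multiplicity = lengths(members),
         members = members,
         meta = aln$meta),
    class = "haplotype_set"
  )
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("Haplotype set:", nrow(x$seq), "haplotypes from",
      sum(x$multiplicity), "specimens\n")
  invisible(x)
}

#' Export a haplotype map as JSON
#'
#' @param haps A [collapse_haplotypes()] result.
#' @param path Output path for a JSON file mapping haplotype id to its
#'   member specimen ids and multiplicity.
#' @return `path`, invisibly.
#' @export
write_haplotype_map <- function(haps, path) {
  stopifnot(inherits(haps, "haplotype_set"))
  obj <- lapply(names(haps$members), function(h) {
    list(haplotype = h,
         multiplicity = unname(haps$multiplicity[h]),
         members = haps$members[[h]])
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
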