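# Packaged case study: evidence tables for the British and Irish slug
# fauna. One row per mitochondrially delimited putative species with its
# NJ bootstrap / Bayesian posterior monophyly support (whole-family and
# subset analyses), morphological-uniqueness flags, the declared split
# groups and merge candidate sets, two species from families whose
# variation was too limited to delimit, and the 36-name checklist of the
# previously recognised fauna. Support and morphology values are external
# evidence consumed by the refinement engine, never computed here; the
# `ssh_expected` column records the published outcome and is used only by
# the test suite, not by `refine()`.

fixture_path <- function(file) {
  system.file("extdata", file, package = "barcodegap", mustWork = TRUE)
}

#' Load the slug-fauna case-study fixture
#'
#' @return A list with `psh` (per-PSH evidence table, see [refine()]),
#'   `merges` (merge candidate sets), `splits` (declared split groups),
#'   `degenerate` (species carried through from datasets too invariant to
#'   delimit) and `checklist` (character vector of the 36 known species
#'   names).
#' @export
load_slug_fixture <- function() {
  read <- function(f) utils::read.csv(fixture_path(f),
                                      stringsAsFactors = FALSE,
                                      colClasses = NA)
  psh <- read("slug_psh_evidence.csv")
  psh$psh_id <- as.character(psh$psh_id)
  psh$split_parent <- ifelse(is.na(psh$split_parent) | psh$split_parent == "",
                             NA_character_, as.character(psh$split_parent))
  splits <- read("slug_split_groups.csv")
  splits$parent <- as.character(splits$parent)
  list(psh = psh,
       merges = read("slug_merge_sets.csv"),
       splits = splits,
       degenerate = read("slug_degenerate_species.csv"),
       checklist = read("slug_fauna_checklist.csv")$species)
}

#' Run the full secondary-species-hypothesis refinement on the case study
#'
#' Applies [refine()] to the packaged evidence table, appends the two
#' species from the undelimitable families, and compares the result to the
#' known-fauna checklist.
#'
#' @param support_threshold NJ bootstrap threshold for monophyly,
#'   default 75.
#' @return A list with `ssh` (the refined `ssh_set`, including the two
#'   degenerate-family species), `ssh_delimited_count` (SSH species
#'   excluding those two), `accepted_unchanged` (PSHs accepted as SSHs
#'   without split or merge), and `fauna` (the [compare_fauna()] result).
#' @export
slug_case_study <- function(support_threshold = 75) {
  fx <- load_slug_fixture()
  ssh <- refine(fx$psh, merges = fx$merges, splits = fx$splits,
                support_threshold = support_threshold)
  delimited <- nrow(ssh$ssh)
  accepted <- sum(ssh$ssh$action == "accept")
  full <- add_degenerate_species(ssh, fx$degenerate)
  fauna <- compare_fauna(full, fx$checklist)
  list(ssh = full,
       ssh_delimited_count = delimited,
       accepted_unchanged = accepted,
       fauna = fauna)
}
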