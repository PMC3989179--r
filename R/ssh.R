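# Integration by congruence: refine primary species hypotheses (PSHs) into
# secondary species hypotheses (SSHs) using monophyly and morphology
# evidence, compare the result to a known faunal checklist, and detect
# mitochondrial/morphological conflicts diagnostic of introgression.
#
# Refinement rules:
#   R1 accept : a monophyletic PSH becomes an SSH unchanged.
#   R2 split  : a non-monophyletic PSH whose declared child groups are each
#               monophyletic and morphologically distinguishable is split
#               into one SSH per child group.
#   R3 merge  : a set of morphologically indistinguishable PSHs whose union
#               is monophyletic is combined into one SSH.
#   R4 keep   : members of such a set stay separate SSHs when their union is
#               not monophyletic.
# "Monophyletic" means NJ bootstrap support >= `support_threshold` (default
# 75) in any available analysis; Bayesian posteriors are carried as
# corroborating evidence only. A PSH represented by a single haplotype is
# trivially monophyletic.

#' Refine primary species hypotheses into secondary species hypotheses
#'
#' @param psh_table Data frame with one row per PSH (and one per split
#'   child), columns: `psh_id` (character), `n_haplotypes`, `n_individuals`,
#'   `nj_whole`, `bi_whole`, `nj_subset`, `bi_subset` (support percentages,
#'   `NA` for "n/a"), `morph_external`, `morph_internal` (each
#'   `"yes"/"no"/"uncertain"`), `split_parent` (id of the parent PSH for
#'   child rows, `NA` otherwise), `name_applied` (optional).
#' @param merges Optional data frame of merge candidate sets (PSHs declared
#'   morphologically indistinguishable from one another): columns `set_id`,
#'   `psh_ids` (`"+"`-separated), `union_nj`, `union_bi` (joint monophyly
#'   support for the union).
#' @param splits Optional data frame describing how non-monophyletic PSHs
#'   would split: columns `parent` (psh_id), `group` (child SSH label, e.g.
#'   `"1B+1C"`), `members` (`"+"`-separated child psh_ids), `group_nj`,
#'   `group_bi` (joint monophyly support of the child group).
#' @param support_threshold NJ bootstrap percentage at or above which a
#'   group counts as monophyletic. Default 75.
#' @return An object of class `ssh_set`: list with `ssh` (data frame:
#'   `ssh_id`, `psh_ids`, `action` in
#'   `accept/split_child/merge/keep_separate/unresolved`, `rule`,
#'   `name_applied`) and `log` (one decision line per PSH).
#' @export
refine <- function(psh_table, merges = NULL, splits = NULL,
                   support_threshold = 75) {
  psh <- as.data.frame(psh_table, stringsAsFactors = FALSE)
  psh$psh_id <- as.character(psh$psh_id)
  need <- c("psh_id", "n_haplotypes", "nj_whole", "nj_subset")
  missing <- setdiff(need, names(psh))
  if (length(missing)) stop("psh_table lacks columns: ",
                            paste(missing, collapse = ", "))
  if (anyDuplicated(psh$psh_id)) stop("duplicate psh_id in psh_table")
  if (!"split_parent" %in% names(psh)) psh$split_parent <- NA_character_
  if (!"name_applied" %in% names(psh)) psh$name_applied <- NA_character_

  child_rows <- !is.na(psh$split_parent) & psh$split_parent != ""
  parents <- unique(psh$split_parent[child_rows])
  merge_sets <- parse_merge_sets(merges, psh$psh_id)
  merged_ids <- unlist(lapply(merge_sets, `[[`, "psh_ids"))
  clash <- intersect(merged_ids, c(parents, psh$psh_id[child_rows]))
  if (length(clash)) {
    stop("PSH in both a merge set and a split: ", paste(clash, collapse = ", "))
  }

  rows <- list()
  log <- character(0)
  add <- function(ssh_id, psh_ids, action, rule, name) {
    rows[[length(rows) + 1L]] <<- data.frame(
      ssh_id = ssh_id, psh_ids = paste(psh_ids, collapse = "+"),
      action = action, rule = rule,
      name_applied = if (is.null(name) || is.na(name)) NA_character_ else name,
      stringsAsFactors = FALSE)
  }

  top_level <- psh[!child_rows, , drop = FALSE]
  for (i in seq_len(nrow(top_level))) {
    row <- top_level[i, ]
    id <- row$psh_id
    if (id %in% merged_ids) next  # handled with its merge set
    mono <- psh_monophyletic(row, support_threshold)
    if (id %in% parents) {
      if (mono) {
        add(id, id, "accept", "R1", row$name_applied)
        log <- c(log, paste0("PSH ", id,
                             ": monophyletic despite declared split children; accepted (R1)"))
        next
      }
      kids <- split_groups_for(splits, id, psh, support_threshold)
      if (kids$ok) {
        for (j in seq_len(nrow(kids$groups))) {
          g <- kids$groups[j, ]
          add(g$group, strsplit(g$members, "\\+")[[1]], "split_child", "R2",
              g$name_applied)
        }
        log <- c(log, paste0("PSH ", id, ": not monophyletic (", row$nj_whole,
                             "/", row$nj_subset,
                             "); split into ",
                             paste(kids$groups$group, collapse = " + "),
                             " (R2)"))
      } else {
        add(id, id, "unresolved", "R2-failed", row$name_applied)
        log <- c(log, paste0("PSH ", id,
                             ": not monophyletic and split groups unsupported; unresolved"))
      }
      next
    }
    if (mono) {
      add(id, id, "accept", "R1", row$name_applied)
      log <- c(log, paste0("PSH ", id, ": monophyletic; accepted (R1)"))
    } else {
      add(id, id, "unresolved", "R1-failed", row$name_applied)
      log <- c(log, paste0("PSH ", id,
                           ": not monophyletic, no split/merge evidence; unresolved"))
    }
  }

  for (ms in merge_sets) {
    ids <- ms$psh_ids
    nm <- first_name(psh, ids)
    if (!is.na(ms$union_nj) && ms$union_nj >= support_threshold) {
      add(paste(ids, collapse = "+"), ids, "merge", "R3", nm)
      log <- c(log, paste0("PSHs ", paste(ids, collapse = "+"),
                           ": morphologically indistinguishable, union monophyletic (",
                           ms$union_nj, "); merged (R3)"))
    } else {
      for (id in ids) {
        row <- psh[psh$psh_id == id, ]
        add(id, id, "keep_separate", "R4", row$name_applied)
      }
      log <- c(log, paste0("PSHs ", paste(ids, collapse = "+"),
                           ": union not monophyletic (",
                           ifelse(is.na(ms$union_nj), "n/a", ms$union_nj),
                           "); kept separate (R4)"))
    }
  }

  ssh <- do.call(rbind, rows)
  structure(list(ssh = ssh, log = log,
                 support_threshold = support_threshold),
            class = "ssh_set")
}

psh_monophyletic <- function(row, threshold) {
  supports <- suppressWarnings(
    as.numeric(c(row$nj_whole, row$nj_subset)))
  supports <- supports[!is.na(supports)]
  if (length(supports) == 0L) {
    if (!is.na(row$n_haplotypes) && row$n_haplotypes == 1L) return(TRUE)
    stop("PSH ", row$psh_id,
         ": no NJ support available and more than one haplotype")
  }
  any(supports >= threshold)
}

parse_merge_sets <- function(merges, known_ids) {
  if (is.null(merges) || nrow(as.data.frame(merges)) == 0L) return(list())
  merges <- as.data.frame(merges, stringsAsFactors = FALSE)
  sets <- lapply(seq_len(nrow(merges)), function(i) {
    ids <- strsplit(as.character(merges$psh_ids[i]), "\\+")[[1]]
    ids <- trimws(ids)
    bad <- setdiff(ids, known_ids)
    if (length(bad)) stop("merge set references unknown PSHs: ",
                          paste(bad, collapse = ", "))
    if (length(ids) < 2L) stop("merge set with fewer than 2 PSHs")
    list(psh_ids = ids,
         union_nj = suppressWarnings(as.numeric(merges$union_nj[i])),
         union_bi = suppressWarnings(as.numeric(merges$union_bi[i])))
  })
  all_ids <- unlist(lapply(sets, `[[`, "psh_ids"))
  if (anyDuplicated(all_ids)) stop("merge sets are not disjoint")
  sets
}

split_groups_for <- function(splits, parent, psh, threshold) {
  if (is.null(splits)) return(list(ok = FALSE))
  splits <- as.data.frame(splits, stringsAsFactors = FALSE)
  g <- splits[as.character(splits$parent) == parent, , drop = FALSE]
  if (nrow(g) < 2L) return(list(ok = FALSE))
  mono <- vapply(seq_len(nrow(g)), function(j) {
    nj <- suppressWarnings(as.numeric(g$group_nj[j]))
    members <- strsplit(g$members[j], "\\+")[[1]]
    if (!is.na(nj)) return(nj >= threshold)
    # no joint support given: a single-haplotype child is trivially a clade
    all(psh$n_haplotypes[match(members, psh$psh_id)] == 1L)
  }, logical(1))
  distinct <- vapply(seq_len(nrow(g)), function(j) {
    members <- strsplit(g$members[j], "\\+")[[1]]
    any(vapply(members, function(m) {
      row <- psh[psh$psh_id == m, ]
      morph_unique(row)
    }, logical(1)))
  }, logical(1))
  if (!"name_applied" %in% names(g)) g$name_applied <- NA_character_
  list(ok = all(mono) && all(distinct), groups = g)
}

morph_unique <- function(row) {
  ext <- if ("morph_external" %in% names(row)) row$morph_external else "no"
  int <- if ("morph_internal" %in% names(row)) row$morph_internal else "no"
  isTRUE(ext == "yes") || isTRUE(int == "yes")
}

first_name <- function(psh, ids) {
  nms <- psh$name_applied[match(ids, psh$psh_id)]
  nms <- nms[!is.na(nms) & nms != ""]
  if (length(nms)) nms[1L] else NA_character_
}

#' @export
print.ssh_set <- function(x, ...) {
  acts <- table(x$ssh$action)
  cat("Secondary species hypothesis:", nrow(x$ssh), "species\n")
  cat("  ", paste(names(acts), acts, sep = ": ", collapse = ", "), "\n")
  invisible(x)
}

#' Append species from datasets too invariant to delimit
#'
#' Datasets whose sequence variation is too limited for barcode-gap
#' analysis are carried through as single species on external grounds.
#'
#' @param ssh An [refine()] result.
#' @param species Data frame with columns `ssh_id` and `name_applied`.
#' @return The augmented `ssh_set`.
#' @export
add_degenerate_species <- function(ssh, species) {
  stopifnot(inherits(ssh, "ssh_set"))
  species <- as.data.frame(species, stringsAsFactors = FALSE)
  extra <- data.frame(ssh_id = as.character(species$ssh_id),
                      psh_ids = NA_character_,
                      action = "degenerate", rule = "external",
                      name_applied = species$name_applied,
                      stringsAsFactors = FALSE)
  ssh$ssh <- rbind(ssh$ssh, extra)
  ssh$log <- c(ssh$log,
               paste0("SSH ", species$ssh_id,
                      ": added as single species (variation too limited to delimit)"))
  ssh
}

#' Compare a secondary species hypothesis to a known faunal checklist
#'
#' Each SSH's applied name(s) are matched against the checklist by exact
#' string comparison. Outcomes: `matched` (one SSH, one checklist name),
#' `lumped` (one SSH covering two or more checklist names), `split` (two or
#' more SSHs sharing one checklist name), `additional` (no checklist name).
#'
#' @param ssh An [refine()] (optionally [add_degenerate_species()]) result.
#' @param checklist Character vector of known species names (no duplicates).
#' @param names Optional character vector, one per SSH row, overriding the
#'   SSHs' `name_applied`; multiple checklist names for one SSH are
#'   separated by `";"`.
#' @return An object of class `fauna_comparison`: list with `table` (per
#'   SSH: `ssh_id`, `names`, `status`), and `counts`: `total_ssh`,
#'   `matched_known`, `known_lumped_pairs`, `known_split`, `additional`,
#'   `checklist_size`, `percent_increase` (additional / checklist size, as
#'   the nearest integer percent).
#' @export
compare_fauna <- function(ssh, checklist, names = NULL) {
  stopifnot(inherits(ssh, "ssh_set"))
  checklist <- as.character(checklist)
  if (anyDuplicated(checklist)) stop("duplicate names in checklist")
  if (length(checklist) == 0L) stop("checklist is empty")
  tab <- ssh$ssh
  nm <- if (is.null(names)) tab$name_applied else names
  if (length(nm) != nrow(tab)) stop("one name entry per SSH required")
  per_ssh_names <- lapply(strsplit(ifelse(is.na(nm), "", nm), ";"), trimws)
  hit_names <- lapply(per_ssh_names, function(x) x[x %in% checklist])
  n_hits <- lengths(hit_names)
  name_usage <- table(unlist(hit_names))
  status <- character(nrow(tab))
  for (i in seq_len(nrow(tab))) {
    status[i] <- if (n_hits[i] == 0L) "additional"
    else if (n_hits[i] >= 2L) "lumped"
    else if (name_usage[[hit_names[[i]]]] >= 2L) "split"
    else "matched"
  }
  counts <- list(
    total_ssh = nrow(tab),
    matched_known = sum(status != "additional"),
    known_lumped_pairs = sum(status == "lumped"),
    known_split = length(unique(unlist(hit_names[status == "split"]))),
    additional = sum(status == "additional"),
    checklist_size = length(checklist),
    percent_increase = round(100 * sum(status == "additional") /
                               length(checklist))
  )
  structure(list(table = data.frame(ssh_id = tab$ssh_id,
                                    names = vapply(per_ssh_names, paste,
                                                   character(1),
                                                   collapse = "; "),
                                    status = status,
                                    stringsAsFactors = FALSE),
                 counts = counts),
            class = "fauna_comparison")
}

#' @export
print.fauna_comparison <- function(x, ...) {
  c <- x$counts
  cat("Fauna comparison:", c$total_ssh, "SSH species vs a checklist of",
      c$checklist_size, "\n")
  cat("  corresponding to known species:", c$matched_known,
      "(", c$known_lumped_pairs, "covering two known names;",
      c$known_split, "known name(s) split across SSHs )\n")
  cat("  additional species:", c$additional,
      paste0("(+", c$percent_increase, "% on the known fauna)\n"))
  invisible(x)
}

#' Tabulate mitochondrial/morphological conflicts and classify introgression
#'
#' Counts specimens by ordered (morphospecies label, mtDNA species) pair.
#' For each unordered species pair `{A, B}` with at least one conflicting
#' specimen: `one_way` when foreign mtDNA crosses in a single direction
#' only (e.g. specimens with A morphology carrying B mtDNA, but never the
#' reverse), `two_way` otherwise. For a one-way conflict the reported
#' `direction` names the morphospecies receiving foreign mtDNA, the pattern
#' expected of introgressed hybrids descended from mothers of the mtDNA
#' species.
#'
#' @param morph Character vector of morphospecies labels, one per specimen.
#' @param mt Character vector of mtDNA species assignments, same length.
#' @return An object of class `conflict_report`: list with `pairs` (data
#'   frame: `morph`, `mt`, `n` over conflicting ordered pairs),
#'   `classification` (data frame: `species_a`, `species_b`, `n_a_mt_b`,
#'   `n_b_mt_a`, `type`, `direction`), and `n_specimens`.
#' @export
conflict_table <- function(morph, mt) {
  if (length(morph) != length(mt)) stop("morph and mt lengths differ")
  if (anyNA(morph) || anyNA(mt)) stop("missing labels")
  morph <- as.character(morph); mt <- as.character(mt)
  conflict <- morph != mt
  if (any(conflict)) {
    pairs <- as.data.frame(table(morph = morph[conflict], mt = mt[conflict]),
                           stringsAsFactors = FALSE)
    pairs <- pairs[pairs$Freq > 0L, , drop = FALSE]
    names(pairs)[3L] <- "n"
    rownames(pairs) <- NULL
  } else {
    pairs <- data.frame(morph = character(0), mt = character(0),
                        n = integer(0), stringsAsFactors = FALSE)
  }
  if (nrow(pairs) == 0L) {
    cls <- data.frame(species_a = character(0), species_b = character(0),
                      n_a_mt_b = integer(0), n_b_mt_a = integer(0),
                      type = character(0), direction = character(0),
                      stringsAsFactors = FALSE)
  } else {
    key <- t(apply(pairs[, c("morph", "mt")], 1L, sort))
    uk <- unique(as.data.frame(key, stringsAsFactors = FALSE))
    cls <- do.call(rbind, lapply(seq_len(nrow(uk)), function(i) {
      a <- uk[i, 1L]; b <- uk[i, 2L]
      n_ab <- sum(morph == a & mt == b)
      n_ba <- sum(morph == b & mt == a)
      if (n_ab > 0L && n_ba > 0L) {
        type <- "two_way"; dir <- NA_character_
      } else {
        type <- "one_way"
        dir <- if (n_ab > 0L) a else b  # morphospecies receiving foreign mtDNA
      }
      data.frame(species_a = a, species_b = b, n_a_mt_b = n_ab,
                 n_b_mt_a = n_ba, type = type, direction = dir,
                 stringsAsFactors = FALSE)
    }))
    rownames(cls) <- NULL
  }
  structure(list(pairs = pairs, classification = cls,
                 n_specimens = length(morph)),
            class = "conflict_report")
}

#' @export
print.conflict_report <- function(x, ...) {
  if (nrow(x$classification) == 0L) {
    cat("No mitochondrial/morphological conflicts among",
        x$n_specimens, "specimens\n")
  } else {
    cat("Mito/morphology conflicts among", x$n_specimens, "specimens:\n")
    for (i in seq_len(nrow(x$classification))) {
      r <- x$classification[i, ]
      if (r$type == "one_way") {
        cat("  ", r$species_a, "/", r$species_b, ": one-way (",
            r$direction, "morphology carrying foreign mtDNA )\n")
      } else {
        cat("  ", r$species_a, "/", r$species_b, ": two-way\n")
      }
    }
  }
  invisible(x)
}

#' Nuclear congruence of mitochondrially delimited species
#'
#' Tests each SSH group for monophyly in a tree from an independent
#' (nuclear) locus. Groups without nuclear sampling are skipped and
#' reported. When two or more groups each fail nuclear monophyly while
#' their union is monophyletic (with respect to the remaining, congruent
#' groups), the set is flagged as drawing on a shared nuclear gene pool --
#' the pattern expected when hybridisation has homogenised the nuclear
#' genome across mitochondrially distinct lineages.
#'
#' @param tree A `phylo` tree from the nuclear locus, tips labelled by
#'   specimen/haplotype ids.
#' @param groups Named list of character vectors: per SSH, the tip labels
#'   belonging to it (ids absent from the tree are dropped per group).
#' @param support Optional named numeric vector of bootstrap support (same
#'   names as `groups`); when given, a group only counts as supported
#'   monophyletic when its support meets `support_threshold`.
#' @param support_threshold Percent threshold, default 75.
#' @return An object of class `nuclear_congruence`: list with `table` (per
#'   group: `group`, `n_tips`, `monophyletic`, `supported`, `skipped`),
#'   `shared_pool` (character vector of groups flagged as sharing a nuclear
#'   pool; empty when none).
#' @export
nuclear_congruence <- function(tree, groups, support = NULL,
                               support_threshold = 75) {
  stopifnot(inherits(tree, "phylo"))
  tips <- tree$tip.label
  res <- lapply(names(groups), function(gn) {
    g <- intersect(groups[[gn]], tips)
    if (length(g) == 0L) {
      return(data.frame(group = gn, n_tips = 0L, monophyletic = NA,
                        supported = NA, skipped = TRUE,
                        stringsAsFactors = FALSE))
    }
    mono <- if (length(g) == length(tips)) NA
    else isTRUE(as.logical(is_monophyletic(tree, g)))
    supp <- mono
    if (!is.null(support) && gn %in% names(support)) {
      supp <- isTRUE(mono) && support[[gn]] >= support_threshold
    }
    data.frame(group = gn, n_tips = length(g), monophyletic = mono,
               supported = supp, skipped = FALSE, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, res)
  shared <- character(0)
  cand <- tab$group[!tab$skipped & !is.na(tab$supported) & !tab$supported]
  if (length(cand) >= 2L) {
    union_tips <- intersect(unique(unlist(groups[cand])), tips)
    if (length(union_tips) < length(tips)) {
      if (isTRUE(as.logical(is_monophyletic(tree, union_tips)))) {
        shared <- cand
      }
    }
  }
  structure(list(table = tab, shared_pool = shared),
            class = "nuclear_congruence")
}

#' @export
print.nuclear_congruence <- function(x, ...) {
  cat("Nuclear congruence:", sum(!x$table$skipped), "group(s) tested,",
      sum(x$table$skipped), "skipped\n")
  if (length(x$shared_pool)) {
    cat("  shared nuclear pool flagged for:",
        paste(x$shared_pool, collapse = ", "), "\n")
  } else {
    cat("  no shared nuclear pool detected\n")
  }
  invisible(x)
}
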