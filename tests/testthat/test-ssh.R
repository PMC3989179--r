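toy_psh <- function() {
  data.frame(
    psh_id = c("1", "1A", "1B", "2", "3", "4", "5"),
    n_haplotypes = c(10L, 6L, 4L, 8L, 3L, 2L, 2L),
    n_individuals = c(20L, 12L, 8L, 9L, 5L, 4L, 4L),
    nj_whole = c(40, 99, 90, 100, 100, 100, 100),
    bi_whole = c(0, 100, 80, 100, 100, 100, 100),
    nj_subset = c(10, 100, 92, 100, NA, NA, NA),
    bi_subset = c(0, 99, 85, 100, NA, NA, NA),
    morph_external = c("no", "yes", "no", "yes", "yes", "yes", "yes"),
    morph_internal = c("yes", "yes", "yes", "yes", "yes", "no", "no"),
    split_parent = c(NA, "1", "1", NA, NA, NA, NA),
    name_applied = c(NA, "Genus alpha", "Genus beta", "Genus gamma",
                     "Genus delta", "Genus epsilon", "Genus epsilon"),
    stringsAsFactors = FALSE)
}

toy_splits <- data.frame(parent = "1", group = c("1A", "1B"),
                         members = c("1A", "1B"),
                         group_nj = c(99, 90), group_bi = c(100, 80),
                         name_applied = c("Genus alpha", "Genus beta"),
                         stringsAsFactors = FALSE)

test_that("refinement applies accept, split, merge and keep rules", {
  # merge set {4,5}: union monophyletic -> one SSH (R3)
  merges_ok <- data.frame(set_id = "eps", psh_ids = "4+5",
                          union_nj = 98, union_bi = 100)
  out <- refine(toy_psh(), merges = merges_ok, splits = toy_splits)
  expect_s3_class(out, "ssh_set")
  expect_setequal(out$ssh$ssh_id, c("1A", "1B", "2", "3", "4+5"))
  expect_equal(out$ssh$action[out$ssh$ssh_id == "1A"], "split_child")
  expect_equal(out$ssh$rule[out$ssh$ssh_id == "4+5"], "R3")
  expect_equal(sum(out$ssh$action == "accept"), 2L)

  # same set with an unsupported union -> kept separate (R4)
  merges_bad <- data.frame(set_id = "eps", psh_ids = "4+5",
                           union_nj = 30, union_bi = 10)
  out2 <- refine(toy_psh(), merges = merges_bad, splits = toy_splits)
  expect_setequal(out2$ssh$ssh_id, c("1A", "1B", "2", "3", "4", "5"))
  expect_equal(out2$ssh$rule[out2$ssh$ssh_id %in% c("4", "5")], c("R4", "R4"))
})

test_that("refinement accounting conserves every PSH exactly once", {
  merges <- data.frame(set_id = "eps", psh_ids = "4+5",
                       union_nj = 98, union_bi = 100)
  out <- refine(toy_psh(), merges = merges, splits = toy_splits)
  constituents <- unlist(strsplit(out$ssh$psh_ids, "\\+"))
  expect_setequal(constituents, c("1A", "1B", "2", "3", "4", "5"))
  expect_false(anyDuplicated(constituents) > 0)
  # determinism
  out_again <- refine(toy_psh(), merges = merges, splits = toy_splits)
  expect_identical(out$ssh, out_again$ssh)
})

test_that("inconsistent evidence is rejected", {
  # a PSH cannot both carry split children and sit in a merge set
  bad <- data.frame(set_id = "x", psh_ids = "1+2", union_nj = 99,
                    union_bi = 99)
  expect_error(refine(toy_psh(), merges = bad, splits = toy_splits),
               "merge set and a split")
  # missing supports on a multi-haplotype PSH
  psh <- toy_psh()
  psh[psh$psh_id == "2", c("nj_whole", "nj_subset")] <- NA
  expect_error(refine(psh, splits = toy_splits), "PSH 2")
  # unknown PSH in a merge set
  bad2 <- data.frame(set_id = "x", psh_ids = "4+9", union_nj = 99,
                     union_bi = 99)
  expect_error(refine(toy_psh(), merges = bad2, splits = toy_splits),
               "unknown")
})

test_that("fauna comparison classifies matched, lumped, split and additional", {
  psh <- data.frame(psh_id = as.character(1:4), n_haplotypes = 2L,
                    n_individuals = 4L,
                    nj_whole = 100, bi_whole = 100, nj_subset = 100,
                    bi_subset = 100,
                    morph_external = "yes", morph_internal = "yes",
                    name_applied = c("Genus one", "Genus two;Genus three",
                                     "Genus four", "Genus nova"),
                    stringsAsFactors = FALSE)
  out <- refine(psh)
  checklist <- c("Genus one", "Genus two", "Genus three", "Genus four")
  fc <- compare_fauna(out, checklist)
  expect_equal(fc$table$status,
               c("matched", "lumped", "matched", "additional"))
  expect_equal(fc$counts$additional, 1L)
  expect_equal(fc$counts$percent_increase, 25)

  # identical faunas: no additional species
  fc2 <- compare_fauna(out, c("Genus one", "Genus two", "Genus three",
                              "Genus four", "Genus nova"))
  expect_equal(fc2$counts$additional, 0L)
  expect_equal(fc2$counts$percent_increase, 0)

  # 11 SSHs against a 10-name checklist with one unmatched -> +10%
  psh11 <- data.frame(psh_id = as.character(1:11), n_haplotypes = 2L,
                      n_individuals = 2L, nj_whole = 100, bi_whole = 100,
                      nj_subset = 100, bi_subset = 100,
                      morph_external = "yes", morph_internal = "yes",
                      name_applied = c(paste("Taxon", 1:10), "Taxon novum"),
                      stringsAsFactors = FALSE)
  fc3 <- compare_fauna(refine(psh11), paste("Taxon", 1:10))
  expect_equal(fc3$counts$additional, 1L)
  expect_equal(fc3$counts$percent_increase, 10)

  expect_error(compare_fauna(out, c("A", "A")), "duplicate")
})

test_that("conflict tables classify one-way and two-way introgression", {
  # three reticulatum-anatomy specimens carry agreste mtDNA, none reversed
  morph <- c(rep("reticulatum", 8), rep("agreste", 4))
  mt <- c(rep("reticulatum", 5), rep("agreste", 3), rep("agreste", 4))
  rep1 <- conflict_table(morph, mt)
  expect_equal(nrow(rep1$classification), 1L)
  expect_equal(rep1$classification$type, "one_way")
  expect_equal(rep1$classification$direction, "reticulatum")
  expect_equal(sum(rep1$pairs$n), 3L)
  expect_equal(rep1$n_specimens, 12L)

  # no conflicts
  rep2 <- conflict_table(c("a", "b"), c("a", "b"))
  expect_equal(nrow(rep2$classification), 0L)

  # both directions -> two_way
  rep3 <- conflict_table(c("a", "a", "b", "b"), c("b", "b", "a", "a"))
  expect_equal(rep3$classification$type, "two_way")
})

test_that("nuclear congruence flags a shared gene pool", {
  # five groups indistinguishable at the nuclear locus + distinct outgroup
  tips_pool <- paste0("p", 1:10)
  tips_out <- paste0("o", 1:3)
  nwk <- paste0("((", paste(paste0(tips_pool, ":0.001"), collapse = ","),
                "):0.2,(", paste(paste0(tips_out, ":0.01"), collapse = ","),
                "):0.2);")
  tree <- ape::read.tree(text = nwk)
  groups <- c(split(tips_pool, rep(1:5, each = 2)), list(out = tips_out))
  res <- nuclear_congruence(tree, groups)
  expect_setequal(res$shared_pool, as.character(1:5))
  expect_true(res$table$monophyletic[res$table$group == "out"])

  # mirror-image nuclear structure: everything congruent, no flag
  nwk2 <- paste0("(", paste(vapply(1:5, function(g) {
    paste0("(p", 2 * g - 1, ":0.01,p", 2 * g, ":0.01):0.2")
  }, character(1)), collapse = ","), ");")
  tree2 <- ape::read.tree(text = nwk2)
  res2 <- nuclear_congruence(tree2, split(tips_pool, rep(1:5, each = 2)))
  expect_length(res2$shared_pool, 0L)
  expect_true(all(res2$table$monophyletic))

  # missing nuclear data for one group: skipped and reported
  res3 <- nuclear_congruence(tree2, list(a = c("p1", "p2"), b = c("z1", "z2")))
  expect_true(res3$table$skipped[res3$table$group == "b"])
})

test_that("the packaged case study reproduces the published refinement", {
  cs <- slug_case_study()
  fx <- load_slug_fixture()
  # every non-split expected SSH id appears exactly as published
  expected <- unique(fx$psh$ssh_expected[fx$psh$ssh_expected != "(split)"])
  expect_setequal(cs$ssh$ssh$ssh_id[cs$ssh$ssh$action != "degenerate"],
                  expected)
  expect_equal(cs$fauna$counts$additional, 8L)
  expect_equal(cs$fauna$counts$percent_increase, 22)
  expect_equal(cs$fauna$counts$total_ssh, 44L)
  expect_equal(cs$fauna$counts$known_lumped_pairs, 1L)
  expect_equal(cs$fauna$counts$known_split, 1L)
})
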