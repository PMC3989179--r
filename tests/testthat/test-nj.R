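test_that("NJ recovers topology and lengths from additive matrices", {
  set.seed(12)
  for (ntax in c(4, 6, 8)) {
    tr <- ape::rtree(ntax, br = stats::runif)
    tr$edge.length <- tr$edge.length + 0.05  # keep branches comfortably positive
    d <- ape::cophenetic.phylo(tr)
    dm <- make_dist(d[tr$tip.label, tr$tip.label], tr$tip.label)
    est <- nj_tree(dm)
    expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(est)), 0,
                 ignore_attr = TRUE)
    # additivity: path lengths reproduce the input matrix
    est_d <- ape::cophenetic.phylo(est)[tr$tip.label, tr$tip.label]
    expect_equal(est_d, d[tr$tip.label, tr$tip.label], tolerance = 1e-9)
  }
})

test_that("three taxa give the unique tree solving the three-point equations", {
  d <- matrix(c(0, 0.3, 0.4,
                0.3, 0, 0.5,
                0.4, 0.5, 0), 3, byrow = TRUE)
  dm <- make_dist(d, c("a", "b", "c"))
  tr <- nj_tree(dm)
  expect_equal(ape::Ntip(tr), 3L)
  len <- stats::setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                         tr$tip.label)
  expect_equal(len[["a"]], (0.3 + 0.4 - 0.5) / 2)
  expect_equal(len[["b"]], (0.3 + 0.5 - 0.4) / 2)
  expect_equal(len[["c"]], (0.4 + 0.5 - 0.3) / 2)
})

test_that("taxon order does not change the NJ topology", {
  set.seed(13)
  tr <- ape::rtree(6, br = stats::runif)
  tr$edge.length <- tr$edge.length + 0.05
  d <- ape::cophenetic.phylo(tr)
  labels <- tr$tip.label
  dm1 <- make_dist(d[labels, labels], labels)
  perm <- sample(length(labels))
  dm2 <- make_dist(d[labels[perm], labels[perm]], labels[perm])
  expect_equal(ape::dist.topo(ape::unroot(nj_tree(dm1)),
                              ape::unroot(nj_tree(dm2))), 0,
               ignore_attr = TRUE)
})

test_that("negative NJ branches are zeroed without breaking the tree", {
  tr <- ape::rtree(5)
  tr$edge.length <- c(-0.02, tr$edge.length[-1])
  fixed <- barcodegap:::fix_negative_branches(tr)
  expect_true(all(fixed$edge.length >= 0))
  expect_equal(ape::Ntip(fixed), 5L)
})

test_that("midpoint rooting splits the diameter path in half", {
  # two leaves joined by 0.4: the root sits 0.2 from each
  tr2 <- ape::read.tree(text = "(a:0.15,b:0.25);")
  rooted <- midpoint_root(tr2)
  depths <- ape::node.depth.edgelength(rooted)
  expect_equal(depths[1:2], c(0.2, 0.2), tolerance = 1e-9)

  # caterpillar: the root lies on the brute-force diameter path
  cat_tree <- ape::read.tree(
    text = "(((a:0.1,b:0.05):0.3,c:0.05):0.2,(d:0.4,e:0.02):0.1);")
  rooted2 <- midpoint_root(ape::unroot(cat_tree))
  d <- ape::cophenetic.phylo(cat_tree)
  diam <- max(d)
  ends <- which(d == diam, arr.ind = TRUE)[1, ]
  depths2 <- ape::node.depth.edgelength(rooted2)
  tipn <- match(rownames(d)[ends], rooted2$tip.label)
  expect_equal(unname(depths2[tipn[1]]), diam / 2, tolerance = 1e-9)
  expect_equal(unname(depths2[tipn[2]]), diam / 2, tolerance = 1e-9)

  # idempotence
  again <- midpoint_root(rooted2)
  expect_equal(ape::cophenetic.phylo(again), ape::cophenetic.phylo(rooted2),
               tolerance = 1e-12)
})

test_that("monophyly agrees with exhaustive bipartition enumeration", {
  set.seed(14)
  for (trial in 1:5) {
    tr <- ape::rtree(8, br = stats::runif)
    tips <- tr$tip.label
    # all true bipartitions of the unrooted tree
    unrooted <- ape::unroot(tr)
    bip <- ape::prop.part(unrooted)
    sides <- c(lapply(bip, function(idx) tips[idx]),
               as.list(tips))  # leaf edges are bipartitions too
    all_splits <- c(sides, lapply(sides, function(s) setdiff(tips, s)))
    all_splits <- Filter(function(s) length(s) > 0 && length(s) < length(tips),
                         all_splits)
    key <- function(s) paste(sort(s), collapse = "|")
    split_keys <- unique(vapply(all_splits, key, character(1)))
    for (rep in 1:10) {
      size <- sample(2:(length(tips) - 1), 1)
      grp <- sample(tips, size)
      expect_equal(isTRUE(as.logical(is_monophyletic(tr, grp))),
                   key(grp) %in% split_keys,
                   info = paste("group:", key(grp)))
    }
    # complement symmetry on a genuine clade
    clade <- sides[[2]]
    if (length(clade) > 0 && length(clade) < length(tips)) {
      expect_true(as.logical(is_monophyletic(tr, clade)))
      expect_true(as.logical(is_monophyletic(tr, setdiff(tips, clade))))
    }
  }
  # singleton convention
  tr <- ape::rtree(5)
  res <- is_monophyletic(tr, tr$tip.label[1])
  expect_true(as.logical(res))
  expect_true(attr(res, "trivial"))
})

test_that("bootstrap support is deterministic, high for clean clades, reproducible", {
  sim <- simulate_dataset(sim_config(K = 2, n = 5, intra = 0.005,
                                     inter = 0.2), seed = 15)
  haps <- collapse_haplotypes(sim$alignment)
  sp <- sim$truth$species[match(vapply(haps$members, `[`, character(1), 1),
                                sim$truth$specimen_id)]
  groups <- split(rownames(haps$seq), sp)
  s1 <- bootstrap_support(haps, groups, reps = 50, seed = 99)
  s2 <- bootstrap_support(haps, groups, reps = 50, seed = 99)
  expect_identical(s1, s2)
  expect_true(all(s1$support >= 90))
  # a random group of the same size does worse than the true species
  set.seed(16)
  rnd <- sample(rownames(haps$seq), length(groups[[1]]))
  while (setequal(rnd, groups[[1]]) || setequal(rnd, groups[[2]]))
    rnd <- sample(rownames(haps$seq), length(groups[[1]]))
  sr <- bootstrap_support(haps, list(random = rnd), reps = 50, seed = 99)
  expect_lt(sr$support, min(s1$support))
})

test_that("trees round-trip through Newick", {
  tr <- ape::rtree(6)
  path <- tempfile(fileext = ".nwk")
  write_tree(tr, path)
  back <- read_tree(path)
  expect_equal(sort(back$tip.label), sort(tr$tip.label))
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(back)), 0,
               ignore_attr = TRUE)
})
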