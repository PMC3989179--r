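# Ground-truth sequence simulator. Sequences evolve under the two-parameter
# (transition-biased, Kimura) substitution process along a star species
# tree, so the branch lengths that hit a target K2P divergence have a
# closed form: the expected K2P estimate between two tips equals the path
# length between them in expected substitutions per site. Optional
# introgression directives replace the mtDNA of a chosen fraction of a
# recipient species' individuals with sequences evolved from the donor
# lineage, while morphology labels (and any nuclear locus) stay with the
# true species -- the maternally inherited marker crossing a species
# boundary.

#' Configuration for a simulated barcode dataset
#'
#' @param K Number of species.
#' @param n Per-species sample sizes: scalar (recycled) or length-`K`
#'   vector. Two or more sequences per species mirrors the sampling the
#'   delimitation rules assume.
#' @param L Alignment length in sites; 650 suits a COI-like fragment,
#'   440 a 16S-like one.
#' @param intra Target mean intraspecific K2P distance (substitutions/site).
#' @param inter Target interspecific K2P distance between species (tip to
#'   tip); must exceed `intra`.
#' @param kappa Transition/transversion rate ratio of the substitution
#'   process, default 4.
#' @param base_freq Root base composition (A, C, G, T), default uniform.
#'   The substitution process itself is symmetric (two-parameter), as the
#'   K2P distance assumes.
#' @param introgression Optional data frame of directives: columns `donor`,
#'   `recipient` (species indices) and `fraction` (of recipient individuals
#'   whose mtDNA descends from the donor; realized count is
#'   `round(fraction * n_recipient)`).
#' @param locus Locus tag recorded in metadata, default `"mtCOI"`.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(K, n = 6, L = 650, intra = 0.01, inter = 0.15,
                       kappa = 4, base_freq = rep(0.25, 4),
                       introgression = NULL, locus = "mtCOI") {
  stopifnot(K >= 1, L >= 1, intra >= 0, kappa > 0, length(base_freq) == 4,
            all(base_freq >= 0), abs(sum(base_freq) - 1) < 1e-8)
  if (K > 1 && inter <= intra) stop("interspecific target must exceed intraspecific")
  n <- rep_len(as.integer(n), K)
  if (any(n < 1L)) stop("each species needs at least 1 individual")
  if (K > 1 && inter * L < 1) {
    stop("targets incompatible with L: expected substitutions below 1 site")
  }
  if (!is.null(introgression)) {
    introgression <- as.data.frame(introgression)
    stopifnot(all(c("donor", "recipient", "fraction") %in% names(introgression)),
              all(introgression$donor %in% seq_len(K)),
              all(introgression$recipient %in% seq_len(K)),
              all(introgression$fraction >= 0 & introgression$fraction <= 1),
              all(introgression$donor != introgression$recipient))
  }
  structure(list(K = as.integer(K), n = n, L = as.integer(L), intra = intra,
                 inter = inter, kappa = kappa, base_freq = base_freq,
                 introgression = introgression, locus = locus),
            class = "sim_config")
}

# K80 substitution probabilities after t expected substitutions/site.
# Rates scaled so alpha + 2*beta = 1 (t is in substitutions per site).
k80_site_probs <- function(t, kappa) {
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  p_ts <- 0.25 + 0.25 * exp(-4 * beta * t) - 0.5 * exp(-2 * (alpha + beta) * t)
  p_tv <- 0.5 - 0.5 * exp(-4 * beta * t)  # total over both transversion targets
  c(same = 1 - p_ts - p_tv, ts = p_ts, tv_each = p_tv / 2)
}

# evolve an integer-coded sequence (1=A,2=C,3=G,4=T) along a branch
# of t expected substitutions/site
TS_PARTNER <- c(3L, 4L, 1L, 2L)          # A<->G, C<->T
TV_PARTNERS <- matrix(c(2L, 4L,           # A -> C,T
                        1L, 3L,           # C -> A,G
                        2L, 4L,           # G -> C,T
                        1L, 3L), 4L, 2L, byrow = TRUE)

evolve_branch <- function(seq_int, t, kappa) {
  if (t <= 0) return(seq_int)
  p <- k80_site_probs(t, kappa)
  u <- stats::runif(length(seq_int))
  out <- seq_int
  ts_hit <- u >= p["same"] & u < p["same"] + p["ts"]
  out[ts_hit] <- TS_PARTNER[seq_int[ts_hit]]
  tv1 <- u >= p["same"] + p["ts"] & u < p["same"] + p["ts"] + p["tv_each"]
  tv2 <- u >= p["same"] + p["ts"] + p["tv_each"]
  out[tv1] <- TV_PARTNERS[cbind(seq_int[tv1], 1L)]
  out[tv2] <- TV_PARTNERS[cbind(seq_int[tv2], 2L)]
  out
}

int_to_char <- function(seq_int) c("A", "C", "G", "T")[seq_int]

#' Simulate an aligned barcode dataset with known species structure
#'
#' Draws a root sequence from the configured base composition, evolves one
#' ancestor per species along a star tree (branch `(inter - intra) / 2`
#' expected substitutions/site, so that tip-to-tip interspecific divergence
#' targets `inter`), then evolves each individual from its species ancestor
#' (branch `intra / 2`, so within-species pairs target `intra`).
#' Introgressed individuals instead take a sequence evolved from the donor
#' species' ancestor; their morphospecies label is untouched.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; identical `cfg` + `seed` give byte-identical
#'   output.
#' @return List with `alignment` (an [alignment()] object; morphospecies
#'   labels are the true species, `"species_1"...`) and `truth` (data
#'   frame: `specimen_id`, `species`, `morph_label`, `mt_origin`).
#' @export
simulate_dataset <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  species_branch <- if (cfg$K > 1) max(cfg$inter - cfg$intra, 0) / 2 else 0
  indiv_branch <- cfg$intra / 2
  root <- sample.int(4L, cfg$L, replace = TRUE, prob = cfg$base_freq)
  ancestors <- lapply(seq_len(cfg$K), function(s)
    evolve_branch(root, species_branch, cfg$kappa))
  species_of <- rep(seq_len(cfg$K), cfg$n)
  mt_origin <- species_of
  if (!is.null(cfg$introgression)) {
    for (i in seq_len(nrow(cfg$introgression))) {
      dir <- cfg$introgression[i, ]
      rec_idx <- which(species_of == dir$recipient)
      n_intro <- round(dir$fraction * length(rec_idx))
      if (n_intro > 0L) mt_origin[rec_idx[seq_len(n_intro)]] <- dir$donor
    }
  }
  seqs <- vapply(seq_along(species_of), function(i) {
    paste(int_to_char(evolve_branch(ancestors[[mt_origin[i]]],
                                    indiv_branch, cfg$kappa)),
          collapse = "")
  }, character(1))
  ids <- sprintf("sp%02d_ind%02d", species_of,
                 stats::ave(species_of, species_of, FUN = seq_along))
  names(seqs) <- ids
  meta <- data.frame(specimen_id = ids,
                     morphospecies_label = paste0("species_", species_of),
                     locality = paste0("site_", species_of),
                     in_britain_or_ireland = TRUE,
                     source = "new",
                     locus = cfg$locus,
                     stringsAsFactors = FALSE)
  truth <- data.frame(specimen_id = ids,
                      species = paste0("species_", species_of),
                      morph_label = paste0("species_", species_of),
                      mt_origin = paste0("species_", mt_origin),
                      stringsAsFactors = FALSE)
  list(alignment = alignment(seqs, meta), truth = truth)
}

#' A fixed battery of simulated datasets exercising the whole pipeline
#'
#' Generates, from one seed: clean multi-species sets with 2, 5 and 9
#' species (intraspecific target 0.01, interspecific 0.15, 650 sites --
#' scales typical of barcode studies where within-species means stay below
#' a few percent and between-species minima run from 5 to over 20 percent);
#' a degenerate set whose variation is too limited to delimit; an
#' unbalanced set (1 sequence in one species vs 50 in the other); a
#' one-way introgression set (a third of the recipient species carrying
#' donor mtDNA); and a paired two-locus set in which five species are
#' mitochondrially distinct but share one nuclear pool, with a sixth
#' species distinct at both loci.
#'
#' @param seed Integer seed.
#' @return Named list of [simulate_dataset()] results (`clean_k2`,
#'   `clean_k5`, `clean_k9`, `degenerate`, `unbalanced`, `introgression`,
#'   and `shared_pool` = list of `mt` and `nuclear` datasets).
#' @export
simulate_paper_like_suite <- function(seed = 1) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, 8L)
  out <- list(
    clean_k2 = simulate_dataset(sim_config(K = 2, n = 6), seed = seeds[1]),
    clean_k5 = simulate_dataset(sim_config(K = 5, n = 6), seed = seeds[2]),
    clean_k9 = simulate_dataset(sim_config(K = 9, n = 6), seed = seeds[3]),
    degenerate = simulate_dataset(
      sim_config(K = 1, n = 8, intra = 0.0005, locus = "mtCOI"),
      seed = seeds[4]),
    unbalanced = simulate_dataset(
      sim_config(K = 2, n = c(1, 50)), seed = seeds[5]),
    introgression = simulate_dataset(
      sim_config(K = 2, n = c(9, 9), inter = 0.05,
                 introgression = data.frame(donor = 1, recipient = 2,
                                            fraction = 1 / 3)),
      seed = seeds[6])
  )
  # shared nuclear pool: mt locus separates six species; at the nuclear
  # locus species 1-5 coalesce into one pool, species 6 stays distinct
  mt <- simulate_dataset(sim_config(K = 6, n = 4), seed = seeds[7])
  pool_cfg <- sim_config(K = 2, n = c(20, 4), intra = 0.005, inter = 0.15,
                         locus = "nuclearITS1")
  nuc <- simulate_dataset(pool_cfg, seed = seeds[8])
  # relabel nuclear specimens to match the mt specimens one-to-one
  ids <- rownames(mt$alignment$seq)
  rownames(nuc$alignment$seq) <- ids
  nuc$alignment$meta$specimen_id <- ids
  nuc$alignment$meta$morphospecies_label <- mt$alignment$meta$morphospecies_label
  nuc$truth$specimen_id <- ids
  nuc$truth$species <- mt$truth$species
  nuc$truth$morph_label <- mt$truth$morph_label
  out$shared_pool <- list(mt = mt, nuclear = nuc)
  out
}

#' True species count of a simulated dataset
#' @param sim A [simulate_dataset()] result.
#' @return Integer.
#' @export
true_species_count <- function(sim) length(unique(sim$truth$species))

#' Run delimitation end to end on a simulated dataset
#'
#' Convenience wrapper: collapse haplotypes, compute the K2P matrix, sweep
#' priors, select the PSH.
#'
#' @param sim A [simulate_dataset()] result.
#' @param config A [sweep_config()].
#' @return A list with `haps`, `dm`, `sweep`, `psh`.
#' @export
delimit <- function(sim, config = sweep_config()) {
  haps <- collapse_haplotypes(sim$alignment)
  if (nrow(haps$seq) < 2L) {
    # a single haplotype cannot be swept; report it as one species
    one <- stats::setNames(1L, rownames(haps$seq))
    sweep <- structure(list(table = data.frame(prior = sweep_priors(config),
                                               n_initial = 1L,
                                               n_recursive = 1L),
                            partitions = list(list(initial = one,
                                                   recursive = one)),
                            degenerate = TRUE, config = config,
                            labels = rownames(haps$seq)),
                       class = "abgd_sweep")
    psh <- select_psh(sweep)
    return(list(haps = haps, dm = NULL, sweep = sweep, psh = psh))
  }
  dm <- k2p_matrix(haps)
  sweep <- prior_sweep(dm, config)
  psh <- select_psh(sweep)
  list(haps = haps, dm = dm, sweep = sweep, psh = psh)
}
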