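#' @include core_io.R distances.R
NULL

#' Simulation configuration for a synthetic flora
#'
#' Bundles and validates the parameters of [simulate_flora()]. The defaults
#' emulate the structure of a tropical cloud-forest pteridophyte survey: a
#' ~1.3 kb plastid barcode alignment over ~176 terminal taxa with a small set
#' of taxon pairs sharing an identical haplotype (maternally inherited
#' plastid captured by putative hybrids), one to five specimens per taxon, a
#' few partial sequences, and per-day detections over 37 sampling units.
#'
#' @param n_species Number of species (terminal taxa).
#' @param seq_length Alignment length in bp.
#' @param birth_rate Yule speciation rate for the species tree.
#' @param subst_rate Expected substitutions/site from root to tip (the tree
#'   is rescaled to this depth).
#' @param n_failure_pairs Number of disjoint taxon pairs forced to share a
#'   haplotype (each pair contributes two barcode failures). Must not exceed
#'   `n_species / 2`.
#' @param p_single Probability a taxon has exactly one specimen; otherwise
#'   the specimen count is uniform on `extra_range`.
#' @param extra_range Two integers: range of specimen counts for multi-
#'   specimen taxa (default 2 to 5).
#' @param T Number of sampling units (collection days).
#' @param detection Two positive shape parameters of the Beta distribution of
#'   per-species daily detection probability.
#' @param habit_probs Named numeric vector over [HABIT_TOKENS]: target
#'   marginal proportion of taxa carrying each growth habit (proportions may
#'   sum past 1; taxa can be multi-habit).
#' @param partial_fraction Fraction of specimens truncated to a 5' or 3'
#'   half (the other half becomes `N`).
#' @param n_nonnative Number of taxa flagged non-native.
#' @param min_overlap Overlap threshold used for the generator's internal
#'   identity checks (matches the analysis default).
#' @param redraw_limit Maximum attempts to re-draw a flora whose sequences
#'   collide outside the designated failure pairs.
#' @param seed Optional integer seed.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_species = 176,
                              seq_length = 1309,
                              birth_rate = 1,
                              subst_rate = 0.15,
                              n_failure_pairs = 16,
                              p_single = 0.8,
                              extra_range = c(2L, 5L),
                              T = 37,
                              detection = c(2, 2),
                              habit_probs = c(
                                climbing = 5 / 178, epipetric = 19 / 178,
                                epiphytic = 94 / 178, terrestrial = 74 / 178
                              ),
                              partial_fraction = 3 / 186,
                              n_nonnative = 1,
                              min_overlap = 100,
                              redraw_limit = 20,
                              seed = NULL) {
  stopifnot(
    n_species >= 2, seq_length >= 1, birth_rate > 0, subst_rate > 0,
    n_failure_pairs >= 0, n_failure_pairs <= n_species / 2,
    p_single >= 0, p_single <= 1, length(extra_range) == 2,
    extra_range[1] >= 1, extra_range[2] >= extra_range[1],
    T >= 1, length(detection) == 2, all(detection > 0),
    partial_fraction >= 0, partial_fraction <= 1,
    n_nonnative >= 0, n_nonnative <= n_species,
    min_overlap >= 1, redraw_limit >= 1
  )
  if (!all(names(habit_probs) %in% HABIT_TOKENS) ||
    any(habit_probs < 0 | habit_probs > 1)) {
    abort("habit_probs must be named probabilities over the habit tokens.")
  }
  structure(
    list(
      n_species = as.integer(n_species), seq_length = as.integer(seq_length),
      birth_rate = birth_rate, subst_rate = subst_rate,
      n_failure_pairs = as.integer(n_failure_pairs), p_single = p_single,
      extra_range = as.integer(extra_range), T = as.integer(T),
      detection = detection, habit_probs = habit_probs,
      partial_fraction = partial_fraction,
      n_nonnative = as.integer(n_nonnative),
      min_overlap = as.integer(min_overlap),
      redraw_limit = as.integer(redraw_limit), seed = seed
    ),
    class = "simulation_config"
  )
}

#' Draw multi-label growth habits
#'
#' Independent per-habit Bernoulli draws whose raw probabilities are
#' calibrated (fixed point) so that, conditional on a taxon carrying at least
#' one habit, the marginal proportion of each habit equals `habit_probs`.
#' Requires `sum(habit_probs) > 1` (otherwise one habit per taxon is drawn
#' from `habit_probs` renormalized).
#'
#' @param n Number of taxa.
#' @param habit_probs Named target marginal proportions.
#' @return List of `n` character vectors (each non-empty).
#' @export
simulate_habits <- function(n, habit_probs = c(
                              climbing = 5 / 178, epipetric = 19 / 178,
                              epiphytic = 94 / 178, terrestrial = 74 / 178
                            )) {
  p <- habit_probs
  toks <- names(p)
  if (sum(p) <= 1) {
    pick <- sample(toks, n, replace = TRUE, prob = p / sum(p))
    return(as.list(pick))
  }
  # solve pi = 1 - prod(1 - p_i * pi); raw prob r_i = p_i * pi gives
  # conditional marginals r_i / pi = p_i exactly
  pi_hat <- 1
  for (it in seq_len(200)) {
    pi_new <- 1 - prod(1 - p * pi_hat)
    if (abs(pi_new - pi_hat) < 1e-12) break
    pi_hat <- pi_new
  }
  r <- p * pi_hat
  out <- vector("list", n)
  for (i in seq_len(n)) {
    repeat {
      h <- toks[runif(length(r)) < r]
      if (length(h) > 0) break
    }
    out[[i]] <- h
  }
  out
}

#' Simulate an incidence matrix with known true richness
#'
#' Each species draws a daily detection probability from a Beta
#' distribution; detections are independent Bernoulli trials per sampling
#' unit. Species never detected are dropped from the matrix (a survey
#' checklist contains only observed species) but retained in the truth
#' record, so richness estimators can be scored against the true count.
#'
#' @param n_species True number of species.
#' @param T Number of sampling units.
#' @param detection Beta shape parameters for per-species daily detection.
#' @param taxa Optional character vector of taxon names (default `sp001`...).
#' @return List with `incidence` (an [incidence_matrix()] over detected
#'   species), `true_richness`, `detected` (names) and `p` (tibble of
#'   per-species detection probabilities).
#' @export
simulate_incidence <- function(n_species, T = 37, detection = c(2, 2),
                               taxa = NULL) {
  stopifnot(n_species >= 1, T >= 1, all(detection > 0))
  if (is.null(taxa)) taxa <- sprintf("sp%04d", seq_len(n_species))
  stopifnot(length(taxa) == n_species)
  p <- rbeta(n_species, detection[1], detection[2])
  m <- matrix(
    rbinom(n_species * T, 1L, rep(p, times = T)),
    nrow = n_species, ncol = T,
    dimnames = list(taxa, sprintf("day%02d", seq_len(T)))
  )
  detected <- rowSums(m) > 0
  list(
    incidence = incidence_matrix(m[detected, , drop = FALSE]),
    true_richness = n_species,
    detected = taxa[detected],
    p = tibble(taxon = taxa, p_detect = p)
  )
}

# Rescale a phylo tree so the maximum root-to-tip depth equals `depth`.
scale_tree_depth <- function(tree, depth) {
  cur <- max(ape::node.depth.edgelength(tree)[seq_len(ape::Ntip(tree))])
  tree$edge.length <- tree$edge.length * depth / cur
  tree
}

# Evolve haplotypes under Jukes-Cantor along a tree (phangorn::simSeq),
# returned as an uppercase character matrix with tip rownames.
evolve_haplotypes <- function(tree, seq_length) {
  sim <- phangorn::simSeq(tree, l = seq_length, type = "DNA")
  m <- toupper(as.character(sim))
  m[tree$tip.label, , drop = FALSE]
}

# Group tips into clades by cutting the tree at `frac` of its depth: each
# group is the first node on the root-to-tip path at or beyond the cutoff.
clade_groups <- function(tree, frac) {
  depths <- ape::node.depth.edgelength(tree)
  cutoff <- frac * max(depths[seq_len(ape::Ntip(tree))])
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  vapply(seq_len(ape::Ntip(tree)), function(tip) {
    node <- tip
    repeat {
      up <- parent[node]
      if (up == 0 || up == root || depths[up] < cutoff) break
      node <- up
    }
    node
  }, integer(1))
}

# Specimen counts per taxon: 1 with prob p_single, else uniform on range.
draw_specimen_counts <- function(n, p_single, extra_range) {
  counts <- rep(1L, n)
  multi <- runif(n) >= p_single
  counts[multi] <- sample(
    seq(extra_range[1], extra_range[2]),
    sum(multi),
    replace = TRUE
  )
  counts
}

# One attempt at a synthetic flora; returns NULL when sequences collide
# outside the designated failure pairs.
simulate_flora_once <- function(cfg) {
  n <- cfg$n_species
  tree <- scale_tree_depth(
    ape::rphylo(n, birth = cfg$birth_rate, death = 0),
    cfg$subst_rate
  )
  # taxonomy from nested depth cuts; the smallest family is labeled as a
  # lycophyte family so checklists carry a small lycophyte component
  fam_id <- clade_groups(tree, 0.25)
  gen_id <- clade_groups(tree, 0.6)
  fam_sizes <- table(fam_id)
  lyco <- as.integer(names(fam_sizes)[order(fam_sizes, as.integer(names(fam_sizes)))][1])
  fam_names <- setNames(
    sprintf("Famplesiaceae%02d", seq_along(unique(fam_id))),
    sort(unique(fam_id))
  )
  fam_names[as.character(lyco)] <- "Lycopodiaceae"
  gen_names <- setNames(
    sprintf("Genus%03d", seq_along(unique(gen_id))),
    sort(unique(gen_id))
  )
  taxa <- sprintf("%s sp%03d", gen_names[as.character(gen_id)], seq_len(n))
  tree$tip.label <- taxa

  hap <- evolve_haplotypes(tree, cfg$seq_length)

  # designated shared-haplotype pairs: the second taxon's haplotype is
  # overwritten by the first's (maternal plastid capture)
  pair_idx <- matrix(integer(0), ncol = 2)
  if (cfg$n_failure_pairs > 0) {
    chosen <- sample.int(n, 2 * cfg$n_failure_pairs)
    pair_idx <- matrix(chosen, ncol = 2, byrow = TRUE)
    for (k in seq_len(nrow(pair_idx))) {
      hap[pair_idx[k, 2], ] <- hap[pair_idx[k, 1], ]
    }
  }
  failure_pairs <- tibble(
    taxon_a = taxa[pair_idx[, 1]],
    taxon_b = taxa[pair_idx[, 2]]
  )
  designated <- unique(c(failure_pairs$taxon_a, failure_pairs$taxon_b))

  # specimens: first carries the haplotype; extras get at most one private
  # mutation each
  counts <- draw_specimen_counts(n, cfg$p_single, cfg$extra_range)
  spec_rows <- vector("list", n)
  for (i in seq_len(n)) {
    seqs <- matrix(
      rep(hap[i, ], counts[i]),
      nrow = counts[i], byrow = TRUE
    )
    if (counts[i] > 1) {
      for (k in 2:counts[i]) {
        if (runif(1) < 0.5) {
          site <- sample.int(cfg$seq_length, 1)
          seqs[k, site] <- sample(setdiff(UNAMBIGUOUS_BASES, seqs[k, site]), 1)
        }
      }
    }
    rownames(seqs) <- sprintf(
      "%s_%02d", gsub(" ", "_", taxa[i]), seq_len(counts[i])
    )
    spec_rows[[i]] <- seqs
  }
  spec_mat <- do.call(rbind, spec_rows)
  spec_taxon <- rep(taxa, counts)

  # partial sequences: a random subset keeps only its 5' or 3' half
  n_spec <- nrow(spec_mat)
  n_partial <- round(cfg$partial_fraction * n_spec)
  partial_ids <- character(0)
  if (n_partial > 0) {
    half <- floor(cfg$seq_length / 2)
    who <- sample.int(n_spec, n_partial)
    for (w in who) {
      if (runif(1) < 0.5) {
        spec_mat[w, seq_len(cfg$seq_length) > half] <- "N" # keep 5' half
      } else {
        spec_mat[w, seq_len(cfg$seq_length) <= half] <- "N" # keep 3' half
      }
    }
    partial_ids <- rownames(spec_mat)[who]
  }

  aln <- aln_from_matrix(spec_mat)

  # identity audit: every defined zero-distance cross-taxon pair must lie
  # within a designated failure pair, else the attempt is discarded
  dm <- build_distance_matrix(aln, min_overlap = cfg$min_overlap)
  zero <- which(dm$d == 0 & upper.tri(dm$d), arr.ind = TRUE)
  if (nrow(zero) > 0) {
    t1 <- spec_taxon[zero[, 1]]
    t2 <- spec_taxon[zero[, 2]]
    cross <- t1 != t2
    if (any(cross)) {
      seen <- unique(paste(
        pmin(t1[cross], t2[cross]), pmax(t1[cross], t2[cross]),
        sep = "\r"
      ))
      ok <- paste(
        pmin(failure_pairs$taxon_a, failure_pairs$taxon_b),
        pmax(failure_pairs$taxon_a, failure_pairs$taxon_b),
        sep = "\r"
      )
      if (!all(seen %in% ok)) {
        return(NULL)
      }
    }
  }

  habits <- simulate_habits(n, cfg$habit_probs)
  native <- rep(TRUE, n)
  if (cfg$n_nonnative > 0) {
    native[sample.int(n, cfg$n_nonnative)] <- FALSE
  }
  taxa_tbl <- tibble(
    taxon = taxa,
    rank = "species",
    genus = gen_names[as.character(gen_id)],
    family = fam_names[as.character(fam_id)],
    habits = habits,
    native = native,
    flora = "synthetic"
  )
  spec_tbl <- tibble(
    specimen_id = rownames(spec_mat),
    taxon = spec_taxon,
    flora = "synthetic",
    sequenced = TRUE
  )
  checklist <- survey_checklist(taxa_tbl, spec_tbl)

  inc_sim <- simulate_incidence(n, T = cfg$T, detection = cfg$detection,
    taxa = taxa)

  truth <- list(
    failure_pairs = failure_pairs,
    failure_taxa = sort(designated),
    true_richness = n,
    detected = inc_sim$detected,
    detection = inc_sim$p,
    nonnative_taxa = taxa[!native],
    partial_specimens = sort(partial_ids),
    tree = ape::write.tree(tree)
  )
  structure(
    list(
      alignment = aln, checklist = checklist,
      incidence = inc_sim$incidence, truth = truth, config = cfg
    ),
    class = "synthetic_flora"
  )
}

#' Simulate a synthetic flora
#'
#' Generates the three inputs the analysis pipeline consumes — an aligned
#' barcode matrix, a survey checklist and a taxon-by-day incidence matrix —
#' plus a truth record, under a known model: a Yule species tree rescaled to
#' `subst_rate` substitutions/site of depth, Jukes–Cantor sequence evolution,
#' designated taxon pairs overwritten to share a haplotype (the injected
#' barcode failures), conspecific specimens within one private mutation of
#' their species haplotype, a fraction of specimens truncated to one half,
#' and Beta-Bernoulli detection over `T` sampling units. Any chance identity
#' between non-designated taxa (including identity created by the
#' half-sequence masking) is detected and the flora re-drawn, so the realized
#' failure set equals the designated one by construction.
#'
#' @param cfg A [simulation_config()].
#' @param seed Integer seed (overrides `cfg$seed`). Identical seeds give
#'   byte-identical outputs.
#' @return A list of class `synthetic_flora` with elements `alignment`,
#'   `checklist`, `incidence`, `truth` and `config`.
#' @export
simulate_flora <- function(cfg = simulation_config(), seed = cfg$seed) {
  stopifnot(inherits(cfg, "simulation_config"))
  with_seed(seed, {
    for (attempt in seq_len(cfg$redraw_limit)) {
      out <- simulate_flora_once(cfg)
      if (!is.null(out)) {
        return(out)
      }
    }
    abort(paste0(
      "could not draw a collision-free flora in ", cfg$redraw_limit,
      " attempts; increase seq_length or subst_rate."
    ))
  })
}

#' @export
print.synthetic_flora <- function(x, ...) {
  cat(
    "<synthetic_flora> ", x$config$n_species, " species, ",
    nrow(x$alignment), " specimens, ",
    nrow(x$truth$failure_pairs), " shared-haplotype pair(s), T = ",
    x$config$T, "\n",
    sep = ""
  )
  invisible(x)
}

#' Write the simulated inputs to disk
#'
#' Writes `alignment.fasta`, `checklist.csv`, `incidence.csv` and
#' `truth.json` into a directory: exactly the files [run_pipeline()]
#' consumes, plus the truth record.
#'
#' @param sim A `synthetic_flora` from [simulate_flora()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the four paths, invisibly.
#' @export
write_flora <- function(sim, dir) {
  stopifnot(inherits(sim, "synthetic_flora"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    alignment = file.path(dir, "alignment.fasta"),
    checklist = file.path(dir, "checklist.csv"),
    incidence = file.path(dir, "incidence.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_aligned_fasta(sim$alignment, paths[["alignment"]])
  write_checklist(sim$checklist, paths[["checklist"]])
  write_incidence(sim$incidence, paths[["incidence"]])
  truth <- sim$truth
  truth$detection <- as.list(setNames(
    truth$detection$p_detect,
    truth$detection$taxon
  ))
  jsonlite::write_json(truth, paths[["truth"]],
    auto_unbox = TRUE, digits = NA, pretty = TRUE,
    dataframe = "rows"
  )
  invisible(paths)
}

# Subset selection on the pool distance matrix, ranked by each tip's
# nearest-neighbour distance. "island" takes the most isolated tips (deep
# splits only: every relative is distant); "continental" takes the least
# isolated (recent splits: close relatives, including shared-haplotype
# partners, come in together); "mixed" samples uniformly. Ties are broken
# at random.
select_flora_species <- function(d, n_pick, profile, preselected = integer(0)) {
  n <- nrow(d)
  avail <- setdiff(seq_len(n), preselected)
  if (profile == "mixed") {
    return(sample(avail, n_pick))
  }
  dd <- d
  diag(dd) <- Inf
  nn <- apply(dd, 1, min)
  ord <- order(nn[avail], runif(length(avail)),
    decreasing = (profile == "island")
  )
  avail[head(ord, n_pick)]
}

#' Simulate labeled floras with contrasting divergence structure
#'
#' Draws one shared species pool (Yule tree + Jukes–Cantor haplotypes, with
#' additional shared-haplotype pairs injected to emulate plastid capture by
#' hybrids) and assembles several floras by subsetting it. An `"island"`
#' flora takes the pool's most isolated tips (largest nearest-neighbour
#' distance: deep splits only, emulating an isolated oceanic flora of
#' long-distance immigrants); a `"continental"` flora takes the least
#' isolated tips (many recent splits, emulating in-situ radiation) and
#' therefore captures shared-haplotype partners — injected or arisen
#' naturally among barely diverged sisters — far more often; `"mixed"`
#' samples at random. A `shared_fraction` of 1 makes all floras identical in
#' species content. Unlike [simulate_flora()], chance haplotype identity is
#' not redrawn here: recent-split identity is part of the continental
#' signal, and the truth record reports the *realized* per-flora failure
#' sets, computed from haplotype identity within each flora.
#'
#' @param n_species Species per flora.
#' @param profiles Named character vector: flora label -> profile (each of
#'   `"island"`, `"continental"`, `"mixed"`).
#' @param pool_multiplier Pool size as a multiple of `n_species`.
#' @param shared_fraction Fraction of each flora drawn from a common species
#'   set shared by all floras.
#' @param failure_fraction Fraction of pool species tied up in injected
#'   shared-haplotype pairs.
#' @param seq_length,birth_rate,subst_rate As in [simulation_config()].
#' @param seed Optional integer seed.
#' @return A list of class `synthetic_floras` with `alignment` (one specimen
#'   per species per flora), `checklist` (taxa keyed by taxon and flora) and
#'   `truth` (`species` and realized `failure_taxa` per flora, plus the
#'   injected pairs and the pool tree).
#' @export
simulate_three_floras <- function(n_species = 30,
                                  profiles = c(
                                    island = "island",
                                    continental = "continental",
                                    mixed = "mixed"
                                  ),
                                  pool_multiplier = 3,
                                  shared_fraction = 0,
                                  failure_fraction = 0.15,
                                  seq_length = 1309,
                                  birth_rate = 1,
                                  subst_rate = 0.1,
                                  seed = NULL) {
  stopifnot(
    n_species >= 2, pool_multiplier >= 1,
    shared_fraction >= 0, shared_fraction <= 1,
    failure_fraction >= 0, failure_fraction <= 1,
    all(profiles %in% c("island", "continental", "mixed")),
    length(names(profiles)) == length(profiles)
  )
  n_pool <- as.integer(ceiling(pool_multiplier * n_species))
  n_pairs <- floor(failure_fraction * n_pool / 2)
  with_seed(seed, {
    tree <- scale_tree_depth(
      ape::rphylo(n_pool, birth = birth_rate, death = 0), subst_rate
    )
    taxa <- sprintf("Poolgenus sp%03d", seq_len(n_pool))
    tree$tip.label <- taxa
    hap <- evolve_haplotypes(tree, seq_length)
    pair_idx <- matrix(integer(0), ncol = 2)
    if (n_pairs > 0) {
      chosen <- sample.int(n_pool, 2 * n_pairs)
      pair_idx <- matrix(chosen, ncol = 2, byrow = TRUE)
      for (k in seq_len(nrow(pair_idx))) {
        hap[pair_idx[k, 2], ] <- hap[pair_idx[k, 1], ]
      }
    }
    hap_string <- apply(hap, 1, paste, collapse = "")
    names(hap_string) <- taxa
    pool_aln <- aligned_seqs(taxa, hap_string)
    dm <- build_distance_matrix(pool_aln, min_overlap = 1)

    n_shared <- round(shared_fraction * n_species)
    shared <- if (n_shared > 0) sample.int(n_pool, n_shared) else integer(0)
    members <- lapply(profiles, function(pr) {
      own <- select_flora_species(
        dm$d, n_species - n_shared, pr,
        preselected = shared
      )
      sort(c(shared, own))
    })

    habits <- simulate_habits(n_pool)
    taxa_tbl <- dplyr::bind_rows(lapply(names(profiles), function(f) {
      idx <- members[[f]]
      tibble(
        taxon = taxa[idx], rank = "species", genus = "Poolgenus",
        family = "Poolfamiliaceae", habits = habits[idx],
        native = TRUE, flora = f
      )
    }))
    spec_tbl <- dplyr::bind_rows(lapply(names(profiles), function(f) {
      idx <- members[[f]]
      tibble(
        specimen_id = sprintf("%s_%s", f, gsub(" ", "_", taxa[idx])),
        taxon = taxa[idx], flora = f, sequenced = TRUE
      )
    }))
    checklist <- survey_checklist(taxa_tbl, spec_tbl)
    aln <- aligned_seqs(spec_tbl$specimen_id, hap_string[spec_tbl$taxon])
    truth <- list(
      pool_size = n_pool,
      injected_pairs = tibble(
        taxon_a = taxa[pair_idx[, 1]], taxon_b = taxa[pair_idx[, 2]]
      ),
      species = lapply(members, function(idx) taxa[idx]),
      failure_taxa = lapply(members, function(idx) {
        h <- hap_string[idx]
        sort(names(h)[h %in% h[duplicated(h)]])
      }),
      tree = ape::write.tree(tree)
    )
    structure(
      list(alignment = aln, checklist = checklist, truth = truth),
      class = "synthetic_floras"
    )
  })
}

#' @export
print.synthetic_floras <- function(x, ...) {
  cat(
    "<synthetic_floras> ", length(x$truth$species), " floras from a pool of ",
    x$truth$pool_size, " species\n",
    sep = ""
  )
  invisible(x)
}
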