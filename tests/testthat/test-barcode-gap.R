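test_that("shared haplotypes fail symmetrically", {
  seq <- strrep("ACGT", 50)
  other <- paste0(strrep("ACGT", 49), "TTTT")
  aln <- aligned_seqs(c("x1", "y1"), c(seq, seq))
  dm <- build_distance_matrix(aln, min_overlap = 1)
  chk <- checklist_from_map(c(x1 = "X", y1 = "Y"))
  rep <- min_interspecific_distances(dm, chk)
  expect_true(all(rep$taxa$failure))
  expect_equal(rep$summary$failure_rate, 1)

  # failure symmetry with a third, distinct taxon present
  aln3 <- aligned_seqs(c("x1", "y1", "z1"), c(seq, seq, other))
  dm3 <- build_distance_matrix(aln3, min_overlap = 1)
  chk3 <- checklist_from_map(c(x1 = "X", y1 = "Y", z1 = "Z"))
  rep3 <- min_interspecific_distances(dm3, chk3)
  tab <- tidy(rep3)
  expect_equal(tab$failure[tab$taxon %in% c("X", "Y")], c(TRUE, TRUE))
  expect_false(tab$failure[tab$taxon == "Z"])
  expect_equal(glance(rep3)$failure_rate, 2 / 3)
})

test_that("conspecific pairs are never considered", {
  base <- strrep("ACGT", 50)
  mut <- paste0("T", substr(base, 2, 200))
  aln <- aligned_seqs(
    c("a1", "a2", "a3", "b1"),
    c(base, base, base, mut) # 3 identical conspecific specimens
  )
  dm <- build_distance_matrix(aln, min_overlap = 1)
  chk <- checklist_from_map(c(a1 = "A", a2 = "A", a3 = "A", b1 = "B"))
  rep <- tidy(min_interspecific_distances(dm, chk))
  expect_equal(rep$min_interspecific[rep$taxon == "A"], 1 / 200)
  expect_equal(rep$n_specimens[rep$taxon == "A"], 3L)
  expect_false(any(rep$failure))
})

test_that("report equals an exhaustive double loop on random fixtures", {
  set.seed(29)
  for (rep_i in 1:5) {
    n <- 12
    taxon_of <- setNames(
      sample(sprintf("tax%02d", 1:8), n, replace = TRUE),
      sprintf("s%02d", 1:n)
    )
    # random distances with some exact zeros and some undefined pairs
    d <- matrix(0, n, n, dimnames = list(names(taxon_of), names(taxon_of)))
    vals <- sample(c(0, 0.002, 0.01, 0.05, NA), n * (n - 1) / 2, TRUE)
    d[upper.tri(d)] <- vals
    d <- d + t(d)
    diag(d) <- 0
    dm <- as_p_dist(d)
    chk <- checklist_from_map(taxon_of)
    got <- tidy(min_interspecific_distances(dm, chk))
    want <- min_inter_oracle(d, taxon_of)
    for (tx in got$taxon) {
      if (got$scorable[got$taxon == tx]) {
        expect_equal(got$min_interspecific[got$taxon == tx], unname(want$min[tx]))
        expect_equal(got$nearest_taxon[got$taxon == tx], unname(want$nearest[tx]))
      } else {
        expect_true(is.na(want$min[tx]))
      }
    }
  }
})

test_that("minimum is a lower bound on every defined interspecific distance", {
  set.seed(31)
  sim <- simulate_flora(
    simulation_config(n_species = 15, n_failure_pairs = 2, n_nonnative = 0),
    seed = 31
  )
  dm <- build_distance_matrix(sim$alignment)
  rep <- tidy(min_interspecific_distances(dm, sim$checklist))
  map <- setNames(sim$checklist$specimens$taxon, sim$checklist$specimens$specimen_id)
  taxon_of <- map[dm$specimen_ids]
  for (k in seq_len(nrow(rep))) {
    tx <- rep$taxon[k]
    rows <- which(taxon_of == tx)
    others <- which(taxon_of != tx)
    all_d <- dm$d[rows, others]
    expect_equal(rep$min_interspecific[k], min(all_d, na.rm = TRUE))
  }
})

test_that("unscorable taxa leave the failure-rate denominator", {
  d <- matrix(NA_real_, 3, 3, dimnames = list(c("a1", "b1", "c1"), c("a1", "b1", "c1")))
  d[1, 2] <- d[2, 1] <- 0.01
  diag(d) <- 0
  dm <- as_p_dist(d)
  chk <- checklist_from_map(c(a1 = "A", b1 = "B", c1 = "C"))
  rep <- min_interspecific_distances(dm, chk)
  expect_false(rep$taxa$scorable[rep$taxa$taxon == "C"])
  expect_equal(rep$summary$n_taxa_scored, 2L)
})

test_that("non-native taxa can be excluded from scoring", {
  seqs <- c(strrep("ACGT", 50), strrep("ACGT", 50), strrep("TCGT", 50))
  aln <- aligned_seqs(c("n1", "x1", "y1"), seqs)
  dm <- build_distance_matrix(aln, min_overlap = 1)
  chk <- checklist_from_map(
    c(n1 = "Nonnat", x1 = "X", y1 = "Y"),
    native = c(Nonnat = FALSE, X = TRUE, Y = TRUE)
  )
  with_nn <- min_interspecific_distances(dm, chk)
  without <- min_interspecific_distances(dm, chk, exclude_nonnative = TRUE)
  expect_equal(with_nn$summary$n_failures, 2L) # Nonnat shares X's haplotype
  expect_equal(without$summary$n_failures, 0L)
  expect_false("Nonnat" %in% without$taxa$taxon)
})

test_that("failure set is invariant to specimen order and case", {
  set.seed(37)
  sim <- simulate_flora(
    simulation_config(n_species = 12, n_failure_pairs = 2, n_nonnative = 0),
    seed = 37
  )
  aln <- sim$alignment
  fails <- function(a) {
    dm <- build_distance_matrix(a)
    rep <- tidy(min_interspecific_distances(dm, sim$checklist))
    sort(rep$taxon[rep$failure %in% TRUE])
  }
  perm <- sample(nrow(aln))
  aln_perm <- aligned_seqs(aln$specimen_id[perm], aln$sequence[perm])
  aln_lower <- aligned_seqs(aln$specimen_id, tolower(aln$sequence))
  expect_equal(fails(aln_perm), fails(aln))
  expect_equal(fails(aln_lower), fails(aln))
  expect_equal(fails(aln), sim$truth$failure_taxa)
})

test_that("removing a non-nearest taxon never changes a minimum", {
  set.seed(43)
  sim <- simulate_flora(
    simulation_config(n_species = 10, n_failure_pairs = 0, n_nonnative = 0),
    seed = 43
  )
  dm <- build_distance_matrix(sim$alignment)
  rep <- tidy(min_interspecific_distances(dm, sim$checklist))
  # focal taxon with the fewest nearest-neighbour ties; victim is any taxon
  # that is neither the focal one nor among its nearest neighbours
  focal_row <- which.min(lengths(rep$nearest_ties))
  focal <- rep$taxon[focal_row]
  victim <- setdiff(rep$taxon, c(focal, rep$nearest_ties[[focal_row]]))[1]
  expect_false(is.na(victim))
  keep <- sim$checklist$specimens$taxon != victim
  spec2 <- sim$checklist$specimens[keep, ]
  chk2 <- survey_checklist(
    sim$checklist$taxa[sim$checklist$taxa$taxon != victim, ], spec2
  )
  keep_seq <- sim$alignment$specimen_id %in% spec2$specimen_id
  aln2 <- aligned_seqs(
    sim$alignment$specimen_id[keep_seq], sim$alignment$sequence[keep_seq]
  )
  rep2 <- tidy(min_interspecific_distances(build_distance_matrix(aln2), chk2))
  expect_equal(
    rep2$min_interspecific[rep2$taxon == focal],
    rep$min_interspecific[rep$taxon == focal]
  )
})

test_that("histogram conserves counts and isolates the zero category", {
  seqA <- strrep("ACGT", 50)
  aln <- aligned_seqs(
    c("a1", "b1", "c1", "d1"),
    c(seqA, seqA, paste0("TT", substr(seqA, 3, 200)), strrep("GTCA", 50))
  )
  dm <- build_distance_matrix(aln, min_overlap = 1)
  chk <- checklist_from_map(c(a1 = "A", b1 = "B", c1 = "C", d1 = "D"))
  rep <- min_interspecific_distances(dm, chk)
  h <- distance_histogram(rep, bin_width = 0.005)
  expect_equal(sum(h$n), rep$summary$n_taxa_scored)
  expect_equal(h$n[h$category == "zero"], 2L)
  # re-binning oracle: direct tally per bin
  d <- rep$taxa$min_interspecific[rep$taxa$scorable & rep$taxa$min_interspecific > 0]
  for (k in seq_len(nrow(h))) {
    if (h$category[k] == "zero") next
    expect_equal(
      h$n[k],
      sum(d >= h$bin_low[k] & d < h$bin_high[k])
    )
  }

  # all-zero report collapses to a single zero bar
  aln0 <- aligned_seqs(c("x1", "y1"), c(seqA, seqA))
  rep0 <- min_interspecific_distances(
    build_distance_matrix(aln0, min_overlap = 1),
    checklist_from_map(c(x1 = "X", y1 = "Y"))
  )
  h0 <- distance_histogram(rep0)
  expect_equal(nrow(h0), 1)
  expect_equal(h0$category, "zero")
})

test_that("per-flora scoring equals scoring separately subset alignments", {
  set.seed(47)
  tf <- simulate_three_floras(n_species = 12, seq_length = 400, seed = 47)
  cmp <- compare_floras(tf$alignment, tf$checklist, min_overlap = 50)
  for (f in names(cmp$reports)) {
    spec <- tf$checklist$specimens
    spec_f <- spec[spec$flora == f, ]
    taxa_f <- tf$checklist$taxa[tf$checklist$taxa$flora == f, ]
    aln_f <- tf$alignment[tf$alignment$specimen_id %in% spec_f$specimen_id, ]
    aln_f <- aligned_seqs(aln_f$specimen_id, aln_f$sequence)
    solo <- min_interspecific_distances(
      build_distance_matrix(aln_f, min_overlap = 50),
      survey_checklist(taxa_f, spec_f)
    )
    expect_equal(cmp$reports[[f]]$taxa, solo$taxa)
    expect_equal(cmp$reports[[f]]$summary, solo$summary)
  }
})

test_that("permuting flora labels permutes outputs identically", {
  set.seed(53)
  tf <- simulate_three_floras(n_species = 10, seq_length = 400, seed = 53)
  cmp1 <- compare_floras(tf$alignment, tf$checklist, min_overlap = 50)
  relabel <- c(island = "mixed", continental = "island", mixed = "continental")
  chk2 <- survey_checklist(
    dplyr::mutate(tf$checklist$taxa, flora = unname(relabel[.data$flora])),
    dplyr::mutate(tf$checklist$specimens, flora = unname(relabel[.data$flora]))
  )
  cmp2 <- compare_floras(tf$alignment, chk2, min_overlap = 50)
  for (f in names(cmp1$reports)) {
    expect_equal(
      cmp2$reports[[unname(relabel[f])]]$summary[-1],
      cmp1$reports[[f]]$summary[-1]
    )
  }
})

test_that("floras with fewer than two taxa are skipped with a warning", {
  seqs <- c(strrep("ACGT", 30), strrep("GGGT", 30), strrep("TTAA", 30))
  aln <- aligned_seqs(c("a1", "b1", "c1"), seqs)
  chk <- survey_checklist(
    tibble::tibble(
      taxon = c("A", "B", "C"), rank = "species", genus = "G", family = "F",
      habits = "terrestrial", native = TRUE,
      flora = c("big", "big", "small")
    ),
    tibble::tibble(
      specimen_id = c("a1", "b1", "c1"), taxon = c("A", "B", "C"),
      flora = c("big", "big", "small")
    )
  )
  expect_warning(cmp <- compare_floras(aln, chk, min_overlap = 1), "small")
  expect_equal(cmp$summary$flora, "big")
})
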