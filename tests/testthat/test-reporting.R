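test_that("checklist summaries follow survey-table conventions", {
  chk <- survey_checklist(
    tibble::tibble(
      taxon = c("Aa bb", "Cc dd", "Ee ff"),
      rank = "species", genus = c("Aa", "Cc", "Ee"),
      family = c("F1aceae", "F1aceae", "Lycopodiaceae"),
      habits = c("epiphytic|epipetric", "terrestrial", "terrestrial"),
      native = TRUE, flora = "f"
    ),
    tibble::tibble(
      specimen_id = c("v1", "v2"), taxon = c("Aa bb", "Cc dd")
    )
  )
  s <- summarize_checklist(chk)
  expect_equal(s$totals$n_taxa, 3)
  expect_equal(s$totals$n_genera, 3)
  expect_equal(s$totals$n_families, 2)
  # the multi-habit taxon is counted once in each habit row
  expect_equal(sum(s$habits$n), 4)
  expect_equal(s$habits$n[s$habits$habit == "epiphytic"], 1L)
  expect_equal(s$habits$n[s$habits$habit == "epipetric"], 1L)
  # clade split inferred from family names
  expect_equal(s$clades$n_species[s$clades$clade == "lycophyte"], 1L)
  # barcode coverage: 2 of 3 taxa have a sequenced specimen
  expect_equal(s$coverage$pct, round(100 * 2 / 3, 1))
  # habitless taxa are an error when tallying habits
  chk_bad <- chk
  chk_bad$taxa$habits[[1]] <- character(0)
  expect_error(summarize_checklist(chk_bad), "without growth habits")
})

test_that("richness per area follows the two-decimal convention", {
  expect_equal(richness_per_area(175, 158), 1.11)
  expect_equal(richness_per_area(197, 1533), 0.13)
  expect_equal(richness_per_area(0, 100), 0)
  expect_equal(richness_per_area(c(281, 147), c(7800, 3800)), c(0.04, 0.04))
  expect_error(richness_per_area(10, 0), "positive")
  expect_error(richness_per_area(-1, 10), "non-negative")
})

test_that("the reference reserve table recomputes its printed ratios", {
  tab <- costa_rica_reserves()
  expect_equal(nrow(tab), 6)
  expect_equal(
    tab$richness_per_area,
    richness_per_area(tab$n_species, tab$area_ha)
  )
})

test_that("rounding of percentages is half-up at one decimal", {
  expect_equal(round_half_up(52.849, 1), 52.8)
  expect_equal(round_half_up(52.85, 1), 52.9)
  expect_equal(round_half_up(0.125, 2), 0.13)
})

test_that("the pipeline runs a simulated survey end to end, reproducibly", {
  sim <- simulate_flora(
    simulation_config(n_species = 15, n_failure_pairs = 2, n_nonnative = 1),
    seed = 173
  )
  dir <- withr::local_tempdir()
  paths <- write_flora(sim, file.path(dir, "in"))
  expect_no_warning(
    res <- run_pipeline(
      paths[["alignment"]], paths[["checklist"]], paths[["incidence"]],
      out_dir = file.path(dir, "out1"), bootstrap = 20, seed = 5,
      exclude_nonnative = FALSE
    )
  )
  expect_s3_class(res, "pipeline_result")
  files <- list.files(file.path(dir, "out1"))
  expect_true(all(c(
    "alignment_stats.tsv", "distances_long.tsv", "barcode_gap.tsv",
    "barcode_gap_summary.json", "gap_histogram.tsv",
    "accumulation_curve.tsv", "richness_summary.json", "nj_tree.nwk",
    "monophyly.tsv", "checklist_summary.json", "manifest.json"
  ) %in% files))

  # regeneration with identical inputs and seed is byte-identical
  run_pipeline(
    paths[["alignment"]], paths[["checklist"]], paths[["incidence"]],
    out_dir = file.path(dir, "out2"), bootstrap = 20, seed = 5,
    exclude_nonnative = FALSE
  )
  for (f in files) {
    expect_identical(
      readLines(file.path(dir, "out1", f)),
      readLines(file.path(dir, "out2", f)),
      info = f
    )
  }
})

test_that("excluding the non-native taxon shrinks the gap report by one", {
  sim <- simulate_flora(
    simulation_config(n_species = 15, n_failure_pairs = 0, n_nonnative = 1),
    seed = 179
  )
  dm <- build_distance_matrix(sim$alignment)
  all_in <- min_interspecific_distances(dm, sim$checklist)
  natives <- min_interspecific_distances(
    dm, sim$checklist,
    exclude_nonnative = TRUE
  )
  expect_equal(nrow(all_in$taxa) - nrow(natives$taxa), 1)
  expect_false(sim$truth$nonnative_taxa %in% natives$taxa$taxon)
})

test_that("manifest checksums change exactly when an input byte changes", {
  sim <- simulate_flora(
    simulation_config(n_species = 8, n_failure_pairs = 0, n_nonnative = 0),
    seed = 181
  )
  dir <- withr::local_tempdir()
  paths <- write_flora(sim, file.path(dir, "in"))
  res1 <- run_pipeline(
    paths[["alignment"]], paths[["checklist"]], paths[["incidence"]],
    out_dir = file.path(dir, "o1"), bootstrap = 5, seed = 1
  )
  res2 <- run_pipeline(
    paths[["alignment"]], paths[["checklist"]], paths[["incidence"]],
    out_dir = file.path(dir, "o2"), bootstrap = 5, seed = 1
  )
  expect_identical(res1$manifest$inputs, res2$manifest$inputs)
  # flip one byte in the incidence file
  txt <- readLines(paths[["incidence"]])
  txt[2] <- sub("0", "1", txt[2])
  writeLines(txt, paths[["incidence"]])
  res3 <- run_pipeline(
    paths[["alignment"]], paths[["checklist"]], paths[["incidence"]],
    out_dir = file.path(dir, "o3"), bootstrap = 5, seed = 1
  )
  expect_identical(
    res3$manifest$inputs$alignment, res1$manifest$inputs$alignment
  )
  expect_false(identical(
    res3$manifest$inputs$incidence, res1$manifest$inputs$incidence
  ))
})

test_that("a failing stage names itself and removes partial outputs", {
  sim <- simulate_flora(
    simulation_config(n_species = 8, n_failure_pairs = 0, n_nonnative = 0),
    seed = 191
  )
  dir <- withr::local_tempdir()
  paths <- write_flora(sim, file.path(dir, "in"))
  # corrupt the incidence file so a mid-pipeline stage fails
  writeLines(c("taxon,day1", "spX,2"), paths[["incidence"]])
  out <- file.path(dir, "out")
  expect_error(
    run_pipeline(
      paths[["alignment"]], paths[["checklist"]], paths[["incidence"]],
      out_dir = out, bootstrap = 5, seed = 1
    ),
    "stage 'read_incidence'.*non-binary"
  )
  expect_equal(length(list.files(out)), 0)
})

test_that("tidiers expose summary tables as tibbles", {
  chk <- synthetic_survey_checklist()
  s <- summarize_checklist(chk)
  td <- tidy(s)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("habit", "fern") %in% c(td$group, td$level)))
  g <- glance(s)
  expect_equal(g$n_taxa, 178)
})
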