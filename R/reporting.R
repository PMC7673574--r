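#' @include core_io.R barcode_gap.R richness.R phylo_screen.R synthetic_data.R
NULL

#' Checklist summary statistics
#'
#' Survey-style tallies of a checklist: totals (terminal taxa, species,
#' genera, families, specimens), per-habit counts, the fern/lycophyte split,
#' and barcode coverage. Conventions follow published floristic survey
#' tables: habit counts are at the terminal-taxon level and a multi-habit
#' taxon is counted once in each habit row (so habit percentages can sum past
#' 100%); the clade split counts *species* (varieties collapsed); every
#' percentage uses the total number of terminal taxa as denominator and is
#' rounded half-up to one decimal.
#'
#' @param checklist A [survey_checklist()]. Every taxon must carry at least
#'   one growth habit (an error lists offenders otherwise).
#' @return A list of class `survey_summary` with tibbles `totals`, `habits`,
#'   `clades` and `coverage`.
#' @export
summarize_checklist <- function(checklist) {
  stopifnot(inherits(checklist, "survey_checklist"))
  taxa <- checklist$taxa
  empty <- lengths(taxa$habits) == 0
  if (any(empty)) {
    abort(paste0(
      "taxa without growth habits: ",
      paste(taxa$taxon[empty], collapse = ", ")
    ))
  }
  n_taxa <- nrow(taxa)
  totals <- tibble(
    n_taxa = n_taxa,
    n_species = length(unique(taxa$species)),
    n_genera = length(unique(taxa$genus)),
    n_families = length(unique(taxa$family)),
    n_specimens = nrow(checklist$specimens)
  )
  habit_long <- tibble(
    taxon = rep(taxa$taxon, lengths(taxa$habits)),
    habit = unlist(taxa$habits)
  )
  habits <- habit_long |>
    dplyr::count(.data$habit, name = "n") |>
    dplyr::right_join(tibble(habit = HABIT_TOKENS), by = "habit") |>
    dplyr::mutate(
      n = as.integer(ifelse(is.na(.data$n), 0L, .data$n)),
      pct = round_half_up(100 * .data$n / n_taxa, 1)
    ) |>
    dplyr::arrange(.data$habit)
  clades <- taxa |>
    dplyr::distinct(.data$species, .data$clade) |>
    dplyr::count(.data$clade, name = "n_species") |>
    dplyr::mutate(pct = round_half_up(100 * .data$n_species / n_taxa, 1)) |>
    dplyr::arrange(.data$clade)
  seq_taxa <- unique(
    checklist$specimens$taxon[checklist$specimens$sequenced %in% TRUE]
  )
  n_cov <- sum(taxa$taxon %in% seq_taxa)
  coverage <- tibble(
    n_taxa_with_barcode = n_cov,
    pct = round_half_up(100 * n_cov / n_taxa, 1)
  )
  structure(
    list(
      totals = totals, habits = habits, clades = clades, coverage = coverage
    ),
    class = "survey_summary"
  )
}

#' @export
print.survey_summary <- function(x, ...) {
  t <- x$totals
  cat(
    "<survey_summary> ", t$n_taxa, " taxa (", t$n_species, " spp., ",
    t$n_genera, " genera, ", t$n_families, " families), ",
    t$n_specimens, " specimens; barcode coverage ",
    x$coverage$pct, "%\n",
    sep = ""
  )
  print(x$habits)
  invisible(x)
}

#' @export
tidy.survey_summary <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::transmute(x$habits,
      group = "habit", level = .data$habit,
      n = .data$n, pct = .data$pct
    ),
    dplyr::transmute(x$clades,
      group = "clade", level = .data$clade,
      n = .data$n_species, pct = .data$pct
    )
  )
}

#' @export
glance.survey_summary <- function(x, ...) {
  dplyr::bind_cols(
    x$totals,
    tibble(
      barcode_coverage_n = x$coverage$n_taxa_with_barcode,
      barcode_coverage_pct = x$coverage$pct
    )
  )
}

#' Species richness per unit area
#'
#' Ratio of species count to reserve area, rounded half-up to two decimals —
#' the convention of richness-per-area comparisons across protected areas.
#'
#' @param n_species Species counts (numeric vector).
#' @param area_ha Areas in hectares (positive).
#' @return Numeric vector of species per hectare, two decimals.
#' @export
#' @examples
#' richness_per_area(175, 158) # 1.11
#' richness_per_area(197, 1533) # 0.13
richness_per_area <- function(n_species, area_ha) {
  stopifnot(is.numeric(n_species), is.numeric(area_ha))
  if (any(area_ha <= 0)) abort("area_ha must be positive.")
  if (any(n_species < 0)) abort("n_species must be non-negative.")
  round_half_up(n_species / area_ha, 2)
}

#' Published pteridophyte richness of Costa Rican protected areas
#'
#' Literature-compiled species counts and reserve areas for six protected
#' areas in Costa Rica that have been floristically surveyed for ferns and
#' lycophytes; the `richness_per_area` column is recomputed by
#' [richness_per_area()]. The 175-species cloud-forest reserve entry excludes
#' one non-native species.
#'
#' @return Tibble with `site`, `area_ha`, `n_species` and
#'   `richness_per_area`.
#' @export
costa_rica_reserves <- function() {
  out <- tibble(
    site = c(
      "Alberto Manuel Brenes Biological Reserve",
      "La Selva Biological Station",
      "Monteverde Cloud Forest Reserve",
      "Nectandra Cloud Forest Reserve",
      "San Luis Biological Reserve",
      "Savegre upper watershed (Los Santos Forest Reserve)"
    ),
    area_ha = c(7800, 1533, 3800, 158, 251, 10000),
    n_species = c(281, 197, 147, 175, 39, 123)
  )
  out$richness_per_area <- richness_per_area(out$n_species, out$area_ha)
  out
}

#' Synthetic checklist matching published cloud-forest survey tallies
#'
#' Deterministically constructs a synthetic [survey_checklist()] whose
#' marginal totals reproduce those reported for a Costa Rican cloud-forest
#' pteridophyte survey: 178 terminal taxa comprising 176 species (two species
#' each split into two varieties), 69 genera, 22 families, 169 fern and 7
#' lycophyte species, habit tallies of 94 epiphytic / 74 terrestrial / 19
#' epipetric / 5 climbing (14 taxa carry two habits), 320 specimens, 173 taxa
#' with a barcode sequence, and a single non-native species. Taxon names are
#' synthetic placeholders; only the marginal counts are meaningful.
#'
#' @return A [survey_checklist()].
#' @export
synthetic_survey_checklist <- function() {
  n_fern_species <- 169
  n_lyco_species <- 7
  n_species <- n_fern_species + n_lyco_species

  # genus/family scaffolding: 66 fern genera in 20 families + 3 lycophyte
  # genera in 2 families = 69 genera, 22 families
  fern_genera <- sprintf("Ferngenus%02d", seq_len(66))
  fern_fams <- sprintf("Fernfam%02daceae", seq_len(20))
  lyco_genera <- c("Lycogenus01", "Lycogenus02", "Lycogenus03")
  lyco_fams <- c("Lycopodiaceae", "Selaginellaceae")

  fern <- tibble(
    species = sprintf("%s species%03d",
      fern_genera[(seq_len(n_fern_species) - 1) %% 66 + 1],
      seq_len(n_fern_species)
    ),
    genus = fern_genera[(seq_len(n_fern_species) - 1) %% 66 + 1],
    family = fern_fams[((seq_len(n_fern_species) - 1) %% 66) %% 20 + 1],
    clade = "fern"
  )
  lyco <- tibble(
    species = sprintf("%s species%03d",
      lyco_genera[(seq_len(n_lyco_species) - 1) %% 3 + 1],
      n_fern_species + seq_len(n_lyco_species)
    ),
    genus = lyco_genera[(seq_len(n_lyco_species) - 1) %% 3 + 1],
    family = lyco_fams[((seq_len(n_lyco_species) - 1) %% 3) %% 2 + 1],
    clade = "lycophyte"
  )
  sp <- dplyr::bind_rows(fern, lyco)

  # two fern species carry two varieties each: 176 species -> 178 terminals
  split_sp <- sp$species[1:2]
  terminals <- dplyr::bind_rows(
    dplyr::mutate(sp[!sp$species %in% split_sp, ],
      taxon = .data$species, rank = "species"
    ),
    dplyr::bind_rows(lapply(split_sp, function(s) {
      row <- sp[sp$species == s, ]
      dplyr::bind_rows(
        dplyr::mutate(row, taxon = paste(s, "var. alpha"), rank = "infraspecies"),
        dplyr::mutate(row, taxon = paste(s, "var. beta"), rank = "infraspecies")
      )
    }))
  )
  terminals <- terminals[order(terminals$taxon), ]
  n_taxa <- nrow(terminals) # 178

  # habit assignment reproducing the published marginals:
  # epiphytic 94, terrestrial 74, epipetric 19, climbing 5 (sum 192; the 14
  # excess assignments are taxa with two habits)
  habits <- vector("list", n_taxa)
  for (i in seq_len(n_taxa)) {
    h <- character(0)
    if (i <= 94) h <- c(h, "epiphytic")
    if (i >= 95 && i <= 168) h <- c(h, "terrestrial")
    if (i >= 169 || i <= 9) h <- c(h, "epipetric")
    if (i >= 10 && i <= 14) h <- c(h, "climbing")
    habits[[i]] <- h
  }
  terminals$habits <- habits
  terminals$native <- TRUE
  terminals$native[100] <- FALSE # one introduced terrestrial species
  terminals$flora <- "cloudforest"

  # 320 specimens over the 178 taxa; the first 173 taxa carry a sequenced
  # voucher (97.2% barcode coverage), the last 5 could not be sequenced
  counts <- rep(1L, n_taxa)
  extra <- 320 - n_taxa
  counts[seq_len(extra)] <- counts[seq_len(extra)] + 1L
  specimens <- tibble(
    specimen_id = sprintf(
      "V%04d",
      seq_len(sum(counts))
    ),
    taxon = rep(terminals$taxon, counts),
    flora = "cloudforest",
    sequenced = rep(seq_len(n_taxa) <= 173, counts)
  )
  survey_checklist(terminals, specimens)
}

# Stage runner: annotates errors with the failing stage name.
run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  })
}

#' Run the full survey analysis pipeline
#'
#' End-to-end orchestration: read and validate the three inputs, compute
#' alignment statistics and the p-distance matrix, score the barcode gap
#' (with the distance histogram and, when several floras are labeled, the
#' per-flora comparison), build the species accumulation curve with Chao2
#' asymptote, construct and midpoint-root the neighbor-joining tree, screen
#' per-taxon monophyly, and summarize the checklist. All reports are written
#' as plain-text TSV/JSON/Newick files plus a manifest recording the package
#' version, seed, parameters and input checksums; outputs are byte-identical
#' across runs with identical inputs and seed. On any stage error the files
#' written by this run are removed.
#'
#' Specimens involved in undefined distance pairs (overlap below
#' `min_overlap`, e.g. opposite-half partial sequences) are excluded from the
#' tree stage only, greedily and recorded in the manifest; they still
#' contribute to distance and barcode-gap reports where defined.
#'
#' @param alignment Path to an aligned FASTA file.
#' @param checklist Path to a checklist CSV.
#' @param incidence Path to an incidence CSV.
#' @param out_dir Output directory (created if needed).
#' @param min_overlap Minimum compared sites for a defined distance pair.
#' @param exclude_nonnative Drop non-native taxa from the barcode-gap and
#'   richness-comparison reports (default `TRUE`, the usual survey
#'   convention).
#' @param bootstrap Bootstrap replicates for the accumulation curve.
#' @param level Confidence level for the curve.
#' @param endpoint Extrapolation endpoint (default `2 * T`).
#' @param bin_width Histogram bin width.
#' @param seed Integer seed controlling the bootstrap.
#' @return Invisibly, a list of class `pipeline_result` with all in-memory
#'   results and the manifest.
#' @export
run_pipeline <- function(alignment, checklist, incidence, out_dir,
                         min_overlap = 100, exclude_nonnative = TRUE,
                         bootstrap = 1000, level = 0.95, endpoint = NULL,
                         bin_width = 0.005, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  note <- function(path) {
    written <<- c(written, path)
    path
  }
  on_failure <- function(e) {
    unlink(written)
    stop(e)
  }
  tryCatch(
    {
      aln <- run_stage("read_alignment", read_aligned_fasta(alignment))
      chk <- run_stage("read_checklist", read_checklist(checklist))
      inc <- run_stage("read_incidence", read_incidence(incidence))

      stats <- run_stage("alignment_stats", alignment_stats(aln))
      dm <- run_stage(
        "distances",
        build_distance_matrix(aln, min_overlap = min_overlap)
      )
      gap <- run_stage(
        "barcode_gap",
        min_interspecific_distances(dm, chk,
          exclude_nonnative = exclude_nonnative
        )
      )
      hist <- run_stage(
        "histogram",
        distance_histogram(gap, bin_width = bin_width)
      )
      comparison <- NULL
      if (length(unique(chk$taxa$flora)) > 1) {
        comparison <- run_stage(
          "compare_floras",
          compare_floras(aln, chk,
            min_overlap = min_overlap,
            exclude_nonnative = exclude_nonnative
          )
        )
      }
      curve <- run_stage(
        "richness",
        accumulation_curve(inc,
          endpoint = endpoint, B = bootstrap,
          level = level, seed = seed
        )
      )
      tree_ids <- run_stage("tree", drop_undefined_specimens(dm))
      tree <- run_stage(
        "tree",
        midpoint_root(neighbor_joining(subset_p_dist(dm, tree_ids)))
      )
      mono_chk <- survey_checklist(
        chk$taxa,
        chk$specimens[chk$specimens$specimen_id %in% tree_ids, ]
      )
      mono <- run_stage("monophyly", assess_monophyly(tree, mono_chk))
      summary <- run_stage("summary", summarize_checklist(chk))

      run_stage("write", {
        readr::write_tsv(stats, note(file.path(out_dir, "alignment_stats.tsv")))
        write_distances(dm, note(file.path(out_dir, "distances_long.tsv")))
        write_gap_report(
          gap, note(file.path(out_dir, "barcode_gap.tsv")),
          note(file.path(out_dir, "barcode_gap_summary.json"))
        )
        readr::write_tsv(hist, note(file.path(out_dir, "gap_histogram.tsv")))
        if (!is.null(comparison)) {
          readr::write_tsv(
            comparison$summary,
            note(file.path(out_dir, "flora_comparison.tsv"))
          )
        }
        write_accumulation(
          curve, note(file.path(out_dir, "accumulation_curve.tsv")),
          note(file.path(out_dir, "richness_summary.json"))
        )
        write_newick(tree, note(file.path(out_dir, "nj_tree.nwk")))
        readr::write_tsv(mono, note(file.path(out_dir, "monophyly.tsv")))
        jsonlite::write_json(
          list(
            totals = as.list(summary$totals),
            habits = summary$habits,
            clades = summary$clades,
            coverage = as.list(summary$coverage)
          ),
          note(file.path(out_dir, "checklist_summary.json")),
          auto_unbox = TRUE, digits = NA, pretty = TRUE, dataframe = "rows"
        )
      })

      manifest <- list(
        package = "pteridosurvey",
        version = as.character(utils::packageVersion("pteridosurvey")),
        seed = seed,
        parameters = list(
          min_overlap = min_overlap, exclude_nonnative = exclude_nonnative,
          bootstrap = bootstrap, level = level,
          endpoint = endpoint %||% (2L * ncol(inc)), bin_width = bin_width
        ),
        inputs = list(
          alignment = unname(tools::md5sum(alignment)),
          checklist = unname(tools::md5sum(checklist)),
          incidence = unname(tools::md5sum(incidence))
        ),
        tree_specimens_dropped = setdiff(dm$specimen_ids, tree_ids)
      )
      jsonlite::write_json(
        manifest, note(file.path(out_dir, "manifest.json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE
      )

      invisible(structure(
        list(
          alignment_stats = stats, distances = dm, barcode_gap = gap,
          histogram = hist, flora_comparison = comparison,
          accumulation = curve, tree = tree, monophyly = mono,
          checklist_summary = summary, manifest = manifest
        ),
        class = "pipeline_result"
      ))
    },
    error = on_failure
  )
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  print(x$barcode_gap)
  print(x$accumulation)
  print(x$checklist_summary)
  invisible(x)
}
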