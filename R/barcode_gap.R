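#' @include distances.R
NULL

#' Per-taxon minimum interspecific distance and barcode failures
#'
#' For each terminal taxon, finds the smallest defined p-distance between any
#' of its specimens and any specimen of a *different* taxon (conspecific
#' pairs are never considered). A taxon fails as a barcode when that minimum
#' is exactly zero, i.e. it shares an identical haplotype with another taxon;
#' failure is symmetric by construction. Taxa whose every interspecific pair
#' is undefined (insufficient overlap) are flagged unscorable and excluded
#' from the failure-rate denominator.
#'
#' @param dm A `p_dist` object from [build_distance_matrix()]. Every specimen
#'   in it must be mapped to a taxon by `checklist`.
#' @param checklist A [survey_checklist()] whose specimen table covers the
#'   distance matrix.
#' @param exclude_nonnative Drop taxa flagged `native = FALSE` (and their
#'   specimens) before scoring. Default `FALSE`.
#' @return A list of class `barcode_gap`: `taxa` (tibble with `taxon`,
#'   `n_specimens`, `min_interspecific`, `nearest_taxon`, `nearest_ties`
#'   list-column, `failure`, `scorable`), and `summary` (one-row tibble with
#'   `n_taxa_scored`, `n_failures`, `failure_rate`).
#' @export
min_interspecific_distances <- function(dm, checklist,
                                        exclude_nonnative = FALSE) {
  stopifnot(inherits(dm, "p_dist"), inherits(checklist, "survey_checklist"))
  map <- specimen_taxon_map(checklist)
  unmapped <- setdiff(dm$specimen_ids, names(map))
  if (length(unmapped) > 0) {
    abort(paste0(
      "specimen(s) not mapped to a taxon: ",
      paste(unmapped, collapse = ", ")
    ))
  }
  ids <- dm$specimen_ids
  taxon_of <- map[ids]
  if (exclude_nonnative) {
    nn <- checklist$taxa$taxon[!checklist$taxa$native]
    keep <- !(taxon_of %in% nn)
    ids <- ids[keep]
    taxon_of <- taxon_of[keep]
  }
  taxa <- sort(unique(taxon_of))
  if (length(taxa) < 2) abort("need at least two taxa to score distances.")
  d <- dm$d[ids, ids, drop = FALSE]

  # taxon x taxon minimum distance: first reduce rows, then columns
  rows_by_taxon <- split(seq_along(ids), taxon_of)[taxa]
  min_rows <- do.call(rbind, lapply(rows_by_taxon, function(r) {
    m <- d[r, , drop = FALSE]
    suppressWarnings(apply(m, 2, min, na.rm = TRUE))
  }))
  tt <- do.call(cbind, lapply(rows_by_taxon, function(r) {
    m <- min_rows[, r, drop = FALSE]
    suppressWarnings(apply(m, 1, min, na.rm = TRUE))
  }))
  tt[!is.finite(tt)] <- NA_real_
  diag(tt) <- NA_real_ # conspecific pairs never considered

  per_taxon <- lapply(seq_along(taxa), function(i) {
    row <- tt[i, ]
    if (all(is.na(row))) {
      return(tibble(
        taxon = taxa[i],
        min_interspecific = NA_real_,
        nearest_taxon = NA_character_,
        nearest_ties = list(character()),
        failure = NA,
        scorable = FALSE
      ))
    }
    dmin <- min(row, na.rm = TRUE)
    ties <- sort(names(row)[!is.na(row) & row == dmin])
    tibble(
      taxon = taxa[i],
      min_interspecific = dmin,
      nearest_taxon = ties[1], # lexicographic tie-break; full list kept
      nearest_ties = list(ties),
      failure = dmin == 0,
      scorable = TRUE
    )
  })
  report <- dplyr::bind_rows(per_taxon)
  nspec <- vapply(rows_by_taxon, length, integer(1))
  report <- dplyr::mutate(report,
    n_specimens = as.integer(nspec[.data$taxon]), .after = "taxon"
  )
  n_scored <- sum(report$scorable)
  n_fail <- sum(report$failure, na.rm = TRUE)
  structure(
    list(
      taxa = report,
      # failure_rate uses the scored taxa as denominator; the rate over all
      # taxa (unscorable ones included) is reported alongside because survey
      # papers are not always explicit about which they print
      summary = tibble(
        n_taxa_total = nrow(report),
        n_taxa_scored = n_scored,
        n_failures = n_fail,
        failure_rate = if (n_scored > 0) n_fail / n_scored else NA_real_,
        failure_rate_total = n_fail / nrow(report)
      ),
      min_overlap = dm$min_overlap
    ),
    class = "barcode_gap"
  )
}

#' @export
print.barcode_gap <- function(x, ...) {
  s <- x$summary
  cat(
    "<barcode_gap> ", nrow(x$taxa), " taxa (", s$n_taxa_scored, " scored), ",
    s$n_failures, " failures (",
    round_half_up(100 * s$failure_rate, 1), "%)\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.barcode_gap <- function(x, ...) x$taxa

#' @export
glance.barcode_gap <- function(x, ...) x$summary

#' Histogram of minimum interspecific distances
#'
#' Bins scored taxa into left-closed intervals of width `bin_width` over
#' (0, 1]; taxa with a minimum interspecific distance of exactly zero (the
#' barcode failures) form their own `"zero"` category, plotted as the red bar
#' in the conventional figure.
#'
#' @param report A `barcode_gap` object.
#' @param bin_width Bin width on the p-distance scale (default 0.005).
#' @return Tibble with `category` (`"zero"` or `"positive"`), `bin_low`,
#'   `bin_high` (left-closed, right-open) and `n`. Counts sum to
#'   `n_taxa_scored`.
#' @export
distance_histogram <- function(report, bin_width = 0.005) {
  stopifnot(inherits(report, "barcode_gap"), bin_width > 0)
  d <- report$taxa$min_interspecific[report$taxa$scorable]
  zero_n <- sum(d == 0)
  pos <- d[d > 0]
  out <- tibble(
    category = "zero", bin_low = 0, bin_high = 0, n = as.integer(zero_n)
  )
  if (length(pos) > 0) {
    idx <- floor(pos / bin_width)
    # a distance exactly at 1 falls in the final bin, keeping bins in [0,1]
    idx[pos == 1] <- ceiling(1 / bin_width) - 1
    tab <- table(idx)
    out <- dplyr::bind_rows(out, tibble(
      category = "positive",
      bin_low = as.numeric(names(tab)) * bin_width,
      bin_high = (as.numeric(names(tab)) + 1) * bin_width,
      n = as.integer(tab)
    ))
  }
  out
}

#' Per-flora barcode-gap comparison on a combined alignment
#'
#' Distances are computed once on the combined alignment (so that all floras
#' are scored on identical alignment columns); each flora's minimum
#' interspecific distances are then computed only among that flora's taxa.
#' Floras with fewer than two taxa are skipped with a warning.
#'
#' @param aln Combined [aligned_seqs()] across floras.
#' @param checklist A [survey_checklist()] in which every specimen carries
#'   exactly one flora label.
#' @param min_overlap Passed to [build_distance_matrix()].
#' @param exclude_nonnative Passed to [min_interspecific_distances()].
#' @return A list of class `flora_comparison`: `summary` (tibble with
#'   `flora`, `n_taxa_scored`, `n_failures`, `failure_rate`) and `reports`
#'   (named list of `barcode_gap` objects).
#' @export
compare_floras <- function(aln, checklist, min_overlap = 100,
                           exclude_nonnative = FALSE) {
  stopifnot(inherits(aln, "aligned_seqs"), inherits(checklist, "survey_checklist"))
  sp <- checklist$specimens
  if (any(is.na(sp$flora))) abort("every specimen needs a flora label.")
  dm <- build_distance_matrix(aln, min_overlap = min_overlap)
  unmapped <- setdiff(dm$specimen_ids, sp$specimen_id)
  if (length(unmapped) > 0) {
    abort(paste0(
      "specimen(s) not in checklist: ", paste(unmapped, collapse = ", ")
    ))
  }
  floras <- sort(unique(checklist$taxa$flora))
  reports <- list()
  for (f in floras) {
    f_taxa <- checklist$taxa[checklist$taxa$flora == f, ]
    f_spec <- sp[sp$flora == f & sp$specimen_id %in% dm$specimen_ids, ]
    if (length(unique(f_spec$taxon)) < 2) {
      warn(paste0("flora '", f, "' has fewer than two taxa; skipped."))
      next
    }
    sub_dm <- subset_p_dist(dm, f_spec$specimen_id)
    sub_chk <- survey_checklist(f_taxa, f_spec)
    reports[[f]] <- min_interspecific_distances(
      sub_dm, sub_chk,
      exclude_nonnative = exclude_nonnative
    )
  }
  summary <- dplyr::bind_rows(
    lapply(names(reports), function(f) {
      dplyr::mutate(reports[[f]]$summary, flora = f, .before = 1)
    })
  )
  structure(
    list(summary = summary, reports = reports),
    class = "flora_comparison"
  )
}

#' @export
print.flora_comparison <- function(x, ...) {
  cat("<flora_comparison> ", nrow(x$summary), " flora(s)\n", sep = "")
  print(x$summary)
  invisible(x)
}

#' @export
tidy.flora_comparison <- function(x, ...) {
  dplyr::bind_rows(lapply(names(x$reports), function(f) {
    dplyr::mutate(tidy(x$reports[[f]]), flora = f, .before = 1)
  }))
}

#' @export
glance.flora_comparison <- function(x, ...) x$summary

#' Write a barcode-gap report to TSV / JSON
#'
#' @param report A `barcode_gap` object.
#' @param path Output TSV path for the per-taxon table.
#' @param summary_path Optional JSON path for the flora-level summary.
#' @return `path`, invisibly.
#' @export
write_gap_report <- function(report, path, summary_path = NULL) {
  stopifnot(inherits(report, "barcode_gap"))
  tab <- report$taxa
  tab$nearest_ties <- vapply(tab$nearest_ties, paste, character(1),
    collapse = "|"
  )
  readr::write_tsv(tab, path)
  if (!is.null(summary_path)) {
    jsonlite::write_json(
      as.list(report$summary), summary_path,
      auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  invisible(path)
}
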