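#' @include utils.R
NULL

# Alphabet of an aligned nucleotide matrix: the four unambiguous bases,
# IUPAC ambiguity codes, alignment gaps and missing-data marks.
UNAMBIGUOUS_BASES <- c("A", "C", "G", "T")
IUPAC_AMBIGUITY <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")
MISSING_CODES <- c("-", "N", "?")
ALLOWED_CHARS <- c(UNAMBIGUOUS_BASES, IUPAC_AMBIGUITY, MISSING_CODES)

#' Growth-habit vocabulary
#'
#' Allowed growth-habit tokens for checklist records. A taxon may carry
#' several (e.g. a fern growing both on rock and as an epiphyte).
#' @export
HABIT_TOKENS <- c("climbing", "epipetric", "epiphytic", "terrestrial")

# Families treated as lycophytes when a checklist lacks an explicit clade
# column; everything else is counted as a fern.
LYCOPHYTE_FAMILIES <- c("Lycopodiaceae", "Selaginellaceae", "Isoetaceae")

#' Construct an aligned sequence set
#'
#' An aligned sequence set is a tibble with one row per specimen and columns
#' `specimen_id` and `sequence` (equal-length uppercase strings over
#' A/C/G/T, IUPAC ambiguity codes, `-`, `N` and `?`), carrying the alignment
#' length as an attribute. It is the in-memory form of an aligned FASTA file.
#'
#' @param specimen_ids Character vector of unique, non-empty specimen labels.
#' @param sequences Character vector of aligned sequences, one per specimen.
#' @return A tibble of class `aligned_seqs`.
#' @export
#' @examples
#' aln <- aligned_seqs(c("sp1", "sp2"), c("ACGT-N?A", "ACGTACGA"))
#' aln_length(aln)
aligned_seqs <- function(specimen_ids, sequences) {
  specimen_ids <- as.character(specimen_ids)
  sequences <- toupper(as.character(sequences))
  if (length(specimen_ids) != length(sequences)) {
    abort("`specimen_ids` and `sequences` must have the same length.")
  }
  if (any(is.na(specimen_ids)) || any(!nzchar(specimen_ids))) {
    abort("specimen ids must be non-empty strings.")
  }
  dup <- specimen_ids[duplicated(specimen_ids)]
  if (length(dup) > 0) {
    abort(paste0(
      "duplicate specimen id(s): ", paste(unique(dup), collapse = ", ")
    ))
  }
  lens <- nchar(sequences)
  if (length(unique(lens)) > 1) {
    ref <- as.integer(names(which.max(table(lens))))
    off <- specimen_ids[lens != ref]
    abort(paste0(
      "unaligned input: record(s) ", paste(off, collapse = ", "),
      " differ in length from the rest (expected ", ref, " bp)."
    ))
  }
  chars <- unique(strsplit(paste(sequences, collapse = ""), "")[[1]])
  bad <- setdiff(chars, ALLOWED_CHARS)
  if (length(bad) > 0) {
    # report the first offending position for a useful error message
    for (i in seq_along(sequences)) {
      pos <- regexpr(paste0("[", paste(gsub("([\\^\\]\\\\-])", "\\\\\\1", bad),
        collapse = ""
      ), "]"), sequences[i])
      if (pos > 0) {
        abort(paste0(
          "illegal character '", substr(sequences[i], pos, pos),
          "' in record '", specimen_ids[i], "' at position ", pos, "."
        ))
      }
    }
    abort(paste0("illegal character(s): ", paste(bad, collapse = ", ")))
  }
  out <- tibble(specimen_id = specimen_ids, sequence = sequences)
  attr(out, "aln_length") <- if (length(lens) > 0) lens[1] else 0L
  class(out) <- c("aligned_seqs", class(out))
  out
}

#' @rdname aligned_seqs
#' @param x An `aligned_seqs` object.
#' @export
aln_length <- function(x) {
  stopifnot(inherits(x, "aligned_seqs"))
  attr(x, "aln_length")
}

# Character matrix view of an alignment: one row per specimen, one column
# per site, rownames = specimen ids.
aln_matrix <- function(x) {
  stopifnot(inherits(x, "aligned_seqs"))
  m <- matrix(
    unlist(strsplit(x$sequence, ""), use.names = FALSE),
    nrow = nrow(x), byrow = TRUE
  )
  rownames(m) <- x$specimen_id
  m
}

# Rebuild an aligned_seqs from a character matrix (inverse of aln_matrix).
aln_from_matrix <- function(m) {
  aligned_seqs(rownames(m), apply(m, 1, paste, collapse = ""))
}

#' Read an aligned FASTA file
#'
#' Reads a pre-aligned nucleotide FASTA (any line wrapping) and validates it
#' as an [aligned_seqs()] object: unique headers (the first
#' whitespace-delimited token is taken as the specimen id), equal-length rows
#' and a restricted alphabet. Lowercase bases are normalized to uppercase.
#'
#' @param path Path to a FASTA file.
#' @return An [aligned_seqs()] tibble.
#' @export
read_aligned_fasta <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(
    strsplit(names(set), "[ \t]+"),
    function(x) x[1], character(1)
  )
  aligned_seqs(ids, as.character(set))
}

#' Write an aligned FASTA file
#'
#' Sequences are wrapped at 80 columns. Output is byte-stable for identical
#' inputs, so written files round-trip through [read_aligned_fasta()]
#' unchanged.
#'
#' @param x An [aligned_seqs()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(x, path) {
  stopifnot(inherits(x, "aligned_seqs"))
  set <- Biostrings::BStringSet(setNames(x$sequence, x$specimen_id))
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Construct a survey checklist
#'
#' A survey checklist pairs per-taxon records (rank, genus, family, growth
#' habits, native flag, flora label) with a specimen table linking specimen
#' ids to taxa. Taxa are keyed by the full terminal name together with the
#' flora label, so the same species may be recorded in several floras.
#'
#' @param taxa Tibble/data frame with columns `taxon`, `rank` (`"species"` or
#'   `"infraspecies"`), `genus`, `family`, `habits` (list-column of character
#'   vectors drawn from [HABIT_TOKENS], or a `|`-delimited string column),
#'   `native` (logical) and `flora` (character). Optional columns: `species`
#'   (binomial; derived from `taxon` when absent) and `clade` (`"fern"` or
#'   `"lycophyte"`; inferred from `family` when absent).
#' @param specimens Tibble/data frame with columns `specimen_id` and `taxon`
#'   (optional `flora`, required when taxa span several floras; optional
#'   logical `sequenced`, default `TRUE`). May be `NULL` for a specimen-less
#'   checklist.
#' @return A list of class `survey_checklist` with elements `taxa` and
#'   `specimens` (both tibbles).
#' @export
survey_checklist <- function(taxa, specimens = NULL) {
  taxa <- as_tibble(taxa)
  req <- c("taxon", "rank", "genus", "family", "habits", "native", "flora")
  miss <- setdiff(req, names(taxa))
  if (length(miss) > 0) {
    abort(paste0(
      "checklist is missing required column(s): ",
      paste(miss, collapse = ", ")
    ))
  }
  if (nrow(taxa) == 0) abort("checklist has no taxon records.")
  if (!is.list(taxa$habits)) {
    taxa$habits <- strsplit(as.character(taxa$habits), "|", fixed = TRUE)
  }
  taxa$habits <- lapply(taxa$habits, function(h) {
    h <- trimws(h[!is.na(h) & nzchar(trimws(h))])
    unique(h)
  })
  toks <- unique(unlist(taxa$habits))
  bad <- setdiff(toks, HABIT_TOKENS)
  if (length(bad) > 0) {
    abort(paste0(
      "unknown growth-habit token(s): ", paste(bad, collapse = ", "),
      ". Allowed tokens: ", paste(HABIT_TOKENS, collapse = ", "), "."
    ))
  }
  if (!all(taxa$rank %in% c("species", "infraspecies"))) {
    abort("`rank` must be 'species' or 'infraspecies'.")
  }
  taxa$native <- as.logical(taxa$native)
  if (any(is.na(taxa$native))) abort("`native` must be TRUE/FALSE.")
  if (!"species" %in% names(taxa)) {
    taxa$species <- ifelse(
      taxa$rank == "infraspecies",
      vapply(
        strsplit(taxa$taxon, " +"),
        function(w) paste(head(w, 2), collapse = " "), character(1)
      ),
      taxa$taxon
    )
  }
  if (!"clade" %in% names(taxa)) {
    taxa$clade <- ifelse(
      taxa$family %in% LYCOPHYTE_FAMILIES, "lycophyte", "fern"
    )
  }
  key <- paste(taxa$taxon, taxa$flora, sep = "\r")
  if (anyDuplicated(key)) {
    abort(paste0(
      "duplicate taxon record(s): ",
      paste(unique(taxa$taxon[duplicated(key)]), collapse = ", ")
    ))
  }

  if (is.null(specimens)) {
    specimens <- tibble(
      specimen_id = character(), taxon = character(),
      flora = character(), sequenced = logical()
    )
  } else {
    specimens <- as_tibble(specimens)
    if (!all(c("specimen_id", "taxon") %in% names(specimens))) {
      abort("specimen table needs columns `specimen_id` and `taxon`.")
    }
    if (!"flora" %in% names(specimens)) {
      # unambiguous only when each taxon name maps to a single flora
      lut <- taxa$flora[match(specimens$taxon, taxa$taxon)]
      multi <- taxa$taxon[duplicated(taxa$taxon)]
      if (any(specimens$taxon %in% multi)) {
        abort("specimens of taxa recorded in several floras need a `flora` column.")
      }
      specimens$flora <- lut
    }
    if (!"sequenced" %in% names(specimens)) specimens$sequenced <- TRUE
    if (anyDuplicated(specimens$specimen_id)) {
      abort("duplicate specimen id(s) in checklist.")
    }
    skey <- paste(specimens$taxon, specimens$flora, sep = "\r")
    orphan <- !(skey %in% key)
    if (any(orphan)) {
      abort(paste0(
        "specimen(s) reference undeclared taxa: ",
        paste(specimens$specimen_id[orphan], collapse = ", ")
      ))
    }
    specimens <- specimens[
      order(specimens$taxon, specimens$specimen_id),
      c("specimen_id", "taxon", "flora", "sequenced")
    ]
  }
  structure(
    list(taxa = taxa[order(taxa$flora, taxa$taxon), ], specimens = specimens),
    class = "survey_checklist"
  )
}

#' @export
print.survey_checklist <- function(x, ...) {
  cat(
    "<survey_checklist> ", nrow(x$taxa), " taxa, ",
    nrow(x$specimens), " specimens, ",
    length(unique(x$taxa$flora)), " flora(s)\n",
    sep = ""
  )
  invisible(x)
}

# specimen_id -> taxon lookup as a named character vector
specimen_taxon_map <- function(checklist) {
  stopifnot(inherits(checklist, "survey_checklist"))
  setNames(checklist$specimens$taxon, checklist$specimens$specimen_id)
}

#' Read a survey checklist from CSV
#'
#' The CSV is flat, one row per specimen, with columns `taxon`, `rank`,
#' `genus`, `family`, `habits` (multi-label, `|`-delimited), `native`,
#' `flora` and `specimen_id`; rows with an empty `specimen_id` declare a
#' taxon without specimens (e.g. a taxon that could not be sequenced).
#' Optional columns `species`, `clade` and `sequenced` are honoured.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @return A [survey_checklist()] object.
#' @export
read_checklist <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  if (nrow(df) == 0) abort("empty checklist file.")
  req <- c(
    "taxon", "rank", "genus", "family", "habits", "native", "flora",
    "specimen_id"
  )
  miss <- setdiff(req, names(df))
  if (length(miss) > 0) {
    abort(paste0(
      "checklist CSV is missing required column(s): ",
      paste(miss, collapse = ", ")
    ))
  }
  tcols <- intersect(
    c("taxon", "rank", "genus", "family", "habits", "native", "flora",
      "species", "clade"),
    names(df)
  )
  taxa <- dplyr::distinct(df[tcols])
  if (anyDuplicated(paste(taxa$taxon, taxa$flora, sep = "\r"))) {
    abort("conflicting attribute rows for the same taxon/flora.")
  }
  has_spec <- !is.na(df$specimen_id) & nzchar(df$specimen_id)
  specimens <- df[has_spec, intersect(
    c("specimen_id", "taxon", "flora", "sequenced"), names(df)
  )]
  if ("sequenced" %in% names(specimens)) {
    specimens$sequenced <- as.logical(specimens$sequenced)
  }
  survey_checklist(taxa, if (nrow(specimens) > 0) specimens else NULL)
}

#' Write a survey checklist to CSV
#'
#' Inverse of [read_checklist()]: one row per specimen plus one row (with an
#' empty `specimen_id`) for each specimen-less taxon. Byte-stable for
#' identical inputs.
#'
#' @param checklist A [survey_checklist()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_checklist <- function(checklist, path) {
  stopifnot(inherits(checklist, "survey_checklist"))
  taxa <- checklist$taxa
  taxa$habits <- vapply(taxa$habits, paste, character(1), collapse = "|")
  sp <- checklist$specimens
  flat <- dplyr::left_join(
    sp[c("specimen_id", "taxon", "flora", "sequenced")],
    taxa,
    by = c("taxon", "flora")
  )
  bare <- taxa[!paste(taxa$taxon, taxa$flora) %in% paste(sp$taxon, sp$flora), ]
  if (nrow(bare) > 0) {
    bare$specimen_id <- NA_character_
    bare$sequenced <- NA
    flat <- dplyr::bind_rows(flat, bare)
  }
  cols <- c(
    "taxon", "rank", "genus", "family", "habits", "native", "flora",
    "species", "clade", "specimen_id", "sequenced"
  )
  flat <- flat[order(flat$flora, flat$taxon, flat$specimen_id), cols]
  readr::write_csv(flat, path, na = "")
  invisible(path)
}

#' Construct an incidence matrix
#'
#' Validates a taxon-by-sampling-unit 0/1 matrix (rows = taxa, columns =
#' sampling units such as collection days). Every taxon must be detected in
#' at least one unit.
#'
#' @param m Numeric/integer matrix with taxon rownames; entries 0 or 1.
#' @return An integer matrix of class `incidence_matrix`.
#' @export
incidence_matrix <- function(m) {
  m <- as.matrix(m)
  if (is.null(rownames(m)) || anyDuplicated(rownames(m))) {
    abort("incidence matrix needs unique taxon rownames.")
  }
  if (ncol(m) < 1) abort("incidence matrix needs at least one sampling unit.")
  if (!all(m %in% c(0, 1))) {
    bad <- which(!(m %in% c(0, 1)))[1]
    abort(paste0(
      "non-binary incidence value '", m[bad], "' (row ",
      rownames(m)[(bad - 1) %% nrow(m) + 1], ")."
    ))
  }
  zero <- rowSums(m) == 0
  if (any(zero)) {
    abort(paste0(
      "taxon row(s) with no detections: ",
      paste(rownames(m)[zero], collapse = ", ")
    ))
  }
  storage.mode(m) <- "integer"
  if (is.null(colnames(m))) colnames(m) <- paste0("unit", seq_len(ncol(m)))
  class(m) <- c("incidence_matrix", class(m))
  m
}

#' Read a taxon-by-unit incidence table from CSV
#'
#' First column is the taxon name; remaining columns are sampling units with
#' 0/1 cells.
#'
#' @param path Path to a CSV file.
#' @return An [incidence_matrix()].
#' @export
read_incidence <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
  if (nrow(df) == 0 || ncol(df) < 2) {
    abort("incidence CSV needs a taxon column and at least one unit column.")
  }
  taxa <- df[[1]]
  vals <- as.matrix(df[-1])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (any(is.na(num))) abort("non-numeric incidence cell.")
  rownames(num) <- taxa
  colnames(num) <- names(df)[-1]
  incidence_matrix(num)
}

#' Write an incidence matrix to CSV
#'
#' @param inc An [incidence_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_incidence <- function(inc, path) {
  stopifnot(inherits(inc, "incidence_matrix"))
  df <- as_tibble(unclass(inc), rownames = "taxon")
  readr::write_csv(df, path)
  invisible(path)
}

#' @export
tidy.incidence_matrix <- function(x, ...) {
  as_tibble(unclass(x), rownames = "taxon") |>
    tidyr::pivot_longer(-"taxon", names_to = "unit", values_to = "present")
}
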