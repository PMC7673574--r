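#' @include core_io.R
NULL

# Integer encoding of an alignment for distance computation: A/C/G/T -> 1:4,
# everything else (gaps, N, ?, IUPAC ambiguity codes) -> NA. Ambiguity codes
# carry partial information but are pairwise-deleted here, matching the raw
# distance model used on exact-identity barcode calls.
encode_bases <- function(chr_matrix) {
  code <- match(chr_matrix, UNAMBIGUOUS_BASES)
  dim(code) <- dim(chr_matrix)
  rownames(code) <- rownames(chr_matrix)
  code
}

#' Raw p-distance between two aligned sequences
#'
#' Uncorrected proportion of differing sites with pairwise deletion: only
#' columns where *both* sequences carry an unambiguous base (A/C/G/T) are
#' compared. Gaps, `N`, `?` and IUPAC ambiguity codes are treated as missing.
#' The pair is undefined when fewer than `min_overlap` sites are compared.
#'
#' @param a,b Aligned sequences of equal length (character strings).
#' @param min_overlap Minimum number of compared sites for the distance to be
#'   defined (default 1 for the bare kernel; matrix construction uses a
#'   stricter default, see [build_distance_matrix()]).
#' @return A list with elements `distance` (proportion in `[0,1]`, `NA` when
#'   undefined), `overlap` (number of compared sites) and `defined` (logical).
#' @export
#' @examples
#' p_distance("ACGT", "ACGA")
#' p_distance("AC-TN", "ACGTA") # sites 1, 2, 4 compared
p_distance <- function(a, b, min_overlap = 1) {
  a <- toupper(a)
  b <- toupper(b)
  if (nchar(a) != nchar(b)) {
    abort("sequences differ in length; p-distance needs aligned input.")
  }
  ca <- match(strsplit(a, "")[[1]], UNAMBIGUOUS_BASES)
  cb <- match(strsplit(b, "")[[1]], UNAMBIGUOUS_BASES)
  both <- !is.na(ca) & !is.na(cb)
  overlap <- sum(both)
  if (overlap < min_overlap) {
    return(list(distance = NA_real_, overlap = overlap, defined = FALSE))
  }
  diffs <- sum(ca[both] != cb[both])
  list(distance = diffs / overlap, overlap = overlap, defined = TRUE)
}

#' Pairwise raw distance matrix with pairwise deletion
#'
#' Computes all pairwise uncorrected p-distances for an alignment, together
#' with per-pair overlap counts (number of sites where both specimens have an
#' unambiguous base). Pairs with overlap below `min_overlap` are recorded as
#' undefined (`NA`), never silently zeroed; downstream minimum-distance
#' searches skip them.
#'
#' @param aln An [aligned_seqs()] object with at least two sequences.
#' @param min_overlap Minimum compared sites for a pair to be defined
#'   (default 100; guards against spurious zero distances between barely
#'   overlapping partial sequences).
#' @return A list of class `p_dist` with elements `specimen_ids`, `d`
#'   (symmetric distance matrix, `NA` where undefined), `overlap` (symmetric
#'   integer matrix; the diagonal holds each specimen's number of unambiguous
#'   sites) and `min_overlap`.
#' @export
build_distance_matrix <- function(aln, min_overlap = 100) {
  stopifnot(inherits(aln, "aligned_seqs"))
  if (nrow(aln) < 2) abort("need at least two sequences.")
  code <- encode_bases(aln_matrix(aln))
  v <- !is.na(code) # informative sites per specimen
  storage.mode(v) <- "double"
  overlap <- v %*% t(v)
  matches <- matrix(0, nrow(code), nrow(code))
  for (b in seq_along(UNAMBIGUOUS_BASES)) {
    ab <- (code == b) & !is.na(code)
    storage.mode(ab) <- "double"
    matches <- matches + ab %*% t(ab)
  }
  d <- (overlap - matches) / overlap
  d[overlap == 0] <- NA_real_
  d[overlap < min_overlap] <- NA_real_
  diag(d) <- 0
  storage.mode(overlap) <- "integer"
  dimnames(d) <- dimnames(overlap) <- list(aln$specimen_id, aln$specimen_id)
  structure(
    list(
      specimen_ids = aln$specimen_id, d = d, overlap = overlap,
      min_overlap = min_overlap
    ),
    class = "p_dist"
  )
}

#' @export
print.p_dist <- function(x, ...) {
  n <- length(x$specimen_ids)
  undef <- sum(is.na(x$d[upper.tri(x$d)]))
  cat(
    "<p_dist> ", n, " specimens, ", choose(n, 2), " pairs (",
    undef, " undefined at min_overlap = ", x$min_overlap, ")\n",
    sep = ""
  )
  invisible(x)
}

#' @export
tidy.p_dist <- function(x, ...) {
  ids <- x$specimen_ids
  idx <- which(upper.tri(x$d), arr.ind = TRUE)
  tibble(
    id_a = ids[idx[, 1]],
    id_b = ids[idx[, 2]],
    distance = x$d[idx],
    overlap = as.integer(x$overlap[idx]),
    defined = !is.na(x$d[idx])
  ) |>
    dplyr::arrange(.data$id_a, .data$id_b)
}

#' Write a distance matrix to TSV
#'
#' @param x A `p_dist` object from [build_distance_matrix()].
#' @param path Output path.
#' @param format `"long"` (id_a, id_b, distance, overlap) or `"square"`
#'   (ids in the first row and column).
#' @return `path`, invisibly.
#' @export
write_distances <- function(x, path, format = c("long", "square")) {
  stopifnot(inherits(x, "p_dist"))
  format <- match.arg(format)
  if (format == "long") {
    readr::write_tsv(tidy(x), path)
  } else {
    df <- as_tibble(x$d, rownames = "specimen_id")
    readr::write_tsv(df, path)
  }
  invisible(path)
}

#' Alignment summary statistics
#'
#' A site is parsimony-informative when at least two distinct unambiguous
#' bases each occur in at least two sequences at that column.
#'
#' @param aln An [aligned_seqs()] object.
#' @return One-row tibble with `n_sequences`, `length` (bp) and
#'   `parsimony_informative` (site count).
#' @export
alignment_stats <- function(aln) {
  stopifnot(inherits(aln, "aligned_seqs"))
  code <- encode_bases(aln_matrix(aln))
  informative <- 0L
  if (nrow(aln) > 0 && aln_length(aln) > 0) {
    informative <- sum(apply(code, 2, function(col) {
      counts <- tabulate(col[!is.na(col)], nbins = 4L)
      sum(counts >= 2L) >= 2L
    }))
  }
  tibble(
    n_sequences = nrow(aln),
    length = as.integer(aln_length(aln)),
    parsimony_informative = as.integer(informative)
  )
}

#' Subset a distance matrix to a set of specimens
#'
#' Because p-distances are strictly pairwise, subsetting the matrix is
#' identical to recomputing distances on the subset alignment; the per-flora
#' comparison and the tree stage both rely on this.
#'
#' @param x A `p_dist` object.
#' @param ids Specimen ids to retain (order preserved).
#' @return A `p_dist` over `ids`.
#' @export
subset_p_dist <- function(x, ids) {
  stopifnot(inherits(x, "p_dist"))
  miss <- setdiff(ids, x$specimen_ids)
  if (length(miss) > 0) {
    abort(paste0("unknown specimen id(s): ", paste(miss, collapse = ", ")))
  }
  structure(
    list(
      specimen_ids = ids, d = x$d[ids, ids, drop = FALSE],
      overlap = x$overlap[ids, ids, drop = FALSE],
      min_overlap = x$min_overlap
    ),
    class = "p_dist"
  )
}
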