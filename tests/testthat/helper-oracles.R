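# Independent brute-force oracles and fixture builders. These deliberately
# use naive position-by-position loops and exhaustive enumeration, not the
# package's vectorized code paths.

# Per-position loop oracle for the raw distance with pairwise deletion.
p_distance_oracle <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  bases <- c("A", "C", "G", "T")
  compared <- 0L
  diffs <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] %in% bases && cb[i] %in% bases) {
      compared <- compared + 1L
      if (ca[i] != cb[i]) diffs <- diffs + 1L
    }
  }
  list(overlap = compared, distance = if (compared > 0) diffs / compared else NA_real_)
}

# Column-scan oracle for parsimony-informative sites.
informative_oracle <- function(chr_matrix) {
  bases <- c("A", "C", "G", "T")
  count <- 0L
  for (j in seq_len(ncol(chr_matrix))) {
    col <- chr_matrix[, j]
    tab <- table(col[col %in% bases])
    if (sum(tab >= 2) >= 2) count <- count + 1L
  }
  count
}

# Exhaustive double loop over all cross-taxon specimen pairs.
min_inter_oracle <- function(d, taxon_of) {
  taxa <- sort(unique(taxon_of))
  out <- setNames(rep(NA_real_, length(taxa)), taxa)
  nearest <- setNames(rep(NA_character_, length(taxa)), taxa)
  n <- nrow(d)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j || taxon_of[i] == taxon_of[j] || is.na(d[i, j])) next
      tx <- taxon_of[i]
      if (is.na(out[tx]) || d[i, j] < out[tx] ||
        (d[i, j] == out[tx] && taxon_of[j] < nearest[tx])) {
        out[tx] <- d[i, j]
        nearest[tx] <- taxon_of[j]
      }
    }
  }
  list(min = out, nearest = nearest)
}

# Exhaustive subset-enumeration oracle for incidence rarefaction.
rarefy_oracle <- function(inc, t) {
  tt <- ncol(inc)
  if (t == 0) {
    return(0)
  }
  subsets <- utils::combn(tt, t)
  mean(apply(subsets, 2, function(cols) {
    sum(rowSums(inc[, cols, drop = FALSE]) > 0)
  }))
}

# Clade enumeration oracle for monophyly, from the raw edge matrix.
monophyly_oracle <- function(tree, taxon_of) {
  ntip <- length(tree$tip.label)
  nodes <- sort(unique(tree$edge[, 1]))
  tips_under <- function(node) {
    if (node <= ntip) {
      return(node)
    }
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_under))
  }
  clades <- lapply(nodes, tips_under)
  taxa <- sort(unique(taxon_of))
  status <- setNames(character(length(taxa)), taxa)
  for (tx in taxa) {
    tips <- which(taxon_of[tree$tip.label] == tx)
    if (length(tips) == 1) {
      status[tx] <- "trivial"
      next
    }
    containing <- Filter(function(cl) all(tips %in% cl), clades)
    smallest <- containing[[which.min(lengths(containing))]]
    status[tx] <- if (length(smallest) == length(tips)) {
      "monophyletic"
    } else {
      "non-monophyletic"
    }
  }
  status
}

# Random aligned sequence with gaps, missing data and ambiguity codes.
random_gapped_seq <- function(len) {
  pool <- c(
    rep(c("A", "C", "G", "T"), 5), "-", "-", "N", "?", "R", "Y"
  )
  paste(sample(pool, len, replace = TRUE), collapse = "")
}

# Wrap a plain symmetric matrix as a p_dist object (fully defined pairs).
as_p_dist <- function(d, min_overlap = 1) {
  ids <- rownames(d)
  structure(
    list(
      specimen_ids = ids, d = d,
      overlap = matrix(100000L, nrow(d), ncol(d), dimnames = dimnames(d)),
      min_overlap = min_overlap
    ),
    class = "p_dist"
  )
}

# Small single-flora checklist around a specimen -> taxon map.
checklist_from_map <- function(map, native = NULL) {
  taxa <- sort(unique(map))
  if (is.null(native)) native <- setNames(rep(TRUE, length(taxa)), taxa)
  survey_checklist(
    tibble::tibble(
      taxon = taxa, rank = "species", genus = "G", family = "F",
      habits = replicate(length(taxa), "terrestrial", simplify = FALSE),
      native = unname(native[taxa]), flora = "testflora"
    ),
    tibble::tibble(specimen_id = names(map), taxon = unname(map))
  )
}

# Random 0/1 incidence matrix with every taxon detected at least once.
random_incidence <- function(n_taxa, T, p = 0.35) {
  repeat {
    m <- matrix(
      rbinom(n_taxa * T, 1, p), n_taxa, T,
      dimnames = list(sprintf("sp%03d", seq_len(n_taxa)), NULL)
    )
    if (all(rowSums(m) > 0)) {
      return(incidence_matrix(m))
    }
  }
}
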