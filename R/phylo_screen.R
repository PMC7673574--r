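#' @include distances.R
NULL

#' Neighbor-joining tree from a p-distance matrix
#'
#' Saitou–Nei agglomeration on the Q criterion
#' \eqn{Q_{ij} = (r-2) d_{ij} - R_i - R_j}. Ties on Q are broken by merging
#' the pair whose smallest contained leaf labels sort first, so topologies
#' are reproducible. Negative branch lengths are clamped to zero with the
#' deficit moved to the sister edge, preserving path lengths where possible.
#' The result is the standard unrooted NJ tree (trifurcation at the base),
#' returned as an ape `"phylo"` object whose tip labels are the specimen ids.
#'
#' @param dm A `p_dist` object with every pair defined and at least three
#'   specimens. Undefined pairs (overlap below the minimum) are an error;
#'   remove the offending specimens or impute before tree building.
#' @return An unrooted `phylo` tree with branch lengths in substitutions/site.
#' @export
neighbor_joining <- function(dm) {
  stopifnot(inherits(dm, "p_dist"))
  n <- length(dm$specimen_ids)
  if (n < 3) abort("neighbor joining needs at least three specimens.")
  d <- dm$d
  if (any(is.na(d))) {
    idx <- which(is.na(d), arr.ind = TRUE)[1, ]
    abort(paste0(
      "undefined distance between '", dm$specimen_ids[idx[1]], "' and '",
      dm$specimen_ids[idx[2]], "' (overlap below min_overlap = ",
      dm$min_overlap, "). Remove these specimens or impute the distance ",
      "before tree building."
    ))
  }
  # each active cluster carries a newick fragment and the lexicographically
  # smallest leaf label it contains (used for deterministic tie-breaking)
  newick <- dm$specimen_ids
  minlab <- dm$specimen_ids
  fmt <- function(x) sprintf("%.12g", x)

  clamp <- function(la, lb) {
    if (la < 0) {
      lb <- lb + la
      la <- 0
    }
    if (lb < 0) {
      la <- la + lb
      lb <- 0
    }
    c(max(la, 0), max(lb, 0))
  }

  while (length(newick) > 3) {
    r <- nrow(d)
    rs <- rowSums(d)
    q <- (r - 2) * d - outer(rs, rs, "+")
    diag(q) <- Inf
    qmin <- min(q)
    tol <- 1e-12 * (1 + abs(qmin))
    cand <- which(q <= qmin + tol, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    lab_lo <- pmin(minlab[cand[, 1]], minlab[cand[, 2]])
    lab_hi <- pmax(minlab[cand[, 1]], minlab[cand[, 2]])
    pick <- order(lab_lo, lab_hi)[1]
    i <- cand[pick, 1]
    j <- cand[pick, 2]

    la <- d[i, j] / 2 + (rs[i] - rs[j]) / (2 * (r - 2))
    lb <- d[i, j] - la
    ll <- clamp(la, lb)
    merged <- paste0(
      "(", newick[i], ":", fmt(ll[1]), ",", newick[j], ":", fmt(ll[2]), ")"
    )
    dnew <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(r), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dnew[keep]), c(dnew[keep], 0))
    d <- d2
    newick <- c(newick[keep], merged)
    minlab <- c(minlab[keep], min(minlab[i], minlab[j]))
  }
  # final three clusters: closed-form three-point branch lengths
  l1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  l2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  l3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  ls <- c(l1, l2, l3)
  for (k in seq_len(3)) {
    if (ls[k] < 0) {
      nxt <- k %% 3 + 1
      ls[nxt] <- ls[nxt] + ls[k]
      ls[k] <- 0
    }
  }
  ls <- pmax(ls, 0)
  txt <- paste0(
    "(", newick[1], ":", fmt(ls[1]), ",", newick[2], ":", fmt(ls[2]), ",",
    newick[3], ":", fmt(ls[3]), ");"
  )
  ape::read.tree(text = txt)
}

# Leaf pair spanning the tree diameter, ties broken by the lexicographically
# smaller (sorted) label pair. Returns c(leaf_a, leaf_b, distance).
longest_leaf_path <- function(tree) {
  co <- ape::cophenetic.phylo(tree)
  labs <- rownames(co)
  idx <- which(upper.tri(co), arr.ind = TRUE)
  dd <- co[idx]
  dmax <- max(dd)
  cand <- idx[dd >= dmax - 1e-12 * (1 + dmax), , drop = FALSE]
  a <- pmin(labs[cand[, 1]], labs[cand[, 2]])
  b <- pmax(labs[cand[, 1]], labs[cand[, 2]])
  pick <- order(a, b)[1]
  list(a = a[pick], b = b[pick], length = dmax)
}

#' Midpoint rooting
#'
#' Roots an unrooted tree with branch lengths at the midpoint of the longest
#' leaf-to-leaf path; ties on the diameter are broken by the
#' lexicographically smaller leaf pair. Re-rooting preserves all leaf-to-leaf
#' path lengths. A tree whose branch lengths are all zero is rooted on its
#' first internal edge with a warning.
#'
#' @param tree A `phylo` tree with branch lengths.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) abort("tree has no branch lengths.")
  path <- longest_leaf_path(tree)
  if (path$length <= 0) {
    warn("all path lengths are zero; rooting on the first internal edge.")
    child <- tree$edge[tree$edge[, 2] > ape::Ntip(tree), 2][1]
    if (is.na(child)) child <- tree$edge[1, 2]
    return(phytools::reroot(tree, child, position = 0))
  }
  tip_a <- which(tree$tip.label == path$a)
  tip_b <- which(tree$tip.label == path$b)
  nodes <- ape::nodepath(tree, from = tip_a, to = tip_b)
  # edge lengths along the path, walking from leaf a towards leaf b
  el <- numeric(length(nodes) - 1)
  parent_first <- logical(length(nodes) - 1)
  for (k in seq_along(el)) {
    n1 <- nodes[k]
    n2 <- nodes[k + 1]
    e <- which(
      (tree$edge[, 1] == n1 & tree$edge[, 2] == n2) |
        (tree$edge[, 1] == n2 & tree$edge[, 2] == n1)
    )
    el[k] <- tree$edge.length[e]
    parent_first[k] <- tree$edge[e, 1] == n1
  }
  half <- path$length / 2
  cum <- cumsum(el)
  k <- which(cum >= half - 1e-12)[1]
  into <- half - (if (k > 1) cum[k - 1] else 0) # distance from nodes[k]
  # phytools::reroot measures `position` from the rootward (parent) end of
  # the edge below `node`
  if (parent_first[k]) {
    child <- nodes[k + 1]
    pos <- into
  } else {
    child <- nodes[k]
    pos <- el[k] - into
  }
  pos <- min(max(pos, 0), el[k])
  phytools::reroot(tree, child, position = pos)
}

#' Assess per-taxon monophyly on a labeled tree
#'
#' A taxon with a single specimen in the tree is `"trivial"`; otherwise it is
#' `"monophyletic"` when the smallest clade containing all of its specimens
#' contains no other taxon's specimen, else `"non-monophyletic"`. Evaluated
#' on the resolved (binary) tree: zero-length internal edges from identical
#' sequences are retained, not collapsed.
#'
#' @param tree A rooted `phylo` tree whose tip labels are specimen ids.
#' @param checklist A [survey_checklist()] mapping every tree tip to a taxon;
#'   a checklist specimen missing from the tree is an error.
#' @return Tibble with `taxon`, `n_specimens` (tips in the tree) and `status`.
#' @export
assess_monophyly <- function(tree, checklist) {
  stopifnot(inherits(tree, "phylo"), inherits(checklist, "survey_checklist"))
  if (!ape::is.rooted(tree)) abort("tree must be rooted (see midpoint_root).")
  map <- specimen_taxon_map(checklist)
  absent <- setdiff(names(map), tree$tip.label)
  if (length(absent) > 0) {
    abort(paste0(
      "specimen(s) absent from tree: ", paste(absent, collapse = ", ")
    ))
  }
  unmapped <- setdiff(tree$tip.label, names(map))
  if (length(unmapped) > 0) {
    abort(paste0(
      "tree tip(s) not mapped to a taxon: ", paste(unmapped, collapse = ", ")
    ))
  }
  taxon_of <- map[tree$tip.label]
  taxa <- sort(unique(taxon_of))
  status <- vapply(taxa, function(tx) {
    tips <- which(taxon_of == tx)
    if (length(tips) == 1) {
      return("trivial")
    }
    mrca <- ape::getMRCA(tree, tips)
    clade_tips <- phangorn::Descendants(tree, mrca, type = "tips")[[1]]
    if (setequal(clade_tips, tips)) "monophyletic" else "non-monophyletic"
  }, character(1))
  tibble(
    taxon = taxa,
    n_specimens = as.integer(table(taxon_of)[taxa]),
    status = unname(status)
  )
}

#' Write a tree to Newick
#'
#' Branch lengths are written with six significant digits.
#'
#' @param tree A `phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' Specimens retained after removing undefined distance pairs
#'
#' Greedily drops the specimens involved in the most undefined pairs
#' (overlap below the matrix's `min_overlap`, e.g. opposite-half partial
#' sequences) until every remaining pair is defined — the specimen-removal
#' remedy [neighbor_joining()] asks for.
#'
#' @param dm A `p_dist` object.
#' @return Character vector of retained specimen ids.
#' @export
drop_undefined_specimens <- function(dm) {
  stopifnot(inherits(dm, "p_dist"))
  d <- dm$d
  ids <- dm$specimen_ids
  repeat {
    undef <- is.na(d)
    diag(undef) <- FALSE
    counts <- rowSums(undef)
    if (all(counts == 0)) break
    worst <- which(counts == max(counts))
    victim <- worst[order(ids[worst], decreasing = TRUE)][1]
    d <- d[-victim, -victim, drop = FALSE]
    ids <- ids[-victim]
  }
  ids
}
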