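#' Reroot a gene tree on a preferred outgroup
#'
#' The root is placed on the edge subtending the first preference species
#' present in the tree (when that species has several transcripts, the edge
#' above their MRCA). A tree containing none of the preference species is
#' returned unchanged but marked unrootable (attribute `"unrootable"`), a
#' status excluding it from downstream placement rather than an error. A tree
#' already rooted with the chosen outgroup clade as a child of the root is
#' returned unchanged.
#'
#' @param gene_tree `phylo` with transcript-id tips.
#' @param map Named character, transcript id -> species id; defaults to
#'   parsing `"Species@copy"` labels.
#' @param preference Ordered character vector of outgroup species ids.
#' @return The rerooted `phylo`; check `attr(x, "unrootable")`.
#' @export
reroot_by_preference <- function(gene_tree, map = NULL, preference) {
  if (length(preference) == 0L) stop("preference must be nonempty")
  if (is.null(map))
    map <- stats::setNames(sub("@.*$", "", gene_tree$tip.label),
                           gene_tree$tip.label)
  sp <- unname(map[gene_tree$tip.label])
  pick <- preference[preference %in% sp][1L]
  if (is.na(pick)) {
    attr(gene_tree, "unrootable") <- TRUE
    return(gene_tree)
  }
  tips <- which(sp == pick)
  target <- if (length(tips) == 1L) tips else
    ape::getMRCA(gene_tree, gene_tree$tip.label[tips])
  root <- root_node(gene_tree)
  if (target != root) {
    par <- parent_vec(gene_tree)
    if (par[target] == root) {
      attr(gene_tree, "unrootable") <- FALSE
      return(gene_tree)                          # already rooted here
    }
  }
  if (target == root) {
    attr(gene_tree, "unrootable") <- FALSE       # outgroup spans the root
    return(gene_tree)
  }
  elen <- gene_tree$edge.length[match(target, gene_tree$edge[, 2L])]
  pos <- if (is.null(gene_tree$edge.length) || is.na(elen)) 0 else elen / 2
  out <- phytools::reroot(gene_tree, node.number = target, position = pos)
  attr(out, "unrootable") <- FALSE
  out
}

#' Enumerate same-species paralog pairs in a gene family
#'
#' For every species contributing `k >= 2` transcripts, all `choose(k, 2)`
#' pairs are returned, each annotated with the gene-tree MRCA of the two
#' transcripts and that node's bootstrap support.
#'
#' @param family A [gene_family()] with a rooted gene tree.
#' @return A data.frame with columns `family`, `transcript_a`, `transcript_b`,
#'   `species`, `mrca_node`, `mrca_support` (NA where the node is unlabeled).
#' @export
enumerate_paralog_pairs <- function(family) {
  tree <- family$tree
  sup <- node_support(tree)
  sp <- unname(family$map[tree$tip.label])
  out <- list()
  for (s in unique(sp)) {
    idx <- which(sp == s)
    if (length(idx) < 2L) next
    prs <- utils::combn(sort(tree$tip.label[idx]), 2L)
    for (j in seq_len(ncol(prs))) {
      m <- ape::getMRCA(tree, prs[, j])
      out[[length(out) + 1L]] <- data.frame(
        family = family$id, transcript_a = prs[1L, j],
        transcript_b = prs[2L, j], species = s,
        mrca_node = m, mrca_support = sup[m],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(family = character(0), transcript_a = character(0),
                      transcript_b = character(0), species = character(0),
                      mrca_node = integer(0), mrca_support = numeric(0)))
  do.call(rbind, out)
}

#' Place one paralog pair on the species tree
#'
#' The acceptance rule: let `T` be the species set of the gene-tree subtree
#' under the pair's MRCA. The candidate placement is the species-tree node
#' whose descendant species set equals `T` exactly (the species tree is first
#' restricted to the species present in this gene family when
#' `prune_species_tree = TRUE`, tolerating incomplete transcriptome
#' sampling). The placement is accepted iff at least one species from the
#' candidate node's sister clade appears in the gene-tree MRCA's sister
#' subtree. A pair whose MRCA is the gene-tree root has no sister and is
#' unplaceable.
#'
#' @param pair One row of [enumerate_paralog_pairs()] output (data.frame or
#'   list with `mrca_node`, `mrca_support`).
#' @param family The [gene_family()] the pair came from.
#' @param species_tree Rooted `phylo` with species-id tips.
#' @param prune_species_tree Restrict clade matching to the family's species.
#' @return A one-row data.frame (a duplication record): `family`,
#'   `species_node` (node id in the full `species_tree`, NA when rejected),
#'   `species_clade` (comma-joined sorted species set), `mrca_node`,
#'   `mrca_support`, `accepted`, `reason` (`"none"`, `"no-matching-clade"`,
#'   `"sister-check-failed"`, `"root-unplaceable"`).
#' @export
place_pair <- function(pair, family, species_tree, prune_species_tree = TRUE) {
  gt <- family$tree
  rec <- function(node = NA_integer_, clade = NA_character_,
                  accepted = FALSE, reason = "none") {
    data.frame(family = family$id, species_node = node,
               species_clade = clade, mrca_node = pair$mrca_node,
               mrca_support = pair$mrca_support, accepted = accepted,
               reason = reason, stringsAsFactors = FALSE)
  }
  m <- pair$mrca_node
  if (m == root_node(gt)) return(rec(reason = "root-unplaceable"))
  gsets <- tip_label_sets(gt)
  T_set <- sort(unique(unname(family$map[gsets[[m]]])))
  fam_sp <- intersect(species_tree$tip.label, family_species(family))
  st <- species_tree
  if (prune_species_tree) {
    if (length(fam_sp) < 2L) return(rec(reason = "no-matching-clade"))
    st <- ape::keep.tip(species_tree, fam_sp)
  }
  ssets <- tip_label_sets(st)
  hit <- which(vapply(ssets, function(s)
    length(s) == length(T_set) && setequal(s, T_set), logical(1L)))
  if (!length(hit)) return(rec(reason = "no-matching-clade"))
  hit <- hit[1L]
  clade_str <- paste(T_set, collapse = ",")
  full_node <- if (length(T_set) == 1L)
    match(T_set, species_tree$tip.label)
  else ape::getMRCA(species_tree, T_set)
  # sister species set S in the (possibly pruned) species tree
  spar <- parent_vec(st)
  if (spar[hit] == 0L) return(rec(full_node, clade_str,
                                  reason = "sister-check-failed"))
  sibs <- setdiff(child_list(st)[[spar[hit]]], hit)
  S_set <- unique(unlist(ssets[sibs]))
  # gene-tree sister subtree species G
  gpar <- parent_vec(gt)
  gsibs <- setdiff(child_list(gt)[[gpar[m]]], m)
  G_set <- unique(unname(family$map[unlist(gsets[gsibs])]))
  if (length(intersect(G_set, S_set)) == 0L)
    return(rec(full_node, clade_str, reason = "sister-check-failed"))
  rec(full_node, clade_str, accepted = TRUE)
}

#' Place every paralog pair of a set of families
#'
#' Convenience pipeline: optionally reroots each family on a preferred
#' outgroup ([reroot_by_preference()]), enumerates paralog pairs and places
#' each ([place_pair()]). Unrootable families are skipped and reported.
#'
#' @param families List of [gene_family()] objects.
#' @param species_tree Rooted `phylo`.
#' @param outgroups Ordered outgroup species preference, or `NULL` to use the
#'   gene trees as rooted.
#' @param prune_species_tree Passed to [place_pair()].
#' @return A data.frame of duplication records (one per pair), with an extra
#'   `species` column.
#' @export
place_families <- function(families, species_tree, outgroups = NULL,
                           prune_species_tree = TRUE) {
  out <- list()
  for (fam in families) {
    if (!is.null(outgroups)) {
      tr <- reroot_by_preference(fam$tree, fam$map, outgroups)
      if (isTRUE(attr(tr, "unrootable"))) next
      fam$tree <- tr
    }
    pairs <- enumerate_paralog_pairs(fam)
    if (!nrow(pairs)) next
    for (i in seq_len(nrow(pairs))) {
      r <- place_pair(pairs[i, ], fam, species_tree, prune_species_tree)
      r$species <- pairs$species[i]
      out[[length(out) + 1L]] <- r
    }
  }
  if (!length(out))
    return(data.frame(family = character(0), species_node = integer(0),
                      species_clade = character(0), mrca_node = integer(0),
                      mrca_support = numeric(0), accepted = logical(0),
                      reason = character(0), species = character(0)))
  do.call(rbind, out)
}

#' Tally accepted duplications per species-tree node
#'
#' Records with MRCA support below `support_min` (or missing support) are
#' dropped. In `"unique"` mode each distinct (family, gene-tree MRCA node)
#' duplication counts once at its species-tree node, regardless of how many
#' paralog pairs coalesce there; `"all_pairs"` counts every accepted pair.
#'
#' @param records Output of [place_families()] (or rbound [place_pair()]
#'   rows).
#' @param mode `"unique"` or `"all_pairs"`.
#' @param support_min Bootstrap threshold in `[0, 100]`; default 80.
#' @return A data.frame `node`, `clade`, `count`, sorted by decreasing count,
#'   with attribute `"total"`.
#' @export
tally_duplications <- function(records, mode = c("unique", "all_pairs"),
                               support_min = 80) {
  mode <- match.arg(mode)
  stopifnot(support_min >= 0, support_min <= 100)
  keep <- records$accepted & !is.na(records$mrca_support) &
    records$mrca_support >= support_min
  r <- records[keep, , drop = FALSE]
  if (mode == "unique")
    r <- r[!duplicated(r[, c("family", "mrca_node")]), , drop = FALSE]
  if (!nrow(r)) {
    out <- data.frame(node = integer(0), clade = character(0),
                      count = integer(0))
    attr(out, "total") <- 0L
    return(out)
  }
  tab <- stats::aggregate(list(count = r$family),
                          by = list(node = r$species_node,
                                    clade = r$species_clade),
                          FUN = length)
  tab <- tab[order(-tab$count, tab$node), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "total") <- sum(tab$count)
  tab
}

#' Annotate a species tree with per-node duplication counts
#'
#' Writes the tallied counts as internal node labels, ready for plotting or
#' Newick export.
#'
#' @param species_tree Rooted `phylo`.
#' @param tally Output of [tally_duplications()].
#' @return The annotated `phylo` (counts as `node.label`, 0 where absent).
#' @export
annotate_counts <- function(species_tree, tally) {
  ntip <- ape::Ntip(species_tree)
  lab <- rep("0", species_tree$Nnode)
  internal <- tally$node[tally$node > ntip]
  lab[internal - ntip] <- as.character(tally$count[tally$node > ntip])
  species_tree$node.label <- lab
  species_tree
}
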