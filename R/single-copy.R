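#' Filter orthogroups by distinct-species count
#'
#' Keeps exactly the families represented by at least `min_taxa` distinct
#' species (the boundary is inclusive: a family with `min_taxa` species is
#' kept). Input order is preserved.
#'
#' @param families List of [gene_family()] objects.
#' @param min_taxa Minimum number of distinct species (>= 1).
#' @return The kept sublist.
#' @export
filter_orthogroups <- function(families, min_taxa = 12) {
  stopifnot(min_taxa >= 1)
  keep <- vapply(families, function(f) length(family_species(f)) >= min_taxa,
                 logical(1L))
  families[keep]
}

#' Collapse well-supported single-species clades to their longest transcript
#'
#' Reimplementation of the clone_reducer step that defines the single-copy
#' gene set: every maximal clade whose tips all belong to one species and
#' whose subtending node has bootstrap support at or above `support_min` is
#' replaced by its single longest transcript (isoforms/alleles collapsed to a
#' representative). Length ties break to the lexicographically smallest
#' transcript id. The pass is applied bottom-up and repeated until a fixpoint
#' (one pass suffices in practice; the loop guards pathological inputs).
#' Single tips are never "collapsed" and clades below the support threshold
#' are left untouched.
#'
#' @param family A [gene_family()] with `lengths` present for every tip
#'   inside a qualifying clade.
#' @param support_min Support threshold in `[0, 100]`; default 50.
#' @return The reduced [gene_family()].
#' @export
collapse_single_species_clades <- function(family, support_min = 50) {
  stopifnot(inherits(family, "gene_family"),
            support_min >= 0, support_min <= 100)
  repeat {
    res <- .collapse_once(family, support_min)
    if (res$changed) family <- res$family else return(res$family)
  }
}

.collapse_once <- function(family, support_min) {
  tree <- family$tree
  ntip <- ape::Ntip(tree)
  if (ntip < 3L || tree$Nnode < 1L)
    return(list(family = family, changed = FALSE))
  sets <- tip_label_sets(tree)
  sup <- node_support(tree)
  par <- parent_vec(tree)
  qualifies <- function(v) {
    if (v <= ntip) return(FALSE)                       # single tips: no-op
    sp <- unique(unname(family$map[sets[[v]]]))
    length(sp) == 1L && !is.na(sup[v]) && sup[v] >= support_min
  }
  drop <- character(0)
  changed <- FALSE
  for (v in (ntip + 1L):(ntip + tree$Nnode)) {
    if (!qualifies(v)) next
    if (par[v] != 0L && qualifies(par[v])) next        # not maximal
    tips <- sets[[v]]
    if (is.null(family$lengths)) stop("transcript lengths required")
    missing <- tips[!(tips %in% names(family$lengths))]
    if (length(missing))
      stop("missing transcript length for tip \"", missing[1L], "\"")
    len <- family$lengths[tips]
    best <- sort(tips[len == max(len)])[1L]
    drop <- c(drop, setdiff(tips, best))
    changed <- TRUE
  }
  if (!changed) return(list(family = family, changed = FALSE))
  if (length(drop) >= ntip - 1L) {
    # collapsing would leave <2 tips; keep the representatives only
    keep <- setdiff(tree$tip.label, drop)
    nt <- ape::read.tree(text = paste0("(", paste(keep, collapse = ","), ");"))
    fam2 <- gene_family(nt, map = family$map, lengths = family$lengths,
                        id = family$id)
    return(list(family = fam2, changed = TRUE))
  }
  nt <- ape::drop.tip(tree, drop)
  fam2 <- gene_family(nt, map = family$map, lengths = family$lengths,
                      id = family$id)
  list(family = fam2, changed = TRUE)
}

#' Is a family single copy after reduction?
#'
#' `TRUE` iff, after [collapse_single_species_clades()], every species occurs
#' exactly once among the tips.
#'
#' @param family A [gene_family()].
#' @param support_min Threshold passed to the reduction; set `reduce = FALSE`
#'   to test the family as-is.
#' @param reduce Apply the reduction first (default).
#' @export
is_single_copy <- function(family, support_min = 50, reduce = TRUE) {
  if (reduce && !is.null(family$lengths))
    family <- collapse_single_species_clades(family, support_min)
  sp <- unname(family$map[family$tree$tip.label])
  all(table(sp) == 1L)
}

#' Summarize the single-copy reduction of a family set
#'
#' @param families List of [gene_family()] objects (with transcript lengths
#'   when reduction should run).
#' @param support_min Support threshold for the reduction.
#' @return A data.frame with one row per family: `family`, `n_species`,
#'   `n_transcripts`, `single_copy`.
#' @export
single_copy_summary <- function(families, support_min = 50) {
  rows <- lapply(families, function(f) {
    data.frame(family = f$id,
               n_species = length(family_species(f)),
               n_transcripts = ape::Ntip(f$tree),
               single_copy = is_single_copy(f, support_min = support_min))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
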