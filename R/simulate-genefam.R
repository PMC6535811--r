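#' Specify a gene-family simulation scenario with an episodic WGD
#'
#' Families evolve inside `species_tree` under a birth-death
#' duplication-loss process. Optionally, a single synchronous duplication is
#' applied at the stem of `wgd_node`: with probability `retention_prob` a
#' family keeps the WGD-derived duplicate (both copies then descend through
#' the subtree, still subject to loss); otherwise the family passes through
#' the node unduplicated, emulating post-polyploid fractionation.
#'
#' @param species_tree Rooted `phylo`.
#' @param wgd_node Internal node id of `species_tree` (or `NULL` for no WGD).
#' @param retention_prob Per-family probability of retaining the WGD
#'   duplicate, in `[0, 1]`.
#' @param background_dup_rate,loss_rate Duplication/loss rates per lineage per
#'   unit branch length (>= 0).
#' @param n_families Number of families to simulate.
#' @param p_low Support-noise probability: each gene-tree internal node draws
#'   support from uniform `{0..79}` with probability `p_low`, else from
#'   uniform `{80..100}`; `p_low = 0` gives support 100 everywhere.
#' @param seed Integer seed.
#' @return An object of class `wgd_scenario`.
#' @export
wgd_scenario <- function(species_tree, wgd_node = NULL, retention_prob = 0,
                         background_dup_rate = 0, loss_rate = 0,
                         n_families = 100, p_low = 0, seed = NULL) {
  ntip <- ape::Ntip(species_tree)
  if (!is.null(wgd_node)) {
    if (wgd_node <= ntip || wgd_node > ntip + species_tree$Nnode)
      stop("wgd_node must be an internal node of species_tree")
  }
  stopifnot(retention_prob >= 0, retention_prob <= 1,
            background_dup_rate >= 0, loss_rate >= 0, n_families >= 1,
            p_low >= 0, p_low <= 1)
  structure(list(species_tree = species_tree, wgd_node = wgd_node,
                 retention_prob = retention_prob,
                 background_dup_rate = background_dup_rate,
                 loss_rate = loss_rate, n_families = as.integer(n_families),
                 p_low = p_low, seed = seed),
            class = "wgd_scenario")
}

#' A gene family: multilabeled gene tree plus transcript-level metadata
#'
#' @param gene_tree `phylo` whose tips are transcript ids.
#' @param map Named character vector, transcript id -> species id. When
#'   `NULL`, derived from tip labels of the form `"Species@copy"`.
#' @param lengths Optional named numeric, transcript id -> sequence length
#'   (nucleotides).
#' @param id Family identifier.
#' @return An object of class `gene_family`.
#' @export
gene_family <- function(gene_tree, map = NULL, lengths = NULL, id = "fam") {
  if (is.null(map)) {
    map <- stats::setNames(sub("@.*$", "", gene_tree$tip.label),
                           gene_tree$tip.label)
  }
  missing <- setdiff(gene_tree$tip.label, names(map))
  if (length(missing))
    stop("no species mapping for transcript \"", missing[1L], "\"")
  structure(list(tree = gene_tree, map = map, lengths = lengths, id = id),
            class = "gene_family")
}

#' @export
print.gene_family <- function(x, ...) {
  sp <- unique(x$map[x$tree$tip.label])
  cat("<gene_family>", x$id, "|", ape::Ntip(x$tree), "transcripts,",
      length(sp), "species\n")
  invisible(x)
}

#' Species represented in a gene family
#' @param family A [gene_family()].
#' @export
family_species <- function(family) {
  unique(unname(family$map[family$tree$tip.label]))
}

#' Simulate gene families under duplication-loss with an episodic WGD
#'
#' Each family starts as one gene lineage at the species-tree root. Along each
#' species-tree edge every gene lineage independently duplicates (rate
#' `background_dup_rate`) or is lost (rate `loss_rate`); at speciation nodes
#' surviving lineages enter both daughter edges. For families sampled with
#' `retention_prob`, one synchronous duplication is applied to every lineage
#' entering the stem edge of `wgd_node`. Tips are labeled `"Species@copyN"`;
#' every internal gene-tree node carries a synthetic bootstrap support (see
#' [wgd_scenario()]'s `p_low`). Families whose lineages all die are
#' resimulated.
#'
#' @param scenario A [wgd_scenario()].
#' @return A list of [gene_family()] objects. Each carries ground-truth
#'   attributes: `wgd_applied` (the family was sampled for the WGD
#'   duplication), `wgd_observable` (both WGD copies survive to tips in at
#'   least one common species, so a paralog pair witnesses the event),
#'   `wgd_left`/`wgd_right` (tip labels descending from each WGD copy) and
#'   `wgd_species_node` (the true species-tree node).
#' @export
simulate_gene_families <- function(scenario) {
  stopifnot(inherits(scenario, "wgd_scenario"))
  with_seed(scenario$seed, {
    out <- vector("list", scenario$n_families)
    for (f in seq_len(scenario$n_families)) {
      wgd_on <- !is.null(scenario$wgd_node) &&
        stats::runif(1L) < scenario$retention_prob
      fam <- NULL
      for (try in 1:200) {
        fam <- .sim_one_family(scenario, wgd_on, sprintf("fam%04d", f))
        if (!is.null(fam)) break
      }
      if (is.null(fam)) stop("family simulation went extinct 200 times; ",
                             "lower loss_rate")
      out[[f]] <- fam
    }
    out
  })
}

# One family; NULL if the whole family is lost.
.sim_one_family <- function(sc, wgd_on, id) {
  tr <- sc$species_tree
  kids <- child_list(tr)
  ntip <- ape::Ntip(tr)
  dup <- sc$background_dup_rate; loss <- sc$loss_rate
  copy_ctr <- new.env(parent = emptyenv())
  wgd_sides <- list(left = character(0), right = character(0))

  tip_label <- function(sp) {
    k <- (get0(sp, envir = copy_ctr, ifnotfound = 0L)) + 1L
    assign(sp, k, envir = copy_ctr)
    paste0(sp, "@", k)
  }
  # returns list(str=, len=) for the subtree hanging below the current point,
  # or NULL if every descendant lineage is lost. `rem` = remaining length on
  # the current species edge above node `v`. `side` tags which WGD copy a tip
  # descends from ("" = none).
  g <- function(v, rem, side) {
    total <- sc$background_dup_rate + sc$loss_rate
    pos <- 0
    while (total > 0) {
      e <- stats::rexp(1L, total)
      if (pos + e >= rem) break
      pos <- pos + e
      if (stats::runif(1L) < dup / total) {
        a <- g(v, rem - pos, side)
        b <- g(v, rem - pos, side)
        if (is.null(a) && is.null(b)) return(NULL)
        if (is.null(a)) return(list(str = b$str, len = b$len + pos))
        if (is.null(b)) return(list(str = a$str, len = a$len + pos))
        return(list(str = paste0("(", a$str, ":", a$len, ",",
                                 b$str, ":", b$len, ")", .support(sc)),
                    len = pos))
      } else {
        return(NULL)                                   # loss
      }
    }
    # reached node v
    if (v <= ntip) {
      lab <- tip_label(tr$tip.label[v])
      if (side != "") wgd_sides[[side]] <<- c(wgd_sides[[side]], lab)
      return(list(str = lab, len = rem))
    }
    subs <- list()
    for (c in kids[[v]]) {
      s <- .enter_edge(c, side, sc, tr, g, wgd_on)
      if (!is.null(s)) subs <- c(subs, list(s))
    }
    if (length(subs) == 0L) return(NULL)
    if (length(subs) == 1L)
      return(list(str = subs[[1L]]$str, len = subs[[1L]]$len + rem))
    inner <- paste(vapply(subs, function(s) paste0(s$str, ":", s$len),
                          character(1L)), collapse = ",")
    list(str = paste0("(", inner, ")", .support(sc)), len = rem)
  }

  root <- root_node(tr)
  subs <- list()
  for (c in kids[[root]]) {
    s <- .enter_edge(c, "", sc, tr, g, wgd_on)
    if (!is.null(s)) subs <- c(subs, list(s))
  }
  if (length(subs) == 0L) return(NULL)
  str <- if (length(subs) == 1L) {
    subs[[1L]]$str
  } else {
    paste0("(", paste(vapply(subs, function(s) paste0(s$str, ":", s$len),
                             character(1L)), collapse = ","),
           ")", .support(sc))
  }
  if (substr(str, 1L, 1L) != "(") return(NULL)   # single surviving tip
  gt <- ape::read.tree(text = paste0(str, ";"))
  if (is.null(gt) || ape::Ntip(gt) < 2L) return(NULL)
  fam <- gene_family(gt, id = id)
  left <- wgd_sides$left; right <- wgd_sides$right
  common <- intersect(sub("@.*$", "", left), sub("@.*$", "", right))
  attr(fam, "wgd_applied") <- wgd_on
  attr(fam, "wgd_left") <- left
  attr(fam, "wgd_right") <- right
  attr(fam, "wgd_observable") <- wgd_on && length(left) > 0 &&
    length(right) > 0 && length(common) > 0
  attr(fam, "wgd_species_node") <- sc$wgd_node
  fam
}

# Lineage entering the top of the stem edge of species node `child`; applies
# the synchronous WGD duplication when configured.
.enter_edge <- function(child, side, sc, tr, g, wgd_on) {
  len <- tr$edge.length[match(child, tr$edge[, 2L])]
  if (is.null(len) || is.na(len)) len <- 0
  if (wgd_on && !is.null(sc$wgd_node) && child == sc$wgd_node && side == "") {
    a <- g(child, len, "left")
    b <- g(child, len, "right")
    if (is.null(a) && is.null(b)) return(NULL)
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    return(list(str = paste0("(", a$str, ":", a$len, ",",
                             b$str, ":", b$len, ")", .support(sc)),
                len = 0))
  }
  g(child, len, side)
}

.support <- function(sc) {
  if (sc$p_low <= 0) return("100")
  if (stats::runif(1L) < sc$p_low) as.character(sample(0:79, 1L))
  else as.character(sample(80:100, 1L))
}

#' Write simulated gene families to disk
#'
#' One Newick file per family plus a tab-delimited transcript-to-species
#' label map and, when present, a ground-truth table of the simulated WGD
#' status per family.
#'
#' @param families List of [gene_family()] objects.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written: `trees` (character vector),
#'   `map`, `truth` (or `NA` when no ground truth is attached).
#' @export
write_gene_families <- function(families, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(length(families))
  maps <- list()
  truth <- list()
  for (i in seq_along(families)) {
    f <- families[[i]]
    paths[i] <- file.path(dir, paste0(f$id, ".nwk"))
    write_newick(f$tree, paths[i])
    maps[[i]] <- data.frame(transcript = names(f$map),
                            species = unname(f$map))
    if (!is.null(attr(f, "wgd_applied"))) {
      truth[[length(truth) + 1L]] <- data.frame(
        family = f$id,
        wgd_applied = isTRUE(attr(f, "wgd_applied")),
        wgd_observable = isTRUE(attr(f, "wgd_observable")),
        wgd_species_node = if (is.null(attr(f, "wgd_species_node")))
          NA_integer_ else attr(f, "wgd_species_node"))
    }
  }
  map_path <- file.path(dir, "label_map.tsv")
  utils::write.table(unique(do.call(rbind, maps)), map_path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth_path <- NA_character_
  if (length(truth)) {
    truth_path <- file.path(dir, "ground_truth.tsv")
    utils::write.table(do.call(rbind, truth), truth_path, sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(list(trees = paths, map = map_path, truth = truth_path))
}
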