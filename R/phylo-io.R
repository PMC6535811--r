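#' Read a Newick tree with validation
#'
#' Parses a single Newick statement into an [ape::read.tree()] `phylo` object.
#' Numeric internal-node labels are interpreted as bootstrap support on the
#' 0--100 scale (the RAxML convention). A secondary dialect carrying support in
#' `[&support=...]` comments after the closing parenthesis is also read (the
#' comment is converted to a node label); this dialect is never written.
#'
#' @param text A length-1 character string containing one Newick statement,
#'   or a path to a file holding one (when `file = TRUE`).
#' @param file Logical; treat `text` as a file path.
#' @return A rooted `phylo` object; support values, when present, are in
#'   `$node.label`.
#' @details Validation errors name the offending token: unbalanced
#'   parentheses, duplicate tip labels, and negative branch lengths are all
#'   rejected.
#' @seealso [write_newick()]
#' @export
read_newick <- function(text, file = FALSE) {
  if (file) text <- paste(readLines(text, warn = FALSE), collapse = "")
  stopifnot(is.character(text), length(text) == 1L)
  text <- trimws(text)
  # secondary dialect: hoist [&support=x] comments into node labels
  text <- gsub("\\)\\[&support=([0-9.eE+-]+)\\]", ")\\1", text)
  text <- gsub("\\[[^]]*\\]", "", text)       # strip any remaining comments
  no <- lengths(regmatches(text, gregexpr("(", text, fixed = TRUE)))
  nc <- lengths(regmatches(text, gregexpr(")", text, fixed = TRUE)))
  if (no != nc)
    stop("unbalanced parentheses in Newick string: ", no, " '(' vs ", nc, " ')'")
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("could not parse Newick string")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup))
    stop("duplicate tip label \"", dup[1L], "\"")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    bad <- which(tree$edge.length < 0)[1L]
    stop("negative branch length ", tree$edge.length[bad],
         " on edge to node ", tree$edge[bad, 2L])
  }
  if (!is.null(tree$node.label)) {
    sup <- suppressWarnings(as.numeric(tree$node.label))
    ok <- is.na(sup) | (sup >= 0 & sup <= 100)
    if (!all(ok))
      stop("support value out of [0, 100]: ", tree$node.label[!ok][1L])
  }
  tree
}

#' Write a tree as a Newick string
#'
#' Support values stored in `$node.label` are written as internal node labels
#' after the closing parenthesis.
#'
#' @param tree A `phylo` object.
#' @param path Optional file path; when `NULL` the string is returned.
#' @return The Newick string (invisibly when written to a file).
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree, digits = 12)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Construct a per-species trait vector
#'
#' A named numeric vector with trait metadata: the trait kind and a per-species
#' provenance flag recording whether the value came from the species itself or
#' from a congener substitute.
#'
#' @param values Named numeric vector (names are species ids, unique).
#' @param kind `"genome_size"` (Mb), `"chromosome_count"` (diploid 2n), or
#'   `"other"`.
#' @param provenance Character vector (`"exact"` or `"congener"`), recycled.
#' @return An object of class `trait_vector`.
#' @export
trait_vector <- function(values,
                         kind = c("genome_size", "chromosome_count", "other"),
                         provenance = "exact") {
  kind <- match.arg(kind)
  if (is.null(names(values)) || anyNA(names(values)) || any(names(values) == ""))
    stop("trait values must be named by species id")
  if (anyDuplicated(names(values)))
    stop("duplicate species key: ", names(values)[duplicated(names(values))][1L])
  if (kind == "chromosome_count") {
    if (any(values <= 0) || any(values != round(values)))
      stop("chromosome counts must be positive integers")
  }
  if (kind == "genome_size" && any(values <= 0))
    stop("genome sizes must be strictly positive")
  provenance <- rep_len(provenance, length(values))
  structure(as.numeric(stats::setNames(values, names(values))),
            names = names(values), kind = kind, provenance = provenance,
            class = "trait_vector")
}

#' @export
print.trait_vector <- function(x, ...) {
  cat("<trait_vector> kind =", attr(x, "kind"),
      "|", length(x), "species |",
      sum(attr(x, "provenance") == "congener"), "congener substitutes\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Read a delimited trait table
#'
#' Expects header columns `species,value[,source]`. Multiple records per
#' species are combined per `aggregate` (the first record by default, the
#' convention for "prime" database estimates; `"mean"` averages them).
#'
#' @param path File path.
#' @param kind Trait kind passed to [trait_vector()].
#' @param delimiter Field delimiter.
#' @param aggregate How to combine duplicate species records.
#' @return A [trait_vector()].
#' @export
read_trait_table <- function(path, kind = "other", delimiter = "\t",
                             aggregate = c("first", "mean")) {
  aggregate <- match.arg(aggregate)
  d <- utils::read.delim(path, sep = delimiter, stringsAsFactors = FALSE)
  if (!all(c("species", "value") %in% names(d)))
    stop("trait table needs 'species' and 'value' columns")
  if (aggregate == "first") {
    d <- d[!duplicated(d$species), , drop = FALSE]
  } else {
    agg <- tapply(d$value, d$species, mean)
    d <- data.frame(species = names(agg), value = as.numeric(agg))
  }
  trait_vector(stats::setNames(d$value, d$species), kind = kind)
}

#' Genus of a species identifier
#'
#' The substring before the first delimiter of a binomial-style id
#' (`"Phoenix_dactylifera"` -> `"Phoenix"`).
#'
#' @param species Character vector of species ids.
#' @param delimiter Genus/epithet delimiter.
#' @export
genus_of <- function(species, delimiter = "_") {
  vapply(strsplit(species, delimiter, fixed = TRUE), `[[`, character(1L), 1L)
}

#' Articulate a tree with trait data, with a genus-level fallback
#'
#' Tips with an exact trait record keep their own value. When
#' `allow_congener = TRUE`, a tip without a record borrows the value of a
#' congeneric species in the trait table (ties among several congeners are
#' broken by the lexicographically smallest species id, so the result is
#' independent of input order); such tips are flagged `"congener"`. Tips with
#' no value after fallback are pruned.
#'
#' @param tree `phylo` with species-id tip labels.
#' @param traits A [trait_vector()].
#' @param allow_congener Enable the genus-level fallback.
#' @param delimiter Genus delimiter for [genus_of()].
#' @return A list with `tree` (pruned), `traits` (aligned [trait_vector()]
#'   named by the retained tips), and `source` (named character: the species
#'   whose record each tip uses).
#' @export
match_tips <- function(tree, traits, allow_congener = TRUE, delimiter = "_") {
  stopifnot(inherits(traits, "trait_vector"))
  tips <- tree$tip.label
  have <- names(traits)
  val <- stats::setNames(rep(NA_real_, length(tips)), tips)
  src <- stats::setNames(rep(NA_character_, length(tips)), tips)
  flag <- stats::setNames(rep(NA_character_, length(tips)), tips)
  tg <- genus_of(tips, delimiter)
  hg <- genus_of(have, delimiter)
  for (i in seq_along(tips)) {
    if (tips[i] %in% have) {
      val[i] <- traits[[which(have == tips[i])]]
      src[i] <- tips[i]; flag[i] <- "exact"
    } else if (allow_congener) {
      cand <- sort(have[hg == tg[i]])
      if (length(cand)) {
        val[i] <- traits[[which(have == cand[1L])]]
        src[i] <- cand[1L]; flag[i] <- "congener"
      }
    }
  }
  keep <- !is.na(val)
  if (!any(keep)) stop("no tips with trait data")
  pruned <- if (all(keep)) tree else ape::drop.tip(tree, tips[!keep])
  ord <- pruned$tip.label
  list(tree = pruned,
       traits = trait_vector(val[ord], kind = attr(traits, "kind"),
                             provenance = flag[ord]),
       source = src[ord])
}
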