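test_that("rerooting follows the outgroup preference order", {
  gt <- read_newick(paste0("((Oryza_sativa@1:1,(Acorus_americanus@1:1,",
                           "Palm_a@1:1):1):1,Palm_b@1:2);"))
  pref <- c("Acorus_americanus", "Oryza_sativa")
  rt <- reroot_by_preference(gt, preference = pref)
  expect_false(attr(rt, "unrootable"))
  # Acorus tip must subtend the root
  root_kids <- rt$edge[rt$edge[, 1L] == ape::Ntip(rt) + 1L, 2L]
  acorus <- match("Acorus_americanus@1", rt$tip.label)
  expect_true(acorus %in% root_kids)

  # no outgroup present: unrootable status, not an error
  gt2 <- read_newick("((Palm_a@1:1,Palm_b@1:1):1,Palm_c@1:2);")
  rt2 <- reroot_by_preference(gt2, preference = pref)
  expect_true(attr(rt2, "unrootable"))

  # already rooted on the chosen outgroup: unchanged
  rt3 <- reroot_by_preference(rt, preference = pref)
  expect_equal(phangorn::RF.dist(rt3, rt), 0)

  expect_error(reroot_by_preference(gt, preference = character(0)),
               "nonempty")
})

test_that("paralog pair enumeration counts choose(k, 2) per species", {
  gt <- read_newick(paste0("(((A@1:1,A@2:1)90:1,(A@3:1,B@1:1)85:1)80:1,",
                           "C@1:3);"))
  fam <- gene_family(gt, id = "f1")
  pp <- enumerate_paralog_pairs(fam)
  expect_equal(nrow(pp), 3L)                  # C(3,2) for A only
  expect_true(all(pp$species == "A"))

  # single-copy family: empty
  fam1 <- gene_family(read_newick("((A@1:1,B@1:1)90:1,C@1:2);"))
  expect_equal(nrow(enumerate_paralog_pairs(fam1)), 0L)

  # S species x 2 copies each -> S pairs
  set.seed(8)
  sp <- paste0("S", 1:5)
  labs <- paste0(rep(sp, each = 2), "@", rep(1:2, 5))
  gt2 <- ape::rtree(10, tip.label = sample(labs))
  gt2$node.label <- rep("100", gt2$Nnode)
  expect_equal(nrow(enumerate_paralog_pairs(gene_family(gt2))), 5L)
})

test_that("textbook duplication is accepted at the matching clade", {
  stree <- read_newick("((A:1,B:1):1,C:2);")
  gt <- read_newick("(((A@1:1,B@1:1)99:1,(A@2:1,B@2:1)98:1)97:1,C@1:3);")
  fam <- gene_family(gt, id = "f1")
  pp <- enumerate_paralog_pairs(fam)
  pair <- pp[pp$transcript_a == "A@1" & pp$transcript_b == "A@2", ]
  rec <- place_pair(pair, fam, stree)
  expect_true(rec$accepted)
  expect_equal(rec$species_node, ape::getMRCA(stree, c("A", "B")))
  expect_equal(rec$species_clade, "A,B")
})

test_that("non-clade gene subtrees are rejected as no-matching-clade", {
  stree <- read_newick("((A:1,B:1):1,(C:1,D:1):1);")
  gt <- read_newick("(((A@1:1,C@1:1)90:1,(A@2:1,D@1:1)90:1)90:1,B@1:3);")
  fam <- gene_family(gt, id = "f1")
  pp <- enumerate_paralog_pairs(fam)
  rec <- place_pair(pp[1L, ], fam, stree)
  expect_false(rec$accepted)
  expect_equal(rec$reason, "no-matching-clade")
})

test_that("pairs whose MRCA is the gene-tree root are unplaceable", {
  stree <- read_newick("((A:1,B:1):1,C:2);")
  gt <- read_newick("((A@1:1,B@1:1)90:1,(A@2:1,C@1:1)90:2);")
  fam <- gene_family(gt, id = "f1")
  pp <- enumerate_paralog_pairs(fam)
  expect_equal(pp$mrca_node, ape::Ntip(gt) + 1L)
  rec <- place_pair(pp[1L, ], fam, stree)
  expect_false(rec$accepted)
  expect_equal(rec$reason, "root-unplaceable")
})

test_that("placement matches the exhaustive oracle on random scenarios", {
  set.seed(17)
  n_scen <- 120
  mismatches <- 0L
  for (i in seq_len(n_scen)) {
    stree <- ape::rtree(6, tip.label = paste0("S", 1:6))
    fam <- random_multilabel_family(paste0("S", 1:6), p_dup = 0.6)
    pp <- enumerate_paralog_pairs(fam)
    if (!nrow(pp)) next
    for (j in seq_len(nrow(pp))) {
      mine <- place_pair(pp[j, ], fam, stree)
      orac <- oracle_place_pair(pp[j, ], fam, stree)
      ok <- if (orac$reason == "accepted")
        isTRUE(mine$accepted) && mine$species_node == orac$node
      else !isTRUE(mine$accepted)
      if (!ok) mismatches <- mismatches + 1L
    }
  }
  expect_equal(mismatches, 0L)
})

test_that("unique tally counts one event per duplication node", {
  stree <- read_newick("((A:1,B:1):1,C:2);")
  gt <- read_newick(paste0("((((A@1:1,B@1:1)99:1,(A@2:1,B@2:1)98:1)97:1,",
                           "(A@3:1,B@3:1)96:2)95:1,C@1:4);"))
  fam <- gene_family(gt, id = "f1")
  recs <- place_families(list(fam), stree)
  # the pairs coalescing at the inner duplication node (support 97) fail the
  # sister check: that node's gene-tree sister is the other WGD copy, not a
  # species from the sister clade
  inner <- recs[recs$mrca_support == 97, ]
  expect_true(all(!inner$accepted & inner$reason == "sister-check-failed"))
  # the four pairs coalescing at the deeper node (support 95) share one
  # duplication: unique counts it once, all_pairs counts every pair
  tu <- tally_duplications(recs, "unique", support_min = 80)
  ta <- tally_duplications(recs, "all_pairs", support_min = 80)
  expect_true(all(tu$count <= ta$count[match(tu$node, ta$node)]))
  node_ab <- ape::getMRCA(stree, c("A", "B"))
  expect_equal(tu$count[tu$node == node_ab], 1L)
  expect_equal(ta$count[ta$node == node_ab], 4L)
})

test_that("the bootstrap filter excludes support below the threshold", {
  stree <- read_newick("((A:1,B:1):1,C:2);")
  gt <- read_newick("(((A@1:1,B@1:1)99:1,(A@2:1,B@2:1)98:1)79:1,C@1:3);")
  fam <- gene_family(gt, id = "f1")
  recs <- place_families(list(fam), stree)
  t80 <- tally_duplications(recs, "unique", support_min = 80)
  t50 <- tally_duplications(recs, "unique", support_min = 50)
  expect_equal(attr(t80, "total"), 0L)     # the MRCA node has support 79
  expect_equal(attr(t50, "total"), 1L)
})

test_that("raising the support threshold never increases tallies", {
  tr <- fixture_tree(8, seed = 5)
  wnode <- setdiff(unique(tr$edge[, 1L]), ape::Ntip(tr) + 1L)[2L]
  fams <- simulate_gene_families(
    wgd_scenario(tr, wgd_node = wnode, retention_prob = 0.5,
                 background_dup_rate = 0.1, n_families = 60, p_low = 0.3,
                 seed = 4))
  recs <- place_families(fams, tr)
  prev <- NULL
  for (thr in c(0, 30, 50, 80, 95)) {
    tl <- tally_duplications(recs, "unique", support_min = thr)
    cnt <- stats::setNames(tl$count, tl$node)
    if (!is.null(prev)) {
      common <- union(names(prev), names(cnt))
      a <- ifelse(is.na(prev[common]), 0L, prev[common])
      b <- ifelse(is.na(cnt[common]), 0L, cnt[common])
      expect_true(all(b <= a))
    }
    prev <- cnt
  }
})

test_that("accepted placements satisfy the set-equality invariant post hoc", {
  tr <- fixture_tree(8, seed = 5)
  wnode <- setdiff(unique(tr$edge[, 1L]), ape::Ntip(tr) + 1L)[2L]
  fams <- simulate_gene_families(
    wgd_scenario(tr, wgd_node = wnode, retention_prob = 0.6,
                 background_dup_rate = 0.15, loss_rate = 0.05,
                 n_families = 40, seed = 9))
  recs <- place_families(fams, tr)
  acc <- recs[recs$accepted, ]
  sets <- tip_sets <- lapply(seq_len(ape::Ntip(tr) + tr$Nnode), function(v)
    if (v <= ape::Ntip(tr)) tr$tip.label[v]
    else ape::extract.clade(tr, v)$tip.label)
  for (i in seq_len(nrow(acc))) {
    clade <- strsplit(acc$species_clade[i], ",")[[1L]]
    fam <- fams[[match(acc$family[i], vapply(fams, `[[`, "", "id"))]]
    present <- intersect(sets[[acc$species_node[i]]], family_species(fam))
    expect_setequal(present, clade)
  }
})
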