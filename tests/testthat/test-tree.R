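test_that("pairwise identity counts co-occupied columns only", {
  aln <- family_alignment(c("a", "b", "c", "d"),
                          c("AC-D", "AC-E", "A---", "---A"))
  m <- pairwise_identity_matrix(aln)
  expect_equal(diag(m), rep(1, 4), ignore_attr = TRUE)
  expect_equal(m["a", "b"], 2 / 3)
  expect_equal(m["c", "d"], 0)     # no shared columns
  expect_equal(m["a", "c"], 1)     # single shared column, identical
  expect_true(isSymmetric(m))
})

test_that("Kerf cut matches the worked 3-leaf example and degenerate cases", {
  tree <- ape::read.tree(text = "((A:1,B:1):1,C:2);")
  ids <- matrix(c(1, .9, .6,  .9, 1, .6,  .6, .6, 1), 3, 3,
                dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  cut <- kerf_cut(tree, ids, 0.7)
  expect_setequal(lapply(cut, function(x) sort(x$members)),
                  list(c("A", "B"), "C"))
  # nothing to cut when every pair clears the threshold
  cut1 <- kerf_cut(tree, ids, 0.5)
  expect_length(cut1, 1)
  expect_setequal(cut1[[1]]$members, c("A", "B", "C"))
  # single-leaf tree
  tr1 <- ape::read.tree(text = "(A:1);")
  expect_equal(kerf_cut(tr1, matrix(1, 1, 1, dimnames = list("A", "A")),
                        0.7)[[1]]$members, "A")
})

test_that("Kerf cut partitions leaves, respects the threshold, and is maximal", {
  set.seed(31)
  for (rep in 1:15) {
    n <- sample(4:10, 1)
    tree <- ape::rtree(n)
    tree$tip.label <- paste0("s", 1:n)
    ids <- matrix(runif(n * n, 0.2, 1), n, n,
                  dimnames = list(tree$tip.label, tree$tip.label))
    ids[lower.tri(ids)] <- t(ids)[lower.tri(ids)]
    diag(ids) <- 1
    thr <- runif(1, 0.4, 0.9)
    cut <- kerf_cut(tree, ids, thr)
    members <- unlist(lapply(cut, `[[`, "members"))
    expect_setequal(members, tree$tip.label)       # partition
    expect_equal(anyDuplicated(members), 0)
    for (cl in cut) {
      if (length(cl$members) > 1) {
        sub <- ids[cl$members, cl$members]
        expect_gte(min(sub[lower.tri(sub)]), thr)  # threshold holds inside
      }
      # maximality: the parent clade (if any) violates the threshold
      parent <- tree$edge[tree$edge[, 2] == cl$node_id, 1]
      if (length(parent) == 1) {
        ptips <- oracle_tips_under(tree, parent)
        psub <- ids[ptips, ptips]
        expect_lt(min(psub[lower.tri(psub)]), thr)
      }
    }
  }
})

test_that("species-overlap duplication inference matches the exhaustive oracle", {
  # worked examples
  tr <- ape::read.tree(text = "((a_hum:1,a_mus:1):1,(b_hum:1,b_mus:1):1);")
  taxa <- c(a_hum = "hum", a_mus = "mus", b_hum = "hum", b_mus = "mus")
  root <- orthoscan:::tree_root(tr)
  expect_equal(infer_duplication_nodes(tr, taxa), root)

  tr2 <- ape::read.tree(text = "((x1:1,x2:1):1,y:1);")
  expect_equal(infer_duplication_nodes(tr2, c(x1 = "t1", x2 = "t1", y = "t2")),
               5)  # the cherry's parent (root = 4 in ape numbering)
  expect_length(infer_duplication_nodes(tr2, c(x1 = "t1", x2 = "t2", y = "t3")),
                0)
  expect_error(infer_duplication_nodes(tr2, c(x1 = "t1", x2 = "t2")), "y")

  # random 16-leaf trees vs oracle
  for (seed in 1:10) {
    rt <- rand_taxon_tree(16, 6, seed)
    expect_setequal(infer_duplication_nodes(rt$tree, rt$taxa),
                    oracle_duplications(rt$tree, rt$taxa))
  }
})

test_that("super-ortholog groups match the exhaustive maximal-clade oracle", {
  tr <- ape::read.tree(text = "((a_hum:1,a_mus:1):1,(b_hum:1,b_mus:1):1);")
  taxa <- c(a_hum = "hum", a_mus = "mus", b_hum = "hum", b_mus = "mus")
  grp <- phog_t0_groups(tr, taxa)
  expect_setequal(lapply(grp, function(g) sort(g$members)),
                  list(c("a_hum", "a_mus"), c("b_hum", "b_mus")))

  # duplication-free tree: one group spanning all leaves
  tr3 <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  g3 <- phog_t0_groups(tr3, c(A = "t1", B = "t2", C = "t3"))
  expect_length(g3, 1)
  expect_setequal(g3[[1]]$members, c("A", "B", "C"))

  # chain of duplications: singletons
  tr4 <- ape::read.tree(text = "((p1:1,p2:1):1,p3:1);")
  g4 <- phog_t0_groups(tr4, c(p1 = "t1", p2 = "t1", p3 = "t1"))
  expect_setequal(lapply(g4, `[[`, "members"), list("p1", "p2", "p3"))

  for (seed in 11:20) {
    rt <- rand_taxon_tree(16, 5, seed)
    got <- lapply(phog_t0_groups(rt$tree, rt$taxa),
                  function(g) sort(g$members))
    expect_setequal(got, oracle_phog_groups(rt$tree, rt$taxa))
    # partition + no taxon repeated within a group
    members <- unlist(got)
    expect_setequal(members, rt$tree$tip.label)
    expect_equal(anyDuplicated(members), 0)
    for (g in got) expect_equal(anyDuplicated(rt$taxa[g]), 0)
  }
})

test_that("subtree bracketing matches the brute-force oracle and is disjoint", {
  lab <- function(...) list(source_name = "src", assignments = c(...))
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  # all-labeled-or-unlabeled single group with both root children labeled
  b1 <- subtree_bracket(tr, lab(A = "G1", B = "G1", D = "G1"))
  expect_length(b1, 1)
  expect_setequal(b1[[1]]$members, c("A", "B", "C", "D"))  # C swept in

  tr2 <- ape::read.tree(text = "((A:1,B:1):1,C:1);")
  b2 <- subtree_bracket(tr2, lab(A = "G1", B = "G1"))
  expect_length(b2, 1)
  expect_setequal(b2[[1]]$members, c("A", "B"))            # root fails

  expect_length(subtree_bracket(tr, lab()), 0)             # no labels at all

  set.seed(99)
  for (rep in 1:12) {
    n <- sample(8:16, 1)
    tree <- ape::rtree(n)
    tree$tip.label <- paste0("s", 1:n)
    labeled <- sample(tree$tip.label, sample(2:n, 1))
    asg <- stats::setNames(paste0("G", sample(1:3, length(labeled),
                                              replace = TRUE)), labeled)
    got <- subtree_bracket(tree, list(source_name = "x", assignments = asg))
    expect_setequal(vapply(got, `[[`, 0, "node_id"),
                    oracle_bracket_nodes(tree, asg))
    mem <- unlist(lapply(got, `[[`, "members"))
    expect_equal(anyDuplicated(mem), 0)                    # pairwise disjoint
  }
})

test_that("enclosing-clade resolution prefers the largest containing support", {
  tr <- ape::read.tree(text = "(((A:1,B:1):1,C:1):1,D:1);")
  sc <- function(node, src) {
    supported_clade(node, src, oracle_tips_under(tr, node))
  }
  ab <- 7  # node above A,B (root=5, next=6, then 7 under ape numbering)
  abc <- 6
  # top node inside a larger super-ortholog clade: the larger clade wins
  out <- resolve_enclosing_clade(tr, ab, list(sc(ab, "kerf"), sc(abc, "phog_t0")))
  expect_equal(out$node_id, abc)
  expect_setequal(out$members, c("A", "B", "C"))
  # top node itself supported, no supported ancestor
  out2 <- resolve_enclosing_clade(tr, ab, list(sc(ab, "kerf")))
  expect_equal(out2$node_id, ab)
  # no support overlaps: fall back to the node itself, flagged
  out3 <- resolve_enclosing_clade(tr, ab, list(sc(1, "kerf")))
  expect_equal(out3$node_id, ab)
  expect_equal(out3$support_sources, "none")
  expect_setequal(out3$members, c("A", "B"))
  # result always contains the top node's leaves
  expect_true(all(c("A", "B") %in% out$members))
  # size tie broken by source priority: bracket beats phog_t0
  out4 <- resolve_enclosing_clade(
    tr, ab, list(sc(abc, "phog_t0"), sc(abc, "bracket:oma")))
  expect_true("bracket:oma" %in% out4$support_sources)
})
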