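## Orthology structure on rooted gene trees: Kerf identity cuts,
## species-overlap duplication inference, super-ortholog (tree-distance zero)
## groups, subtree bracketing of third-party orthology labels, and
## enclosing-clade resolution.

tree_root <- function(tree) {
  setdiff(tree$edge[, 1], tree$edge[, 2])[1]
}

node_children <- function(tree, node) {
  tree$edge[tree$edge[, 1] == node, 2]
}

## tip labels under each node, indexed by node id (tips 1..n, internals n+1..)
tip_sets <- function(tree) {
  n <- length(tree$tip.label)
  sets <- phangorn::Descendants(tree, seq_len(n + tree$Nnode), type = "tips")
  lapply(sets, function(i) tree$tip.label[i])
}

#' Construct an orthology-supported clade
#'
#' @param node_id tree node id whose leaf set the clade covers
#' @param sources character vector of supporting evidence ("kerf", "phog_t0",
#'   "bracket:<source>", or "none")
#' @param members leaf labels under `node_id`
#' @return an object of class `supported_clade`
#' @export
supported_clade <- function(node_id, sources, members) {
  structure(list(node_id = node_id, support_sources = sources,
                 members = members), class = "supported_clade")
}

#' Kerf cut: partition a tree into maximal identity-consistent subtrees
#'
#' Cuts the tree into the unique set of maximal clades such that every leaf
#' pair within a clade has pairwise identity at least `min_identity`
#' (singletons allowed). Computed top-down: a clade is accepted iff its minimum
#' pairwise identity clears the threshold, otherwise its children are visited.
#'
#' @param tree rooted `phylo` whose tip labels index `identities`
#' @param identities symmetric identity matrix from
#'   [pairwise_identity_matrix()]
#' @param min_identity threshold in (0, 1]; the conventional default for
#'   ortholog-oriented cuts is 0.70
#' @return list of clades, each `list(node_id, members)`; members partition the
#'   leaf set
#' @export
kerf_cut <- function(tree, identities, min_identity = 0.70) {
  stopifnot(min_identity > 0, min_identity <= 1)
  sets <- tip_sets(tree)
  out <- list()
  visit <- function(node) {
    tips <- sets[[node]]
    ok <- if (length(tips) == 1) TRUE else {
      sub <- identities[tips, tips]
      min(sub[lower.tri(sub)]) >= min_identity
    }
    if (ok) {
      out[[length(out) + 1]] <<- list(node_id = node, members = tips)
    } else {
      for (ch in node_children(tree, node)) visit(ch)
    }
  }
  visit(tree_root(tree))
  out
}

#' Infer duplication nodes by the species-overlap rule
#'
#' An internal node is called a duplication iff at least two of its child
#' subtrees share at least one taxon: a speciation cannot leave the same
#' species on both sides of the split.
#'
#' @param tree rooted `phylo`
#' @param taxon_of named character vector mapping every tip label to a taxon
#' @return integer vector of duplication node ids (possibly empty)
#' @export
infer_duplication_nodes <- function(tree, taxon_of) {
  miss <- setdiff(tree$tip.label, names(taxon_of))
  if (length(miss) > 0) {
    stop("tips without taxon assignment: ", paste(miss, collapse = ", "))
  }
  n <- length(tree$tip.label)
  sets <- tip_sets(tree)
  internal <- (n + 1):(n + tree$Nnode)
  dup <- integer(0)
  for (node in internal) {
    kids <- node_children(tree, node)
    per_child <- lapply(kids, function(ch) unique(taxon_of[sets[[ch]]]))
    if (length(unlist(per_child)) > length(unique(unlist(per_child)))) {
      dup <- c(dup, node)
    }
  }
  dup
}

#' Super-ortholog groups (tree-distance threshold zero)
#'
#' Partitions the leaves into maximal clades containing no duplication node
#' anywhere within them; all sequences in such a clade are each other's
#' orthologs under the species-overlap interpretation, with no duplication
#' allowed after any speciation.
#'
#' @inheritParams infer_duplication_nodes
#' @param duplications optional precomputed duplication node ids
#' @return list of clades `list(node_id, members)` partitioning the leaf set
#' @export
phog_t0_groups <- function(tree, taxon_of, duplications = NULL) {
  if (is.null(duplications)) duplications <- infer_duplication_nodes(tree, taxon_of)
  n <- length(tree$tip.label)
  sets <- tip_sets(tree)
  ## nodes whose subtree (including themselves) contains a duplication
  tainted <- logical(n + tree$Nnode)
  if (length(duplications) > 0) {
    for (d in duplications) {
      tainted[d] <- TRUE
      anc <- phangorn::Ancestors(tree, d, type = "all")
      tainted[anc] <- TRUE
    }
  }
  out <- list()
  visit <- function(node) {
    if (!tainted[node]) {
      out[[length(out) + 1]] <<- list(node_id = node, members = sets[[node]])
    } else {
      for (ch in node_children(tree, node)) visit(ch)
    }
  }
  visit(tree_root(tree))
  out
}

#' Bracket maximal subtrees consistent with one external orthology group
#'
#' For a (possibly partial) labeling of leaves with orthology group ids,
#' returns the maximal subtrees whose labeled members all belong to a single
#' group and in which at least two children of the subtree root each contain a
#' labeled member of that group. Unlabeled leaves falling inside a bracket are
#' included. The two-children criterion generalises the left/right-child rule
#' to polytomies.
#'
#' @param tree rooted `phylo`
#' @param labeling `list(source_name, assignments)` with `assignments` a named
#'   character vector tip label -> group id (partial)
#' @return list of [supported_clade()] objects, pairwise disjoint
#' @export
subtree_bracket <- function(tree, labeling) {
  asg <- labeling$assignments
  n <- length(tree$tip.label)
  sets <- tip_sets(tree)
  out <- list()
  visit <- function(node) {
    if (node <= n) return(invisible())
    tips <- sets[[node]]
    labs <- asg[intersect(tips, names(asg))]
    ok <- FALSE
    if (length(labs) >= 1 && length(unique(labs)) == 1) {
      kids <- node_children(tree, node)
      with_lab <- sum(vapply(kids, function(ch)
        any(sets[[ch]] %in% names(asg)), logical(1)))
      ok <- with_lab >= 2
    }
    if (ok) {
      out[[length(out) + 1]] <<- supported_clade(
        node, paste0("bracket:", labeling$source_name), tips)
    } else {
      for (ch in node_children(tree, node)) visit(ch)
    }
  }
  visit(tree_root(tree))
  out
}

## All orthology-supported clades of a family: Kerf cuts, super-ortholog
## groups, and one bracket set per labeling source.
compute_supported_clades <- function(family, kerf_threshold = 0.70,
                                     identities = NULL) {
  if (is.null(identities)) identities <- pairwise_identity_matrix(family$alignment)
  taxa <- stats::setNames(family$seq_meta$taxon_id, family$seq_meta$seq_id)
  supports <- list()
  for (cl in kerf_cut(family$tree, identities, kerf_threshold)) {
    supports[[length(supports) + 1]] <-
      supported_clade(cl$node_id, "kerf", cl$members)
  }
  for (cl in phog_t0_groups(family$tree, taxa)) {
    supports[[length(supports) + 1]] <-
      supported_clade(cl$node_id, "phog_t0", cl$members)
  }
  for (lab in family$labelings) {
    supports <- c(supports, subtree_bracket(family$tree, lab))
  }
  supports
}

#' Resolve the enclosing clade around a placement node
#'
#' Returns the largest orthology-supported clade containing (or equal to) the
#' top-scoring node; if no supported clade contains it, the node itself is
#' returned flagged with support "none" (admissibility is decided downstream
#' by the preset). Ties on size are broken by source priority
#' bracket > phog_t0 > kerf, then by smallest node id.
#'
#' @param tree rooted `phylo`
#' @param top_node node id of the top-scoring subtree
#' @param supports list of [supported_clade()] objects
#' @return `list(node_id, support_sources, members)` of class
#'   `supported_clade`
#' @export
resolve_enclosing_clade <- function(tree, top_node, supports) {
  sets <- tip_sets(tree)
  top_tips <- sets[[top_node]]
  prio <- function(src) max(c(0, ifelse(grepl("^bracket:", src), 3,
                               ifelse(src == "phog_t0", 2,
                               ifelse(src == "kerf", 1, 0)))))
  containing <- Filter(function(s) all(top_tips %in% s$members), supports)
  if (length(containing) == 0) {
    return(supported_clade(top_node, "none", top_tips))
  }
  sizes <- vapply(containing, function(s) length(s$members), numeric(1))
  prios <- vapply(containing, function(s) prio(s$support_sources), numeric(1))
  ids <- vapply(containing, function(s) s$node_id, numeric(1))
  ord <- order(-sizes, -prios, ids)
  best <- containing[[ord[1]]]
  ## merge sources of every support at the winning node
  same <- Filter(function(s) s$node_id == best$node_id, containing)
  best$support_sources <- unique(unlist(lapply(same, `[[`, "support_sources")))
  best
}
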