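# Independent brute-force oracles used across the suite. Each reimplements a
# quantity from first principles (enumeration/recursion on the definition),
# deliberately sharing no code with the package internals it checks.

# --- tree plumbing (recursive, no phangorn) ---------------------------------

oracle_children <- function(tree, node) tree$edge[tree$edge[, 1] == node, 2]

oracle_root <- function(tree) setdiff(tree$edge[, 1], tree$edge[, 2])[1]

oracle_tips_under <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  unlist(lapply(oracle_children(tree, node), oracle_tips_under, tree = tree))
}

oracle_internal_nodes <- function(tree) {
  n <- length(tree$tip.label)
  (n + 1):(n + tree$Nnode)
}

# --- species overlap / super-orthologs / brackets ---------------------------

oracle_duplications <- function(tree, taxon_of) {
  dups <- integer(0)
  for (node in oracle_internal_nodes(tree)) {
    kids <- oracle_children(tree, node)
    sets <- lapply(kids, function(k) unique(taxon_of[oracle_tips_under(tree, k)]))
    overlap <- FALSE
    if (length(kids) >= 2) {
      for (a in 1:(length(kids) - 1)) {
        for (b in (a + 1):length(kids)) {
          if (length(intersect(sets[[a]], sets[[b]])) > 0) overlap <- TRUE
        }
      }
    }
    if (overlap) dups <- c(dups, node)
  }
  dups
}

oracle_phog_groups <- function(tree, taxon_of) {
  dups <- oracle_duplications(tree, taxon_of)
  n <- length(tree$tip.label)
  clean <- function(node) {
    # TRUE iff no duplication node inside the subtree rooted here
    if (node <= n) return(TRUE)
    if (node %in% dups) return(FALSE)
    all(vapply(oracle_children(tree, node), clean, logical(1)))
  }
  nodes <- c(seq_len(n), oracle_internal_nodes(tree))
  ok <- nodes[vapply(nodes, clean, logical(1))]
  has_parent_ok <- function(node) {
    parents <- tree$edge[tree$edge[, 2] == node, 1]
    length(parents) > 0 && parents[1] %in% ok
  }
  maximal <- ok[!vapply(ok, has_parent_ok, logical(1))]
  lapply(maximal, function(node) sort(oracle_tips_under(tree, node)))
}

oracle_bracket_nodes <- function(tree, assignments) {
  labs_of <- function(node) {
    tips <- oracle_tips_under(tree, node)
    assignments[intersect(tips, names(assignments))]
  }
  qualifies <- function(node) {
    labs <- labs_of(node)
    if (length(labs) < 1 || length(unique(labs)) != 1) return(FALSE)
    kids <- oracle_children(tree, node)
    sum(vapply(kids, function(k)
      any(oracle_tips_under(tree, k) %in% names(assignments)),
      logical(1))) >= 2
  }
  ok <- Filter(qualifies, oracle_internal_nodes(tree))
  strict_anc_ok <- function(node) {
    any(vapply(setdiff(ok, node), function(a)
      node %in% oracle_descendant_nodes(tree, a), logical(1)))
  }
  Filter(function(node) !strict_anc_ok(node), ok)
}

oracle_descendant_nodes <- function(tree, node) {
  kids <- oracle_children(tree, node)
  c(kids, unlist(lapply(kids[kids > length(tree$tip.label)],
                        oracle_descendant_nodes, tree = tree)))
}

# --- profile HMM forward by path enumeration --------------------------------

# Exhaustive path enumeration mirroring the scoring semantics: free query
# flanks, insert states I_1..I_{K-1} only, glocal exits via M_K/D_K, local
# with uniform entry/exit over match states. Returns the forward log-odds.
oracle_forward <- function(hmm, code, mode = "glocal") {
  K <- hmm$n_match
  L <- length(code)
  em <- hmm$em_logodds     # K x 21
  tr <- hmm$log_trans      # (K+1) x 9, rows k = 0..K
  ci <- function(t) match(t, c("MM","MI","MD","IM","II","ID","DM","DD","DI"))
  weights <- c()
  rec <- function(type, k, i, lw) {
    if (type == "M" && mode == "local") {
      weights <<- c(weights, lw - log(K))     # exit allowed from any match
    }
    if (type == "M" && k == K && mode == "glocal") {
      weights <<- c(weights, lw + tr[K + 1, ci("MM")])
    }
    if (type == "D" && k == K && mode == "glocal") {
      weights <<- c(weights, lw + tr[K + 1, ci("DM")])
    }
    if (k >= K) return(invisible())
    row <- k + 1
    pre <- substr(type, 1, 1)
    if (i < L) {
      rec("M", k + 1, i + 1,
          lw + tr[row, ci(paste0(pre, "M"))] + em[k + 1, code[i + 1]])
    }
    rec("D", k + 1, i, lw + tr[row, ci(paste0(pre, "D"))])
    if (k >= 1 && k <= K - 1 && i < L) {
      rec("I", k, i + 1, lw + tr[row, ci(paste0(pre, "I"))])
    }
  }
  if (mode == "glocal") {
    for (f in 0:L) rec("M", 0, f, 0)
  } else {
    for (f in 0:(L - 1)) {
      for (k in 1:K) {
        rec("M", k, f + 1, -log(K) + em[k, code[f + 1]])
      }
    }
  }
  m <- max(weights)
  m + log(sum(exp(weights - m)))
}

# --- pairwise alignment by exhaustive enumeration ---------------------------

# Optimal global affine-gap score: gap of length l costs open + l * ext
# (the Biostrings convention), substitution scores from `submat`. Pure
# recursion over all alignments; lengths must be tiny.
oracle_global_score <- function(a, b, submat, open = 10, ext = 1) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(av) && j > length(bv)) return(0)
    best <- -Inf
    if (i <= length(av) && j <= length(bv)) {
      best <- max(best, submat[av[i], bv[j]] + rec(i + 1, j + 1, "m"))
    }
    if (i <= length(av)) {
      cost <- if (state == "ga") ext else open + ext
      best <- max(best, -cost + rec(i + 1, j, "ga"))
    }
    if (j <= length(bv)) {
      cost <- if (state == "gb") ext else open + ext
      best <- max(best, -cost + rec(i, j + 1, "gb"))
    }
    best
  }
  rec(1, 1, "m")
}

# --- misc -------------------------------------------------------------------

oracle_ktuple <- function(a, b, k) {
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  na <- length(av) - k + 1; nb <- length(bv) - k + 1
  if (na < 1 || nb < 1) return(0)
  hits <- 0
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (all(av[i:(i + k - 1)] == bv[j:(j + k - 1)])) hits <- hits + 1
    }
  }
  hits / (na * nb)
}

# transitive closure partition of a symmetric logical adjacency matrix
oracle_closure_partition <- function(adj) {
  reach <- adj | diag(TRUE, nrow(adj))
  repeat {
    nxt <- (reach %*% reach) > 0
    if (identical(nxt, reach)) break
    reach <- nxt
  }
  comp <- rep(NA_integer_, nrow(adj))
  cl <- 0
  for (i in seq_len(nrow(adj))) {
    if (is.na(comp[i])) { cl <- cl + 1; comp[which(reach[i, ])] <- cl }
  }
  comp
}

# random rooted tree with taxa assigned to tips
rand_taxon_tree <- function(n, n_taxa, seed) {
  set.seed(seed)
  tree <- ape::rtree(n)
  tree$tip.label <- sprintf("s%02d", seq_len(n))
  taxa <- stats::setNames(sprintf("t%02d", sample.int(n_taxa, n, replace = TRUE)),
                          tree$tip.label)
  list(tree = tree, taxa = taxa)
}
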