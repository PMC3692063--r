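## Seeded gene-family simulator with known orthology ground truth, plus the
## leave-one-out placement benchmark harness.
##
## Construction: each family is a duplication backbone joining g
## speciation-only group subtrees. Every group's leaves carry distinct taxa
## and every group contains an anchor taxon shared across groups, so the
## species-overlap rule recovers exactly the backbone nodes as duplications
## and the super-ortholog groups equal the simulated ground truth. Sequences
## evolve from a random ancestral protein with one uniform-replacement
## substitution draw per branch per site; a global branch-length scale is
## tuned by bisection so within-group identity stays above and between-group
## identity below the configured targets.

#' Simulation configuration
#'
#' Defaults state the benchmark world: 20 families of 12-32 leaves over 12
#' taxa, duplication-delimited orthology groups with within-group identity
#' >= 0.70 and between-group identity <= 0.50, mixed curation tiers and
#' evidence codes.
#'
#' @param n_families number of families
#' @param leaves_range inclusive range of leaves per family
#' @param n_taxa number of taxa (caps group size: taxa are unique in a group)
#' @param duplication_prob controls the expected number of duplication-
#'   delimited groups; 0 forces a single group
#' @param seq_length ancestral protein length (residues)
#' @param subst_rate substitutions per site per unit branch length
#' @param within_group_identity_min,between_group_identity_max identity targets
#' @param tier_mix probabilities of curated/automatic curation tiers
#' @param evidence_mix probabilities of the three evidence tiers
#' @param label_keep_frac fraction of each group labeled by the two simulated
#'   third-party orthology sources (partial labels exercise bracketing)
#' @param seed master seed; generation is fully reproducible from it
#' @param max_retries attempts before declaring identity targets unattainable
#' @return a `simulation_config` list
#' @export
simulation_config <- function(n_families = 20, leaves_range = c(12, 32),
                              n_taxa = 12, duplication_prob = 0.5,
                              seq_length = 100, subst_rate = 1,
                              within_group_identity_min = 0.70,
                              between_group_identity_max = 0.50,
                              tier_mix = c(curated = 0.3, automatic = 0.7),
                              evidence_mix = c(experimental = 0.2,
                                               curated = 0.3,
                                               computational = 0.5),
                              label_keep_frac = 0.8, seed = 42,
                              max_retries = 8) {
  stopifnot(leaves_range[1] >= 3, leaves_range[2] >= leaves_range[1],
            duplication_prob >= 0, duplication_prob <= 1,
            within_group_identity_min > between_group_identity_max)
  structure(list(n_families = n_families, leaves_range = leaves_range,
                 n_taxa = n_taxa, duplication_prob = duplication_prob,
                 seq_length = seq_length, subst_rate = subst_rate,
                 within_group_identity_min = within_group_identity_min,
                 between_group_identity_max = between_group_identity_max,
                 tier_mix = tier_mix, evidence_mix = evidence_mix,
                 label_keep_frac = label_keep_frac, seed = seed,
                 max_retries = max_retries),
            class = "simulation_config")
}

## random rooted binary topology as a nested list of leaf labels
rand_topology <- function(labels) {
  if (length(labels) == 1) return(labels)
  labels <- sample(labels)
  cut <- if (length(labels) == 2) 1 else sample(seq_len(length(labels) - 1), 1)
  list(rand_topology(labels[seq_len(cut)]),
       rand_topology(labels[-seq_len(cut)]))
}

## newick string with branch lengths drawn from `draw_bl()` at every edge
topo_to_newick <- function(topo, draw_bl) {
  render <- function(node) {
    if (is.character(node)) return(node)
    paste0("(", render(node[[1]]), ":", format(draw_bl(), nsmall = 6),
           ",", render(node[[2]]), ":", format(draw_bl(), nsmall = 6), ")")
  }
  paste0(render(topo), ";")
}

## evolve sequences down `tree` with per-edge precomputed mutation draws;
## returns integer matrix (tips x sites)
evolve_sequences <- function(tree, root_seq, u, roll, rate, scale) {
  n <- length(tree$tip.label)
  L <- length(root_seq)
  seqs <- matrix(0L, n, L)
  node_seq <- vector("list", n + tree$Nnode)
  node_seq[[tree_root(tree)]] <- root_seq
  ord <- ape::reorder.phylo(tree, "cladewise")$edge
  for (e in seq_len(nrow(tree$edge))) {
    parent <- ord[e, 1]; child <- ord[e, 2]
    ei <- which(tree$edge[, 1] == parent & tree$edge[, 2] == child)[1]
    p <- 1 - exp(-rate * scale * tree$edge.length[ei])
    s <- node_seq[[parent]]
    mut <- u[ei, ] < p
    s[mut] <- ((s[mut] - 1L + roll[ei, mut]) %% 20L) + 1L
    node_seq[[child]] <- s
    if (child <= n) seqs[child, ] <- s
  }
  rownames(seqs) <- tree$tip.label
  seqs
}

seq_identity <- function(a, b) mean(a == b)

#' Simulate one family with known orthology ground truth
#'
#' @param config a [simulation_config()]
#' @param family_index index used for naming and seed derivation
#' @return list(family = `ortho_family` (labelings include the full "truth"
#'   source plus two partial pseudo-sources), truth = named group map,
#'   scale = fitted branch-length scale)
#' @export
simulate_family <- function(config, family_index = 1) {
  cfg <- config
  with_seed(derive_seed(cfg$seed, family_index), {
    for (attempt in seq_len(cfg$max_retries)) {
      sizes_pool <- seq(cfg$leaves_range[1], cfg$leaves_range[2])
      n_leaves <- sizes_pool[sample.int(length(sizes_pool), 1)]
      if (cfg$duplication_prob == 0) {
        if (n_leaves > cfg$n_taxa) {
          stop("duplication_prob = 0 requires leaves <= n_taxa (",
               cfg$n_taxa, "); got ", n_leaves)
        }
        g <- 1L
      } else {
        gmin <- max(1L, as.integer(ceiling(n_leaves / cfg$n_taxa)))
        gmax <- max(gmin, n_leaves %/% 3L)
        g <- min(max(gmin, 1L + stats::rbinom(1, 3, cfg$duplication_prob)), gmax)
      }
      sizes <- rep(n_leaves %/% g, g)
      extra <- n_leaves - sum(sizes)
      if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L

      leaf_ids <- lapply(seq_len(g), function(gi)
        sprintf("F%03dG%02dL%02d", family_index, gi, seq_len(sizes[gi])))
      taxa <- lapply(seq_len(g), function(gi) {
        pool <- if (sizes[gi] > 1)
          c(1L, sample(2:cfg$n_taxa, sizes[gi] - 1L)) else 1L
        sample(pool)  # anchor taxon 1 in every group, order randomised
      })

      grp_nwk <- vapply(seq_len(g), function(gi)
        sub(";$", "", topo_to_newick(rand_topology(leaf_ids[[gi]]),
                                     function() stats::runif(1, 0.01, 0.04))),
        character(1))
      nwk <- if (g == 1) paste0(grp_nwk, ";") else {
        topo <- rand_topology(as.character(seq_len(g)))
        render <- function(node) {
          if (is.character(node)) return(grp_nwk[as.integer(node)])
          paste0("(", render(node[[1]]), ":",
                 format(stats::runif(1, 0.5, 1.0), nsmall = 6), ",",
                 render(node[[2]]), ":",
                 format(stats::runif(1, 0.5, 1.0), nsmall = 6), ")")
        }
        paste0(render(topo), ";")
      }
      tree <- ape::read.tree(text = nwk)

      root_seq <- sample.int(20L, cfg$seq_length, replace = TRUE)
      ne <- nrow(tree$edge)
      u <- matrix(stats::runif(ne * cfg$seq_length), ne)
      roll <- matrix(sample.int(19L, ne * cfg$seq_length, replace = TRUE), ne)

      group_of <- stats::setNames(
        rep(sprintf("G%02d", seq_len(g)), sizes), unlist(leaf_ids))

      stats_at <- function(scale) {
        seqs <- evolve_sequences(tree, root_seq, u, roll, cfg$subst_rate, scale)
        ids <- rownames(seqs)
        win <- 1; btw <- 0
        for (i in seq_len(nrow(seqs) - 1)) {
          for (j in (i + 1):nrow(seqs)) {
            idt <- seq_identity(seqs[i, ], seqs[j, ])
            if (group_of[ids[i]] == group_of[ids[j]]) win <- min(win, idt)
            else btw <- max(btw, idt)
          }
        }
        list(seqs = seqs, min_within = win, max_between = btw)
      }
      target <- if (g > 1) cfg$between_group_identity_max - 0.05 else
        cfg$within_group_identity_min + 0.10
      lo <- 0.02; hi <- 8
      for (it in 1:30) {
        mid <- (lo + hi) / 2
        st <- stats_at(mid)
        val <- if (g > 1) st$max_between else st$min_within
        if (val > target) lo <- mid else hi <- mid
      }
      st <- stats_at((lo + hi) / 2)
      scale <- (lo + hi) / 2
      ok <- st$min_within >= cfg$within_group_identity_min &&
        (g == 1 || st$max_between <= cfg$between_group_identity_max)
      if (!ok) next

      tree$edge.length <- tree$edge.length * scale
      ids <- rownames(st$seqs)
      rows <- apply(st$seqs, 1, function(cd)
        paste(AA_LETTERS[cd], collapse = ""))
      aln <- family_alignment(ids, unname(rows), occupancy_min = 0.5)
      taxon_of <- stats::setNames(
        sprintf("t%02d", unlist(taxa)), unlist(leaf_ids))[ids]
      tiers <- sample(names(cfg$tier_mix), length(ids), replace = TRUE,
                      prob = cfg$tier_mix)
      seq_meta <- data.frame(seq_id = ids, taxon_id = unname(taxon_of),
                             curation_tier = tiers, stringsAsFactors = FALSE)

      labelings <- list(truth = list(source_name = "truth",
                                     assignments = group_of[ids]))
      for (src in c("simOMA", "simMCL")) {
        kept <- unlist(lapply(split(ids, group_of[ids]), function(mem) {
          k <- max(min(length(mem), 2L),
                   as.integer(round(cfg$label_keep_frac * length(mem))))
          sample(mem, k)
        }))
        labelings[[src]] <- list(
          source_name = src,
          assignments = stats::setNames(
            paste0(src, "_", group_of[kept]), kept))
      }

      vocab <- c("ATP-dependent transporter", "serine protease",
                 "zinc-finger regulator", "NADH dehydrogenase subunit",
                 "ribosomal assembly factor", "glycosyl hydrolase")
      ann <- do.call(rbind, lapply(ids, function(id) {
        gi <- as.integer(sub("G", "", group_of[[id]]))
        word <- vocab[((family_index + gi) %% length(vocab)) + 1]
        rbind(
          data.frame(seq_id = id, kind = "description",
                     value = sprintf("%s subfamily %d", word, gi),
                     evidence = sample(names(cfg$evidence_mix), 1,
                                       prob = cfg$evidence_mix)),
          data.frame(seq_id = id, kind = "go_term",
                     value = sprintf("GO:%07d", family_index * 100 + gi),
                     evidence = sample(names(cfg$evidence_mix), 1,
                                       prob = cfg$evidence_mix)))
      }))
      fam <- ortho_family(sprintf("fam%03d", family_index), aln, tree,
                          seq_meta = seq_meta, labelings = labelings,
                          annotations = ann, family_type = "mda")
      return(list(family = fam, truth = group_of[ids], scale = scale))
    }
    stop("identity targets unattainable after ", cfg$max_retries,
         " attempts for family ", family_index)
  })
}

#' Simulate a family library
#'
#' @param config a [simulation_config()]
#' @param out_dir optional directory; families are written one subdirectory
#'   each via [write_family()]
#' @return named list of `ortho_family` objects (each carries its truth map in
#'   the "truth" labeling), with the config stored as an attribute
#' @export
simulate_library <- function(config = simulation_config(), out_dir = NULL) {
  sims <- lapply(seq_len(config$n_families), function(i)
    simulate_family(config, i))
  fams <- lapply(sims, `[[`, "family")
  names(fams) <- vapply(fams, `[[`, "", "family_id")
  if (!is.null(out_dir)) {
    for (f in fams) write_family(f, file.path(out_dir, f$family_id))
  }
  attr(fams, "sim_config") <- config
  fams
}

#' Leave-one-out placement benchmark
#'
#' For every family and every leaf, withholds the leaf, rebuilds the subtree
#' HMMs on the pruned family and classifies the held-out sequence to the
#' top-scoring node. Precision is the fraction of classifications whose top
#' node falls inside the held-out sequence's true orthology group, among
#' classifications passing the Stage 2 criteria; recall is the fraction of
#' held-out sequences classified at all.
#'
#' @param library list of simulated `ortho_family` objects carrying a "truth"
#'   labeling
#' @param config a [preset_config()] (default high-recall settings)
#' @param seed calibration seed
#' @return object of class `loo_benchmark`: list(results, precision,
#'   n_classified, n_total, recall, per_family); precision is NA (undefined,
#'   distinct from 0) when nothing passes Stage 2
#' @export
run_loo_benchmark <- function(library, config = preset_config(), seed = 1) {
  rows <- list()
  for (fam in library_families(library)) {
    truth <- fam$labelings[["truth"]]$assignments
    ## one cache and one seed per family: HMMs and calibrations for subtrees
    ## untouched by the pruning are shared across its leave-one-out runs
    cache <- new.env(parent = emptyenv())
    fam_seed <- derive_seed(seed, fam$family_id)
    for (id in fam$alignment$row_ids) {
      r <- leave_one_out_placement(fam, id, config, truth = truth,
                                   seed = fam_seed, cache = cache)
      rows[[length(rows) + 1]] <- data.frame(
        family_id = fam$family_id, held_out = id,
        skipped = r$skipped,
        passes = if (r$skipped) NA else r$placement$passes_stage2,
        correct = if (r$skipped) NA else r$correct,
        bit_score = if (r$skipped) NA_real_ else r$placement$score$bit_score,
        top_node = if (r$skipped) NA_integer_ else r$placement$top_node_id,
        top_leaves = if (r$skipped) "" else
          paste(r$placement$top_leaves, collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, rows)
  summarize_loo(results)
}

summarize_loo <- function(results) {
  done <- results[!results$skipped, , drop = FALSE]
  passing <- done[done$passes, , drop = FALSE]
  per_family <- do.call(rbind, lapply(split(done, done$family_id), function(d) {
    p <- d[d$passes, , drop = FALSE]
    data.frame(family_id = d$family_id[1], n = nrow(d),
               n_classified = nrow(p),
               precision = if (nrow(p)) mean(p$correct) else NA_real_)
  }))
  rownames(per_family) <- NULL
  structure(list(
    results = results,
    precision = if (nrow(passing)) mean(passing$correct) else NA_real_,
    precision_defined = nrow(passing) > 0,
    n_classified = nrow(passing), n_total = nrow(done),
    recall = if (nrow(done)) nrow(passing) / nrow(done) else NA_real_,
    per_family = per_family), class = "loo_benchmark")
}

#' @export
print.loo_benchmark <- function(x, ...) {
  cat(sprintf("<loo_benchmark> precision %s over %d/%d classified placements\n",
              if (x$precision_defined) sprintf("%.4f", x$precision) else
                "undefined (none passing)",
              x$n_classified, x$n_total))
  invisible(x)
}

#' Re-score a benchmark under a different ground truth
#'
#' Recomputes correctness of stored placements against an alternative truth
#' map (e.g. permuted labels as a negative control) without re-running any
#' placement.
#'
#' @param bench a `loo_benchmark`
#' @param truth_maps named list: family_id -> named character vector
#'   seq_id -> group
#' @return a new `loo_benchmark` with correctness and precision recomputed
#' @export
benchmark_precision <- function(bench, truth_maps) {
  res <- bench$results
  for (i in seq_len(nrow(res))) {
    if (isTRUE(res$skipped[i])) next
    truth <- truth_maps[[res$family_id[i]]]
    grp <- names(truth)[truth == truth[[res$held_out[i]]]]
    top <- strsplit(res$top_leaves[i], ";", fixed = TRUE)[[1]]
    res$correct[i] <- all(top %in% setdiff(grp, res$held_out[i]))
  }
  summarize_loo(res)
}
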