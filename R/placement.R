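## Stages 1-2: family-root HMM scan and exhaustive subtree-HMM placement.

#' Pipeline preset configuration
#'
#' Four preset parameter families cover common use cases; every parameter can
#' be overridden individually. The exact numeric defaults are this package's
#' own calibration of the qualitative preset descriptions (see the methods
#' vignette): high_recall is the default and tolerant of small gene-model
#' errors; high_precision restricts orthologs to near-global, high-identity
#' alignments and requires orthology support for the placement subtree;
#' remote_homolog relaxes E-value, overlap and identity constraints;
#' partial_sequence drops query-coverage constraints for incomplete inputs.
#'
#' @param preset one of "high_recall", "high_precision", "remote_homolog",
#'   "partial_sequence", "custom"
#' @param ... individual parameter overrides (e.g. `stage3_identity_min = 0.5`)
#' @return a `preset_config` list
#' @export
preset_config <- function(preset = c("high_recall", "high_precision",
                                     "remote_homolog", "partial_sequence",
                                     "custom"), ...) {
  preset <- match.arg(preset)
  base <- list(
    preset_name = preset,
    stage1_evalue_max = 1e-3, stage1_query_coverage_min = 0.5,
    stage2_evalue_max = 1e-3, stage2_query_coverage_min = 0.5,
    stage2_model_coverage_min = 0.3,
    stage3_identity_min = 0.30, stage3_query_coverage_min = 0.5,
    stage3_subject_coverage_min = 0.3,
    require_orthology_support = FALSE,
    align_mode = "overlap",
    max_query_length = 2000,
    kerf_threshold = 0.70,
    occupancy_min = 0.5, pseudocount_alpha = 0.5,
    intra_identity_min = 0.97,
    calibration_n = 100,
    fastcat = FALSE, fastcat_k = 4, fastcat_top_n = 10, fastcat_min_subtree = 5
  )
  tweaks <- switch(preset,
    high_recall = list(),
    high_precision = list(
      stage1_evalue_max = 1e-5, stage2_evalue_max = 1e-5,
      stage1_query_coverage_min = 0.8, stage2_query_coverage_min = 0.8,
      stage2_model_coverage_min = 0.8,
      stage3_identity_min = 0.60, stage3_query_coverage_min = 0.8,
      stage3_subject_coverage_min = 0.8,
      require_orthology_support = TRUE, align_mode = "global"),
    remote_homolog = list(
      stage1_evalue_max = 1.0, stage2_evalue_max = 1.0,
      stage1_query_coverage_min = 0.3, stage2_query_coverage_min = 0.3,
      stage2_model_coverage_min = 0.3,
      stage3_identity_min = 0.15, stage3_query_coverage_min = 0.3,
      stage3_subject_coverage_min = 0.3, align_mode = "local"),
    partial_sequence = list(
      stage1_query_coverage_min = 0, stage2_query_coverage_min = 0,
      stage2_model_coverage_min = 0,
      stage3_query_coverage_min = 0, stage3_subject_coverage_min = 0.5,
      align_mode = "global_local"),
    custom = list())
  cfg <- utils::modifyList(base, tweaks)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad) > 0) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  cfg <- utils::modifyList(cfg, over)
  fracs <- c("stage1_query_coverage_min", "stage2_query_coverage_min",
             "stage2_model_coverage_min", "stage3_identity_min",
             "stage3_query_coverage_min", "stage3_subject_coverage_min",
             "kerf_threshold", "occupancy_min", "intra_identity_min")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) stop(f, " must lie in [0, 1]")
  }
  if (cfg$stage1_evalue_max <= 0 || cfg$stage2_evalue_max <= 0) {
    stop("E-value bounds must be positive")
  }
  structure(cfg, class = "preset_config")
}

scoring_mode <- function(family) {
  if (identical(family$family_type, "domain")) "local" else "glocal"
}

## Build (or fetch from cache) the HMM for the row subset under one tree node.
node_hmm <- function(family, tips, config, cache = NULL) {
  key <- NULL
  if (!is.null(cache)) {
    key <- paste0(family$family_id, "|",
                  paste(which(family$alignment$match_mask), collapse = "."),
                  "|", paste(sort(tips), collapse = ","))
    if (!is.null(cache[[key]])) return(cache[[key]])
  }
  hmm <- build_profile_hmm(family$alignment, row_subset = tips,
                           pseudocount_alpha = config$pseudocount_alpha)
  if (!is.null(cache)) cache[[key]] <- hmm
  hmm
}

#' Stage 1: scan family-root HMMs
#'
#' Scores the query against the HMM at the root of each family tree (built
#' from all rows). Families whose calibrated E-value is at most
#' `stage1_evalue_max` and whose query coverage reaches
#' `stage1_query_coverage_min` pass, sorted by ascending E-value. `db_size`
#' for the E-values is the number of families scanned.
#'
#' @param query a [sequence_record()]
#' @param library named list of `ortho_family` objects (or a `family_library`)
#' @param config a [preset_config()]
#' @param seed seed for E-value calibration draws
#' @return data.frame (family_id, bit_score, e_value, query_coverage,
#'   model_coverage) of passing families
#' @export
stage1_family_scan <- function(query, library, config = preset_config(),
                               seed = 1) {
  families <- library_families(library)
  if (length(families) == 0) stop("family library is empty")
  cache <- library_cache(library)
  rows <- lapply(seq_along(families), function(i) {
    fam <- families[[i]]
    hmm <- node_hmm(fam, fam$alignment$row_ids, config, cache)
    hmm <- calibrate_evalue(hmm, n_random = config$calibration_n,
                            seed = derive_seed(seed, 101, i),
                            db_size = length(families),
                            mode = scoring_mode(fam))
    sc <- score_sequence(hmm, query, mode = scoring_mode(fam))
    data.frame(family_id = fam$family_id, bit_score = sc$bit_score,
               e_value = sc$e_value, query_coverage = sc$query_coverage,
               model_coverage = sc$model_coverage, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  pass <- tab$e_value <= config$stage1_evalue_max &
    tab$query_coverage >= config$stage1_query_coverage_min
  out <- tab[pass, , drop = FALSE]
  out <- out[order(out$e_value, out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "all_scores") <- tab
  out
}

#' Stage 2: place the query at the top-scoring subtree node
#'
#' Builds an HMM for every node of the family tree (leaves included, as
#' single-sequence models) on the family's shared match mask, scores the query
#' against each, and takes the node with the maximal forward bit score. Ties
#' are broken toward the most specific placement (fewest leaves), then the
#' smallest node id. The top model is then calibrated and the stage criteria
#' (E-value, query/model coverage, and optionally orthology support of the
#' subtree) are evaluated; violations are recorded, not raised.
#'
#' @param query a [sequence_record()]
#' @param family an `ortho_family`
#' @param config a [preset_config()]
#' @param supports optional precomputed list of supported clades (computed on
#'   demand when `require_orthology_support` is set)
#' @param seed calibration seed
#' @param cache optional HMM cache environment
#' @return object of class `subtree_placement`: family_id, top_node_id, score
#'   (`hmm_score`), node_scores, passes_stage2, failure_reasons
#' @export
stage2_place <- function(query, family, config = preset_config(),
                         supports = NULL, seed = 1, cache = NULL) {
  tree <- family$tree
  n <- length(tree$tip.label)
  sets <- tip_sets(tree)
  nodes <- seq_len(n + tree$Nnode)
  mode <- scoring_mode(family)
  qcode <- encode_residues(query$residues)
  bits <- numeric(length(nodes))
  hmms <- vector("list", length(nodes))
  for (node in nodes) {
    hmm <- node_hmm(family, sets[[node]], config, cache)
    hmms[[node]] <- hmm
    bits[node] <- cpp_forward_only(hmm$em_logodds, hmm$log_trans, qcode,
                                   if (mode == "local") 1L else 0L) / log(2)
  }
  nleaves <- lengths(sets)
  ord <- order(-bits, nleaves, nodes)
  top <- nodes[ord[1]]

  ## calibration depends only on the model content, the draw count and the
  ## seed, so it is cached alongside the HMM when a cache is supplied
  calib_key <- if (!is.null(cache)) {
    paste0(family$family_id, "|calib|", mode, "|", config$calibration_n, "|",
           seed, "|", length(nodes), "|",
           paste(which(family$alignment$match_mask), collapse = "."), "|",
           paste(sort(sets[[top]]), collapse = ","))
  } else NULL
  top_hmm <- if (!is.null(calib_key) && !is.null(cache[[calib_key]])) {
    cache[[calib_key]]
  } else {
    h <- calibrate_evalue(hmms[[top]], n_random = config$calibration_n,
                          seed = derive_seed(seed, 202),
                          db_size = length(nodes), mode = mode)
    if (!is.null(calib_key)) cache[[calib_key]] <- h
    h
  }
  score <- score_sequence(top_hmm, query, mode = mode)

  reasons <- character(0)
  if (score$e_value > config$stage2_evalue_max) {
    reasons <- c(reasons, sprintf("e_value>%g", config$stage2_evalue_max))
  }
  if (score$query_coverage < config$stage2_query_coverage_min) {
    reasons <- c(reasons, sprintf("query_coverage<%g", config$stage2_query_coverage_min))
  }
  if (score$model_coverage < config$stage2_model_coverage_min) {
    reasons <- c(reasons, sprintf("model_coverage<%g", config$stage2_model_coverage_min))
  }
  if (config$require_orthology_support) {
    if (is.null(supports)) {
      supports <- compute_supported_clades(family, config$kerf_threshold)
    }
    top_tips <- sets[[top]]
    inside <- any(vapply(supports, function(s) all(top_tips %in% s$members),
                         logical(1)))
    if (!inside) reasons <- c(reasons, "no_orthology_support")
  }
  structure(list(family_id = family$family_id, top_node_id = top,
                 top_leaves = sets[[top]], score = score,
                 node_bits = stats::setNames(bits, nodes),
                 passes_stage2 = length(reasons) == 0,
                 failure_reasons = reasons),
            class = "subtree_placement")
}

#' @export
print.subtree_placement <- function(x, ...) {
  cat(sprintf("<subtree_placement> family %s node %d (%d leaves) %.2f bits E=%s %s\n",
              x$family_id, x$top_node_id, length(x$top_leaves),
              x$score$bit_score, format(x$score$e_value, digits = 3),
              if (x$passes_stage2) "PASS" else
                paste("FAIL:", paste(x$failure_reasons, collapse = ","))))
  invisible(x)
}

#' Leave-one-out placement of a family member
#'
#' Prunes one leaf from the tree and alignment, recomputes the match mask,
#' rebuilds the subtree HMMs and classifies the held-out full-length sequence.
#' The classification is correct iff the top-scoring node's leaf set is a
#' subset of the held-out sequence's true orthology group (minus itself).
#'
#' @param family an `ortho_family` with at least 3 leaves
#' @param held_out seq_id to withhold
#' @param config a [preset_config()]
#' @param truth named character vector seq_id -> group id; defaults to the
#'   family's labeling named "truth"
#' @param seed calibration seed
#' @return list(placement, correct, skipped); `skipped` is TRUE when pruning
#'   would leave fewer than 2 sequences
#' @export
leave_one_out_placement <- function(family, held_out, config = preset_config(),
                                    truth = NULL, seed = 1, cache = NULL) {
  ids <- family$alignment$row_ids
  stopifnot(held_out %in% ids)
  if (length(ids) - 1 < 2) {
    return(list(placement = NULL, correct = NA, skipped = TRUE))
  }
  if (is.null(truth)) {
    if (!"truth" %in% names(family$labelings)) {
      stop("no ground-truth labeling available for family ", family$family_id)
    }
    truth <- family$labelings[["truth"]]$assignments
  }
  keep <- setdiff(ids, held_out)
  sub_aln <- family_alignment(keep,
                              family$alignment$rows[match(keep, ids)],
                              occupancy_min = config$occupancy_min)
  sub_tree <- ape::drop.tip(family$tree, held_out)
  pruned <- ortho_family(family$family_id, sub_aln, sub_tree,
                         seq_meta = family$seq_meta[family$seq_meta$seq_id %in% keep, ],
                         labelings = lapply(family$labelings, function(lab) {
                           lab$assignments <- lab$assignments[
                             setdiff(names(lab$assignments), held_out)]
                           lab
                         }),
                         annotations = family$annotations[
                           family$annotations$seq_id %in% keep, , drop = FALSE],
                         family_type = family$family_type)
  query <- row_as_record(family, held_out)
  pl <- stage2_place(query, pruned, config, seed = derive_seed(seed, 303),
                     cache = cache)
  group <- names(truth)[truth == truth[[held_out]]]
  correct <- all(pl$top_leaves %in% setdiff(group, held_out))
  list(placement = pl, correct = correct, skipped = FALSE)
}
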