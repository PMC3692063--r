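## End-to-end orchestration (Stages 1-4) and the library/report plumbing.

#' Build a validated family library with precomputed indexes
#'
#' Validates each family, precomputes the identity matrix, supported-clade
#' index (Kerf cuts at the configured threshold, super-ortholog groups,
#' brackets per labeling source) and a cache holding the HMM of every tree
#' node (leaves included). Cached entries are keyed by family, match mask and
#' row-subset content, so a rebuild on unchanged inputs is a cache hit and an
#' edited alignment misses. Invalid families are skipped with a logged reason.
#'
#' @param families list of `ortho_family` objects, or a library directory path
#' @param config a [preset_config()]
#' @return object of class `family_library`: list(families, supports,
#'   identities, hmm_cache, skipped)
#' @export
build_library <- function(families, config = preset_config()) {
  if (is.character(families)) families <- read_library(families, config$occupancy_min)
  if (inherits(families, "ortho_family")) families <- list(families)
  cache <- new.env(parent = emptyenv())
  fams <- list(); supports <- list(); identities <- list()
  skipped <- character(0)
  for (fam in families) {
    ok <- tryCatch({
      idm <- pairwise_identity_matrix(fam$alignment)
      sup <- compute_supported_clades(fam, config$kerf_threshold, idm)
      sets <- tip_sets(fam$tree)
      for (tips in sets) node_hmm(fam, tips, config, cache)
      fams[[fam$family_id]] <- fam
      supports[[fam$family_id]] <- sup
      identities[[fam$family_id]] <- idm
      TRUE
    }, error = function(e) {
      message("skipping family '", fam$family_id, "': ", conditionMessage(e))
      FALSE
    })
    if (!ok) skipped <- c(skipped, fam$family_id)
  }
  structure(list(families = fams, supports = supports,
                 identities = identities, hmm_cache = cache,
                 skipped = skipped, config = config),
            class = "family_library")
}

#' @export
print.family_library <- function(x, ...) {
  cat(sprintf("<family_library> %d families (%d skipped), %d cached HMMs\n",
              length(x$families), length(x$skipped),
              length(ls(x$hmm_cache))))
  invisible(x)
}

## Accept a plain list of families, one family, or a family_library.
library_families <- function(library) {
  if (inherits(library, "family_library")) return(library$families)
  if (inherits(library, "ortho_family")) return(list(library))
  library
}

library_cache <- function(library) {
  if (inherits(library, "family_library")) library$hmm_cache else NULL
}

library_supports <- function(library, family) {
  if (inherits(library, "family_library") &&
      family$family_id %in% names(library$supports)) {
    library$supports[[family$family_id]]
  } else NULL
}

#' Run the full placement-to-annotation pipeline for one query
#'
#' Stage 1 scans family-root HMMs; Stage 2 places the query at the top-scoring
#' subtree node of each passing family and applies the placement criteria;
#' Stage 3 resolves the orthology-supported enclosing clade, extracts and
#' filters candidate orthologs (optionally through the fast k-tuple bypass),
#' clusters same-genome entries and designates ortholog/paralog status;
#' Stage 4 derives weighted consensus annotations over all accepted orthologs.
#' Per-family errors are captured and the pipeline continues; the result is
#' deterministic given (query, library, config, seed).
#'
#' @param query a [sequence_record()]
#' @param library a `family_library`, list of families, or one family
#' @param config a [preset_config()]
#' @param seed seed driving all calibration randomness
#' @return object of class `pipeline_result`
#' @export
run_pipeline <- function(query, library, config = preset_config(), seed = 1) {
  if (nchar(query$residues) > config$max_query_length) {
    stop("query length ", nchar(query$residues), " exceeds the maximum of ",
         config$max_query_length, " amino acids")
  }
  families <- library_families(library)
  cache <- library_cache(library)
  fam_matches <- stage1_family_scan(query, library, config, seed = seed)

  placements <- list(); clades <- list(); cands <- list(); errors <- list()
  for (fid in fam_matches$family_id) {
    fam <- families[[fid]]
    tryCatch({
      supports <- library_supports(library, fam)
      if (is.null(supports)) {
        supports <- compute_supported_clades(fam, config$kerf_threshold)
      }
      pl <- stage2_place(query, fam, config, supports = supports,
                         seed = derive_seed(seed, fid), cache = cache)
      placements[[fid]] <- pl
      if (pl$passes_stage2) {
        clade <- resolve_enclosing_clade(fam$tree, pl$top_node_id, supports)
        clades[[fid]] <- clade
        cands[[fid]] <- stage3_orthologs(query, clade, fam, config)
      }
    }, error = function(e) {
      errors[[fid]] <<- conditionMessage(e)
    })
  }

  cand_tab <- if (length(cands)) {
    do.call(rbind, lapply(names(cands), function(fid)
      cbind(family_id = fid, cands[[fid]], stringsAsFactors = FALSE)))
  } else data.frame(family_id = character(), seq_id = character(),
                    taxon_id = character(), curation_tier = character(),
                    percent_identity = numeric(), query_coverage = numeric(),
                    subject_coverage = numeric(), status = character(),
                    rejection_reasons = character(),
                    genome_cluster_id = character(),
                    is_representative = logical(), stringsAsFactors = FALSE)
  accepted <- cand_tab[cand_tab$status %in% c("ortholog", "paralog"), , drop = FALSE]
  rejected <- cand_tab[cand_tab$status == "rejected", , drop = FALSE]

  orth <- cand_tab[cand_tab$status == "ortholog", , drop = FALSE]
  all_ann <- do.call(rbind, lapply(names(families), function(fid)
    families[[fid]]$annotations))
  cons <- consensus_annotations(orth, if (is.null(all_ann))
    data.frame(seq_id = character(), kind = character(), value = character(),
               evidence = character()) else all_ann)

  placement_tab <- if (length(placements)) {
    do.call(rbind, lapply(placements, function(p) data.frame(
      family_id = p$family_id, top_node_id = p$top_node_id,
      n_leaves = length(p$top_leaves), bit_score = p$score$bit_score,
      e_value = p$score$e_value, query_coverage = p$score$query_coverage,
      model_coverage = p$score$model_coverage,
      passes_stage2 = p$passes_stage2,
      failure_reasons = paste(p$failure_reasons, collapse = ";"),
      stringsAsFactors = FALSE)))
  } else data.frame(family_id = character(), top_node_id = integer(),
                    n_leaves = integer(), bit_score = numeric(),
                    e_value = numeric(), query_coverage = numeric(),
                    model_coverage = numeric(), passes_stage2 = logical(),
                    failure_reasons = character(), stringsAsFactors = FALSE)
  rownames(placement_tab) <- NULL

  clade_tab <- if (length(clades)) {
    do.call(rbind, lapply(names(clades), function(fid) data.frame(
      family_id = fid, node_id = clades[[fid]]$node_id,
      support = paste(clades[[fid]]$support_sources, collapse = ","),
      n_members = length(clades[[fid]]$members),
      members = paste(clades[[fid]]$members, collapse = ";"),
      stringsAsFactors = FALSE)))
  } else data.frame(family_id = character(), node_id = integer(),
                    support = character(), n_members = integer(),
                    members = character(), stringsAsFactors = FALSE)
  rownames(clade_tab) <- NULL

  structure(list(
    job_summary = list(query_id = query$seq_id,
                       query_length = nchar(query$residues),
                       seed = seed, n_families_in_library = length(families),
                       config = unclass(config)),
    family_matches = fam_matches,
    placements = placement_tab,
    distant_matches = placement_tab[!placement_tab$passes_stage2, , drop = FALSE],
    enclosing_clades = clade_tab,
    candidate_orthologs = accepted,
    other_sequence_matches = rejected,
    consensus_annotations = cons$annotations,
    annotation_drilldown = cons$drilldown,
    no_annotation_derived = cons$no_annotation_derived,
    family_errors = errors), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> query %s: %d family match(es), %d passing placement(s), %d ortholog(s), %d annotation value(s)%s\n",
    x$job_summary$query_id, nrow(x$family_matches),
    sum(x$placements$passes_stage2),
    sum(x$candidate_orthologs$status == "ortholog"),
    nrow(x$consensus_annotations),
    if (x$no_annotation_derived) " [no annotation derived]" else ""))
  invisible(x)
}

## canonical JSON-able representation (stable key order, data.frames by rows)
result_to_list <- function(result) {
  df <- function(d) if (nrow(d) == 0) list() else
    lapply(seq_len(nrow(d)), function(i) as.list(d[i, , drop = FALSE]))
  list(job_summary = result$job_summary,
       family_matches = df(result$family_matches),
       placements = df(result$placements),
       distant_matches = df(result$distant_matches),
       enclosing_clades = df(result$enclosing_clades),
       candidate_orthologs = df(result$candidate_orthologs),
       other_sequence_matches = df(result$other_sequence_matches),
       consensus_annotations = df(result$consensus_annotations),
       annotation_drilldown = lapply(result$annotation_drilldown, function(d)
         list(kind = d$kind, value = d$value, contributing = df(d$contributing))),
       no_annotation_derived = result$no_annotation_derived,
       family_errors = result$family_errors)
}

#' Write a pipeline result to disk
#'
#' Writes `report.json` (full machine-readable result, round-trippable) plus
#' TSVs mirroring the result views: `family_matches.tsv`,
#' `candidate_orthologs.tsv`, `other_sequence_matches.tsv`,
#' `annotations.tsv`, and `job_summary.tsv` recording the query and every
#' effective parameter. Empty views are written with headers only.
#'
#' @param result a `pipeline_result`
#' @param out_dir output directory (created if needed)
#' @return `out_dir`, invisibly
#' @export
write_report <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(result_to_list(result),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(result$family_matches, "family_matches.tsv")
  wt(result$candidate_orthologs, "candidate_orthologs.tsv")
  wt(result$other_sequence_matches, "other_sequence_matches.tsv")
  wt(result$consensus_annotations, "annotations.tsv")
  js <- result$job_summary
  flat <- c(list(query_id = js$query_id, query_length = js$query_length,
                 seed = js$seed,
                 n_families_in_library = js$n_families_in_library),
            js$config)
  wt(data.frame(parameter = names(flat),
                value = vapply(flat, function(v)
                  paste(format(v), collapse = ","), character(1)),
                stringsAsFactors = FALSE), "job_summary.tsv")
  invisible(out_dir)
}

#' Re-read a written report's JSON
#' @param out_dir directory written by [write_report()]
#' @return the parsed report list
#' @export
read_report <- function(out_dir) {
  jsonlite::read_json(file.path(out_dir, "report.json"), simplifyVector = FALSE)
}
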