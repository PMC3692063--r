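## Stage 3: candidate-ortholog extraction from the enclosing clade, pairwise
## alignment evaluation, same-genome clustering, ortholog/paralog designation,
## and the fast k-tuple reduction bypass.

#' Pairwise alignment statistics between query and candidate
#'
#' Affine-gap dynamic-programming alignment (BLOSUM62, gap open 10, extend 1
#' via Biostrings). `percent_identity` counts identical pairs over aligned
#' residue pairs (columns with a residue on both sides); each coverage is the
#' fraction of that sequence's residues inside the aligned region.
#'
#' @param query,subject [sequence_record()]s or plain strings
#' @param mode "overlap" (ends-free), "global", "local", or "global_local"
#'   (global in the query, local in the subject; for partial queries)
#' @return list(percent_identity, query_coverage, subject_coverage, score)
#' @export
pairwise_align <- function(query, subject,
                           mode = c("overlap", "global", "local", "global_local")) {
  mode <- match.arg(mode)
  q <- if (inherits(query, "sequence_record")) query$residues else toupper(query)
  s <- if (inherits(subject, "sequence_record")) subject$residues else toupper(subject)
  stopifnot(nchar(q) > 0, nchar(s) > 0)
  type <- c(overlap = "overlap", global = "global", local = "local",
            global_local = "global-local")[[mode]]
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(q), Biostrings::AAString(s),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
    type = type)
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  both <- ap != "-" & as_ != "-"
  ident <- if (sum(both) == 0) 0 else sum(ap[both] == as_[both]) / sum(both)
  list(percent_identity = ident,
       query_coverage = sum(ap != "-") / nchar(q),
       subject_coverage = sum(as_ != "-") / nchar(s),
       score = Biostrings::score(pa))
}

#' Evaluate enclosing-clade members as candidate orthologs
#'
#' Aligns every clade member to the query and applies the preset's identity
#' and overlap criteria. Members failing any criterion get status "rejected"
#' with the violated criteria listed (these are routed to the "other sequence
#' matches" report table); survivors are "candidate" until same-genome
#' clustering and designation.
#'
#' @param query a [sequence_record()]
#' @param clade a [supported_clade()] (the enclosing clade)
#' @param family the `ortho_family` the clade belongs to
#' @param config a [preset_config()]
#' @return data.frame with one row per clade member
#' @export
evaluate_candidates <- function(query, clade, family, config = preset_config()) {
  rows <- lapply(clade$members, function(id) {
    rec <- row_as_record(family, id)
    al <- pairwise_align(query, rec, mode = config$align_mode)
    reasons <- character(0)
    if (al$percent_identity < config$stage3_identity_min) reasons <- c(reasons, "identity")
    if (al$query_coverage < config$stage3_query_coverage_min) reasons <- c(reasons, "query_coverage")
    if (al$subject_coverage < config$stage3_subject_coverage_min) reasons <- c(reasons, "subject_coverage")
    data.frame(seq_id = id, taxon_id = rec$taxon_id,
               curation_tier = rec$curation_tier,
               percent_identity = al$percent_identity,
               query_coverage = al$query_coverage,
               subject_coverage = al$subject_coverage,
               status = if (length(reasons)) "rejected" else "candidate",
               rejection_reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Single-linkage clusters (union-find) from a logical adjacency matrix.
single_linkage <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i < j && adj[i, j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Cluster same-genome candidates and pick representatives
#'
#' Sequence databases often hold several entries for one gene (isoforms,
#' alternative gene models); these appear as near-identical same-species
#' clusters in family trees. Within each taxon, members are single-linkage
#' clustered at pairwise identity >= `intra_identity_min`; each cluster gets
#' one representative - a curated-tier member if available, else the member
#' with the highest identity to the query (ties toward the lexicographically
#' smallest id).
#'
#' @param candidates data.frame from [evaluate_candidates()]
#' @param records named list of [sequence_record()]s for the candidates
#' @param intra_identity_min within-genome clustering threshold (default 0.97)
#' @return `candidates` with `genome_cluster_id` and `is_representative`
#'   columns added
#' @export
cluster_same_genome <- function(candidates, records, intra_identity_min = 0.97) {
  candidates$genome_cluster_id <- NA_character_
  candidates$is_representative <- FALSE
  if (nrow(candidates) == 0) return(candidates)
  for (tax in unique(candidates$taxon_id)) {
    idx <- which(candidates$taxon_id == tax)
    ids <- candidates$seq_id[idx]
    m <- length(idx)
    adj <- diag(TRUE, m)
    if (m > 1) {
      for (a in 1:(m - 1)) {
        for (b in (a + 1):m) {
          al <- pairwise_align(records[[ids[a]]], records[[ids[b]]],
                               mode = "overlap")
          adj[a, b] <- adj[b, a] <- al$percent_identity >= intra_identity_min
        }
      }
    }
    comp <- single_linkage(adj)
    for (cc in unique(comp)) {
      sel <- idx[comp == cc]
      cid <- paste0(tax, ".c", min(match(candidates$seq_id[sel], candidates$seq_id)))
      candidates$genome_cluster_id[sel] <- cid
      sub <- candidates[sel, , drop = FALSE]
      pool <- if (any(sub$curation_tier == "curated")) {
        sel[sub$curation_tier == "curated"]
      } else sel
      subp <- candidates[pool, , drop = FALSE]
      rep_i <- pool[order(-subp$percent_identity, subp$seq_id)[1]]
      candidates$is_representative[rep_i] <- TRUE
    }
  }
  candidates
}

#' Designate ortholog/paralog status per genome
#'
#' Among the clusters of one taxon whose representatives pass the alignment
#' criteria, the cluster with the highest representative identity to the query
#' is designated orthologous; the remaining passing clusters are paralogous.
#' Identity ties go to a cluster containing a curated sequence, then to the
#' lexicographically smallest representative id. Rejected members keep their
#' status.
#'
#' @param candidates clustered data.frame from [cluster_same_genome()]
#' @param config a [preset_config()] (unused thresholds already applied)
#' @return `candidates` with status set to "ortholog"/"paralog"/"rejected"
#' @export
designate_status <- function(candidates, config = preset_config()) {
  if (nrow(candidates) == 0) return(candidates)
  for (tax in unique(candidates$taxon_id)) {
    idx <- which(candidates$taxon_id == tax)
    sub <- candidates[idx, , drop = FALSE]
    passing_clusters <- unique(sub$genome_cluster_id[sub$status != "rejected"])
    if (length(passing_clusters) == 0) next
    info <- do.call(rbind, lapply(passing_clusters, function(cid) {
      cl <- sub[sub$genome_cluster_id == cid & sub$status != "rejected", , drop = FALSE]
      rep_row <- cl[order(-cl$is_representative, -cl$percent_identity, cl$seq_id)[1], ]
      data.frame(cid = cid, ident = rep_row$percent_identity,
                 curated = any(cl$curation_tier == "curated"),
                 rep_id = rep_row$seq_id, stringsAsFactors = FALSE)
    }))
    best <- info$cid[order(-info$ident, -info$curated, info$rep_id)[1]]
    for (cid in passing_clusters) {
      sel <- idx[candidates$genome_cluster_id[idx] == cid &
                   candidates$status[idx] != "rejected"]
      candidates$status[sel] <- if (cid == best) "ortholog" else "paralog"
    }
  }
  candidates
}

#' Normalised shared k-tuple similarity between two sequences
#'
#' Counts position pairs (i, j) whose length-k words match, normalised by the
#' product of word counts: equivalent to the hash-free double loop over all
#' positions.
#'
#' @param a,b amino-acid strings
#' @param k word length (>= 2)
#' @return similarity in [0, 1]
#' @export
ktuple_similarity <- function(a, b, k = 4) {
  stopifnot(k >= 2)
  a <- toupper(a); b <- toupper(b)
  na <- nchar(a) - k + 1; nb <- nchar(b) - k + 1
  if (na < 1 || nb < 1) return(0)
  wa <- substring(a, 1:na, k:(na + k - 1))
  wb <- substring(b, 1:nb, k:(nb + k - 1))
  ta <- table(wa); tb <- table(wb)
  shared <- intersect(names(ta), names(tb))
  sum(as.numeric(ta[shared]) * as.numeric(tb[shared])) / (na * nb)
}

#' Fast-path reduction of an enclosing clade
#'
#' The fast bypass replaces per-member alignment of large clades by a k-tuple
#' prefilter plus a guide-tree subtree extraction: members are ranked by
#' shared k-tuple similarity with the query and the `top_n` best kept; a guide
#' alignment is formed over the family's match columns (the query mapped in by
#' Viterbi against the clade HMM), a neighbor-joining tree is estimated from
#' identity-derived distances, and the smallest clade around the query holding
#' at least `min(fastcat_min_subtree, n)` members is retained. With
#' `top_n >= |clade|` the reduction keeps every member.
#'
#' @param query a [sequence_record()]
#' @param clade a [supported_clade()]
#' @param family the owning `ortho_family`
#' @param config a [preset_config()] (uses fastcat_k, fastcat_top_n,
#'   fastcat_min_subtree)
#' @return character vector of retained member ids
#' @export
fastcat_reduce <- function(query, clade, family, config = preset_config()) {
  members <- clade$members
  if (config$fastcat_top_n >= length(members)) return(members)
  sims <- vapply(members, function(id)
    ktuple_similarity(query$residues, row_as_record(family, id)$residues,
                      k = config$fastcat_k), numeric(1))
  keep <- members[order(-sims, members)][seq_len(config$fastcat_top_n)]

  ## guide alignment over match columns; query mapped by Viterbi
  aln <- family$alignment
  mask <- aln$match_mask
  hmm <- build_profile_hmm(aln, row_subset = members,
                           pseudocount_alpha = config$pseudocount_alpha)
  qcode <- encode_residues(query$residues)
  sc <- cpp_hmm_score(hmm$em_logodds, hmm$log_trans, qcode, 0L)
  K <- sum(mask)
  qrow <- integer(K)
  if (length(sc$match_k) > 0) qrow[sc$match_k] <- qcode[sc$match_q]
  guide <- rbind(aln$mat[match(keep, aln$row_ids), mask, drop = FALSE],
                 query = qrow)
  rownames(guide) <- c(keep, ".query.")
  m <- nrow(guide)
  if (m < 4) return(keep)
  idm <- matrix(1, m, m, dimnames = list(rownames(guide), rownames(guide)))
  for (i in 1:(m - 1)) {
    for (j in (i + 1):m) {
      both <- guide[i, ] > 0 & guide[j, ] > 0
      idm[i, j] <- idm[j, i] <-
        if (!any(both)) 0 else sum(guide[i, both] == guide[j, both]) / sum(both)
    }
  }
  d <- -log(pmax(idm, exp(-5)))
  nj <- tryCatch(phangorn::midpoint(ape::nj(stats::as.dist(d))),
                 error = function(e) NULL)
  if (is.null(nj)) return(keep)
  nj$edge.length[nj$edge.length < 0] <- 0
  sets <- tip_sets(nj)
  qtip <- match(".query.", nj$tip.label)
  want <- min(config$fastcat_min_subtree, length(keep))
  anc <- c(qtip, phangorn::Ancestors(nj, qtip, type = "all"))
  for (node in anc) {
    mem <- setdiff(sets[[node]], ".query.")
    if (length(mem) >= want) return(keep[keep %in% mem])
  }
  keep
}

#' Run Stage 3 on one enclosing clade
#'
#' Convenience wrapper: optional fast-path reduction, candidate evaluation,
#' same-genome clustering and ortholog/paralog designation.
#'
#' @inheritParams evaluate_candidates
#' @return data.frame of candidates with cluster and status columns
#' @export
stage3_orthologs <- function(query, clade, family, config = preset_config()) {
  clade_used <- clade
  if (isTRUE(config$fastcat)) {
    clade_used$members <- fastcat_reduce(query, clade, family, config)
  }
  cands <- evaluate_candidates(query, clade_used, family, config)
  records <- stats::setNames(lapply(cands$seq_id, row_as_record, family = family),
                             cands$seq_id)
  cands <- cluster_same_genome(cands, records, config$intra_identity_min)
  designate_status(cands, config)
}
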