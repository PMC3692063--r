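## Stage 4: weighted consensus functional annotation from accepted orthologs.
## Annotations from closer orthologs weigh more than distant ones, and
## manually curated evidence more than computational; the distance proxy is
## the Stage 3 percent identity (the query is not a tree member, so patristic
## distance is unavailable).

default_tier_weights <- c(experimental = 1.0, curated = 0.8, computational = 0.3)

#' Weight of one transferred annotation
#'
#' `weight = tier_weights[evidence] * identity ^ sharpness`: strictly
#' increasing in identity and in evidence tier rank.
#'
#' @param identity query-ortholog percent identity in [0, 1]
#' @param evidence "experimental", "curated" or "computational"
#' @param tier_weights named weights per evidence tier
#' @param sharpness exponent on identity (default 2)
#' @return numeric weight
#' @export
annotation_weight <- function(identity, evidence,
                              tier_weights = default_tier_weights,
                              sharpness = 2) {
  stopifnot(identity >= 0, identity <= 1, sharpness > 0)
  if (!evidence %in% names(tier_weights)) {
    stop("unknown evidence tier: ", evidence)
  }
  unname(tier_weights[[evidence]] * identity^sharpness)
}

normalize_value <- function(x) {
  tolower(gsub("\\s+", " ", trimws(x)))
}

#' Weighted consensus annotations over accepted orthologs
#'
#' For each annotation kind, identical values (after case folding and
#' whitespace normalisation) are pooled; a value's score is the sum of its
#' supporters' weights and its confidence the score divided by the total over
#' competing values of that kind, so confidences per kind sum to 1. Evidence
#' codes and per-supporter weights are kept for drill-down.
#'
#' @param orthologs data.frame of candidates with `status == "ortholog"`
#'   (columns seq_id, percent_identity)
#' @param annotations data.frame (seq_id, kind, value, evidence)
#' @param tier_weights,sharpness see [annotation_weight()]
#' @return list(annotations = ranked data.frame, drilldown = list,
#'   no_annotation_derived = logical)
#' @export
consensus_annotations <- function(orthologs, annotations,
                                  tier_weights = default_tier_weights,
                                  sharpness = 2) {
  orth <- orthologs[orthologs$status == "ortholog", , drop = FALSE]
  empty <- data.frame(kind = character(), value = character(),
                      confidence = numeric(), n_supporting = integer(),
                      top_evidence = character(), stringsAsFactors = FALSE)
  if (nrow(orth) == 0 || nrow(annotations) == 0) {
    return(list(annotations = empty, drilldown = list(),
                no_annotation_derived = TRUE))
  }
  ann <- annotations[annotations$seq_id %in% orth$seq_id, , drop = FALSE]
  if (nrow(ann) == 0) {
    return(list(annotations = empty, drilldown = list(),
                no_annotation_derived = TRUE))
  }
  ann$identity <- orth$percent_identity[match(ann$seq_id, orth$seq_id)]
  ann$weight <- mapply(annotation_weight, ann$identity, ann$evidence,
                       MoreArgs = list(tier_weights = tier_weights,
                                       sharpness = sharpness))
  ann$norm_value <- normalize_value(ann$value)

  tier_rank <- c(experimental = 3, curated = 2, computational = 1)
  rows <- list(); drill <- list()
  for (kind in sort(unique(ann$kind))) {
    sub <- ann[ann$kind == kind, , drop = FALSE]
    total <- sum(sub$weight)
    vals <- unique(sub$norm_value)
    scores <- vapply(vals, function(v) sum(sub$weight[sub$norm_value == v]),
                     numeric(1))
    conf <- if (total > 0) scores / total else rep(0, length(vals))
    ord <- order(-conf, vals)
    for (i in ord) {
      supp <- sub[sub$norm_value == vals[i], , drop = FALSE]
      rows[[length(rows) + 1]] <- data.frame(
        kind = kind, value = supp$value[1], confidence = conf[i],
        n_supporting = nrow(supp),
        top_evidence = names(which.max(tier_rank[unique(supp$evidence)])),
        stringsAsFactors = FALSE)
      drill[[length(drill) + 1]] <- list(
        kind = kind, value = supp$value[1],
        contributing = data.frame(seq_id = supp$seq_id, weight = supp$weight,
                                  evidence = supp$evidence,
                                  identity = supp$identity,
                                  stringsAsFactors = FALSE))
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  list(annotations = tab, drilldown = drill, no_annotation_derived = FALSE)
}
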