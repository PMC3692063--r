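#' Family multiple sequence alignment
#'
#' Container for an aligned set of protein sequences together with the shared
#' match-column mask used by every subtree HMM of the family. Rows are gapped
#' strings of equal length; the mask marks the columns modelled by match
#' states.
#'
#' @param row_ids character vector of unique row identifiers
#' @param rows character vector of gapped residue strings (equal length)
#' @param match_mask optional logical mask; computed from `occupancy_min` when
#'   omitted
#' @param occupancy_min minimum fraction of non-gap residues for a column to be
#'   a match column (default 0.5)
#' @return an object of class `family_alignment` with fields `row_ids`, `rows`,
#'   `match_mask` and an integer residue matrix `mat`
#' @export
family_alignment <- function(row_ids, rows, match_mask = NULL,
                             occupancy_min = 0.5) {
  stopifnot(length(row_ids) == length(rows), length(rows) >= 1)
  if (anyDuplicated(row_ids)) {
    stop("duplicate row identifiers: ",
         paste(unique(row_ids[duplicated(row_ids)]), collapse = ", "))
  }
  row_ids <- unname(row_ids)
  rows <- unname(toupper(rows))
  w <- unique(nchar(rows))
  if (length(w) != 1) stop("alignment rows are not all the same length")
  mat <- t(vapply(rows, encode_residues, integer(w), USE.NAMES = FALSE))
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = length(rows))
  rownames(mat) <- row_ids
  aln <- structure(list(row_ids = row_ids, rows = rows, mat = mat,
                        match_mask = NULL),
                   class = "family_alignment")
  if (is.null(match_mask)) {
    match_mask <- select_match_columns(aln, occupancy_min = occupancy_min)
  }
  if (length(match_mask) != w) stop("match_mask length does not match rows")
  if (!any(match_mask)) stop("match_mask has no match columns")
  aln$match_mask <- match_mask
  aln
}

#' @export
print.family_alignment <- function(x, ...) {
  cat(sprintf("<family_alignment> %d rows x %d columns (%d match columns)\n",
              length(x$row_ids), ncol(x$mat), sum(x$match_mask)))
  invisible(x)
}

#' Select match columns by occupancy
#'
#' A column is a match column iff the fraction of non-gap residues is at least
#' `occupancy_min`. The mask is shared by all subtree HMMs of a family so that
#' their bit scores are mutually comparable.
#'
#' @param alignment a `family_alignment` (its mask, if any, is ignored) or a
#'   character vector of gapped rows
#' @param occupancy_min fraction in (0, 1]
#' @return logical vector, one entry per column
#' @export
select_match_columns <- function(alignment, occupancy_min = 0.5) {
  mat <- if (inherits(alignment, "family_alignment")) alignment$mat else
    t(vapply(toupper(alignment), encode_residues,
             integer(nchar(alignment[1])), USE.NAMES = FALSE))
  if (!is.matrix(mat)) mat <- matrix(mat, nrow = 1)
  occ <- colMeans(mat > 0)
  mask <- occ >= occupancy_min
  if (!any(mask)) {
    stop("no column reaches occupancy ", occupancy_min,
         "; lower occupancy_min")
  }
  mask
}

#' Pairwise percent identity over co-occupied alignment columns
#'
#' identity(i, j) = identical residue pairs / number of columns where both rows
#' carry a residue; pairs sharing no column get identity 0, and the diagonal
#' is 1.
#'
#' @param alignment a `family_alignment`
#' @return symmetric numeric matrix with row/column names set to the row ids
#' @export
pairwise_identity_matrix <- function(alignment) {
  mat <- alignment$mat
  n <- nrow(mat)
  out <- diag(1, n)
  if (n > 1) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        both <- mat[i, ] > 0 & mat[j, ] > 0
        nb <- sum(both)
        out[i, j] <- out[j, i] <-
          if (nb == 0) 0 else sum(mat[i, both] == mat[j, both]) / nb
      }
    }
  }
  dimnames(out) <- list(alignment$row_ids, alignment$row_ids)
  out
}

## Ungapped sequence of one alignment row, as a sequence_record.
row_as_record <- function(family, seq_id) {
  stopifnot(seq_id %in% family$alignment$row_ids)
  res <- gsub("[-.]", "", family$alignment$rows[match(seq_id, family$alignment$row_ids)])
  meta <- family$seq_meta[family$seq_meta$seq_id == seq_id, , drop = FALSE]
  sequence_record(seq_id, res,
                  taxon_id = if (nrow(meta)) meta$taxon_id[1] else "unknown",
                  curation_tier = if (nrow(meta)) meta$curation_tier[1] else "automatic")
}
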