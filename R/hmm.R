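## Profile HMM construction and scoring.
##
## Architecture: a Plan7-style chain of match/insert/delete states over the
## family's shared match-column mask, with free (null-emitting) query flanks.
## "glocal" scoring is global in the model and local in the query (used for
## whole-protein families); "local" adds uniform entry/exit over match states
## (used for domain families). Insert emissions equal the background, so all
## scores are log-odds against the null and inserts/flanks contribute only
## their transition costs.

TRANS_TYPES <- c("MM", "MI", "MD", "IM", "II", "ID", "DM", "DD", "DI")

#' Build a profile HMM from a subset of alignment rows
#'
#' Emissions are weighted residue frequencies (position-based Henikoff weights
#' over the subset, normalised to sum to 1) mixed with the background:
#' `e = (freq + alpha * bg) / (1 + alpha)`. Transition distributions use the
#' same single-parameter pseudocount scheme with a uniform prior over each
#' state's allowed targets. Leaf HMMs (a single row) are valid and yield a
#' pseudocounted point mass.
#'
#' @param alignment a [family_alignment()]
#' @param row_subset identifiers of the rows to train on (default: all rows)
#' @param pseudocount_alpha background-mixture pseudocount (default 0.5)
#' @param background amino-acid background frequencies over the 20-letter
#'   alphabet (default uniform; also the null model for log-odds scoring)
#' @return an object of class `profile_hmm`
#' @export
build_profile_hmm <- function(alignment, row_subset = NULL,
                              pseudocount_alpha = 0.5, background = NULL) {
  stopifnot(inherits(alignment, "family_alignment"), pseudocount_alpha > 0)
  if (is.null(row_subset)) row_subset <- alignment$row_ids
  unknown <- setdiff(row_subset, alignment$row_ids)
  if (length(unknown) > 0) {
    stop("unknown row id(s): ", paste(unknown, collapse = ", "))
  }
  if (length(row_subset) == 0) stop("row_subset is empty")
  if (is.null(background)) background <- rep(1 / 20, 20)
  stopifnot(length(background) == 20, abs(sum(background) - 1) < 1e-9)

  sub <- alignment$mat[match(row_subset, alignment$row_ids), , drop = FALSE]
  cnt <- cpp_hmm_counts(sub, alignment$match_mask)
  K <- sum(alignment$match_mask)
  alpha <- pseudocount_alpha

  em_counts <- cnt$em_counts
  rs <- rowSums(em_counts)
  freq <- em_counts
  freq[rs > 0, ] <- em_counts[rs > 0, , drop = FALSE] / rs[rs > 0]
  if (any(rs == 0)) {
    freq[rs == 0, ] <- matrix(background, sum(rs == 0), 20, byrow = TRUE)
  }
  match_emissions <- (freq + alpha * matrix(background, K, 20, byrow = TRUE)) /
    (1 + alpha)

  tc <- cnt$trans_counts
  transitions <- matrix(0, K + 1, 9, dimnames = list(NULL, TRANS_TYPES))
  for (k in 0:K) {
    for (src in c("M", "I", "D")) {
      targets <- if (k < K) c("M", "I", "D") else c("M", "I")  # no D beyond K
      cols <- match(paste0(src, targets), TRANS_TYPES)
      cts <- tc[k + 1, cols]
      transitions[k + 1, cols] <-
        (cts + alpha / length(cols)) / (sum(cts) + alpha)
    }
  }

  lens <- rowSums(sub > 0)
  hmm <- structure(list(
    n_match = K,
    match_emissions = match_emissions,
    insert_emissions = background,
    transitions = transitions,
    null_model = background,
    match_mask = alignment$match_mask,
    n_train = length(row_subset),
    mean_seq_length = mean(lens),
    evd_mu = NULL, evd_lambda = NULL, db_size = 1
  ), class = "profile_hmm")
  hmm$em_logodds <- cbind(log(match_emissions) -
                            matrix(log(background), K, 20, byrow = TRUE), 0)
  hmm$log_trans <- log(transitions)
  hmm
}

#' @export
print.profile_hmm <- function(x, ...) {
  cat(sprintf("<profile_hmm> %d match states, trained on %d sequence(s)%s\n",
              x$n_match, x$n_train,
              if (is.null(x$evd_mu)) "" else
                sprintf(", calibrated (mu=%.2f, lambda=%.3f)", x$evd_mu, x$evd_lambda)))
  invisible(x)
}

#' Score a sequence against a profile HMM
#'
#' The bit score is `log2` of the forward probability over the null; spans and
#' coverages come from the Viterbi traceback (query/model positions visited in
#' match states, 1-based inclusive). The E-value is reported only once the HMM
#' is calibrated (see [calibrate_evalue()]).
#'
#' @param hmm a `profile_hmm`
#' @param seq a [sequence_record()] or plain amino-acid string
#' @param mode "glocal" (model-global) or "local"
#' @return an object of class `hmm_score` with fields `bit_score`,
#'   `viterbi_bits`, `e_value`, `query_span`, `model_span`, `query_coverage`,
#'   `model_coverage`
#' @export
score_sequence <- function(hmm, seq, mode = c("glocal", "local")) {
  mode <- match.arg(mode)
  res <- if (inherits(seq, "sequence_record")) seq$residues else
    toupper(gsub("[-. ]", "", seq))
  if (nchar(res) == 0) stop("empty sequence")
  code <- encode_residues(res)
  sc <- cpp_hmm_score(hmm$em_logodds, hmm$log_trans, code,
                      if (mode == "local") 1L else 0L)
  bits <- sc$fwd / log(2)
  vit_bits <- sc$vit / log(2)
  L <- length(code); K <- hmm$n_match
  qspan <- c(sc$qstart, sc$qend)
  mspan <- c(sc$kstart, sc$kend)
  qcov <- if (qspan[1] > 0) (qspan[2] - qspan[1] + 1) / L else 0
  mcov <- if (mspan[1] > 0) (mspan[2] - mspan[1] + 1) / K else 0
  structure(list(
    bit_score = bits, viterbi_bits = vit_bits,
    e_value = if (is.null(hmm$evd_mu)) NA_real_ else evalue_from_bits(hmm, bits),
    query_span = qspan, model_span = mspan,
    query_coverage = qcov, model_coverage = mcov, mode = mode
  ), class = "hmm_score")
}

#' @export
print.hmm_score <- function(x, ...) {
  cat(sprintf("<hmm_score> %.2f bits  E=%s  q[%d-%d] (%.2f)  m[%d-%d] (%.2f)\n",
              x$bit_score, format(x$e_value, digits = 3),
              x$query_span[1], x$query_span[2], x$query_coverage,
              x$model_span[1], x$model_span[2], x$model_coverage))
  invisible(x)
}

## i.i.d. null-model sequence
random_aa_sequence <- function(length, background) {
  paste(sample(AA_LETTERS, length, replace = TRUE, prob = background),
        collapse = "")
}

#' Calibrate an HMM's E-value by fitting a Gumbel to null scores
#'
#' Scores `n_random` i.i.d. background sequences of the model's mean training
#' length and fits a Gumbel (mu, lambda) by maximum likelihood. E-values are
#' then `db_size * P(S >= s)` under the fitted distribution, with `db_size`
#' the number of models scored in the current search stage.
#'
#' @param hmm a `profile_hmm`
#' @param n_random number of null sequences (>= 100)
#' @param seed RNG seed; same seed gives identical (mu, lambda)
#' @param db_size multiplicity correction for the search
#' @param mode scoring mode used for calibration
#' @return the HMM with `evd_mu`, `evd_lambda` and `db_size` set
#' @export
calibrate_evalue <- function(hmm, n_random = 200, seed = 1, db_size = 1,
                             mode = c("glocal", "local")) {
  mode <- match.arg(mode)
  stopifnot(n_random >= 100)
  len <- max(5L, as.integer(round(hmm$mean_seq_length)))
  scores <- with_seed(seed, {
    seqs <- lapply(seq_len(n_random), function(i)
      encode_residues(random_aa_sequence(len, hmm$null_model)))
    cpp_forward_batch(hmm$em_logodds, hmm$log_trans, seqs,
                      if (mode == "local") 1L else 0L) / log(2)
  })
  if (stats::sd(scores) < 1e-8) {
    stop("degenerate null-score variance; cannot calibrate E-values")
  }
  beta0 <- stats::sd(scores) * sqrt(6) / pi
  mu0 <- mean(scores) - 0.5772156649 * beta0
  nll <- function(p) {
    mu <- p[1]; beta <- exp(p[2])
    z <- (scores - mu) / beta
    sum(log(beta) + z + exp(-z))
  }
  fit <- stats::optim(c(mu0, log(beta0)), nll, method = "BFGS")
  hmm$evd_mu <- fit$par[1]
  hmm$evd_lambda <- 1 / exp(fit$par[2])
  hmm$db_size <- db_size
  hmm
}

#' E-value of a bit score under a calibrated HMM
#' @param hmm calibrated `profile_hmm`
#' @param bits bit score(s)
#' @return E-value(s); monotonically non-increasing in `bits`
#' @export
evalue_from_bits <- function(hmm, bits) {
  if (is.null(hmm$evd_mu)) stop("HMM is not calibrated")
  p <- -expm1(-exp(-hmm$evd_lambda * (bits - hmm$evd_mu)))  # P(S >= s)
  hmm$db_size * p
}
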