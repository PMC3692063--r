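# helper: manual HMM whose match emissions equal the background and whose
# transition probabilities are 1 along the forced M-chain
uniform_hmm <- function(K) {
  tr <- matrix(-Inf, K + 1, 9,
               dimnames = list(NULL, orthoscan:::TRANS_TYPES))
  tr[, "MM"] <- 0
  structure(list(n_match = K,
                 em_logodds = matrix(0, K, 21),
                 log_trans = tr,
                 null_model = rep(1 / 20, 20),
                 mean_seq_length = K,
                 evd_mu = NULL, evd_lambda = NULL, db_size = 1),
            class = "profile_hmm")
}

test_that("match-column selection follows the occupancy rule", {
  rows <- c("AC-D", "AC-D", "A--D", "A---")
  expect_identical(select_match_columns(rows, 0.5),
                   c(TRUE, TRUE, FALSE, TRUE))
  # boundary: 2 of 4 occupied at threshold 0.5 is a match (0.5 >= 0.5)
  expect_true(select_match_columns(c("A-", "A-", "AC", "AC"), 0.5)[2])
  expect_error(select_match_columns(c("--", "--"), 0.5), "occupancy")
})

test_that("profile construction: weighting, pseudocounts and normalization", {
  a1 <- family_alignment("r1", "ACD")
  a2 <- family_alignment(c("r1", "r2"), c("ACD", "ACD"))
  h1 <- build_profile_hmm(a1, pseudocount_alpha = 0.5)
  h2 <- build_profile_hmm(a2, pseudocount_alpha = 0.5)
  # duplicate rows share weight: emissions identical to the single-row model
  expect_equal(h1$match_emissions, h2$match_emissions, tolerance = 1e-12)

  # alpha -> infinity: emissions converge to the null model
  hb <- build_profile_hmm(a1, pseudocount_alpha = 1e9)
  expect_equal(as.vector(hb$match_emissions),
               rep(rep(1 / 20, 20), each = 3), tolerance = 1e-8)

  expect_error(build_profile_hmm(a1, row_subset = "nope"), "nope")

  # every emission and outgoing transition distribution sums to 1
  cfgs <- list(c("ACDEFG", "AC-EFG", "A-DE-G"), c("MKVL", "MK-L"))
  for (rows in cfgs) {
    aln <- family_alignment(paste0("s", seq_along(rows)), rows)
    h <- build_profile_hmm(aln)
    expect_equal(rowSums(h$match_emissions), rep(1, h$n_match),
                 tolerance = 1e-9)
    for (k in 0:h$n_match) {
      for (src in c("M", "I", "D")) {
        cols <- grep(paste0("^", src), orthoscan:::TRANS_TYPES)
        expect_equal(sum(h$transitions[k + 1, cols]), 1, tolerance = 1e-9)
      }
    }
  }
})

test_that("single training sequence aligns to itself through the match chain", {
  aln <- family_alignment("r1", "ACD")
  h <- build_profile_hmm(aln)
  sc <- score_sequence(h, "ACD")
  expect_equal(sc$query_span, c(1, 3))
  expect_equal(sc$model_span, c(1, 3))
  expect_equal(sc$query_coverage, 1)
  expect_equal(sc$model_coverage, 1)
  expect_gt(sc$bit_score, 0)
})

test_that("null-equal emissions with a forced path give a zero bit score", {
  h <- uniform_hmm(4)
  sc <- score_sequence(h, "ACDE")   # L == K: a single path of weight 1
  expect_equal(sc$bit_score, 0, tolerance = 1e-12)
  expect_equal(sc$viterbi_bits, 0, tolerance = 1e-12)
})

test_that("forward log-odds equals exhaustive path enumeration on toy models", {
  cases <- list(
    list(rows = c("AC", "AC"), q = "AC"),
    list(rows = c("AC", "A-"), q = "WY"),
    list(rows = c("ACD", "AC-", "A-D"), q = "AD"),
    list(rows = c("AWA", "AYA"), q = "KK")
  )
  for (cs in cases) {
    aln <- family_alignment(paste0("r", seq_along(cs$rows)), cs$rows,
                            match_mask = rep(TRUE, nchar(cs$rows[1])))
    h <- build_profile_hmm(aln)
    code <- orthoscan:::encode_residues(cs$q)
    for (mode in c("glocal", "local")) {
      got <- orthoscan:::cpp_forward_only(h$em_logodds, h$log_trans, code,
                                          if (mode == "local") 1L else 0L)
      want <- oracle_forward(h, code, mode)
      expect_equal(got, want, tolerance = 1e-9,
                   info = paste(mode, paste(cs$rows, collapse = "/"), cs$q))
    }
  }
})

test_that("forward score dominates Viterbi everywhere", {
  set.seed(71)
  for (rep in 1:12) {
    n <- sample(2:5, 1)
    len <- sample(5:12, 1)
    rows <- replicate(n, paste(sample(c(orthoscan:::AA_LETTERS, "-"), len,
                                      replace = TRUE, prob = c(rep(0.045, 20), 0.1)),
                               collapse = ""))
    aln <- tryCatch(family_alignment(paste0("r", 1:n), rows),
                    error = function(e) NULL)
    if (is.null(aln)) next
    h <- build_profile_hmm(aln)
    q <- paste(sample(orthoscan:::AA_LETTERS, sample(4:15, 1), replace = TRUE),
               collapse = "")
    for (mode in c("glocal", "local")) {
      sc <- score_sequence(h, q, mode = mode)
      expect_gte(sc$bit_score, sc$viterbi_bits - 1e-9)
    }
  }
})

test_that("a query matching its leaf model outscores permuted decoys", {
  base <- "MKVLATTAGGHEWILSDNQRCYFPKDE"
  h <- build_profile_hmm(family_alignment("leaf", base))
  real <- score_sequence(h, base)$bit_score
  set.seed(13)
  for (i in 1:100) {
    dec <- paste(sample(strsplit(base, "")[[1]]), collapse = "")
    expect_gte(real, score_sequence(h, dec)$bit_score)
  }
})

test_that("X residues are scored at the background", {
  h <- build_profile_hmm(family_alignment("r1", "ACDEF"))
  sc <- score_sequence(h, "XXXXX")
  expect_true(is.finite(sc$bit_score))
  expect_lte(sc$bit_score, 0.01)  # no information content in an all-X query
})

test_that("E-value calibration is seeded, monotone and centered", {
  aln <- family_alignment(c("a", "b"), c("MKVLATTAGGHEWILS", "MKVLATSAGGHEWILS"))
  h <- build_profile_hmm(aln)
  hc1 <- calibrate_evalue(h, n_random = 1000, seed = 9, db_size = 1)
  hc2 <- calibrate_evalue(h, n_random = 1000, seed = 9, db_size = 1)
  expect_identical(c(hc1$evd_mu, hc1$evd_lambda), c(hc2$evd_mu, hc2$evd_lambda))

  # median of fresh null scores has E close to db_size * 0.5
  scores <- orthoscan:::with_seed(77, {
    seqs <- lapply(1:400, function(i) orthoscan:::encode_residues(
      orthoscan:::random_aa_sequence(16, h$null_model)))
    orthoscan:::cpp_forward_batch(h$em_logodds, h$log_trans, seqs, 0L) / log(2)
  })
  e_med <- evalue_from_bits(hc1, stats::median(scores))
  expect_gt(e_med, 0.4)
  expect_lt(e_med, 0.6)

  # monotone non-increasing in the bit score
  grid <- seq(min(scores), max(scores) + 20, length.out = 50)
  expect_true(all(diff(evalue_from_bits(hc1, grid)) <= 1e-12))

  # degenerate variance cannot be calibrated
  expect_error(calibrate_evalue(uniform_hmm(6), n_random = 100, seed = 1),
               "degenerate|variance")
})
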