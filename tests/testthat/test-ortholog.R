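test_that("pairwise alignment statistics behave on constructed cases", {
  q <- "MKVLATTAGGHEWILSDNQR"
  al <- pairwise_align(q, q, mode = "global")
  expect_equal(al$percent_identity, 1)
  expect_equal(al$query_coverage, 1)
  expect_equal(al$subject_coverage, 1)

  # subject = left half of the query, local mode
  half <- substr(q, 1, 10)
  al2 <- pairwise_align(q, half, mode = "local")
  expect_equal(al2$subject_coverage, 1)
  expect_equal(al2$query_coverage, 0.5, tolerance = 0.11)
  expect_equal(al2$percent_identity, 1)

  # global-local: query global, subject local
  long_subject <- paste0("WWWWWWWW", q, "YYYYYYYY")
  al3 <- pairwise_align(q, long_subject, mode = "global_local")
  expect_equal(al3$query_coverage, 1)
  expect_lt(al3$subject_coverage, 1)
})

test_that("global alignment score equals exhaustive enumeration (length <= 6)", {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  set.seed(41)
  for (rep in 1:12) {
    a <- paste(sample(orthoscan:::AA_LETTERS, sample(2:6, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(orthoscan:::AA_LETTERS, sample(2:6, 1), replace = TRUE),
               collapse = "")
    got <- pairwise_align(a, b, mode = "global")$score
    want <- oracle_global_score(a, b, BLOSUM62, open = 10, ext = 1)
    expect_equal(got, want, info = paste(a, b))
  }
})

make_test_family <- function(seed = 21) {
  cfg <- simulation_config(n_families = 1, leaves_range = c(10, 10),
                           n_taxa = 8, seed = seed)
  simulate_family(cfg, 1)$family
}

test_that("candidate evaluation applies thresholds with named reasons", {
  fam <- make_test_family()
  clade <- supported_clade(orthoscan:::tree_root(fam$tree), "none",
                          fam$alignment$row_ids)
  q <- orthoscan:::row_as_record(fam, fam$alignment$row_ids[1])
  cands <- evaluate_candidates(q, clade, fam, preset_config("high_precision"))
  expect_setequal(cands$seq_id, clade$members)
  # same-group members pass; other groups fall below the 0.6 identity bar
  truth <- fam$labelings[["truth"]]$assignments
  other <- cands[truth[cands$seq_id] != truth[[q$seq_id]], ]
  expect_true(all(other$status == "rejected"))
  expect_true(all(grepl("identity", other$rejection_reasons)))
  expect_true(all((cands$status == "rejected") ==
                    (nchar(cands$rejection_reasons) > 0)))

  # self among candidates: identical sequence passes everything
  self <- cands[cands$seq_id == q$seq_id, ]
  expect_equal(self$percent_identity, 1)
  expect_equal(self$status, "candidate")
})

test_that("preset thresholds nest: precision within recall within remote", {
  fam <- make_test_family(22)
  clade <- supported_clade(orthoscan:::tree_root(fam$tree), "none",
                          fam$alignment$row_ids)
  q <- orthoscan:::row_as_record(fam, fam$alignment$row_ids[3])
  pass <- function(preset) {
    cands <- evaluate_candidates(q, clade, fam, preset_config(preset))
    cands$seq_id[cands$status != "rejected"]
  }
  hp <- pass("high_precision"); hr <- pass("high_recall"); rh <- pass("remote_homolog")
  expect_true(all(hp %in% hr))
  expect_true(all(hr %in% rh))
})

test_that("same-genome clustering matches a transitive-closure oracle", {
  # one taxon with three near-identical isoforms plus one diverged paralog,
  # a second taxon untouched
  base <- "MKVLATTAGGHEWILSDNQRCYFPKDEAGHWRQS"
  mut <- function(s, pos, to) {
    v <- strsplit(s, "")[[1]]; v[pos] <- to; paste(v, collapse = "")
  }
  seqs <- list(
    i1 = base, i2 = mut(base, 2, "R"), i3 = mut(mut(base, 2, "R"), 5, "W"),
    par = paste(rev(strsplit(base, "")[[1]]), collapse = ""),
    other = mut(base, 10, "K"))
  taxa <- c(i1 = "tA", i2 = "tA", i3 = "tA", par = "tA", other = "tB")
  tiers <- c(i1 = "automatic", i2 = "curated", i3 = "automatic",
             par = "automatic", other = "automatic")
  records <- lapply(names(seqs), function(id)
    sequence_record(id, seqs[[id]], taxa[[id]], tiers[[id]]))
  names(records) <- names(seqs)
  cands <- data.frame(seq_id = names(seqs), taxon_id = unname(taxa),
                      curation_tier = unname(tiers),
                      percent_identity = c(1, 0.97, 0.94, 0.2, 0.97),
                      query_coverage = 1, subject_coverage = 1,
                      status = "candidate", rejection_reasons = "",
                      stringsAsFactors = FALSE)
  out <- cluster_same_genome(cands, records, intra_identity_min = 0.9)

  # oracle: single-linkage closure over the same pairwise identities
  for (tax in unique(taxa)) {
    ids <- names(taxa)[taxa == tax]
    adj <- diag(TRUE, length(ids))
    for (a in seq_along(ids)) {
      for (b in seq_along(ids)) {
        if (a < b) {
          idp <- pairwise_align(records[[ids[a]]], records[[ids[b]]],
                                mode = "overlap")$percent_identity
          adj[a, b] <- adj[b, a] <- idp >= 0.9
        }
      }
    }
    comp <- oracle_closure_partition(adj)
    got <- out$genome_cluster_id[match(ids, out$seq_id)]
    expect_equal(length(unique(comp)), length(unique(got)))
    expect_true(all(tapply(got, comp, function(x) length(unique(x)) == 1)))
  }
  # curated member wins representation within its cluster
  iso_cluster <- out$genome_cluster_id[out$seq_id == "i1"]
  rep_id <- out$seq_id[out$genome_cluster_id == iso_cluster & out$is_representative]
  expect_equal(rep_id, "i2")
  # clusters never span taxa; exactly one representative per cluster
  expect_true(all(tapply(out$taxon_id, out$genome_cluster_id,
                         function(x) length(unique(x)) == 1)))
  expect_true(all(tapply(out$is_representative, out$genome_cluster_id, sum) == 1))
})

test_that("ortholog/paralog designation follows the higher-identity rule", {
  cands <- data.frame(
    seq_id = c("a1", "a2", "b1"), taxon_id = c("tA", "tA", "tB"),
    curation_tier = c("automatic", "automatic", "automatic"),
    percent_identity = c(0.85, 0.80, 0.75),
    query_coverage = 1, subject_coverage = 1,
    status = "candidate", rejection_reasons = "",
    genome_cluster_id = c("tA.c1", "tA.c2", "tB.c1"),
    is_representative = TRUE, stringsAsFactors = FALSE)
  out <- designate_status(cands, preset_config())
  expect_equal(out$status[out$seq_id == "a1"], "ortholog")
  expect_equal(out$status[out$seq_id == "a2"], "paralog")
  expect_equal(out$status[out$seq_id == "b1"], "ortholog")  # single cluster
  # at most one ortholog cluster per taxon
  orth <- out[out$status == "ortholog", ]
  expect_equal(anyDuplicated(orth$taxon_id), 0)

  # exact identity tie: the cluster holding a curated sequence wins
  tie <- cands
  tie$percent_identity <- c(0.8, 0.8, 0.7)
  tie$curation_tier <- c("automatic", "curated", "automatic")
  out2 <- designate_status(tie, preset_config())
  expect_equal(out2$status[out2$seq_id == "a2"], "ortholog")
  expect_equal(out2$status[out2$seq_id == "a1"], "paralog")
})

test_that("k-tuple similarity equals the double-loop oracle and ranks self first", {
  set.seed(55)
  for (rep in 1:8) {
    a <- paste(sample(orthoscan:::AA_LETTERS[1:6], sample(8:14, 1),
                      replace = TRUE), collapse = "")
    b <- paste(sample(orthoscan:::AA_LETTERS[1:6], sample(8:14, 1),
                      replace = TRUE), collapse = "")
    expect_equal(ktuple_similarity(a, b, k = 3), oracle_ktuple(a, b, 3))
  }
  fam <- make_test_family(23)
  q <- orthoscan:::row_as_record(fam, fam$alignment$row_ids[4])
  sims <- vapply(fam$alignment$row_ids, function(id)
    ktuple_similarity(q$residues,
                      orthoscan:::row_as_record(fam, id)$residues, 4),
    numeric(1))
  expect_equal(names(which.max(sims)), q$seq_id)
})

test_that("the fast bypass is the identity when top_n covers the clade", {
  fam <- make_test_family(24)
  clade <- supported_clade(orthoscan:::tree_root(fam$tree), "none",
                          fam$alignment$row_ids)
  q <- orthoscan:::row_as_record(fam, fam$alignment$row_ids[2])
  cfg_full <- preset_config(fastcat = TRUE,
                            fastcat_top_n = length(clade$members))
  expect_setequal(fastcat_reduce(q, clade, fam, cfg_full), clade$members)
  # full-path and bypass Stage 3 agree whenever top_n >= clade size
  a <- stage3_orthologs(q, clade, fam, preset_config())
  b <- stage3_orthologs(q, clade, fam, cfg_full)
  expect_equal(a[order(a$seq_id), ], b[order(b$seq_id), ],
               ignore_attr = TRUE)
  # reduction below the clade size keeps the query's group
  cfg_red <- preset_config(fastcat = TRUE, fastcat_top_n = 5)
  red <- fastcat_reduce(q, clade, fam, cfg_red)
  expect_lte(length(red), 5)
  expect_true(q$seq_id %in% red)
})
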