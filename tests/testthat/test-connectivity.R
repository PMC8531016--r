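test_that("KS enrichment reproduces the enumerated worked examples", {
  rl <- make_ranked(10:1, sprintf("g%03d", 1:10))
  # t = 2, n = 10, positions {1,2}: a = 0.8, b = 0.1 -> 0.8
  expect_equal(ks_enrichment(c("g001", "g002"), rl), 0.8)
  # positions {9,10}: a = 0.0, b = 0.9 -> -0.9
  expect_equal(ks_enrichment(c("g009", "g010"), rl), -0.9)
})

test_that("uniformly interleaved tags score within the 1/t + 1/n bound", {
  n <- 100; t <- 10
  rl <- make_ranked(n:1, sprintf("g%03d", 1:n))
  tags <- sprintf("g%03d", seq(5, 95, by = 10))
  expect_lte(abs(ks_enrichment(tags, rl)), 1 / t + 1 / n)
})

test_that("KS enrichment equals the running-walk oracle on random instances", {
  set.seed(99)
  for (i in 1:300) {
    n <- sample(5:50, 1)
    t <- sample(seq_len(n - 1), 1)
    pos <- sort(sample.int(n, t))
    rl <- make_ranked(n:1, sprintf("g%03d", 1:n))
    hits <- seq_len(n) %in% pos
    expect_identical(ks_enrichment(rl$gene[pos], rl), ks_walk_oracle(hits))
  }
})

test_that("KS enrichment validates its inputs", {
  rl <- make_ranked(10:1, sprintf("g%03d", 1:10))
  expect_error(ks_enrichment(c("x1", "x2"), rl), class = "sigrev_scoring_error")
  expect_error(ks_enrichment(c("g001", "x1", "x2", "x3", "x4"), rl),
               class = "sigrev_coverage_error")
  expect_error(ks_enrichment(rl$gene, rl), class = "sigrev_degenerate_error")
})

test_that("connectivity score composes the two tag enrichments with sign-opposition zeroing", {
  rl <- make_ranked(10:1, sprintf("g%03d", 1:10))
  sc <- connectivity_score(make_pair(c("g001", "g002"), c("g009", "g010")), rl)
  expect_equal(sc$score, (0.8 - (-0.9)) / 2)
  expect_equal(sc$score, 0.85)
  # both sets at the top share a sign -> zeroed
  same <- connectivity_score(make_pair(c("g001", "g002"), c("g003", "g004")), rl)
  expect_identical(same$score, 0)
  expect_false(same$raw == 0)
})

test_that("swapping up and down tag sets negates the score exactly", {
  set.seed(41)
  rl <- make_ranked(60:1, sprintf("g%03d", 1:60))
  for (i in 1:50) {
    picks <- sample(rl$gene, 12)
    a <- connectivity_score(make_pair(picks[1:6], picks[7:12]), rl)
    b <- connectivity_score(make_pair(picks[7:12], picks[1:6]), rl)
    expect_identical(a$score, -b$score)
    expect_identical(a$raw, -b$raw)
  }
})

test_that("reversing the ranked list nearly negates each KS enrichment", {
  # The magnitude is always preserved within 1/t + 1/n; the signed negation
  # additionally holds whenever the two branch maxima a and b are separated
  # by at least 2/n (inside that window the dominant branch can swap).
  set.seed(43)
  for (i in 1:100) {
    n <- sample(10:50, 1)
    t <- sample(2:(n - 2), 1)
    genes <- sprintf("g%03d", 1:n)
    rl <- make_ranked(n:1, genes)
    rl_rev <- make_ranked(n:1, rev(genes))
    tags <- sample(genes, t)
    e1 <- ks_enrichment(tags, rl)
    e2 <- ks_enrichment(tags, rl_rev)
    expect_lte(abs(abs(e1) - abs(e2)), 1 / t + 1 / n + 1e-12)
    pos <- sort(match(tags, rl$gene))
    j <- seq_len(t)
    a <- max(j / t - pos / n); b <- max(pos / n - (j - 1) / t)
    if (abs(a - b) >= 2 / n + 1e-9)
      expect_lte(abs(e1 + e2), 1 / t + 1 / n + 1e-12)
  }
})

test_that("permutation p agrees with the exhaustive 8x7 single-tag enumeration", {
  n <- 8
  genes <- sprintf("g%03d", 1:n)
  rl <- make_ranked(n:1, genes)
  # exhaustive null: all ordered placements of a distinct up and down tag
  enum <- c()
  for (u in 1:n) for (d in setdiff(1:n, u)) {
    eu <- ks_walk_oracle(seq_len(n) == u)
    ed <- ks_walk_oracle(seq_len(n) == d)
    enum <- c(enum, (eu - ed) / 2)
  }
  expect_length(enum, 56)
  for (pick in list(c(1, 8), c(2, 5))) {
    pair <- make_pair(genes[pick[1]], genes[pick[2]])
    res <- permutation_significance(pair, rl, n_perm = 1000, seed = 17)
    pi_exact <- mean(abs(enum) >= abs(res$observed))
    half <- 2.58 * sqrt(pi_exact * (1 - pi_exact) / 1000) + 2 / 1000
    expect_lt(abs(res$p - pi_exact), half + 1e-12)
  }
})

test_that("permutation significance enforces its floor and configuration", {
  rl <- make_ranked(20:1, sprintf("g%03d", 1:20))
  pair <- make_pair(c("g001", "g002"), c("g019", "g020"))
  expect_error(permutation_significance(pair, rl, n_perm = 50, seed = 1),
               class = "sigrev_config_error")
  res <- permutation_significance(pair, rl, n_perm = 100, seed = 1)
  expect_gte(res$p, 1 / 101)
  expect_length(res$null, 100)
})

test_that("score_library returns one BH family over all scoreable rows", {
  cfg <- small_config(seed = 11)
  tr <- ground_truth(cfg)
  lib <- generate_compound_library(cfg, tr)[1:4]
  dis <- generate_disease_library(cfg, tr)[1:2]
  sets <- lapply(lib, function(cc) signature_gene_sets(
    differential_signature(cc$treated, cc$control), n_top = 50))
  ranks <- lapply(dis, function(d) ranked_list(differential_signature(d$case, d$control)))
  tab <- score_library(sets, ranks, n_perm = 200, seed = 5)
  expect_identical(nrow(tab), 8L)
  expect_equal(tab$q, bh_brute(tab$p), tolerance = 1e-12)
  expect_true(all(tab$p >= 1 / (tab$n_perm + 1)))
  # singleton family: q equals p
  tab1 <- score_library(sets[1], ranks[1], n_perm = 200, seed = 5)
  expect_identical(nrow(tab1), 1L)
  expect_identical(tab1$q, tab1$p)
})

test_that("rows failing coverage are flagged and excluded from the BH family", {
  cfg <- small_config(seed = 11)
  tr <- ground_truth(cfg)
  lib <- generate_compound_library(cfg, tr)[1:2]
  dis <- generate_disease_library(cfg, tr)[1:2]
  sets <- lapply(lib, function(cc) signature_gene_sets(
    differential_signature(cc$treated, cc$control), n_top = 50))
  sets[[2]]$up <- paste0("missing", 1:50) # no overlap with any ranked list
  ranks <- lapply(dis, function(d) ranked_list(differential_signature(d$case, d$control)))
  tab <- score_library(sets, ranks, n_perm = 200, seed = 5)
  flagged <- tab$flag != ""
  expect_identical(sum(flagged), 2L)
  expect_true(all(is.na(tab$q[flagged])))
  expect_equal(tab$q[!flagged], bh_brute(tab$p[!flagged]), tolerance = 1e-12)
})

test_that("inverse concordance requires every condition below threshold with negative score", {
  base <- data.frame(compound = "cpdX", disease = "disY",
                     condition = c("a", "b", "c", "d"),
                     es_up = -0.5, es_down = 0.5,
                     score = c(-0.5, -0.4, -0.6, -0.3),
                     p = 0.001, q = c(0.001, 0.001, 0.001, 0.001),
                     n_perm = 1000, flag = "", stringsAsFactors = FALSE)
  expect_true(concordant_inverse(base, "cpdX", "disY")$inverse_concordant)
  one_off <- base; one_off$q[2] <- 0.02
  expect_false(concordant_inverse(one_off, "cpdX", "disY")$inverse_concordant)
  at_threshold <- base; at_threshold$q[] <- 0.01
  expect_false(concordant_inverse(at_threshold, "cpdX", "disY")$inverse_concordant)
  positive <- base; positive$score[1] <- 0.2
  expect_false(concordant_inverse(positive, "cpdX", "disY")$inverse_concordant)
  expect_error(concordant_inverse(base[1:3, ], "cpdX", "disY"),
               class = "sigrev_incomplete_evidence_error")
  expect_error(concordant_inverse(base, "cpdZ", "disY"),
               class = "sigrev_incomplete_evidence_error")
})

test_that("percentile rank follows best-rank tie semantics", {
  scores <- c(-0.9, seq(-0.5, 0.5, length.out = 49))
  expect_equal(percentile_rank(-0.9, scores), 2.0)
  expect_equal(percentile_rank(max(scores), scores), 100.0)
  tied <- c(rep(-1, 2), runif(98))
  expect_equal(percentile_rank(-1, tied), 1.0)
  expect_error(percentile_rank(-5, scores), class = "sigrev_lookup_error")
})
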