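toy_matrix <- function(values, prefix, group) {
  m <- matrix(values, nrow = 6)
  rownames(m) <- sprintf("g%02d", 1:6)
  colnames(m) <- paste0(prefix, seq_len(ncol(m)))
  expression_matrix(m, rep(group, ncol(m)))
}

test_that("moderated t on a printed 6-gene 3v3 fixture matches brute-force recomputation", {
  trt <- toy_matrix(c(90, 10, 50, 200, 5, 145,
                      110, 12, 55, 180, 8, 135,
                      95, 9, 60, 210, 6, 120), "t", "treated")
  ctl <- toy_matrix(c(40, 30, 50, 120, 20, 240,
                      55, 25, 45, 130, 25, 220,
                      45, 35, 52, 110, 18, 240), "c", "control")
  sig <- differential_signature(trt, ctl, pseudocount = 0.5, prior_df = 10)

  # independent brute-force evaluation with plain loops
  X <- trt$values; Y <- ctl$values
  lX <- X; lY <- Y
  for (j in 1:3) lX[, j] <- log2(X[, j] / sum(X[, j]) * 1e6 + 0.5)
  for (j in 1:3) lY[, j] <- log2(Y[, j] / sum(Y[, j]) * 1e6 + 0.5)
  fc <- st <- pv <- numeric(6)
  s2g <- numeric(6)
  for (g in 1:6) {
    m1 <- mean(lX[g, ]); m2 <- mean(lY[g, ])
    s2g[g] <- (sum((lX[g, ] - m1)^2) + sum((lY[g, ] - m2)^2)) / 4
    fc[g] <- m1 - m2
  }
  for (g in 1:6) {
    s2mod <- (10 * mean(s2g) + 4 * s2g[g]) / 14
    st[g] <- fc[g] / sqrt(s2mod * (2 / 3))
    pv[g] <- 2 * pt(-abs(st[g]), df = 14)
  }
  expect_equal(sig$log2fc, fc, tolerance = 1e-12)
  expect_equal(sig$stat, st, tolerance = 1e-12)
  expect_equal(sig$p, pv, tolerance = 1e-12)
  expect_equal(sig$q, bh_brute(pv), tolerance = 1e-12)
})

test_that("identity contrast gives zero fold-change, zero statistic, p = 1", {
  m <- matrix(c(10, 20, 30, 40, 50, 60,
                12, 18, 33, 37, 52, 61,
                11, 22, 28, 41, 49, 58), nrow = 6,
              dimnames = list(sprintf("g%02d", 1:6), NULL))
  trt <- expression_matrix(`colnames<-`(m, paste0("t", 1:3)), rep("treated", 3))
  ctl <- expression_matrix(`colnames<-`(m, paste0("c", 1:3)), rep("control", 3))
  sig <- differential_signature(trt, ctl)
  expect_equal(sig$log2fc, rep(0, 6))
  expect_equal(sig$stat, rep(0, 6))
  expect_equal(sig$p, rep(1, 6))
})

test_that("signature negates exactly under arm exchange", {
  cfg <- small_config(seed = 21)
  cc <- generate_compound_library(cfg)[[1]]
  fwd <- differential_signature(cc$treated, cc$control)
  swapped_t <- expression_matrix(cc$control$values, rep("treated", 5))
  swapped_c <- expression_matrix(cc$treated$values, rep("control", 5))
  rev <- differential_signature(swapped_t, swapped_c)
  expect_equal(rev$log2fc, -fwd$log2fc, tolerance = 1e-12)
  expect_equal(rev$stat, -fwd$stat, tolerance = 1e-12)
  expect_equal(rev$p, fwd$p, tolerance = 1e-12)
})

test_that("sample order within an arm does not change the signature", {
  cfg <- small_config(seed = 22)
  cc <- generate_compound_library(cfg)[[1]]
  perm <- c(3, 1, 5, 2, 4)
  shuffled <- expression_matrix(cc$treated$values[, perm], rep("treated", 5))
  s1 <- differential_signature(cc$treated, cc$control)
  s2 <- differential_signature(shuffled, cc$control)
  expect_equal(s1$stat, s2$stat, tolerance = 1e-12)
})

test_that("BH adjustment equals the brute-force step-up on random p-vectors", {
  set.seed(31)
  for (n in c(1, 5, 100, 1000)) {
    p <- runif(n)
    expect_equal(stats::p.adjust(p, "BH"), bh_brute(p), tolerance = 1e-12)
  }
})

test_that("FDR thresholding returns exactly the brute-force BH gene set", {
  cfg <- synthetic_config(n_genes = 1000, n_effect_genes = 100, effect_size = 1.5,
                          n_compounds = 1, n_diseases = 1, seed = 8)
  cc <- generate_compound_library(cfg)[[1]]
  sig <- differential_signature(cc$treated, cc$control)
  q_brute <- bh_brute(sig$p)
  expect_setequal(sig$gene[sig$q < 0.1], sig$gene[q_brute < 0.1])
  expect_gt(sum(sig$q < 0.1), 0)
})

test_that("single-sample arms yield fold-changes with tests flagged unavailable", {
  m1 <- matrix(c(10, 20, 30), ncol = 1, dimnames = list(c("a", "b", "c"), "t1"))
  m2 <- matrix(c(30, 20, 10, 28, 22, 12), ncol = 2,
               dimnames = list(c("a", "b", "c"), c("c1", "c2")))
  sig <- differential_signature(expression_matrix(m1, "treated"),
                                expression_matrix(m2, rep("control", 2)))
  expect_false(attr(sig, "tests_available"))
  expect_true(all(is.na(sig$p)))
  expect_false(anyNA(sig$log2fc))
})

test_that("mismatched gene universes raise an alignment error", {
  m1 <- matrix(1:4, 2, dimnames = list(c("a", "b"), c("t1", "t2")))
  m2 <- matrix(1:4, 2, dimnames = list(c("a", "c"), c("c1", "c2")))
  expect_error(differential_signature(expression_matrix(m1, rep("treated", 2)),
                                      expression_matrix(m2, rep("control", 2))),
               class = "sigrev_alignment_error")
})

test_that("tag-set extraction honours both sizing modes", {
  sig <- structure(data.frame(gene = c("a", "b", "c"),
                              log2fc = c(2, 0, -2), stat = c(2, 0, -2),
                              p = c(0.01, 0.9, 0.01), q = c(0.02, 0.9, 0.02),
                              stringsAsFactors = FALSE),
                   tests_available = TRUE,
                   class = c("differential_signature", "data.frame"))
  pair <- signature_gene_sets(sig, n_top = 1)
  expect_identical(pair$up, "a")
  expect_identical(pair$down, "c")
  cut <- signature_gene_sets(sig, q_cutoff = 0.05)
  expect_identical(cut$up, "a")
  expect_identical(cut$down, "c")
  expect_length(intersect(pair$up, pair$down), 0)
  expect_error(signature_gene_sets(sig, n_top = 2), class = "sigrev_config_error")
  expect_error(signature_gene_sets(sig), class = "sigrev_config_error")
  expect_error(signature_gene_sets(sig, n_top = 1, q_cutoff = 0.1),
               class = "sigrev_config_error")
})

test_that("an all-null signature yields the empty-tag-set error in cutoff mode", {
  cfg <- synthetic_config(n_genes = 500, n_effect_genes = 10, effect_size = 0,
                          n_compounds = 1, n_diseases = 1, seed = 4)
  cc <- generate_compound_library(cfg)[[1]]
  sig <- differential_signature(cc$treated, cc$control)
  expect_error(signature_gene_sets(sig, q_cutoff = 0.05),
               class = "sigrev_empty_tagset_error")
})

test_that("ranked lists sort by statistic with deterministic lexicographic ties", {
  sig <- structure(data.frame(gene = c("z", "m", "a", "b"),
                              log2fc = c(1, 0.5, 0.5, -1),
                              stat = c(3, 1, 1, -2),
                              p = rep(0.1, 4), q = rep(0.2, 4),
                              stringsAsFactors = FALSE),
                   tests_available = TRUE,
                   class = c("differential_signature", "data.frame"))
  rl <- ranked_list(sig)
  expect_identical(rl$gene, c("z", "a", "m", "b"))
  # negating all statistics reverses the order up to tie blocks
  sig_neg <- sig; sig_neg$stat <- -sig$stat
  rl_neg <- ranked_list(sig_neg)
  expect_identical(rl_neg$stat, rev(-rl$stat))
  expect_identical(rl_neg$gene, c("b", "a", "m", "z"))
})

test_that("top tag sets recover planted effect genes at strong effect sizes", {
  cfg <- synthetic_config(n_genes = 2000, n_effect_genes = 150, effect_size = 2,
                          n_compounds = 1, n_diseases = 1, samples_per_arm = 5,
                          seed = 7)
  tr <- ground_truth(cfg)
  cc <- generate_compound_library(cfg, tr)[["cpd001|cellA_high"]]
  pair <- signature_gene_sets(differential_signature(cc$treated, cc$control),
                              n_top = 100)
  up_true <- tr$effect_genes[tr$effect_directions > 0]
  expect_gte(length(intersect(pair$up, up_true)) / length(up_true), 0.9)
})
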