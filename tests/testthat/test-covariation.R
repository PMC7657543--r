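test_that("pair counts exclude gapped rows and split ambiguity fractionally", {
  msa <- new_msa(c("AU", "AU", "GC", "GC"))
  cp <- count_pair(msa, select_columns(msa, 1), 1, 2)
  expect_equal(cp$counts["A", "U"], 2)
  expect_equal(cp$counts["G", "C"], 2)
  expect_equal(cp$n_eff, 4)

  msa2 <- new_msa(c("AU", "AU", "--", "-U"))
  cp2 <- count_pair(msa2, select_columns(msa2, 1), 1, 2)
  expect_equal(cp2$n_eff, 2)
  expect_equal(cp2$counts["A", "U"], 2)

  msa3 <- new_msa(c("RU", "RU"))
  cp3 <- count_pair(msa3, select_columns(msa3, 1), 1, 2)
  expect_equal(cp3$counts["A", "U"], 1)
  expect_equal(cp3$counts["G", "U"], 1)
})

test_that("G-test matches its closed form and the 2nMI identity", {
  msa <- new_msa(c("AU", "AU", "GC", "GC"))
  cp <- count_pair(msa, select_columns(msa, 1), 1, 2)
  expect_equal(g_test(cp), 8 * log(2), tolerance = 1e-12)

  indep <- matrix(c(1, 1, 1, 1), 2, 2)
  m <- matrix(0, 4, 4); m[1:2, 1:2] <- indep
  expect_equal(g_test(m), 0)

  expect_equal(g_test(2 * cp$counts), 2 * g_test(cp$counts), tolerance = 1e-12)

  # G = 2 * n * MI(nats) on random count tables
  set.seed(11)
  for (r in 1:20) {
    tab <- matrix(rpois(16, 3), 4, 4)
    n <- sum(tab)
    if (n == 0) next
    p <- tab / n; px <- rowSums(p); py <- colSums(p)
    mi <- sum(p[p > 0] * log(p[p > 0] / outer(px, py)[p > 0]))
    expect_equal(g_test(tab), 2 * n * mi, tolerance = 1e-9)
  }

  # the all-pairs matrix agrees with per-pair computation
  set.seed(12)
  mm <- matrix(sample(c("A", "C", "G", "U", "-"), 10 * 6, replace = TRUE), 10)
  msa_r <- new_msa(apply(mm, 1, paste0, collapse = ""))
  mask <- select_columns(msa_r, 1)
  G <- g_test_matrix(msa_r, mask)
  for (pair in list(c(1, 2), c(2, 5), c(3, 6))) {
    expect_equal(G[pair[1], pair[2]],
                 g_test(count_pair(msa_r, mask, pair[1], pair[2])),
                 tolerance = 1e-9)
  }
})

test_that("APC correction zeroes constant matrices and matches brute force", {
  S <- matrix(3, 5, 5); diag(S) <- 0
  expect_equal(apc_correct(S), matrix(0, 5, 5), tolerance = 1e-12)
  expect_equal(apc_correct(matrix(0, 4, 4)), matrix(0, 4, 4))

  set.seed(4)
  S <- matrix(runif(16), 4, 4); S <- S + t(S); diag(S) <- 0
  A <- apc_correct(S)
  for (i in 1:3) for (j in (i + 1):4) {
    mi <- mean(S[i, -i]); mj <- mean(S[j, -j])
    ma <- mean(S[upper.tri(S)])
    expect_equal(A[i, j], S[i, j] - mi * mj / ma, tolerance = 1e-12)
  }
})

test_that("candidate pair count matches L(L-1)/2", {
  expect_equal(n_candidate_pairs(414L), 85491)
  msa <- new_msa(c("ACGUA", "ACGUA"))
  expect_equal(n_candidate_pairs(select_columns(msa, 1)), 10)
})

test_that("tree inference is deterministic and consistent with distances", {
  msa2 <- new_msa(c("AAAAAAAAAA", "AAAAAAAACC"))
  tr <- infer_tree(msa2)
  expect_equal(sum(tr$edge.length), 0.2, tolerance = 1e-8)

  # additive 4-taxon distances: NJ recovers the generating split (s1,s2|s3,s4)
  msa4 <- new_msa(c("AAAAAAAAAACCCCC", "AAAAAAAAAAGGGGG",
                    "UUUUUUUUUUCCCCC", "UUUUUUUUUUGGGGG"))
  tr4 <- infer_tree(msa4)
  expect_s3_class(tr4, "phylo")
  unr <- ape::unroot(tr4)
  s12 <- ape::getMRCA(tr4, c("s1", "s2"))
  tips_under <- ape::extract.clade(tr4, s12)$tip.label
  expect_true(setequal(tips_under, c("s1", "s2")) ||
                setequal(tips_under, c("s3", "s4")))
  expect_identical(ape::write.tree(tr4), ape::write.tree(infer_tree(msa4)))
})

test_that("null simulation is seeded, variation-matched and silent for invariant input", {
  spec <- fixture_spec(data.frame(i = integer(0), j = integer(0)),
                       n_columns = 25L, n_sequences = 16L,
                       tree_shape = "binary", rate = 0.2,
                       compensatory_fraction = 0, seed = 5)
  fix <- generate_alignment(spec)
  mask <- select_columns(fix$msa, 1)
  tree <- infer_tree(fix$msa)
  ns1 <- simulate_null(fix$msa, mask, tree, n_null = 5, seed = 9)
  ns2 <- simulate_null(fix$msa, mask, tree, n_null = 5, seed = 9)
  expect_identical(as.numeric(ns1), as.numeric(ns2))

  # measured (parsimony) variation of null alignments tracks the input
  ns3 <- simulate_null(fix$msa, mask, tree, n_null = 20, seed = 10,
                       return_alignments = TRUE)
  input_subs <- sum(cacofold:::column_substitutions(fix$msa, mask, tree))
  null_subs <- vapply(attr(ns3, "alignments"), function(m)
    sum(cacofold:::column_substitutions(m, mask, tree)), numeric(1))
  expect_equal(mean(null_subs) / input_subs, 1, tolerance = 0.2)

  # zero variation in, zero variation out
  msa0 <- new_msa(rep("ACGUACGUAC", 6))
  mask0 <- select_columns(msa0, 1)
  ns0 <- simulate_null(msa0, mask0, infer_tree(msa0), n_null = 3, seed = 1)
  expect_true(all(ns0 == 0))
})

test_that("E-value calibration is monotone and anchored at the null extremes", {
  set.seed(21)
  scores <- c(rgamma(900, shape = 2, rate = 1), rgamma(100, 6, 1))
  nm <- fit_evalues(scores, n_tests = 500)
  expect_equal(evalue_of(nm, min(scores) - 1e-9), 500, tolerance = 0.01)
  grid <- seq(min(scores), max(scores) + 10, length.out = 200)
  ev <- evalue_of(nm, grid)
  expect_true(all(diff(ev) <= 1e-9))
  expect_lt(evalue_of(nm, max(scores) + 50), 1e-4)

  # fitted tail consistent with a held-out empirical survival
  set.seed(22)
  all_s <- rgamma(20000, shape = 1.5, rate = 0.8)
  half <- all_s[1:10000]; held <- all_s[10001:20000]
  nm2 <- fit_evalues(half, n_tests = 1)
  for (q in c(0.9, 0.97, 0.995)) {
    s <- unname(quantile(held, q))
    expect_equal(evalue_of(nm2, s), 1 - q, tolerance = 0.5,
                 ignore_attr = TRUE)
  }

  # degenerate all-equal null scores: step-function fallback
  nm3 <- fit_evalues(rep(1, 200), n_tests = 10)
  expect_lt(evalue_of(nm3, 2), evalue_of(nm3, 0.5))
  expect_error(fit_evalues(1:50, 10), "at least 100")
})

test_that("covariation power is zero without variation and monotone in substitutions", {
  msa0 <- new_msa(rep("ACGUACGU", 5))
  mask0 <- select_columns(msa0, 1)
  tree0 <- infer_tree(msa0)
  expect_equal(estimate_power(msa0, mask0, tree0, 1, 5), 0)

  p <- cacofold:::power_from_subs(0:40)
  expect_true(all(diff(p) >= 0))
  expect_equal(p[1], 0)
  expect_true(all(p >= 0 & p <= 1))
})

test_that("power estimates match the observed detection rate on covarying pairs", {
  pairs <- data.frame(i = seq(1, 16, by = 2), j = seq(50, 36, by = -2))
  spec <- fixture_spec(pairs, n_columns = 50L, n_sequences = 32L,
                       tree_shape = "binary", rate = 0.3,
                       compensatory_fraction = 1, seed = 31)
  fix <- generate_alignment(spec)
  mask <- select_columns(fix$msa, 1)
  tree <- infer_tree(fix$msa)
  A <- apc_correct(g_test_matrix(fix$msa, mask))
  ns <- simulate_null(fix$msa, mask, tree, n_null = 10, seed = 32)
  nm <- fit_evalues(ns, n_candidate_pairs(mask))
  power <- estimate_power(fix$msa, mask, tree, pairs$i, pairs$j)
  detected <- mapply(function(i, j) evalue_of(nm, A[i, j]) < 0.05,
                     pairs$i, pairs$j)
  expect_equal(mean(power), mean(detected), tolerance = 0.15)
})

test_that("pairs are classified by the strict E-value and power thresholds", {
  stats <- data.frame(evalue = c(0.01, 2.0, 0.5, 0.05, 1.0, 1.5),
                      power = c(0.1, 0.97, 0.99, 0.99, 0.99, 0.5))
  cls <- classify_pairs(stats)$class
  expect_equal(cls, c("positive", "negative", "allowed",
                      "allowed",   # E = 0.05 is not < 0.05
                      "allowed",   # E = 1 is not > 1
                      "allowed"))  # high E but power below 0.95
})

test_that("two-test mode partitions the pairs and tests the sets separately", {
  toy <- generate_pseudoknot_toy(seed = 2)
  mask <- select_columns(toy$msa, 1)
  ss_pairs <- toy$planted_nested
  stats <- covariation_analysis(toy$msa, mask, mode = "two-test",
                                ss_pairs = ss_pairs, n_null = 8, seed = 3)
  expect_setequal(unique(stats$set), c("proposed", "rest"))
  expect_equal(sum(stats$set == "proposed"), nrow(ss_pairs))
  expect_equal(nrow(stats), n_candidate_pairs(mask))
  expect_false(any(stats$class == "positive" & stats$class == "negative"))

  # same scores give smaller E-values in the small proposed set
  nm <- attr(stats, "null_model")
  s <- quantile(nm$null_scores, 0.999)
  expect_lt(evalue_of(nm, s, n_tests = nrow(ss_pairs)),
            evalue_of(nm, s, n_tests = sum(stats$set == "rest")))
})
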