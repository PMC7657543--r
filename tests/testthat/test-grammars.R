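test_that("trained parameters are normalised and concentrate on observed pairs", {
  hairpin <- list(list(seq = "GGGGAAAACCCC", ss = "((((....))))"))
  par <- train_params(hairpin, "RBG", pseudocount = 0.1)
  for (nt in names(par$transitions))
    expect_equal(sum(exp(par$transitions[[nt]])), 1, tolerance = 1e-9)
  expect_equal(sum(exp(par$e_single)), 1, tolerance = 1e-9)
  expect_equal(sum(exp(par$e_pair)), 1, tolerance = 1e-9)
  expect_true(all(abs(rowSums(exp(par$e_stack)) - 1) < 1e-9))
  for (len_d in par$lengths)
    expect_equal(sum(exp(len_d)), 1, tolerance = 1e-9)
  # the only observed pair type dominates the pair and stack emissions
  nuc <- c("A", "C", "G", "U")
  expect_equal(which.max(exp(par$e_pair)),
               which(outer(nuc, nuc, paste0) == "GC"), ignore_attr = TRUE)
  expect_gt(exp(par$e_pair)["G", "C"], 0.4)
  expect_gt(exp(par$e_stack)["GC", "GC"], 0.5)
  expect_gt(exp(par$e_single)["A"], 0.5)
})

test_that("parameter files round-trip through the plain-text format", {
  par <- default_params("RBG")
  f <- withr::local_tempfile(fileext = ".txt")
  write_params(par, f)
  back <- read_params(f)
  expect_equal(back$transitions, par$transitions, tolerance = 1e-7)
  expect_equal(back$e_pair, par$e_pair, tolerance = 1e-7)
  expect_equal(back$e_stack, par$e_stack, tolerance = 1e-7)
  expect_equal(back$lengths$hairpin, par$lengths$hairpin, tolerance = 1e-7)

  g6 <- default_params("G6X")
  expect_false(is.null(g6$e_pair_parallel))
  expect_error(train_params(list(), "RBG"), "empty training set")
})

test_that("training on data sampled from known parameters recovers them", {
  truth <- default_params("G6X")
  set.seed(41)
  samples <- list()
  while (length(samples) < 2000) {
    s <- sample_g6x(truth, max_len = 100)
    if (!is.null(s)) samples[[length(samples) + 1L]] <- s
  }
  fit <- train_params(samples, "G6X", pseudocount = 0.1)
  for (nt in names(truth$transitions))
    expect_lt(max(abs(exp(fit$transitions[[nt]]) -
                        exp(truth$transitions[[nt]]))), 0.05)
  expect_lt(max(abs(exp(fit$e_single) - exp(truth$e_single))), 0.05)
  expect_lt(max(abs(exp(fit$e_pair) - exp(truth$e_pair))), 0.05)
})

test_that("unconstrained folds of unstructured profiles stay finite and sane", {
  msa <- new_msa(rep("AAAAAAAAAAAA", 4))
  pr <- build_profile(msa, select_columns(msa, 1))
  f <- cyk_rbg(pr)
  expect_true(is.finite(f$log_probability))
  expect_equal(nrow(f$pairs), 0L)
  g <- cyk_g6x(pr)
  expect_true(is.finite(g$log_probability))
})

test_that("forced pairs always appear and forbidden pairs never do", {
  msa <- new_msa(rep("GGGGAAAACCCC", 3))
  pr <- build_profile(msa, select_columns(msa, 1))
  cons <- fold_constraints(forced = data.frame(i = 1:3, j = c(10L, 9L, 8L)))
  f <- cyk_rbg(pr, cons)
  expect_true(all(paste(1:3, c(10, 9, 8)) %in% paste(f$pairs$i, f$pairs$j)))

  # a single forced pair in an otherwise unfavorable region
  msa2 <- new_msa(rep("AAAAAAAAAAAAAAAAAAAA", 3))
  pr2 <- build_profile(msa2, select_columns(msa2, 1))
  g <- cyk_g6x(pr2, fold_constraints(forced = data.frame(i = 5L, j = 15L)))
  expect_equal(g$pairs[, c("i", "j")], data.frame(i = 5L, j = 15L),
               ignore_attr = TRUE)

  # backbone-adjacent forced pair is representable in G6X
  g2 <- cyk_g6x(pr2, fold_constraints(forced = data.frame(i = 7L, j = 8L)))
  expect_true(any(g2$pairs$i == 7 & g2$pairs$j == 8))

  # random constraint soundness
  set.seed(19)
  for (r in 1:8) {
    pr_r <- random_profile(14, 100 + r)
    partner <- random_nested(14, p_pair = 0.3, min_hairpin = 3L)
    forced <- partner_to_pairs(partner)
    if (nrow(forced) > 2) forced <- forced[1:2, ]
    fi <- sample(setdiff(1:13, c(forced$i, forced$j)), 2)
    forbidden <- data.frame(i = fi, j = pmin(fi + sample(1:3, 2, replace = TRUE), 14))
    forbidden <- forbidden[forbidden$i < forbidden$j &
                             !(paste(forbidden$i, forbidden$j) %in%
                                 paste(forced$i, forced$j)), ]
    cons_r <- fold_constraints(forced = forced, forbidden = forbidden)
    for (fold in list(cyk_rbg(pr_r, cons_r), cyk_g6x(pr_r, cons_r))) {
      key <- paste(fold$pairs$i, fold$pairs$j)
      expect_true(all(paste(forced$i, forced$j) %in% key))
      expect_false(any(paste(forbidden$i, forbidden$j) %in% key))
    }
  }
})

test_that("CYK equals exhaustive parse enumeration on short profiles", {
  prbg <- default_params("RBG")
  pg6 <- default_params("G6X")
  strs3 <- enumerate_nested(9, 3)
  strs0 <- enumerate_nested(9, 0)
  cons_sets <- list(
    fold_constraints(),
    fold_constraints(forced = data.frame(i = 2L, j = 8L)),
    fold_constraints(forbidden = data.frame(i = c(1L, 2L), j = c(9L, 8L))))
  for (sd in 1:3) {
    pr <- random_profile(9, 200 + sd)
    for (cons in cons_sets) {
      f <- cyk_rbg(pr, cons)
      best <- max(vapply(strs3, function(s)
        score_structure(s, pr, prbg, cons), numeric(1)))
      expect_equal(f$log_probability, best, tolerance = 1e-9)
      g <- cyk_g6x(pr, cons)
      best6 <- max(vapply(strs0, function(s)
        score_structure(s, pr, pg6, cons), numeric(1)))
      expect_equal(g$log_probability, best6, tolerance = 1e-9)
    }
  }
})

test_that("adding a forbidden pair never increases the fold probability", {
  set.seed(37)
  for (r in 1:5) {
    pr <- random_profile(16, 300 + r)
    base_rbg <- cyk_rbg(pr)$log_probability
    base_g6 <- cyk_g6x(pr)$log_probability
    i <- sample(1:12, 1); j <- i + sample(4:3, 1)
    j <- min(i + 4, 16)
    cons <- fold_constraints(forbidden = data.frame(i = i, j = j))
    expect_lte(cyk_rbg(pr, cons)$log_probability, base_rbg + 1e-9)
    expect_lte(cyk_g6x(pr, cons)$log_probability, base_g6 + 1e-9)
  }
})

test_that("both grammars derive each nested structure exactly once", {
  set.seed(43)
  for (r in 1:30) {
    partner3 <- random_nested(12, p_pair = 0.5, min_hairpin = 3L)
    expect_equal(count_derivations_rbg(partner3, min_hairpin = 3L), 1)
    partner0 <- random_nested(12, p_pair = 0.5, min_hairpin = 0L)
    expect_equal(count_derivations_g6x(partner0), 1)
  }
})

test_that("unsatisfiable constraints raise an error", {
  pr <- random_profile(8, 7)
  # forcing (i,j) and forbidding it is rejected up front
  expect_error(fold_constraints(forced = data.frame(i = 2L, j = 6L),
                                forbidden = data.frame(i = 2L, j = 6L)),
               "both forced and forbidden")
  # RBG cannot close a 0-nt hairpin loop without a forced pair;
  # forcing the adjacent pair makes it representable
  f <- cyk_rbg(pr, fold_constraints(forced = data.frame(i = 4L, j = 5L)))
  expect_true(any(f$pairs$i == 4 & f$pairs$j == 5))
})

test_that("parallel-orientation forced pairs carry their flag through G6X", {
  pr <- random_profile(12, 55)
  forced <- data.frame(i = 3L, j = 9L, orientation = "parallel")
  g <- cyk_g6x(pr, fold_constraints(forced = forced))
  row <- g$pairs[g$pairs$i == 3 & g$pairs$j == 9, ]
  expect_equal(row$orientation, "parallel")
})
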