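test_that("helix decomposition honors the bulge and internal-loop tolerance", {
  h1 <- decompose_helices(data.frame(i = c(1, 2, 3), j = c(20, 19, 18)))
  expect_equal(unique(h1$helix), 1L)

  # 2-residue bulge on one strand, none on the other: still one helix
  h2 <- decompose_helices(data.frame(i = c(1, 2, 5), j = c(20, 19, 18)))
  expect_equal(unique(h2$helix), 1L)

  # 3-residue bulge: split
  h3 <- decompose_helices(data.frame(i = c(1, 2, 6), j = c(20, 19, 18)))
  expect_equal(max(h3$helix), 2L)

  # 1x1 internal loop: one helix; 2x1: split
  h4 <- decompose_helices(data.frame(i = c(1, 3), j = c(20, 18)))
  expect_equal(unique(h4$helix), 1L)
  h5 <- decompose_helices(data.frame(i = c(1, 4), j = c(20, 18)))
  expect_equal(max(h5$helix), 2L)

  # single-pair helices are allowed
  h6 <- decompose_helices(data.frame(i = 5, j = 9))
  expect_equal(nrow(h6), 1L)

  # positivity is per helix
  h7 <- decompose_helices(data.frame(i = c(1, 2, 10), j = c(20, 19, 15)),
                          positives = data.frame(i = 2, j = 19))
  expect_equal(attr(h7, "helix_positive"), c(TRUE, FALSE))
})

test_that("decomposition partitions every pair into exactly one helix", {
  set.seed(8)
  for (r in 1:10) {
    partner <- random_nested(30, p_pair = 0.5, min_hairpin = 2L)
    pairs <- partner_to_pairs(partner)
    if (nrow(pairs) == 0) next
    d <- decompose_helices(pairs)
    expect_equal(nrow(d), nrow(pairs))
    expect_setequal(paste(d$i, d$j), paste(pairs$i, pairs$j))
    expect_false(any(duplicated(paste(d$i, d$j))))
  }
})

test_that("alternative helix filtering follows the support and overlap rules", {
  s0 <- data.frame(i = 1:10, j = 40:31)
  mk_layer <- function(pairs, positives = NULL, layer = 1L) {
    d <- decompose_helices(pairs, positives)
    attr(d, "layer_index") <- layer
    d
  }
  # a 14-pair unsupported helix is removed (needs >= 15)
  l14 <- mk_layer(data.frame(i = 41:54, j = 100:87))
  expect_equal(nrow(filter_alternative_helices(s0, list(l14))), 0L)

  # a 15-pair unsupported disjoint helix is kept
  l15 <- mk_layer(data.frame(i = 41:55, j = 100:86))
  expect_equal(nrow(filter_alternative_helices(s0, list(l15))), 15L)

  # a single-pair positive helix is always kept
  l1 <- mk_layer(data.frame(i = 50, j = 60),
                 positives = data.frame(i = 50, j = 60), layer = 2L)
  k1 <- filter_alternative_helices(s0, list(l1))
  expect_equal(nrow(k1), 1L)

  # a 16-pair unsupported helix with > 50% of its residues inside S0 is removed
  lo <- mk_layer(data.frame(i = 2:17, j = 40:25))
  res <- cacofold:::helix_residues(lo)
  s0res <- cacofold:::helix_residues(s0)
  expect_gt(length(intersect(res, s0res)) / length(res), 0.5)
  expect_equal(nrow(filter_alternative_helices(s0, list(lo))), 0L)

  # filtering is idempotent: re-filtering the kept helices changes nothing
  kept <- filter_alternative_helices(s0, list(l15, l1))
  relayers <- lapply(split(kept, kept$layer), function(d) {
    d2 <- decompose_helices(d[, c("i", "j")],
                            positives = d[d$positive, c("i", "j")])
    attr(d2, "layer_index") <- d$layer[1]
    d2
  })
  kept2 <- filter_alternative_helices(s0, relayers)
  expect_setequal(paste(kept2$i, kept2$j), paste(kept$i, kept$j))
})

test_that("pk / tr labels follow residue overlap with the nested structure", {
  nested <- data.frame(i = c(1, 2, 3), j = c(20, 19, 18),
                       positive = c(TRUE, TRUE, FALSE))
  alt_pk <- data.frame(i = c(6, 7), j = c(30, 29), layer = 1L, helix = 1L,
                       positive = TRUE)
  alt_tr <- data.frame(i = 3, j = 25, layer = 2L, helix = 1L, positive = TRUE)
  st <- structure(list(nested = nested, alt = rbind(alt_pk, alt_tr), map = NULL),
                  class = "annotated_structure")
  st <- annotate_structure(st)
  expect_equal(st$alt$label, c("pk", "pk", "tr"))
})

test_that("side- and cross-covariations are recognised within a helix", {
  nested <- data.frame(i = c(10, 11), j = c(30, 29),
                       positive = c(TRUE, TRUE))
  # extra covarying pair between the two left-strand residues: sc
  sc_alt <- data.frame(i = 10, j = 11, layer = 1L, helix = 1L, positive = TRUE)
  st <- annotate_structure(structure(list(nested = nested, alt = sc_alt,
                                          map = NULL),
                                     class = "annotated_structure"))
  expect_equal(st$alt$label, "sc")
  # extra covarying pair across the two strands: xc
  xc_alt <- data.frame(i = 10, j = 29, layer = 1L, helix = 1L, positive = TRUE)
  st2 <- annotate_structure(structure(list(nested = nested, alt = xc_alt,
                                           map = NULL),
                                      class = "annotated_structure"))
  expect_equal(st2$alt$label, "xc")
})

test_that("merging keeps every positive once and excludes negatives", {
  s0 <- list(pairs = data.frame(i = c(1, 2), j = c(12, 11)))
  positives <- data.frame(i = c(1, 2, 4), j = c(12, 11, 16))
  negatives <- data.frame(i = 5, j = 9)
  kept <- data.frame(i = 4, j = 16, layer = 1L, helix = 1L, positive = TRUE)
  st <- merge_structure(s0, kept, positives, negatives, map = 1:20)
  all_keys <- c(paste(st$nested$i, st$nested$j), paste(st$alt$i, st$alt$j))
  expect_true(all(paste(positives$i, positives$j) %in% all_keys))
  expect_false(any(paste(negatives$i, negatives$j) %in% all_keys))

  # a lost positive trips the internal guarantee
  expect_error(merge_structure(s0, kept[0, ], positives, negatives),
               "positive pairs")

  # zero positives: the merged structure is the layer-0 fold alone
  st0 <- merge_structure(s0, kept[0, ], positives[0, ], negatives[0, ])
  expect_equal(nrow(st0$alt), 0L)
  expect_equal(nrow(st0$nested), 2L)
})
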