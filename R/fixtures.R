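# Synthetic alignment generator: sequences evolved on a star or balanced
# binary tree from an ancestral sequence folded to a known structure, with
# compensatory double substitutions at paired columns and independent
# substitutions elsewhere. Used for tests and for the power calibration.

CANONICAL_PAIRS <- matrix(c("A", "U", "U", "A", "C", "G", "G", "C",
                            "G", "U", "U", "G"), ncol = 2, byrow = TRUE)

#' Specification of a synthetic test alignment
#'
#' @param true_structure data.frame of planted pairs (\code{i}, \code{j};
#'   may include crossing pairs and shared residues).
#' @param n_columns alignment length.
#' @param n_sequences number of sequences.
#' @param tree_shape "star" or "binary" (balanced).
#' @param rate expected substitution events per unpaired column per branch;
#'   pair sites use twice this rate.
#' @param compensatory_fraction probability that a substitution event at a
#'   paired site exchanges the whole pair for another canonical pair type.
#' @param seed integer seed; generation is deterministic given the seed.
#' @return A \code{fixture_spec} list.
#' @export
fixture_spec <- function(true_structure, n_columns, n_sequences = 20L,
                         tree_shape = c("star", "binary"), rate = 0.15,
                         compensatory_fraction = 1, seed = 1L) {
  tree_shape <- match.arg(tree_shape)
  stopifnot(rate >= 0, compensatory_fraction >= 0, compensatory_fraction <= 1)
  if (nrow(true_structure) > 0L) {
    stopifnot(all(true_structure$i < true_structure$j))
    if (max(c(true_structure$i, true_structure$j)) > n_columns)
      stop("structure indices exceed the number of columns")
  }
  structure(list(true_structure = true_structure, n_columns = n_columns,
                 n_sequences = n_sequences, tree_shape = tree_shape,
                 rate = rate, compensatory_fraction = compensatory_fraction,
                 seed = seed),
            class = "fixture_spec")
}

fixture_tree_branches <- function(spec) {
  # list of root-to-tip paths as branch counts; star = 1 branch per tip,
  # balanced binary = log2(n) branches per tip (shared internal branches)
  if (spec$tree_shape == "star") {
    lapply(seq_len(spec$n_sequences), function(k) k)  # branch ids, one each
  } else {
    depth <- ceiling(log2(spec$n_sequences))
    lapply(seq_len(spec$n_sequences), function(k) {
      # path through a complete binary tree: branch id per level
      path <- integer(depth)
      node <- k - 1L
      for (d in depth:1) {
        path[d] <- node + 2^d  # unique id per (level, node)
        node <- node %/% 2L
      }
      path
    })
  }
}

#' Generate a synthetic alignment with planted covariation
#'
#' The ancestral sequence is folded to the planted structure (canonical
#' Watson-Crick / G:U pairs at paired columns). Evolution proceeds
#' independently along each branch: pair sites draw Poisson(2 x rate)
#' events per branch, each of which is compensatory (a new canonical pair
#' type on both columns) with probability \code{compensatory_fraction} and
#' otherwise changes a single side; unpaired columns draw Poisson(rate)
#' independent substitutions. No indels are generated.
#'
#' @param spec a \code{fixture_spec}.
#' @return List with \code{msa} (an \code{rna_msa}), \code{truth} (the
#'   planted pair data.frame) and \code{col_events} (realised substitution
#'   events per column).
#' @export
generate_alignment <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(spec$seed))

  L <- spec$n_columns
  n <- spec$n_sequences
  pairs <- spec$true_structure
  # a residue may sit in several planted pairs (triplets); evolve it with
  # its first pair and let later pairs covary through the shared column
  in_pair <- integer(L)
  pair_sites <- list()
  if (nrow(pairs) > 0L) {
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$i[k]; j <- pairs$j[k]
      if (in_pair[i] == 0L && in_pair[j] == 0L) {
        pair_sites[[length(pair_sites) + 1L]] <- c(i, j)
        in_pair[c(i, j)] <- length(pair_sites)
      }
    }
  }
  single_sites <- which(in_pair == 0L)

  root <- character(L)
  for (ps in pair_sites) {
    tp <- CANONICAL_PAIRS[sample.int(6L, 1L), ]
    root[ps[1]] <- tp[1]; root[ps[2]] <- tp[2]
  }
  root[single_sites] <- sample(NUCS, length(single_sites), replace = TRUE)

  paths <- fixture_tree_branches(spec)
  branch_ids <- sort(unique(unlist(paths)))
  # realise per-branch event lists once so shared branches are shared
  branch_events <- lapply(branch_ids, function(b) {
    ev <- list()
    for (si in seq_along(pair_sites)) {
      m <- rpois(1L, 2 * spec$rate)
      if (m > 0L) ev[[length(ev) + 1L]] <- list(type = "pair", site = si,
                                                n = m,
                                                comp = runif(m) < spec$compensatory_fraction,
                                                draw = runif(m * 3L))
    }
    for (ci in single_sites) {
      m <- rpois(1L, spec$rate)
      if (m > 0L) ev[[length(ev) + 1L]] <- list(type = "single", site = ci,
                                                n = m, draw = runif(m))
    }
    ev
  })
  names(branch_events) <- as.character(branch_ids)

  col_events <- numeric(L)
  seqs <- character(n)
  for (s in seq_len(n)) {
    sq <- root
    for (b in paths[[s]]) {
      for (ev in branch_events[[as.character(b)]]) {
        if (ev$type == "pair") {
          ps <- pair_sites[[ev$site]]
          for (m in seq_len(ev$n)) {
            d <- ev$draw[(m - 1L) * 3L + 1:3]
            if (ev$comp[m]) {
              cur <- paste0(sq[ps[1]], sq[ps[2]])
              alts <- which(paste0(CANONICAL_PAIRS[, 1], CANONICAL_PAIRS[, 2]) != cur)
              tp <- CANONICAL_PAIRS[alts[ceiling(d[1] * length(alts))], ]
              sq[ps[1]] <- tp[1]; sq[ps[2]] <- tp[2]
            } else {
              side <- ps[if (d[1] < 0.5) 1L else 2L]
              alts <- setdiff(NUCS, sq[side])
              sq[side] <- alts[ceiling(d[2] * 3)]
            }
          }
        } else {
          ci <- ev$site
          for (m in seq_len(ev$n)) {
            alts <- setdiff(NUCS, sq[ci])
            sq[ci] <- alts[ceiling(ev$draw[m] * 3)]
          }
        }
      }
    }
    seqs[s] <- paste0(sq, collapse = "")
  }
  # realised events per column (counted once per branch, not per tip)
  for (b in branch_ids) {
    for (ev in branch_events[[as.character(b)]]) {
      if (ev$type == "pair") {
        ps <- pair_sites[[ev$site]]
        col_events[ps] <- col_events[ps] + ev$n
      } else col_events[ev$site] <- col_events[ev$site] + ev$n
    }
  }

  truth <- spec$true_structure
  list(msa = new_msa(seqs), truth = truth, col_events = col_events)
}

#' Toy two-hairpin alignment with a planted pseudoknot
#'
#' A small star-tree alignment whose true structure has two stem-loops
#' (with three strongly covarying nested pairs among the planted positives)
#' plus a two-pair helix between the two hairpin loops that crosses the
#' nested set. The cascade needs exactly two layers for this topology and
#' the crossing helix is residue-disjoint from the nested structure, so it
#' is annotated as a pseudoknot.
#'
#' @param seed integer seed.
#' @param n_sequences number of sequences (default 24).
#' @param rate per-column branch substitution rate (default 0.4).
#' @return As \code{\link{generate_alignment}}, plus \code{planted_nested}
#'   and \code{planted_pk} pair data.frames.
#' @export
generate_pseudoknot_toy <- function(seed = 1L, n_sequences = 24L, rate = 0.4) {
  L <- 30L
  # conserved stems of the two hairpins (not planted as covarying)
  stem <- data.frame(i = c(2L, 5L, 17L, 20L), j = c(13L, 10L, 28L, 25L))
  nested_cov <- data.frame(i = c(3L, 4L, 18L), j = c(12L, 11L, 27L))
  pk_cov <- data.frame(i = c(7L, 8L), j = c(22L, 21L))
  truth <- rbind(nested_cov, pk_cov)
  spec <- fixture_spec(truth, n_columns = L, n_sequences = n_sequences,
                       tree_shape = "star", rate = rate,
                       compensatory_fraction = 1, seed = seed)
  out <- generate_alignment(spec)
  # overlay deterministic background: conserved canonical stems, conserved A
  # at the remaining unpaired columns (so only the planted pairs covary and
  # spurious helix extensions are emission-unfavorable)
  m <- msa_matrix(out$msa)
  fixed <- CANONICAL_PAIRS[c(3, 4, 4, 3), ]
  for (k in seq_len(nrow(stem))) {
    m[, stem$i[k]] <- fixed[k, 1]
    m[, stem$j[k]] <- fixed[k, 2]
  }
  filler <- setdiff(seq_len(L), c(stem$i, stem$j, truth$i, truth$j))
  m[, filler] <- "A"
  out$msa <- new_msa(apply(m, 1, paste0, collapse = ""),
                     names = out$msa$names)
  out$planted_nested <- nested_cov
  out$planted_pk <- pk_cov
  out$stem <- stem
  out
}

#' Write a fixture as Stockholm plus a truth TSV
#'
#' @param fix result of \code{\link{generate_alignment}}.
#' @param sto_path,truth_path output paths.
#' @return \code{sto_path}, invisibly.
#' @export
write_fixture <- function(fix, sto_path, truth_path) {
  write_annotated_stockholm(fix$msa, NULL, sto_path)
  write.table(fix$truth, truth_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(sto_path)
}
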