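# Covariation analysis: G-test scores with APC correction for all analyzed
# column pairs, E-values calibrated against a tree-based phylogenetic null,
# covariation power, and positive / negative / allowed classification.

#' Joint nucleotide counts for a column pair
#'
#' Counts over the 16 ordered nucleotide pairs, summed over sequences that
#' carry a residue (non-gap) at both columns. Ambiguity codes contribute
#' fractionally.
#'
#' @param msa an \code{rna_msa}.
#' @param mask a \code{column_mask}.
#' @param i,j analyzed-column indices (positions within \code{mask$analyzed}).
#' @return List with \code{i}, \code{j}, \code{counts} (4 x 4 matrix, rows =
#'   nucleotide at \code{i}, columns = nucleotide at \code{j}) and
#'   \code{n_eff}.
#' @export
count_pair <- function(msa, mask, i, j) {
  stopifnot(i != j, i >= 1, j >= 1,
            i <= length(mask$analyzed), j <= length(mask$analyzed))
  W <- msa_weights(msa, mask$analyzed[c(i, j)])
  counts <- crossprod(W[, 1:4, drop = FALSE], W[, 5:8, drop = FALSE])
  dimnames(counts) <- list(NUCS, NUCS)
  list(i = i, j = j, counts = counts, n_eff = sum(counts))
}

#' G-test statistic of a joint count table
#'
#' \eqn{G = 2 \sum_{xy} n_{xy} \ln(n_{xy}/e_{xy})} with expected counts
#' \eqn{e_{xy}} from the table margins; cells with zero count contribute
#' nothing and an empty table scores 0. Numerically identical to
#' \eqn{2 n \cdot MI} (MI in nats) computed from the table frequencies.
#'
#' @param counts a 4 x 4 count matrix, or the result of
#'   \code{\link{count_pair}}.
#' @return Non-negative G score.
#' @export
g_test <- function(counts) {
  if (is.list(counts)) counts <- counts$counts
  n <- sum(counts)
  if (n <= 0) return(0)
  e <- outer(rowSums(counts), colSums(counts)) / n
  nz <- counts > 0
  g <- 2 * sum(counts[nz] * log(counts[nz] / e[nz]))
  max(g, 0)
}

#' G-test scores for all analyzed column pairs
#'
#' @param msa an \code{rna_msa}.
#' @param mask a \code{column_mask}.
#' @return Symmetric L x L matrix of G scores (analyzed coordinates), zero
#'   diagonal.
#' @export
g_test_matrix <- function(msa, mask) {
  W <- msa_weights(msa, mask$analyzed)
  gtest_from_crossprod(crossprod(W), length(mask$analyzed))
}

#' Average-product correction of a score matrix
#'
#' \eqn{APC(i,j) = S(i,j) - \bar S_i \bar S_j / \bar S} where the row, column
#' and grand means exclude the diagonal. An all-zero matrix is returned
#' unchanged.
#'
#' @param S symmetric score matrix.
#' @return Corrected matrix (diagonal zero).
#' @export
apc_correct <- function(S) {
  L <- nrow(S)
  if (L < 2L) return(S)
  diag(S) <- 0
  rowm <- rowSums(S) / (L - 1)
  grand <- sum(S) / (L * (L - 1))
  if (grand == 0) return(S)
  A <- S - outer(rowm, rowm) / grand
  diag(A) <- 0
  A
}

#' Number of candidate column pairs under a mask
#'
#' @param mask a \code{column_mask}, or an integer number of analyzed columns.
#' @return \code{L * (L - 1) / 2} for L analyzed columns.
#' @export
n_candidate_pairs <- function(mask) {
  L <- if (inherits(mask, "column_mask")) length(mask$analyzed) else as.integer(mask)
  L * (L - 1) / 2
}

# ---- tree and null model ----------------------------------------------------

#' Infer a phylogenetic tree from the alignment
#'
#' Neighbor-joining on pairwise-identity distances (fraction of mismatches
#' over columns where both sequences carry residues), midpoint-rooted, with
#' negative NJ branch lengths clamped to zero. Deterministic given the
#' alignment. Tip labels are \code{s<k>} for sequence k.
#'
#' @param msa an \code{rna_msa} with at least 2 sequences.
#' @return An \code{ape::phylo} tree.
#' @export
infer_tree <- function(msa) {
  n <- length(msa$sequences)
  if (n < 2L) stop("need at least 2 sequences to infer a tree")
  m <- msa_matrix(msa)
  codes <- matrix(match(m, c(NUCS, setdiff(names(IUPAC), NUCS)), nomatch = 0L),
                  nrow = nrow(m))
  valid <- tcrossprod((codes != 0L) * 1)
  same <- matrix(0, n, n)
  for (x in unique(codes[codes != 0L]))
    same <- same + tcrossprod((codes == x) * 1)
  d <- 1 - same / pmax(valid, 1)
  d[valid == 0] <- 1
  diag(d) <- 0
  labels <- paste0("s", seq_len(n))
  dimnames(d) <- list(labels, labels)
  if (n == 2L) {
    tr <- ape::read.tree(text = sprintf("(s1:%.8f,s2:%.8f);", d[1, 2] / 2, d[1, 2] / 2))
    return(tr)
  }
  tr <- ape::nj(as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- phangorn::midpoint(tr)
  tr <- ape::multi2di(tr)
  tr$edge.length[is.na(tr$edge.length)] <- 0
  tr
}

# per analyzed column parsimony substitution counts on the tree
column_substitutions <- function(msa, mask, tree) {
  m <- msa_matrix(msa)[, mask$analyzed, drop = FALSE]
  m[m %in% GAP_CHARS] <- "-"
  m[m == "U"] <- "T"
  rownames(m) <- paste0("s", seq_len(nrow(m)))
  # columns with a single distinct residue need no parsimony call
  dat <- phangorn::phyDat(m, type = "DNA")
  sc <- phangorn::fitch(tree, dat, site = "site")
  as.numeric(sc[attr(dat, "index")])
}

#' Simulate null alignments on the tree and collect APC-G scores
#'
#' Each null alignment evolves every analyzed column independently down the
#' tree under a composition-preserving substitution process: column c uses
#' its own (renormalized) residue composition as the stationary distribution
#' and a Poisson substitution rate calibrated so the expected number of
#' substitutions matches the column's parsimony count on the tree. The
#' original gap pattern is retained, so null alignments match the input in
#' size, composition and amount of variation while carrying no pair
#' covariation. APC-corrected G scores of all pairs are pooled.
#'
#' @param msa an \code{rna_msa}.
#' @param mask a \code{column_mask}.
#' @param tree tree from \code{\link{infer_tree}}.
#' @param n_null number of null alignments (default 20).
#' @param seed integer seed; the same seed reproduces the scores exactly.
#' @param return_alignments also return the simulated null alignments.
#' @return Numeric vector of pooled null APC-G scores, with attributes
#'   \code{n_null} and \code{n_pairs_per_null} (and, if requested,
#'   \code{alignments}, a list of \code{rna_msa}).
#' @export
simulate_null <- function(msa, mask, tree, n_null = 20, seed = 42,
                          return_alignments = FALSE) {
  stopifnot(n_null >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  profile <- build_profile(msa, mask)
  freqs <- profile_freqs(profile)          # 4 x L stationary composition
  freqs[, colSums(freqs) <= 0] <- 0.25     # all-gap columns: uniform
  subs <- column_substitutions(msa, mask, tree)
  L <- profile$length
  n_seq <- length(msa$sequences)
  Ttot <- sum(tree$edge.length)
  rate <- if (Ttot > 0) subs / Ttot else rep(0, L)
  # columns whose composition admits no alternative residue cannot change
  rate[colSums(freqs > 0) < 2L] <- 0

  gap_mask <- msa_matrix(msa)[, mask$analyzed, drop = FALSE] %in% GAP_CHARS
  gap_mask <- matrix(gap_mask, nrow = n_seq)

  tr <- ape::reorder.phylo(tree, "cladewise")  # parent before child
  n_tip <- length(tr$tip.label)
  tip_order <- as.integer(sub("^s", "", tr$tip.label))
  root <- n_tip + 1L

  scores <- vector("list", n_null)
  alignments <- if (return_alignments) vector("list", n_null)
  n_pilot <- 2L
  pilot_subs <- matrix(0, n_pilot, L)
  homoplasy_scale <- rep(1, L)
  for (rep_i in c(-(n_pilot - 1L):0L, seq_len(n_null))) {
    # reps <= 0 are pilots: parsimony undercounts the substitutions actually
    # placed on the tree, so calibrate per-column rate scales that make the
    # null's *measured* (parsimony) variation match the input's
    node_state <- matrix(0L, n_tip + tr$Nnode, L)
    node_state[root, ] <- vapply(seq_len(L), function(c)
      sample.int(4L, 1L, prob = freqs[, c]), integer(1))
    for (e in seq_len(nrow(tr$edge))) {
      par <- tr$edge[e, 1L]; child <- tr$edge[e, 2L]
      t_e <- tr$edge.length[e]
      st <- node_state[par, ]
      nev <- rpois(L, homoplasy_scale * rate * t_e)
      for (c in which(nev > 0L)) {
        f <- freqs[, c]
        for (k in seq_len(nev[c])) {
          f2 <- f; f2[st[c]] <- 0
          if (sum(f2) <= 0) break
          st[c] <- sample.int(4L, 1L, prob = f2)
        }
      }
      node_state[child, ] <- st
    }
    chars <- matrix(NUCS[node_state[seq_len(n_tip), , drop = FALSE]], nrow = n_tip)
    chars <- chars[order(tip_order), , drop = FALSE]
    chars[gap_mask] <- "-"
    null_msa <- new_msa(apply(chars, 1, paste0, collapse = ""))
    null_mask <- structure(list(analyzed = seq_len(L),
                                gap_fraction = colMeans(gap_mask),
                                gap_cutoff = 1),
                           class = "column_mask")
    if (rep_i <= 0L) {
      pilot_subs[1L - rep_i, ] <- column_substitutions(null_msa, null_mask, tree)
      if (rep_i == 0L) {
        mean_sim <- colMeans(pilot_subs)
        homoplasy_scale <- pmin(pmax((subs + 0.5) / (mean_sim + 0.5), 1), 4)
      }
      next
    }
    A <- apc_correct(g_test_matrix(null_msa, null_mask))
    scores[[rep_i]] <- A[upper.tri(A)]
    if (return_alignments) alignments[[rep_i]] <- null_msa
  }
  out <- unlist(scores)
  attr(out, "n_null") <- n_null
  attr(out, "n_pairs_per_null") <- L * (L - 1) / 2
  if (return_alignments) attr(out, "alignments") <- alignments
  out
}

# ---- E-values ---------------------------------------------------------------

#' Fit the null score tail and build an E-value calibration
#'
#' The right tail (scores above the 75th percentile) of the pooled null
#' APC-G scores is fitted with a gamma survival function (maximum likelihood
#' on the exceedances); below the threshold the empirical survival is used.
#' \eqn{E(s) = n_{tests} \times survival(s)}, monotone non-increasing, with
#' smooth extrapolation beyond the largest null score. Degenerate all-equal
#' null scores fall back to a step-function survival.
#'
#' @param null_scores pooled null scores from \code{\link{simulate_null}}
#'   (at least 100).
#' @param n_tests number of pairs in the tested set.
#' @return Object of class \code{null_model}.
#' @export
fit_evalues <- function(null_scores, n_tests) {
  n_null <- attr(null_scores, "n_null")
  null_scores <- as.numeric(null_scores)
  if (length(null_scores) < 100L)
    stop("need at least 100 pooled null scores, got ", length(null_scores))
  thr <- as.numeric(quantile(null_scores, 0.75, names = FALSE))
  exceed <- null_scores[null_scores > thr] - thr
  tail_frac <- length(exceed) / length(null_scores)
  fit <- NULL
  if (length(exceed) >= 20L && stats::sd(exceed) > 1e-12) {
    m <- mean(exceed); v <- stats::var(exceed)
    shape0 <- max(m^2 / v, 1e-2); rate0 <- max(m / v, 1e-8)
    nll <- function(p) {
      sh <- exp(p[1]); ra <- exp(p[2])
      -sum(stats::dgamma(exceed, shape = sh, rate = ra, log = TRUE))
    }
    op <- try(optim(c(log(shape0), log(rate0)), nll, method = "Nelder-Mead"),
              silent = TRUE)
    if (!inherits(op, "try-error") && is.finite(op$value)) {
      fit <- list(shape = exp(op$par[1]), rate = exp(op$par[2]))
    } else {
      fit <- list(shape = 1, rate = 1 / max(m, 1e-12))
    }
  }
  structure(list(null_scores = sort(null_scores), threshold = thr,
                 tail_frac = tail_frac, tail_fit = fit, n_tests = n_tests,
                 n_null = n_null),
            class = "null_model")
}

# survival function of the fitted null distribution (vectorized)
null_survival <- function(nm, s) {
  ns <- nm$null_scores
  n <- length(ns)
  emp <- (n - findInterval(s, ns)) / n  # P(S > s), right-continuous
  if (is.null(nm$tail_fit)) return(pmax(emp, 0.5 / n))
  tail <- nm$tail_frac *
    stats::pgamma(pmax(s - nm$threshold, 0), shape = nm$tail_fit$shape,
                  rate = nm$tail_fit$rate, lower.tail = FALSE)
  ifelse(s <= nm$threshold, pmax(emp, nm$tail_frac), tail)
}

#' E-value of a covariation score
#'
#' Expected number of pairs in a null alignment of the same size reaching a
#' score of at least \code{s}: \code{n_tests * survival(s)}.
#'
#' @param nm a \code{null_model} from \code{\link{fit_evalues}}.
#' @param s score(s).
#' @param n_tests override of the number of tests (for two-test mode).
#' @return E-value(s).
#' @export
evalue_of <- function(nm, s, n_tests = nm$n_tests) {
  n_tests * null_survival(nm, s)
}

# ---- covariation power ------------------------------------------------------

the_calibration <- new.env(parent = emptyenv())

power_calibration <- function() {
  if (is.null(the_calibration$table)) {
    path <- system.file("extdata", "power_calibration.tsv", package = "cacofold")
    tab <- read.table(path, header = TRUE, sep = "\t")
    stopifnot(!is.unsorted(tab$subs), !is.unsorted(tab$power))
    the_calibration$table <- tab
  }
  the_calibration$table
}

#' Covariation power of column pairs
#'
#' Power is the expected probability that a true basepair at the pair's
#' observed variation level would be detected as significantly covarying
#' (E < 0.05). Per-column substitution counts are estimated by parsimony on
#' the tree; the pair's aggregate substitution count (sum over the two
#' columns) is mapped through a monotone calibration curve fitted once on
#' synthetic covarying alignments (shipped with the package). Invariant
#' pairs have power 0; power never decreases when substitutions are added.
#'
#' @param msa an \code{rna_msa}.
#' @param mask a \code{column_mask}.
#' @param tree tree from \code{\link{infer_tree}}.
#' @param i,j analyzed-column indices (vectors of equal length).
#' @return Power value(s) in [0, 1].
#' @export
estimate_power <- function(msa, mask, tree, i, j) {
  subs <- column_substitutions(msa, mask, tree)
  power_from_subs(subs[i] + subs[j])
}

# map aggregate substitution counts through the shipped calibration curve
power_from_subs <- function(n_subs) {
  tab <- power_calibration()
  p <- approx(tab$subs, tab$power, xout = n_subs, rule = 2, ties = "ordered")$y
  p[n_subs <= 0] <- 0
  pmin(pmax(p, 0), 1)
}

# ---- classification ---------------------------------------------------------

#' Classify pairs as positive, negative or allowed
#'
#' Positive: E-value below \code{positive_evalue_cutoff} (default 0.05).
#' Negative: E-value above \code{negative_evalue_cutoff} (default 1) and
#' power above \code{negative_power_cutoff} (default 0.95). All other pairs
#' are allowed (may pair but are not forced). Inequalities are strict.
#'
#' @param stats data.frame with columns \code{evalue} and \code{power}.
#' @param positive_evalue_cutoff,negative_evalue_cutoff,negative_power_cutoff
#'   classification thresholds.
#' @return \code{stats} with a \code{class} column added.
#' @export
classify_pairs <- function(stats, positive_evalue_cutoff = 0.05,
                           negative_evalue_cutoff = 1,
                           negative_power_cutoff = 0.95) {
  cls <- rep("allowed", nrow(stats))
  cls[stats$evalue < positive_evalue_cutoff] <- "positive"
  cls[stats$evalue > negative_evalue_cutoff &
        stats$power > negative_power_cutoff] <- "negative"
  stats$class <- cls
  stats
}

# ---- full covariation analysis ---------------------------------------------

#' Covariation analysis of all analyzed column pairs
#'
#' Computes APC-corrected G-test scores for every analyzed pair, calibrates
#' E-values against the phylogenetic null, estimates covariation power and
#' classifies each pair. In \code{"one-test"} mode all pairs form a single
#' test set; in \code{"two-test"} mode the pairs of a proposed structure
#' (\code{ss_pairs}) and all remaining pairs are tested independently, each
#' with its own multiple-testing burden.
#'
#' @param msa an \code{rna_msa}.
#' @param mask a \code{column_mask}.
#' @param mode \code{"one-test"} or \code{"two-test"}.
#' @param ss_pairs data.frame of proposed pairs in analyzed coordinates
#'   (two-test mode only).
#' @param n_null number of null alignments.
#' @param seed seed for the null simulation.
#' @param tree optional precomputed tree.
#' @param ... classification cutoffs passed to \code{\link{classify_pairs}}.
#' @return data.frame of class \code{pair_stats} with columns \code{i},
#'   \code{j}, \code{gtest}, \code{apc}, \code{evalue}, \code{power},
#'   \code{set}, \code{class}; the fitted \code{null_model} and the tree are
#'   attached as attributes.
#' @export
covariation_analysis <- function(msa, mask, mode = c("one-test", "two-test"),
                                 ss_pairs = NULL, n_null = 20, seed = 42,
                                 tree = NULL, ...) {
  mode <- match.arg(mode)
  L <- length(mask$analyzed)
  G <- g_test_matrix(msa, mask)
  A <- apc_correct(G)
  ut <- which(upper.tri(A), arr.ind = TRUE)
  stats <- data.frame(i = ut[, 1], j = ut[, 2],
                      gtest = G[ut], apc = A[ut])
  if (is.null(tree)) tree <- infer_tree(msa)
  null_scores <- simulate_null(msa, mask, tree, n_null = n_null, seed = seed)

  n_pairs <- nrow(stats)
  stats$set <- "all"
  if (mode == "two-test") {
    if (is.null(ss_pairs) || nrow(ss_pairs) == 0L)
      stop("two-test mode requires the proposed-structure pair set")
    in_a <- paste(stats$i, stats$j) %in% paste(ss_pairs$i, ss_pairs$j)
    stats$set[in_a] <- "proposed"
    stats$set[!in_a] <- "rest"
  }
  nm <- fit_evalues(null_scores, n_tests = n_pairs)
  stats$evalue <- NA_real_
  for (s in unique(stats$set)) {
    sel <- stats$set == s
    stats$evalue[sel] <- evalue_of(nm, stats$apc[sel], n_tests = sum(sel))
  }
  subs <- column_substitutions(msa, mask, tree)
  stats$power <- power_from_subs(subs[stats$i] + subs[stats$j])
  stats <- classify_pairs(stats, ...)
  attr(stats, "null_model") <- nm
  attr(stats, "tree") <- tree
  attr(stats, "column_subs") <- subs
  class(stats) <- c("pair_stats", class(stats))
  stats
}

#' Export the per-pair covariation report as TSV
#'
#' One row per analyzed pair: analyzed and original coordinates, G score,
#' APC-corrected score, E-value, power and class.
#'
#' @param stats a \code{pair_stats} data.frame.
#' @param mask the \code{column_mask} used (for original coordinates).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_pairs_tsv <- function(stats, mask, path) {
  df <- data.frame(i = stats$i, j = stats$j,
                   col_i = mask$analyzed[stats$i],
                   col_j = mask$analyzed[stats$j],
                   G = stats$gtest, APC_G = stats$apc,
                   evalue = stats$evalue, power = stats$power,
                   set = stats$set, class = stats$class)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
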