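# End-to-end drivers: predict a structure from an alignment alone ("fold",
# one covariation test over all pairs) or rebuild a proposed structure
# ("improve", two independent tests: proposed pairs vs all others).

#' Run configuration
#'
#' @param gap_cutoff maximum per-column gap fraction (default 0.75).
#' @param positive_evalue_cutoff E-value below which a pair is positive
#'   (default 0.05).
#' @param negative_evalue_cutoff E-value above which a variable pair is
#'   negative (default 1).
#' @param negative_power_cutoff power above which a non-covarying pair is
#'   negative (default 0.95).
#' @param n_null number of null alignments for E-value calibration.
#' @param seed seed for the null simulation.
#' @param min_alt_helix minimum basepairs for an unsupported alternative
#'   helix (default 15).
#' @param max_overlap_frac maximum residue overlap of an unsupported
#'   alternative helix with previously selected helices (default 0.5).
#' @param params_rbg,params_g6x grammar parameters (default: shipped).
#' @return A \code{run_config} list.
#' @export
run_config <- function(gap_cutoff = 0.75, positive_evalue_cutoff = 0.05,
                       negative_evalue_cutoff = 1, negative_power_cutoff = 0.95,
                       n_null = 20L, seed = 42L, min_alt_helix = 15L,
                       max_overlap_frac = 0.5,
                       params_rbg = NULL, params_g6x = NULL) {
  stopifnot(gap_cutoff > 0, gap_cutoff <= 1,
            positive_evalue_cutoff > 0,
            negative_evalue_cutoff >= positive_evalue_cutoff,
            negative_power_cutoff > 0, negative_power_cutoff <= 1,
            n_null >= 1, min_alt_helix >= 1,
            max_overlap_frac >= 0, max_overlap_frac <= 1)
  structure(list(gap_cutoff = gap_cutoff,
                 positive_evalue_cutoff = positive_evalue_cutoff,
                 negative_evalue_cutoff = negative_evalue_cutoff,
                 negative_power_cutoff = negative_power_cutoff,
                 n_null = as.integer(n_null), seed = as.integer(seed),
                 min_alt_helix = as.integer(min_alt_helix),
                 max_overlap_frac = max_overlap_frac,
                 params_rbg = params_rbg, params_g6x = params_g6x),
            class = "run_config")
}

#' Predict a consensus structure from an alignment
#'
#' One single covariation test over all analyzed pairs, followed by the
#' cascade: maxCov layering of the positive pairs, constrained RBG fold of
#' layer 0 and G6X folds of the alternative layers, helix filtering,
#' merging and annotation. Every positive pair is incorporated; every
#' negative pair is excluded.
#'
#' @param msa an \code{rna_msa} (the proposed consensus structure, if any,
#'   is ignored in this mode).
#' @param config a \code{run_config}.
#' @param verbose print a one-line machine-readable summary to stderr.
#' @return A \code{cacofold_result}: list with \code{structure}
#'   (\code{annotated_structure}), \code{stats} (\code{pair_stats}),
#'   \code{layers}, \code{folds}, \code{mask}, \code{profile},
#'   \code{config}, \code{mode}.
#' @export
cacofold_fold <- function(msa, config = run_config(), verbose = TRUE) {
  run_pipeline(msa, config, mode = "fold", verbose = verbose)
}

#' Rebuild an annotated consensus structure using covariation
#'
#' Requires a consensus structure annotation (\code{SS_cons}). Two
#' independent covariation tests are performed: one on the proposed
#' basepairs, one on all other pairs, each with its own multiple-testing
#' burden. The structure is then built anew from the positive and negative
#' constraints exactly as in \code{\link{cacofold_fold}}; the report lists
#' positive pairs gained relative to the proposed structure.
#'
#' @inheritParams cacofold_fold
#' @return A \code{cacofold_result}, with \code{new_positives} and
#'   \code{proposed_positives} pair data.frames added.
#' @export
cacofold_improve <- function(msa, config = run_config(), verbose = TRUE) {
  if (is.null(msa$ss_cons))
    stop("improve mode requires a consensus structure (#=GC SS_cons) ",
         "in the input alignment")
  run_pipeline(msa, config, mode = "improve", verbose = verbose)
}

run_pipeline <- function(msa, config, mode, verbose = TRUE) {
  mask <- select_columns(msa, config$gap_cutoff)
  profile <- build_profile(msa, mask)
  L <- profile$length

  ss_pairs <- NULL
  if (mode == "improve") {
    ss_orig <- parse_wuss(msa$ss_cons)
    keep <- ss_orig$i %in% mask$analyzed & ss_orig$j %in% mask$analyzed
    ss_pairs <- data.frame(i = match(ss_orig$i[keep], mask$analyzed),
                           j = match(ss_orig$j[keep], mask$analyzed))
  }
  test_mode <- if (mode == "improve" && nrow(ss_pairs) > 0L) "two-test" else "one-test"
  stats <- covariation_analysis(
    msa, mask, mode = test_mode, ss_pairs = ss_pairs,
    n_null = config$n_null, seed = config$seed,
    positive_evalue_cutoff = config$positive_evalue_cutoff,
    negative_evalue_cutoff = config$negative_evalue_cutoff,
    negative_power_cutoff = config$negative_power_cutoff)

  positives <- stats[stats$class == "positive",
                     c("i", "j", "evalue"), drop = FALSE]
  negatives <- stats[stats$class == "negative", c("i", "j"), drop = FALSE]
  if (nrow(positives) == 0L)
    warning("no positive basepairs: the proposed structure has no ",
            "evolutionary support", call. = FALSE)

  layers <- build_layers(positives)
  pos_key <- paste(positives$i, positives$j)
  folds <- vector("list", length(layers))
  for (k in seq_along(layers)) {
    ly <- layers[[k]]
    fkey <- paste(ly$forced$i, ly$forced$j)
    other_pos <- positives[!(pos_key %in% fkey), c("i", "j"), drop = FALSE]
    forbidden <- rbind(negatives, other_pos)
    cons <- fold_constraints(forced = ly$forced[, c("i", "j"), drop = FALSE],
                             forbidden = forbidden)
    folds[[k]] <- if (ly$grammar == "RBG") {
      cyk_rbg(profile, cons,
              params = config$params_rbg %||% default_params("RBG"))
    } else {
      cyk_g6x(profile, cons,
              params = config$params_g6x %||% default_params("G6X"))
    }
    layers[[k]]$n_forbidden <- nrow(forbidden)
  }

  alt_layers <- lapply(seq_along(folds)[-1], function(k) {
    d <- decompose_helices(folds[[k]]$pairs[, c("i", "j"), drop = FALSE],
                           positives)
    attr(d, "layer_index") <- layers[[k]]$index
    d
  })
  kept <- filter_alternative_helices(folds[[1]]$pairs, alt_layers,
                                     min_alt_helix = config$min_alt_helix,
                                     max_overlap_frac = config$max_overlap_frac)
  st <- merge_structure(folds[[1]], kept, positives, negatives, map = profile$map)

  res <- structure(list(structure = st, stats = stats, layers = layers,
                        folds = folds, mask = mask, profile = profile,
                        config = config, mode = mode, msa = msa),
                   class = "cacofold_result")
  if (mode == "improve") {
    sskey <- paste(ss_pairs$i, ss_pairs$j)
    res$proposed_positives <- positives[pos_key %in% sskey, , drop = FALSE]
    res$new_positives <- positives[!(pos_key %in% sskey), , drop = FALSE]
  }
  if (verbose) {
    message(sprintf(
      "cacofold %s: columns=%d/%d pairs=%d positives=%d negatives=%d layers=%d nested=%d alt=%d pk=%d tr=%d",
      mode, L, msa$n_columns, nrow(stats), nrow(positives), nrow(negatives),
      length(layers), nrow(st$nested), nrow(st$alt),
      sum(st$alt$label == "pk"), sum(st$alt$label %in% c("tr", "sc", "xc"))))
  }
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.cacofold_result <- function(x, ...) {
  st <- x$structure
  cat("cacofold", x$mode, "result\n")
  cat("  analyzed columns:", x$profile$length, "of", x$msa$n_columns, "\n")
  cat("  pairs tested:", nrow(x$stats),
      "| positive:", sum(x$stats$class == "positive"),
      "| negative:", sum(x$stats$class == "negative"), "\n")
  cat("  cascade layers:", length(x$layers), "\n")
  cat("  structure:", nrow(st$nested), "nested +", nrow(st$alt),
      "alternative pairs\n")
  if (nrow(st$alt) > 0L) {
    tab <- table(st$alt$label)
    cat("  alternative labels:",
        paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Write all reports for a pipeline result
#'
#' Emits the annotated Stockholm alignment, the per-pair covariation TSV,
#' the layer TSV, the final structure TSV and an SVG arc diagram, using
#' \code{prefix} as the common path stem.
#'
#' @param res a \code{cacofold_result}.
#' @param prefix output path prefix.
#' @return Character vector of the files written, invisibly.
#' @export
write_reports <- function(res, prefix) {
  files <- c(sto = paste0(prefix, ".cacofold.sto"),
             pairs = paste0(prefix, ".pairs.tsv"),
             layers = paste0(prefix, ".layers.tsv"),
             structure = paste0(prefix, ".structure.tsv"),
             svg = paste0(prefix, ".svg"))
  write_annotated_stockholm(res$msa, res$structure, files["sto"])
  write_pairs_tsv(res$stats, res$mask, files["pairs"])
  write_layers_tsv(res$layers, files["layers"],
                   n_forbidden = vapply(res$layers, function(l)
                     l$n_forbidden %||% NA_integer_, numeric(1)))
  write_structure_tsv(res$structure, res$stats, files["structure"])
  write_structure_svg(res$structure, res$profile, files["svg"])
  invisible(files)
}
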