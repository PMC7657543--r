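# Constrained CYK folding of the profile sequence with the RBG and G6X
# grammars. Emission scores are composition-weighted expected log emissions
# over the profile columns; constraints are applied by masking: forbidden
# pairs score -1e30, positions of forced pairs may neither be unpaired nor
# pair elsewhere.

NEG_SCORE <- -1e30

#' Fold constraints
#'
#' @param forced data.frame of nested pairs (columns \code{i}, \code{j},
#'   optional \code{orientation} = "antiparallel"/"parallel") that must pair
#'   with each other.
#' @param forbidden data.frame of pairs that may not pair with each other.
#' @return A \code{fold_constraints} object.
#' @export
fold_constraints <- function(forced = NULL, forbidden = NULL) {
  empty <- data.frame(i = integer(0), j = integer(0))
  if (is.null(forced)) forced <- empty
  if (is.null(forbidden)) forbidden <- empty
  if (nrow(forced) > 0L) {
    stopifnot(all(forced$i != forced$j))
    pairs_to_partner(forced, max(c(forced$i, forced$j)))  # nested + disjoint
    if (any(paste(forced$i, forced$j) %in% paste(forbidden$i, forbidden$j)))
      stop("a pair cannot be both forced and forbidden")
  }
  if (is.null(forced$orientation))
    forced$orientation <- rep("antiparallel", nrow(forced))
  structure(list(forced = forced, forbidden = forbidden),
            class = "fold_constraints")
}

# expected log emission scores over the profile, with constraint masking
build_fold_scores <- function(profile, params, constraints) {
  comp <- profile$composition  # 4 x L raw proportions
  L <- profile$length
  s1 <- colSums(comp * as.numeric(params$e_single))
  ep <- t(comp) %*% params$e_pair %*% comp

  est <- matrix(0, L, L)
  pl <- cbind(0, comp[, -L, drop = FALSE])   # composition of column i-1
  pr <- cbind(comp[, -1, drop = FALSE], 0)   # composition of column j+1
  for (x in 1:4) for (y in 1:4) {
    Mxy <- matrix(params$e_stack[x + 4L * (y - 1L), ], 4, 4)
    est <- est + outer(pl[x, ], pr[y, ]) * (t(comp) %*% Mxy %*% comp)
  }
  est[1, ] <- NEG_SCORE
  est[, L] <- NEG_SCORE

  forced <- constraints$forced
  forbidden <- constraints$forbidden
  partner <- integer(L)
  if (nrow(forced) > 0L) {
    if (max(c(forced$i, forced$j)) > L) stop("forced pair outside profile")
    partner[forced$i] <- forced$j
    partner[forced$j] <- forced$i
  }
  if (nrow(forbidden) > 0L) {
    if (max(c(forbidden$i, forbidden$j)) > L) stop("forbidden pair outside profile")
    idx <- cbind(c(forbidden$i, forbidden$j), c(forbidden$j, forbidden$i))
    ep[idx] <- NEG_SCORE
    est[idx] <- NEG_SCORE
  }
  if (nrow(forced) > 0L) {
    for (k in seq_len(nrow(forced))) {
      i <- forced$i[k]; j <- forced$j[k]
      s1[c(i, j)] <- NEG_SCORE
      keep_i <- ep[i, j]; keep_j <- ep[j, i]
      keep_si <- est[i, j]; keep_sj <- est[j, i]
      ep[c(i, j), ] <- NEG_SCORE; ep[, c(i, j)] <- NEG_SCORE
      est[c(i, j), ] <- NEG_SCORE; est[, c(i, j)] <- NEG_SCORE
      if (identical(forced$orientation[k], "parallel") &&
          !is.null(params$e_pair_parallel)) {
        keep_i <- keep_j <- crossprod(comp[, i], params$e_pair_parallel %*% comp[, j])[1]
      }
      ep[i, j] <- keep_i; ep[j, i] <- keep_j
      est[i, j] <- keep_si; est[j, i] <- keep_sj
    }
  }
  list(s1 = s1, ep = ep, est = est, partner = partner)
}

length_logvec <- function(params, which) {
  as.numeric(params$lengths[[which]])
}

#' Fold the profile with the RBG grammar (main nested structure)
#'
#' Highest-log-probability nested parse under the RNA Basic Grammar,
#' honoring the constraints. RBG models hairpin / bulge / internal-loop /
#' multiloop architecture with explicit loop length distributions and
#' stacked-pair emissions. The minimum hairpin loop is 3 nt except under a
#' forced closing pair.
#'
#' @param profile a \code{profile_seq}.
#' @param constraints a \code{fold_constraints} (default: none).
#' @param params RBG \code{grammar_params} (default: shipped parameters).
#' @param min_hairpin minimum hairpin loop length for unforced pairs.
#' @return A \code{fold_result}: list with \code{pairs} (data.frame
#'   \code{i}, \code{j}, \code{forced}, \code{orientation}),
#'   \code{log_probability}, \code{grammar}.
#' @export
cyk_rbg <- function(profile, constraints = fold_constraints(),
                    params = default_params("RBG"), min_hairpin = 3L) {
  stopifnot(params$grammar_id == "RBG")
  sc <- build_fold_scores(profile, params, constraints)
  par <- c(params$transitions,
           list(lh = length_logvec(params, "hairpin"),
                lb = length_logvec(params, "bulge"),
                li = length_logvec(params, "intloop_side")))
  res <- cyk_rbg_cpp(sc$s1, sc$ep, sc$est, sc$partner, par,
                     as.integer(min_hairpin), 30L)
  finish_fold(res, constraints, profile, "RBG")
}

#' Fold the profile with the G6X grammar (alternative layers)
#'
#' Helix-centric grammar for the cascade's alternative layers: stacked-pair
#' F states with single-stranded runs, zero minimum hairpin length (so
#' backbone-adjacent forced pairs are representable), and a dedicated
#' emission for parallel-orientation forced pairs.
#'
#' @inheritParams cyk_rbg
#' @param params G6X \code{grammar_params}.
#' @return A \code{fold_result}.
#' @export
cyk_g6x <- function(profile, constraints = fold_constraints(),
                    params = default_params("G6X")) {
  stopifnot(params$grammar_id == "G6X")
  sc <- build_fold_scores(profile, params, constraints)
  res <- cyk_g6x_cpp(sc$s1, sc$ep, sc$est, params$transitions)
  finish_fold(res, constraints, profile, "G6X")
}

finish_fold <- function(res, constraints, profile, grammar) {
  if (res$logp < NEG_SCORE / 2)
    stop("fold constraints are unsatisfiable under the ", grammar, " grammar")
  pairs <- as.data.frame(res$pairs)
  names(pairs) <- c("i", "j")
  if (nrow(pairs) > 0L) pairs <- pairs[order(pairs$i), , drop = FALSE]
  rownames(pairs) <- NULL
  key <- paste(pairs$i, pairs$j)
  fkey <- paste(constraints$forced$i, constraints$forced$j)
  if (!all(fkey %in% key))
    stop("internal error: a forced pair is missing from the ", grammar, " fold")
  pairs$forced <- key %in% fkey
  pairs$orientation <- rep("antiparallel", nrow(pairs))
  if (any(pairs$forced) && nrow(constraints$forced) > 0L) {
    m <- match(key, fkey)
    ok <- !is.na(m)
    pairs$orientation[ok] <- constraints$forced$orientation[m[ok]]
  }
  structure(list(pairs = pairs, log_probability = res$logp,
                 grammar = grammar, length = profile$length),
            class = "fold_result")
}

#' @export
print.fold_result <- function(x, ...) {
  cat(x$grammar, "fold:", nrow(x$pairs), "pairs, log probability",
      format(x$log_probability, digits = 6), "\n")
  invisible(x)
}

#' Score the unique parse of a given nested structure
#'
#' Recursive single-parse scorer used as an independent check of the CYK
#' engines: walks the structure's unique derivation under the grammar and
#' sums transition, emission and length log-probabilities over the same
#' profile scores the CYK uses. Returns \code{-Inf} (a large negative
#' sentinel) for structures the constrained grammar cannot derive.
#'
#' @param pairs data.frame of nested pairs (\code{i}, \code{j}).
#' @param profile a \code{profile_seq}.
#' @param params a \code{grammar_params}.
#' @param constraints a \code{fold_constraints}.
#' @param min_hairpin RBG minimum hairpin loop for unforced closing pairs.
#' @return Log-probability of the parse.
#' @export
score_structure <- function(pairs, profile, params,
                            constraints = fold_constraints(),
                            min_hairpin = 3L) {
  sc <- build_fold_scores(profile, params, constraints)
  partner <- pairs_to_partner(pairs, profile$length)
  lh <- if (!is.null(params$lengths)) length_logvec(params, "hairpin")
  lb <- if (!is.null(params$lengths)) length_logvec(params, "bulge")
  li <- if (!is.null(params$lengths)) length_logvec(params, "intloop_side")
  tot <- 0
  visit <- function(what, ...) {
    a <- list(...)
    add <- if (what %in% names(params$transitions)) {
      params$transitions[[what]][[a[[1]]]]
    } else if (what == "single") {
      sc$s1[a[[1]]]
    } else if (what == "pair") {
      sc$ep[a[[1]], a[[2]]]
    } else if (what == "stack") {
      sc$est[a[[3]], a[[4]]]
    } else if (what == "len_hairpin") {
      len <- a[[1]]
      minh <- if (length(a) >= 3 && sc$partner[a[[2]]] == a[[3]]) 0L else min_hairpin
      if (len < minh || len + 1L > length(lh)) NEG_SCORE else lh[len + 1L]
    } else if (what == "len_bulge") {
      if (a[[1]] > length(lb)) NEG_SCORE else lb[a[[1]]]
    } else if (what == "len_intloop") {
      if (a[[1]] > 30L || a[[1]] > length(li)) NEG_SCORE else li[a[[1]]]
    } else 0
    tot <<- tot + add
  }
  walk_parse(params$grammar_id, partner, visit)
  tot
}
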