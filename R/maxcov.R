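# Cascade maxCov: group positive pairs into nested, residue-disjoint layers,
# each layer a maximum-weight nested subset (weight = -log E-value) found by
# the Nussinov recursion.

EVALUE_FLOOR <- 1e-50

#' Maximum-weight nested subset of weighted pairs
#'
#' Finds the nested, residue-disjoint subset of pairs maximizing the summed
#' weight, via the Nussinov interval recursion. Coordinates are compressed to
#' the pair endpoints first (nesting, crossing and residue sharing depend
#' only on endpoint order), so the recursion runs on at most 2 x npairs
#' positions. Ties break deterministically: pairing is preferred over not
#' pairing, and among pairs the one with smaller (i, j) wins.
#'
#' @param pairs data.frame with columns \code{i}, \code{j} (i < j) and
#'   \code{weight} (positive).
#' @return The selected rows of \code{pairs}.
#' @export
max_nested_subset <- function(pairs) {
  if (is.null(pairs) || nrow(pairs) == 0L) return(pairs[integer(0), , drop = FALSE])
  stopifnot(all(pairs$i < pairs$j), all(pairs$weight > 0))
  ord <- order(pairs$i, pairs$j)
  pairs <- pairs[ord, , drop = FALSE]
  pos <- sort(unique(c(pairs$i, pairs$j)))
  n <- length(pos)
  ci <- match(pairs$i, pos); cj <- match(pairs$j, pos)
  by_left <- split(seq_len(nrow(pairs)), factor(ci, levels = seq_len(n)))

  # W[a, b+1]: best weight on compressed interval a..b (b = a-1 -> 0)
  W <- matrix(0, n + 1L, n + 1L)
  CH <- matrix(0L, n + 1L, n + 1L)  # 0 = leave a unpaired, else pair row index
  for (len in 1:n) {
    for (a in 1:(n - len + 1L)) {
      b <- a + len - 1L
      best <- -1; ch <- -2L
      for (p in by_left[[a]]) {
        k <- cj[p]
        if (k > b) next
        v <- pairs$weight[p] +
          (if (k - 1L >= a + 1L) W[a + 1L, k - 1L + 1L] else 0) +
          (if (b >= k + 1L) W[k + 1L, b + 1L] else 0)
        if (v > best) { best <- v; ch <- p }
      }
      v0 <- W[a + 1L, b + 1L]
      if (v0 > best) { best <- v0; ch <- 0L }
      W[a, b + 1L] <- best; CH[a, b + 1L] <- ch
    }
  }

  sel <- integer(0)
  stack <- list(c(1L, n))
  while (length(stack) > 0L) {
    iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    a <- iv[1]; b <- iv[2]
    if (a > b) next
    ch <- CH[a, b + 1L]
    if (ch == 0L) {
      stack[[length(stack) + 1L]] <- c(a + 1L, b)
    } else {
      sel <- c(sel, ch)
      k <- cj[ch]
      stack[[length(stack) + 1L]] <- c(a + 1L, k - 1L)
      stack[[length(stack) + 1L]] <- c(k + 1L, b)
    }
  }
  out <- pairs[sort(sel), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Group positive pairs into cascade layers
#'
#' Repeatedly extracts a maximum-weight nested subset of the remaining
#' positive pairs (weight = -log E-value, E floored at 1e-50) until every
#' positive pair is assigned to exactly one layer. With no positive pairs a
#' single empty layer is returned. Layer 0 is folded with the RBG grammar,
#' later layers with G6X.
#'
#' @param positives data.frame with columns \code{i}, \code{j} and
#'   \code{evalue} (or a precomputed \code{weight}).
#' @return List of layers; each layer is a list with \code{index},
#'   \code{forced} (the layer's nested positive pairs) and \code{grammar}
#'   ("RBG" or "G6X").
#' @export
build_layers <- function(positives) {
  if (is.null(positives)) positives <- data.frame(i = integer(0), j = integer(0))
  if (nrow(positives) > 0L && is.null(positives$weight)) {
    positives$weight <- -log(pmax(positives$evalue, EVALUE_FLOOR))
  }
  layers <- list()
  remaining <- positives
  k <- 0L
  repeat {
    if (nrow(remaining) == 0L) {
      if (k == 0L) {
        layers[[1L]] <- list(index = 0L, forced = remaining,
                             grammar = "RBG")
      }
      break
    }
    sel <- max_nested_subset(remaining)
    if (nrow(sel) == 0L)
      stop("internal error: maxCov selected no pairs from a non-empty set")
    layers[[k + 1L]] <- list(index = k,
                             forced = sel,
                             grammar = if (k == 0L) "RBG" else "G6X")
    key <- paste(remaining$i, remaining$j)
    remaining <- remaining[!(key %in% paste(sel$i, sel$j)), , drop = FALSE]
    k <- k + 1L
  }
  layers
}

#' Export the cascade layer report as TSV
#'
#' @param layers result of \code{\link{build_layers}}.
#' @param path output path.
#' @param n_forbidden optional vector of forbidden-pair counts per layer.
#' @return \code{path}, invisibly.
#' @export
write_layers_tsv <- function(layers, path, n_forbidden = NULL) {
  rows <- do.call(rbind, lapply(layers, function(ly) {
    if (nrow(ly$forced) == 0L)
      return(data.frame(layer = ly$index, grammar = ly$grammar,
                        i = NA_integer_, j = NA_integer_,
                        evalue = NA_real_))
    data.frame(layer = ly$index, grammar = ly$grammar,
               i = ly$forced$i, j = ly$forced$j,
               evalue = if (!is.null(ly$forced$evalue)) ly$forced$evalue else NA_real_)
  }))
  if (!is.null(n_forbidden))
    rows$n_forbidden <- n_forbidden[rows$layer + 1L]
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
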