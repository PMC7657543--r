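# Assembly of the final structure: decompose layer folds into helices,
# filter alternative helices without covariation support, merge all layers
# and annotate interaction classes (pk / tr / sc / xc).

#' Decompose a nested pair set into helices
#'
#' A helix is a run of contiguous basepairs; pairs separated by a bulge of
#' one or two residues on one strand (none on the other) or by a 1x1
#' internal loop still belong to the same helix. Every pair belongs to
#' exactly one helix; a helix may consist of a single pair. A helix is
#' positive if it contains at least one positive pair.
#'
#' @param pairs data.frame of nested pairs (\code{i}, \code{j}).
#' @param positives data.frame of positive pairs (or NULL).
#' @return \code{pairs} sorted by \code{i}, with columns \code{helix}
#'   (1-based id) and \code{positive} (per pair) added; the per-helix flag
#'   is attached as attribute \code{helix_positive}.
#' @export
decompose_helices <- function(pairs, positives = NULL) {
  if (nrow(pairs) == 0L) {
    pairs$helix <- integer(0); pairs$positive <- logical(0)
    attr(pairs, "helix_positive") <- logical(0)
    return(pairs)
  }
  pairs <- pairs[order(pairs$i, pairs$j), , drop = FALSE]
  rownames(pairs) <- NULL
  h <- integer(nrow(pairs))
  h[1] <- 1L
  if (nrow(pairs) > 1L) {
    for (k in 2:nrow(pairs)) {
      di <- pairs$i[k] - pairs$i[k - 1] - 1L
      dj <- pairs$j[k - 1] - pairs$j[k] - 1L
      same <- di >= 0L && dj >= 0L &&            # nested continuation
        ((dj == 0L && di <= 2L) || (di == 0L && dj <= 2L) ||
           (di == 1L && dj == 1L))
      h[k] <- if (same) h[k - 1] else h[k - 1] + 1L
    }
  }
  pkey <- if (!is.null(positives) && nrow(positives) > 0L)
    paste(positives$i, positives$j) else character(0)
  pairs$helix <- h
  pairs$positive <- paste(pairs$i, pairs$j) %in% pkey
  attr(pairs, "helix_positive") <-
    as.logical(tapply(pairs$positive, pairs$helix, any))
  pairs
}

helix_residues <- function(df) unique(c(df$i, df$j))

#' Filter alternative helices against previously selected structure
#'
#' Helices from the alternative layers are processed in cascade order.
#' Positive helices (containing at least one positive pair) are always
#' kept. Helices without covariation support are kept only if they have at
#' least \code{min_alt_helix} basepairs and share no more than
#' \code{max_overlap_frac} of their residues with the union of helices
#' already selected (seeded with the layer-0 structure).
#'
#' @param s0_pairs layer-0 (nested) pairs data.frame.
#' @param alt_layers list over layers >= 1 of \code{decompose_helices}
#'   results.
#' @param min_alt_helix minimum basepairs for an unsupported helix
#'   (default 15).
#' @param max_overlap_frac maximum residue-overlap fraction (default 0.5),
#'   measured relative to the candidate helix.
#' @return data.frame of kept alternative pairs with columns \code{i},
#'   \code{j}, \code{layer}, \code{helix}, \code{positive}.
#' @export
filter_alternative_helices <- function(s0_pairs, alt_layers,
                                       min_alt_helix = 15L,
                                       max_overlap_frac = 0.5) {
  selected_res <- helix_residues(s0_pairs)
  kept <- list()
  for (ly in seq_along(alt_layers)) {
    df <- alt_layers[[ly]]
    if (is.null(df) || nrow(df) == 0L) next
    layer_index <- attr(df, "layer_index")
    if (is.null(layer_index)) layer_index <- ly
    hpos <- attr(df, "helix_positive")
    for (hx in sort(unique(df$helix))) {
      hdf <- df[df$helix == hx, , drop = FALSE]
      res <- helix_residues(hdf)
      keep <- if (hpos[hx]) TRUE else {
        overlap <- length(intersect(res, selected_res)) / length(res)
        nrow(hdf) >= min_alt_helix && overlap <= max_overlap_frac
      }
      if (keep) {
        hdf$layer <- layer_index
        kept[[length(kept) + 1L]] <- hdf
        selected_res <- union(selected_res, res)
      }
    }
  }
  if (length(kept) == 0L)
    return(data.frame(i = integer(0), j = integer(0), layer = integer(0),
                      helix = integer(0), positive = logical(0)))
  out <- do.call(rbind, lapply(kept, function(d)
    d[, c("i", "j", "layer", "helix", "positive"), drop = FALSE]))
  rownames(out) <- NULL
  out
}

#' Merge layer folds into the final annotated structure
#'
#' Combines the layer-0 nested structure with the kept alternative helices,
#' flags covariation support per pair, and verifies the central guarantees:
#' every positive pair appears exactly once, and no negative pair appears.
#'
#' @param s0 layer-0 \code{fold_result}.
#' @param kept_alt kept alternative pairs from
#'   \code{\link{filter_alternative_helices}}.
#' @param positives,negatives positive / negative pair data.frames.
#' @param map analyzed-to-original column index map.
#' @return An \code{annotated_structure}: list with \code{nested} (layer-0
#'   pairs with \code{positive} flag), \code{alt} (extra pairs with
#'   \code{layer}, \code{helix}, \code{positive} and \code{label}),
#'   \code{map}.
#' @export
merge_structure <- function(s0, kept_alt, positives, negatives, map = NULL) {
  pkey <- paste(positives$i, positives$j)
  nested <- s0$pairs[, c("i", "j"), drop = FALSE]
  nested$positive <- paste(nested$i, nested$j) %in% pkey

  alt <- kept_alt
  if (nrow(alt) > 0L) {
    # drop unsupported duplicates of pairs already present
    dup <- paste(alt$i, alt$j) %in% paste(nested$i, nested$j) & !alt$positive
    alt <- alt[!dup, , drop = FALSE]
  }
  st <- structure(list(nested = nested, alt = alt, map = map),
                  class = "annotated_structure")
  st <- annotate_structure(st)

  all_pairs <- rbind(nested[, c("i", "j")], alt[, c("i", "j")])
  akey <- paste(all_pairs$i, all_pairs$j)
  if (!all(pkey %in% akey) || any(table(akey[akey %in% pkey]) > 1L))
    stop("internal error: positive pairs are not represented exactly once")
  if (nrow(negatives) > 0L && any(akey %in% paste(negatives$i, negatives$j)))
    stop("internal error: a negative pair entered the final structure")
  st
}

#' Annotate interaction classes of the alternative pairs
#'
#' Alternative helices sharing no residue with the main nested structure
#' are pseudoknots ("pk"); helices sharing a residue are triplets ("tr").
#' Among covarying pairs, an extra covarying pair between residues on the
#' same strand of one helix is a side-covariation ("sc"), between opposite
#' strands a cross-covariation ("xc"); these labels refine pk/tr for the
#' pairs concerned and never change which pairs are kept.
#'
#' @param st an \code{annotated_structure}.
#' @return \code{st} with a \code{label} column on \code{st$alt}.
#' @export
annotate_structure <- function(st) {
  alt <- st$alt
  if (is.null(alt) || nrow(alt) == 0L) {
    if (!is.null(alt)) alt$label <- character(0)
    st$alt <- alt
    return(st)
  }
  nested_res <- helix_residues(st$nested)
  lab <- character(nrow(alt))
  for (key in unique(paste(alt$layer, alt$helix))) {
    sel <- paste(alt$layer, alt$helix) == key
    res <- helix_residues(alt[sel, , drop = FALSE])
    lab[sel] <- if (length(intersect(res, nested_res)) == 0L) "pk" else "tr"
  }
  # sc / xc refinement among covarying pairs of the final structure
  helices <- rbind(
    cbind(decompose_helices(st$nested,
                            st$nested[st$nested$positive, , drop = FALSE])[
      , c("i", "j", "helix", "positive")], group = "nested"),
    if (nrow(alt) > 0L)
      data.frame(i = alt$i, j = alt$j,
                 helix = as.integer(factor(paste(alt$layer, alt$helix))),
                 positive = alt$positive, group = "alt"))
  cov_alt <- which(alt$positive)
  for (k in cov_alt) {
    a <- alt$i[k]; b <- alt$j[k]
    for (g in unique(helices$group)) {
      hsub <- helices[helices$group == g & helices$positive, , drop = FALSE]
      for (hx in unique(hsub$helix)) {
        hp <- hsub[hsub$helix == hx, , drop = FALSE]
        if (nrow(hp) < 2L) next
        same_key <- paste(a, b)
        for (p1 in seq_len(nrow(hp) - 1L)) for (p2 in (p1 + 1L):nrow(hp)) {
          i1 <- hp$i[p1]; j1 <- hp$j[p1]; i2 <- hp$i[p2]; j2 <- hp$j[p2]
          if (paste(i1, j1) == same_key || paste(i2, j2) == same_key) next
          ends <- sort(c(a, b))
          if (identical(ends, sort(c(i1, i2))) || identical(ends, sort(c(j1, j2))))
            lab[k] <- "sc"
          else if (identical(ends, sort(c(i1, j2))) || identical(ends, sort(c(i2, j1))))
            lab[k] <- "xc"
        }
      }
    }
  }
  alt$label <- lab
  st$alt <- alt
  st
}

#' @export
print.annotated_structure <- function(x, ...) {
  cat("annotated structure:", nrow(x$nested), "nested pairs,",
      nrow(x$alt), "alternative pairs\n")
  if (nrow(x$alt) > 0L) {
    tab <- table(x$alt$label)
    cat("  labels:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Export the final structure as a pairs TSV
#'
#' @param st an \code{annotated_structure}.
#' @param stats optional \code{pair_stats} to attach E-values and power.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_structure_tsv <- function(st, stats = NULL, path) {
  nested <- st$nested
  df <- rbind(
    data.frame(i = nested$i, j = nested$j, layer = 0L,
               label = "nested", positive = nested$positive),
    if (nrow(st$alt) > 0L)
      data.frame(i = st$alt$i, j = st$alt$j, layer = st$alt$layer,
                 label = st$alt$label, positive = st$alt$positive))
  if (!is.null(st$map)) {
    df$col_i <- st$map[df$i]; df$col_j <- st$map[df$j]
  }
  if (!is.null(stats)) {
    m <- match(paste(df$i, df$j), paste(stats$i, stats$j))
    df$evalue <- stats$evalue[m]
    df$power <- stats$power[m]
  }
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a minimal SVG arc diagram of the structure
#'
#' Residue positions on a horizontal backbone; nested pairs drawn as arcs
#' above, alternative pairs below, covarying pairs highlighted in green.
#' Conservation display thresholds follow the convention red > 97%%,
#' black > 90%%, gray > 75%% (legend only).
#'
#' @param st an \code{annotated_structure}.
#' @param profile optional \code{profile_seq} for the conservation legend.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_structure_svg <- function(st, profile = NULL, path) {
  n <- max(c(st$nested$i, st$nested$j, st$alt$i, st$alt$j, 10L))
  xscale <- 8; x0 <- 20; y0 <- 160
  width <- x0 * 2 + n * xscale
  arc <- function(i, j, up, col) {
    xi <- x0 + i * xscale; xj <- x0 + j * xscale
    r <- (xj - xi) / 2
    sprintf('<path d="M %g %g A %g %g 0 0 %d %g %g" stroke="%s" fill="none" stroke-width="1.2"/>',
            xi, y0, r, min(r, 120), if (up) 1 else 0, xj, y0, col)
  }
  elems <- c(sprintf('<line x1="%g" y1="%g" x2="%g" y2="%g" stroke="black"/>',
                     x0, y0, x0 + n * xscale, y0))
  for (k in seq_len(nrow(st$nested)))
    elems <- c(elems, arc(st$nested$i[k], st$nested$j[k], TRUE,
                          if (st$nested$positive[k]) "green" else "black"))
  if (nrow(st$alt) > 0L)
    for (k in seq_len(nrow(st$alt)))
      elems <- c(elems, arc(st$alt$i[k], st$alt$j[k], FALSE,
                            if (st$alt$positive[k]) "green" else "gray"))
  legend <- paste0('<text x="20" y="20" font-size="10">green = significant ',
                   'covariation; conservation: red &gt; 97%, black &gt; 90%, ',
                   'gray &gt; 75%</text>')
  svg <- c(sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%g" height="320">', width),
           legend, elems, "</svg>")
  writeLines(svg, path)
  invisible(path)
}
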