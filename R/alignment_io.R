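#' @useDynLib cacofold, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim quantile rpois runif setNames approx
#' @importFrom utils write.table read.table head tail
NULL

GAP_CHARS <- c("-", ".", "~")

# IUPAC ambiguity -> membership over A,C,G,U (row-normalised later)
IUPAC <- list(
  A = "A", C = "C", G = "G", U = "U",
  R = c("A", "G"), Y = c("C", "U"), S = c("C", "G"), W = c("A", "U"),
  K = c("G", "U"), M = c("A", "C"),
  B = c("C", "G", "U"), D = c("A", "G", "U"), H = c("A", "C", "U"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "U"), X = c("A", "C", "G", "U")
)

NUCS <- c("A", "C", "G", "U")

#' Multiple sequence alignment container
#'
#' Light S3 container for an RNA alignment: equal-length sequences over
#' \code{A,C,G,U}, IUPAC ambiguity codes and the gap symbols \code{- . ~}.
#' \code{T} is normalised to \code{U} and residues are upper-cased on
#' construction.
#'
#' @param sequences character vector of aligned sequences (equal length).
#' @param names sequence names, one per sequence.
#' @param ss_cons optional consensus structure string in WUSS notation, same
#'   length as the alignment.
#' @param gc optional named list of additional per-column annotation lines.
#' @return An object of class \code{rna_msa} with elements \code{sequences},
#'   \code{names}, \code{n_columns}, \code{ss_cons}, \code{gc}.
#' @export
new_msa <- function(sequences, names = NULL, ss_cons = NULL, gc = list()) {
  if (length(sequences) < 1L) stop("alignment must contain at least one sequence")
  sequences <- unname(toupper(sequences))
  sequences <- gsub("T", "U", sequences, fixed = TRUE)
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]
    lab <- if (!is.null(names)) names[bad] else paste0("sequence ", bad)
    stop("ragged alignment: '", lab, "' has length ", lens[bad],
         " but expected ", lens[1L])
  }
  n_col <- lens[1L]
  if (n_col < 1L) stop("alignment must have at least one column")
  if (is.null(names)) names <- paste0("seq", seq_along(sequences))
  if (!is.null(ss_cons)) {
    if (nchar(ss_cons) != n_col)
      stop("ss_cons length ", nchar(ss_cons), " != alignment length ", n_col)
    parse_wuss(ss_cons)  # validates balance
  }
  structure(list(sequences = sequences, names = names, n_columns = n_col,
                 ss_cons = ss_cons, gc = gc),
            class = "rna_msa")
}

#' @export
print.rna_msa <- function(x, ...) {
  cat("RNA alignment:", length(x$sequences), "sequences x", x$n_columns,
      "columns", if (!is.null(x$ss_cons)) "(with SS_cons)" else "", "\n")
  invisible(x)
}

#' Read a Stockholm 1.0 alignment
#'
#' Reads single-block or interleaved Stockholm files, concatenating sequence
#' blocks. The \code{#=GC SS_cons} line (and any other \code{#=GC} lines) are
#' captured. \code{T} is normalised to \code{U}; residues are upper-cased.
#'
#' @param path path to a Stockholm file.
#' @return An \code{rna_msa}.
#' @export
read_stockholm <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  if (!any(grepl("^# STOCKHOLM", lines)))
    stop("not a Stockholm file (missing '# STOCKHOLM' header): ", path)
  if (!any(trimws(lines) == "//"))
    stop("malformed Stockholm file (missing '//' terminator): ", path)
  end <- which(trimws(lines) == "//")[1L]
  lines <- lines[seq_len(end - 1L)]

  seqs <- character(0); nms <- character(0)
  gc <- list()
  for (ln in lines) {
    if (grepl("^#=GC\\s", ln)) {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) >= 3) {
        tag <- f[2]; txt <- f[3]
        gc[[tag]] <- paste0(if (is.null(gc[[tag]])) "" else gc[[tag]], txt)
      }
    } else if (grepl("^#", ln) || !nzchar(trimws(ln))) {
      next
    } else {
      f <- strsplit(trimws(ln), "\\s+")[[1]]
      if (length(f) < 2) next
      nm <- f[1]; sq <- f[2]
      k <- match(nm, nms)
      if (is.na(k)) { nms <- c(nms, nm); seqs <- c(seqs, sq) }
      else seqs[k] <- paste0(seqs[k], sq)
    }
  }
  if (length(seqs) == 0L) stop("no sequences found in ", path)
  ss <- gc[["SS_cons"]]
  new_msa(seqs, nms, ss_cons = ss, gc = gc)
}

#' Read an aligned FASTA file
#'
#' @param path path to an aligned (equal-length) FASTA file.
#' @return An \code{rna_msa}.
#' @export
read_aligned_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    ss <- Biostrings::readBStringSet(path)
    new_msa(as.character(ss), names(ss))
  } else {
    lines <- readLines(path, warn = FALSE)
    hdr <- grepl("^>", lines)
    if (!any(hdr)) stop("not a FASTA file: ", path)
    idx <- cumsum(hdr)
    nms <- sub("^>\\s*", "", lines[hdr])
    nms <- sub("\\s.*$", "", nms)
    seqs <- vapply(seq_along(nms), function(k)
      paste0(lines[!hdr & idx == k], collapse = ""), character(1))
    new_msa(seqs, nms)
  }
}

# ---- WUSS -------------------------------------------------------------------

WUSS_OPEN  <- c("<", "(", "[", "{", LETTERS)
WUSS_CLOSE <- c(">", ")", "]", "}", letters)
WUSS_CLASS <- c("<>", "()", "[]", "{}", paste0(LETTERS, letters))

#' Parse a WUSS secondary-structure string
#'
#' Each bracket class (\code{<>}, \code{()}, \code{[]}, \code{\{\}}, and the
#' pseudoknot letter classes \code{Aa}..\code{Zz}) is decoded independently by
#' stack matching. Unpaired symbols are \code{. , : _ - ~}.
#'
#' @param ss a WUSS string.
#' @return data.frame with columns \code{i}, \code{j} (1-based, \code{i < j})
#'   and \code{wuss_class}; zero rows for a fully unpaired string.
#' @export
parse_wuss <- function(ss) {
  chars <- strsplit(ss, "")[[1]]
  out_i <- integer(0); out_j <- integer(0); out_c <- character(0)
  for (k in seq_along(WUSS_OPEN)) {
    op <- WUSS_OPEN[k]; cl <- WUSS_CLOSE[k]
    if (!any(chars == op) && !any(chars == cl)) next
    stack <- integer(0)
    for (p in seq_along(chars)) {
      if (chars[p] == op) stack <- c(stack, p)
      else if (chars[p] == cl) {
        if (length(stack) == 0L)
          stop("unbalanced WUSS class '", WUSS_CLASS[k],
               "': unmatched '", cl, "' at position ", p)
        out_i <- c(out_i, stack[length(stack)])
        out_j <- c(out_j, p)
        out_c <- c(out_c, WUSS_CLASS[k])
        stack <- stack[-length(stack)]
      }
    }
    if (length(stack) > 0L)
      stop("unbalanced WUSS class '", WUSS_CLASS[k],
           "': unmatched '", op, "' at position ", stack[length(stack)])
  }
  known <- c(WUSS_OPEN, WUSS_CLOSE, ".", ",", ":", "_", "-", "~")
  bad <- setdiff(unique(chars), known)
  if (length(bad) > 0L)
    stop("unknown WUSS character(s): ", paste(bad, collapse = " "))
  df <- data.frame(i = out_i, j = out_j, wuss_class = out_c,
                   stringsAsFactors = FALSE)
  df[order(df$i, df$j), , drop = FALSE]
}

#' Render a nested pair set as a WUSS string
#'
#' @param pairs data.frame with columns \code{i}, \code{j} (1-based, nested).
#' @param n total number of columns.
#' @param class a two-character WUSS bracket class, e.g. \code{"<>"} or
#'   \code{"Aa"}.
#' @return A string of length \code{n}.
#' @export
wuss_string <- function(pairs, n, class = "<>") {
  k <- match(class, WUSS_CLASS)
  if (is.na(k)) stop("unknown WUSS class: ", class)
  chars <- rep(".", n)
  if (nrow(pairs) > 0) {
    chars[pairs$i] <- WUSS_OPEN[k]
    chars[pairs$j] <- WUSS_CLOSE[k]
  }
  paste0(chars, collapse = "")
}

# ---- column selection and profile ------------------------------------------

#' Select analyzable alignment columns by gap fraction
#'
#' Columns whose gap fraction exceeds \code{gap_cutoff} are removed from the
#' analysis; all statistics and folding run on the retained (analyzed)
#' columns, with an explicit map back to original coordinates.
#'
#' @param msa an \code{rna_msa}.
#' @param gap_cutoff maximum tolerated gap fraction (default 0.75). Use 1 to
#'   analyze all columns.
#' @return An object of class \code{column_mask}: list with \code{analyzed}
#'   (strictly increasing original 1-based indices), \code{gap_fraction}
#'   (per original column) and \code{gap_cutoff}.
#' @export
select_columns <- function(msa, gap_cutoff = 0.75) {
  stopifnot(inherits(msa, "rna_msa"))
  if (!(gap_cutoff > 0 && gap_cutoff <= 1))
    stop("gap_cutoff must be in (0, 1]")
  m <- msa_matrix(msa)
  gap_frac <- colMeans(matrix(m %in% GAP_CHARS, nrow = nrow(m)))
  analyzed <- which(gap_frac <= gap_cutoff)
  if (length(analyzed) == 0L)
    stop("no columns left after applying gap cutoff ", gap_cutoff)
  structure(list(analyzed = analyzed, gap_fraction = gap_frac,
                 gap_cutoff = gap_cutoff),
            class = "column_mask")
}

# character matrix view of the alignment (rows = sequences)
msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$sequences, ""))
}

# N x 4L weight matrix: per sequence/column fractional nucleotide membership
# (gaps = all-zero). Column block c occupies columns (4(c-1)+1)..4c.
msa_weights <- function(msa, columns = NULL) {
  m <- msa_matrix(msa)
  if (!is.null(columns)) m <- m[, columns, drop = FALSE]
  n <- nrow(m); L <- ncol(m)
  W <- matrix(0, n, 4L * L)
  for (sym in names(IUPAC)) {
    hits <- which(m == sym, arr.ind = TRUE)
    if (nrow(hits) == 0L) next
    mem <- IUPAC[[sym]]
    w <- 1 / length(mem)
    for (nt in mem) {
      x <- match(nt, NUCS)
      W[cbind(hits[, 1], 4L * (hits[, 2] - 1L) + x)] <- w
    }
  }
  W
}

#' Build the profile sequence over analyzed columns
#'
#' The profile records, for every analyzed column, the proportion of each
#' nucleotide (over all sequences; ambiguity codes contribute fractionally;
#' the remainder up to 1 is the gap fraction), the consensus residue and the
#' column occupancy. Folding grammars score emissions against this profile.
#'
#' @param msa an \code{rna_msa}.
#' @param mask a \code{column_mask} derived from \code{msa}.
#' @return Object of class \code{profile_seq}: list with \code{length},
#'   \code{composition} (4 x length matrix, rows A,C,G,U, columns summing to
#'   the column occupancy), \code{consensus_residue}, \code{occupancy} and
#'   \code{map} (analyzed -> original column indices).
#' @export
build_profile <- function(msa, mask) {
  stopifnot(inherits(msa, "rna_msa"), inherits(mask, "column_mask"))
  W <- msa_weights(msa, mask$analyzed)
  n <- nrow(W); L <- length(mask$analyzed)
  comp <- matrix(colSums(W), nrow = 4L)  # 4 x L, raw proportions * n
  comp <- comp / n
  occupancy <- colSums(comp)
  consensus <- NUCS[apply(comp, 2, which.max)]
  consensus[occupancy == 0] <- "-"
  rownames(comp) <- NUCS
  structure(list(length = L, composition = comp,
                 consensus_residue = consensus, occupancy = occupancy,
                 map = mask$analyzed),
            class = "profile_seq")
}

# renormalised composition (columns sum to 1 where occupancy > 0)
profile_freqs <- function(profile) {
  comp <- profile$composition
  occ <- profile$occupancy
  ok <- occ > 0
  comp[, ok] <- sweep(comp[, ok, drop = FALSE], 2, occ[ok], "/")
  comp
}

# ---- annotated Stockholm output --------------------------------------------

#' Write an alignment with a layered consensus structure annotation
#'
#' Emits the original alignment plus a \code{#=GC SS_cons} line for the
#' nested (layer 0) structure and one additional \code{#=GC SS_cons_k} line
#' per extra layer, each extra layer using a distinct WUSS pseudoknot letter
#' class. Structure coordinates (analyzed columns) are mapped back to
#' original alignment columns exactly.
#'
#' @param msa the \code{rna_msa} that was analyzed.
#' @param structure an \code{annotated_structure} from
#'   \code{\link{merge_structure}}, or NULL for no structure lines.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_annotated_stockholm <- function(msa, structure, path) {
  n_col <- msa$n_columns
  lines <- c("# STOCKHOLM 1.0", "")
  w <- max(nchar(msa$names), nchar("#=GC SS_cons_XX"))
  fmt <- function(nm, txt) sprintf("%-*s %s", w, nm, txt)
  lines <- c(lines, mapply(fmt, msa$names, msa$sequences, USE.NAMES = FALSE))

  if (!is.null(structure)) {
    map <- structure$map
    to_orig <- function(df) {
      df$i <- map[df$i]; df$j <- map[df$j]; df
    }
    nested <- to_orig(structure$nested)
    lines <- c(lines, fmt("#=GC SS_cons", wuss_string(nested, n_col, "<>")))
    alt <- structure$alt
    if (!is.null(alt) && nrow(alt) > 0) {
      layers <- sort(unique(alt$layer))
      if (length(layers) > 26L)
        stop("more alternative layers (", length(layers),
             ") than available WUSS pseudoknot classes (26)")
      for (k in seq_along(layers)) {
        cls <- WUSS_CLASS[4L + k]
        sub <- to_orig(alt[alt$layer == layers[k], , drop = FALSE])
        lines <- c(lines,
                   fmt(paste0("#=GC SS_cons_", k), wuss_string(sub, n_col, cls)))
      }
    }
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Export a column mask as TSV
#'
#' @param mask a \code{column_mask}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_mask_tsv <- function(mask, path) {
  df <- data.frame(column = seq_along(mask$gap_fraction),
                   gap_fraction = mask$gap_fraction,
                   analyzed = seq_along(mask$gap_fraction) %in% mask$analyzed)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
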