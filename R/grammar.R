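# Probabilistic grammar parameters for the RBG and G6X folding engines:
# plain-text parameter files, maximum-likelihood training from nested
# structures (both grammars are unambiguous, so each structure has exactly
# one parse and rule counts are well defined), and a recursive single-parse
# scorer used as the enumeration oracle in the tests.

PAIR_NAMES <- as.vector(outer(NUCS, NUCS, paste0))  # AA AC .. UU (row-major x)
MAX_LOOP_LEN <- 400L     # support of the length distributions
LOOP_TRUNC <- 30L        # observed lengths are modelled up to here ...
LOOP_TAIL_Q <- 0.9       # ... with a geometric tail beyond

rbg_transition_spec <- list(
  tS = c("aS", "F0S", "end"),
  tF0 = c("stack", "close"),
  tF5 = c("stack", "close"),
  tP = c("hairpin", "bulgeL", "bulgeR", "intloop", "multi"),
  tM = c("M1M", "R"),
  tM1 = c("aM1", "F0"),
  tR = c("Ra", "M1")
)
g6x_transition_spec <- list(
  tS = c("LS", "eps"),
  tL = c("pair", "a"),
  tF = c("pair", "LS", "eps")
)

#' Construct a grammar parameter object
#'
#' @param grammar_id "RBG" or "G6X".
#' @param transitions named list of per-nonterminal probability vectors
#'   (linear scale, each summing to 1).
#' @param e_single length-4 single-residue emission distribution (A,C,G,U).
#' @param e_pair 4 x 4 basepair emission distribution.
#' @param e_stack 16 x 16 stacked-pair emission (rows: enclosing pair,
#'   columns: emitted pair; each row sums to 1) -- the shorthand for the 16
#'   context-conditioned pair nonterminals.
#' @param e_pair_parallel 4 x 4 emission for parallel-orientation pairs
#'   (G6X only).
#' @param lengths named list of loop length distributions (RBG only):
#'   \code{hairpin} (lengths 0..), \code{bulge} and \code{intloop_side}
#'   (lengths 1..), each summing to 1.
#' @return Object of class \code{grammar_params} (log-probabilities stored).
#' @export
grammar_params <- function(grammar_id, transitions, e_single, e_pair,
                           e_stack, e_pair_parallel = NULL, lengths = NULL) {
  spec <- if (grammar_id == "RBG") rbg_transition_spec else g6x_transition_spec
  stopifnot(identical(sort(names(transitions)), sort(names(spec))))
  for (nt in names(spec)) {
    v <- transitions[[nt]]
    stopifnot(length(v) == length(spec[[nt]]),
              abs(sum(v) - 1) < 1e-9, all(v >= 0))
  }
  norm1 <- function(x) abs(sum(x) - 1) < 1e-9
  stopifnot(norm1(e_single), norm1(e_pair), all(apply(e_stack, 1, norm1)))
  if (!is.null(lengths)) stopifnot(all(vapply(lengths, norm1, logical(1))))
  obj <- list(grammar_id = grammar_id,
              transitions = lapply(transitions, log),
              e_single = log(e_single),
              e_pair = log(e_pair),
              e_stack = log(e_stack),
              e_pair_parallel = if (!is.null(e_pair_parallel)) log(e_pair_parallel),
              lengths = if (!is.null(lengths)) lapply(lengths, log))
  class(obj) <- "grammar_params"
  obj
}

# geometric-tailed, pseudocount-regularised length distribution from counts
length_distribution <- function(counts_by_len, min_len, pseudocount = 0.5) {
  lens <- min_len:MAX_LOOP_LEN
  u <- numeric(length(lens))
  trunc_idx <- which(lens <= LOOP_TRUNC)
  u[trunc_idx] <- pseudocount
  for (l in as.integer(names(counts_by_len))) {
    k <- match(min(l, LOOP_TRUNC), lens)
    u[k] <- u[k] + counts_by_len[[as.character(l)]]
  }
  last <- u[match(LOOP_TRUNC, lens)]
  tail_idx <- which(lens > LOOP_TRUNC)
  u[tail_idx] <- last * LOOP_TAIL_Q^(lens[tail_idx] - LOOP_TRUNC)
  p <- u / sum(u)
  names(p) <- lens
  p
}

# ---- unique-parse walker ----------------------------------------------------

# Walks the unique parse of a nested structure under one of the grammars and
# calls the visitor for every rule application and emission. `partner` is the
# 0-defaulted partner vector. Used for both training counts and for the
# recursive parse scorer.
walk_parse <- function(grammar_id, partner, visit) {
  L <- length(partner)
  # top-level components of an interval: list of (start, end) of helices
  components <- function(i, j) {
    out <- list(); p <- i
    while (p <= j) {
      if (partner[p] > p && partner[p] <= j) {
        out[[length(out) + 1L]] <- c(p, partner[p]); p <- partner[p] + 1L
      } else p <- p + 1L
    }
    out
  }
  if (grammar_id == "RBG") {
    wS <- function(i, j) {
      if (i > j) { visit("tS", "end"); return(invisible()) }
      if (partner[i] == 0) {
        visit("tS", "aS"); visit("single", i); wS(i + 1, j)
      } else {
        k <- partner[i]
        visit("tS", "F0S"); wF(i, k, outer = NULL); wS(k + 1, j)
      }
    }
    wF <- function(i, j, outer) {  # pair (i,j); outer = enclosing pair or NULL
      nt <- if (is.null(outer)) "tF0" else "tF5"
      if (is.null(outer)) visit("pair", i, j) else visit("stack", outer[1], outer[2], i, j)
      if ((j - 1) - (i + 1) >= 1 && partner[i + 1] == j - 1) {
        visit(nt, "stack"); wF(i + 1, j - 1, outer = c(i, j))
      } else {
        visit(nt, "close"); wP(i + 1, j - 1, closing = c(i, j))
      }
    }
    wP <- function(i, j, closing) {
      comps <- components(i, j)
      len <- j - i + 1
      if (length(comps) == 0L) {
        visit("tP", "hairpin")
        visit("len_hairpin", len, closing[1], closing[2])
        for (p in seq_len(len)) visit("single", i + p - 1)
      } else if (length(comps) == 1L) {
        a <- comps[[1]][1]; b <- comps[[1]][2]
        l1 <- a - i; l2 <- j - b
        stopifnot(l1 > 0 || l2 > 0)  # flush helix would be a stacked pair
        if (l1 > 0 && l2 == 0) { visit("tP", "bulgeL"); visit("len_bulge", l1) }
        else if (l1 == 0 && l2 > 0) { visit("tP", "bulgeR"); visit("len_bulge", l2) }
        else { visit("tP", "intloop"); visit("len_intloop", l1); visit("len_intloop", l2) }
        for (p in seq_len(l1)) visit("single", i + p - 1)
        for (p in seq_len(l2)) visit("single", b + p)
        wF(a, b, outer = NULL)
      } else {
        visit("tP", "multi"); wM(i, j, comps)
      }
    }
    wM <- function(i, j, comps) {
      if (length(comps) >= 2L) {
        visit("tM", "M1M")
        k <- comps[[1]][2]
        wM1(i, k, comps[[1]])
        wM(k + 1, j, comps[-1])
      } else {
        visit("tM", "R"); wR(i, j, comps[[1]])
      }
    }
    wM1 <- function(i, k, comp) {
      while (i < comp[1]) { visit("tM1", "aM1"); visit("single", i); i <- i + 1 }
      visit("tM1", "F0"); wF(comp[1], comp[2], outer = NULL)
    }
    wR <- function(i, j, comp) {
      while (j > comp[2]) { visit("tR", "Ra"); visit("single", j); j <- j - 1 }
      visit("tR", "M1"); wM1(i, comp[2], comp)
    }
    wS(1, L)
  } else {  # G6X
    wS <- function(i, j) {
      if (i > j) { visit("tS", "eps"); return(invisible()) }
      visit("tS", "LS")
      if (partner[i] == 0) {
        visit("tL", "a"); visit("single", i); wS(i + 1, j)
      } else {
        k <- partner[i]
        visit("tL", "pair"); visit("pair", i, k)
        wF(i + 1, k - 1, outer = c(i, k)); wS(k + 1, j)
      }
    }
    wF <- function(i, j, outer) {
      if (i > j) { visit("tF", "eps"); return(invisible()) }
      if (partner[i] == j) {
        visit("tF", "pair"); visit("stack", outer[1], outer[2], i, j)
        wF(i + 1, j - 1, outer = c(i, j))
      } else {
        visit("tF", "LS")
        if (partner[i] == 0) {
          visit("tL", "a"); visit("single", i); wS(i + 1, j)
        } else {
          k <- partner[i]
          visit("tL", "pair"); visit("pair", i, k)
          wF(i + 1, k - 1, outer = c(i, k)); wS(k + 1, j)
        }
      }
    }
    wS(1, L)
  }
  invisible()
}

pairs_to_partner <- function(pairs, L) {
  partner <- integer(L)
  if (!is.null(pairs) && nrow(pairs) > 0L) {
    stopifnot(all(pairs$i < pairs$j), all(pairs$j <= L))
    if (anyDuplicated(c(pairs$i, pairs$j)))
      stop("structure is not a nested pair set: shared residue")
    partner[pairs$i] <- pairs$j
    partner[pairs$j] <- pairs$i
  }
  partner
}

# ---- training ---------------------------------------------------------------

#' Train grammar parameters on nested structures
#'
#' Maximum-likelihood parameters from rule and emission counts of the unique
#' parse of each training structure, with Laplace-style pseudocounts, and
#' geometric-tailed loop length distributions. Pseudoknot letter classes in
#' the structures are stripped (only nested pairs are used).
#'
#' @param training list of entries, each a list with \code{seq} (RNA string)
#'   and \code{ss} (dot-bracket/WUSS string of the same length), or the path
#'   of a file with alternating sequence / structure lines.
#' @param grammar_id "RBG" or "G6X".
#' @param pseudocount added to every transition and emission count.
#' @return A \code{grammar_params} object.
#' @export
train_params <- function(training, grammar_id = c("RBG", "G6X"),
                         pseudocount = 0.5) {
  grammar_id <- match.arg(grammar_id)
  if (is.character(training) && length(training) == 1L)
    training <- read_training_file(training)
  if (length(training) == 0L)
    stop("empty training set; use the bundled default parameters instead")

  spec <- if (grammar_id == "RBG") rbg_transition_spec else g6x_transition_spec
  tc <- lapply(spec, function(opts) setNames(numeric(length(opts)), opts))
  e1 <- setNames(numeric(4), NUCS)
  epair <- matrix(0, 4, 4, dimnames = list(NUCS, NUCS))
  estack <- matrix(0, 16, 16, dimnames = list(PAIR_NAMES, PAIR_NAMES))
  lh <- new.env(); lb <- new.env(); li <- new.env()
  bump <- function(env, len) {
    k <- as.character(len)
    assign(k, (if (exists(k, env)) get(k, env) else 0) + 1, env)
  }

  for (entry in training) {
    sq <- strsplit(toupper(gsub("T", "U", entry$seq)), "")[[1]]
    wdf <- parse_wuss(entry$ss)
    wdf <- wdf[!grepl("^[A-Z][a-z]$", wdf$wuss_class), , drop = FALSE]  # nested only
    partner <- pairs_to_partner(wdf, length(sq))
    visit <- function(what, ...) {
      a <- list(...)
      if (what %in% names(tc)) {
        tc[[what]][[a[[1]]]] <<- tc[[what]][[a[[1]]]] + 1
      } else if (what == "single") {
        x <- sq[a[[1]]]
        if (x %in% NUCS) e1[x] <<- e1[x] + 1
      } else if (what == "pair") {
        x <- sq[a[[1]]]; y <- sq[a[[2]]]
        if (x %in% NUCS && y %in% NUCS) epair[x, y] <<- epair[x, y] + 1
      } else if (what == "stack") {
        ox <- sq[a[[1]]]; oy <- sq[a[[2]]]; x <- sq[a[[3]]]; y <- sq[a[[4]]]
        if (all(c(ox, oy, x, y) %in% NUCS))
          estack[paste0(ox, oy), paste0(x, y)] <<-
            estack[paste0(ox, oy), paste0(x, y)] + 1
      } else if (what == "len_hairpin") bump(lh, a[[1]])
      else if (what == "len_bulge") bump(lb, a[[1]])
      else if (what == "len_intloop") bump(li, a[[1]])
    }
    walk_parse(grammar_id, partner, visit)
  }

  norm <- function(x) (x + pseudocount) / sum(x + pseudocount)
  transitions <- lapply(tc, norm)
  e_single <- norm(e1)
  e_pair <- matrix(norm(c(epair)), 4, 4, dimnames = dimnames(epair))
  # stacked emissions are sparse: smooth each context row towards the
  # unconditional pair distribution (one pseudo-observation per row)
  e_stack <- t(apply(estack, 1, function(r) (r + c(e_pair)) / (sum(r) + 1)))
  dimnames(e_stack) <- dimnames(estack)
  lengths <- NULL
  if (grammar_id == "RBG") {
    lengths <- list(hairpin = length_distribution(as.list(lh), 0L),
                    bulge = length_distribution(as.list(lb), 1L),
                    intloop_side = length_distribution(as.list(li), 1L))
  }
  e_par <- if (grammar_id == "G6X") e_pair else NULL
  grammar_params(grammar_id, transitions, e_single, e_pair, e_stack,
                 e_pair_parallel = e_par, lengths = lengths)
}

read_training_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !grepl("^#", lines)]
  if (length(lines) %% 2L != 0L)
    stop("training file must contain alternating sequence/structure lines")
  lapply(seq_len(length(lines) / 2L), function(k)
    list(seq = lines[2L * k - 1L], ss = lines[2L * k]))
}

# ---- parameter file I/O -----------------------------------------------------

#' Write grammar parameters to a plain-text file
#'
#' Key/value format, linear-scale probabilities, one distribution per line.
#'
#' @param params a \code{grammar_params} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_params <- function(params, path) {
  num <- function(x) paste(format(exp(x), digits = 10, scientific = TRUE), collapse = " ")
  lines <- c(paste("grammar", params$grammar_id), "version 1")
  for (nt in names(params$transitions))
    lines <- c(lines, paste(nt, num(params$transitions[[nt]])))
  lines <- c(lines, paste("e_single", num(params$e_single)),
             paste("e_pair", num(c(params$e_pair))))
  for (r in seq_len(16))
    lines <- c(lines, paste0("e_stack_", PAIR_NAMES[r], " ",
                             num(params$e_stack[r, ])))
  if (!is.null(params$e_pair_parallel))
    lines <- c(lines, paste("e_pair_parallel", num(c(params$e_pair_parallel))))
  if (!is.null(params$lengths))
    for (nm in names(params$lengths))
      lines <- c(lines, paste(paste0("len_", nm), num(params$lengths[[nm]])))
  writeLines(lines, path)
  invisible(path)
}

#' Read grammar parameters from a plain-text file
#'
#' @param path a file written by \code{\link{write_params}}.
#' @return A \code{grammar_params} object.
#' @export
read_params <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s+")
  keys <- vapply(kv, `[`, character(1), 1)
  val <- function(key) as.numeric(kv[[match(key, keys)]][-1])
  grammar_id <- kv[[match("grammar", keys)]][2]
  spec <- if (grammar_id == "RBG") rbg_transition_spec else g6x_transition_spec
  transitions <- lapply(setNames(nm = names(spec)), function(nt)
    setNames(val(nt), spec[[nt]]))
  e_stack <- t(vapply(PAIR_NAMES, function(p) val(paste0("e_stack_", p)),
                      numeric(16)))
  dimnames(e_stack) <- list(PAIR_NAMES, PAIR_NAMES)
  lengths <- NULL
  if (grammar_id == "RBG") {
    lengths <- list(hairpin = val("len_hairpin"), bulge = val("len_bulge"),
                    intloop_side = val("len_intloop_side"))
    names(lengths$hairpin) <- 0:(length(lengths$hairpin) - 1L)
    names(lengths$bulge) <- seq_along(lengths$bulge)
    names(lengths$intloop_side) <- seq_along(lengths$intloop_side)
  }
  e_par <- if ("e_pair_parallel" %in% keys)
    matrix(val("e_pair_parallel"), 4, 4, dimnames = list(NUCS, NUCS))
  grammar_params(grammar_id, transitions,
                 setNames(val("e_single"), NUCS),
                 matrix(val("e_pair"), 4, 4, dimnames = list(NUCS, NUCS)),
                 e_stack, e_pair_parallel = e_par, lengths = lengths)
}

the_params <- new.env(parent = emptyenv())

#' Default grammar parameters
#'
#' Loads the parameter files shipped with the package, which were trained
#' with \code{\link{train_params}} on the bundled synthetic training set of
#' nested structures (\code{inst/extdata/training_structures.txt}).
#'
#' @param grammar_id "RBG" or "G6X".
#' @return A \code{grammar_params} object.
#' @export
default_params <- function(grammar_id = c("RBG", "G6X")) {
  grammar_id <- match.arg(grammar_id)
  key <- tolower(grammar_id)
  if (is.null(the_params[[key]])) {
    path <- system.file("extdata", paste0(key, "_params.txt"),
                        package = "cacofold")
    the_params[[key]] <- read_params(path)
  }
  the_params[[key]]
}
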