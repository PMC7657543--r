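# Independent oracles used by the tests: exhaustive enumeration of nested
# structures, brute-force maximum-weight nested subsets, and derivation
# counters for the grammar unambiguity property.

# all nested pair sets over L positions with hairpin loops >= min_hairpin
enumerate_nested <- function(L, min_hairpin = 0L) {
  memo <- new.env()
  rec <- function(i, j) {
    if (i > j) return(list(data.frame(i = integer(0), j = integer(0))))
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    out <- list()
    # position i unpaired
    for (s in rec(i + 1L, j)) out[[length(out) + 1L]] <- s
    # position i paired to k
    if (i + 1L + min_hairpin <= j) {
      for (k in (i + 1L + min_hairpin):j) {
        for (inner in rec(i + 1L, k - 1L)) for (rest in rec(k + 1L, j)) {
          out[[length(out) + 1L]] <-
            rbind(data.frame(i = i, j = k), inner, rest)
        }
      }
    }
    memo[[key]] <- out
    out
  }
  rec(1L, as.integer(L))
}

# brute force: maximum-weight nested residue-disjoint subset by subset search
brute_max_nested <- function(pairs) {
  n <- nrow(pairs)
  if (n == 0L) return(pairs)
  crossing <- function(a, b) {
    (pairs$i[a] < pairs$i[b] & pairs$i[b] < pairs$j[a] & pairs$j[a] < pairs$j[b]) ||
      (pairs$i[b] < pairs$i[a] & pairs$i[a] < pairs$j[b] & pairs$j[b] < pairs$j[a])
  }
  shares <- function(a, b) {
    length(intersect(c(pairs$i[a], pairs$j[a]), c(pairs$i[b], pairs$j[b]))) > 0
  }
  best <- 0; best_set <- integer(0)
  for (mask in 0:(2^n - 1)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    ok <- TRUE
    if (length(idx) > 1L) {
      for (a in seq_along(idx)[-1]) for (b in seq_len(a - 1L)) {
        if (crossing(idx[a], idx[b]) || shares(idx[a], idx[b])) { ok <- FALSE; break }
      }
    }
    if (ok) {
      w <- sum(pairs$weight[idx])
      if (w > best) { best <- w; best_set <- idx }
    }
  }
  list(weight = best, pairs = pairs[best_set, , drop = FALSE])
}

# brute-force greedy layering using the subset oracle
brute_layers <- function(pairs) {
  layers <- list()
  remaining <- pairs
  while (nrow(remaining) > 0L) {
    sel <- brute_max_nested(remaining)$pairs
    layers[[length(layers) + 1L]] <- sel
    key <- paste(remaining$i, remaining$j)
    remaining <- remaining[!(key %in% paste(sel$i, sel$j)), , drop = FALSE]
  }
  layers
}

# number of distinct derivations of a given structure under the RBG rules
count_derivations_rbg <- function(partner, min_hairpin = 3L, forced = integer(0)) {
  L <- length(partner)
  if (length(forced) == 0L) forced <- integer(L)
  components <- function(i, j) {
    out <- list(); p <- i
    while (p <= j) {
      if (partner[p] > p && partner[p] <= j) {
        out[[length(out) + 1L]] <- c(p, partner[p]); p <- partner[p] + 1L
      } else p <- p + 1L
    }
    out
  }
  cS <- function(i, j) {
    if (i > j) return(1L)
    if (partner[i] == 0L) return(cS(i + 1L, j))
    if (partner[i] > j) return(0L)
    cF(i, partner[i]) * cS(partner[i] + 1L, j)
  }
  cF <- function(i, j) {  # derivations of pair (i,j) via F0/F5 -> {F5 | P}
    if ((j - 1L) - (i + 1L) >= 1L && partner[i + 1L] == j - 1L)
      return(cF(i + 1L, j - 1L))
    cP(i + 1L, j - 1L, forced_closing = (forced[i] == j))
  }
  cP <- function(i, j, forced_closing) {
    comps <- components(i, j)
    len <- j - i + 1L
    if (length(comps) == 0L) {
      minh <- if (forced_closing) 0L else min_hairpin
      return(if (len >= minh) 1L else 0L)
    }
    if (length(comps) == 1L) {
      a <- comps[[1]][1]; b <- comps[[1]][2]
      if (a == i && b == j) return(0L)  # would be a stacked pair, not P
      return(cF(a, b))
    }
    # multiloop: M1 M ... R chain is deterministic given the components
    prod(vapply(comps, function(cc) cF(cc[1], cc[2]), numeric(1)))
  }
  cS(1L, L)
}

# number of distinct derivations of a structure under the G6X rules
count_derivations_g6x <- function(partner) {
  L <- length(partner)
  cS <- function(i, j) {
    if (i > j) return(1L)
    if (partner[i] == 0L) return(cS(i + 1L, j))
    if (partner[i] > j) return(0L)
    cF(i + 1L, partner[i] - 1L) * cS(partner[i] + 1L, j)
  }
  cF <- function(i, j) {  # loop content of a pair
    if (i > j) return(1L)
    n <- 0L
    if (partner[i] == j) n <- n + cF(i + 1L, j - 1L)  # stacked continuation
    # F -> L S (single full-span paired L excluded)
    if (partner[i] == 0L) n <- n + cS(i + 1L, j)
    else if (partner[i] < j && partner[i] > i)
      n <- n + cF(i + 1L, partner[i] - 1L) * cS(partner[i] + 1L, j)
    n
  }
  cS(1L, L)
}

# random nested structure on L positions (for property tests)
random_nested <- function(L, p_pair = 0.4, min_hairpin = 0L) {
  partner <- integer(L)
  rec <- function(i, j) {
    while (i <= j) {
      if (runif(1) < p_pair && j - i >= min_hairpin + 1L) {
        k <- i + min_hairpin + sample.int(j - i - min_hairpin, 1L)
        partner[i] <<- k; partner[k] <<- i
        rec(i + 1L, k - 1L)
        i <- k + 1L
      } else i <- i + 1L
    }
  }
  rec(1L, L)
  partner
}

partner_to_pairs <- function(partner) {
  i <- which(partner > seq_along(partner))
  data.frame(i = i, j = partner[i])
}

# small helper MSA fixtures ---------------------------------------------------

toy_stockholm <- function(path, interleaved = FALSE) {
  seqs <- c(s1 = "GGGGAAAACCCCACGUACGU",
            s2 = "GGGGAAAACCCCACGUACGU",
            s3 = "GGCGAAAACGCCACGUACGU",
            s4 = "GGAGAAAACUCCACGUACGU",
            s5 = "GGUGAAAACACCACGUACGU")
  ss <-          "<<<<....>>>>........"
  if (!interleaved) {
    lines <- c("# STOCKHOLM 1.0", "",
               paste(names(seqs), seqs),
               paste("#=GC SS_cons", ss), "//")
  } else {
    lines <- c("# STOCKHOLM 1.0", "",
               paste(names(seqs), substr(seqs, 1, 10)),
               paste("#=GC SS_cons", substr(ss, 1, 10)), "",
               paste(names(seqs), substr(seqs, 11, 20)),
               paste("#=GC SS_cons", substr(ss, 11, 20)), "//")
  }
  writeLines(lines, path)
  path
}

# generative sampler from G6X parameters (linear scale), for the
# parameter-recovery training test; aborts samples longer than max_len
sample_g6x <- function(params, max_len = 120L) {
  tS <- exp(params$transitions$tS); tL <- exp(params$transitions$tL)
  tF <- exp(params$transitions$tF)
  e1 <- exp(params$e_single); ep <- exp(params$e_pair)
  es <- exp(params$e_stack)
  nuc <- c("A", "C", "G", "U")
  count <- 0L
  too_long <- FALSE
  bump <- function(k) {
    count <<- count + k
    if (count > max_len) too_long <<- TRUE
  }
  gen_L <- function() {
    if (runif(1) < tL[["pair"]]) {
      xy <- sample.int(16L, 1L, prob = c(ep))
      x <- nuc[(xy - 1L) %% 4L + 1L]; y <- nuc[(xy - 1L) %/% 4L + 1L]
      bump(2L); if (too_long) return(NULL)
      inner <- gen_F(paste0(x, y))
      if (is.null(inner)) return(NULL)
      list(seq = paste0(x, inner$seq, y), ss = paste0("(", inner$ss, ")"))
    } else {
      bump(1L); if (too_long) return(NULL)
      list(seq = nuc[sample.int(4L, 1L, prob = e1)], ss = ".")
    }
  }
  gen_S <- function() {
    sq <- ""; ss <- ""
    while (runif(1) < tS[["LS"]]) {
      el <- gen_L()
      if (is.null(el)) return(NULL)
      sq <- paste0(sq, el$seq); ss <- paste0(ss, el$ss)
    }
    list(seq = sq, ss = ss)
  }
  gen_F <- function(outer) {
    u <- runif(1)
    if (u < tF[["pair"]]) {
      xy <- sample.int(16L, 1L, prob = es[outer, ])
      x <- nuc[(xy - 1L) %% 4L + 1L]; y <- nuc[(xy - 1L) %/% 4L + 1L]
      bump(2L); if (too_long) return(NULL)
      inner <- gen_F(paste0(x, y))
      if (is.null(inner)) return(NULL)
      list(seq = paste0(x, inner$seq, y), ss = paste0("(", inner$ss, ")"))
    } else if (u < tF[["pair"]] + tF[["LS"]]) {
      el <- gen_L(); if (is.null(el)) return(NULL)
      rest <- gen_S(); if (is.null(rest)) return(NULL)
      list(seq = paste0(el$seq, rest$seq), ss = paste0(el$ss, rest$ss))
    } else list(seq = "", ss = "")
  }
  out <- gen_S()
  if (is.null(out) || nchar(out$seq) == 0L) return(NULL)
  out
}

# random profile over L columns (columns renormalised)
random_profile <- function(L, seed) {
  set.seed(seed)
  comp <- matrix(runif(4 * L), 4, L)
  comp <- sweep(comp, 2, colSums(comp), "/")
  rownames(comp) <- c("A", "C", "G", "U")
  structure(list(length = L, composition = comp,
                 consensus_residue = rep("A", L), occupancy = rep(1, L),
                 map = seq_len(L)),
            class = "profile_seq")
}
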