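# Independent oracles used to cross-check package computations. These are
# deliberately written with different algorithms from the implementation
# (recursion instead of permutation tables, direct summation instead of
# stats wrappers) so that agreement is informative.

# Brute-force Nei-Gojobori pathway enumeration between two sense codons:
# recursive depth-first walk over all orderings of the differing positions.
# Returns c(Nd, Sd). Pathways through stop codons are excluded unless every
# pathway is blocked, in which case all are used.
oracle_ng_pair <- function(from, to) {
  gc <- Biostrings::GENETIC_CODE
  pos <- which(strsplit(from, "")[[1]] != strsplit(to, "")[[1]])
  if (!length(pos)) return(c(0, 0))
  acc <- list()
  rec <- function(cur, remaining, nd, sd, blocked) {
    if (!length(remaining)) {
      acc[[length(acc) + 1L]] <<- c(nd, sd, as.numeric(blocked))
      return(invisible(NULL))
    }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(to, p, p)
      hit_stop <- blocked || gc[[nxt]] == "*"
      if (gc[[nxt]] == gc[[cur]])
        rec(nxt, setdiff(remaining, p), nd, sd + 1, hit_stop)
      else rec(nxt, setdiff(remaining, p), nd + 1, sd, hit_stop)
    }
  }
  rec(from, pos, 0, 0, FALSE)
  m <- do.call(rbind, acc)
  use <- if (any(m[, 3] == 0)) m[m[, 3] == 0, , drop = FALSE] else m
  c(mean(use[, 1]), mean(use[, 2]))
}

# Independent fractional-site count for one sense codon, written as a flat
# enumeration over the 9 possible point mutations.
oracle_ng_sites <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  syn <- 0
  for (pos in 1:3) {
    outcomes <- character(0)
    for (b in c("A", "C", "G", "T")) {
      if (b == substr(codon, pos, pos)) next
      alt <- codon
      substr(alt, pos, pos) <- b
      outcomes <- c(outcomes, gc[[alt]])
    }
    keep <- outcomes != "*"
    if (any(keep)) syn <- syn + mean(outcomes[keep] == gc[[codon]])
  }
  c(S = syn, N = 3 - syn)
}

# One-sided Fisher p by direct hypergeometric tail summation for the table
# rbind(c(a, b), c(cc, d)); side "less" sums P(X <= a) for the (1,1) cell.
oracle_fisher_tail <- function(a, b, cc, d, side = c("less", "greater")) {
  side <- match.arg(side)
  k <- a + cc                 # first-column total
  m <- a + b                  # first-row total
  n <- cc + d                 # second-row total
  support <- max(0L, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  if (side == "less") sum(probs[support <= a]) else sum(probs[support >= a])
}

# Pearson chi-squared statistic by the textbook formula.
oracle_chisq_stat <- function(tab) {
  e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sum((tab - e)^2 / e)
}

sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

# Reverse-translate a protein with one fixed codon per amino acid; useful
# for building CDS fixtures around the packaged numbering references.
fixed_codon_cds <- function(protein) {
  aa2codon <- c(A = "GCT", C = "TGT", D = "GAT", E = "GAA", F = "TTT",
                G = "GGT", H = "CAT", I = "ATT", K = "AAA", L = "CTT",
                M = "ATG", N = "AAT", P = "CCT", Q = "CAA", R = "CGT",
                S = "TCT", T = "ACT", V = "GTT", W = "TGG", Y = "TAT")
  paste(aa2codon[strsplit(protein, "")[[1]]], collapse = "")
}

codon_match_fraction <- function(a, b) {
  n <- nchar(a)
  mean(substring(a, seq(1, n, 3), seq(3, n, 3)) ==
         substring(b, seq(1, n, 3), seq(3, n, 3)))
}
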