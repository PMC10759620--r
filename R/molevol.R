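#' Codon alignment on a fixed rooted topology
#'
#' @param sequences named character vector of equal-length, in-frame,
#'   gap-free coding sequences (A/C/G/T only, no internal stop codons).
#' @param topology rooted `phylo` tree or Newick string whose tips are a
#'   subset of `names(sequences)`.
#' @return an object of class `codon_alignment`.
#' @export
codon_alignment <- function(sequences, topology) {
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop_input("sequences must be a named character vector")
  sequences <- toupper(unlist(sequences))
  lens <- nchar(sequences)
  if (length(unique(lens)) != 1L)
    stop_input("all sequences must have equal length")
  if (lens[1L] %% 3L != 0L)
    stop_input("sequence length must be divisible by 3")
  if (any(grepl("[^ACGT]", sequences)))
    stop_input("sequences must be gap-free and contain only A/C/G/T")
  for (id in names(sequences)) {
    if (has_internal_stop(translate_cds(sequences[[id]])))
      stop_input("sequence '", id, "' contains an internal stop codon")
  }
  tree <- as_rooted_tree(topology)
  if (!all(tree$tip.label %in% names(sequences)))
    stop_input("topology tips must all appear among the sequences")
  structure(list(taxa = names(sequences), sequences = sequences,
                 topology = tree, n_codons = lens[1L] %/% 3L),
            class = "codon_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat(sprintf("<codon_alignment> %d taxa, %d codons\n",
              length(x$taxa), x$n_codons))
  invisible(x)
}

#' Read a codon alignment from FASTA plus Newick files
#'
#' @param fasta path to an in-frame, gap-free FASTA alignment.
#' @param newick path to a rooted Newick topology.
#' @return a [codon_alignment()].
#' @export
read_codon_alignment <- function(fasta, newick) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  codon_alignment(setNames(as.character(seqs), names(seqs)),
                  ape::read.tree(newick))
}

# ---- Nei-Gojobori (1986) counting -----------------------------------------

.ng_cache <- new.env(parent = emptyenv())

# Fractional synonymous site count per sense codon. Per codon position the
# synonymous fraction is (synonymous changes) / (changes not creating a stop
# codon), so synonymous + nonsynonymous sites sum to exactly 3 per codon.
ng_site_table <- function() {
  if (!is.null(.ng_cache$sites)) return(.ng_cache$sites)
  gc <- genetic_code()
  bases <- c("A", "C", "G", "T")
  syn <- setNames(rep(NA_real_, length(gc)), names(gc))
  for (cod in names(gc)) {
    if (gc[[cod]] == "*") next
    s <- 0
    for (pos in 1:3) {
      n_ok <- 0L; n_syn <- 0L
      for (b in setdiff(bases, substr(cod, pos, pos))) {
        alt <- cod
        substr(alt, pos, pos) <- b
        if (gc[[alt]] == "*") next
        n_ok <- n_ok + 1L
        if (gc[[alt]] == gc[[cod]]) n_syn <- n_syn + 1L
      }
      if (n_ok > 0L) s <- s + n_syn / n_ok
    }
    syn[[cod]] <- s
  }
  .ng_cache$sites <- syn
  syn
}

.path_perms <- list(`1` = list(1L),
                    `2` = list(c(1L, 2L), c(2L, 1L)),
                    `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))

# Fractional (Nd, Sd) between two sense codons: average over all orderings
# of single-nucleotide steps, excluding pathways through stop codons. If
# every pathway passes through a stop codon, all pathways are used, with a
# step into or out of a stop codon classified as nonsynonymous.
ng_pair_diffs <- function(from, to) {
  if (from == to) return(c(0, 0))
  key <- paste0(from, to)
  hit <- .ng_cache[[key]]
  if (!is.null(hit)) return(hit)
  gc <- genetic_code()
  pos <- which(strsplit(from, "")[[1L]] != strsplit(to, "")[[1L]])
  paths <- lapply(.path_perms[[as.character(length(pos))]],
                  function(p) pos[p])
  walk <- function(order_pos) {
    cur <- from; nd <- 0; sdiff <- 0; blocked <- FALSE
    for (p in order_pos) {
      nxt <- cur
      substr(nxt, p, p) <- substr(to, p, p)
      if (gc[[nxt]] == "*") blocked <- TRUE
      if (gc[[nxt]] == gc[[cur]]) sdiff <- sdiff + 1 else nd <- nd + 1
      cur <- nxt
    }
    c(nd, sdiff, blocked)
  }
  res <- vapply(paths, walk, numeric(3))
  ok <- res[3L, ] == 0
  use <- if (any(ok)) res[, ok, drop = FALSE] else res
  out <- c(mean(use[1L, ]), mean(use[2L, ]))
  assign(key, out, envir = .ng_cache)
  out
}

#' Nei--Gojobori substitution counts for one branch
#'
#' Classic unweighted NG86 counting between a parent and child sequence:
#' fractional synonymous/nonsynonymous site counts (averaged over the two
#' sequences; stop-codon-creating changes are excluded from a position's
#' mutational opportunity so sites sum to 3 per codon) and fractional
#' synonymous/nonsynonymous differences (codons differing at several
#' positions are averaged over all orderings of single steps, excluding
#' pathways through stop codons). Counts are symmetric in the two
#' sequences.
#'
#' @param parent_seq,child_seq equal-length in-frame sequences, no gaps or
#'   internal stops.
#' @param branch optional label, e.g. `"anc->tip"`.
#' @return an object of class `branch_subst_counts` with fields `N_sites`,
#'   `S_sites`, `Nd`, `Sd`, `pN`, `pS`, `omega` (`pN/pS`; `NA` when
#'   undefined), `fisher_p` (`NA` until [branch_omega_test()]) and `flag`.
#' @export
count_branch_substitutions <- function(parent_seq, child_seq, branch = NULL) {
  parent_seq <- toupper(parent_seq); child_seq <- toupper(child_seq)
  if (nchar(parent_seq) != nchar(child_seq))
    stop_input("parent and child sequences must have equal length")
  cp <- split_codons(parent_seq)
  cc <- split_codons(child_seq)
  st <- ng_site_table()
  sp <- st[cp]; sc <- st[cc]
  if (anyNA(sp) || anyNA(sc))
    stop_input("sequences must consist of sense codons only")
  S_sites <- (sum(sp) + sum(sc)) / 2
  N_sites <- 3 * length(cp) - S_sites
  nd <- 0; sdiff <- 0
  for (i in which(cp != cc)) {
    d <- ng_pair_diffs(cp[i], cc[i])
    nd <- nd + d[1L]; sdiff <- sdiff + d[2L]
  }
  pN <- if (N_sites > 0) nd / N_sites else NaN
  pS <- if (S_sites > 0) sdiff / S_sites else NaN
  flag <- "ok"
  omega <- if (nd == 0 && sdiff == 0) {
    flag <- "identical"
    NA_real_
  } else if (!is.finite(pS) || pS == 0) {
    flag <- "pS_zero"
    NA_real_
  } else pN / pS
  structure(list(branch = branch, n_codons = length(cp),
                 N_sites = N_sites, S_sites = S_sites,
                 Nd = nd, Sd = sdiff, pN = pN, pS = pS,
                 omega = omega, fisher_p = NA_real_, side = NA_character_,
                 flag = flag),
            class = "branch_subst_counts")
}

#' @export
print.branch_subst_counts <- function(x, ...) {
  cat(sprintf(
    "<branch_subst_counts>%s N = %.1f, S = %.1f, Nd = %.2f, Sd = %.2f, omega = %s, p = %s [%s]\n",
    if (is.null(x$branch)) "" else paste0(" ", x$branch, ":"),
    x$N_sites, x$S_sites, x$Nd, x$Sd,
    if (is.na(x$omega)) "NA" else sprintf("%.3g", x$omega),
    if (is.na(x$fisher_p)) "NA" else sprintf("%.3g", x$fisher_p),
    x$flag))
  invisible(x)
}

#' Fisher's exact test for dN/dS on one branch
#'
#' One-sided Fisher's exact test on the 2x2 table
#' `[[round(Nd), round(N_sites - Nd)], [round(Sd), round(S_sites - Sd)]]`
#' (half-up rounding; Fisher's test needs integer cells, while the raw
#' fractional counts are preserved in the returned object). Side
#' `"purifying"` tests `pN < pS` (the default, matching an omega-below-one
#' claim); `"positive"` tests `pN > pS`. A branch with no substitutions is
#' reported with `fisher_p = 1` and flag `"identical"`.
#'
#' @param counts a [count_branch_substitutions()] result.
#' @param side `"purifying"` or `"positive"`.
#' @return the input with `fisher_p` and `side` filled.
#' @export
branch_omega_test <- function(counts, side = c("purifying", "positive")) {
  side <- match.arg(side)
  stopifnot(inherits(counts, "branch_subst_counts"))
  if (counts$N_sites <= 0 || counts$S_sites <= 0)
    stop_input("site counts must be positive")
  tab <- matrix(round_half_up(c(counts$Nd, counts$N_sites - counts$Nd,
                                counts$Sd, counts$S_sites - counts$Sd)),
                nrow = 2L, byrow = TRUE)
  if (any(tab < 0))
    stop("internal error: negative cell in the Fisher table")
  counts$side <- side
  counts$fisher_p <- if (sum(tab[, 1L]) == 0L) 1 else
    fisher.test(tab, alternative = if (side == "purifying") "less"
                else "greater")$p.value
  counts
}

# ---- Fitch parsimony -------------------------------------------------------

.nuc_bits <- c(A = 1L, C = 2L, G = 4L, T = 8L)
.bit_nuc <- setNames(c("A", "C", "G", "T"), c(1L, 2L, 4L, 8L))

# lowest set bit = alphabetically first nucleotide (A < C < G < T)
lowest_bit <- function(bits) bitwAnd(bits, -bits)

#' Ancestral codon sequences by Fitch parsimony
#'
#' Reconstructs internal-node sequences on the fixed rooted topology by
#' Fitch parsimony applied to each nucleotide column (a deliberate
#' simplification of likelihood-based ancestral inference; with a closely
#' related ingroup pair plus outgroup and strongly conserved genes the two
#' coincide except at saturated sites). Ambiguous states are resolved
#' deterministically: prefer the outgroup tip's state when it is in the
#' node's state set, otherwise the alphabetically first nucleotide.
#' Reconstructed internal stop codons are replaced by the nearest non-stop
#' combination drawn from the columns' Fitch state sets.
#'
#' @param alignment a [codon_alignment()] with a rooted topology of at
#'   least 3 tips.
#' @param outgroup optional outgroup tip name used for tie-breaking.
#' @return named character vector of internal-node sequences (root
#'   included), names from the topology's node labels.
#' @export
infer_ancestral_codons <- function(alignment, outgroup = NULL) {
  stopifnot(inherits(alignment, "codon_alignment"))
  tree <- alignment$topology
  if (!ape::is.rooted(tree)) stop_input("topology must be rooted")
  n_tip <- length(tree$tip.label)
  if (n_tip < 3L) stop_input("topology must have at least 3 tips")
  if (!is.null(outgroup) && !outgroup %in% tree$tip.label)
    stop_input("outgroup '", outgroup, "' is not a tip of the topology")
  L <- nchar(alignment$sequences[[1L]])
  n_node <- n_tip + tree$Nnode
  sets <- matrix(0L, nrow = n_node, ncol = L)
  for (i in seq_len(n_tip)) {
    chars <- strsplit(alignment$sequences[[tree$tip.label[i]]], "")[[1L]]
    sets[i, ] <- .nuc_bits[chars]
  }
  # bottom-up: intersection where non-empty, else union
  pre <- reorder_edges_preorder(tree)
  for (e in rev(pre)) {
    par <- tree$edge[e, 1L]
    chi <- tree$edge[e, 2L]
    if (all(sets[par, ] == 0L)) {
      sets[par, ] <- sets[chi, ]
    } else {
      inter <- bitwAnd(sets[par, ], sets[chi, ])
      uni <- bitwOr(sets[par, ], sets[chi, ])
      sets[par, ] <- ifelse(inter > 0L, inter, uni)
    }
  }
  og_bits <- if (is.null(outgroup)) rep(0L, L) else
    sets[match(outgroup, tree$tip.label), ]
  choose_state <- function(node_set, parent_state = NULL) {
    s <- if (is.null(parent_state)) rep(0L, L) else
      bitwAnd(node_set, parent_state)
    og <- bitwAnd(node_set, og_bits)
    ifelse(s > 0L, s, ifelse(og > 0L, og, lowest_bit(node_set)))
  }
  root <- n_tip + 1L
  state <- matrix(0L, nrow = n_node, ncol = L)
  state[root, ] <- choose_state(sets[root, ])
  for (e in pre) {
    chi <- tree$edge[e, 2L]
    if (chi <= n_tip) next
    state[chi, ] <- choose_state(sets[chi, ], state[tree$edge[e, 1L], ])
  }
  gc <- genetic_code()
  internal_ids <- root:n_node
  out <- vapply(internal_ids, function(node) {
    chars <- .bit_nuc[as.character(state[node, ])]
    seqv <- paste(chars, collapse = "")
    cods <- split_codons(seqv)
    bad <- which(gc[cods] == "*")
    bad <- bad[bad < length(cods)]  # a terminal stop codon is legitimate
    for (i in bad) {
      cols <- (i - 1L) * 3L + 1:3
      opts <- lapply(cols, function(cl) {
        b <- sets[node, cl]
        .bit_nuc[as.character(.nuc_bits[bitwAnd(b, .nuc_bits) > 0L])]
      })
      combos <- expand.grid(opts, stringsAsFactors = FALSE)
      cands <- do.call(paste0, combos)
      cands <- cands[gc[cands] != "*"]
      if (!length(cands)) next  # no sense codon reachable; keep as is
      ndiff <- vapply(cands, function(cd)
        sum(strsplit(cd, "")[[1L]] != chars[cols]), integer(1))
      pick <- cands[order(ndiff, cands)][1L]
      chars[cols] <- strsplit(pick, "")[[1L]]
    }
    paste(chars, collapse = "")
  }, character(1))
  setNames(out, node_name(tree, internal_ids))
}

# ---- Pipeline --------------------------------------------------------------

#' Per-branch purifying-selection test over a codon alignment
#'
#' Composes the three stages of the branch test: Fitch ancestral
#' reconstruction on the fixed rooted topology, Nei--Gojobori counting on
#' each branch leading from its ancestor to an ingroup tip, and the
#' one-sided Fisher's exact test on each branch's counts. A branch with no
#' substitutions is reported with omega undefined, `fisher_p = 1` and flag
#' `"identical"`.
#'
#' @param alignment a [codon_alignment()].
#' @param outgroup name(s) of the outgroup tip(s); excluded from the tested
#'   branches and used for parsimony tie-breaking.
#' @param side test side, see [branch_omega_test()].
#' @return a data frame of class `branch_test_result` with one row per
#'   ancestor-to-ingroup-tip branch (columns `branch`, `N_sites`,
#'   `S_sites`, `Nd`, `Sd`, `pN`, `pS`, `omega`, `fisher_p`, `flag`); the
#'   ancestral sequences and tree are attached as attributes.
#' @export
pipeline_branch_test <- function(alignment, outgroup,
                                 side = c("purifying", "positive")) {
  side <- match.arg(side)
  stopifnot(inherits(alignment, "codon_alignment"))
  tree <- alignment$topology
  if (missing(outgroup) || !all(outgroup %in% tree$tip.label))
    stop_input("outgroup must name tip(s) of the topology")
  anc <- infer_ancestral_codons(alignment, outgroup = outgroup[1L])
  ingroup <- setdiff(tree$tip.label, outgroup)
  n_tip <- length(tree$tip.label)
  rows <- lapply(ingroup, function(tip) {
    tip_id <- match(tip, tree$tip.label)
    par_id <- tree$edge[tree$edge[, 2L] == tip_id, 1L]
    par_name <- node_name(tree, par_id)
    cts <- count_branch_substitutions(anc[[par_name]],
                                      alignment$sequences[[tip]],
                                      branch = paste0(par_name, "->", tip))
    branch_omega_test(cts, side = side)
  })
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(branch = r$branch, N_sites = r$N_sites, S_sites = r$S_sites,
               Nd = r$Nd, Sd = r$Sd, pN = r$pN, pS = r$pS,
               omega = r$omega, fisher_p = r$fisher_p, flag = r$flag,
               stringsAsFactors = FALSE)))
  attr(out, "ancestral_sequences") <- anc
  attr(out, "tree") <- tree
  attr(out, "side") <- side
  class(out) <- c("branch_test_result", "data.frame")
  out
}

#' Annotated Newick string for a branch-test result
#'
#' Suffixes each tested tip with `#omega=..;p=..` so the per-branch result
#' travels with the topology.
#'
#' @param result a [pipeline_branch_test()] result.
#' @return a Newick string.
#' @export
annotated_newick <- function(result) {
  stopifnot(inherits(result, "branch_test_result"))
  tree <- attr(result, "tree")
  tips <- sub("^.*->", "", result$branch)
  lab <- sprintf("%s#omega=%s;p=%.3g", tips,
                 ifelse(is.na(result$omega), "NA",
                        sprintf("%.3g", result$omega)),
                 result$fisher_p)
  tree$tip.label[match(tips, tree$tip.label)] <- lab
  ape::write.tree(tree)
}

#' Write a branch-test result as TSV
#'
#' @param result a [pipeline_branch_test()] result.
#' @param path output file.
#' @export
write_branch_test_tsv <- function(result, path) {
  utils::write.table(as.data.frame(result), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
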