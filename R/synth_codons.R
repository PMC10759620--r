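#' Parameters for codon-evolution simulation
#'
#' Describes an accept/reject codon substitution process used as ground
#' truth for the branch dN/dS test: point mutations arrive along each
#' branch at a rate set by the branch length (expected attempted
#' substitutions per nucleotide site), transitions are proposed `kappa`
#' times as often as each transversion, mutations creating stop codons are
#' rejected, and nonsynonymous changes are accepted with relative
#' probability `min(1, omega)` (synonymous with `min(1, 1/omega)`, so
#' `omega > 1` is also expressible).
#'
#' The default `kappa = 1` mirrors the unweighted Nei--Gojobori counting
#' used downstream, which keeps the simulator/estimator pair interpretable
#' for parameter-recovery checks; transition bias is available but biases
#' the unweighted proportion-ratio estimator downward (see the methods
#' vignette).
#'
#' @param ancestral_cds in-frame root coding sequence (A/C/G/T only, no
#'   internal stop codons).
#' @param branch_lengths expected attempted substitutions per nucleotide
#'   site: either a single value recycled to every edge, or a vector with
#'   one entry per edge of the topology (in `tree$edge` order), or `NULL`
#'   to use the topology's own edge lengths.
#' @param omega dN/dS ratio of the simulated process, `> 0`.
#' @param kappa transition/transversion proposal ratio, `> 0`.
#' @param seed optional RNG seed.
#' @return an object of class `codon_sim_params`.
#' @export
codon_sim_params <- function(ancestral_cds, branch_lengths = NULL,
                             omega = 0.2, kappa = 1, seed = NULL) {
  ancestral_cds <- toupper(ancestral_cds)
  prot <- translate_cds(ancestral_cds)
  if (grepl("*", substr(prot, 1L, nchar(prot) - 1L), fixed = TRUE))
    stop_input("ancestral_cds contains an internal stop codon")
  if (!is.null(branch_lengths) && any(branch_lengths < 0))
    stop_input("branch_lengths must be >= 0")
  if (omega <= 0) stop_input("omega must be > 0")
  if (kappa <= 0) stop_input("kappa must be > 0")
  structure(list(ancestral_cds = ancestral_cds,
                 branch_lengths = branch_lengths,
                 omega = omega, kappa = kappa, seed = seed),
            class = "codon_sim_params")
}

#' Default rooted three-taxon topology
#'
#' An ingroup pair plus one outgroup, the layout of the per-branch
#' selection test (common ancestor of the two focal species against an
#' outgroup root).
#'
#' @param ingroup two tip names.
#' @param outgroup one tip name.
#' @param ingroup_bl,stem_bl,outgroup_bl branch lengths.
#' @return an `ape` `phylo` tree with labelled internal nodes.
#' @export
three_taxon_topology <- function(ingroup = c("echidna", "platypus"),
                                 outgroup = "outgroup",
                                 ingroup_bl = 0.02, stem_bl = 0.02,
                                 outgroup_bl = 0.05) {
  stopifnot(length(ingroup) == 2L, length(outgroup) == 1L)
  txt <- sprintf("((%s:%g,%s:%g)anc:%g,%s:%g)root;",
                 ingroup[1L], ingroup_bl, ingroup[2L], ingroup_bl,
                 stem_bl, outgroup, outgroup_bl)
  ape::read.tree(text = txt)
}

# Evolve one sequence along one branch under the accept/reject scheme.
evolve_branch <- function(cds, bl, omega, kappa) {
  gc <- genetic_code()
  chars <- strsplit(cds, "")[[1L]]
  n_nt <- length(chars)
  n_attempts <- rpois(1L, bl * n_nt)
  if (n_attempts == 0L) return(cds)
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  for (k in seq_len(n_attempts)) {
    pos <- sample.int(n_nt, 1L)
    cur <- chars[pos]
    alts <- setdiff(bases, cur)
    w <- ifelse(alts == transition[[cur]], kappa, 1)
    prop <- sample(alts, 1L, prob = w)
    cod_i <- (pos - 1L) %/% 3L
    cod_from <- paste(chars[cod_i * 3L + 1:3], collapse = "")
    cod_chars <- chars[cod_i * 3L + 1:3]
    cod_chars[(pos - 1L) %% 3L + 1L] <- prop
    cod_to <- paste(cod_chars, collapse = "")
    aa_from <- gc[[cod_from]]
    aa_to <- gc[[cod_to]]
    if (aa_to == "*") next
    p_accept <- if (aa_to == aa_from) min(1, 1 / omega) else min(1, omega)
    if (runif(1L) <= p_accept) chars[pos] <- prop
  }
  paste(chars, collapse = "")
}

#' Simulate codon evolution on a rooted tree
#'
#' Runs the accept/reject codon substitution process of
#' [codon_sim_params()] from the root sequence down every edge of a rooted
#' topology, and returns the tip alignment together with the true internal
#' node sequences (the ground truth for ancestral-reconstruction and
#' dN/dS-recovery checks).
#'
#' @param params a `codon_sim_params` object.
#' @param topology a rooted `phylo` tree (e.g. [three_taxon_topology()]) or
#'   a Newick string.
#' @return a list with `tip_seqs` (named character), `node_seqs` (named
#'   character, root and internal nodes), `alignment` (a
#'   [codon_alignment()] over the tips), and `tree`.
#' @export
simulate_codon_evolution <- function(params, topology = three_taxon_topology()) {
  stopifnot(inherits(params, "codon_sim_params"))
  tree <- as_rooted_tree(topology)
  n_tip <- length(tree$tip.label)
  n_edge <- nrow(tree$edge)
  bl <- params$branch_lengths
  bl <- if (is.null(bl)) tree$edge.length else rep_len(bl, n_edge)
  if (is.null(bl)) stop_input("no branch lengths available")

  with_seed(params$seed, {
    root <- n_tip + 1L
    seqs <- vector("list", n_tip + tree$Nnode)
    seqs[[root]] <- params$ancestral_cds
    for (e in reorder_edges_preorder(tree)) {
      par <- tree$edge[e, 1L]; chi <- tree$edge[e, 2L]
      seqs[[chi]] <- evolve_branch(seqs[[par]], bl[e],
                                   params$omega, params$kappa)
    }
    tip_seqs <- setNames(unlist(seqs[seq_len(n_tip)]), tree$tip.label)
    node_ids <- root:(n_tip + tree$Nnode)
    node_seqs <- setNames(unlist(seqs[node_ids]), node_name(tree, node_ids))
    list(tip_seqs = tip_seqs, node_seqs = node_seqs,
         alignment = codon_alignment(tip_seqs, tree), tree = tree)
  })
}

# Edge indices ordered so each parent is visited before its children.
reorder_edges_preorder <- function(tree) {
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  out <- integer(0)
  stack <- root
  while (length(stack)) {
    node <- stack[[1L]]; stack <- stack[-1L]
    kids <- which(tree$edge[, 1L] == node)
    out <- c(out, kids)
    stack <- c(stack, tree$edge[kids, 2L])
  }
  out
}

node_name <- function(tree, ids) {
  n_tip <- length(tree$tip.label)
  vapply(ids, function(i) {
    if (i <= n_tip) tree$tip.label[i]
    else if (!is.null(tree$node.label) &&
             nzchar(tree$node.label[i - n_tip])) tree$node.label[i - n_tip]
    else paste0("node", i)
  }, character(1))
}

as_rooted_tree <- function(topology) {
  tree <- if (inherits(topology, "phylo")) topology
  else ape::read.tree(text = topology)
  if (is.null(tree) || !inherits(tree, "phylo"))
    stop_input("topology must be a phylo object or a Newick string")
  if (!ape::is.rooted(tree)) stop_input("topology must be rooted")
  tree
}

#' Generate a random in-frame coding sequence
#'
#' Convenience generator for simulation roots: uniform sense codons
#' (internal stops excluded).
#'
#' @param n_codons number of codons.
#' @param seed optional RNG seed.
#' @return a single character string of length `3 * n_codons`.
#' @export
random_cds <- function(n_codons, seed = NULL) {
  gc <- genetic_code()
  sense <- names(gc)[gc != "*"]
  with_seed(seed, paste(sample(sense, n_codons, replace = TRUE),
                        collapse = ""))
}

#' Write a simulated codon data set to FASTA and Newick files
#'
#' @param sim result of [simulate_codon_evolution()].
#' @param fasta,newick output paths.
#' @export
write_codon_sim <- function(sim, fasta, newick) {
  writeLines(unlist(lapply(names(sim$tip_seqs), function(id)
    c(paste0(">", id), sim$tip_seqs[[id]]))), fasta)
  ape::write.tree(sim$tree, file = newick)
  invisible(c(fasta, newick))
}
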