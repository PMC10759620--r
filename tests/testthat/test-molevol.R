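# Nei-Gojobori counting, Fisher branch test, Fitch ancestors, pipeline.

test_that("count_branch_substitutions handles canonical codon pairs", {
  same <- count_branch_substitutions("TTTAAA", "TTTAAA")
  expect_equal(same$Nd, 0)
  expect_equal(same$Sd, 0)
  expect_identical(same$flag, "identical")
  expect_true(is.na(same$omega))

  syn <- count_branch_substitutions("TTT", "TTC")  # Phe -> Phe
  expect_equal(syn$Sd, 1)
  expect_equal(syn$Nd, 0)

  # TTT -> GTA: two 2-step pathways, enumerated by hand:
  #   TTT -> GTT (F>V, N) -> GTA (V>V, S)  and  TTT -> TTA (F>L, N) -> GTA (L>V, N)
  two <- count_branch_substitutions("TTT", "GTA")
  expect_equal(two$Nd, 1.5)
  expect_equal(two$Sd, 0.5)
  expect_equal(two$Nd + two$Sd, 2)

  expect_error(count_branch_substitutions("TTT", "TTTAAA"), "equal length")
  expect_error(count_branch_substitutions("TAA", "TAC"), "sense codons")
})

test_that("site counts conserve N + S = 3 x codons and are symmetric", {
  set.seed(7)
  for (i in 1:20) {
    a <- random_cds(40, seed = i)
    b <- random_cds(40, seed = 100 + i)
    ab <- count_branch_substitutions(a, b)
    expect_equal(ab$N_sites + ab$S_sites, 3 * 40)
    ba <- count_branch_substitutions(b, a)
    expect_equal(ab$Nd, ba$Nd)       # reversal symmetry of differences
    expect_equal(ab$Sd, ba$Sd)
    expect_lte(ab$Nd, ab$N_sites)
    expect_lte(ab$Sd, ab$S_sites)
  }
})

test_that("counting matches the brute-force oracle on random codon pairs", {
  # the exhaustive 61x61 sweep lives in the acceptance suite; spot-check a
  # random subset here, including the site counts
  set.seed(11)
  sc <- sense_codons()
  for (k in 1:150) {
    a <- sample(sc, 1)
    b <- sample(sc, 1)
    got <- count_branch_substitutions(a, b)
    exp_d <- oracle_ng_pair(a, b)
    expect_equal(c(got$Nd, got$Sd), exp_d)
    exp_s <- (oracle_ng_sites(a) + oracle_ng_sites(b)) / 2
    expect_equal(got$S_sites, unname(exp_s["S"]))
    expect_equal(got$N_sites, unname(exp_s["N"]))
  }
})

test_that("branch_omega_test builds the rounded table and matches dhyper tails", {
  # balanced proportions: no signal on either side
  cts <- count_branch_substitutions(strrep("TTT", 50), strrep("TTT", 50))
  cts$Nd <- 10; cts$Sd <- 10 * cts$S_sites / cts$N_sites
  cts$pN <- cts$Nd / cts$N_sites; cts$pS <- cts$Sd / cts$S_sites
  p <- branch_omega_test(cts)$fisher_p
  expect_gt(p, 0.5)

  # frozen example: table [[0, 300], [20, 100]], purifying side
  mk <- function(Nd, N, Sd, S) {
    structure(list(branch = NULL, n_codons = (N + S) / 3, N_sites = N,
                   S_sites = S, Nd = Nd, Sd = Sd, pN = Nd / N, pS = Sd / S,
                   omega = (Nd / N) / (Sd / S), fisher_p = NA_real_,
                   side = NA_character_, flag = "ok"),
              class = "branch_subst_counts")
  }
  got <- branch_omega_test(mk(0, 300, 20, 120))$fisher_p
  expect_equal(got, oracle_fisher_tail(0, 300, 20, 100, "less"))

  # random small tables against direct hypergeometric summation
  set.seed(13)
  for (k in 1:50) {
    Nd <- sample(0:12, 1); Sd <- sample(0:12, 1)
    N <- Nd + sample(5:200, 1); S <- Sd + sample(5:200, 1)
    for (side in c("purifying", "positive")) {
      got <- branch_omega_test(mk(Nd, N, Sd, S), side = side)$fisher_p
      want <- oracle_fisher_tail(Nd, N - Nd, Sd, S - Sd,
                                 if (side == "purifying") "less" else
                                   "greater")
      expect_equal(got, want)
    }
  }
})

test_that("fractional counts are rounded half-up for the Fisher table only", {
  a <- paste0("TTT", "GTA", strrep("AAA", 30))
  b <- paste0("TTT", "TTT", strrep("AAA", 30))
  cts <- count_branch_substitutions(a, b)
  expect_equal(cts$Nd, 1.5)  # raw fractional values preserved
  tested <- branch_omega_test(cts)
  expect_equal(tested$Nd, 1.5)
  half_up <- function(x) floor(x + 0.5)
  expect_equal(tested$fisher_p,
               oracle_fisher_tail(half_up(1.5), half_up(cts$N_sites - 1.5),
                                  half_up(0.5), half_up(cts$S_sites - 0.5),
                                  "less"))
})

test_that("Fitch ancestors: forced cases and recovery of simulated truth", {
  tr <- three_taxon_topology(c("A", "B"), "C")
  seqs <- c(A = "ATGAAA", B = "ATGAAA", C = "ATGAAA")
  anc <- infer_ancestral_codons(codon_alignment(seqs, tr), outgroup = "C")
  expect_identical(unname(anc[["anc"]]), "ATGAAA")
  expect_identical(unname(anc[["root"]]), "ATGAAA")

  # A = B != C at one column: the (A,B) ancestor takes the shared state
  seqs2 <- c(A = "ATGAAG", B = "ATGAAG", C = "ATGAAA")
  anc2 <- infer_ancestral_codons(codon_alignment(seqs2, tr), outgroup = "C")
  expect_identical(unname(anc2[["anc"]]), "ATGAAG")

  # short branches, 500 codons: >= 99% of ancestral codons recovered
  sim <- simulate_codon_evolution(
    codon_sim_params(random_cds(500, seed = 21), branch_lengths = 0.02,
                     omega = 0.2, seed = 22))
  anc3 <- infer_ancestral_codons(sim$alignment, outgroup = "outgroup")
  expect_gte(codon_match_fraction(anc3[["anc"]], sim$node_seqs[["anc"]]),
             0.99)

  unrooted <- ape::unroot(ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);"))
  expect_false(ape::is.rooted(unrooted))
  expect_error(
    infer_ancestral_codons(
      structure(list(taxa = c("A", "B", "C", "D"),
                     sequences = c(A = "AAA", B = "AAA", C = "AAA",
                                   D = "AAA"),
                     topology = unrooted, n_codons = 1L),
                class = "codon_alignment")),
    "rooted")
})

test_that("reconstructed ancestors avoid internal stop codons", {
  # tips force T[A][A/G] columns whose naive parsimony choice could be TAA
  tr <- three_taxon_topology(c("A", "B"), "C")
  seqs <- c(A = "ATGTATAAA", B = "ATGTACAAA", C = "ATGTATAAA")
  anc <- infer_ancestral_codons(codon_alignment(seqs, tr), outgroup = "C")
  gc <- Biostrings::GENETIC_CODE
  for (nm in names(anc)) {
    cods <- substring(anc[[nm]], c(1, 4, 7), c(3, 6, 9))
    expect_false(any(gc[cods[-3]] == "*"))
  }
})

test_that("pipeline_branch_test composes the stages and flags identical branches", {
  tr <- three_taxon_topology(c("echidna", "platypus"), "outgroup")
  base <- random_cds(100, seed = 31)
  aln <- codon_alignment(c(echidna = base, platypus = base,
                           outgroup = base), tr)
  res <- pipeline_branch_test(aln, outgroup = "outgroup")
  expect_equal(nrow(res), 2)
  expect_true(all(res$flag == "identical"))
  expect_true(all(is.na(res$omega)))
  expect_true(all(res$fisher_p == 1))

  sim <- simulate_codon_evolution(
    codon_sim_params(random_cds(1095, seed = 41), branch_lengths = 0.1,
                     omega = 0.1, seed = 42))
  res2 <- pipeline_branch_test(sim$alignment, outgroup = "outgroup")
  expect_true(all(res2$omega < 1))
  expect_true(all(res2$fisher_p < 0.05))

  nwk <- annotated_newick(res2)
  expect_match(nwk, "omega=")
  f <- tempfile(fileext = ".tsv")
  write_branch_test_tsv(res2, f)
  back <- read.delim(f)
  expect_equal(back$omega, res2$omega, tolerance = 1e-6)

  expect_error(pipeline_branch_test(aln, outgroup = "nosuch"), "outgroup")
})

test_that("codon_alignment validates its invariants", {
  tr <- three_taxon_topology(c("A", "B"), "C")
  expect_error(codon_alignment(c("AAA", "AAA", "AAA"), tr), "named")
  expect_error(codon_alignment(c(A = "AAA", B = "AAAAAA", C = "AAA"), tr),
               "equal length")
  expect_error(codon_alignment(c(A = "AA", B = "AA", C = "AA"), tr),
               "divisible by 3")
  expect_error(codon_alignment(c(A = "TAAAAA", B = "AAAAAA", C = "AAAAAA"),
                               tr), "stop")
  expect_error(codon_alignment(c(A = "A-A", B = "AAA", C = "AAA"), tr),
               "A/C/G/T")
  expect_error(codon_alignment(c(A = "AAA", B = "AAA"), tr), "topology tips")
})
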