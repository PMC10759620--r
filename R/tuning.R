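#' Opsin haplotype from a coding sequence
#'
#' One phased (or unphased consensus) opsin coding sequence. Heterozygous
#' single-nucleotide variants are carried as IUPAC ambiguity codes in the
#' CDS; a sequence with ambiguity codes has no single translation and must
#' be expanded with [enumerate_haplotype_genotypes()].
#'
#' @param id sequence identifier.
#' @param gene opsin class, `"LWS"`, `"SWS2"` or `"RH1"`.
#' @param cds in-frame nucleotide sequence, possibly with IUPAC ambiguity
#'   codes.
#' @return an object of class `opsin_haplotype` with the translated
#'   `protein` (or `NA` if ambiguous) and the `ambiguous_positions`.
#' @export
opsin_haplotype <- function(id, gene = c("LWS", "SWS2", "RH1"), cds) {
  gene <- match.arg(gene)
  cds <- toupper(gsub("\\s", "", cds))
  if (nchar(cds) %% 3L != 0L)
    stop_input("CDS length must be divisible by 3")
  amb <- ambiguous_positions(cds)
  bad <- setdiff(strsplit(cds, "")[[1L]][amb],
                 names(Biostrings::IUPAC_CODE_MAP))
  if (length(bad))
    stop_input("CDS contains non-IUPAC characters: ",
               paste(unique(bad), collapse = ", "))
  protein <- NA_character_
  if (!length(amb)) {
    protein <- translate_cds(cds)
    if (has_internal_stop(protein))
      stop_input("translation of '", id, "' has an internal stop codon")
  }
  structure(list(id = id, gene = gene, cds = cds, protein = protein,
                 ambiguous_positions = amb),
            class = "opsin_haplotype")
}

#' Read opsin haplotypes from a FASTA file
#'
#' @param path FASTA of coding sequences (IUPAC ambiguity codes allowed).
#' @param gene opsin class applied to every record.
#' @return list of [opsin_haplotype()] objects.
#' @export
read_opsin_fasta <- function(path, gene = c("LWS", "SWS2", "RH1")) {
  gene <- match.arg(gene)
  seqs <- Biostrings::readDNAStringSet(path)
  lapply(seq_along(seqs), function(i)
    opsin_haplotype(names(seqs)[i], gene, as.character(seqs[[i]])))
}

#' Spectral-tuning site sets per gene
#'
#' LWS uses the five additive tuning sites 180, 197, 277, 285 and 308 (in
#' the numbering of the packaged LWS reference); SWS2 uses the seven key
#' sites 91, 94, 116, 122, 261, 292 and 295 (fish SWS2 numbering).
#'
#' @param gene `"LWS"` or `"SWS2"`.
#' @return integer vector of reference site numbers.
#' @export
default_tuning_sites <- function(gene = c("LWS", "SWS2")) {
  switch(match.arg(gene),
         LWS = c(180L, 197L, 277L, 285L, 308L),
         SWS2 = c(91L, 94L, 116L, 122L, 261L, 292L, 295L))
}

#' Packaged numbering-reference protein
#'
#' Returns the packaged alignment reference that defines site numbering for
#' a gene. The shipped references are SYNTHETIC stand-ins (deterministic
#' pseudo-random proteins of realistic length carrying the canonical
#' residues at the tuning sites), not real opsin sequences: community
#' numbering references could not be redistributed here, and within this
#' package every analyzed sequence is synthetic anyway. Supply your own
#' reference (a named length-1 character vector or single-record FASTA) to
#' number real data.
#'
#' @param gene `"LWS"` or `"SWS2"`.
#' @return named character vector of length 1 (protein sequence, name =
#'   reference id).
#' @export
numbering_reference <- function(gene = c("LWS", "SWS2")) {
  gene <- match.arg(gene)
  path <- system.file("extdata",
                      sprintf("synthetic_%s_numbering_reference.fasta",
                              tolower(gene)),
                      package = "monovis", mustWork = TRUE)
  aa <- Biostrings::readAAStringSet(path)
  setNames(as.character(aa[[1L]]), names(aa)[1L])
}

as_reference_protein <- function(reference) {
  if (is.null(reference)) stop_input("a numbering reference is required")
  if (length(reference) == 1L && is.character(reference) &&
      file.exists(reference) && grepl("\\.fa(sta)?$", reference)) {
    aa <- Biostrings::readAAStringSet(reference)
    return(setNames(as.character(aa[[1L]]), names(aa)[1L]))
  }
  stopifnot(is.character(reference), length(reference) == 1L)
  if (is.null(names(reference))) names(reference) <- "reference"
  reference
}

align_to_reference <- function(protein, reference_protein) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(protein),
    Biostrings::AAString(unname(reference_protein)),
    type = "global",
    substitutionMatrix = "BLOSUM62",
    gapOpening = 10, gapExtension = 0.5)
  if (Biostrings::pid(aln) < 25)
    stop_input("sequence is not alignable to the numbering reference ",
               "(identity < 25%)")
  list(pattern = strsplit(as.character(Biostrings::pattern(aln)), "")[[1L]],
       subject = strsplit(as.character(Biostrings::subject(aln)), "")[[1L]])
}

#' Tuning-site genotype
#'
#' Residues of one sequence at a gene's tuning sites, under the numbering
#' of a stated reference. For LWS the site set must be exactly
#' `{180, 197, 277, 285, 308}` and for SWS2 exactly
#' `{91, 94, 116, 122, 261, 292, 295}`.
#'
#' @param gene opsin class.
#' @param site_residues named character vector, names = reference site
#'   numbers, values = one-letter residues (`NA` for a site lost in a gap).
#' @param numbering_reference id of the reference that defines the
#'   numbering.
#' @param id optional sequence id.
#' @return an object of class `tuning_genotype`.
#' @export
tuning_genotype <- function(gene = c("LWS", "SWS2", "RH1"), site_residues,
                            numbering_reference = "unspecified",
                            id = NULL) {
  gene <- match.arg(gene)
  if (is.null(names(site_residues)))
    stop_input("site_residues must be named by reference site number")
  sites <- sort(as.integer(names(site_residues)))
  if (gene %in% c("LWS", "SWS2")) {
    expected <- default_tuning_sites(gene)
    if (!identical(sites, expected))
      stop_input(gene, " genotypes must cover exactly sites ",
                 paste(expected, collapse = ", "))
  }
  site_residues <- site_residues[order(as.integer(names(site_residues)))]
  structure(list(gene = gene,
                 site_residues = site_residues,
                 numbering_reference = numbering_reference,
                 id = id),
            class = "tuning_genotype")
}

#' @export
print.tuning_genotype <- function(x, ...) {
  cat(sprintf("<tuning_genotype> %s%s: %s (numbering: %s)\n", x$gene,
              if (is.null(x$id)) "" else paste0(" ", x$id),
              paste0(x$site_residues, names(x$site_residues),
                     collapse = " "),
              x$numbering_reference))
  invisible(x)
}

#' Extract tuning-site residues from a haplotype
#'
#' Globally aligns the haplotype's protein to the numbering reference
#' (BLOSUM62, affine gaps) and reads off the residues at the requested
#' reference positions. A requested site that falls in an alignment gap is
#' reported as `NA` with a warning.
#'
#' @param haplotype an [opsin_haplotype()] (unambiguous) or a plain protein
#'   string.
#' @param reference numbering reference: `NULL` to use the packaged
#'   [numbering_reference()] for the haplotype's gene, a named character
#'   protein, or a FASTA path.
#' @param sites reference site numbers; default [default_tuning_sites()].
#' @return a [tuning_genotype()].
#' @export
extract_tuning_sites <- function(haplotype, reference = NULL, sites = NULL) {
  if (inherits(haplotype, "opsin_haplotype")) {
    if (is.na(haplotype$protein))
      stop_input("haplotype has ambiguity codes; use ",
                 "enumerate_haplotype_genotypes()")
    protein <- haplotype$protein
    gene <- haplotype$gene
    id <- haplotype$id
  } else {
    protein <- as.character(haplotype)
    gene <- attr(haplotype, "gene") %||% "LWS"
    id <- NULL
  }
  protein <- sub("\\*$", "", protein)
  if (is.null(reference)) reference <- numbering_reference(gene)
  ref <- as_reference_protein(reference)
  if (is.null(sites)) sites <- default_tuning_sites(gene)
  aln <- align_to_reference(protein, ref)
  refpos <- cumsum(aln$subject != "-")
  res <- setNames(rep(NA_character_, length(sites)), sites)
  for (k in seq_along(sites)) {
    j <- which(refpos == sites[k] & aln$subject != "-")[1L]
    if (!is.na(j) && aln$pattern[j] != "-") res[k] <- aln$pattern[j]
  }
  if (anyNA(res))
    warning("site(s) ", paste(names(res)[is.na(res)], collapse = ", "),
            " fall in an alignment gap and are reported as missing",
            call. = FALSE)
  tuning_genotype(gene, res, names(ref), id = id)
}

#' Additive LWS lambda-max shift table
#'
#' The five-site tuning model for LWS pigments: a base genotype
#' (S180, H197, Y277, T285, A308) with lambda-max 560 nm and an additive
#' shift per single substitution away from it. The shift magnitudes ship
#' as a data file transcribed from the five-site-rule literature; this
#' package anchors only the base value (560 nm) and the S180A shift
#' (-5 nm).
#'
#' @param path optional CSV with columns `site`, `from_residue`,
#'   `to_residue`, `shift_nm`; default the packaged table.
#' @return an object of class `lws_shift_table`.
#' @export
lws_shift_table <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "lws_five_site_shifts.csv",
                        package = "monovis", mustWork = TRUE)
  shifts <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("site", "from_residue", "to_residue", "shift_nm")
  if (!all(need %in% names(shifts)))
    stop_input("shift table must have columns ",
               paste(need, collapse = ", "))
  base_genotype <- c(`180` = "S", `197` = "H", `277` = "Y",
                     `285` = "T", `308` = "A")
  s180a <- shifts$shift_nm[shifts$site == 180 &
                             shifts$from_residue == "S" &
                             shifts$to_residue == "A"]
  if (length(s180a) != 1L || s180a != -5)
    stop_input("shift table fails validation: S180A must shift -5 nm")
  structure(list(gene = "LWS", base_genotype = base_genotype,
                 base_lambda_max = 560, shifts = shifts),
            class = "lws_shift_table")
}

#' Predict LWS lambda-max by the additive five-site rule
#'
#' `base_lambda_max` plus the sum of per-site shifts over the sites where
#' the genotype deviates from the base genotype. Exactly additive and
#' independent of site order; a deviation with no entry in the shift table
#' is an error naming the site.
#'
#' @param genotype an LWS [tuning_genotype()] with all five sites present.
#' @param table a [lws_shift_table()].
#' @return predicted lambda-max in nm.
#' @export
predict_lws_lambda_max <- function(genotype, table = lws_shift_table()) {
  stopifnot(inherits(genotype, "tuning_genotype"),
            inherits(table, "lws_shift_table"))
  if (genotype$gene != "LWS")
    stop_input("the five-site rule applies to LWS genotypes only")
  if (anyNA(genotype$site_residues))
    stop_input("all five sites must be present to predict lambda-max")
  total <- table$base_lambda_max
  for (s in names(table$base_genotype)) {
    from <- table$base_genotype[[s]]
    to <- genotype$site_residues[[s]]
    if (to == from) next
    hit <- table$shifts$shift_nm[table$shifts$site == as.integer(s) &
                                   table$shifts$from_residue == from &
                                   table$shifts$to_residue == to]
    if (length(hit) != 1L)
      stop_input("unsupported genotype: no shift entry for site ", s,
                 " substitution ", from, "->", to)
    total <- total + hit
  }
  total
}

#' Compare residues at key sites across genotypes
#'
#' @param genotypes list of [tuning_genotype()] objects over one gene and
#'   one site set.
#' @return a data frame (class `key_site_comparison`) with one row per
#'   site: the residue of every genotype and a `differs` flag; the overall
#'   `any_difference` flag is attached as an attribute.
#' @export
compare_key_sites <- function(genotypes) {
  if (!is.list(genotypes) || length(genotypes) < 2L ||
      !all(vapply(genotypes, inherits, logical(1), "tuning_genotype")))
    stop_input("genotypes must be a list of >= 2 tuning_genotype objects")
  genes <- unique(vapply(genotypes, `[[`, character(1), "gene"))
  if (length(genes) != 1L)
    stop_input("all genotypes must be over the same gene, got: ",
               paste(genes, collapse = ", "))
  sitesets <- unique(vapply(genotypes, function(g)
    paste(names(g$site_residues), collapse = ","), character(1)))
  if (length(sitesets) != 1L)
    stop_input("all genotypes must cover the same site set")
  ids <- vapply(seq_along(genotypes), function(i)
    genotypes[[i]]$id %||% names(genotypes)[i] %||% paste0("g", i),
    character(1))
  ids[!nzchar(ids)] <- paste0("g", which(!nzchar(ids)))
  mat <- vapply(genotypes, function(g) unname(g$site_residues),
                character(length(genotypes[[1L]]$site_residues)))
  colnames(mat) <- make.unique(ids)
  differs <- apply(mat, 1L, function(r) length(unique(r[!is.na(r)])) > 1L)
  out <- data.frame(site = as.integer(names(genotypes[[1L]]$site_residues)),
                    mat, differs = differs, stringsAsFactors = FALSE,
                    row.names = NULL, check.names = FALSE)
  attr(out, "any_difference") <- any(differs)
  attr(out, "gene") <- genes
  class(out) <- c("key_site_comparison", "data.frame")
  out
}

#' @export
print.key_site_comparison <- function(x, ...) {
  cat(sprintf("<key_site_comparison> %s, any difference: %s\n",
              attr(x, "gene"), attr(x, "any_difference")))
  print.data.frame(x)
  invisible(x)
}

#' Expand an unphased heterozygous haplotype into concrete genotypes
#'
#' Expands every IUPAC ambiguity code in the CDS into its nucleotides,
#' translates each concrete sequence, extracts the tuning sites, and
#' returns the deduplicated genotype set. Expansions whose translation
#' gains an internal stop codon are dropped with a warning. The output has
#' between 1 and `2^k` genotypes for `k` ambiguous positions.
#'
#' @param haplotype an [opsin_haplotype()] (with or without ambiguity
#'   codes).
#' @param reference,sites as in [extract_tuning_sites()].
#' @param max_ambiguous combinatorial guard on the number of ambiguous
#'   positions (default 8).
#' @return list of distinct [tuning_genotype()] objects.
#' @export
enumerate_haplotype_genotypes <- function(haplotype, reference = NULL,
                                          sites = NULL, max_ambiguous = 8L) {
  stopifnot(inherits(haplotype, "opsin_haplotype"))
  amb <- haplotype$ambiguous_positions
  if (length(amb) > max_ambiguous)
    stop_input("too many ambiguous positions (", length(amb), " > ",
               max_ambiguous, ")")
  if (!length(amb))
    return(list(extract_tuning_sites(haplotype, reference, sites)))
  chars <- strsplit(haplotype$cds, "")[[1L]]
  opts <- lapply(chars[amb], function(ch)
    strsplit(Biostrings::IUPAC_CODE_MAP[[ch]], "")[[1L]])
  combos <- expand.grid(opts, stringsAsFactors = FALSE)
  genos <- list()
  seen <- character(0)
  n_dropped <- 0L
  for (r in seq_len(nrow(combos))) {
    cc <- chars
    cc[amb] <- unlist(combos[r, ])
    cds <- paste(cc, collapse = "")
    prot <- translate_cds(cds)
    if (has_internal_stop(prot)) {
      n_dropped <- n_dropped + 1L
      next
    }
    hap <- opsin_haplotype(paste0(haplotype$id, "_exp", r),
                           haplotype$gene, cds)
    g <- extract_tuning_sites(hap, reference, sites)
    key <- paste(g$site_residues, collapse = "")
    if (!key %in% seen) {
      seen <- c(seen, key)
      genos <- c(genos, list(g))
    }
  }
  if (n_dropped)
    warning(n_dropped, " expansion(s) dropped for internal stop codons",
            call. = FALSE)
  if (!length(genos))
    stop_input("every expansion of '", haplotype$id,
               "' has an internal stop codon")
  genos
}
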