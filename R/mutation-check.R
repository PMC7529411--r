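#' CDS substitution variant
#'
#' A substitution replacing a reference nucleotide fragment with an alternate
#' fragment at a 1-based CDS coordinate. Coordinates refer to the coding
#' sequence (position 1 = the A of the start codon), matching the convention
#' in which a variant "after nucleotide N" starts at position N + 1.
#'
#' @param position 1-based CDS coordinate of the first replaced base.
#' @param ref_allele reference nucleotide fragment (A/C/G/T, nonempty).
#' @param alt_allele replacement fragment (A/C/G/T, nonempty).
#' @return object of class `cds_variant`.
#' @export
cds_variant <- function(position, ref_allele, alt_allele) {
  if (!is.numeric(position) || length(position) != 1L || position < 1 ||
      position != round(position)) {
    stop_field("position", "must be a positive 1-based integer coordinate")
  }
  ref_allele <- toupper(ref_allele)
  alt_allele <- toupper(alt_allele)
  for (al in list(c("ref_allele", ref_allele), c("alt_allele", alt_allele))) {
    if (nchar(al[2]) == 0L) stop_field(al[1], "must be nonempty")
    if (grepl("[^ACGT]", al[2])) {
      stop_field(al[1], "alphabet must be A/C/G/T")
    }
  }
  structure(list(position = as.integer(position), ref_allele = ref_allele,
                 alt_allele = alt_allele),
            class = "cds_variant")
}

#' The Lam^A25^ allele variant
#'
#' The published frameshift substitution in the Drosophila B-type lamin gene
#' `Lam` (Dm0): `GATCC` is replaced by `TCTACCA` starting after CDS
#' nucleotide 1830, i.e. at CDS position 1831. The net +2 nt change shifts
#' the reading frame after codon 610 (Gly), removing the C-terminal CaaX box.
#'
#' @return a [cds_variant].
#' @export
lam_a25_variant <- function() {
  cds_variant(position = 1831L, ref_allele = "GATCC", alt_allele = "TCTACCA")
}

#' Apply a substitution to a CDS
#'
#' Splices `alt_allele` in place of `ref_allele` at the variant position,
#' after verifying that the CDS actually carries the reference fragment
#' there.
#'
#' @param cds nucleotide string (A/C/G/T).
#' @param variant a [cds_variant].
#' @return the mutant nucleotide string; its length differs from the input by
#'   `nchar(alt) - nchar(ref)`.
#' @examples
#' apply_substitution("ATGGATCCA", cds_variant(4, "GATCC", "TCTACCA"))
#' @export
apply_substitution <- function(cds, variant) {
  cds <- toupper(as.character(cds))
  if (grepl("[^ACGT]", cds)) stop_field("cds", "alphabet must be A/C/G/T")
  pos <- variant$position
  ref <- variant$ref_allele
  end <- pos + nchar(ref) - 1L
  if (end > nchar(cds)) {
    stop(sprintf("variant spans positions %d-%d but the CDS has %d nt",
                 pos, end, nchar(cds)), call. = FALSE)
  }
  found <- substr(cds, pos, end)
  if (found != ref) {
    stop(sprintf("reference mismatch at CDS position %d: expected '%s', found '%s'",
                 pos, ref, found), call. = FALSE)
  }
  paste0(substr(cds, 1L, pos - 1L), variant$alt_allele,
         substr(cds, end + 1L, nchar(cds)))
}

#' Translate a CDS
#'
#' Standard-code translation from position 1 in frame 0, stopping at the
#' first stop codon; a trailing partial codon is ignored.
#'
#' @param cds nucleotide string (A/C/G/T, length >= 3).
#' @return list with `protein` (residues before the first stop), `stop_found`,
#'   and `full` (the complete translation including any post-stop residues,
#'   with `*` for stops).
#' @examples
#' translate_cds("ATGAAATAA")  # "MK", stop found
#' @export
translate_cds <- function(cds) {
  cds <- toupper(as.character(cds))
  if (grepl("[^ACGT]", cds)) stop_field("cds", "alphabet must be A/C/G/T")
  if (nchar(cds) < 3L) stop_field("cds", "need at least one full codon")
  trimmed <- substr(cds, 1L, (nchar(cds) %/% 3L) * 3L)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(trimmed)))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0L) {
    list(protein = substr(aa, 1L, stop_at - 1L), stop_found = TRUE, full = aa)
  } else {
    list(protein = aa, stop_found = FALSE, full = aa)
  }
}

#' Frameshift report for a CDS variant
#'
#' Applies the variant, translates both alleles, and reports: the last intact
#' residue (the last codon lying entirely upstream of the substitution), the
#' frameshift flag (net length change not a multiple of 3), and the novel
#' peptide — every mutant residue after the last intact one up to (and
#' excluding) the first stop codon.
#'
#' @param wt_cds wild-type CDS nucleotide string.
#' @param variant a [cds_variant].
#' @return object of class `frameshift_report`: `last_intact_residue`,
#'   `is_frameshift`, `novel_residues`, `novel_count`, `stop_found`,
#'   `wt_protein`, `mutant_protein`.
#' @export
frameshift_report <- function(wt_cds, variant) {
  mut_cds <- apply_substitution(wt_cds, variant)
  wt_tr <- translate_cds(wt_cds)
  mut_tr <- translate_cds(mut_cds)
  last_intact <- (variant$position - 1L) %/% 3L
  shift <- (nchar(variant$alt_allele) - nchar(variant$ref_allele)) %% 3L
  novel <- if (last_intact < nchar(mut_tr$protein)) {
    substr(mut_tr$protein, last_intact + 1L, nchar(mut_tr$protein))
  } else {
    ""
  }
  structure(list(last_intact_residue = last_intact,
                 is_frameshift = shift != 0L,
                 novel_residues = novel,
                 novel_count = nchar(novel),
                 stop_found = mut_tr$stop_found,
                 wt_protein = wt_tr$protein,
                 mutant_protein = mut_tr$protein),
            class = "frameshift_report")
}

#' @export
print.frameshift_report <- function(x, ...) {
  cat(sprintf("<frameshift_report> frameshift: %s\n",
              if (x$is_frameshift) "yes" else "no"))
  cat(sprintf("  last intact residue: %d\n", x$last_intact_residue))
  cat(sprintf("  novel residues (%d%s): %s\n", x$novel_count,
              if (x$stop_found) ", stop reached" else ", no stop found",
              if (nzchar(x$novel_residues)) x$novel_residues else "-"))
  invisible(x)
}

#' Antibody-epitope integrity after a frameshift
#'
#' Counts how many residues of a 1-based epitope interval survive a
#' frameshift unchanged: residues up to the last intact residue are
#' preserved, everything downstream is replaced by the novel peptide.
#'
#' @param epitope length-2 numeric `(start, end)`, 1-based inclusive protein
#'   coordinates with `start <= end`.
#' @param report a [frameshift_report], or a number taken as the last intact
#'   residue.
#' @return list with `intact_residues` and `total_residues`.
#' @examples
#' epitope_integrity(c(528, 622), 610)  # 83 of 95 residues preserved
#' @export
epitope_integrity <- function(epitope, report) {
  if (length(epitope) != 2L || !is.numeric(epitope) ||
      epitope[1] < 1 || epitope[1] > epitope[2]) {
    stop_field("epitope", "must be (start, end) with 1 <= start <= end")
  }
  last_intact <- if (inherits(report, "frameshift_report")) {
    report$last_intact_residue
  } else {
    as.numeric(report)
  }
  total <- epitope[2] - epitope[1] + 1
  intact <- max(0, min(epitope[2], last_intact) - epitope[1] + 1)
  list(intact_residues = as.integer(intact), total_residues = as.integer(total))
}

#' Read a single sequence from a FASTA file or raw string
#'
#' Accepts either a path to a FASTA file (first record is used; an error names
#' the file if it holds none) or a raw nucleotide string.
#'
#' @param x FASTA path or nucleotide string.
#' @return uppercase nucleotide string.
#' @export
read_cds <- function(x) {
  if (length(x) == 1L && !grepl("^[ACGTacgt]+$", x) && file.exists(x)) {
    set <- Biostrings::readDNAStringSet(x)
    if (length(set) == 0L) {
      stop(sprintf("no sequences in FASTA file '%s'", x), call. = FALSE)
    }
    toupper(as.character(set[[1L]]))
  } else {
    toupper(as.character(x))
  }
}

#' Synthetic lamin-like CDS for exercising the frameshift machinery
#'
#' Generates a random 1866-nt CDS (622 codons, no internal stop in frame 0)
#' that carries the `GATCC` reference fragment at positions 1831-1835, so the
#' published variant coordinates of [lam_a25_variant] can be applied to it.
#' This is a synthetic stand-in: it is NOT the Lam gene sequence, and
#' frame-shifted translation products downstream of the substitution are
#' arbitrary. Use it to validate the arithmetic, never to reproduce
#' sequence-specific results.
#'
#' @param seed integer seed for the random codons.
#' @return nucleotide string of length 1866 plus a TAA stop (1869 nt).
#' @export
synthetic_lam_like_cds <- function(seed = 101L) {
  codons <- c("GCT", "GCC", "CGT", "AAC", "GAC", "TGC", "GAA", "CAA", "GGT",
              "CAC", "ATC", "CTG", "AAA", "ATG", "TTC", "CCG", "TCT", "ACC",
              "TGG", "TAC", "GTT")  # one codon per amino acid, no stops
  body <- with_seed(seed, {
    paste(sample(codons, 621, replace = TRUE), collapse = "")
  })
  cds <- paste0("ATG", body)
  # splice the reference fragment across positions 1831-1835
  cds <- paste0(substr(cds, 1, 1830), "GATCC", substr(cds, 1836, 1866))
  paste0(cds, "TAA")
}
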