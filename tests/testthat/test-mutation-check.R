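test_that("substitutions splice correctly and verify the reference allele", {
  v <- cds_variant(4, "GATCC", "TCTACCA")
  expect_equal(apply_substitution("ATGGATCCA", v), "ATGTCTACCAA")

  # identity substitution returns the input
  vi <- cds_variant(4, "GATCC", "GATCC")
  expect_equal(apply_substitution("ATGGATCCA", vi), "ATGGATCCA")

  # mismatching reference reports expected vs found
  vbad <- cds_variant(4, "AAAAA", "TTTTT")
  expect_error(apply_substitution("ATGGATCCA", vbad), "expected 'AAAAA'")
  expect_error(apply_substitution("ATGGATCCA", vbad), "found 'GATCC'")

  # out of range
  expect_error(apply_substitution("ATGGAT", cds_variant(5, "ATCC", "A")),
               "has 6 nt")
  expect_error(cds_variant(0, "A", "T"), "position")
  expect_error(cds_variant(3, "", "T"), "ref_allele")
  expect_error(cds_variant(3, "ANA", "T"), "ref_allele")
})

test_that("translation follows the standard code and stops at the first stop", {
  tr <- translate_cds("ATGAAATAA")
  expect_equal(tr$protein, "MK")
  expect_true(tr$stop_found)

  tr2 <- translate_cds("ATGGGG")
  expect_equal(tr2$protein, "MG")
  expect_false(tr2$stop_found)

  # trailing partial codon ignored
  expect_equal(translate_cds("ATGGGGTT")$protein, "MG")

  expect_error(translate_cds("ATGNGG"), "A/C/G/T")

  # agreement with an independent codon-walk oracle on random sequences
  set.seed(8)
  for (k in 1:10) {
    cds <- paste(sample(c("A", "C", "G", "T"), 3 * sample(5:40, 1),
                        replace = TRUE), collapse = "")
    got <- translate_cds(cds)
    orc <- oracle_translate(cds)
    expect_equal(got$protein, orc$protein)
    expect_equal(got$stop_found, orc$stop_found)
  }
})

test_that("frameshift reports locate the last intact codon and novel peptide", {
  # the published substitution coordinates: replacement begins after CDS
  # nucleotide 1830, i.e. at position 1831, so codon 610 is the last intact one
  cds <- synthetic_lam_like_cds()
  v <- lam_a25_variant()
  expect_equal(substr(cds, 1831, 1835), "GATCC")
  rep <- frameshift_report(cds, v)
  expect_equal(rep$last_intact_residue, 610L)
  expect_true(rep$is_frameshift)

  # the novel peptide equals what an independent codon walk of the mutant
  # CDS yields beyond residue 610
  mut <- apply_substitution(cds, v)
  orc <- oracle_translate(mut)
  expect_equal(rep$novel_residues, substr(orc$protein, 611, nchar(orc$protein)))
  expect_equal(rep$novel_count, nchar(rep$novel_residues))
  expect_equal(rep$stop_found, orc$stop_found)
  # the wild-type and mutant proteins agree up to the last intact residue
  expect_equal(substr(rep$mutant_protein, 1, 610),
               substr(rep$wt_protein, 1, 610))

  # an in-frame 3-nt insertion is not a frameshift
  v3 <- cds_variant(4, "GATCC", "GATGGGCC")
  rep3 <- frameshift_report("ATGGATCCAAAATAA", v3)
  expect_false(rep3$is_frameshift)

  # net length change divisible by 3 keeps downstream translation intact
  set.seed(15)
  base <- synthetic_lam_like_cds(seed = 5)
  for (k in 1:5) {
    pos <- 3 * sample(20:100, 1) + 1
    refl <- sample(1:4, 1)
    v_in <- cds_variant(pos, substr(base, pos, pos + refl - 1),
                        paste(sample(c("A", "C", "G", "T"), refl + 3,
                                     replace = TRUE), collapse = ""))
    mut_k <- apply_substitution(base, v_in)
    wt_tail <- substr(base, pos + refl, nchar(base))
    mut_tail <- substr(mut_k, pos + refl + 3, nchar(mut_k))
    expect_equal(mut_tail, wt_tail)
  }
})

test_that("applying a variant and then its inverse restores the CDS", {
  cds <- synthetic_lam_like_cds()
  v <- lam_a25_variant()
  mut <- apply_substitution(cds, v)
  back <- apply_substitution(mut, cds_variant(v$position, v$alt_allele,
                                              v$ref_allele))
  expect_identical(back, cds)
})

test_that("epitope integrity counts preserved residues", {
  # the C-terminal antibody epitope spans 528-622; a frameshift after 610
  # preserves 83 of its 95 residues
  e1 <- epitope_integrity(c(528, 622), 610)
  expect_equal(e1$intact_residues, 83L)
  expect_equal(e1$total_residues, 95L)

  # the N-terminal epitope 22-28 is untouched
  e2 <- epitope_integrity(c(22, 28), 610)
  expect_equal(e2$intact_residues, 7L)
  expect_equal(e2$total_residues, 7L)

  # an epitope entirely downstream of the last intact residue is lost
  e3 <- epitope_integrity(c(615, 640), 610)
  expect_equal(e3$intact_residues, 0L)
  expect_equal(e3$total_residues, 26L)

  expect_error(epitope_integrity(c(10, 5), 610), "start <= end")

  # accepts a report object directly
  rep <- frameshift_report(synthetic_lam_like_cds(), lam_a25_variant())
  expect_equal(epitope_integrity(c(528, 622), rep)$intact_residues, 83L)
})

test_that("CDS input is accepted as raw string or FASTA", {
  dir <- withr::local_tempdir()
  cds <- synthetic_lam_like_cds()
  fa <- file.path(dir, "cds.fasta")
  writeLines(c(">synthetic lamin-like CDS (not a real gene sequence)",
               substring(cds, seq(1, nchar(cds), 60),
                         pmin(seq(60, nchar(cds) + 59, 60), nchar(cds)))), fa)
  expect_equal(read_cds(fa), cds)
  expect_equal(read_cds("atggatcca"), "ATGGATCCA")
})
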