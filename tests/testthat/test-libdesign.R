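test_that("theoretical complexity is the product of allowed-codon set sizes", {
  expect_equal(theoretical_complexity(flt3_library_spec()), 65536)
  # empty variable set: empty product
  null_spec <- library_spec("ATGGCC", integer(0), list(),
                            flank5 = "ACGTACGTAC", flank3 = "TTGCATGCAA",
                            mode = "degenerate_scan")
  expect_equal(theoretical_complexity(null_spec), 1)
  # two fully degenerate positions
  kit2 <- kit_library_spec()
  two_pos <- library_spec(kit2$reference_orf, c(1L, 2L),
                          kit2$allowed_codons[1:2],
                          flank5 = kit2$flank5, flank3 = kit2$flank3,
                          mode = "degenerate_scan")
  expect_equal(theoretical_complexity(two_pos), 64^2)
})

test_that("spec invariants are enforced", {
  expect_error(library_spec("ATGGC", 1L, list("1" = c("ATG", "GTG")),
                            "A", "T", "combinatorial"),
               "divisible by 3")
  expect_error(library_spec("ATGGCC", 5L, list("5" = c("ATG", "GTG")),
                            "A", "T", "combinatorial"),
               "outside")
  # combinatorial set must contain the reference codon
  expect_error(library_spec("ATGGCC", 2L, list("2" = c("GTC", "GAC")),
                            "A", "T", "combinatorial"),
               "reference codon")
  expect_error(library_spec("ATGGCC", 2L, list("2" = c("GC", "GACT")),
                            "A", "T", "degenerate_scan"),
               "3-mers")
})

test_that("enumeration emits every assignment once, in lexicographic order", {
  spec <- toy_spec()
  vs <- enumerate_variants(spec)
  expect_equal(length(vs), theoretical_complexity(spec))
  keys <- apply(vs$codons, 1, paste, collapse = "|")
  expect_equal(anyDuplicated(keys), 0L)
  expect_equal(keys, sort(keys))  # lexicographic by position then codon
  # boundary members of the FLT3 space
  flt3 <- flt3_library_spec()
  all16 <- enumerate_variants(flt3)
  subs <- variant_substitutions(all16)
  nsub <- lengths(strsplit(subs, ";"))
  nsub[subs == ""] <- 0L
  expect_true(any(nsub == 0L))   # all-reference assignment
  expect_true(any(nsub == 16L))  # all-alternative assignment
  expect_equal(nrow(all16$codons), 65536L)
  expect_error(enumerate_variants(flt3, limit = 10), "exceeds limit")
})

test_that("a single degenerate position encodes the brute-force amino-acid set", {
  kit <- kit_library_spec()
  one <- library_spec(kit$reference_orf, 5L,
                      kit$allowed_codons[as.character(5L)],
                      flank5 = kit$flank5, flank3 = kit$flank3,
                      mode = "degenerate_scan",
                      numbering_offset = kit$numbering_offset)
  vs <- enumerate_variants(one)
  expect_equal(length(vs), 64L)
  ref_codon <- one$reference_codons[[1]]
  expect_equal(sum(vs$codons[, 1] != ref_codon), 63L)
  # encoded non-reference amino acids match codon-by-codon translation
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  ref_aa <- gc[[ref_codon]]
  expected_aas <- sort(unique(gc[setdiff(vs$codons[, 1], ref_codon)]))
  expected_aas <- setdiff(expected_aas, ref_aa)
  subs <- variant_substitutions(vs)
  got <- sort(unique(sub("^[A-Z][0-9]+", "", subs[subs != ""])))
  expect_equal(got, expected_aas)
})

test_that("sampling is reproducible, unbiased and position-wise uniform", {
  flt3 <- flt3_library_spec()
  a <- sample_variants(flt3, 100, seed = 7)
  b <- sample_variants(flt3, 100, seed = 7)
  expect_identical(a$codons, b$codons)
  # mean substitution count ~ Binomial(16, 1/2)
  big <- sample_variants(flt3, 10000, seed = 11)
  subs <- variant_substitutions(big)
  nsub <- lengths(strsplit(subs, ";"))
  nsub[subs == ""] <- 0L
  expect_lt(abs(mean(nsub) - 8), 0.2)
  # single position, single draw
  one <- sample_variants(toy_spec(), 1, seed = 3)
  expect_equal(nrow(one$codons), 1L)
  # per-position codon frequencies within 2% of uniform at n = 50,000
  toy <- toy_spec()
  s <- sample_variants(toy, 50000, seed = 5)
  for (j in 1:2) {
    fr <- table(s$codons[, j]) / 50000
    expect_true(all(abs(fr - 0.5) < 0.02))
  }
})

test_that("emitted inserts are flanked, expandable and round-trip through read processing", {
  spec <- toy_spec()
  vs <- enumerate_variants(spec)
  ins <- emit_inserts(vs, as_string = TRUE)
  ref_idx <- which(variant_substitutions(vs) == "")
  expect_equal(unname(ins[ref_idx]),
               paste0(spec$flank5, spec$reference_orf, spec$flank3))
  # one degenerate position expands to 64 records
  kit <- kit_library_spec()
  one <- library_spec(kit$reference_orf, 1L, kit$allowed_codons["1"],
                      flank5 = kit$flank5, flank3 = kit$flank3,
                      mode = "degenerate_scan")
  expect_equal(length(emit_inserts(enumerate_variants(one))), 64L)
  # round trip: exact reads recover each variant's protein
  flt3 <- flt3_library_spec()
  sv <- sample_variants(flt3, 100, seed = 13)
  reads <- emit_inserts(sv, as_string = TRUE)
  vc <- process_reads(unname(reads), flt3)
  expect_equal(sum(vc$counts), 100L)
  expect_equal(vc$discarded_indel_reads + vc$discarded_unanchored_reads, 0L)
  orfs <- substr(unname(reads), nchar(flt3$flank5) + 1,
                 nchar(flt3$flank5) + nchar(flt3$reference_orf))
  expected <- table(as.character(Biostrings::translate(
    Biostrings::DNAStringSet(orfs), no.init.codon = TRUE)))
  expect_equal(vc$counts[names(expected)],
               stats::setNames(as.integer(expected), names(expected)))
})

test_that("stop-carrying degenerate variants are flagged", {
  kit <- kit_library_spec()
  one <- library_spec(kit$reference_orf, 1L, kit$allowed_codons["1"],
                      flank5 = kit$flank5, flank3 = kit$flank3,
                      mode = "degenerate_scan")
  vs <- enumerate_variants(one)
  expect_equal(sum(has_stop(vs)), 3L)  # TAA, TAG, TGA
})
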