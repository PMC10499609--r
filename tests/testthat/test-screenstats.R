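test_that("read processing anchors, discards indels and aggregates synonyms", {
  spec <- toy_spec()
  ref_read <- paste0(spec$flank5, spec$reference_orf, spec$flank3)
  vc <- process_reads(ref_read, spec)
  expect_equal(unname(vc$counts), 1L)
  expect_equal(names(vc$counts), spec$reference_protein)
  # 1-nt deletion between anchors
  del_read <- paste0(spec$flank5, substr(spec$reference_orf, 2, 12),
                     spec$flank3)
  vc <- process_reads(c(ref_read, del_read), spec)
  expect_equal(vc$discarded_indel_reads, 1L)
  expect_equal(sum(vc$counts), 1L)
  # synonymous codons aggregate to one protein variant
  syn <- spec$reference_orf
  substr(syn, 9, 9) <- "T"  # AAC -> AAT, still Asn
  syn_read <- paste0(spec$flank5, syn, spec$flank3)
  vc <- process_reads(c(ref_read, syn_read), spec)
  expect_equal(unname(vc$counts), 2L)
  expect_equal(length(vc$counts), 1L)
  # missing anchor
  vc <- process_reads(c(ref_read, substr(ref_read, 3, nchar(ref_read))), spec)
  expect_equal(vc$discarded_unanchored_reads, 1L)
  # empty input is not an error
  vc <- process_reads(character(0), spec)
  expect_equal(vc$total_reads, 0L)
})

test_that("read conservation: discards plus aggregated reads equal input", {
  spec <- flt3_library_spec()
  sim <- simulate_screen(screen_truth(spec, depth = 2000L), seed = 5)
  vc <- process_reads(sim$sp, spec)
  expect_equal(sum(vc$counts) + vc$discarded_indel_reads +
                 vc$discarded_unanchored_reads, 2000L)
  expect_equal(vc$total_reads, 2000L)
})

test_that("abundance filter uses strict inequality against pre-filter frequencies", {
  spec <- toy_spec()
  vs <- enumerate_variants(spec)
  # two variants at 999 : 1
  vc <- counts_from_table(spec, variant_set(spec, vs$codons[c(1, 4), ]),
                          c(999L, 1L))
  kept <- filter_by_abundance(vc, 0.001)
  expect_equal(length(kept$counts), 1L)  # freq 0.001 is not > 0.001
  expect_equal(unname(kept$counts), 999L)
  # threshold 0 keeps everything with >= 1 read
  kept0 <- filter_by_abundance(vc, 0)
  expect_equal(length(kept0$counts), 2L)
  # frequencies stay relative to the pre-filter aggregate
  expect_equal(unname(variant_frequencies(kept)), 0.999)
  # random table against a brute-force filter
  set.seed(42)
  big <- kit_library_spec()
  vsb <- sample_variants(big, 50, seed = 21)
  vsb <- variant_set(big, vsb$codons[!has_stop(vsb), , drop = FALSE])
  n <- nrow(vsb$codons)
  cnt <- sample(1:40, n, replace = TRUE)
  vcb <- counts_from_table(big, vsb, cnt)
  thr <- 0.02
  kept <- filter_by_abundance(vcb, thr)
  brute <- names(vcb$counts)[vcb$counts / sum(vcb$counts) > thr]
  expect_setequal(names(kept$counts), brute)
})

test_that("joint filtering across fractions requires the threshold in every one", {
  spec <- toy_spec()
  vs <- enumerate_variants(spec)
  a <- counts_from_table(spec, variant_set(spec, vs$codons[c(1, 4), ]),
                         c(50L, 50L), "sp")
  b <- counts_from_table(spec, variant_set(spec, vs$codons[c(1, 4), ]),
                         c(99L, 1L), "dp")
  both <- filter_by_abundance(list(sp = a, dp = b), 0.05)
  expect_equal(length(both$sp$counts), 1L)
  expect_equal(length(both$dp$counts), 1L)
})

test_that("positional frequency matrix matches analytic and brute-force tallies", {
  spec <- toy_spec()
  vs <- enumerate_variants(spec)
  subs <- variant_substitutions(vs)
  ref_i <- which(subs == "")
  one_i <- which(subs == "N3D")
  # single variant at 100%
  vc <- counts_from_table(spec, variant_set(spec, vs$codons[ref_i, , drop = FALSE]),
                          10L)
  m <- positional_aa_frequency(vc, positions = 1:4)
  expect_true(all(abs(rowSums(m) - 1) < 1e-9))
  for (p in 1:4)
    expect_equal(unname(m[p, substr(spec$reference_protein, p, p)]), 1)
  # 50/50 split differing at one position
  vc2 <- counts_from_table(spec,
                           variant_set(spec, vs$codons[c(ref_i, one_i), ]),
                           c(10L, 10L))
  m2 <- positional_aa_frequency(vc2, positions = 1:4)
  expect_equal(unname(m2["3", "N"]), 0.5)
  expect_equal(unname(m2["3", "D"]), 0.5)
  expect_equal(unname(m2["2", "A"]), 1)
  # random 20-variant table against a brute-force tally
  flt3 <- flt3_library_spec()
  sv <- sample_variants(flt3, 20, seed = 9)
  cnt <- sample(1:30, 20, replace = TRUE)
  vcr <- counts_from_table(flt3, sv, cnt)
  pos <- flt3$variable_positions + flt3$numbering_offset
  m3 <- positional_aa_frequency(vcr, positions = pos)
  prots <- names(vcr$counts); w <- as.numeric(vcr$counts)
  for (k in seq_along(pos)) {
    loc <- flt3$variable_positions[k]
    tal <- tapply(w, substr(prots, loc, loc), sum) / sum(w)
    expect_equal(m3[as.character(pos[k]), names(tal)], tal,
                 ignore_attr = TRUE)
  }
})

test_that("substitution log fold change matches hand calculations", {
  spec <- toy_spec()
  vs <- enumerate_variants(spec)
  subs <- variant_substitutions(vs)
  ref_i <- which(subs == "")
  n3d_i <- which(subs == "N3D")
  a2v_i <- which(subs == "A2V")
  # sp: N3D at 2/100 reads; dp: N3D at 2/1000 -> logfc exactly 1 (pc = 0)
  sp <- counts_from_table(spec, variant_set(spec, vs$codons[c(ref_i, n3d_i), ]),
                          c(98L, 2L), "sp")
  dp <- counts_from_table(spec, variant_set(spec, vs$codons[c(ref_i, n3d_i), ]),
                          c(998L, 2L), "dp")
  cfg <- screen_config(pseudocount = 0)
  et <- substitution_logfc(sp, dp, cfg)
  expect_equal(et$logfc[et$substitution == "N3D"], 1)
  # equal abundances -> logfc 0, fails filter
  et0 <- substitution_logfc(sp, sp, cfg)
  expect_equal(et0$logfc, 0)
  expect_false(any(et0$passes_filter))
  # absent from dp with pseudocount 0.5: finite, hand-computed
  sp3 <- counts_from_table(spec,
                           variant_set(spec, vs$codons[c(ref_i, n3d_i, a2v_i), ]),
                           c(6L, 3L, 1L), "sp")
  dp3 <- counts_from_table(spec,
                           variant_set(spec, vs$codons[c(ref_i, a2v_i), ]),
                           c(8L, 2L), "dp")
  et3 <- substitution_logfc(sp3, dp3, screen_config(pseudocount = 0.5))
  # table rows: A2V and N3D -> denominators total + 0.5 * 2
  hand_sp <- (3 + 0.5) / (10 + 0.5 * 2)
  hand_dp <- (0 + 0.5) / (10 + 0.5 * 2)
  row <- et3[et3$substitution == "N3D", ]
  expect_equal(row$abundance_sp, hand_sp)
  expect_equal(row$abundance_dp, hand_dp)
  expect_equal(row$logfc, log10(hand_sp / hand_dp))
  expect_true(is.finite(row$logfc) && row$logfc > 0)
})

test_that("log fold change is antisymmetric under fraction swap", {
  flt3 <- flt3_library_spec()
  sim <- simulate_screen(screen_truth(flt3, depth = 3000L), seed = 17)
  sp <- process_reads(sim$sp, flt3, "sp")
  dp <- process_reads(sim$dp, flt3, "dp")
  ab <- substitution_logfc(sp, dp)
  ba <- substitution_logfc(dp, sp)
  ba <- ba[match(ab$substitution, ba$substitution), ]
  expect_equal(ab$logfc, -ba$logfc, tolerance = 1e-12)
})

test_that("candidate ranking applies filters and tie rules", {
  tab <- data.frame(
    position = c(10L, 20L, 30L, 40L),
    ref_aa = "A", alt_aa = "V",
    substitution = c("s1", "s2", "s3", "s4"),
    reads_sp = 1, reads_dp = 1,
    abundance_sp = c(0.5, 0.2, 0.8, 0.8),
    abundance_dp = 0.01,
    logfc = c(2, 2, 2, 0.1),
    passes_filter = c(TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  r <- rank_epitope_candidates(tab)
  expect_equal(r$substitution, c("s3", "s1", "s2"))
  one <- rank_epitope_candidates(tab[1, ])
  expect_equal(nrow(one), 1L)
})

test_that("premature-stop variants are excluded from enrichment denominators", {
  kit <- kit_library_spec()
  one <- library_spec(kit$reference_orf, 1L, kit$allowed_codons["1"],
                      flank5 = kit$flank5, flank3 = kit$flank3,
                      mode = "degenerate_scan",
                      numbering_offset = kit$numbering_offset)
  vs <- enumerate_variants(one)
  stops <- which(has_stop(vs))
  ref_codon <- one$reference_codons[[1]]
  ref_i <- which(vs$codons[, 1] == ref_codon)
  pick <- c(ref_i, stops[1], which(variant_substitutions(vs) != "" &
                                     !has_stop(vs))[1])
  sp <- counts_from_table(one, variant_set(one, vs$codons[pick, ]),
                          c(10L, 5L, 5L), "sp")
  dp <- counts_from_table(one, variant_set(one, vs$codons[pick, ]),
                          c(10L, 5L, 5L), "dp")
  et <- substitution_logfc(sp, dp, screen_config(pseudocount = 0))
  # denominator excludes the 5 stop reads: abundance = 5/15
  nonstop_sub <- et[!grepl("\\*", et$substitution), ]
  expect_equal(nonstop_sub$abundance_sp, 5 / 15)
})
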