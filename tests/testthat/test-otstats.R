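test_that("intercept-only penalized fits equal the (y + 1/2)/(n + 1) closed form", {
  for (case in list(c(0, 100), c(100, 100), c(3, 10))) {
    f <- firth_fit(matrix(1, 1, 1), case[1], case[2])
    expect_equal(unname(f$fitted), (case[1] + 0.5) / (case[2] + 1),
                 tolerance = 1e-8)
    expect_true(is.finite(f$se))
  }
})

test_that("multi-parameter fits match numeric maximization of the penalized likelihood", {
  set.seed(11)
  # 2-parameter: intercept + treatment
  X <- cbind(1, c(0, 0, 1, 1))
  y <- c(2, 4, 60, 48); n <- c(500, 480, 510, 490)
  f <- firth_fit(X, y, n)
  b_oracle <- oracle_firth_beta(X, y, n,
                                starts = list(c(0, 0), f$coefficients + 0.3,
                                              c(-5, 3)))
  expect_lt(max(abs(unname(f$coefficients) - b_oracle)), 1e-5)
  # 1-parameter slope-only model
  X1 <- matrix(c(0.2, 0.7, 1.3, 2.1), ncol = 1)
  y1 <- c(1, 3, 9, 30); n1 <- rep(100, 4)
  f1 <- firth_fit(X1, y1, n1)
  b1 <- optimize(function(b) -oracle_penalized_loglik(b, X1, y1, n1),
                 c(-10, 10), tol = 1e-10)$minimum
  expect_lt(abs(unname(f1$coefficients) - b1), 1e-5)
})

test_that("complete separation yields finite estimates and standard errors", {
  tab <- data.frame(
    DonorID = rep(c("D1", "D2"), each = 2),
    treatment = rep(c(0L, 1L), 2),
    EditedReads = c(0L, 25L, 0L, 31L),
    TotalReads = c(1000L, 1000L, 900L, 1100L))
  f <- firth_logistic(tab)
  expect_true(all(is.finite(f$coefficients)))
  expect_true(all(is.finite(f$se)))
  expect_true(f$converged)
  expect_gt(f$b_treatment, 0)
  # fitted proportions and CIs are proper probabilities
  expect_true(all(f$samples$ci_lo >= 0 & f$samples$ci_hi <= 1))
  expect_true(all(f$samples$ci_lo <= f$samples$fitted_proportion))
})

test_that("fits are exactly invariant to row permutation", {
  tab <- simulate_offtarget_counts(n_loci = 1, seed = 3)
  f1 <- firth_logistic(tab)
  f2 <- firth_logistic(tab[sample(nrow(tab)), ])
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-12)
  expect_equal(f1$se, f2$se, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  expect_error(firth_fit(cbind(1, c(1, 1)), c(1, 1), c(10, 10)),
               "rank deficient")
  expect_error(firth_fit(matrix(1, 2, 1), c(1, 0), c(10, 0)), "zero Total")
  expect_error(firth_fit(matrix(1, 1, 1), 5, 4), "0 <= EditedReads")
})

test_that("off-target calls require a positive and significant treatment effect", {
  fake <- function(b, p) {
    structure(list(b_treatment = b, p_treatment = p,
                   se = c(treatment = 0.4)), class = "firth_fit")
  }
  calls <- call_offtargets(list(up = fake(1.2, 0.01),
                                down = fake(-1.2, 0.01),
                                weak = fake(0.8, 0.2)))
  expect_equal(calls$flagged, c(TRUE, FALSE, FALSE))
  adj <- call_offtargets(list(a = fake(1, 0.03), b = fake(1, 0.04)),
                         adjust = "bonferroni")
  expect_false(any(adj$flagged))
})

test_that("indel model is the same estimator as the deamination model", {
  tab <- simulate_offtarget_counts(n_loci = 1, seed = 9)
  expect_equal(firth_logistic(tab)$coefficients,
               indel_glm(tab)$coefficients)
})

test_that("treatment shifts are recovered on simulated count tables", {
  errs <- vapply(1:10, function(s) {
    tab <- simulate_offtarget_counts(n_loci = 1, baseline = -5,
                                     treatment_shift = 3, seed = 100 + s)
    firth_logistic(tab)$b_treatment - 3
  }, numeric(1))
  expect_lt(abs(stats::median(errs)), 0.3)
})

test_that("site filtering and annotation match a brute-force oracle", {
  # worked boundary cases
  sites <- data.frame(chrom = "chr1",
                      start = c(100L, 300L, 500L),
                      end = c(130L, 330L, 530L),
                      mismatches = c(4L, 6L, 2L),
                      bulges = c(1L, 0L, 1L),
                      unique_reads = c(10L, 8L, 6L))
  genes <- GenomicRanges::GRanges("chr1", IRanges::IRanges(450, 700))
  exons <- GenomicRanges::GRanges("chr1", IRanges::IRanges(600, 650))
  out <- filter_guideseq_sites(sites, NULL, exons = exons, genes = genes)
  expect_equal(out$start, c(100L, 500L))   # 4+1 kept, 6+0 dropped
  expect_equal(out$annotation, c("intergenic", "intronic"))
  # random fixture vs oracle
  set.seed(23)
  for (rep in 1:10) {
    ns <- 30
    rs <- sample(1:5000, ns)
    sites <- data.frame(chrom = sample(c("chr1", "chr2"), ns, TRUE),
                        start = rs, end = rs + sample(20:40, ns, TRUE),
                        mismatches = sample(0:7, ns, TRUE),
                        bulges = sample(0:2, ns, TRUE))
    rc <- sample(1:5000, 8)
    ctrl <- data.frame(chrom = sample(c("chr1", "chr2"), 8, TRUE),
                       start = rc, end = rc + 50)
    ge <- sample(1:5000, 6)
    gene_df <- data.frame(chrom = sample(c("chr1", "chr2"), 6, TRUE),
                          start = ge, end = ge + sample(200:800, 6, TRUE))
    exon_df <- data.frame(chrom = gene_df$chrom,
                          start = gene_df$start + 10,
                          end = gene_df$start + 60)
    got <- filter_guideseq_sites(
      sites, ctrl,
      exons = granges_from_df(exon_df),
      genes = granges_from_df(gene_df))
    want <- oracle_filter_sites(sites, ctrl, exon_df, gene_df, 6L)
    expect_equal(got$start, want$start)
    expect_equal(got$annotation, want$annotation)
  }
})

test_that("BED gene models are parsed into exons and gene spans", {
  bed6 <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t99\t200\tgeneA\t0\t+",
               "chr1\t299\t400\tgeneA\t0\t+",
               "chr2\t49\t150\tgeneB\t0\t-"), bed6)
  gm <- read_gene_model_bed(bed6)
  expect_equal(length(gm$exons), 3L)
  expect_equal(length(gm$genes), 2L)
  # geneA span covers both exons including the intron between
  spanA <- gm$genes[GenomicRanges::seqnames(gm$genes) == "chr1"]
  expect_equal(IRanges::start(spanA), 100L)
  expect_equal(IRanges::end(spanA), 400L)
})

test_that("editing-rate summaries select top-coverage adenines like the brute-force filter", {
  # point examples
  p <- data.frame(chrom = "c", pos = 1:2, ref = c("A", "A"),
                  coverage = c(100L, 10L), A = c(98L, 10L),
                  C = 0L, G = c(2L, 0L), T = 0L)
  r <- rna_editing_rates(p, top_fraction = 0.25)
  expect_equal(r$sites$rate, 0.02)
  expect_equal(r$n_sites, 1L)
  # zero transitions anywhere
  p$G <- 0L; p$A <- p$coverage
  r0 <- rna_editing_rates(p, top_fraction = 1)
  expect_true(all(r0$sites$rate == 0))
  expect_error(rna_editing_rates(p[p$ref == "C", , drop = FALSE]), "no A")
  # synthetic pileup vs oracle
  pl <- simulate_pileup(n_sites = 10000, background_rate = 0.02, seed = 6)
  got <- rna_editing_rates(pl)
  want <- oracle_top_sites(pl, 0.05)
  expect_equal(got$n_sites, nrow(want))
  expect_setequal(got$sites$pos, want$pos)
  expect_lt(abs(got$mean_rate - 0.02), 0.005)
})
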