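# Independent brute-force oracles and small fixture builders used across
# the suite. Oracles deliberately use different code paths than the
# implementations they check.

# Tiny two-position combinatorial spec for fast unit tests.
toy_spec <- function() {
  # ORF: M A N C (ATG GCC AAC TGC); positions 2 and 3 variable
  library_spec(
    reference_orf = "ATGGCCAACTGC",
    variable_positions = c(2L, 3L),
    allowed_codons = list("2" = c("GCC", "GTC"),   # A2V alternative
                          "3" = c("AAC", "GAC")),  # N3D alternative
    flank5 = "ACGTACGTAC", flank3 = "TTGCATGCAA",
    mode = "combinatorial")
}

# Build a variant_counts object from an explicit count table by
# replicating exact reads through the public read-processing path.
counts_from_table <- function(spec, variants, counts, fraction = "sp") {
  inserts <- emit_inserts(variants, as_string = TRUE)
  reads <- rep(unname(inserts), counts)
  process_reads(reads, spec, fraction)
}

# Brute-force guide scan: test every spacer placement + PAM on both
# strands with naive string handling.
oracle_scan <- function(sense, target_position, editor) {
  comp <- function(s) chartr("ACGT", "TGCA", s)
  rc <- function(s) paste(rev(strsplit(comp(s), "")[[1]]), collapse = "")
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                D = "AGT", H = "ACT", V = "ACG", N = "ACGT")
  pam_ok <- function(p, pat) {
    pc <- strsplit(p, "")[[1]]; tc <- strsplit(pat, "")[[1]]
    all(vapply(seq_along(tc), function(i)
      grepl(pc[i], iupac[[tc[i]]], fixed = TRUE), logical(1)))
  }
  sl <- editor$spacer_length; pl <- nchar(editor$pam)
  L <- nchar(sense)
  sub_base <- if (editor$conversion == "AG") "A" else "C"
  hits <- list()
  for (j in seq_len(max(0, L - sl + 1))) {
    proto <- substr(sense, j, j + sl - 1)
    # plus strand
    if (j + sl + pl - 1 <= L &&
        pam_ok(substr(sense, j + sl, j + sl + pl - 1), editor$pam)) {
      tp <- target_position - j + 1
      if (tp >= editor$window[1] && tp <= editor$window[2] &&
          substr(proto, tp, tp) == sub_base)
        hits[[length(hits) + 1]] <- c(strand = "+", start = j - 1, tp = tp)
    }
    # minus strand
    if (j - pl >= 1 && pam_ok(rc(substr(sense, j - pl, j - 1)), editor$pam)) {
      spacer <- rc(proto)
      tp <- j + sl - target_position
      if (tp >= editor$window[1] && tp <= editor$window[2] &&
          substr(spacer, tp, tp) == sub_base)
        hits[[length(hits) + 1]] <- c(strand = "-", start = j - 1, tp = tp)
    }
  }
  if (length(hits) == 0)
    return(data.frame(strand = character(0), start = integer(0),
                      tp = integer(0)))
  df <- as.data.frame(do.call(rbind, hits), stringsAsFactors = FALSE)
  df$start <- as.integer(df$start); df$tp <- as.integer(df$tp)
  df[order(match(df$strand, c("+", "-")), df$start), , drop = FALSE]
}

# Penalized binomial log-likelihood (Jeffreys prior), written directly
# from its definition, for oracle maximization with optim.
oracle_penalized_loglik <- function(beta, X, y, n) {
  eta <- drop(X %*% beta)
  pi <- 1 / (1 + exp(-eta))
  w <- n * pi * (1 - pi)
  I <- t(X) %*% (X * w)
  ll <- sum(y * log(pi) + (n - y) * log1p(-pi))
  ll + 0.5 * log(det(I))
}

oracle_firth_beta <- function(X, y, n, starts = NULL) {
  p <- ncol(X)
  if (is.null(starts))
    starts <- list(rep(0, p), rep(-2, p), c(-4, rep(1, p - 1)))
  best <- NULL
  for (s in starts) {
    o <- optim(s, function(b) -oracle_penalized_loglik(b, X, y, n),
               method = "Nelder-Mead",
               control = list(maxit = 20000, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  best$par
}

# Brute-force interval overlap (1-based inclusive internally).
oracle_overlaps <- function(s1, e1, s2, e2) {
  any(s1 <= e2 & s2 <= e1)
}

oracle_filter_sites <- function(sites, control, exon_df, gene_df, max_mb) {
  keep <- logical(nrow(sites))
  ann <- character(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    s <- sites$start[i] + 1; e <- sites$end[i]
    in_ctrl <- FALSE
    if (!is.null(control)) for (j in seq_len(nrow(control))) {
      if (sites$chrom[i] == control$chrom[j] &&
          oracle_overlaps(s, e, control$start[j] + 1, control$end[j]))
        in_ctrl <- TRUE
    }
    keep[i] <- !in_ctrl && (sites$mismatches[i] + sites$bulges[i]) < max_mb
    a <- "intergenic"
    for (j in seq_len(nrow(gene_df))) {
      if (sites$chrom[i] == gene_df$chrom[j] &&
          oracle_overlaps(s, e, gene_df$start[j], gene_df$end[j]))
        a <- "intronic"
    }
    for (j in seq_len(nrow(exon_df))) {
      if (sites$chrom[i] == exon_df$chrom[j] &&
          oracle_overlaps(s, e, exon_df$start[j], exon_df$end[j]))
        a <- "exonic"
    }
    ann[i] <- a
  }
  out <- sites[keep, , drop = FALSE]
  out$annotation <- ann[keep]
  rownames(out) <- NULL
  out
}

# Brute-force top-coverage percentile selection with ties included.
oracle_top_sites <- function(pileup, top_fraction = 0.05) {
  a <- pileup[pileup$ref == "A" & pileup$coverage > 0, , drop = FALSE]
  cv <- sort(a$coverage)
  k <- ceiling(length(cv) * (1 - top_fraction))
  thr <- cv[k]
  a[a$coverage >= thr, , drop = FALSE]
}

granges_from_df <- function(df) {
  GenomicRanges::GRanges(df$chrom,
                         IRanges::IRanges(start = df$start, end = df$end))
}
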