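#' Screen analysis configuration
#'
#' Thresholds for sorted-fraction enrichment analysis. Defaults follow the
#' published pipelines: variant abundance filter > 0.001 (combinatorial
#' screen), detection floor 0.0001, single-positive substitution abundance
#' > 0.0015 and log fold change > 0.5 (degenerate screen). Fold changes
#' are log10 with an additive pseudocount of 0.5 reads; both are exposed
#' here because the published analyses state neither the base nor the
#' zero-count handling.
#'
#' @param min_variant_frequency Variant-level abundance filter (strict >).
#' @param detection_floor Minimum frequency for a variant to count as
#'   detected at all (strict >).
#' @param min_sp_abundance Substitution-level abundance floor in the
#'   single-positive fraction (strict >).
#' @param logfc_threshold Enrichment call threshold (strict >).
#' @param log_base Base for fold changes: 10, 2 or `exp(1)`.
#' @param pseudocount Additive reads added to each substitution tally.
#' @return A `screen_config` list.
#' @export
screen_config <- function(min_variant_frequency = 0.001,
                          detection_floor = 0.0001,
                          min_sp_abundance = 0.0015,
                          logfc_threshold = 0.5,
                          log_base = 10,
                          pseudocount = 0.5) {
  stopifnot(min_variant_frequency >= 0, min_variant_frequency <= 1,
            min_sp_abundance >= 0, min_sp_abundance <= 1,
            pseudocount >= 0, log_base > 0, log_base != 1)
  structure(list(min_variant_frequency = min_variant_frequency,
                 detection_floor = detection_floor,
                 min_sp_abundance = min_sp_abundance,
                 logfc_threshold = logfc_threshold,
                 log_base = log_base,
                 pseudocount = pseudocount), class = "screen_config")
}

#' Count protein variants in a sorted fraction's reads
#'
#' Translates merged reads into protein variants and aggregates reads
#' encoding the same protein. A read must carry the exact 5' anchor
#' (`flank5`) and, after it, the exact 3' anchor (`flank3`); otherwise it
#' is discarded as unanchored. A between-anchor segment whose length
#' differs from the reference ORF (equivalently, is not the expected
#' multiple of 3) is discarded as an indel read -- for fixed-length
#' designs this alignment-free length criterion is exact. Remaining
#' segments are translated with the standard genetic code and aggregated
#' by protein sequence.
#'
#' @param reads Character vector, `DNAStringSet`, or path to a
#'   FASTA/FASTQ file of merged, oriented reads.
#' @param spec The `library_spec` the reads derive from.
#' @param fraction Label for the sorted fraction (e.g. `"single_positive"`).
#' @param anchor_mismatch Allowed Hamming mismatches in each anchor
#'   (default 0, exact matching; 1 tolerates a single sequencing error in
#'   an anchor at the cost of reproducibility against exact pipelines).
#' @return A `variant_counts` object: named integer vector of read counts
#'   per protein sequence, plus discard tallies.
#' @export
process_reads <- function(reads, spec, fraction = "unlabelled",
                          anchor_mismatch = 0L) {
  stopifnot(inherits(spec, "library_spec"))
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  }
  s <- toupper(as.character(reads))
  n_in <- length(s)
  if (n_in == 0L) {
    return(new_variant_counts(integer(0), spec, fraction, 0L, 0L))
  }
  f5 <- spec$flank5; f3 <- spec$flank3
  n5 <- nchar(f5); n3 <- nchar(f3)
  if (anchor_mismatch == 0L) {
    pos5 <- ifelse(startsWith(s, f5), 1L,
                   regexpr(f5, s, fixed = TRUE))
  } else {
    # tolerant prefix match only (anchor expected at read start)
    pref <- substr(s, 1L, n5)
    mm <- hamming_dist(pref, f5)
    pos5 <- ifelse(mm <= anchor_mismatch, 1L, regexpr(f5, s, fixed = TRUE))
  }
  anchored5 <- pos5 > 0L
  seg_start <- pos5 + n5
  # first 3' anchor occurrence after the 5' anchor
  rest <- substr(s, seg_start, nchar(s))
  pos3 <- regexpr(f3, rest, fixed = TRUE)
  anchored <- anchored5 & pos3 > 0L
  discarded_unanchored <- sum(!anchored)
  seg <- substr(rest[anchored], 1L, pos3[anchored] - 1L)
  expected <- nchar(spec$reference_orf)
  ok <- nchar(seg) == expected
  discarded_indel <- sum(!ok)
  seg <- seg[ok]
  counts <- integer(0)
  if (length(seg) > 0) {
    prot <- translate_dna(seg)
    tab <- table(prot)
    counts <- stats::setNames(as.integer(tab), names(tab))
  }
  new_variant_counts(counts, spec, fraction,
                     as.integer(discarded_indel),
                     as.integer(discarded_unanchored))
}

hamming_dist <- function(x, ref) {
  L <- nchar(ref)
  d <- integer(length(x))
  for (i in seq_len(L)) {
    d <- d + (substr(x, i, i) != substr(ref, i, i))
  }
  d
}

new_variant_counts <- function(counts, spec, fraction,
                               discarded_indel, discarded_unanchored,
                               prefilter_total = NULL) {
  structure(list(
    fraction = fraction,
    counts = counts,
    discarded_indel_reads = discarded_indel,
    discarded_unanchored_reads = discarded_unanchored,
    total_reads = sum(counts) + discarded_indel + discarded_unanchored,
    prefilter_total = prefilter_total %||% sum(counts),
    spec = spec
  ), class = "variant_counts")
}

#' @export
print.variant_counts <- function(x, ...) {
  cat(sprintf(
    "variant_counts [%s]: %d variants, %d aggregated reads (%d indel, %d unanchored discarded)\n",
    x$fraction, length(x$counts), sum(x$counts),
    x$discarded_indel_reads, x$discarded_unanchored_reads))
  invisible(x)
}

#' Variant frequencies
#'
#' Frequencies relative to the pre-filter aggregated read total, so
#' abundances are comparable before and after [filter_by_abundance()].
#'
#' @param counts A `variant_counts` object.
#' @return Named numeric vector.
#' @export
variant_frequencies <- function(counts) {
  if (counts$prefilter_total == 0) return(stats::setNames(numeric(0), NULL))
  counts$counts / counts$prefilter_total
}

#' Filter variants by minimum abundance
#'
#' Keeps a variant iff its frequency is strictly greater than
#' `min_frequency` in every supplied fraction (matching the published
#' strict ">" filters). Frequencies are not recomputed after filtering:
#' abundances stay relative to the pre-filter aggregate.
#'
#' @param counts A `variant_counts` object or a list of them (one per
#'   fraction; the filter then requires the threshold in all of them and
#'   returns a list).
#' @param min_frequency Strict lower bound on frequency.
#' @return Filtered `variant_counts` (or list thereof).
#' @export
filter_by_abundance <- function(counts, min_frequency) {
  single <- inherits(counts, "variant_counts")
  lst <- if (single) list(counts) else counts
  keep_sets <- lapply(lst, function(vc) {
    fr <- variant_frequencies(vc)
    names(fr)[fr > min_frequency]
  })
  keep <- Reduce(intersect, keep_sets)
  out <- lapply(lst, function(vc) {
    vc$counts <- vc$counts[names(vc$counts) %in% keep]
    vc
  })
  if (single) out[[1]] else out
}

#' Positional amino-acid frequency matrix
#'
#' Read-weighted relative frequency of each amino acid at each protein
#' position within a sorted fraction -- the matrix behind the sequence
#' logos. Variants containing a premature stop are excluded from the
#' tally (they cannot be surface-stained and sorted; any observed are
#' read errors). Rows sum to 1 over the observed residues.
#'
#' @param counts A `variant_counts` object.
#' @param positions Published-numbering positions to tabulate (default:
#'   the spec's variable positions).
#' @return Numeric matrix, positions x amino acids.
#' @export
positional_aa_frequency <- function(counts, positions = NULL) {
  spec <- counts$spec
  off <- spec$numbering_offset
  if (is.null(positions)) positions <- spec$variable_positions + off
  local <- as.integer(positions) - off
  plen <- nchar(spec$reference_protein)
  if (any(local < 1L | local > plen))
    stop("position outside the reference protein")
  prots <- names(counts$counts)
  w <- as.numeric(counts$counts)
  keep <- !grepl("*", prots, fixed = TRUE)
  prots <- prots[keep]; w <- w[keep]
  if (length(prots) == 0L) stop("no stop-free variants to tabulate")
  res <- lapply(local, function(p) substr(prots, p, p))
  aas <- sort(unique(unlist(res)))
  m <- matrix(0, nrow = length(local), ncol = length(aas),
              dimnames = list(as.character(positions), aas))
  for (i in seq_along(local)) {
    tal <- tapply(w, res[[i]], sum)
    m[i, names(tal)] <- tal / sum(w)
  }
  m
}

#' Single- vs double-positive substitution enrichment
#'
#' For every single amino-acid substitution observed in either fraction,
#' aggregates the reads of all (stop-free) variants carrying it, computes
#' pseudocounted abundances in the single-positive (therapeutic-binding
#' lost) and double-positive (binding retained) fractions, and the log
#' fold change between them. A substitution passes the filter iff
#' `logfc > logfc_threshold` and its single-positive abundance exceeds
#' `min_sp_abundance` (both strict).
#'
#' Abundance is `(reads + pseudocount) / (fraction total + pseudocount *
#' n_substitutions)`, making the log fold change finite and antisymmetric
#' under fraction swap.
#'
#' @param sp,dp `variant_counts` for the single- and double-positive
#'   fractions (same spec).
#' @param config A [screen_config()].
#' @return An `enrichment_table` data.frame: position, ref_aa, alt_aa,
#'   substitution, reads_sp, reads_dp, abundance_sp, abundance_dp, logfc,
#'   passes_filter.
#' @export
substitution_logfc <- function(sp, dp, config = screen_config()) {
  spec <- sp$spec
  tal_sp <- .substitution_reads(sp)
  tal_dp <- .substitution_reads(dp)
  if (attr(tal_sp, "total") == 0 || attr(tal_dp, "total") == 0)
    stop("a fraction has zero aggregate (stop-free) reads")
  subs <- sort(union(names(tal_sp), names(tal_dp)))
  if (length(subs) == 0L)
    return(.empty_enrichment())
  r_sp <- ifelse(subs %in% names(tal_sp), tal_sp[subs], 0)
  r_dp <- ifelse(subs %in% names(tal_dp), tal_dp[subs], 0)
  pc <- config$pseudocount
  ab_sp <- (r_sp + pc) / (attr(tal_sp, "total") + pc * length(subs))
  ab_dp <- (r_dp + pc) / (attr(tal_dp, "total") + pc * length(subs))
  logfc <- log(ab_sp / ab_dp, base = config$log_base)
  m <- regmatches(subs, regexec("^([A-Z])([0-9]+)([A-Z*])$", subs))
  pos <- vapply(m, function(g) as.integer(g[3]), integer(1))
  out <- data.frame(
    position = pos,
    ref_aa = vapply(m, `[`, character(1), 2),
    alt_aa = vapply(m, `[`, character(1), 4),
    substitution = subs,
    reads_sp = as.numeric(r_sp), reads_dp = as.numeric(r_dp),
    abundance_sp = ab_sp, abundance_dp = ab_dp,
    logfc = logfc,
    passes_filter = logfc > config$logfc_threshold &
      ab_sp > config$min_sp_abundance,
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("enrichment_table", "data.frame")
  out
}

.empty_enrichment <- function() {
  out <- data.frame(position = integer(0), ref_aa = character(0),
                    alt_aa = character(0), substitution = character(0),
                    reads_sp = numeric(0), reads_dp = numeric(0),
                    abundance_sp = numeric(0), abundance_dp = numeric(0),
                    logfc = numeric(0), passes_filter = logical(0))
  class(out) <- c("enrichment_table", "data.frame")
  out
}

# Per-substitution read tallies across multi-substitution variants,
# excluding stop-containing variants from counts and denominator.
.substitution_reads <- function(vc) {
  spec <- vc$spec
  prots <- names(vc$counts)
  w <- as.numeric(vc$counts)
  keep <- !grepl("*", prots, fixed = TRUE)
  prots <- prots[keep]; w <- w[keep]
  total <- sum(w)
  ref <- strsplit(spec$reference_protein, "")[[1]]
  tal <- new.env(parent = emptyenv())
  if (length(prots) > 0) {
    pm <- matrix(unlist(strsplit(prots, ""), use.names = FALSE),
                 ncol = length(ref), byrow = TRUE)
    for (j in seq_len(ncol(pm))) {
      diff <- which(pm[, j] != ref[j])
      if (length(diff) == 0L) next
      lab <- paste0(ref[j], j + spec$numbering_offset, pm[diff, j])
      agg <- tapply(w[diff], lab, sum)
      for (k in seq_along(agg)) {
        nm <- names(agg)[k]
        tal[[nm]] <- (tal[[nm]] %||% 0) + agg[[k]]
      }
    }
  }
  out <- unlist(as.list(tal))
  if (is.null(out)) out <- stats::setNames(numeric(0), character(0))
  attr(out, "total") <- total
  out
}

#' Rank epitope candidates
#'
#' Substitutions passing the enrichment filters, ordered by log fold
#' change descending; ties broken by single-positive abundance descending,
#' then position ascending.
#'
#' @param table An `enrichment_table` from [substitution_logfc()].
#' @return The passing rows, reordered.
#' @export
rank_epitope_candidates <- function(table) {
  stopifnot(nrow(table) >= 0)
  hits <- table[table$passes_filter, , drop = FALSE]
  hits[order(-hits$logfc, -hits$abundance_sp, hits$position), ,
       drop = FALSE]
}

#' End-to-end screen analysis
#'
#' Runs the full sorted-fraction analysis: read processing per fraction,
#' a per-fraction detection floor (variants must exceed
#' `config$detection_floor` within their own sample -- this is what
#' removes single-read sequencing-error artifacts in a clonally
#' bottlenecked library), substitution-level enrichment, and candidate
#' ranking.
#'
#' @param sp_reads,dp_reads Reads for the single- and double-positive
#'   fractions (anything [process_reads()] accepts).
#' @param spec The `library_spec`.
#' @param config A [screen_config()].
#' @return list: `sp`, `dp` (filtered `variant_counts`), `enrichment`
#'   (full table), `candidates` (ranked passing substitutions).
#' @export
analyze_screen <- function(sp_reads, dp_reads, spec,
                           config = screen_config()) {
  sp <- process_reads(sp_reads, spec, "single_positive")
  dp <- process_reads(dp_reads, spec, "double_positive")
  sp_f <- filter_by_abundance(sp, config$detection_floor)
  dp_f <- filter_by_abundance(dp, config$detection_floor)
  et <- substitution_logfc(sp_f, dp_f, config)
  list(sp = sp_f, dp = dp_f, enrichment = et,
       candidates = rank_epitope_candidates(et))
}
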