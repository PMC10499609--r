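#' Allele table constructor
#'
#' An amplicon-sequencing allele table in the style of standard amplicon
#' quantification pipelines: one row per distinct aligned allele with its
#' read support and indel annotations. Aligned sequences are in sense
#' (reference) coordinates; deleted bases are encoded as `-` so non-indel
#' alleles have the reference length.
#'
#' @param alleles data.frame with columns `Aligned_Sequence`, `Reads`,
#'   `n_inserted`, `n_deleted`, `n_mutated` (extra columns kept).
#' @param reference Amplicon reference sequence.
#' @param window Integer `c(start, end)`, 1-based inclusive quantification
#'   window on sense coordinates (the amplicon interval overlapping the
#'   sgRNA).
#' @return An `allele_table` object.
#' @export
allele_table <- function(alleles, reference, window) {
  reference <- toupper(reference)
  need <- c("Aligned_Sequence", "Reads", "n_inserted", "n_deleted")
  if (!all(need %in% names(alleles)))
    stop("allele table needs columns: ", paste(need, collapse = ", "))
  if (any(alleles$Reads < 0)) stop("read counts must be >= 0")
  window <- as.integer(window)
  stopifnot(length(window) == 2L, window[1] >= 1L,
            window[2] <= nchar(reference), window[1] <= window[2])
  alleles$Aligned_Sequence <- toupper(alleles$Aligned_Sequence)
  structure(list(alleles = alleles, reference = reference, window = window),
            class = "allele_table")
}

#' Read an allele table from TSV
#'
#' @param path TSV file with the columns of [allele_table()].
#' @param reference,window As in [allele_table()].
#' @return An `allele_table`.
#' @export
read_allele_table <- function(path, reference, window) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  allele_table(df, reference, window)
}

#' Quantify base-editing outcomes in an amplicon
#'
#' Computes per-position conversion rates inside the quantification
#' window, the edited-read proportion, and the indel proportion.
#'
#' A read is an indel read iff `n_inserted > 0` or `n_deleted > 0`; indel
#' reads are excluded from per-position conversion denominators (their
#' coordinates are shifted) but counted in the totals used for
#' proportions. Among non-indel reads, a position's conversion rate is
#' the fraction of reads carrying the substrate-to-product substitution
#' there, and a read is edited iff it carries at least one in-window
#' conversion. For guides on the antisense strand the conversion class is
#' complemented before scanning sense-coordinate alleles.
#'
#' Because whether the published indel proportion is taken over all reads
#' or over edited reads is ambiguous, both `indel_of_total` and
#' `indel_of_edited` are reported.
#'
#' @param table An [allele_table()].
#' @param conversion `"AG"` or `"CT"` (protospacer-strand chemistry).
#' @param guide_strand `"+"` or `"-"`: strand of the protospacer relative
#'   to the sense reference.
#' @param conf_level Confidence level for Wilson intervals.
#' @return An `amplicon_quant` object: `per_position` data.frame
#'   (position, ref_base, converted_reads, nonindel_reads, rate, ci_lo,
#'   ci_hi), counts (`edited_reads`, `unedited_reads`, `indel_reads`,
#'   `total_reads`) and proportions with Wilson CIs.
#' @export
quantify_amplicon <- function(table, conversion = c("AG", "CT"),
                              guide_strand = "+", conf_level = 0.95) {
  conversion <- match.arg(conversion)
  al <- table$alleles
  total <- sum(al$Reads)
  if (total == 0) stop("zero total reads")
  cb <- .conv_bases(conversion, guide_strand)
  is_indel <- al$n_inserted > 0 | al$n_deleted > 0
  ni <- al[!is_indel, , drop = FALSE]
  if (any(nchar(ni$Aligned_Sequence) != nchar(table$reference)))
    stop("non-indel alleles must have reference length")
  w <- table$window
  pos <- w[1]:w[2]
  ref_bases <- strsplit(substr(table$reference, w[1], w[2]), "")[[1]]
  n_nonindel <- sum(ni$Reads)
  conv_reads <- integer(length(pos))
  edited_flag <- rep(FALSE, nrow(ni))
  for (i in seq_along(pos)) {
    if (ref_bases[i] != cb["sub"]) { conv_reads[i] <- NA_integer_; next }
    hit <- substr(ni$Aligned_Sequence, pos[i], pos[i]) == cb[["prod"]]
    conv_reads[i] <- sum(ni$Reads[hit])
    edited_flag <- edited_flag | hit
  }
  edited <- sum(ni$Reads[edited_flag])
  unedited <- n_nonindel - edited
  indel <- sum(al$Reads[is_indel])
  rate <- ifelse(is.na(conv_reads), NA_real_,
                 if (n_nonindel > 0) conv_reads / n_nonindel else NA_real_)
  cis <- t(vapply(seq_along(pos), function(i) {
    if (is.na(conv_reads[i]) || n_nonindel == 0) return(c(NA_real_, NA_real_))
    wilson_ci(conv_reads[i], n_nonindel, conf_level)
  }, numeric(2)))
  per_position <- data.frame(
    position = pos, ref_base = ref_bases,
    converted_reads = conv_reads, nonindel_reads = n_nonindel,
    rate = rate, ci_lo = cis[, 1], ci_hi = cis[, 2],
    stringsAsFactors = FALSE)
  prop <- function(x, n) {
    ci <- wilson_ci(x, n, conf_level)
    c(estimate = if (n > 0) x / n else NA_real_, lo = ci[1], hi = ci[2])
  }
  structure(list(
    per_position = per_position,
    edited_reads = edited, unedited_reads = unedited,
    indel_reads = indel, total_reads = total,
    edited_proportion = prop(edited, total),
    indel_of_total = prop(indel, total),
    indel_of_edited = prop(indel, edited + indel),
    conversion = conversion, guide_strand = guide_strand
  ), class = "amplicon_quant")
}

#' @export
print.amplicon_quant <- function(x, ...) {
  cat(sprintf(
    "amplicon_quant: %d reads (%d edited, %d unedited, %d indel); edited %.3f, indel(total) %.4f\n",
    x$total_reads, x$edited_reads, x$unedited_reads, x$indel_reads,
    x$edited_proportion["estimate"], x$indel_of_total["estimate"]))
  invisible(x)
}

#' Long-format per-position editing table across samples
#'
#' Binds the per-position conversion rates of several quantification
#' results into one tidy table for editing-window plots, preserving
#' sample labels and performing no aggregation across positions.
#'
#' @param results Named list of `amplicon_quant` objects (names = sample
#'   labels), or a single object.
#' @param spacer_start Optional 1-based sense coordinate of spacer
#'   position 1; when given, a `spacer_position` column is added.
#' @return data.frame (sample, position, [spacer_position,] ref_base,
#'   rate); substrate positions only.
#' @export
summarize_window <- function(results, spacer_start = NULL) {
  if (inherits(results, "amplicon_quant")) results <- list(sample1 = results)
  if (length(results) == 0L) stop("need >= 1 result")
  if (is.null(names(results)))
    names(results) <- paste0("sample", seq_along(results))
  rows <- lapply(names(results), function(nm) {
    pp <- results[[nm]]$per_position
    pp <- pp[!is.na(pp$rate), , drop = FALSE]
    out <- data.frame(sample = nm, position = pp$position,
                      ref_base = pp$ref_base, rate = pp$rate,
                      stringsAsFactors = FALSE)
    if (!is.null(spacer_start))
      out$spacer_position <- out$position - spacer_start + 1L
    out
  })
  do.call(rbind, rows)
}
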