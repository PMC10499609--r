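#' Mutagenesis library specification
#'
#' Defines an epitope mutagenesis library over an in-frame reference ORF:
#' either a combinatorial library (each variable position carries the
#' reference codon or exactly one alternative, e.g. a human/mouse codon
#' swap) or a degenerate scan (all 64 codons at each scanned position).
#'
#' @param reference_orf In-frame DNA sequence (length divisible by 3).
#' @param variable_positions 1-based protein positions (construct-local)
#'   that vary in the library.
#' @param allowed_codons Named list mapping each variable position
#'   (as character) to its allowed DNA codons. In combinatorial mode each
#'   set must contain the reference codon plus at least one alternative.
#' @param flank5,flank3 DNA anchor sequences added around the ORF in
#'   emitted inserts; used downstream to locate and frame reads.
#' @param mode `"combinatorial"` or `"degenerate_scan"`.
#' @param numbering_offset Offset mapping construct-local protein
#'   coordinates to the published residue numbering
#'   (published = local + offset). Default 0.
#'
#' @return An object of class `library_spec`.
#' @export
library_spec <- function(reference_orf, variable_positions, allowed_codons,
                         flank5, flank3,
                         mode = c("combinatorial", "degenerate_scan"),
                         numbering_offset = 0L) {
  mode <- match.arg(mode)
  reference_orf <- toupper(reference_orf)
  if (nchar(reference_orf) %% 3L != 0L)
    stop("reference_orf length must be divisible by 3")
  protein <- translate_dna(reference_orf)
  plen <- nchar(protein)
  variable_positions <- as.integer(variable_positions)
  if (any(variable_positions < 1L | variable_positions > plen))
    stop("variable position outside the reference protein")
  if (!all(as.character(variable_positions) %in% names(allowed_codons)))
    stop("allowed_codons must cover every variable position")
  allowed_codons <- allowed_codons[as.character(variable_positions)]
  ref_codons <- if (length(variable_positions) == 0L) character(0) else
    substring(reference_orf,
              3L * (variable_positions - 1L) + 1L,
              3L * variable_positions)
  for (i in seq_along(variable_positions)) {
    cods <- toupper(allowed_codons[[i]])
    if (length(cods) == 0L || any(nchar(cods) != 3L) ||
        any(grepl("[^ACGT]", cods)))
      stop("allowed codons must be non-empty 3-mers over A/C/G/T")
    if (mode == "combinatorial" &&
        (length(cods) < 2L || !(ref_codons[i] %in% cods)))
      stop("combinatorial mode needs the reference codon plus >= 1 alternative")
    allowed_codons[[i]] <- sort(unique(cods))
  }
  structure(list(
    reference_orf = reference_orf,
    reference_protein = protein,
    variable_positions = variable_positions,
    allowed_codons = allowed_codons,
    reference_codons = stats::setNames(ref_codons,
                                       as.character(variable_positions)),
    flank5 = toupper(flank5), flank3 = toupper(flank3),
    mode = mode,
    numbering_offset = as.integer(numbering_offset)
  ), class = "library_spec")
}

#' @export
print.library_spec <- function(x, ...) {
  cat(sprintf("library_spec (%s): %d-aa ORF, %d variable position(s), complexity %s\n",
              x$mode, nchar(x$reference_protein), length(x$variable_positions),
              format(theoretical_complexity(x), big.mark = ",")))
  invisible(x)
}

# A widely used human codon per amino acid, for building synthetic ORFs.
.aa_codon <- c(A = "GCC", R = "CGG", N = "AAC", D = "GAC", C = "TGC",
               Q = "CAG", E = "GAG", G = "GGC", H = "CAC", I = "ATC",
               L = "CTG", K = "AAG", M = "ATG", F = "TTC", P = "CCC",
               S = "TCC", T = "ACC", W = "TGG", Y = "TAC", V = "GTG")

.filler_aas <- c("G", "S", "T", "V", "L", "P", "A", "E")

# Build a synthetic in-frame ORF with given residues pinned at given
# published positions and deterministic filler elsewhere.
.synthetic_orf <- function(from, to, pinned) {
  pos <- from:to
  aas <- .filler_aas[(pos %% length(.filler_aas)) + 1L]
  names(aas) <- as.character(pos)
  aas[names(pinned)] <- pinned
  paste0(.aa_codon[aas], collapse = "")
}

# Published FLT3 ECD4 variable residues (human identity at each) and the
# murine alternative used by the two-codon swap library. The position list
# and the Asp alternative at 399 follow the published design; the other
# murine residues are synthetic stand-ins since only the positions, not
# the orthologue sequences, are printed.
.flt3_positions <- c(
  "354" = "N", "356" = "S", "358" = "D", "363" = "Q", "366" = "E",
  "378" = "Q", "384" = "T", "387" = "R", "388" = "K", "395" = "K",
  "398" = "D", "399" = "N", "408" = "N", "411" = "H", "412" = "Q",
  "419" = "H")
.flt3_mouse <- c(
  "354" = "K", "356" = "P", "358" = "E", "363" = "H", "366" = "D",
  "378" = "R", "384" = "A", "387" = "Q", "388" = "R", "395" = "E",
  "398" = "E", "399" = "D", "408" = "S", "411" = "Y", "412" = "R",
  "419" = "Q")

#' Built-in FLT3 ECD4 combinatorial library specification
#'
#' Sixteen-position human/mouse codon-swap library over FLT3 extracellular
#' domain 4 (residues 354-419): each variable position carries either the
#' human reference codon or one murine alternative, for a theoretical
#' complexity of 2^16 = 65,536 codon assignments. The ORF is a synthetic
#' stand-in carrying the published human residues at the published
#' positions; the murine residue at 399 is Asp (the N399D route), the
#' remaining murine residues are representative placeholders.
#'
#' @return A `library_spec` in combinatorial mode with numbering offset 353.
#' @export
flt3_library_spec <- function() {
  from <- 354L; to <- 419L
  orf <- .synthetic_orf(from, to, .flt3_positions)
  local_pos <- as.integer(names(.flt3_positions)) - (from - 1L)
  allowed <- stats::setNames(vector("list", length(local_pos)),
                             as.character(local_pos))
  for (i in seq_along(local_pos)) {
    allowed[[i]] <- c(unname(.aa_codon[.flt3_positions[i]]),
                      unname(.aa_codon[.flt3_mouse[i]]))
  }
  library_spec(orf, local_pos, allowed,
               flank5 = "ACGTCTGAACTCCAGTCACG",
               flank3 = "GATCGGAAGAGCACACGTCT",
               mode = "combinatorial",
               numbering_offset = from - 1L)
}

#' FLT3 full mouse-swap variant
#'
#' The construct carrying the murine alternative codon at all 16 variable
#' positions of [flt3_library_spec()] (the ECD4 orthologue swap used to
#' confirm loss of therapeutic-antibody binding).
#'
#' @return A `variant_set` with one variant.
#' @export
flt3_mouse_swap_variant <- function() {
  spec <- flt3_library_spec()
  # per-position: alternative = the non-reference member of each pair
  codons <- vapply(seq_along(spec$allowed_codons), function(i) {
    setdiff(spec$allowed_codons[[i]], spec$reference_codons[i])[1]
  }, character(1))
  variant_set(spec, matrix(codons, nrow = 1,
                           dimnames = list(NULL, names(spec$allowed_codons))))
}

# Published KIT ECD4 residues pinned in the synthetic ORF: the ten
# contact-point positions of the multi-mutant plus Asp332/Asp357 named by
# the degenerate screen.
.kit_pinned <- c(
  "316" = "F", "318" = "M", "319" = "I", "323" = "V", "332" = "D",
  "334" = "I", "357" = "D", "360" = "E", "363" = "P", "366" = "E",
  "376" = "E", "378" = "H")
.kit_multimutant_subs <- c(
  "316" = "S", "318" = "V", "319" = "K", "323" = "I", "334" = "V",
  "360" = "K", "363" = "V", "366" = "D", "376" = "Q", "378" = "R")

#' Built-in KIT ECD4 degenerate-scan library specification
#'
#' Single-position NNN scan across KIT extracellular domain 4 (residues
#' 314-381): every scanned position admits all 64 codons. The ORF is a
#' synthetic stand-in carrying the published residue identities at the
#' positions named by the screen and the multi-mutant.
#'
#' @return A `library_spec` in degenerate-scan mode with numbering
#'   offset 313.
#' @export
kit_library_spec <- function() {
  from <- 314L; to <- 381L
  orf <- .synthetic_orf(from, to, .kit_pinned)
  local_pos <- seq_len(to - from + 1L)
  all64 <- sort(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                  c("A","C","G","T"),
                                  stringsAsFactors = FALSE),
                      1, function(r) paste0(r[3], r[2], r[1])))
  allowed <- stats::setNames(rep(list(all64), length(local_pos)),
                             as.character(local_pos))
  library_spec(orf, local_pos, allowed,
               flank5 = "TGCACTGACGACATCGATCG",
               flank3 = "CGTACGATCGATGTCAGTCA",
               mode = "degenerate_scan",
               numbering_offset = from - 1L)
}

#' KIT ten-substitution multi-mutant variant
#'
#' The validated orthologue multi-mutant carrying F316S, M318V, I319K,
#' V323I, I334V, E360K, P363V, E366D, E376Q and H378R on the KIT ECD4
#' construct of [kit_library_spec()].
#'
#' @return A `variant_set` with one variant.
#' @export
kit_multimutant_variant <- function() {
  spec <- kit_library_spec()
  codons <- spec$reference_codons
  local <- as.integer(names(.kit_multimutant_subs)) - spec$numbering_offset
  codons[as.character(local)] <- unname(.aa_codon[.kit_multimutant_subs])
  variant_set(spec, matrix(unname(codons), nrow = 1,
                           dimnames = list(NULL, names(spec$allowed_codons))))
}

#' Variant set container
#'
#' A set of codon assignments over a library's variable positions, stored
#' as a character matrix (rows = variants, columns = variable positions).
#'
#' @param spec The parent `library_spec`.
#' @param codons Character matrix of codons, one column per variable
#'   position (columns named by local position).
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(spec, codons) {
  stopifnot(inherits(spec, "library_spec"))
  codons <- as.matrix(codons)
  if (is.null(colnames(codons)))
    colnames(codons) <- as.character(spec$variable_positions)
  if (!identical(colnames(codons), as.character(spec$variable_positions)))
    stop("codon matrix columns must match the spec's variable positions")
  for (j in seq_len(ncol(codons))) {
    bad <- !(codons[, j] %in% spec$allowed_codons[[j]])
    if (any(bad)) stop("codon not allowed at position ", colnames(codons)[j])
  }
  structure(list(spec = spec, codons = codons), class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("variant_set: %d variant(s) over %d position(s)\n",
              nrow(x$codons), ncol(x$codons)))
  invisible(x)
}

#' @export
length.variant_set <- function(x) nrow(x$codons)

#' Theoretical library complexity
#'
#' Number of distinct codon assignments the library can produce: the
#' product over variable positions of the allowed-codon set sizes (1 for
#' an empty variable set).
#'
#' @param spec A `library_spec`.
#' @return A numeric count (may exceed integer range for degenerate scans).
#' @export
theoretical_complexity <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  prod(vapply(spec$allowed_codons, length, integer(1)))
}

#' Enumerate all library variants
#'
#' Materializes every codon assignment exactly once, in deterministic
#' lexicographic order (first variable position most significant, codons
#' alphabetical), so outputs are stable across runs.
#'
#' @param spec A `library_spec`.
#' @param limit Refuse to enumerate more than this many variants; callers
#'   hitting the limit should sample instead.
#' @return A `variant_set`.
#' @export
enumerate_variants <- function(spec, limit = 70000) {
  n <- theoretical_complexity(spec)
  if (n > limit)
    stop("theoretical complexity (", n, ") exceeds limit (", limit,
         "); use sample_variants()")
  cods <- lapply(spec$allowed_codons, sort)
  grid <- expand.grid(rev(cods), stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[, rev(seq_along(cods)), drop = FALSE]
  m <- as.matrix(grid)
  dimnames(m) <- list(NULL, names(spec$allowed_codons))
  variant_set(spec, m)
}

#' Sample library variants uniformly
#'
#' Draws codons independently and uniformly from each position's allowed
#' set; reproducible for a fixed seed.
#'
#' @param spec A `library_spec`.
#' @param n Number of variants to draw (>= 1).
#' @param seed Integer seed.
#' @return A `variant_set` of `n` variants.
#' @export
sample_variants <- function(spec, n, seed) {
  stopifnot(inherits(spec, "library_spec"))
  n <- as.integer(n)
  if (is.na(n) || n < 1L) stop("n must be >= 1")
  m <- with_seed(seed, {
    vapply(spec$allowed_codons, function(cods)
      cods[sample.int(length(cods), n, replace = TRUE)], character(n))
  })
  if (n == 1L) m <- matrix(m, nrow = 1)
  dimnames(m) <- list(NULL, names(spec$allowed_codons))
  variant_set(spec, m)
}

#' Amino-acid substitutions carried by each variant
#'
#' Translates each variant's codon assignment and reports non-reference
#' residues in published numbering, e.g. `"N399D"`; premature stops are
#' reported with `*`. The reference assignment yields an empty string.
#'
#' @param variants A `variant_set`.
#' @return Character vector, one `";"`-joined substitution string per
#'   variant.
#' @export
variant_substitutions <- function(variants) {
  spec <- variants$spec
  gc <- .codon_table()
  ref_aa <- strsplit(spec$reference_protein, "")[[1]]
  vapply(seq_len(nrow(variants$codons)), function(i) {
    aas <- gc[variants$codons[i, ]]
    pos <- spec$variable_positions
    diff <- which(aas != ref_aa[pos])
    if (length(diff) == 0L) return("")
    paste0(ref_aa[pos[diff]], pos[diff] + spec$numbering_offset, aas[diff],
           collapse = ";")
  }, character(1))
}

#' Emit DNA inserts for a variant set
#'
#' Builds `flank5 + mutagenized ORF + flank3` for every variant. Record
#' ids encode the substitution set (`"ref"` for the reference assignment),
#' so inserts round-trip through [process_reads()].
#'
#' @param variants A `variant_set`.
#' @param as_string If `TRUE` return a named character vector instead of a
#'   `DNAStringSet`.
#' @return A named `Biostrings::DNAStringSet` (or character vector).
#' @export
emit_inserts <- function(variants, as_string = FALSE) {
  spec <- variants$spec
  orfs <- mutate_orf(spec, variants$codons)
  seqs <- paste0(spec$flank5, orfs, spec$flank3)
  subs <- variant_substitutions(variants)
  ids <- sprintf("var%05d|%s", seq_along(seqs),
                 ifelse(subs == "", "ref", gsub(";", "+", subs)))
  names(seqs) <- ids
  if (as_string) return(seqs)
  Biostrings::DNAStringSet(seqs)
}

# Substitute codons into the reference ORF at the spec's variable
# positions; `codons` is a matrix with one column per variable position.
mutate_orf <- function(spec, codons) {
  orfs <- rep(spec$reference_orf, nrow(codons))
  for (j in seq_along(spec$variable_positions)) {
    p <- spec$variable_positions[j]
    substr(orfs, 3L * (p - 1L) + 1L, 3L * p) <- codons[, j]
  }
  orfs
}

#' Flag variants encoding a premature stop
#'
#' Degenerate scans produce stop codons; they are retained in enumeration
#' but flagged here, and excluded from enrichment denominators downstream
#' (a truncated receptor cannot be surface-stained and sorted).
#'
#' @param variants A `variant_set`.
#' @return Logical vector.
#' @export
has_stop <- function(variants) {
  gc <- .codon_table()
  apply(variants$codons, 1, function(r) any(gc[r] == "*"))
}
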