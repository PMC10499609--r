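#' Base-editor specification
#'
#' Describes a base editor by its conversion chemistry, editing window
#' and PAM requirement. Spacer positions are numbered 1-20 from the
#' PAM-distal (5') end, so the conventional high-activity window of
#' eighth-generation adenine deaminases is positions 3-9. Windows differ
#' between editor generations and are therefore configuration, not
#' constants.
#'
#' @param name Editor label.
#' @param conversion `"AG"` (adenine base editor, A->G on the protospacer
#'   strand) or `"CT"` (cytosine base editor, C->T).
#' @param window Inclusive spacer-position interval, default `c(3, 9)`.
#' @param pam IUPAC PAM pattern immediately 3' of the protospacer, e.g.
#'   `"NGG"`, `"NGN"`, `"NRN"`.
#' @param spacer_length Spacer length, default 20.
#' @return An `editor_spec` object.
#' @export
editor_spec <- function(name, conversion = c("AG", "CT"),
                        window = c(3L, 9L), pam = "NGG",
                        spacer_length = 20L) {
  conversion <- match.arg(conversion)
  window <- as.integer(window)
  stopifnot(length(window) == 2L, window[1] >= 1L,
            window[2] <= spacer_length, window[1] <= window[2])
  iupac_regex(pam)  # validates the pattern
  structure(list(name = name, conversion = conversion, window = window,
                 pam = toupper(pam), spacer_length = as.integer(spacer_length)),
            class = "editor_spec")
}

#' Default adenine-editor panel
#'
#' ABE8e-class editors with the three PAM stringencies used for guide
#' nomination: canonical NGG, relaxed NGN and near-PAMless NRN.
#'
#' @param window Editing window shared by the panel.
#' @return Named list of `editor_spec`s.
#' @export
default_editors <- function(window = c(3L, 9L)) {
  list(ABE8e_NGG = editor_spec("ABE8e_NGG", "AG", window, "NGG"),
       ABE8e_NGN = editor_spec("ABE8e_NGN", "AG", window, "NGN"),
       ABE8e_NRN = editor_spec("ABE8e_NRN", "AG", window, "NRN"))
}

# Substrate/product base on the sense strand for a conversion applied on
# the given protospacer strand.
.conv_bases <- function(conversion, strand) {
  if (conversion == "AG") {
    if (strand == "+") c(sub = "A", prod = "G") else c(sub = "T", prod = "C")
  } else {
    if (strand == "+") c(sub = "C", prod = "T") else c(sub = "G", prod = "A")
  }
}

#' Scan a locus for base-editing guide candidates
#'
#' Slides every spacer placement on both strands of a sense sequence
#' (1 bp staggered), keeps placements whose PAM matches the editor's
#' pattern and whose target base lies within the editing window as a
#' substrate base, and returns them in deterministic order (strand `+`
#' then `-`, then protospacer start).
#'
#' @param sense DNA sense sequence (character).
#' @param target_position 1-based position of the target base on the
#'   sense sequence.
#' @param editors List of `editor_spec`s (or a single one).
#' @return A data.frame of guide candidates: editor, strand, start
#'   (0-based half-open protospacer interval on sense coordinates), end,
#'   spacer, pam, target_spacer_pos, editable_positions (comma-separated
#'   spacer indices of substrate bases in the window).
#' @export
scan_guides <- function(sense, target_position, editors = default_editors()) {
  sense <- toupper(sense)
  if (inherits(editors, "editor_spec")) editors <- list(editors)
  L <- nchar(sense)
  stopifnot(target_position >= 1L, target_position <= L)
  rc_fast <- function(s)
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  rows <- list()
  for (ed in editors) {
    sl <- ed$spacer_length; pl <- nchar(ed$pam)
    pam_re <- paste0("^", iupac_regex(ed$pam), "$")
    for (strand in c("+", "-")) {
      cb <- .conv_bases(ed$conversion, strand)
      if (substr(sense, target_position, target_position) != cb["sub"]) next
      # j = 1-based sense start of the protospacer; only placements with
      # the target inside the window need a PAM check
      j_range <- if (strand == "+") {
        (target_position - ed$window[2] + 1L):(target_position - ed$window[1] + 1L)
      } else {
        (target_position - sl + ed$window[1]):(target_position - sl + ed$window[2])
      }
      j_range <- j_range[j_range >= 1L & j_range <= L - sl + 1L]
      for (j in j_range) {
        proto <- substr(sense, j, j + sl - 1L)
        if (strand == "+") {
          if (j + sl + pl - 1L > L) next
          pam_seq <- substr(sense, j + sl, j + sl + pl - 1L)
          spacer <- proto
          tpos <- target_position - j + 1L
        } else {
          if (j - pl < 1L) next
          pam_seq <- rc_fast(substr(sense, j - pl, j - 1L))
          spacer <- rc_fast(proto)
          tpos <- j + sl - target_position
        }
        if (!grepl(pam_re, pam_seq)) next
        if (tpos < ed$window[1] || tpos > ed$window[2]) next
        sp_chars <- strsplit(spacer, "")[[1]]
        wpos <- ed$window[1]:ed$window[2]
        substrate_on_spacer <- if (ed$conversion == "AG") "A" else "C"
        editable <- wpos[sp_chars[wpos] == substrate_on_spacer]
        rows[[length(rows) + 1L]] <- data.frame(
          editor = ed$name, strand = strand,
          start = j - 1L, end = j + sl - 1L,
          spacer = spacer, pam = pam_seq,
          target_spacer_pos = tpos,
          editable_positions = paste(editable, collapse = ","),
          target_in_window = TRUE,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(editor = character(0), strand = character(0),
                      start = integer(0), end = integer(0),
                      spacer = character(0), pam = character(0),
                      target_spacer_pos = integer(0),
                      editable_positions = character(0),
                      target_in_window = logical(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(match(out$strand, c("+", "-")), out$start,
            match(out$editor, vapply(editors, `[[`, "", "name"))), ,
      drop = FALSE]
}

# Map a spacer index of a candidate to its 1-based sense coordinate.
.spacer_to_sense <- function(start0, spacer_length, strand, idx) {
  if (strand == "+") start0 + idx else start0 + spacer_length + 1L - idx
}

#' Predict codon outcomes of a guide candidate
#'
#' Enumerates every subset of the candidate's editable window positions,
#' applies the conversions to the sense sequence, re-translates the
#' affected codons and classifies each outcome as `silent` (no amino-acid
#' change), `intended` (exactly the requested substitution) or
#' `bystander` (any other amino-acid change present). Conversion
#' probability is deliberately not modelled: window bases are treated as
#' editable or not, and efficiencies belong to the quantification layer.
#'
#' @param candidate One row of [scan_guides()] output.
#' @param editor The `editor_spec` used for the scan.
#' @param sense The sense sequence scanned.
#' @param orf_start 1-based sense coordinate where the ORF reading frame
#'   begins.
#' @param intended Optional intended substitution string (e.g.
#'   `"N399D"`) used for classification; published-numbering when
#'   `numbering_offset` is given.
#' @param numbering_offset Offset added to ORF-local residue numbers.
#' @param max_positions Cap on enumerated editable positions (subset count
#'   capped at `2^max_positions`, with a `truncated` attribute).
#' @return A data.frame with one row per conversion subset: edited
#'   spacer positions, resulting amino-acid changes, classification.
#' @export
predict_outcomes <- function(candidate, editor, sense, orf_start = 1L,
                             intended = NULL, numbering_offset = 0L,
                             max_positions = 8L) {
  sense <- toupper(sense)
  if ((nchar(sense) - orf_start + 1L) < 3L || orf_start < 1L)
    stop("coding frame inconsistent with the sense sequence")
  editable <- if (nzchar(candidate$editable_positions))
    as.integer(strsplit(candidate$editable_positions, ",")[[1]]) else integer(0)
  truncated <- FALSE
  if (length(editable) > max_positions) {
    editable <- editable[seq_len(max_positions)]
    truncated <- TRUE
  }
  cb <- .conv_bases(editor$conversion, candidate$strand)
  coords <- vapply(editable, function(i)
    .spacer_to_sense(candidate$start, editor$spacer_length,
                     candidate$strand, i), integer(1))
  in_seq <- coords >= 1L & coords <= nchar(sense)
  editable <- editable[in_seq]; coords <- coords[in_seq]
  is_sub <- vapply(coords, function(p)
    substr(sense, p, p) == cb["sub"], logical(1))
  editable <- editable[is_sub]; coords <- coords[is_sub]
  k <- length(editable)
  gc <- .codon_table()
  subsets <- if (k == 0) list(integer(0)) else {
    unlist(lapply(0:k, function(sz) utils::combn(k, sz, simplify = FALSE)),
           recursive = FALSE)
  }
  ref_orf_len <- (nchar(sense) - orf_start + 1L) %/% 3L * 3L
  ref_orf <- substr(sense, orf_start, orf_start + ref_orf_len - 1L)
  ref_prot <- strsplit(translate_dna(ref_orf), "")[[1]]
  rows <- lapply(subsets, function(ss) {
    seq2 <- sense
    for (p in coords[ss]) substr(seq2, p, p) <- cb[["prod"]]
    orf2 <- substr(seq2, orf_start, orf_start + ref_orf_len - 1L)
    prot2 <- strsplit(translate_dna(orf2), "")[[1]]
    diff <- which(prot2 != ref_prot)
    changes <- if (length(diff) == 0) "" else
      paste0(ref_prot[diff], diff + numbering_offset, prot2[diff],
             collapse = ";")
    cls <- if (changes == "") "silent"
    else if (!is.null(intended) &&
             identical(strsplit(changes, ";")[[1]], intended)) "intended"
    else "bystander"
    data.frame(edited_spacer_positions = paste(editable[ss], collapse = ","),
               n_edits = length(ss),
               aa_changes = changes, classification = cls,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "truncated") <- truncated
  out
}

#' Which editors can install a substitution in a codon
#'
#' Tests, for every editor and both strands, whether applying the
#' editor's single-base conversion class to some subset of the codon's
#' substrate bases yields a codon encoding the desired amino acid.
#'
#' @param ref_aa,alt_aa Single-letter reference and desired amino acids.
#' @param codon The reference DNA codon (must encode `ref_aa`).
#' @param editors List of `editor_spec`s.
#' @return data.frame (editor, strand, codon_outcome) of feasible routes;
#'   zero rows when no route exists.
#' @export
editability <- function(ref_aa, alt_aa, codon, editors = list(
  ABE = editor_spec("ABE", "AG"), CBE = editor_spec("CBE", "CT"))) {
  codon <- toupper(codon)
  gc <- .codon_table()
  stopifnot(nchar(codon) == 3L)
  if (gc[[codon]] != ref_aa)
    stop("codon ", codon, " does not encode ", ref_aa)
  rows <- list()
  for (ed in editors) {
    for (strand in c("+", "-")) {
      cb <- .conv_bases(ed$conversion, strand)
      bases <- strsplit(codon, "")[[1]]
      conv <- which(bases == cb["sub"])
      if (length(conv) == 0L) next
      for (sz in seq_along(conv)) {
        for (ss in utils::combn(length(conv), sz, simplify = FALSE)) {
          b2 <- bases
          b2[conv[ss]] <- cb[["prod"]]
          out_codon <- paste(b2, collapse = "")
          if (gc[[out_codon]] == alt_aa) {
            rows[[length(rows) + 1L]] <- data.frame(
              editor = ed$name, strand = strand, codon_outcome = out_codon,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(editor = character(0), strand = character(0),
                      codon_outcome = character(0), stringsAsFactors = FALSE))
  unique(do.call(rbind, rows))
}
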