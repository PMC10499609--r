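# Internal helpers shared across modules.

# Standard genetic code keyed by DNA codon ("TAA" etc.).
.codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc) <- chartr("U", "T", names(gc))
  gc
}

# Translate a character vector of in-frame DNA sequences to protein.
translate_dna <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::translate(
    Biostrings::DNAStringSet(x),
    if.fuzzy.codon = "X", no.init.codon = TRUE))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Convert an IUPAC pattern (e.g. "NGG", "NRN") to a fixed-width regex.
iupac_regex <- function(pattern) {
  map <- Biostrings::IUPAC_CODE_MAP
  chars <- strsplit(toupper(pattern), "")[[1]]
  bad <- setdiff(chars, names(map))
  if (length(bad) > 0)
    stop("invalid IUPAC code(s) in PAM pattern: ", paste(bad, collapse = ", "))
  paste0(vapply(chars, function(ch) {
    opts <- strsplit(map[[ch]], "")[[1]]
    if (length(opts) == 1L) opts else paste0("[", paste(opts, collapse = ""), "]")
  }, character(1)), collapse = "")
}

# Run code with a temporary RNG state seeded at `seed`, restoring the
# caller's stream afterwards so generators are pure in (config, seed).
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a component sub-seed so separate random streams (cells, errors,
# indels, ...) stay stable when one component's rate changes.
sub_seed <- function(seed, k) {
  as.integer((as.double(seed) * 1009L + 97L * k) %% 2147483587)
}

# Wilson score interval for a binomial proportion; behaves at p = 0 or 1.
wilson_ci <- function(x, n, level = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  centre <- (p + z^2 / (2 * n)) / den
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
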