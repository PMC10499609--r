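#' Screen ground truth
#'
#' Generative description of a sort-seq epitope screen: a library, a map
#' from substitution to the probability a cell carrying it stains
#' therapeutic-positive (abrogating substitutions near 0, neutral near
#' 1), the sorter's misassignment rate, and sequencing substitution/indel
#' error rates. Defaults are the conditions the pipeline is validated
#' under: one abrogating substitution, 50,000 reads per fraction, 0.3%
#' per-base substitution error, 0.5% indel reads, 5% sort misassignment.
#'
#' @param spec A `library_spec`.
#' @param binding_map Named numeric vector: substitution (e.g.
#'   `"N399D"`) -> probability of therapeutic-positive staining.
#'   Substitutions not listed are neutral (probability `neutral_prob`).
#' @param neutral_prob Staining probability for unlisted substitutions.
#' @param sort_misassignment Probability a cell lands in the wrong
#'   sorted fraction.
#' @param per_base_error Per-base substitution error rate in reads.
#' @param indel_rate Per-read probability of a 1-nt insertion or
#'   deletion.
#' @param depth Reads per sorted fraction.
#' @param n_clones Size of the transduced clone pool: the cell library
#'   is a clonal bottleneck of the theoretical variant space (single-copy
#'   transduction followed by expansion), so reads cluster on the clones
#'   actually present. Default 5,000 clones, roughly the unique-variant
#'   to read ratio observed in bottlenecked sort-seq screens; this is
#'   what makes a per-sample detection floor meaningful. `NULL` draws
#'   every cell independently from the full variant space.
#' @param clone_bias Optional per-clone relative abundance weights
#'   (recycled); default uniform.
#' @return A `screen_truth` list.
#' @export
screen_truth <- function(spec,
                         binding_map = c(N399D = 0),
                         neutral_prob = 1,
                         sort_misassignment = 0.05,
                         per_base_error = 0.003,
                         indel_rate = 0.005,
                         depth = 50000L,
                         n_clones = 5000L,
                         clone_bias = NULL) {
  stopifnot(inherits(spec, "library_spec"),
            all(binding_map >= 0 & binding_map <= 1),
            sort_misassignment >= 0, sort_misassignment <= 1,
            per_base_error >= 0, per_base_error < 1,
            indel_rate >= 0, indel_rate < 1, depth >= 1)
  structure(list(spec = spec, binding_map = binding_map,
                 neutral_prob = neutral_prob,
                 sort_misassignment = sort_misassignment,
                 per_base_error = per_base_error,
                 indel_rate = indel_rate, depth = as.integer(depth),
                 n_clones = if (is.null(n_clones)) NULL else
                   as.integer(n_clones),
                 clone_bias = clone_bias),
            class = "screen_truth")
}

# Apply per-base substitution errors to reads, in place, event-wise.
.mutate_bases <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  L <- nchar(reads[1])
  n_events <- stats::rbinom(1, length(reads) * L, rate)
  if (n_events == 0) return(reads)
  idx <- sample.int(length(reads), n_events, replace = TRUE)
  pos <- sample.int(L, n_events, replace = TRUE)
  bases <- c("A", "C", "G", "T")
  for (j in seq_len(n_events)) {
    cur <- substr(reads[idx[j]], pos[j], pos[j])
    substr(reads[idx[j]], pos[j], pos[j]) <-
      sample(setdiff(bases, cur), 1)
  }
  reads
}

# Apply 1-nt insertions/deletions to a fraction of reads; positions are
# restricted to [lo, hi] (the synthesized insert region) when given.
.mutate_indels <- function(reads, rate, lo = 1L, hi = NULL) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  hit <- which(stats::runif(length(reads)) < rate)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    L <- nchar(reads[i])
    top <- min(hi %||% L, L)
    p <- sample.int(top - lo + 1L, 1) + lo - 1L
    if (stats::runif(1) < 0.5) {
      # deletion
      reads[i] <- paste0(substr(reads[i], 1, p - 1),
                         substr(reads[i], p + 1, L))
    } else {
      reads[i] <- paste0(substr(reads[i], 1, p), sample(bases, 1),
                         substr(reads[i], p + 1, L))
    }
  }
  reads
}

#' Simulate a sorted-fraction epitope screen
#'
#' Generative mirror of a FACS sort-seq screen. A clone pool is drawn
#' once from the library (the transduction bottleneck); cells are then
#' drawn from the pool, each staining therapeutic-positive with
#' probability equal to the minimum binding-map value over its
#' substitutions (cells without substitutions are neutral; premature-stop
#' clones cannot be surface-stained and sort negative). Positive cells
#' sort double-positive and negative cells single-positive, with
#' assignments flipped at the misassignment rate. One read per cell is
#' emitted carrying substitution errors and 1-nt indels. Separate random
#' streams are used for the clone pool, cell draws, fraction assignment,
#' substitution errors and indels, so changing one rate leaves the other
#' components' draws unchanged.
#'
#' @param truth A [screen_truth()].
#' @param seed Integer seed.
#' @return A `screen_sim` list: `sp`, `dp` (character read vectors),
#'   `truth`, `seed`.
#' @export
simulate_screen <- function(truth, seed) {
  spec <- truth$spec
  depth <- truth$depth
  # clone pool (drawn once) with per-clone insert, binding probability
  n_pool <- truth$n_clones %||% (4L * depth)
  pool <- sample_variants(spec, n_pool, seed = sub_seed(seed, 1L))
  subs <- variant_substitutions(pool)
  p_bind <- vapply(strsplit(subs, ";"), function(ss) {
    ss <- ss[nzchar(ss)]
    if (length(ss) == 0) return(truth$neutral_prob)
    probs <- ifelse(ss %in% names(truth$binding_map),
                    truth$binding_map[ss], truth$neutral_prob)
    min(probs)
  }, numeric(1))
  p_bind[has_stop(pool)] <- 0
  inserts <- unname(emit_inserts(pool, as_string = TRUE))
  clone_w <- if (is.null(truth$clone_bias)) rep(1, n_pool) else
    rep_len(truth$clone_bias, n_pool)
  # draw cells until both fractions are filled
  sp_idx <- integer(0); dp_idx <- integer(0)
  batch <- max(1000L, ceiling(2.5 * depth))
  guard <- 0L
  while ((length(sp_idx) < depth || length(dp_idx) < depth) &&
         guard < 20L) {
    guard <- guard + 1L
    cells <- with_seed(sub_seed(seed, 10L + guard),
                       sample.int(n_pool, batch, replace = TRUE,
                                  prob = clone_w))
    assign_dp <- with_seed(sub_seed(seed, 100L + guard), {
      pos <- stats::runif(batch) < p_bind[cells]
      flip <- stats::runif(batch) < truth$sort_misassignment
      xor(pos, flip)
    })
    sp_new <- cells[!assign_dp]
    dp_new <- cells[assign_dp]
    sp_idx <- c(sp_idx, sp_new[seq_len(min(depth - length(sp_idx),
                                           length(sp_new)))])
    dp_idx <- c(dp_idx, dp_new[seq_len(min(depth - length(dp_idx),
                                           length(dp_new)))])
  }
  if (length(sp_idx) < depth || length(dp_idx) < depth)
    stop("could not fill both fractions; check the binding map")
  sp_reads <- inserts[sp_idx]
  dp_reads <- inserts[dp_idx]
  sp_reads <- with_seed(sub_seed(seed, 201L),
                        .mutate_bases(sp_reads, truth$per_base_error))
  dp_reads <- with_seed(sub_seed(seed, 202L),
                        .mutate_bases(dp_reads, truth$per_base_error))
  lo <- nchar(spec$flank5) + 1L
  hi <- nchar(spec$flank5) + nchar(spec$reference_orf)
  sp_reads <- with_seed(sub_seed(seed, 301L),
                        .mutate_indels(sp_reads, truth$indel_rate, lo, hi))
  dp_reads <- with_seed(sub_seed(seed, 302L),
                        .mutate_indels(dp_reads, truth$indel_rate, lo, hi))
  structure(list(sp = sp_reads, dp = dp_reads, truth = truth, seed = seed),
            class = "screen_sim")
}

#' Write simulated screen reads as FASTQ
#'
#' Constant quality ('I') since the downstream analysis ignores
#' qualities; the seed is recorded in each record id. A truth sidecar
#' JSON is written next to the FASTQ files.
#'
#' @param sim A `screen_sim`.
#' @param dir Output directory.
#' @return Invisibly, the paths written.
#' @export
write_screen_fastq <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(sp = file.path(dir, "single_positive.fastq"),
             dp = file.path(dir, "double_positive.fastq"),
             truth = file.path(dir, "truth.json"))
  for (fr in c("sp", "dp")) {
    reads <- sim[[fr]]
    ids <- sprintf("@%s_read%06d seed=%d", fr, seq_along(reads), sim$seed)
    qual <- vapply(nchar(reads), function(L)
      paste(rep("I", L), collapse = ""), character(1))
    writeLines(rbind(ids, reads, "+", qual), paths[fr])
  }
  truth <- sim$truth
  jsonlite::write_json(list(
    binding_map = as.list(truth$binding_map),
    neutral_prob = truth$neutral_prob,
    sort_misassignment = truth$sort_misassignment,
    per_base_error = truth$per_base_error,
    indel_rate = truth$indel_rate,
    depth = truth$depth, seed = sim$seed), paths["truth"],
    auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Simulate an amplicon allele table
#'
#' Realizes reads from per-position conversion efficiencies plus an
#' indel rate, and aggregates them into an allele table. Indel reads get
#' a 1-nt deletion (encoded as `-`) or an insertion recorded in
#' `n_inserted` with the aligned string left at reference length.
#'
#' @param reference Amplicon reference sequence.
#' @param efficiencies Named numeric vector: 1-based sense position ->
#'   conversion probability. Positions must carry the substrate base.
#' @param conversion `"AG"` or `"CT"` (sense-strand chemistry).
#' @param indel_rate Per-read indel probability.
#' @param depth Number of reads.
#' @param window Quantification window (default: span of the efficiency
#'   positions).
#' @param seed Integer seed.
#' @return An [allele_table()] with a `truth` attribute.
#' @export
simulate_amplicon <- function(reference, efficiencies, conversion = "AG",
                              indel_rate = 0.002, depth = 10000L,
                              window = NULL, seed = 1L) {
  reference <- toupper(reference)
  pos <- as.integer(names(efficiencies))
  stopifnot(length(pos) > 0, !anyNA(pos), all(efficiencies >= 0),
            all(efficiencies <= 1))
  cb <- .conv_bases(conversion, "+")
  ref_at <- substring(reference, pos, pos)
  if (any(ref_at != cb["sub"]))
    stop("efficiency positions must carry the substrate base ", cb["sub"])
  if (is.null(window)) window <- c(min(pos), max(pos))
  res <- with_seed(seed, {
    conv <- vapply(efficiencies, function(p)
      stats::rbinom(depth, 1L, p), integer(depth))
    if (depth == 1L) conv <- matrix(conv, nrow = 1)
    is_indel <- stats::runif(depth) < indel_rate
    indel_kind <- ifelse(stats::runif(depth) < 0.5, "del", "ins")
    indel_pos <- sample.int(nchar(reference), depth, replace = TRUE)
    list(conv = conv, is_indel = is_indel, indel_kind = indel_kind,
         indel_pos = indel_pos)
  })
  seqs <- rep(reference, depth)
  for (j in seq_along(pos)) {
    hit <- res$conv[, j] == 1L
    if (any(hit)) substr(seqs[hit], pos[j], pos[j]) <- cb[["prod"]]
  }
  n_ins <- integer(depth); n_del <- integer(depth)
  del <- which(res$is_indel & res$indel_kind == "del")
  for (i in del) {
    p <- res$indel_pos[i]
    substr(seqs[i], p, p) <- "-"
    n_del[i] <- 1L
  }
  ins <- which(res$is_indel & res$indel_kind == "ins")
  n_ins[ins] <- 1L
  key <- paste(seqs, n_ins, n_del, sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  alleles <- data.frame(
    Aligned_Sequence = vapply(parts, `[`, character(1), 1),
    Reads = as.integer(tab),
    n_inserted = as.integer(vapply(parts, `[`, character(1), 2)),
    n_deleted = as.integer(vapply(parts, `[`, character(1), 3)),
    n_mutated = NA_integer_,
    stringsAsFactors = FALSE, row.names = NULL)
  alleles$n_mutated <- vapply(seq_len(nrow(alleles)), function(i) {
    sum(strsplit(alleles$Aligned_Sequence[i], "")[[1]] !=
          strsplit(reference, "")[[1]])
  }, integer(1))
  out <- allele_table(alleles, reference, window)
  attr(out, "truth") <- list(efficiencies = efficiencies,
                             conversion = conversion,
                             indel_rate = indel_rate, depth = depth,
                             seed = seed)
  out
}

#' Simulate per-locus off-target count tables
#'
#' Edited-read counts follow
#' `EditedReads ~ Binomial(TotalReads, plogis(b0 + donor effect +
#' b_treatment * treatment))`, with one row per donor x treatment arm
#' per locus. Defaults mirror the validated recovery conditions: 3
#' donors, baseline logit -5, totals near 5,000.
#'
#' @param n_loci Number of loci.
#' @param n_donors Number of donors.
#' @param baseline Intercept on the logit scale.
#' @param donor_sd SD of donor effects (drawn once per locus).
#' @param treatment_shift Treatment log-odds shift (0 for a null
#'   simulation).
#' @param total_reads Mean total reads per sample (Poisson-distributed,
#'   floor 100).
#' @param seed Integer seed.
#' @return data.frame (locus, DonorID, treatment, EditedReads,
#'   TotalReads) with a `truth` attribute.
#' @export
simulate_offtarget_counts <- function(n_loci = 1L, n_donors = 3L,
                                      baseline = -5, donor_sd = 0.5,
                                      treatment_shift = 3,
                                      total_reads = 5000L, seed = 1L) {
  with_seed(seed, {
    rows <- vector("list", n_loci)
    for (l in seq_len(n_loci)) {
      donors <- stats::rnorm(n_donors, 0, donor_sd)
      grid <- expand.grid(DonorID = paste0("D", seq_len(n_donors)),
                          treatment = c(0L, 1L),
                          KEEP.OUT.ATTRS = FALSE)
      eta <- baseline + donors[as.integer(factor(grid$DonorID))] +
        treatment_shift * grid$treatment
      tot <- pmax(100L, stats::rpois(nrow(grid), total_reads))
      rows[[l]] <- data.frame(
        locus = sprintf("locus%04d", l),
        DonorID = as.character(grid$DonorID),
        treatment = grid$treatment,
        EditedReads = stats::rbinom(nrow(grid), tot, stats::plogis(eta)),
        TotalReads = tot, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(baseline = baseline, donor_sd = donor_sd,
                               treatment_shift = treatment_shift,
                               total_reads = total_reads, seed = seed)
    out
  })
}

#' Simulate a dose-response table
#'
#' LL.4 means plus Gaussian noise. Default truth emulates a normalized
#' antibody-binding curve: `b = 1, c = 0, d = 1, e = 50` ng/ml over a
#' half-log dose ladder, `sigma = 0.05`, 3 replicates.
#'
#' @param params Named list of parameter vectors `c(b, c, d, e)`, one
#'   per group.
#' @param doses Dose ladder (ng/ml).
#' @param replicates Replicates per dose.
#' @param sigma Gaussian noise SD.
#' @param seed Integer seed.
#' @return data.frame (group, dose, response, replicate) with a `truth`
#'   attribute.
#' @export
simulate_dose_response <- function(params = list(WT = c(1, 0, 1, 50)),
                                   doses = c(0.5, 1.6, 5, 16, 50, 160,
                                             500, 1600),
                                   replicates = 3L, sigma = 0.05,
                                   seed = 1L) {
  with_seed(seed, {
    rows <- lapply(names(params), function(g) {
      th <- params[[g]]
      d <- rep(doses, each = replicates)
      mu <- ll4_mean(d, th[1], th[2], th[3], th[4])
      data.frame(group = g, dose = d,
                 response = mu + stats::rnorm(length(d), 0, sigma),
                 replicate = rep(seq_len(replicates), times = length(doses)),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(params = params, sigma = sigma, seed = seed)
    out
  })
}

#' Simulate a transcriptome pileup
#'
#' Per-site coverage is drawn from a long-tailed log-normal so a
#' top-coverage percentile cut is meaningful; at reference-adenine sites
#' A>G transitions occur at the background editing rate, other sites are
#' pure reference.
#'
#' @param n_sites Number of pileup rows.
#' @param background_rate Background A>G editing rate at adenine sites.
#' @param coverage_meanlog,coverage_sdlog Log-normal coverage parameters.
#' @param seed Integer seed.
#' @return data.frame (chrom, pos, ref, coverage, A, C, G, T) with a
#'   `truth` attribute.
#' @export
simulate_pileup <- function(n_sites = 10000L, background_rate = 0.02,
                            coverage_meanlog = log(100),
                            coverage_sdlog = 1, seed = 1L) {
  with_seed(seed, {
    ref <- sample(c("A", "C", "G", "T"), n_sites, replace = TRUE)
    cov <- pmax(1L, as.integer(round(stats::rlnorm(
      n_sites, coverage_meanlog, coverage_sdlog))))
    counts <- matrix(0L, nrow = n_sites, ncol = 4,
                     dimnames = list(NULL, c("A", "C", "G", "T")))
    is_a <- ref == "A"
    g <- integer(n_sites)
    g[is_a] <- stats::rbinom(sum(is_a), cov[is_a], background_rate)
    for (b in c("A", "C", "G", "T")) {
      at_ref <- ref == b
      counts[at_ref, b] <- cov[at_ref]
    }
    counts[is_a, "A"] <- cov[is_a] - g[is_a]
    counts[is_a, "G"] <- counts[is_a, "G"] + g[is_a]
    out <- data.frame(chrom = "chrS", pos = seq_len(n_sites), ref = ref,
                      coverage = cov, counts, stringsAsFactors = FALSE)
    attr(out, "truth") <- list(background_rate = background_rate,
                               n_sites = n_sites, seed = seed)
    out
  })
}
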