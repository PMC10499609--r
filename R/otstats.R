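#' Bias-reduced (Firth-penalized) binomial logistic regression
#'
#' Maximizes the Jeffreys-prior penalized binomial log-likelihood
#' `l(beta) + 0.5 * log det I(beta)` by Newton iteration on the adjusted
#' score. For the canonical logit link this coincides with mean-bias
#' reduction, so estimates and standard errors stay finite under complete
#' separation (e.g. loci where every mock sample has zero edited reads) --
#' the property that makes per-locus off-target modelling possible where
#' ordinary maximum likelihood diverges.
#'
#' The adjusted score is `U*(b) = X'(y - n*pi + h*(1/2 - pi))` with `h`
#' the hat diagonals of the weighted design; the update solves against
#' the Fisher information `X'WX`, with step-halving on penalized
#' log-likelihood decrease.
#'
#' @param X Design matrix (full column rank).
#' @param y Successes (e.g. edited reads) per row.
#' @param n Trials (total reads) per row; all > 0.
#' @param max_iter,tol Newton controls.
#' @return A `firth_fit`: `coefficients`, `se`, `z`, `p` (two-sided
#'   Wald), `vcov`, `fitted` (per-row proportions), `loglik_penalized`,
#'   `converged`.
#' @export
firth_fit <- function(X, y, n, max_iter = 100L, tol = 1e-10) {
  X <- as.matrix(X)
  y <- as.numeric(y); n <- as.numeric(n)
  stopifnot(length(y) == nrow(X), length(n) == nrow(X))
  if (any(n <= 0)) stop("rows with zero TotalReads are not allowed")
  if (any(y < 0 | y > n)) stop("need 0 <= EditedReads <= TotalReads")
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  p <- ncol(X)
  beta <- rep(0, p)
  pen_ll <- function(beta) {
    eta <- drop(X %*% beta)
    pi <- stats::plogis(eta)
    w <- n * pi * (1 - pi)
    XtWX <- crossprod(X, X * w)
    ll <- sum(y * stats::plogis(eta, log.p = TRUE) +
                (n - y) * stats::plogis(-eta, log.p = TRUE))
    ll + 0.5 * determinant(XtWX, logarithm = TRUE)$modulus
  }
  ll_old <- pen_ll(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    pi <- stats::plogis(eta)
    w <- n * pi * (1 - pi)
    XtWX <- crossprod(X, X * w)
    V <- solve(XtWX)
    h <- rowSums((X %*% V) * X) * w
    U <- drop(crossprod(X, y - n * pi + h * (0.5 - pi)))
    if (max(abs(U)) < tol) { converged <- TRUE; break }
    step <- drop(V %*% U)
    # step-halving against the penalized objective
    for (half in 0:20) {
      cand <- beta + step / 2^half
      ll_new <- pen_ll(cand)
      if (is.finite(ll_new) && ll_new >= ll_old - 1e-12) break
    }
    beta <- cand
    ll_old <- ll_new
  }
  eta <- drop(X %*% beta)
  pi <- stats::plogis(eta)
  w <- n * pi * (1 - pi)
  V <- solve(crossprod(X, X * w))
  se <- sqrt(diag(V))
  z <- beta / se
  names(beta) <- names(se) <- names(z) <- colnames(X)
  structure(list(
    coefficients = beta, se = se, z = z,
    p = 2 * stats::pnorm(-abs(z)),
    vcov = V, fitted = pi, linear_predictors = eta,
    loglik_penalized = as.numeric(ll_old),
    converged = converged, iterations = it,
    X = X, y = y, n = n
  ), class = "firth_fit")
}

#' @export
print.firth_fit <- function(x, ...) {
  cat("Firth-penalized binomial logistic fit\n")
  print(data.frame(estimate = x$coefficients, se = x$se, z = x$z, p = x$p))
  invisible(x)
}

#' Per-locus Firth logistic model for edited-read proportions
#'
#' Fits, for one locus, `EditedReads/TotalReads ~ DonorID + treatment`
#' with the bias-reduced estimator of [firth_fit()], and returns the
#' coefficient table plus per-sample fitted proportions with 95%
#' confidence intervals (Wald on the logit scale, inverse-transformed --
#' the interval construction used throughout this package for
#' model-based proportions).
#'
#' @param table data.frame with columns `EditedReads`, `TotalReads`,
#'   `DonorID` (factor/character), `treatment` (0 mock / 1 edited); rows
#'   of one locus.
#' @param conf_level Confidence level for fitted-proportion intervals.
#' @return A `firth_fit` with an added `samples` data.frame (fitted
#'   proportion + CI per row) and `b_treatment`, `p_treatment` fields.
#' @export
firth_logistic <- function(table, conf_level = 0.95) {
  need <- c("EditedReads", "TotalReads", "DonorID", "treatment")
  if (!all(need %in% names(table)))
    stop("table needs columns: ", paste(need, collapse = ", "))
  table$DonorID <- factor(table$DonorID)
  X <- stats::model.matrix(~ DonorID + treatment, data = table)
  fit <- firth_fit(X, table$EditedReads, table$TotalReads)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  se_eta <- sqrt(rowSums((X %*% fit$vcov) * X))
  fit$samples <- data.frame(
    DonorID = table$DonorID, treatment = table$treatment,
    EditedReads = table$EditedReads, TotalReads = table$TotalReads,
    fitted_proportion = fit$fitted,
    ci_lo = stats::plogis(fit$linear_predictors - zq * se_eta),
    ci_hi = stats::plogis(fit$linear_predictors + zq * se_eta))
  fit$b_treatment <- unname(fit$coefficients["treatment"])
  fit$p_treatment <- unname(fit$p["treatment"])
  fit
}

#' On-target indel model
#'
#' The indel-proportion analysis uses the same bias-reduced binomial
#' model as the deamination analysis, with indel-carrying reads (reads
#' with `n_deleted > 0` or `n_inserted > 0`) as the success count.
#'
#' @inheritParams firth_logistic
#' @return As [firth_logistic()].
#' @export
indel_glm <- function(table, conf_level = 0.95) {
  firth_logistic(table, conf_level = conf_level)
}

#' Call off-target activity across loci
#'
#' A locus is flagged as bona fide off-target editor activity iff its
#' treatment coefficient is positive and Wald-significant at `alpha`
#' (two-sided p < alpha with positive sign). Loci are analysed
#' separately with no multiplicity adjustment by default, matching the
#' per-locus published procedure; an adjustment method can be supplied.
#'
#' @param fits Named list of [firth_logistic()] fits (names = locus ids),
#'   or a data.frame with columns `locus` and those of a full count
#'   table, which is split and fitted per locus.
#' @param alpha Significance level.
#' @param adjust p-adjustment method passed to [stats::p.adjust()]
#'   (default `"none"`).
#' @return data.frame: locus, b_treatment, se, p, p_adj, flagged.
#' @export
call_offtargets <- function(fits, alpha = 0.05, adjust = "none") {
  if (is.data.frame(fits)) {
    fits <- lapply(split(fits, fits$locus), firth_logistic)
  }
  if (is.null(names(fits))) names(fits) <- paste0("locus", seq_along(fits))
  b <- vapply(fits, function(f) f$b_treatment, numeric(1))
  se <- vapply(fits, function(f) unname(f$se["treatment"]), numeric(1))
  p <- vapply(fits, function(f) f$p_treatment, numeric(1))
  p_adj <- stats::p.adjust(p, method = adjust)
  data.frame(locus = names(fits), b_treatment = b, se = se,
             p = p, p_adj = p_adj,
             flagged = b > 0 & p_adj < alpha,
             row.names = NULL, stringsAsFactors = FALSE)
}

.sites_to_granges <- function(sites) {
  GenomicRanges::GRanges(
    seqnames = sites$chrom,
    ranges = IRanges::IRanges(start = sites$start + 1L, end = sites$end))
}

#' Filter and annotate candidate off-target sites
#'
#' Applies the site-table filters used after double-strand-break tagging
#' assays: drop sites overlapping any control (background) site interval
#' -- hot spots and sequencing noise found without nuclease -- then keep
#' sites with `mismatches + bulges < max_mm_plus_bulge` (strict, per the
#' published "< 6" rule), and annotate each survivor as `exonic` if it
#' overlaps an exon, else `intronic` if it lies within a gene span, else
#' `intergenic` (precedence exon > intron > intergenic; overlap means at
#' least one shared base).
#'
#' @param sites data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `mismatches`, `bulges` and any extras (e.g.
#'   `unique_reads`).
#' @param control_sites Background site table (same columns) or `NULL`.
#' @param exons,genes `GRanges` of exon intervals and gene spans. A BED
#'   file path can be given as `exons` (BED12: blocks become exons,
#'   records become gene spans; requires rtracklayer).
#' @param max_mm_plus_bulge Strict upper bound on mismatches + bulges.
#' @return The filtered site table with an `annotation` column.
#' @export
filter_guideseq_sites <- function(sites, control_sites = NULL,
                                  exons = NULL, genes = NULL,
                                  max_mm_plus_bulge = 6L) {
  stopifnot(all(c("chrom", "start", "end", "mismatches", "bulges") %in%
                  names(sites)))
  if (any(sites$mismatches < 0 | sites$bulges < 0))
    stop("mismatch and bulge counts must be >= 0")
  if (is.character(exons) && length(exons) == 1L) {
    bed <- read_gene_model_bed(exons)
    exons <- bed$exons; genes <- bed$genes
  }
  gr <- .sites_to_granges(sites)
  keep <- rep(TRUE, nrow(sites))
  if (!is.null(control_sites) && nrow(control_sites) > 0) {
    ctrl <- .sites_to_granges(control_sites)
    keep <- keep & !IRanges::overlapsAny(gr, ctrl, ignore.strand = TRUE)
  }
  keep <- keep & (sites$mismatches + sites$bulges) < max_mm_plus_bulge
  out <- sites[keep, , drop = FALSE]
  gr <- gr[keep]
  ann <- rep("intergenic", length(gr))
  if (!is.null(genes) && length(genes) > 0)
    ann[IRanges::overlapsAny(gr, genes, ignore.strand = TRUE)] <- "intronic"
  if (!is.null(exons) && length(exons) > 0)
    ann[IRanges::overlapsAny(gr, exons, ignore.strand = TRUE)] <- "exonic"
  out$annotation <- ann
  rownames(out) <- NULL
  out
}

#' Read a gene model from BED
#'
#' BED12 records yield gene spans with their blocks as exons; BED6 (or
#' fewer columns) records are taken as an exon list, with gene spans as
#' the per-name range.
#'
#' @param path BED file path.
#' @return list(exons = GRanges, genes = GRanges).
#' @export
read_gene_model_bed <- function(path) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading BED files requires the rtracklayer package")
  gr <- try(rtracklayer::import(path, format = "BED"), silent = TRUE)
  if (inherits(gr, "try-error")) stop("malformed BED file: ", path)
  if (!is.null(S4Vectors::mcols(gr)$blocks)) {
    exons <- unlist(rtracklayer::blocks(gr))
    genes <- gr
  } else {
    exons <- gr
    nm <- S4Vectors::mcols(gr)$name
    if (!is.null(nm) && !anyNA(nm)) {
      genes <- unlist(range(S4Vectors::split(gr, nm)))
    } else genes <- gr
  }
  list(exons = GenomicRanges::granges(exons),
       genes = GenomicRanges::granges(genes))
}

#' Transcriptome A-to-G editing rates from a pileup
#'
#' Restricts a pileup to reference-adenine sites whose coverage reaches
#' the per-sample (100 * (1 - top_fraction))th percentile of
#' reference-adenine coverages -- the top-coverage slice where editing
#' rates are estimable -- and reports the per-site transition rate
#' (product-base reads / coverage). The percentile threshold is the
#' order-statistic quantile (type 1) and ties at the threshold are
#' included.
#'
#' @param pileup data.frame with columns `chrom`, `pos`, `ref`,
#'   `coverage`, `A`, `C`, `G`, `T`.
#' @param substrate,product Reference and product bases (defaults A, G;
#'   deaminase transitions).
#' @param top_fraction Fraction of highest-coverage substrate sites to
#'   retain (default 0.05).
#' @return An `rna_editing_summary`: `sites` (per-site rates),
#'   `coverage_threshold`, `n_sites`, `mean_rate`, `quantiles`.
#' @export
rna_editing_rates <- function(pileup, substrate = "A", product = "G",
                              top_fraction = 0.05) {
  need <- c("chrom", "pos", "ref", "coverage", "A", "C", "G", "T")
  stopifnot(all(need %in% names(pileup)))
  a <- pileup[pileup$ref == substrate & pileup$coverage > 0, , drop = FALSE]
  if (nrow(a) == 0L) stop("no ", substrate, " sites in the pileup")
  thr <- stats::quantile(a$coverage, probs = 1 - top_fraction,
                         type = 1, names = FALSE)
  keep <- a[a$coverage >= thr, , drop = FALSE]
  rate <- keep[[product]] / keep$coverage
  sites <- data.frame(chrom = keep$chrom, pos = keep$pos,
                      coverage = keep$coverage,
                      transitions = keep[[product]], rate = rate,
                      stringsAsFactors = FALSE)
  structure(list(
    sites = sites,
    coverage_threshold = thr,
    n_sites = nrow(sites),
    mean_rate = mean(rate),
    quantiles = stats::quantile(rate, c(0, 0.25, 0.5, 0.75, 1)),
    substrate = substrate, product = product,
    top_fraction = top_fraction
  ), class = "rna_editing_summary")
}

#' @export
print.rna_editing_summary <- function(x, ...) {
  cat(sprintf(
    "rna_editing_summary: %d %s sites at coverage >= %d; mean %s>%s rate %.4g\n",
    x$n_sites, x$substrate, x$coverage_threshold, x$substrate, x$product,
    x$mean_rate))
  invisible(x)
}
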