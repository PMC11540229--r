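#' Filter under-represented barcodes
#'
#' Removes the barcodes in the bottom 5% (by default) of total counts across
#' the generation-0 samples present in `sheet`, plus any barcode with zero
#' reads in every sample. Exactly `floor(frac * n)` barcodes are removed by
#' the quantile rule, with ties broken by lexicographic barcode ID. To filter
#' per batch, subset `counts`/`sheet` to one batch before calling.
#'
#' @param counts Integer count matrix (barcodes x samples).
#' @param sheet Sample sheet covering the matrix columns.
#' @param frac Fraction of lowest-abundance barcodes to drop (default 0.05).
#' @return List with `retained` (barcode IDs), `removed_low`, `removed_zero`
#'   (all-zero barcodes not already removed), and `n_removed`.
#' @export
filter_barcodes <- function(counts, sheet, frac = 0.05) {
  validate_experiment(counts, sheet)
  g0 <- sheet$sample_id[sheet$generation == 0]
  if (length(g0) == 0)
    stop("no generation-0 samples in the sample sheet", call. = FALSE)
  tot0 <- rowSums(counts[, g0, drop = FALSE])
  ord <- order(tot0, rownames(counts))  # ties by lexicographic barcode ID
  n_low <- floor(frac * nrow(counts))
  removed_low <- rownames(counts)[ord[seq_len(n_low)]]
  all_zero <- rownames(counts)[rowSums(counts) == 0]
  removed_zero <- setdiff(all_zero, removed_low)
  retained <- setdiff(rownames(counts), c(removed_low, removed_zero))
  if (length(retained) == 0)
    stop("all barcodes removed by filtering", call. = FALSE)
  list(retained = retained, removed_low = removed_low,
       removed_zero = removed_zero,
       n_removed = length(removed_low) + length(removed_zero))
}

#' Add a pseudocount of 1 to every measurement
#'
#' Applied after barcode filtering and before normalization so that every
#' cell is positive.
#'
#' @param counts Integer count matrix.
#' @return The matrix with every cell incremented by exactly 1.
#' @export
add_pseudocount <- function(counts) {
  stopifnot(is.numeric(counts), all(counts == round(counts)))
  counts + 1L
}

#' Trimmed-mean-of-M-values (TMM) normalization factors
#'
#' Computes composition-correcting scale factors by the TMM method: per-pair
#' M (log ratio) and A (log abundance) values against a reference sample,
#' doubly trimmed, combined as a precision-weighted mean. The reference is
#' the sample whose upper quartile of library-size-scaled counts is closest
#' to the mean upper quartile. Factors are rescaled to geometric mean 1. The
#' computation is delegated to \pkg{edgeR}.
#'
#' @param counts Positive (pseudocounted) count matrix with >= 2 samples.
#' @param trim_M Two-sided trim proportion on M values (default 0.30).
#' @param trim_A Two-sided trim proportion on A values (default 0.05).
#' @return Object of class `tmm_factors`: list with `factors` (named, geometric
#'   mean 1), `lib_size`, `reference_sample`, `trim_M`, `trim_A`.
#' @export
tmm_factors <- function(counts, trim_M = 0.30, trim_A = 0.05) {
  stopifnot(is.matrix(counts))
  if (ncol(counts) < 2) stop("TMM requires >= 2 samples", call. = FALSE)
  lib <- colSums(counts)
  if (any(lib == 0)) stop("sample(s) with zero library size: ",
                          paste(colnames(counts)[lib == 0], collapse = ", "),
                          call. = FALSE)
  f75 <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref <- which.min(abs(f75 - mean(f75)))
  f <- edgeR::calcNormFactors(counts, method = "TMM", refColumn = ref,
                              logratioTrim = trim_M, sumTrim = trim_A)
  names(f) <- colnames(counts)
  out <- list(factors = f, lib_size = lib,
              reference_sample = colnames(counts)[ref],
              trim_M = trim_M, trim_A = trim_A)
  class(out) <- "tmm_factors"
  out
}

#' Normalized relative abundances
#'
#' Divides each sample's counts by its effective library size
#' (`lib_size * factor`).
#'
#' @param counts Count matrix.
#' @param factors A [tmm_factors()] object (or `NULL` for plain library-size
#'   normalization).
#' @return Matrix of normalized abundances.
#' @export
normalized_abundance <- function(counts, factors = NULL) {
  if (is.null(factors)) return(sweep(counts, 2, colSums(counts), "/"))
  stopifnot(inherits(factors, "tmm_factors"),
            identical(colnames(counts), names(factors$factors)))
  sweep(counts, 2, factors$lib_size * factors$factors, "/")
}

#' Per-gene fitness scores from a count matrix
#'
#' For every strain in the sample sheet, computes per-replicate fitness
#' scores: `f = log2(normalized abundance at generation G) - log2(normalized
#' abundance at generation 0)`, pairing each outgrowth replicate with the
#' generation-0 sample of its transformation stock. Barcodes are collapsed
#' to genes; genes cloned on multiple plasmids (multiple barcodes) are
#' removed. The gene-level score is the arithmetic mean over replicates.
#'
#' @param counts Positive (filtered, pseudocounted) count matrix.
#' @param factors A [tmm_factors()] for these columns, or `NULL` for plain
#'   library-size normalization.
#' @param sheet Sample sheet.
#' @param catalog Barcode catalog.
#' @param strains Strains to score (default: all with generation-G samples).
#' @return Object of class `fitness_set`: named list per strain with
#'   elements `strain_id`, `logfc` (genes x replicates), `score` (mean),
#'   `n_replicates`, `generations`, plus attribute `removed_multi` (genes
#'   dropped for having multiple plasmids).
#' @export
fitness_scores <- function(counts, factors, sheet, catalog, strains = NULL) {
  validate_experiment(counts, sheet)
  catalog <- validate_catalog(catalog)
  norm <- normalized_abundance(counts, factors)

  idx <- match(rownames(norm), catalog$barcode_id)
  if (anyNA(idx))
    stop("count matrix contains barcodes absent from the catalog",
         call. = FALSE)
  multi <- catalog$n_plasmids_for_gene[idx] > 1
  removed_multi <- unique(catalog$gene_id[idx][multi])
  norm <- norm[!multi, , drop = FALSE]
  gene <- catalog$gene_id[idx][!multi]
  rownames(norm) <- gene
  lnorm <- log2(norm)

  grown <- sheet[sheet$generation > 0, ]
  if (is.null(strains)) strains <- unique(grown$strain_id)
  out <- lapply(strains, function(st) {
    gg <- grown[grown$strain_id == st, ]
    if (nrow(gg) == 0)
      stop("strain has no generation-G samples: ", st, call. = FALSE)
    g0 <- sheet[sheet$generation == 0 & sheet$strain_id == st, ]
    if (nrow(g0) == 0)
      stop("strain has no generation-0 sample: ", st, call. = FALSE)
    g0_of_stock <- stats::setNames(g0$sample_id, g0$stock)
    lf <- vapply(seq_len(nrow(gg)), function(i)
      lnorm[, gg$sample_id[i]] - lnorm[, g0_of_stock[[gg$stock[i]]]],
      numeric(nrow(lnorm)))
    colnames(lf) <- gg$sample_id
    list(strain_id = st, logfc = lf, score = rowMeans(lf),
         n_replicates = ncol(lf), generations = unique(gg$generation))
  })
  names(out) <- strains
  attr(out, "removed_multi") <- removed_multi
  class(out) <- "fitness_set"
  out
}

# variance floor guarding degenerate (zero-variance) inputs
VAR_FLOOR <- 1e-10

moderated_fit <- function(v, df) {
  v <- pmax(v, VAR_FLOOR)
  if (stats::sd(v) < VAR_FLOOR || length(v) < 2) {
    # degenerate prior: no shrinkage possible
    return(list(var.post = v, df.prior = 0))
  }
  sq <- limma::squeezeVar(v, df = df)
  sq$var.post <- pmax(sq$var.post, VAR_FLOOR)
  sq
}

#' Test fitness scores for significance
#'
#' One-sample mode tests, per gene, whether the mean replicate log2
#' fold-change differs from 0; contrast mode tests whether two strains' mean
#' scores differ. Both use a moderated t statistic: per-gene variances are
#' shrunk toward a common prior estimated across genes by empirical Bayes
#' (method of moments), adding the prior degrees of freedom to the residual
#' ones. P-values are Benjamini-Hochberg corrected across all tested genes.
#'
#' @param x A single strain's entry of a [fitness_scores()] result (list
#'   with a `logfc` matrix), or a bare genes-x-replicates matrix of log2
#'   fold-changes.
#' @param mode `"one_sample"` or `"contrast"`.
#' @param y Second strain (same form as `x`) for contrast mode.
#' @param fdr_threshold Significance threshold recorded in the output.
#' @return Data frame with columns `gene`, `score` (and `score_ref`,
#'   `contrast` in contrast mode), `t`, `df`, `p_value`, `fdr`,
#'   `significant`.
#' @export
test_differential <- function(x, mode = c("one_sample", "contrast"),
                              y = NULL, fdr_threshold = 0.05) {
  mode <- match.arg(mode)
  lf <- if (is.matrix(x)) x else x$logfc
  if (ncol(lf) < 2)
    stop("at least 2 replicates required", call. = FALSE)
  n <- ncol(lf)
  m <- rowMeans(lf)
  v <- rowSums((lf - m)^2) / (n - 1)

  if (mode == "one_sample") {
    sq <- moderated_fit(v, n - 1)
    se <- sqrt(sq$var.post / n)
    df <- sq$df.prior + n - 1
    tt <- m / se
    res <- data.frame(gene = rownames(lf), score = m, t = tt, df = df,
                      p_value = 2 * stats::pt(-abs(tt), df),
                      stringsAsFactors = FALSE)
  } else {
    if (is.null(y)) stop("contrast mode needs a second strain", call. = FALSE)
    lf2 <- if (is.matrix(y)) y else y$logfc
    if (ncol(lf2) < 2)
      stop("at least 2 replicates per group required", call. = FALSE)
    shared <- intersect(rownames(lf), rownames(lf2))
    lf <- lf[shared, , drop = FALSE]; lf2 <- lf2[shared, , drop = FALSE]
    n2 <- ncol(lf2)
    m <- rowMeans(lf); m2 <- rowMeans(lf2)
    v1 <- rowSums((lf - m)^2) / (n - 1)
    v2 <- rowSums((lf2 - m2)^2) / (n2 - 1)
    vp <- ((n - 1) * v1 + (n2 - 1) * v2) / (n + n2 - 2)
    sq <- moderated_fit(vp, n + n2 - 2)
    se <- sqrt(sq$var.post * (1 / n + 1 / n2))
    df <- sq$df.prior + n + n2 - 2
    tt <- (m - m2) / se
    res <- data.frame(gene = shared, score = m, score_ref = m2,
                      contrast = m - m2, t = tt, df = df,
                      p_value = 2 * stats::pt(-abs(tt), df),
                      stringsAsFactors = FALSE)
  }
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res$significant <- res$fdr < fdr_threshold
  rownames(res) <- NULL
  res
}

#' Full fitness table for an experiment
#'
#' Convenience wrapper running the standard pipeline on one batch: filter
#' under-represented barcodes, add the pseudocount, TMM-normalize, compute
#' per-replicate and mean fitness scores per strain, and test each strain's
#' scores against 0 (one-sample moderated t, BH-corrected).
#'
#' @param counts Raw integer count matrix.
#' @param sheet Sample sheet.
#' @param catalog Barcode catalog.
#' @param filter_frac Bottom quantile of generation-0 totals to remove.
#' @param fdr_threshold Significance threshold.
#' @return List with `table` (long data frame: gene, strain, score, p_value,
#'   fdr, n_replicates, generations), `fitness` (the `fitness_set`),
#'   `factors`, and `filter` (the retained/removed report).
#' @export
score_experiment <- function(counts, sheet, catalog, filter_frac = 0.05,
                             fdr_threshold = 0.05) {
  flt <- filter_barcodes(counts, sheet, frac = filter_frac)
  m <- add_pseudocount(counts[flt$retained, , drop = FALSE])
  nf <- tmm_factors(m)
  fs <- fitness_scores(m, nf, sheet, catalog)
  tabs <- lapply(fs, function(st) {
    res <- test_differential(st, "one_sample", fdr_threshold = fdr_threshold)
    res$strain <- st$strain_id
    res$n_replicates <- st$n_replicates
    res$generations <- st$generations
    res
  })
  list(table = do.call(rbind, c(tabs, make.row.names = FALSE)),
       fitness = fs, factors = nf, filter = flt)
}
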