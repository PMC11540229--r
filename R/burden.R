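#' Relative fitness of each aneuploid chromosome
#'
#' Ratio of the mean growth rate of each wild-type aneuploid to the mean
#' wild-type euploid rate (ratio of means by default; a paired mean-of-ratios
#' mode is available).
#'
#' @param growth Growth-rate table: columns `strain_id`, `background`,
#'   `amplified_chromosome`, `condition`, `replicate`, `rate`.
#' @param condition Condition to use (default `"control"`).
#' @param mode `"ratio_of_means"` (default) or `"mean_of_ratios"` (pairs
#'   replicates by index).
#' @return Named numeric vector, one value per amplified chromosome.
#' @export
relative_fitness <- function(growth, condition = "control",
                             mode = c("ratio_of_means", "mean_of_ratios")) {
  mode <- match.arg(mode)
  g <- growth[growth$condition == condition, ]
  eu <- g[g$background == "SSD1+" & is.na(g$amplified_chromosome), ]
  if (nrow(eu) == 0) stop("no wild-type euploid measurements", call. = FALSE)
  an <- g[g$background == "SSD1+" & !is.na(g$amplified_chromosome), ]
  out <- vapply(split(an, an$amplified_chromosome), function(ch) {
    if (mode == "ratio_of_means") mean(ch$rate) / mean(eu$rate)
    else mean(ch$rate[order(ch$replicate)] /
              eu$rate[order(eu$replicate)][seq_len(nrow(ch))])
  }, 0)
  out
}

#' Chromosome-level Ssd1 dependence
#'
#' Ratio of the mean ssd1-null aneuploid growth rate to the mean wild-type
#' aneuploid rate, per chromosome. Chromosomes lacking either background
#' (e.g. unculturable ssd1-null strains) are omitted, not imputed.
#'
#' @inheritParams relative_fitness
#' @return Named numeric vector over the chromosomes measured in both
#'   backgrounds.
#' @export
chromosome_ssd1_dependence <- function(growth, condition = "control",
                                       mode = c("ratio_of_means",
                                                "mean_of_ratios")) {
  mode <- match.arg(mode)
  g <- growth[growth$condition == condition &
                !is.na(growth$amplified_chromosome), ]
  chrs <- intersect(unique(g$amplified_chromosome[g$background == "ssd1d"]),
                    unique(g$amplified_chromosome[g$background == "SSD1+"]))
  out <- vapply(chrs, function(ch) {
    wt <- g[g$background == "SSD1+" & g$amplified_chromosome == ch, ]
    mu <- g[g$background == "ssd1d" & g$amplified_chromosome == ch, ]
    if (mode == "ratio_of_means") mean(mu$rate) / mean(wt$rate)
    else mean(mu$rate[order(mu$replicate)] /
              wt$rate[order(wt$replicate)][seq_len(nrow(mu))])
  }, 0)
  names(out) <- chrs
  out
}

#' Gene-level Ssd1 dependence
#'
#' Difference of log2 fitness scores between the ssd1-null euploid and the
#' wild-type euploid for each gene scored in both strains: negative values
#' mark duplications more costly without Ssd1.
#'
#' @param fitness Long fitness table (`gene`, `strain`, `score`).
#' @param ssd1d_strain,wt_strain Strain IDs of the two euploids.
#' @return Named numeric vector over the shared genes; attribute `excluded`
#'   lists genes present in only one strain.
#' @export
gene_ssd1_dependence <- function(fitness, ssd1d_strain, wt_strain) {
  mu <- strain_slice(fitness, ssd1d_strain)
  wt <- strain_slice(fitness, wt_strain)
  shared <- intersect(mu$gene, wt$gene)
  out <- lookup(mu, shared, "score") - lookup(wt, shared, "score")
  attr(out, "excluded") <- setdiff(union(mu$gene, wt$gene), shared)
  out
}

#' Per-chromosome cumulative score of a gene set
#'
#' Sums the supplied per-gene values over the set members encoded on each
#' chromosome; chromosomes without set members get 0.
#'
#' @param genes Character vector (or [gene_set()]) of genes.
#' @param values Named per-gene numeric vector (e.g. fitness scores or
#'   [gene_ssd1_dependence()] values).
#' @param chromosome_of Named chromosome assignment per gene.
#' @param chromosomes Chromosomes to report (default: all in
#'   `chromosome_of`).
#' @return Named numeric vector of per-chromosome sums.
#' @export
cumulative_score <- function(genes, values, chromosome_of,
                             chromosomes = NULL) {
  if (inherits(genes, "gene_set")) genes <- genes$genes
  if (is.null(chromosomes))
    chromosomes <- sort(unique(unname(chromosome_of)))
  genes <- intersect(genes, names(values))
  missing_chr <- setdiff(genes, names(chromosome_of))
  if (length(missing_chr))
    stop("no chromosome assignment for: ",
         paste(utils::head(missing_chr, 5), collapse = ", "), call. = FALSE)
  out <- stats::setNames(numeric(length(chromosomes)), chromosomes)
  if (length(genes)) {
    sums <- tapply(values[genes], chromosome_of[genes], sum)
    out[names(sums)] <- sums
  }
  out
}

#' Fit the cumulative-burden linear model
#'
#' Ordinary least squares of an observed per-chromosome quantity (relative
#' fitness or Ssd1 dependence) on its prediction from summed per-gene scores.
#'
#' @param predicted Named per-chromosome predictor (e.g. from
#'   [cumulative_score()]).
#' @param observed Named per-chromosome response; matched to `predicted` by
#'   name, using the intersection.
#' @param exclude Chromosomes to drop before fitting (e.g. an unculturable
#'   strain).
#' @return Object of class `burden_fit`: `slope`, `intercept`, `r_squared`,
#'   `adj_r_squared`, `f_p_value` (slope F-test), `n`, `data` (per-chromosome
#'   predicted/observed/fitted), and the underlying `lm` fit.
#' @export
fit_burden_model <- function(predicted, observed, exclude = NULL) {
  chrs <- intersect(names(predicted), names(observed))
  chrs <- setdiff(chrs, exclude)
  if (length(chrs) < 3)
    stop("need >= 3 chromosomes to fit (have ", length(chrs), ")",
         call. = FALSE)
  x <- predicted[chrs]; y <- observed[chrs]
  if (stats::sd(x) == 0) stop("zero-variance predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  out <- list(slope = unname(stats::coef(fit)[2]),
              intercept = unname(stats::coef(fit)[1]),
              r_squared = sm$r.squared,
              adj_r_squared = sm$adj.r.squared,
              f_p_value = unname(stats::pf(sm$fstatistic[1],
                                           sm$fstatistic[2],
                                           sm$fstatistic[3],
                                           lower.tail = FALSE)),
              n = length(chrs),
              data = data.frame(chromosome = chrs, predicted = unname(x),
                                observed = unname(y),
                                fitted = unname(stats::fitted(fit))),
              lm = fit)
  class(out) <- "burden_fit"
  out
}

#' @export
print.burden_fit <- function(x, ...) {
  cat(sprintf(
    "<burden_fit> n = %d: observed = %.4g + %.4g * predicted; R^2 = %.3f (adj %.3f), slope F-test p = %.3g\n",
    x$n, x$intercept, x$slope, x$r_squared, x$adj_r_squared, x$f_p_value))
  invisible(x)
}

#' Null distribution of the burden-model R-squared by label permutation
#'
#' Permutes the chromosome labels of the predictor and refits; for unrelated
#' vectors of n points the expected R-squared is about 1/(n-1).
#'
#' @param predicted,observed Named per-chromosome vectors.
#' @param n_perm Number of permutations.
#' @param seed Seed.
#' @return Numeric vector of permuted R-squared values.
#' @export
permute_burden_r2 <- function(predicted, observed, n_perm = 500, seed = 1L) {
  chrs <- intersect(names(predicted), names(observed))
  x <- predicted[chrs]; y <- observed[chrs]
  set.seed(seed)
  vapply(seq_len(n_perm), function(i) {
    stats::cor(sample(x), y)^2
  }, 0)
}
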