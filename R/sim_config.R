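#' Configuration for the pooled-competition simulator
#'
#' Collects every tunable of the generative model in one validated object.
#' Defaults emulate the screen the package is designed around: a ~5,000-
#' plasmid barcoded library competed for 10 generations, sequenced at about
#' 3 million reads per sample, with replicates structured by independent
#' library transformations ("stocks").
#'
#' Fitness effects are parameterized per generation in log2 units: a gene
#' with effect `s` doubles `2^(1 + s)`-fold per generation, so over `G`
#' generations its expected log2 fold-change relative to a neutral pool is
#' approximately `G * s` (minus a gene-independent pool-average shift).
#'
#' @param n_genes Number of barcodes in the library (one plasmid each).
#' @param generations Generations of competitive outgrowth (10 by default;
#'   strains with extreme fitness defects are grown for 5).
#' @param replicates Outgrowth replicates per strain.
#' @param n_stocks Number of independent transformation stocks; replicates
#'   are assigned to stocks round-robin. Each stock contributes one
#'   generation-0 sample shared by its outgrowth replicates. The default
#'   (one stock per replicate) mirrors a design of independent
#'   transformations; set `n_stocks < replicates` for repeated outgrowths of
#'   the same stock.
#' @param depth Sequencing reads per sample.
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @param frac_deleterious,frac_beneficial Fractions of genes whose
#'   duplication is deleterious/beneficial in every context.
#' @param effect_scale_deleterious,effect_scale_beneficial Mean magnitude
#'   (exponential scale) of the per-generation log2 effects of those genes.
#' @param context_set_sizes Named counts of planted context-specific genes.
#'   `ssd1_sensitive` genes are neutral in the SSD1+ euploid but toxic in the
#'   ssd1-null euploid and in aneuploids; `aneuploid_beneficial` genes are
#'   beneficial only in ssd1-null aneuploids.
#' @param context_effect_toxic,context_effect_beneficial Per-generation
#'   magnitude of the planted context-specific effects.
#' @param stock_sd,rep_sd Standard deviations of gene-level random effects at
#'   the transformation-stock and within-stock replicate tiers (per-generation
#'   log2 units). Two tiers make within-stock replicates correlate more
#'   strongly than across-stock replicates.
#' @param init_sd Log-scale jitter of starting relative abundances around the
#'   uniform pool, drawn once per stock.
#' @param overdispersion Dirichlet concentration multiplier for sequencing;
#'   `Inf` (default) gives pure multinomial sampling, smaller values add
#'   overdispersion (e.g. library-prep PCR jackpotting).
#' @param dicentric_loss Extra per-generation log2 disadvantage of
#'   centromere-adjacent plasmids (dicentric, mitotically unstable) in
#'   aneuploid contexts.
#' @param frac_centromere_adjacent Fraction of genes naturally encoded next
#'   to a centromere, hence carried on dicentric plasmids.
#' @param n_multi_plasmid_genes Number of genes represented by two barcodes
#'   (cloned on multiple plasmids); these are excluded downstream.
#' @param barcode_length Length of the simulated barcode sequences.
#' @param burden_coefficient Slope `c` linking a chromosome's summed gene
#'   effects to its relative growth rate: `relative rate = 1 + c * sum(s)`.
#' @param growth_noise_sd Standard deviation of the noise on simulated
#'   relative growth rates.
#' @param baseline_rate Euploid growth rate (per hour).
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_genes = 100, depth = 1e4, seed = 42)
#' cfg$generations
#' @export
sim_config <- function(n_genes = 4872L,
                       generations = 10L,
                       replicates = 3L,
                       n_stocks = replicates,
                       depth = 3e6,
                       seed = 1L,
                       frac_deleterious = 0.10,
                       frac_beneficial = 0.02,
                       effect_scale_deleterious = 0.05,
                       effect_scale_beneficial = 0.02,
                       context_set_sizes = c(ssd1_sensitive = 200L,
                                             aneuploid_beneficial = 100L),
                       context_effect_toxic = 0.25,
                       context_effect_beneficial = 0.08,
                       stock_sd = 0.03,
                       rep_sd = 0.01,
                       init_sd = 0.25,
                       overdispersion = Inf,
                       dicentric_loss = 0.15,
                       frac_centromere_adjacent = 0.02,
                       n_multi_plasmid_genes = 0L,
                       barcode_length = 20L,
                       burden_coefficient = 0.1,
                       growth_noise_sd = 0.02,
                       baseline_rate = 0.45) {
  cfg <- list(
    n_genes = as.integer(n_genes), generations = as.integer(generations),
    replicates = as.integer(replicates), n_stocks = as.integer(n_stocks),
    depth = depth, seed = as.integer(seed),
    frac_deleterious = frac_deleterious, frac_beneficial = frac_beneficial,
    effect_scale_deleterious = effect_scale_deleterious,
    effect_scale_beneficial = effect_scale_beneficial,
    context_set_sizes = context_set_sizes,
    context_effect_toxic = context_effect_toxic,
    context_effect_beneficial = context_effect_beneficial,
    stock_sd = stock_sd, rep_sd = rep_sd, init_sd = init_sd,
    overdispersion = overdispersion,
    dicentric_loss = dicentric_loss,
    frac_centromere_adjacent = frac_centromere_adjacent,
    n_multi_plasmid_genes = as.integer(n_multi_plasmid_genes),
    barcode_length = as.integer(barcode_length),
    burden_coefficient = burden_coefficient,
    growth_noise_sd = growth_noise_sd, baseline_rate = baseline_rate
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  props <- c(cfg$frac_deleterious, cfg$frac_beneficial,
             cfg$frac_centromere_adjacent)
  if (any(props < 0 | props > 1))
    stop("all proportions must lie in [0, 1]", call. = FALSE)
  if (cfg$frac_deleterious + cfg$frac_beneficial > 1)
    stop("frac_deleterious + frac_beneficial must not exceed 1", call. = FALSE)
  if (cfg$n_genes < 1L || cfg$generations < 1L || cfg$replicates < 1L ||
      cfg$depth < 1)
    stop("n_genes, generations, replicates and depth must all be >= 1",
         call. = FALSE)
  if (cfg$n_stocks < 1L || cfg$n_stocks > cfg$replicates)
    stop("n_stocks must be between 1 and replicates", call. = FALSE)
  scales <- c(cfg$effect_scale_deleterious, cfg$effect_scale_beneficial,
              cfg$context_effect_toxic, cfg$context_effect_beneficial,
              cfg$stock_sd, cfg$rep_sd, cfg$init_sd, cfg$dicentric_loss,
              cfg$growth_noise_sd)
  if (any(scales < 0))
    stop("effect scales and standard deviations must be >= 0", call. = FALSE)
  if (!is.infinite(cfg$overdispersion) && cfg$overdispersion <= 0)
    stop("overdispersion must be positive (or Inf for pure multinomial)",
         call. = FALSE)
  if (sum(cfg$context_set_sizes) > cfg$n_genes)
    stop("context_set_sizes exceed the number of genes", call. = FALSE)
  if (2L * cfg$n_multi_plasmid_genes > cfg$n_genes)
    stop("too many multi-plasmid genes for the barcode count", call. = FALSE)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", x$n_genes, "barcodes,", x$generations, "generations,",
      x$replicates, "replicates in", x$n_stocks, "stocks, depth",
      format(x$depth, big.mark = ","), "reads/sample, seed", x$seed, "\n")
  invisible(x)
}

#' Describe a strain used in a competition experiment
#'
#' @param strain_id Strain identifier.
#' @param background `"SSD1+"` (wild type) or `"ssd1d"` (ssd1-null).
#' @param amplified_chromosome Chromosome carried in two copies, or `NA` for
#'   a euploid strain.
#' @param generations Generations of outgrowth for this strain (10, or 5 for
#'   strains with extreme fitness defects).
#'
#' @return An object of class `strain_context`.
#' @examples
#' strain_context("wt_chr12", "SSD1+", "chr12")
#' @export
strain_context <- function(strain_id,
                           background = c("SSD1+", "ssd1d"),
                           amplified_chromosome = NA_character_,
                           generations = 10L) {
  background <- match.arg(background)
  if (!generations %in% c(5L, 10L))
    warning("unusual generation count: ", generations)
  out <- list(strain_id = as.character(strain_id),
              background = background,
              amplified_chromosome = as.character(amplified_chromosome),
              generations = as.integer(generations))
  class(out) <- "strain_context"
  out
}

#' Map a strain to its cellular context
#'
#' @param context A [strain_context()].
#' @return One of [CELL_CONTEXTS].
#' @export
context_of <- function(context) {
  stopifnot(inherits(context, "strain_context"))
  euploid <- is.na(context$amplified_chromosome)
  if (context$background == "SSD1+") {
    if (euploid) "wt_euploid" else "wt_aneuploid"
  } else {
    if (euploid) "ssd1d_euploid" else "ssd1d_aneuploid"
  }
}
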