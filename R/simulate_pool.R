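#' Deterministic pool evolution
#'
#' Advances relative abundances through `generations` doublings where each
#' lineage grows `2^(1 + s)`-fold per generation. Used internally and exposed
#' for testing the growth model in closed form.
#'
#' @param p0 Initial relative abundances (summing to 1).
#' @param s Per-generation log2 fitness effects, one per lineage.
#' @param generations Number of generations.
#' @return Relative abundances after growth (summing to 1).
#' @keywords internal
evolve_abundance <- function(p0, s, generations) {
  stopifnot(length(p0) == length(s))
  # subtract max for numerical stability; 2^(G*(1+s)) cancels its common part
  lw <- log2(p0) + generations * s
  w <- 2^(lw - max(lw))
  w / sum(w)
}

draw_counts <- function(p, depth, overdispersion = Inf) {
  if (depth < 1) stop("sequencing depth must be >= 1", call. = FALSE)
  if (is.finite(overdispersion)) {
    g <- stats::rgamma(length(p), shape = p * overdispersion)
    if (sum(g) == 0) g <- p
    p <- g / sum(g)
  }
  as.integer(stats::rmultinom(1, size = depth, prob = p))
}

#' Simulate a pooled competition experiment for one strain
#'
#' Mechanistic model of competitive outgrowth of a barcoded plasmid pool:
#' per transformation stock, starting abundances are drawn around uniform
#' with log-normal jitter and the frozen aliquot is sequenced once
#' (generation 0, shared by that stock's outgrowth replicates); each
#' replicate then grows for `context$generations` generations with
#' per-lineage growth `2^(1 + s)` per generation, where `s` is the gene's
#' true context effect plus stock- and replicate-level gene noise, minus the
#' dicentric-instability penalty for centromere-adjacent plasmids in
#' aneuploid strains; the outgrown pool is sequenced multinomially (or
#' Dirichlet-multinomially) at the configured depth.
#'
#' @param truth A [sim_truth()].
#' @param context A [strain_context()]; its cellular context must be one of
#'   [CELL_CONTEXTS].
#' @param config A [sim_config()].
#' @param seed Seed for this strain's randomness (default `config$seed`).
#' @param batch Batch label recorded in the sample sheet.
#'
#' @return List with `counts` (integer matrix, barcodes x samples) and
#'   `sheet` (sample-sheet data frame).
#' @examples
#' cfg <- sim_config(n_genes = 50, depth = 1e4, replicates = 2, seed = 3,
#'   context_set_sizes = c(ssd1_sensitive = 5, aneuploid_beneficial = 2))
#' truth <- make_truth(cfg)
#' sim <- simulate_pool(truth, strain_context("wt_eu", "SSD1+"), cfg)
#' dim(sim$counts)
#' @export
simulate_pool <- function(truth, context, config, seed = config$seed,
                          batch = "B1") {
  stopifnot(inherits(truth, "sim_truth"), inherits(context, "strain_context"))
  config <- validate_sim_config(config)
  ctx <- context_of(context)
  set.seed(seed)

  cat <- truth$catalog
  s_bc <- truth$s[cat$gene_id, ctx]
  aneuploid <- !is.na(context$amplified_chromosome)
  if (aneuploid) s_bc <- s_bc - config$dicentric_loss * cat$centromere_adjacent
  nb <- nrow(cat)
  G <- context$generations

  stock_of_rep <- rep(seq_len(config$n_stocks), length.out = config$replicates)
  stock_ids <- sprintf("%s_stock%d", context$strain_id,
                       seq_len(config$n_stocks))

  cols <- list(); sheet <- list()
  for (k in seq_len(config$n_stocks)) {
    p0 <- exp(stats::rnorm(nb, 0, config$init_sd))
    p0 <- p0 / sum(p0)
    e_stock <- stats::rnorm(nrow(truth$s), 0, config$stock_sd)[
      match(cat$gene_id, rownames(truth$s))]
    g0_id <- sprintf("%s_g0_s%d", context$strain_id, k)
    cols[[g0_id]] <- draw_counts(p0, config$depth, config$overdispersion)
    sheet[[g0_id]] <- data.frame(
      sample_id = g0_id, strain_id = context$strain_id,
      background = context$background,
      amplified_chromosome = context$amplified_chromosome,
      generation = 0L, replicate = NA_integer_, batch = batch,
      stock = stock_ids[k], stringsAsFactors = FALSE)
    for (r in which(stock_of_rep == k)) {
      e_rep <- stats::rnorm(nrow(truth$s), 0, config$rep_sd)[
        match(cat$gene_id, rownames(truth$s))]
      pG <- evolve_abundance(p0, s_bc + e_stock + e_rep, G)
      gg_id <- sprintf("%s_g%d_r%d", context$strain_id, G, r)
      cols[[gg_id]] <- draw_counts(pG, config$depth, config$overdispersion)
      sheet[[gg_id]] <- data.frame(
        sample_id = gg_id, strain_id = context$strain_id,
        background = context$background,
        amplified_chromosome = context$amplified_chromosome,
        generation = G, replicate = r, batch = batch,
        stock = stock_ids[k], stringsAsFactors = FALSE)
    }
  }
  counts <- do.call(cbind, cols)
  rownames(counts) <- cat$barcode_id
  list(counts = counts, sheet = do.call(rbind, c(sheet, make.row.names = FALSE)))
}

#' Simulate a full multi-strain experiment
#'
#' Runs [simulate_pool()] for each strain with a seed derived from
#' `config$seed` and the strain's position, and binds the results.
#'
#' @param truth A [sim_truth()].
#' @param contexts List of [strain_context()] objects.
#' @param config A [sim_config()].
#' @param batch Batch label.
#' @return List with combined `counts` and `sheet`.
#' @export
simulate_experiment <- function(truth, contexts, config, batch = "B1") {
  sims <- lapply(seq_along(contexts), function(i)
    simulate_pool(truth, contexts[[i]], config,
                  seed = (config$seed + 7919L * i) %% .Machine$integer.max,
                  batch = batch))
  list(counts = do.call(cbind, lapply(sims, `[[`, "counts")),
       sheet = do.call(rbind, lapply(sims, `[[`, "sheet")))
}

#' Simulate strain growth rates under the additive-burden model
#'
#' The euploid grows at the baseline rate. Each aneuploid's relative rate is
#' `1 + c * sum(s[g, context])` over the genes on its amplified chromosome,
#' plus Gaussian noise per replicate, clipped to be positive; `c` and the
#' noise standard deviation come from the truth object.
#'
#' @param truth A [sim_truth()].
#' @param contexts List of [strain_context()] objects.
#' @param n_reps Replicates per strain.
#' @param seed Seed.
#' @return Data frame with columns `strain_id`, `background`,
#'   `amplified_chromosome`, `condition`, `replicate`, `rate`,
#'   `relative_rate`.
#' @export
simulate_growth_rates <- function(truth, contexts, n_reps = 4L,
                                  seed = 1L) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(seed)
  rows <- lapply(contexts, function(ctx) {
    stopifnot(inherits(ctx, "strain_context"))
    if (is.na(ctx$amplified_chromosome)) {
      rel <- rep(1, n_reps)
    } else {
      on_chr <- names(truth$chromosome_of)[
        truth$chromosome_of == ctx$amplified_chromosome]
      burden <- sum(truth$s[on_chr, context_of(ctx)])
      rel <- 1 + truth$burden_coefficient * burden +
        stats::rnorm(n_reps, 0, truth$noise_sd)
      rel <- pmax(rel, 1e-6)
    }
    data.frame(strain_id = ctx$strain_id, background = ctx$background,
               amplified_chromosome = ctx$amplified_chromosome,
               condition = "control", replicate = seq_len(n_reps),
               rate = truth$baseline_rate * rel, relative_rate = rel,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, make.row.names = FALSE))
}
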