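#' Construct a ground-truth object for the simulator
#'
#' Low-level constructor; most users call [make_truth()]. `s` holds the true
#' per-generation log2 fitness effect of each gene duplication in each
#' cellular context (0 = neutral).
#'
#' @param s Numeric matrix, genes x contexts, with gene IDs as row names and
#'   [CELL_CONTEXTS] as column names.
#' @param chromosome_of Named character vector assigning each gene to a
#'   chromosome. Defaults to a uniform assignment over 16 chromosomes.
#' @param catalog Barcode catalog data frame (see [make_catalog()]); built
#'   automatically (one barcode per gene) when `NULL`.
#' @param planted_sets Named list of character vectors of gene IDs.
#' @param burden_coefficient,noise_sd,baseline_rate Parameters for
#'   [simulate_growth_rates()].
#'
#' @return An object of class `sim_truth`.
#' @export
sim_truth <- function(s,
                      chromosome_of = NULL,
                      catalog = NULL,
                      planted_sets = list(),
                      burden_coefficient = 0.1,
                      noise_sd = 0.02,
                      baseline_rate = 0.45) {
  stopifnot(is.matrix(s), !is.null(rownames(s)))
  if (is.null(colnames(s)) || !setequal(colnames(s), CELL_CONTEXTS))
    stop("s must have columns ", paste(CELL_CONTEXTS, collapse = ", "),
         call. = FALSE)
  s <- s[, CELL_CONTEXTS, drop = FALSE]
  genes <- rownames(s)
  if (is.null(chromosome_of)) {
    chromosome_of <- paste0("chr", rep_len(1:16, length(genes)))
    names(chromosome_of) <- genes
  }
  if (!setequal(names(chromosome_of), genes))
    stop("chromosome_of must name every gene exactly once", call. = FALSE)
  chromosome_of <- chromosome_of[genes]
  if (is.null(catalog)) catalog <- make_catalog(genes, chromosome_of)
  for (nm in names(planted_sets))
    if (!all(planted_sets[[nm]] %in% genes))
      stop("planted set '", nm, "' contains genes outside the universe",
           call. = FALSE)
  out <- list(s = s, chromosome_of = chromosome_of, catalog = catalog,
              planted_sets = planted_sets,
              burden_coefficient = burden_coefficient,
              noise_sd = noise_sd, baseline_rate = baseline_rate)
  class(out) <- "sim_truth"
  out
}

#' Build a barcode catalog for a set of genes
#'
#' @param genes Character vector of gene IDs.
#' @param chromosome_of Named chromosome assignment per gene.
#' @param centromere_adjacent Named logical per gene (default all `FALSE`).
#' @param multi_plasmid_genes Genes to represent with two barcodes each.
#' @param barcode_length Barcode sequence length.
#' @param seed Seed for barcode sequence generation.
#'
#' @return Data frame with columns `barcode_id`, `barcode_seq`, `gene_id`,
#'   `chromosome`, `centromere_adjacent`, `n_plasmids_for_gene`.
#' @export
make_catalog <- function(genes, chromosome_of,
                         centromere_adjacent = NULL,
                         multi_plasmid_genes = character(),
                         barcode_length = 20L,
                         seed = 0L) {
  if (is.null(centromere_adjacent)) {
    centromere_adjacent <- stats::setNames(rep(FALSE, length(genes)), genes)
  }
  gene_per_bc <- c(genes, multi_plasmid_genes)  # extra barcode for multis
  n_bc <- length(gene_per_bc)
  seqs <- random_barcodes(n_bc, barcode_length, seed)
  n_plasmids <- table(gene_per_bc)
  data.frame(
    barcode_id = sprintf("BC%05d", seq_len(n_bc)),
    barcode_seq = seqs,
    gene_id = gene_per_bc,
    chromosome = unname(chromosome_of[gene_per_bc]),
    centromere_adjacent = unname(centromere_adjacent[gene_per_bc]),
    n_plasmids_for_gene = as.integer(n_plasmids[gene_per_bc]),
    stringsAsFactors = FALSE
  )
}

random_barcodes <- function(n, len, seed) {
  # deterministic unique barcode sequences, independent of the caller's RNG
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  repeat {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
            collapse = ""), "")
    if (!anyDuplicated(seqs)) return(seqs)
  }
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Draw a ground truth from a simulation configuration
#'
#' Genes are split into a neutral majority, a deleterious tail and a
#' beneficial minority whose per-generation log2 effects apply in every
#' cellular context. On top of this, two context-specific sets are planted
#' among the neutral genes: `ssd1_sensitive` genes (effect exactly 0 in the
#' SSD1+ euploid; toxic in the ssd1-null euploid and in both aneuploid
#' contexts) and `aneuploid_beneficial` genes (beneficial only in ssd1-null
#' aneuploids). Genes are assigned uniformly to 16 chromosomes and a fraction
#' are flagged centromere-adjacent (dicentric plasmid).
#'
#' @param config A [sim_config()].
#' @return A [sim_truth()] object; deterministic given `config$seed`.
#' @examples
#' truth <- make_truth(sim_config(n_genes = 200, seed = 1,
#'   context_set_sizes = c(ssd1_sensitive = 10, aneuploid_beneficial = 5)))
#' table(truth$s[, "wt_euploid"] < 0)
#' @export
make_truth <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$seed)
  n_multi <- config$n_multi_plasmid_genes
  n_gene_ids <- config$n_genes - n_multi
  genes <- sprintf("G%05d", seq_len(n_gene_ids))
  chromosome_of <- stats::setNames(
    sample(paste0("chr", 1:16), n_gene_ids, replace = TRUE), genes)

  # baseline effects shared across contexts
  u <- stats::runif(n_gene_ids)
  s0 <- numeric(n_gene_ids)
  del <- u < config$frac_deleterious
  ben <- !del & u < config$frac_deleterious + config$frac_beneficial
  s0[del] <- -stats::rexp(sum(del), rate = 1 / config$effect_scale_deleterious)
  s0[ben] <- stats::rexp(sum(ben), rate = 1 / config$effect_scale_beneficial)
  s <- matrix(s0, n_gene_ids, length(CELL_CONTEXTS),
              dimnames = list(genes, CELL_CONTEXTS))

  sizes <- config$context_set_sizes
  neutral <- genes[s0 == 0]
  if (sum(sizes) > length(neutral))
    stop("not enough neutral genes to plant the context sets", call. = FALSE)
  planted <- list()
  if (!is.na(sizes["ssd1_sensitive"]) && sizes["ssd1_sensitive"] > 0) {
    set1 <- sample(neutral, sizes["ssd1_sensitive"])
    neutral <- setdiff(neutral, set1)
    s[set1, c("ssd1d_euploid", "wt_aneuploid", "ssd1d_aneuploid")] <-
      s[set1, c("ssd1d_euploid", "wt_aneuploid", "ssd1d_aneuploid")] -
      config$context_effect_toxic
    planted$ssd1_sensitive <- set1
  }
  if (!is.na(sizes["aneuploid_beneficial"]) && sizes["aneuploid_beneficial"] > 0) {
    set2 <- sample(neutral, sizes["aneuploid_beneficial"])
    s[set2, "ssd1d_aneuploid"] <- s[set2, "ssd1d_aneuploid"] +
      config$context_effect_beneficial
    planted$aneuploid_beneficial <- set2
  }

  cen <- stats::setNames(
    stats::runif(n_gene_ids) < config$frac_centromere_adjacent, genes)
  multi <- if (n_multi > 0) sample(genes, n_multi) else character()
  catalog <- make_catalog(genes, chromosome_of, cen, multi,
                          config$barcode_length, seed = config$seed)

  sim_truth(s, chromosome_of, catalog, planted,
            burden_coefficient = config$burden_coefficient,
            noise_sd = config$growth_noise_sd,
            baseline_rate = config$baseline_rate)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>", nrow(x$s), "genes,", nrow(x$catalog), "barcodes;",
      "planted sets:",
      if (length(x$planted_sets))
        paste(names(x$planted_sets), lengths(x$planted_sets),
              collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Write a ground truth to disk
#'
#' Emits `truth.tsv` (gene, chromosome, one effect column per context),
#' `catalog.tsv`, one `planted_<name>.tsv` per planted set, and a YAML
#' `manifest.yaml` recording scalar parameters.
#'
#' @param truth A [sim_truth()].
#' @param dir Output directory (created if needed).
#' @param config Optional [sim_config()] recorded in the manifest.
#' @return `dir`, invisibly.
#' @export
write_sim_truth <- function(truth, dir, config = NULL) {
  stopifnot(inherits(truth, "sim_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tt <- data.frame(gene_id = rownames(truth$s),
                   chromosome = unname(truth$chromosome_of),
                   truth$s, check.names = FALSE)
  utils::write.table(tt, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_catalog(truth$catalog, file.path(dir, "catalog.tsv"))
  for (nm in names(truth$planted_sets)) {
    utils::write.table(
      data.frame(set = nm, gene_id = truth$planted_sets[[nm]]),
      file.path(dir, paste0("planted_", nm, ".tsv")),
      sep = "\t", quote = FALSE, row.names = FALSE)
  }
  manifest <- list(
    burden_coefficient = truth$burden_coefficient,
    noise_sd = truth$noise_sd, baseline_rate = truth$baseline_rate,
    n_genes = nrow(truth$s), n_barcodes = nrow(truth$catalog))
  if (!is.null(config))
    manifest$config <- config[vapply(config, is.atomic, TRUE)]
  if (requireNamespace("yaml", quietly = TRUE)) {
    writeLines(yaml::as.yaml(manifest), file.path(dir, "manifest.yaml"))
  } else {
    dput(manifest, file.path(dir, "manifest.yaml"))
  }
  invisible(dir)
}
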