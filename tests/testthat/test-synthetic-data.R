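test_that("config validation rejects impossible settings", {
  expect_error(sim_config(frac_deleterious = 0.8, frac_beneficial = 0.5),
               "exceed 1")
  expect_error(sim_config(depth = 0), ">= 1")
  expect_error(sim_config(effect_scale_deleterious = -1), ">= 0")
  expect_error(sim_config(n_genes = 50,
                          context_set_sizes = c(ssd1_sensitive = 60)),
               "exceed")
})

test_that("null configuration yields an all-neutral truth", {
  cfg <- small_config(frac_deleterious = 0, frac_beneficial = 0,
                      context_set_sizes = c(ssd1_sensitive = 0L,
                                            aneuploid_beneficial = 0L))
  truth <- make_truth(cfg)
  expect_true(all(truth$s == 0))
  expect_length(truth$planted_sets, 0)
})

test_that("ground truth is deterministic given the seed", {
  t1 <- make_truth(small_config())
  t2 <- make_truth(small_config())
  expect_identical(t1, t2)
  s1 <- simulate_pool(t1, strain_context("wt", "SSD1+"), small_config())
  s2 <- simulate_pool(t2, strain_context("wt", "SSD1+"), small_config())
  expect_identical(s1$counts, s2$counts)
})

test_that("planted ssd1-sensitive genes are context-specific", {
  cfg <- small_config(n_genes = 600L,
                      context_set_sizes = c(ssd1_sensitive = 100L,
                                            aneuploid_beneficial = 0L))
  truth <- make_truth(cfg)
  set1 <- truth$planted_sets$ssd1_sensitive
  expect_length(set1, 100)
  expect_true(all(truth$s[set1, "ssd1d_euploid"] < 0))
  expect_true(all(truth$s[set1, "wt_aneuploid"] < 0))
  expect_true(all(abs(truth$s[set1, "wt_euploid"]) < 1e-12))
  # planted count equals the number of genes negative in ssd1d euploid but
  # neutral in wild-type euploid among otherwise-neutral genes
  flag <- truth$s[, "ssd1d_euploid"] < 0 & abs(truth$s[, "wt_euploid"]) < 1e-12
  expect_identical(sum(flag), 100L)
})

test_that("every gene sits on exactly one of 16 chromosomes", {
  truth <- make_truth(small_config(n_genes = 2000L))
  expect_setequal(names(truth$chromosome_of), rownames(truth$s))
  expect_true(all(truth$chromosome_of %in% paste0("chr", 1:16)))
})

test_that("relative abundances stay normalized through growth", {
  set.seed(42)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    p0 <- rexp(n); p0 <- p0 / sum(p0)
    s <- rnorm(n, 0, 0.2)
    pG <- aneuscreen:::evolve_abundance(p0, s, sample(1:12, 1))
    expect_equal(sum(pG), 1, tolerance = 1e-12)
    expect_true(all(pG >= 0))
  }
})

test_that("a neutral pool drifts nowhere on average", {
  cfg <- small_config(n_genes = 100L, depth = 2e5, replicates = 6L,
                      n_stocks = 6L, frac_deleterious = 0,
                      frac_beneficial = 0, stock_sd = 0, rep_sd = 0,
                      context_set_sizes = c(ssd1_sensitive = 0L,
                                            aneuploid_beneficial = 0L))
  truth <- make_truth(cfg)
  sim <- simulate_pool(truth, strain_context("wt", "SSD1+"), cfg)
  res <- score_experiment(sim$counts, sim$sheet, truth$catalog)
  expect_lt(abs(mean(res$table$score)), 0.03)
})

test_that("a rare beneficial lineage gains G*s log2 units", {
  # one gene at s = +0.1 among neutral genes: expected logFC ~ G*s = 1
  n <- 2000L
  genes <- sprintf("G%05d", 1:n)
  s <- matrix(0, n, 4, dimnames = list(genes, CELL_CONTEXTS))
  s[1, ] <- 0.1
  truth <- sim_truth(s)
  cfg <- sim_config(n_genes = n, depth = 1e6, replicates = 8L, n_stocks = 8L,
                    seed = 7L, stock_sd = 0, rep_sd = 0, init_sd = 0,
                    frac_deleterious = 0, frac_beneficial = 0,
                    context_set_sizes = c(ssd1_sensitive = 0L,
                                          aneuploid_beneficial = 0L))
  sim <- simulate_pool(truth, strain_context("wt", "SSD1+"), cfg)
  m <- add_pseudocount(sim$counts)
  fs <- fitness_scores(m, NULL, sim$sheet, truth$catalog)
  expect_equal(unname(fs$wt$score["G00001"]), 1.0, tolerance = 0.05)
})

test_that("dicentric plasmids lose G*loss log2 units in aneuploids only", {
  n <- 1000L
  genes <- sprintf("G%05d", 1:n)
  s <- matrix(0, n, 4, dimnames = list(genes, CELL_CONTEXTS))
  chr <- setNames(paste0("chr", rep_len(1:16, n)), genes)
  cen <- setNames(c(TRUE, rep(FALSE, n - 1)), genes)
  catalog <- make_catalog(genes, chr, cen)
  truth <- sim_truth(s, chr, catalog)
  cfg <- sim_config(n_genes = n, depth = 1e6, replicates = 8L, n_stocks = 8L,
                    seed = 9L, stock_sd = 0, rep_sd = 0, init_sd = 0,
                    dicentric_loss = 0.15,
                    context_set_sizes = c(ssd1_sensitive = 0L,
                                          aneuploid_beneficial = 0L))
  an <- simulate_pool(truth, strain_context("an", "SSD1+", "chr3"), cfg)
  fs <- fitness_scores(add_pseudocount(an$counts), NULL, an$sheet,
                       truth$catalog)
  expect_equal(unname(fs$an$score["G00001"]), -10 * 0.15, tolerance = 0.08)
  # no penalty in the euploid
  eu <- simulate_pool(truth, strain_context("eu", "SSD1+"), cfg)
  fe <- fitness_scores(add_pseudocount(eu$counts), NULL, eu$sheet,
                       truth$catalog)
  expect_lt(abs(fe$eu$score["G00001"]), 0.08)
})

test_that("doubling depth reduces logFC sampling error", {
  truth <- uniform_truth(400, seed = 3)
  mse <- sapply(c(5e4, 1e5, 2e5, 4e5), function(d) {
    cfg <- sim_config(n_genes = 400L, depth = d, replicates = 2L,
                      n_stocks = 2L, seed = 13L, stock_sd = 0, rep_sd = 0,
                      context_set_sizes = c(ssd1_sensitive = 0L,
                                            aneuploid_beneficial = 0L))
    sim <- simulate_pool(truth, strain_context("wt", "SSD1+"), cfg)
    fs <- fitness_scores(add_pseudocount(sim$counts), NULL, sim$sheet,
                         truth$catalog)
    shift <- mean(fs$wt$score - 10 * truth$s[names(fs$wt$score), "wt_euploid"])
    median((fs$wt$score - 10 * truth$s[names(fs$wt$score), "wt_euploid"] -
              shift)^2)
  })
  expect_true(all(diff(mse) < 0))
})

test_that("growth rates follow the additive-burden model", {
  truth <- make_truth(small_config(n_genes = 800L))
  contexts <- four_strains("chr2")
  # noiseless: relative rate is exactly 1 + c * sum(s)
  truth0 <- truth; truth0$noise_sd <- 0
  gr <- simulate_growth_rates(truth0, contexts, n_reps = 2, seed = 5)
  eu <- gr[gr$strain_id == "wt_eu", ]
  expect_true(all(eu$relative_rate == 1))
  an <- gr[gr$strain_id == "wt_chr2", ]
  on_chr <- names(truth$chromosome_of)[truth$chromosome_of == "chr2"]
  expect_equal(unique(an$relative_rate),
               1 + truth$burden_coefficient * sum(truth$s[on_chr,
                                                          "wt_aneuploid"]))
  # zero coefficient and zero noise: everything at baseline
  truth00 <- truth0; truth00$burden_coefficient <- 0
  gr0 <- simulate_growth_rates(truth00, contexts, n_reps = 2, seed = 5)
  expect_true(all(gr0$relative_rate == 1))
})

test_that("truth serialization writes the promised files", {
  truth <- make_truth(small_config(n_genes = 100L,
                                   context_set_sizes =
                                     c(ssd1_sensitive = 5L,
                                       aneuploid_beneficial = 3L)))
  d <- tempfile()
  write_sim_truth(truth, d, config = small_config())
  expect_true(file.exists(file.path(d, "truth.tsv")))
  expect_true(file.exists(file.path(d, "catalog.tsv")))
  expect_true(file.exists(file.path(d, "manifest.yaml")))
  tt <- read.delim(file.path(d, "truth.tsv"), check.names = FALSE)
  expect_equal(tt$gene_id, rownames(truth$s))
  expect_equal(tt[["ssd1d_euploid"]], unname(truth$s[, "ssd1d_euploid"]))
})
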