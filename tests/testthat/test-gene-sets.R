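test_that("detrimental rule applies score, FDR and margin thresholds", {
  fit <- toy_fitness(
    list("g1", "focal", -2.0, 0.01), list("g1", "ref", 0.0, 0.5),
    list("g2", "focal", -2.0, 0.01), list("g2", "ref", -1.0, 0.5),
    list("g3", "focal", -2.0, 0.20), list("g3", "ref", 0.5, 0.5),
    list("g4", "focal", 0.5, 0.01), list("g4", "ref", 2.5, 0.5))
  gs <- call_detrimental_in_focal(fit, "focal", "ref")
  expect_identical(gs$genes, "g1")      # g2: margin 1.0 < 1.5; g3: FDR;
                                        # g4: positive score
  # union over multiple references with provenance
  fit2 <- rbind(fit, toy_fitness(list("g2", "ref2", 0.8, 0.5),
                                 list("g1", "ref2", -2.0, 0.5),
                                 list("g3", "ref2", 0, 0.5),
                                 list("g4", "ref2", 0, 0.5)))
  gs2 <- call_detrimental_in_focal(fit2, "focal", c("ref", "ref2"))
  expect_setequal(gs2$genes, c("g1", "g2"))
  expect_setequal(gs2$provenance$reference[gs2$provenance$gene == "g1"],
                  "ref")
})

test_that("ameliorated rule is the sign-mirror of the detrimental rule", {
  fit <- toy_fitness(
    list("g1", "eu", -2.0, 0.01), list("g1", "an", 0.0, 0.5),
    list("g2", "eu", -2.0, 0.01), list("g2", "an", -1.0, 0.5),
    list("g3", "eu", -0.5, 0.20), list("g3", "an", 1.5, 0.5))
  gs <- call_ameliorated_in_aneuploid(fit, "eu", "an")
  expect_identical(gs$genes, "g1")
})

test_that("raising the margin threshold never grows a called set", {
  set.seed(6)
  genes <- sprintf("g%03d", 1:200)
  fit <- rbind(
    data.frame(gene = genes, strain = "focal",
               score = rnorm(200, -0.5, 1), fdr = runif(200, 0, 0.1)),
    data.frame(gene = genes, strain = "ref",
               score = rnorm(200, 0, 1), fdr = runif(200)))
  prev <- NULL
  for (d in c(0, 0.5, 1, 1.5, 2)) {
    cur <- call_detrimental_in_focal(fit, "focal", "ref",
                                     delta_threshold = d)$genes
    if (!is.null(prev)) expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("ssd1-sensitive calls require negative contrast and low FDR", {
  ct <- data.frame(gene = c("g1", "g2", "g3"),
                   contrast = c(-1.5, 1.5, -1.5),
                   fdr = c(0.01, 0.001, 0.2))
  expect_identical(call_ssd1_sensitive(ct)$genes, "g1")
})

test_that("ssd1-sensitive contrast is calibrated and powered", {
  set.seed(77)
  # null: no planted difference -> false-positive fraction <= 7%
  fp <- replicate(10, {
    a <- matrix(rnorm(300 * 7, 0, 0.3), 300, 7,
                dimnames = list(sprintf("g%03d", 1:300), NULL))
    b <- matrix(rnorm(300 * 7, 0, 0.3), 300, 7,
                dimnames = list(sprintf("g%03d", 1:300), NULL))
    length(call_ssd1_sensitive(test_differential(a, "contrast",
                                                 y = b))$genes) / 300
  })
  expect_lte(mean(fp), 0.07)
  # planted -1.5 contrast, 7 vs 7 replicates: power >= 0.9
  pow <- replicate(20, {
    a <- matrix(rnorm(300 * 7, 0, 0.3), 300, 7,
                dimnames = list(sprintf("g%03d", 1:300), NULL))
    b <- matrix(rnorm(300 * 7, 0, 0.3), 300, 7,
                dimnames = list(sprintf("g%03d", 1:300), NULL))
    a[1:15, ] <- a[1:15, ] - 1.5
    hits <- call_ssd1_sensitive(test_differential(a, "contrast", y = b))
    mean(sprintf("g%03d", 1:15) %in% hits$genes)
  })
  expect_gte(mean(pow), 0.9)
})

test_that("beneficial rule honors strict margins, relaxed mode and 'if available'", {
  fit <- toy_fitness(
    list("g1", "focal", 0.6, 0.01), list("g1", "wt_eu", 0.0, 0.5),
    list("g1", "mu_eu", 0.05, 0.5), list("g1", "wt_an", 0.1, 0.5),
    list("g2", "focal", 0.6, 0.01), list("g2", "wt_eu", 0.3, 0.5),
    list("g2", "mu_eu", 0.0, 0.5), list("g2", "wt_an", 0.0, 0.5))
  strict <- call_beneficial_in_ssd1_aneuploid(fit, "focal", "wt_eu",
                                              "mu_eu", "wt_an")
  relaxed <- call_beneficial_in_ssd1_aneuploid(fit, "focal", "wt_eu",
                                               "mu_eu", "wt_an",
                                               relaxed = TRUE)
  expect_identical(strict$genes, "g1")          # g2 margin 0.3 < 0.5
  expect_setequal(relaxed$genes, c("g1", "g2"))
  expect_true(all(strict$genes %in% relaxed$genes))
  # missing wild-type aneuploid is silently skipped
  no_an <- call_beneficial_in_ssd1_aneuploid(fit, "focal", "wt_eu", "mu_eu",
                                             wt_aneuploid = NA)
  expect_setequal(no_an$genes, "g1")
  # a required euploid reference must exist
  expect_error(call_beneficial_in_ssd1_aneuploid(fit, "focal", "absent",
                                                 "mu_eu"), "absent")
})

test_that("strict beneficial sets are subsets of relaxed sets", {
  set.seed(17)
  genes <- sprintf("g%03d", 1:150)
  fit <- do.call(rbind, lapply(c("focal", "wt_eu", "mu_eu", "wt_an"),
    function(st) data.frame(gene = genes, strain = st,
                            score = rnorm(150, 0, 0.8),
                            fdr = runif(150, 0, 0.2))))
  strict <- call_beneficial_in_ssd1_aneuploid(fit, "focal", "wt_eu",
                                              "mu_eu", "wt_an")
  relaxed <- call_beneficial_in_ssd1_aneuploid(fit, "focal", "wt_eu",
                                               "mu_eu", "wt_an",
                                               relaxed = TRUE)
  expect_true(all(strict$genes %in% relaxed$genes))
})

test_that("set overlaps match brute-force enumeration", {
  a <- gene_set("A", c("g1", "g2", "g3"))
  b <- gene_set("B", c("g3", "g4"))
  ov <- overlap_sets(list(A = a, B = b))
  expect_equal(unname(ov$regions["A"]), 2)      # g1, g2
  expect_equal(unname(ov$regions["B"]), 1)      # g4
  expect_equal(unname(ov$regions["A&B"]), 1)    # g3
  # disjoint and identical
  expect_equal(unname(overlap_sets(list(A = c("x"), B = c("y")))$regions),
               c(1, 1, 0))
  expect_equal(unname(overlap_sets(list(A = c("x", "y"),
                                        B = c("x", "y")))$regions),
               c(0, 0, 2))
  # random 3 sets against direct enumeration
  set.seed(30)
  univ <- sprintf("g%02d", 1:30)
  sets <- list(A = sample(univ, 12), B = sample(univ, 8),
               C = sample(univ, 15))
  ov3 <- overlap_sets(sets)
  for (g in unique(unlist(sets))) {
    inc <- vapply(sets, function(s) g %in% s, TRUE)
    region <- paste(names(sets)[inc], collapse = "&")
    expect_true(ov3$regions[region] >= 1)
  }
  expect_equal(sum(ov3$regions), length(unique(unlist(sets))))
})

test_that("set tallies count per-gene membership across strains", {
  sets <- list(gene_set("s1", c("a", "b")), gene_set("s2", c("b", "c")),
               gene_set("s3", c("b")))
  tl <- set_tally(sets)
  expect_equal(tl$n_sets[tl$gene == "b"], 3L)
  expect_equal(tl$n_sets[tl$gene == "a"], 1L)
})

test_that("hypergeometric p equals exhaustive enumeration", {
  # k = 0 is certain
  expect_equal(hypergeometric_enrichment(
    character(), list(cat = c("g1")), c("g1", "g2"))$p_value, 1)
  # N=20, K=5, n=6, k=3 against enumeration of all C(20,6) draws
  univ <- sprintf("g%02d", 1:20)
  categories <- list(cat = univ[1:5])
  set <- c(univ[1:3], univ[10:12])
  res <- hypergeometric_enrichment(set, categories, univ)
  expect_equal(res$p_value, oracle_hyper_tail(20, 5, 6, 3),
               tolerance = 1e-12)
  # entire set inside the category
  res2 <- hypergeometric_enrichment(univ[1:4], list(cat = univ[1:4]), univ)
  expect_equal(res2$p_value, oracle_hyper_tail(20, 4, 4, 4),
               tolerance = 1e-12)
  expect_equal(res2$p_value, 1 / choose(20, 4), tolerance = 1e-12)
})

test_that("enrichment p-values are invariant to gene relabeling", {
  set.seed(12)
  univ <- sprintf("g%02d", 1:40)
  categories <- list(c1 = sample(univ, 10), c2 = sample(univ, 5))
  set <- sample(univ, 8)
  p1 <- hypergeometric_enrichment(set, categories, univ)$p_value
  # permute labels consistently
  perm <- setNames(sample(univ), univ)
  p2 <- hypergeometric_enrichment(unname(perm[set]),
                                  lapply(categories, function(x)
                                    unname(perm[x])),
                                  unname(perm[univ]))$p_value
  expect_equal(p1, p2)
})

test_that("gene sets round-trip through TSV", {
  sets <- list(gene_set("alpha", c("g2", "g1")), gene_set("beta", "g3"))
  p <- tempfile()
  write_gene_sets(sets, p)
  rt <- read_gene_sets(p)
  expect_setequal(rt$alpha$genes, c("g1", "g2"))
  expect_identical(rt$beta$genes, "g3")
})
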