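# Shared small fixtures, generated in code.

small_config <- function(...) {
  defaults <- list(n_genes = 300L, depth = 1e5, replicates = 3L, seed = 101L,
                   context_set_sizes = c(ssd1_sensitive = 20L,
                                         aneuploid_beneficial = 10L))
  args <- utils::modifyList(defaults, list(...))
  do.call(sim_config, args)
}

four_strains <- function(chr = "chr5") {
  list(wt_eu = strain_context("wt_eu", "SSD1+"),
       ssd1d_eu = strain_context("ssd1d_eu", "ssd1d"),
       wt_an = strain_context(paste0("wt_", chr), "SSD1+", chr),
       ssd1d_an = strain_context(paste0("ssd1d_", chr), "ssd1d", chr))
}

# hand-built long fitness table for rule tests
toy_fitness <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(gene = r[[1]], strain = r[[2]], score = as.numeric(r[[3]]),
               fdr = as.numeric(r[[4]]), stringsAsFactors = FALSE)))
}

# a uniform-effect truth with all noise in the sampling step
uniform_truth <- function(n_genes, lo = -0.25, hi = 0.05, seed = 1) {
  set.seed(seed)
  genes <- sprintf("G%05d", seq_len(n_genes))
  s <- matrix(runif(n_genes, lo, hi), n_genes, 4,
              dimnames = list(genes, CELL_CONTEXTS))
  sim_truth(s)
}

write_tiny_fastq <- function(reads, path = tempfile(fileext = ".fastq")) {
  lines <- unlist(lapply(seq_along(reads), function(i)
    c(paste0("@read", i), reads[i], "+", strrep("I", nchar(reads[i])))))
  writeLines(as.character(lines), path)
  path
}
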