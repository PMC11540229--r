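#' Gene-set objects
#'
#' A named set of gene IDs with provenance: which focal/reference comparison
#' admitted each member.
#'
#' @param name Set name.
#' @param genes Character vector of member gene IDs (deduplicated).
#' @param provenance Optional data frame (`gene`, `reference`) recording
#'   which reference strain(s) satisfied the rule for each gene.
#' @return Object of class `gene_set`.
#' @export
gene_set <- function(name, genes, provenance = NULL) {
  out <- list(name = name, genes = sort(unique(genes)),
              provenance = provenance)
  class(out) <- "gene_set"
  out
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set>", x$name, ":", length(x$genes), "genes\n")
  invisible(x)
}

strain_slice <- function(fitness, strain) {
  sl <- fitness[fitness$strain == strain, ]
  if (nrow(sl) == 0) stop("strain not in fitness table: ", strain,
                          call. = FALSE)
  sl
}

shared_universe <- function(fitness, strains) {
  sets <- lapply(strains, function(st) strain_slice(fitness, st)$gene)
  universe <- Reduce(intersect, sets)
  dropped <- setdiff(unique(unlist(sets)), universe)
  list(universe = universe, dropped = dropped)
}

lookup <- function(slice, genes, col) {
  stats::setNames(slice[[col]], slice$gene)[genes]
}

#' Genes more detrimental in a focal strain than in reference strain(s)
#'
#' Calls genes with a negative fitness score in the focal strain at
#' FDR below threshold whose score is more than `delta_threshold` lower
#' (in log2 units) than in at least one reference strain. With multiple
#' references the result is the union, with per-gene provenance.
#'
#' @param fitness Long fitness table (columns `gene`, `strain`, `score`,
#'   `fdr`), e.g. `score_experiment()$table`.
#' @param focal Focal strain ID.
#' @param references Character vector of reference strain IDs.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param delta_threshold Required score difference (default 1.5).
#' @param name Set name.
#' @return A [gene_set()]; attribute `dropped` lists genes absent from some
#'   strain (excluded from the universe).
#' @export
call_detrimental_in_focal <- function(fitness, focal, references,
                                      fdr_threshold = 0.05,
                                      delta_threshold = 1.5,
                                      name = paste0("detrimental_in_",
                                                    focal)) {
  stopifnot(delta_threshold >= 0, !focal %in% references)
  su <- shared_universe(fitness, c(focal, references))
  fo <- strain_slice(fitness, focal)
  f_sc <- lookup(fo, su$universe, "score")
  f_fdr <- lookup(fo, su$universe, "fdr")
  base <- f_sc < 0 & f_fdr < fdr_threshold
  prov <- list()
  for (ref in references) {
    r_sc <- lookup(strain_slice(fitness, ref), su$universe, "score")
    hit <- base & (r_sc - f_sc) > delta_threshold
    if (any(hit))
      prov[[ref]] <- data.frame(gene = su$universe[hit], reference = ref,
                                stringsAsFactors = FALSE)
  }
  prov <- do.call(rbind, c(prov, make.row.names = FALSE))
  gs <- gene_set(name, if (is.null(prov)) character() else prov$gene, prov)
  attr(gs, "dropped") <- su$dropped
  gs
}

#' Genes deleterious in the euploid but ameliorated in aneuploid(s)
#'
#' Mirror rule: genes with a negative score at FDR below threshold in the
#' euploid whose score is more than `delta_threshold` higher (less
#' deleterious) in one or more aneuploid strains.
#'
#' @inheritParams call_detrimental_in_focal
#' @param euploid Euploid strain ID (where the gene must be deleterious).
#' @param aneuploids Aneuploid strain IDs (where it must be ameliorated).
#' @return A [gene_set()].
#' @export
call_ameliorated_in_aneuploid <- function(fitness, euploid, aneuploids,
                                          fdr_threshold = 0.05,
                                          delta_threshold = 1.5,
                                          name = "ameliorated_in_aneuploid") {
  stopifnot(delta_threshold >= 0, !euploid %in% aneuploids)
  su <- shared_universe(fitness, c(euploid, aneuploids))
  eu <- strain_slice(fitness, euploid)
  e_sc <- lookup(eu, su$universe, "score")
  e_fdr <- lookup(eu, su$universe, "fdr")
  base <- e_sc < 0 & e_fdr < fdr_threshold
  prov <- list()
  for (an in aneuploids) {
    a_sc <- lookup(strain_slice(fitness, an), su$universe, "score")
    hit <- base & (a_sc - e_sc) > delta_threshold
    if (any(hit))
      prov[[an]] <- data.frame(gene = su$universe[hit], reference = an,
                               stringsAsFactors = FALSE)
  }
  prov <- do.call(rbind, c(prov, make.row.names = FALSE))
  gs <- gene_set(name, if (is.null(prov)) character() else prov$gene, prov)
  attr(gs, "dropped") <- su$dropped
  gs
}

#' Genes significantly more detrimental in the ssd1-null euploid
#'
#' Takes the result of a contrast-mode [test_differential()] between the
#' ssd1-null euploid and the wild-type euploid and returns the genes whose
#' contrast (ssd1-null minus wild type) is negative at FDR below threshold.
#' A gene more deleterious in the wild type is excluded regardless of FDR.
#'
#' @param contrast Data frame from `test_differential(..., mode="contrast")`
#'   with the ssd1-null strain as `x`.
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param name Set name.
#' @return A [gene_set()].
#' @export
call_ssd1_sensitive <- function(contrast, fdr_threshold = 0.05,
                                name = "ssd1_sensitive") {
  stopifnot(all(c("gene", "contrast", "fdr") %in% names(contrast)))
  gene_set(name,
           contrast$gene[contrast$contrast < 0 &
                         contrast$fdr < fdr_threshold])
}

#' Genes beneficial in an ssd1-null aneuploid relative to reference strains
#'
#' Strict mode requires a significantly beneficial effect in the focal
#' strain (score > 0, FDR below threshold) and a score at least
#' `delta_threshold` higher than in every available reference: the wild-type
#' euploid, the ssd1-null euploid, and the corresponding wild-type aneuploid
#' when one exists. Relaxed ("commonly beneficial") mode drops the magnitude
#' requirement, asking only for a strictly higher score than each reference.
#'
#' @param fitness Long fitness table.
#' @param focal Focal ssd1-null aneuploid strain ID.
#' @param wt_euploid,ssd1d_euploid Required reference strain IDs.
#' @param wt_aneuploid Corresponding wild-type aneuploid strain ID, or `NA`
#'   when no such strain exists (silently skipped).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @param delta_threshold Required margin in strict mode (default 0.5).
#' @param relaxed Use the relaxed rule.
#' @param name Set name.
#' @return A [gene_set()].
#' @export
call_beneficial_in_ssd1_aneuploid <- function(fitness, focal,
                                              wt_euploid, ssd1d_euploid,
                                              wt_aneuploid = NA,
                                              fdr_threshold = 0.05,
                                              delta_threshold = 0.5,
                                              relaxed = FALSE,
                                              name = paste0("beneficial_in_",
                                                            focal)) {
  refs <- c(wt_euploid, ssd1d_euploid)
  if (!is.na(wt_aneuploid)) refs <- c(refs, wt_aneuploid)
  su <- shared_universe(fitness, c(focal, refs))
  fo <- strain_slice(fitness, focal)
  f_sc <- lookup(fo, su$universe, "score")
  f_fdr <- lookup(fo, su$universe, "fdr")
  ok <- f_sc > 0 & f_fdr < fdr_threshold
  for (ref in refs) {
    r_sc <- lookup(strain_slice(fitness, ref), su$universe, "score")
    ok <- ok & if (relaxed) f_sc > r_sc else (f_sc - r_sc) >= delta_threshold
  }
  gs <- gene_set(name, su$universe[ok])
  attr(gs, "dropped") <- su$dropped
  gs
}

#' Tally in how many sets each gene appears
#'
#' Used for "beneficial in at least k ssd1-null aneuploids" summaries.
#'
#' @param sets List of [gene_set()] objects.
#' @return Data frame `gene`, `n_sets`, sorted by decreasing `n_sets`.
#' @export
set_tally <- function(sets) {
  genes <- unlist(lapply(sets, `[[`, "genes"))
  if (length(genes) == 0)
    return(data.frame(gene = character(), n_sets = integer()))
  tab <- sort(table(genes), decreasing = TRUE)
  data.frame(gene = names(tab), n_sets = as.integer(tab),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Membership table and exclusive region counts for a list of sets
#'
#' @param sets Named list of [gene_set()] objects (or character vectors).
#' @return List with `membership` (logical matrix, genes x sets) and
#'   `regions` (named counts of every exclusive region of the Venn diagram,
#'   names like `"A&B"`, in deterministic order).
#' @export
overlap_sets <- function(sets) {
  sets <- lapply(sets, function(s) if (inherits(s, "gene_set")) s$genes else s)
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- LETTERS[seq_along(sets)]
  genes <- sort(unique(unlist(sets)))
  membership <- vapply(sets, function(s) genes %in% s,
                       logical(length(genes)))
  if (length(genes) == 1) membership <- matrix(membership, nrow = 1,
                                               dimnames = list(genes,
                                                               names(sets)))
  rownames(membership) <- genes
  k <- length(sets)
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(combos) <- names(sets)
  regions <- apply(combos, 1, function(inc) {
    sum(apply(membership, 1, function(row) all(row == inc)))
  })
  names(regions) <- apply(combos, 1, function(inc)
    paste(names(sets)[as.logical(inc)], collapse = "&"))
  list(membership = membership, regions = regions)
}

#' Hypergeometric enrichment of a gene set in categories
#'
#' For each category, tests over-representation of the set among category
#' members with the upper-tail hypergeometric probability
#' `P(X >= k)`, `X ~ Hypergeom(N, K, n)`, against a background universe of
#' all measured genes; BH correction across categories.
#'
#' @param set Character vector (or [gene_set()]) of genes, a subset of
#'   `universe`.
#' @param categories Named list of character vectors, subsets of `universe`.
#' @param universe Character vector of all measured genes.
#' @return Data frame: `category`, `overlap` (k), `set_size` (n),
#'   `category_size` (K), `universe_size` (N), `p_value`, `fdr`.
#' @export
hypergeometric_enrichment <- function(set, categories, universe) {
  if (inherits(set, "gene_set")) set <- set$genes
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (!all(set %in% universe))
    stop("set contains genes outside the universe", call. = FALSE)
  n <- length(set); N <- length(universe)
  res <- lapply(names(categories), function(nm) {
    cat_genes <- intersect(categories[[nm]], universe)
    K <- length(cat_genes)
    k <- length(intersect(set, cat_genes))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(category = nm, overlap = k, set_size = n, category_size = K,
               universe_size = N, p_value = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(res, make.row.names = FALSE))
  res$fdr <- stats::p.adjust(res$p_value, method = "BH")
  res
}

#' Read and write gene sets as two-column TSV
#'
#' @param sets List of [gene_set()] objects.
#' @param path File path (`set`, `gene` columns).
#' @return `write_gene_sets` returns `path` invisibly; `read_gene_sets` a
#'   named list of [gene_set()] objects.
#' @export
write_gene_sets <- function(sets, path) {
  df <- do.call(rbind, lapply(sets, function(s)
    data.frame(set = s$name, gene = s$genes, stringsAsFactors = FALSE)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gene_sets
#' @export
read_gene_sets <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("set", "gene") %in% names(df)))
  parts <- split(df$gene, df$set)
  Map(gene_set, names(parts), parts)
}
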