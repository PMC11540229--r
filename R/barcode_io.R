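#' Read and write barcode count matrices
#'
#' Count matrices are TSV files whose first column (`barcode_id`) holds
#' unique barcode identifiers and whose remaining columns hold non-negative
#' integer counts, one column per sample. `read_count_matrix(write_count_matrix(x))`
#' round-trips exactly.
#'
#' @param counts Integer matrix with barcode row names and sample column
#'   names.
#' @param path File path.
#' @return `write_count_matrix` returns `path` invisibly;
#'   `read_count_matrix` returns the validated integer matrix.
#' @export
write_count_matrix <- function(counts, path) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)))
  df <- data.frame(barcode_id = rownames(counts), counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "barcode_id")
    stop("count matrix must start with a 'barcode_id' column", call. = FALSE)
  if (anyDuplicated(df$barcode_id))
    stop("duplicated barcode IDs in count matrix: ",
         paste(unique(df$barcode_id[duplicated(df$barcode_id)]),
               collapse = ", "), call. = FALSE)
  m <- as.matrix(df[-1])
  if (!is.numeric(m) || any(is.na(m)) || any(m < 0) || any(m != round(m)))
    stop("counts must be complete non-negative integers", call. = FALSE)
  storage.mode(m) <- "integer"
  rownames(m) <- df$barcode_id
  m
}

SAMPLE_SHEET_COLS <- c("sample_id", "strain_id", "background",
                       "amplified_chromosome", "generation", "replicate",
                       "batch", "stock")

#' Read and write sample sheets
#'
#' A sample sheet has one row per count-matrix column with columns
#' `sample_id`, `strain_id`, `background` (`SSD1+` or `ssd1d`),
#' `amplified_chromosome` (`NA` for euploid), `generation` (0 or the final
#' generation), `replicate`, `batch` and `stock` (transformation stock).
#'
#' @param sheet Sample-sheet data frame.
#' @param path File path.
#' @return `write_sample_sheet` returns `path` invisibly;
#'   `read_sample_sheet` the validated data frame.
#' @export
write_sample_sheet <- function(sheet, path) {
  stopifnot(all(SAMPLE_SHEET_COLS %in% names(sheet)))
  utils::write.table(sheet[SAMPLE_SHEET_COLS], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_sheet
#' @export
read_sample_sheet <- function(path) {
  sheet <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(SAMPLE_SHEET_COLS, names(sheet))
  if (length(missing))
    stop("sample sheet missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(sheet$sample_id))
    stop("duplicated sample IDs in sample sheet", call. = FALSE)
  if (!all(sheet$background %in% c("SSD1+", "ssd1d")))
    stop("background must be 'SSD1+' or 'ssd1d'", call. = FALSE)
  sheet$amplified_chromosome <- as.character(sheet$amplified_chromosome)
  sheet
}

#' Read and write barcode catalogs
#'
#' A catalog maps each barcode sequence to a gene, each gene to a chromosome,
#' and flags centromere-adjacent (dicentric) plasmids and genes cloned on
#' multiple plasmids.
#'
#' @param catalog Catalog data frame (see [make_catalog()]).
#' @param path File path.
#' @return `write_catalog` returns `path` invisibly; `read_catalog` the
#'   validated data frame.
#' @export
write_catalog <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  cat <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_catalog(cat)
}

validate_catalog <- function(cat) {
  req <- c("barcode_id", "barcode_seq", "gene_id", "chromosome",
           "centromere_adjacent", "n_plasmids_for_gene")
  missing <- setdiff(req, names(cat))
  if (length(missing))
    stop("catalog missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(cat$barcode_id))
    stop("duplicated barcode IDs in catalog", call. = FALSE)
  if (anyDuplicated(cat$barcode_seq))
    stop("duplicated barcode sequences in catalog: ",
         paste(unique(cat$barcode_seq[duplicated(cat$barcode_seq)]),
               collapse = ", "), call. = FALSE)
  if (length(unique(nchar(cat$barcode_seq))) != 1)
    stop("catalog barcodes must all have the same length", call. = FALSE)
  if (any(grepl("[^ACGT]", cat$barcode_seq)))
    stop("barcode sequences must be uppercase ACGT", call. = FALSE)
  # n_plasmids_for_gene must agree with the barcode-per-gene tally
  tally <- table(cat$gene_id)
  if (any(cat$n_plasmids_for_gene != as.integer(tally[cat$gene_id])))
    stop("n_plasmids_for_gene inconsistent with barcode-to-gene mapping",
         call. = FALSE)
  cat$centromere_adjacent <- as.logical(cat$centromere_adjacent)
  cat
}

#' Validate that a count matrix and sample sheet describe one experiment
#'
#' Checks that every matrix column has exactly one sample-sheet row and that
#' every generation-G sample's transformation stock has a generation-0
#' sample.
#'
#' @param counts Count matrix.
#' @param sheet Sample sheet.
#' @return Invisibly `TRUE`; errors name the offending sample.
#' @export
validate_experiment <- function(counts, sheet) {
  orphan <- setdiff(colnames(counts), sheet$sample_id)
  if (length(orphan))
    stop("count-matrix column(s) missing from sample sheet: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  extra <- setdiff(sheet$sample_id, colnames(counts))
  if (length(extra))
    stop("sample-sheet row(s) missing from count matrix: ",
         paste(extra, collapse = ", "), call. = FALSE)
  grown <- sheet[sheet$generation > 0, ]
  g0 <- sheet[sheet$generation == 0, ]
  bad <- !grown$stock %in% g0$stock
  if (any(bad))
    stop("generation-G sample(s) without a generation-0 sample of the same ",
         "stock: ", paste(grown$sample_id[bad], collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}
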