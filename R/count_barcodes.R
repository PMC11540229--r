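#' Count exact barcode matches in a FASTQ file
#'
#' Extracts the barcode window from every read and increments a barcode's
#' count iff the extracted substring exactly equals that barcode's sequence;
#' no mismatch rescue is attempted. Reads whose window matches no catalog
#' barcode are tallied as unmatched. The barcode position within the read is
#' library-prep specific and must be supplied.
#'
#' @param fastq Path to a FASTQ file (plain or gzipped).
#' @param catalog Barcode catalog (see [read_catalog()]).
#' @param barcode_start 1-based offset of the barcode within the read.
#' @param barcode_length Barcode length; must equal the catalog's barcode
#'   length.
#' @return List with `counts` (named integer vector per `barcode_id`),
#'   `total_reads`, `matched_reads` and `match_rate` (0 when no reads).
#' @examples
#' \donttest{
#' cat <- make_catalog(c("G1", "G2"), c(G1 = "chr1", G2 = "chr2"),
#'                     barcode_length = 6)
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", paste0(cat$barcode_seq[1], "ACGT"), "+",
#'              strrep("I", 10)), fq)
#' count_barcodes(fq, cat, barcode_start = 1, barcode_length = 6)$match_rate
#' }
#' @export
count_barcodes <- function(fastq, catalog, barcode_start, barcode_length) {
  catalog <- validate_catalog(catalog)
  if (nrow(catalog) == 0) stop("empty barcode catalog", call. = FALSE)
  cat_len <- unique(nchar(catalog$barcode_seq))
  if (barcode_length != cat_len)
    stop("barcode_length (", barcode_length, ") does not match catalog ",
         "barcode length (", cat_len, ")", call. = FALSE)
  reads <- Biostrings::readDNAStringSet(fastq, format = "fastq")
  n <- length(reads)
  counts <- stats::setNames(integer(nrow(catalog)), catalog$barcode_id)
  if (n == 0)
    return(list(counts = counts, total_reads = 0L, matched_reads = 0L,
                match_rate = 0))
  if (any(Biostrings::width(reads) < barcode_start + barcode_length - 1))
    stop("read(s) shorter than the barcode window", call. = FALSE)
  window <- as.character(Biostrings::subseq(reads, start = barcode_start,
                                            width = barcode_length))
  hit <- match(window, catalog$barcode_seq)
  tab <- table(hit[!is.na(hit)])
  counts[as.integer(names(tab))] <- as.integer(tab)
  matched <- sum(!is.na(hit))
  list(counts = counts, total_reads = n, matched_reads = matched,
       match_rate = matched / n)
}

#' Summarize sequencing depth per batch
#'
#' @param counts Count matrix (matched reads per barcode and sample).
#' @param sheet Sample sheet with a `batch` column.
#' @return Data frame with one row per batch: total matched reads, sample
#'   count, mean reads per sample and the same mean in millions rounded to
#'   one decimal (the unit such screens are usually reported in).
#' @export
summarize_run <- function(counts, sheet) {
  if (!is.matrix(counts) || ncol(counts) == 0 || nrow(counts) == 0)
    stop("non-empty count matrix required", call. = FALSE)
  validate_experiment(counts, sheet)
  totals <- colSums(counts)
  batches <- split(sheet$sample_id, sheet$batch)
  out <- lapply(names(batches), function(b) {
    ids <- batches[[b]]
    tot <- sum(totals[ids])
    data.frame(batch = b, total_reads = tot, n_samples = length(ids),
               mean_reads_per_sample = tot / length(ids),
               mean_reads_millions = round(tot / length(ids) / 1e6, 1),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
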