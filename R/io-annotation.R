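#' Write / read the annotation as a GFF3-style table
#'
#' The feature class is carried in GFF column 3 (`type`); gene identifiers
#' and UTR lengths travel as `ID`, `utr5_len` and `utr3_len` attributes.
#' Writing and parsing are delegated to \pkg{rtracklayer}; on read the
#' attribute columns are coerced back to their native types so a
#' write-read cycle reproduces the annotation.
#'
#' @param annotation a [GenomicRanges::GRanges] with metadata columns
#'   `type`, `ID`, `utr5_len`, `utr3_len`.
#' @param path file path.
#' @return `writeAnnotationGff` returns `path` invisibly;
#'   `readAnnotationGff` a `GRanges`.
#' @export
writeAnnotationGff <- function(annotation, path) {
    stopifnot(is(annotation, "GRanges"))
    gr <- annotation
    mcols(gr) <- mcols(gr)[, c("type", "ID", "utr5_len", "utr3_len")]
    rtracklayer::export.gff3(gr, path)
    invisible(path)
}

#' @rdname writeAnnotationGff
#' @export
readAnnotationGff <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    gr <- rtracklayer::import(path, format = "gff3")
    out <- GRanges(seqnames(gr), IRanges::ranges(gr), strand = strand(gr))
    mcols(out)$type <- as.character(gr$type)
    mcols(out)$ID <- as.character(gr$ID)
    mcols(out)$utr5_len <- .asIntOrNA(gr$utr5_len)
    mcols(out)$utr3_len <- .asIntOrNA(gr$utr3_len)
    GenomeInfoDb::seqlengths(out) <- GenomeInfoDb::seqlengths(gr)
    out
}

.asIntOrNA <- function(x) {
    if (is.null(x)) return(NA_integer_)
    suppressWarnings(as.integer(as.character(x)))
}

#' Write / read the genome sequence as FASTA
#'
#' Thin wrappers over \pkg{Biostrings}.
#'
#' @param sequence a [Biostrings::DNAStringSet].
#' @param path file path.
#' @return `writeGenomeFasta` returns `path` invisibly;
#'   `readGenomeFasta` a `DNAStringSet`.
#' @export
writeGenomeFasta <- function(sequence, path) {
    Biostrings::writeXStringSet(sequence, path)
    invisible(path)
}

#' @rdname writeGenomeFasta
#' @export
readGenomeFasta <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    Biostrings::readDNAStringSet(path)
}

#' Write / read a tab-delimited table with typed round trip
#'
#' Used for truth tables, augmented gene tables, per-gene counts and
#' report summaries.  `NA` is written as the literal string `NA`.
#'
#' @param df a data.frame.
#' @param path file path.
#' @return `writeTsv` returns `path` invisibly; `readTsv` a data.frame.
#' @export
writeTsv <- function(df, path) {
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
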