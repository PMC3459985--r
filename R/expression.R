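#' Length- and depth-normalized expression quantification
#'
#' Reads-per-kilobase-per-million style normalization:
#' `value = count * 1e9 / (libraryTotal * geneLength)` -- i.e. the count
#' corrected for total read count and divided by gene length in kilobases.
#'
#' @param counts integer per-gene read counts (named by gene id).
#' @param geneLengths gene lengths in bases (> 0), aligned with `counts`.
#' @param libraryTotal total read count of the library (> 0); defaults to
#'   `sum(counts)`.
#' @return numeric normalized values, named like `counts`.
#' @examples
#' quantifyExpression(c(g = 500), 1000, 1e6)  # 500
#' @export
quantifyExpression <- function(counts, geneLengths,
                               libraryTotal = sum(counts)) {
    if (length(libraryTotal) != 1L || libraryTotal <= 0)
        stop("libraryTotal must be a single positive number")
    if (any(geneLengths <= 0)) stop("gene lengths must be > 0")
    counts * 1e9 / (libraryTotal * geneLengths)
}

#' Fold-change gene lists at a cutoff
#'
#' The per-gene ratio is `(mut + pseudocount) / (wt + pseudocount)`;
#' genes with ratio `>= cutoff` are reported up, those with ratio
#' `<= 1 / cutoff` down.  The two lists are disjoint for any
#' `cutoff > 1`.
#'
#' @param wt,mut numeric expression vectors over the same genes (named by
#'   gene id or aligned by position).
#' @param cutoff fold cutoff (default 1.5).
#' @param pseudocount added to both sides of the ratio (default 1).
#' @return list with character vectors `up` and `down` and the numeric
#'   `ratio` vector.
#' @examples
#' foldChangeLists(c(a = 10, b = 10), c(a = 20, b = 10))$up
#' @export
foldChangeLists <- function(wt, mut, cutoff = 1.5, pseudocount = 1) {
    if (length(wt) != length(mut))
        stop("wt and mut must cover the same gene universe")
    ids <- names(wt)
    if (is.null(ids)) ids <- as.character(seq_along(wt))
    if (!is.null(names(mut))) {
        if (!setequal(ids, names(mut)))
            stop("wt and mut must cover the same gene universe")
        mut <- mut[ids]
    }
    ratio <- (mut + pseudocount) / (wt + pseudocount)
    names(ratio) <- ids
    list(up = ids[ratio >= cutoff], down = ids[ratio <= 1 / cutoff],
         ratio = ratio)
}

#' Fold-coverage bookkeeping
#'
#' `fold = readCount * readLength / genomeLength`, the standard sequencing
#' depth summary reported alongside library sizes.
#'
#' @param readCount number of (single-end equivalent) reads.
#' @param readLength read length in bases.
#' @param genomeLength genome length in bases (> 0).
#' @param digits rounding for the reported value (default 1).
#' @return single numeric fold coverage.
#' @examples
#' coverageReport(1e6, 36, 12e6)  # 3
#' @export
coverageReport <- function(readCount, readLength, genomeLength,
                           digits = 1L) {
    if (genomeLength <= 0) stop("genomeLength must be > 0")
    if (readCount < 0 || readLength <= 0)
        stop("readCount must be >= 0 and readLength > 0")
    round(readCount * readLength / genomeLength, digits)
}
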