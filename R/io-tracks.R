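#' Write and read .sgr genome tracks
#'
#' The .sgr format is three tab-separated columns -- chromosome name,
#' zero-referenced bin start coordinate, value -- with one line per bin.
#' Values are serialized with 10 significant digits so that reading back a
#' written track reproduces it to well within numerical test tolerance.
#'
#' `readSgr` infers the bin width from the coordinate spacing and raises a
#' format error when bins are unevenly spaced or out of order.
#'
#' @param track a [BinnedTrack-class].
#' @param path file path.
#' @param valueType value-semantics label to attach on read.
#' @param seqlengths optional named chromosome lengths; when omitted each
#'   chromosome length is recovered as `n_bins * binWidth`.
#' @return `writeSgr` returns `path` invisibly; `readSgr` a
#'   [BinnedTrack-class].
#' @examples
#' tr <- BinnedTrack(list(chrI = c(0, 3, 1)), binWidth = 15)
#' tf <- tempfile(fileext = ".sgr")
#' writeSgr(tr, tf)
#' readLines(tf)
#' @export
writeSgr <- function(track, path) {
    stopifnot(is(track, "BinnedTrack"))
    con <- file(path, "w")
    on.exit(close(con))
    bw <- track@binWidth
    for (chr in names(track@values)) {
        v <- track@values[[chr]]
        writeLines(sprintf("%s\t%d\t%.10g", chr,
                           (seq_along(v) - 1L) * bw, v), con)
    }
    invisible(path)
}

#' @rdname writeSgr
#' @export
readSgr <- function(path, valueType = "frequency", seqlengths = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    tab <- read.table(path, sep = "\t", header = FALSE,
                      col.names = c("chrom", "pos", "value"),
                      colClasses = c("character", "integer", "numeric"))
    if (!nrow(tab)) stop("empty .sgr file: ", path)
    chroms <- unique(tab$chrom)
    widths <- integer()
    for (chr in chroms) {
        p <- tab$pos[tab$chrom == chr]
        if (length(p) >= 2L) {
            d <- unique(diff(p))
            if (length(d) != 1L || d[1L] <= 0L)
                stop("inconsistent bin spacing on ", chr, " in ", path)
            widths <- c(widths, d)
        }
    }
    if (!length(widths))
        stop("cannot infer bin width from single-bin track: ", path)
    if (length(unique(widths)) != 1L)
        stop("bin width differs between chromosomes in ", path)
    bw <- unique(widths)
    vals <- lapply(chroms, function(chr) {
        sub <- tab[tab$chrom == chr, , drop = FALSE]
        if (sub$pos[1L] != 0L)
            stop("track on ", chr, " does not start at coordinate 0")
        sub$value
    })
    names(vals) <- chroms
    if (is.null(seqlengths))
        seqlengths <- vapply(vals, function(v) length(v) * bw, numeric(1))
    BinnedTrack(vals, binWidth = bw, seqlengths = seqlengths,
                valueType = valueType)
}

#' Write a BinnedTrack as bedGraph
#'
#' Standard 4-column bedGraph with half-open intervals, one interval per
#' bin, preceded by a `track type=bedGraph` line.
#'
#' @param track a [BinnedTrack-class].
#' @param path file path.
#' @param name track name for the header line.
#' @return `path`, invisibly.
#' @export
writeBedgraph <- function(track, path, name = "track") {
    stopifnot(is(track, "BinnedTrack"))
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("track type=bedGraph name=\"%s\"", name), con)
    bw <- track@binWidth
    for (chr in names(track@values)) {
        v <- track@values[[chr]]
        if (!length(v)) next
        s <- (seq_along(v) - 1L) * bw
        e <- pmin(s + bw, track@seqlengths[[chr]])
        writeLines(sprintf("%s\t%d\t%d\t%.10g", chr, s, e, v), con)
    }
    invisible(path)
}
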