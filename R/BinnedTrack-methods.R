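#' Construct a BinnedTrack
#'
#' @param values named list of numeric vectors (one per chromosome), or a
#'   single numeric vector together with `seqlengths` of length 1.
#' @param binWidth bin width in bases.
#' @param seqlengths named integer vector of chromosome lengths.  If
#'   omitted, lengths are taken as `length(v) * binWidth` per chromosome.
#' @param valueType value-semantics label; see [BinnedTrack-class].
#'
#' @return A [BinnedTrack-class] object.
#' @examples
#' BinnedTrack(list(chrS1 = c(0, 3, 1)), binWidth = 15)
#' @export
BinnedTrack <- function(values, binWidth, seqlengths = NULL,
                        valueType = "frequency") {
    if (is.numeric(values)) values <- list(chr = values)
    binWidth <- as.integer(binWidth)
    if (is.null(seqlengths))
        seqlengths <- vapply(values, function(v)
            length(v) * binWidth, numeric(1))
    seqlengths <- structure(as.integer(seqlengths), names = names(seqlengths))
    if (is.null(names(seqlengths))) names(seqlengths) <- names(values)
    values <- lapply(values, as.numeric)
    new("BinnedTrack", values = values, binWidth = binWidth,
        seqlengths = seqlengths[names(values)], valueType = valueType)
}

#' @describeIn BinnedTrack-class bin width in bases.
#' @param x,object a `BinnedTrack`.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname BinnedTrack-class
#' @export
setMethod("binWidth", "BinnedTrack", function(x) x@binWidth)

#' @describeIn BinnedTrack-class named list of per-chromosome bin values.
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))

#' @rdname BinnedTrack-class
#' @export
setMethod("trackValues", "BinnedTrack", function(x) x@values)

#' @describeIn BinnedTrack-class value-semantics label.
#' @export
setGeneric("valueType", function(x) standardGeneric("valueType"))

#' @rdname BinnedTrack-class
#' @export
setMethod("valueType", "BinnedTrack", function(x) x@valueType)

#' @describeIn BinnedTrack-class chromosome names.
#' @export
setMethod("seqnames", "BinnedTrack", function(x) names(x@values))

#' @describeIn BinnedTrack-class named chromosome lengths (bases).
#' @export
setMethod("seqlengths", "BinnedTrack", function(x) x@seqlengths)

#' @rdname BinnedTrack-class
#' @export
setMethod("show", "BinnedTrack", function(object) {
    nb <- sum(vapply(object@values, length, integer(1)))
    cat(sprintf(
        "BinnedTrack: %d chromosome(s), %d bins of %d bp [%s]\n",
        length(object@values), nb, object@binWidth, object@valueType))
    for (chr in head(names(object@values), 5L)) {
        v <- object@values[[chr]]
        cat(sprintf("  %s: %d bins, value range [%.4g, %.4g]\n",
                    chr, length(v), min(v), max(v)))
    }
    if (length(object@values) > 5L)
        cat(sprintf("  ... and %d more\n", length(object@values) - 5L))
    invisible(NULL)
})

## internal: assert two tracks share grid and chromosomes
.checkSameBinning <- function(a, b) {
    stopifnot(is(a, "BinnedTrack"), is(b, "BinnedTrack"))
    if (a@binWidth != b@binWidth)
        stop("tracks have different bin widths (", a@binWidth, " vs ",
             b@binWidth, ")")
    if (!identical(sort(names(a@values)), sort(names(b@values))))
        stop("tracks cover different chromosomes")
    for (chr in names(a@values))
        if (length(a@values[[chr]]) != length(b@values[[chr]]))
            stop("tracks differ in bin count on ", chr)
    invisible(TRUE)
}

## internal: apply f per chromosome over one or two tracks
.mapTrack <- function(a, f, b = NULL, valueType = a@valueType) {
    vals <- if (is.null(b)) {
        lapply(a@values, f)
    } else {
        .checkSameBinning(a, b)
        lapply(names(a@values), function(chr) f(a@values[[chr]],
                                                b@values[[chr]]))
    }
    names(vals) <- names(a@values)
    new("BinnedTrack", values = vals, binWidth = a@binWidth,
        seqlengths = a@seqlengths, valueType = valueType)
}

## internal: 0-based bin index range covered by a 0-based half-open interval
.binsOfInterval <- function(start0, end0, binWidth) {
    if (end0 <= start0) return(integer(0))
    seq.int(start0 %/% binWidth, (end0 - 1L) %/% binWidth)
}
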