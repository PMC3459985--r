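#' Depth- and probe-length-normalize a binned count track
#'
#' Converts raw per-bin counts to reads per million (library size
#' `totalCount`) per kilobase of probe: `value * (1e6 / totalCount) *
#' (1e3 / probeLength)`.  `probeLength` defaults to the track's bin width.
#'
#' @param track a [BinnedTrack-class] of raw counts.
#' @param totalCount total read count of the library, > 0.
#' @param probeLength probe (bin) length in bases.
#' @return a [BinnedTrack-class] with `valueType = "normalized"`.
#' @examples
#' tr <- BinnedTrack(list(c = c(20, 0)), 10)
#' trackValues(normalizeTrack(tr, totalCount = 1e6, probeLength = 1000))
#' @export
normalizeTrack <- function(track, totalCount, probeLength = binWidth(track)) {
    stopifnot(is(track, "BinnedTrack"))
    if (length(totalCount) != 1L || is.na(totalCount) || totalCount <= 0)
        stop("totalCount must be a single positive number")
    f <- (1e6 / totalCount) * (1e3 / probeLength)
    .mapTrack(track, function(v) v * f, valueType = "normalized")
}

#' Input-normalized log2 ChIP enrichment track
#'
#' Both tracks are depth- and probe-length-normalized, then the per-bin
#' ratio is taken on the log2 scale:
#' `log2((chip_norm + pseudocount) / (input_norm + pseudocount))`.  With
#' `pseudocount = 0`, bins with zero input (or zero ChIP) become `NA`
#' with a message reporting how many.
#'
#' @param chip,input [BinnedTrack-class] raw count tracks on the same bin
#'   grid.
#' @param chipTotal,inputTotal library sizes; default to the track sums.
#' @param pseudocount added to both normalized values (normalized units);
#'   the default 0.5 keeps zero-input bins finite.
#' @return a [BinnedTrack-class] with `valueType = "log2-enrichment"`.
#' @export
log2Enrichment <- function(chip, input, chipTotal = NULL, inputTotal = NULL,
                           pseudocount = 0.5) {
    r <- .normalizedRatio(chip, input, chipTotal, inputTotal, pseudocount)
    .mapTrack(r, log2, valueType = "log2-enrichment")
}

#' Input-corrected linear occupancy track
#'
#' As [log2Enrichment()] but reporting the plain normalized ChIP/input
#' ratio; with `pseudocount = 0` it equals `2^log2Enrichment` wherever
#' both are defined.
#'
#' @inheritParams log2Enrichment
#' @return a [BinnedTrack-class] with `valueType = "linear-occupancy"`.
#' @export
linearOccupancy <- function(chip, input, chipTotal = NULL, inputTotal = NULL,
                            pseudocount = 0.5) {
    r <- .normalizedRatio(chip, input, chipTotal, inputTotal, pseudocount)
    .mapTrack(r, identity, valueType = "linear-occupancy")
}

.normalizedRatio <- function(chip, input, chipTotal, inputTotal,
                             pseudocount) {
    stopifnot(is(chip, "BinnedTrack"), is(input, "BinnedTrack"))
    .checkSameBinning(chip, input)
    if (pseudocount < 0) stop("pseudocount must be >= 0")
    if (is.null(chipTotal))
        chipTotal <- sum(vapply(chip@values, sum, numeric(1)))
    if (is.null(inputTotal))
        inputTotal <- sum(vapply(input@values, sum, numeric(1)))
    cn <- normalizeTrack(chip, chipTotal)
    inn <- normalizeTrack(input, inputTotal)
    n.undef <- 0L
    out <- .mapTrack(cn, function(c, i) {
        num <- c + pseudocount
        den <- i + pseudocount
        r <- num / den
        bad <- den == 0
        n.undef <<- n.undef + sum(bad)
        r[bad] <- NA_real_
        r
    }, b = inn, valueType = "normalized")
    if (n.undef > 0L)
        message(n.undef, " bin(s) with zero input and zero pseudocount set to NA")
    out
}

#' Per-bin difference of two tracks
#'
#' `a - b` bin by bin; used for genotype difference tracks (mutant minus
#' wild type).  Tracks must share the bin grid and value semantics.
#'
#' @param a,b [BinnedTrack-class] objects.
#' @return a [BinnedTrack-class] with `valueType = "difference"`.
#' @export
differenceTrack <- function(a, b) {
    stopifnot(is(a, "BinnedTrack"), is(b, "BinnedTrack"))
    .checkSameBinning(a, b)
    if (a@valueType != b@valueType)
        stop("cannot subtract tracks with different value semantics (",
             a@valueType, " vs ", b@valueType, ")")
    .mapTrack(a, function(x, y) x - y, b = b, valueType = "difference")
}

#' Mean track value over a set of feature intervals
#'
#' For each feature, the mean of the track values over the bins its
#' interval overlaps (NA bins excluded).
#'
#' @param track a [BinnedTrack-class].
#' @param features a [GenomicRanges::GRanges] (1-based, inclusive).
#' @return numeric vector of per-feature means, named by `features$ID`
#'   when present.
#' @export
featureMeans <- function(track, features) {
    stopifnot(is(track, "BinnedTrack"), is(features, "GRanges"))
    bw <- track@binWidth
    chrv <- as.character(seqnames(features))
    s0 <- start(features) - 1L
    e0 <- end(features)
    out <- vapply(seq_along(features), function(i) {
        v <- track@values[[chrv[i]]]
        if (is.null(v)) return(NA_real_)
        bins <- .binsOfInterval(s0[i], e0[i], bw) + 1L
        bins <- bins[bins >= 1L & bins <= length(v)]
        if (!length(bins)) return(NA_real_)
        mean(v[bins], na.rm = TRUE)
    }, numeric(1))
    if (!is.null(features$ID)) names(out) <- features$ID
    out
}

#' Box-plot statistics of enrichment per feature class
#'
#' For every feature class, computes five-number summaries (minimum, lower
#' quartile, median, upper quartile, maximum) over the per-feature mean
#' track values of that class.  Quartiles use the linear-interpolation
#' convention (R `quantile` type 7).  Classes with no usable feature are
#' omitted with a warning.
#'
#' @param track a [BinnedTrack-class] (typically log2 enrichment).
#' @param features a [GenomicRanges::GRanges] with a `type` metadata
#'   column carrying the feature class.
#' @return data.frame with columns `class`, `n`, `min`, `q1`, `median`,
#'   `q3`, `max`, ordered by descending median.
#' @export
featureBoxStats <- function(track, features) {
    stopifnot(is(track, "BinnedTrack"), is(features, "GRanges"))
    if (is.null(features$type)) stop("features need a 'type' column")
    classes <- unique(as.character(features$type))
    rows <- lapply(classes, function(cl) {
        m <- featureMeans(track, features[features$type == cl])
        m <- m[!is.na(m)]
        if (!length(m)) {
            warning("feature class '", cl, "' has no usable feature; omitted")
            return(NULL)
        }
        q <- unname(quantile(m, c(0, 0.25, 0.5, 0.75, 1), type = 7))
        data.frame(class = cl, n = length(m), min = q[1], q1 = q[2],
                   median = q[3], q3 = q[4], max = q[5],
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out <- out[order(-out$median), , drop = FALSE]
    rownames(out) <- NULL
    out
}
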