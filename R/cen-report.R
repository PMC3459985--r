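#' Extract a track window around a centromere
#'
#' Slices the bins covering `[cen_start - flank, cen_end + flank)`,
#' clipped at chromosome ends.
#'
#' @param track a [BinnedTrack-class] (a smoothed nucleosome-class dyad
#'   track for centromere analysis).
#' @param cen a single-interval [GenomicRanges::GRanges] (1-based).
#' @param flank bases up- and downstream of the centromere (default 5000).
#' @return list with `chrom`, `values` (the window bins), `firstBin`
#'   (0-based index of the first window bin), `binWidth`, and the 0-based
#'   half-open centromere interval `cenStart0`, `cenEnd0`.
#' @export
extractWindow <- function(track, cen, flank = 5000L) {
    stopifnot(is(track, "BinnedTrack"), is(cen, "GRanges"),
              length(cen) == 1L)
    chr <- as.character(seqnames(cen))
    v <- track@values[[chr]]
    if (is.null(v)) stop("track has no chromosome ", chr)
    bw <- track@binWidth
    s0 <- start(cen) - 1L
    e0 <- end(cen)
    lo <- max(0L, s0 - as.integer(flank))
    hi <- min(track@seqlengths[[chr]], e0 + as.integer(flank))
    bins <- .binsOfInterval(lo, hi, bw)
    bins <- bins[bins + 1L <= length(v)]
    list(chrom = chr, values = v[bins + 1L], firstBin = bins[1L],
         binWidth = bw, cenStart0 = s0, cenEnd0 = e0)
}

## local maxima of a window, in genomic coordinates (bin centers)
.windowPeaks <- function(w, minHeight = 0) {
    tr <- BinnedTrack(list(x = w$values), binWidth = w$binWidth)
    pk <- callPeaks(tr, minHeight = minHeight)
    if (!nrow(pk))
        return(data.frame(bin = integer(), pos = numeric(),
                          height = numeric()))
    bin <- pk$bin + w$firstBin
    data.frame(bin = bin, pos = bin * w$binWidth + (w$binWidth - 1) / 2,
               height = pk$height)
}

#' Detect the centromeric core particle
#'
#' The highest local maximum of the smoothed dyad window whose position
#' falls within the centromere interval extended by one bin on each side;
#' among equal maxima the leftmost is reported.  Returns `NULL` when no
#' local maximum lies there (e.g. zero coverage).
#'
#' @param window a window from [extractWindow()].
#' @return one-row data.frame with `pos` (bin-center coordinate, bases),
#'   `bin`, `height`, or `NULL` if absent.
#' @export
detectCorePeak <- function(window) {
    pk <- .windowPeaks(window)
    bw <- window$binWidth
    inside <- pk$pos >= window$cenStart0 - bw & pk$pos < window$cenEnd0 + bw
    pk <- pk[inside, , drop = FALSE]
    if (!nrow(pk)) return(NULL)
    pk[which.max(pk$height), c("pos", "bin", "height"), drop = FALSE]
}

#' Match centromere-flanking peaks between genotypes
#'
#' Local maxima outside the centromere (interval plus one bin) are paired
#' between the wild-type and mutant windows greedily by nearest position
#' within `tolerance` bases (about one nucleosome footprint); remaining
#' peaks are reported unmatched (disappeared from wild type or appeared in
#' the mutant).  The shift of a matched pair is `mutant - wild-type`
#' position.  To suppress noise maxima, only peaks of at least
#' `minHeightFrac` of the window maximum are considered.
#'
#' @param wtWindow,mutWindow windows from [extractWindow()] on the same
#'   bin grid.
#' @param tolerance maximal pairing distance (bases, default 150).
#' @param minHeightFrac minimal peak height as a fraction of the window
#'   maximum (default 0.2).
#' @return data.frame with columns `wt_pos`, `mut_pos`, `shift` (NA for
#'   unmatched peaks), one row per wild-type or mutant flank peak.
#' @export
matchFlankPeaks <- function(wtWindow, mutWindow, tolerance = 150,
                            minHeightFrac = 0.2) {
    if (wtWindow$binWidth != mutWindow$binWidth)
        stop("windows have different bin widths")
    flankOf <- function(w) {
        mh <- minHeightFrac * max(w$values, 0)
        pk <- .windowPeaks(w, minHeight = mh)
        bw <- w$binWidth
        pk[pk$pos < w$cenStart0 - bw | pk$pos >= w$cenEnd0 + bw, ,
           drop = FALSE]
    }
    wt <- flankOf(wtWindow)
    mut <- flankOf(mutWindow)
    if (nrow(wt) && nrow(mut)) {
        cand <- expand.grid(i = seq_len(nrow(wt)), j = seq_len(nrow(mut)))
        cand$d <- abs(wt$pos[cand$i] - mut$pos[cand$j])
        cand <- cand[cand$d <= tolerance, , drop = FALSE]
        cand <- cand[order(cand$d, cand$i, cand$j), , drop = FALSE]
        used.i <- logical(nrow(wt)); used.j <- logical(nrow(mut))
        pairs <- list()
        for (r in seq_len(nrow(cand))) {
            i <- cand$i[r]; j <- cand$j[r]
            if (used.i[i] || used.j[j]) next
            used.i[i] <- TRUE; used.j[j] <- TRUE
            pairs[[length(pairs) + 1L]] <- c(i, j)
        }
    } else {
        used.i <- logical(nrow(wt)); used.j <- logical(nrow(mut))
        pairs <- list()
    }
    rows <- lapply(pairs, function(p)
        data.frame(wt_pos = wt$pos[p[1]], mut_pos = mut$pos[p[2]],
                   shift = mut$pos[p[2]] - wt$pos[p[1]]))
    if (any(!used.i))
        rows <- c(rows, lapply(which(!used.i), function(i)
            data.frame(wt_pos = wt$pos[i], mut_pos = NA_real_,
                       shift = NA_real_)))
    if (any(!used.j))
        rows <- c(rows, lapply(which(!used.j), function(j)
            data.frame(wt_pos = NA_real_, mut_pos = mut$pos[j],
                       shift = NA_real_)))
    out <- if (length(rows)) do.call(rbind, rows)
           else data.frame(wt_pos = numeric(), mut_pos = numeric(),
                           shift = numeric())
    out <- out[order(ifelse(is.na(out$wt_pos), out$mut_pos, out$wt_pos)), ,
               drop = FALSE]
    rownames(out) <- NULL
    out
}

#' Per-centromere chromatin comparison between genotypes
#'
#' For every centromere, detects the core particle in both genotypes,
#' computes the mutant/wild-type core height ratio, matches flanking
#' nucleosome peaks, and calls qualitative changes: a flank-shift call
#' when any matched peak moved by at least `shiftMin` bins, and a
#' core-accessibility call when the core height ratio is at least
#' `heightRatioMin` away from 1 in either direction or the core is
#' detected in only one genotype.
#'
#' @param wtTrack,mutTrack smoothed nucleosome-class dyad
#'   [BinnedTrack-class] objects on the same bin grid.
#' @param cens [GenomicRanges::GRanges] of centromeres with an `ID`
#'   metadata column.
#' @param flank window extent around each centromere (bases).
#' @param tolerance flank-peak pairing tolerance (bases).
#' @param shiftMin minimal shift, in bins, for a flank-shift call.
#' @param heightRatioMin minimal core height-ratio deviation for a
#'   core-accessibility call.
#' @param minHeightFrac noise floor for flank peaks (fraction of window
#'   maximum).
#' @return a [CenChromatinReport-class]; its `table` slot has one row per
#'   centromere with the detection results and the calls
#'   (`flank_shift`, `core_change`, logical, and `call`, a label in
#'   `no-change` / `flank-shift` / `core-accessibility-change` / `both`).
#' @export
cenReport <- function(wtTrack, mutTrack, cens, flank = 5000L,
                      tolerance = 150, shiftMin = 2L,
                      heightRatioMin = 1.25, minHeightFrac = 0.2) {
    stopifnot(is(wtTrack, "BinnedTrack"), is(mutTrack, "BinnedTrack"),
              is(cens, "GRanges"))
    .checkSameBinning(wtTrack, mutTrack)
    bw <- binWidth(wtTrack)
    rows <- list(); match.rows <- list()
    for (i in seq_along(cens)) {
        id <- if (!is.null(cens$ID)) cens$ID[i] else paste0("CEN", i)
        wtw <- extractWindow(wtTrack, cens[i], flank)
        mutw <- extractWindow(mutTrack, cens[i], flank)
        core.wt <- detectCorePeak(wtw)
        core.mut <- detectCorePeak(mutw)
        ratio <- if (!is.null(core.wt) && !is.null(core.mut))
            core.mut$height / core.wt$height else NA_real_
        mt <- matchFlankPeaks(wtw, mutw, tolerance, minHeightFrac)
        matched <- mt[!is.na(mt$shift), , drop = FALSE]
        max.shift <- if (nrow(matched)) max(abs(matched$shift)) else 0
        flank.call <- nrow(matched) > 0 && max.shift >= shiftMin * bw
        core.call <- if (is.null(core.wt) != is.null(core.mut)) TRUE
            else if (is.na(ratio)) FALSE
            else ratio >= heightRatioMin || ratio <= 1 / heightRatioMin
        call.lab <- if (flank.call && core.call) "both"
            else if (flank.call) "flank-shift"
            else if (core.call) "core-accessibility-change"
            else "no-change"
        rows[[i]] <- data.frame(
            cen_id = id, chrom = as.character(seqnames(cens[i])),
            core_wt_pos = if (is.null(core.wt)) NA_real_ else core.wt$pos,
            core_wt_height = if (is.null(core.wt)) NA_real_
                             else core.wt$height,
            core_mut_pos = if (is.null(core.mut)) NA_real_
                           else core.mut$pos,
            core_mut_height = if (is.null(core.mut)) NA_real_
                              else core.mut$height,
            core_height_ratio = ratio,
            n_flank_matched = nrow(matched),
            n_wt_unmatched = sum(is.na(mt$mut_pos)),
            n_mut_unmatched = sum(is.na(mt$wt_pos)),
            max_abs_shift = max.shift,
            flank_shift = flank.call, core_change = core.call,
            call = call.lab, stringsAsFactors = FALSE)
        if (nrow(mt))
            match.rows[[i]] <- cbind(cen_id = id, mt)
    }
    tab <- do.call(rbind, rows)
    rownames(tab) <- NULL
    matches <- if (length(match.rows)) do.call(rbind, match.rows)
               else data.frame(cen_id = character(), wt_pos = numeric(),
                               mut_pos = numeric(), shift = numeric())
    rownames(matches) <- NULL
    new("CenChromatinReport", table = tab, matches = matches,
        params = list(flank = flank, tolerance = tolerance,
                      shiftMin = shiftMin, heightRatioMin = heightRatioMin,
                      minHeightFrac = minHeightFrac,
                      binWidth = bw))
}

#' @describeIn cenReport the per-centromere summary table.
#' @param report a `CenChromatinReport`.
#' @export
cenReportTable <- function(report) {
    stopifnot(is(report, "CenChromatinReport"))
    report@table
}

#' @describeIn cenReport the per-peak flank match table.
#' @export
cenReportMatches <- function(report) {
    stopifnot(is(report, "CenChromatinReport"))
    report@matches
}

#' @rdname cenReport
#' @param object a `CenChromatinReport`.
#' @export
setMethod("show", "CenChromatinReport", function(object) {
    t <- object@table
    cat(sprintf("CenChromatinReport: %d centromere(s), %d changed\n",
                nrow(t), sum(t$call != "no-change")))
    cat(sprintf("  flank-shift calls: %d; core-accessibility calls: %d\n",
                sum(t$flank_shift), sum(t$core_change)))
    invisible(NULL)
})
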