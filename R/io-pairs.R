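#' Read paired-end alignments as AlignedPair records
#'
#' Reads either a BEDPE file or a minimal SAM ("SAM-subset") file into the
#' package's aligned-pair representation: one row per properly oriented
#' pair with the chromosome, the 0-based leftmost 5' coordinate of the
#' pair, and the end-to-end insert size (the SAM template length).
#'
#' For BEDPE, `left5 = min(start1, start2)` and
#' `isize = max(end1, end2) - min(start1, start2)`; mates on different
#' chromosomes are dropped and counted.  For SAM, unmapped, secondary and
#' supplementary records are skipped; each pair is taken from the record
#' with positive template length (the leftmost mate).  Records naming a
#' chromosome absent from the `@SQ` header are skipped with a warning.
#'
#' @param path input file.
#' @param dialect `"bedpe"` or `"sam"`.
#' @return data.frame with columns `chrom`, `left5`, `isize`; the number
#'   of skipped records is attached as attribute `"skipped"`.
#' @examples
#' tf <- tempfile(fileext = ".bedpe")
#' writeLines("chr1\t100\t176\tchr1\t200\t250\tp1\t0\t+\t-", tf)
#' readPairs(tf, "bedpe")
#' @export
readPairs <- function(path, dialect = c("bedpe", "sam")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("file not found: ", path)
    if (dialect == "bedpe") .readBedpe(path) else .readSamSubset(path)
}

.readBedpe <- function(path) {
    ln <- readLines(path)
    ln <- ln[nzchar(ln)]
    if (!length(ln)) {
        out <- data.frame(chrom = character(), left5 = integer(),
                          isize = integer())
        attr(out, "skipped") <- 0L
        return(out)
    }
    f <- strsplit(ln, "\t", fixed = TRUE)
    nf <- vapply(f, length, integer(1))
    bad <- which(nf < 6L)
    if (length(bad))
        stop("malformed BEDPE record at line ", bad[1L], ": ", ln[bad[1L]])
    chrom1 <- vapply(f, `[`, character(1), 1L)
    chrom2 <- vapply(f, `[`, character(1), 4L)
    s1 <- as.integer(vapply(f, `[`, character(1), 2L))
    e1 <- as.integer(vapply(f, `[`, character(1), 3L))
    s2 <- as.integer(vapply(f, `[`, character(1), 5L))
    e2 <- as.integer(vapply(f, `[`, character(1), 6L))
    if (anyNA(s1) || anyNA(e1) || anyNA(s2) || anyNA(e2))
        stop("malformed BEDPE coordinates at line ",
             which(is.na(s1 + e1 + s2 + e2))[1L])
    concordant <- chrom1 == chrom2
    skipped <- sum(!concordant)
    if (skipped)
        warning(skipped, " discordant (cross-chromosome) pair(s) dropped")
    left5 <- pmin(s1, s2)[concordant]
    isize <- (pmax(e1, e2) - pmin(s1, s2))[concordant]
    out <- data.frame(chrom = chrom1[concordant], left5 = left5,
                      isize = isize, stringsAsFactors = FALSE)
    attr(out, "skipped") <- skipped
    out
}

.readSamSubset <- function(path) {
    ln <- readLines(path)
    hdr <- ln[startsWith(ln, "@")]
    sq <- hdr[startsWith(hdr, "@SQ")]
    known <- if (length(sq)) {
        vapply(strsplit(sq, "\t", fixed = TRUE), function(f) {
            sn <- f[startsWith(f, "SN:")]
            if (length(sn)) substring(sn[1L], 4L) else NA_character_
        }, character(1))
    } else NULL
    rec <- ln[!startsWith(ln, "@") & nzchar(ln)]
    if (!length(rec)) {
        out <- data.frame(chrom = character(), left5 = integer(),
                          isize = integer())
        attr(out, "skipped") <- 0L
        return(out)
    }
    f <- strsplit(rec, "\t", fixed = TRUE)
    nf <- vapply(f, length, integer(1))
    bad <- which(nf < 11L)
    if (length(bad))
        stop("malformed SAM record at line ",
             which(!startsWith(ln, "@"))[bad[1L]])
    flag <- as.integer(vapply(f, `[`, character(1), 2L))
    rname <- vapply(f, `[`, character(1), 3L)
    pos <- as.integer(vapply(f, `[`, character(1), 4L))
    tlen <- as.integer(vapply(f, `[`, character(1), 9L))
    if (anyNA(flag) || anyNA(pos) || anyNA(tlen))
        stop("malformed SAM numeric field")
    skipped <- 0L
    usable <- bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 256L) == 0L &
        bitwAnd(flag, 2048L) == 0L
    skipped <- skipped + sum(!usable)
    if (!is.null(known)) {
        unk <- usable & !(rname %in% known)
        if (any(unk)) {
            warning(sum(unk), " record(s) on unknown chromosome skipped")
            skipped <- skipped + sum(unk)
            usable <- usable & !unk
        }
    }
    keep <- usable & tlen > 0L
    out <- data.frame(chrom = rname[keep], left5 = pos[keep] - 1L,
                      isize = tlen[keep], stringsAsFactors = FALSE)
    attr(out, "skipped") <- skipped
    out
}

#' Write aligned pairs as BEDPE or minimal SAM
#'
#' `writePairsBedpe` emits one 10-column BEDPE line per pair with two
#' synthetic mates of up to 36 bases anchored at the pair's outer
#' coordinates, so that `readPairs` recovers `left5` and `isize` exactly.
#' `writePairsSam` emits a minimal SAM file (`@HD`/`@SQ` header and two
#' records per pair carrying the template length in the TLEN field).
#'
#' @param pairs data.frame with columns `chrom`, `left5`, `isize`.
#' @param path output file.
#' @param seqlengths named chromosome lengths for the SAM `@SQ` header.
#' @param readLength synthetic mate length (bases).
#' @return `path`, invisibly.
#' @export
writePairsBedpe <- function(pairs, path, readLength = 36L) {
    rl <- pmin(as.integer(readLength), pairs$isize)
    ln <- sprintf("%s\t%d\t%d\t%s\t%d\t%d\tpair%d\t0\t+\t-",
                  pairs$chrom, pairs$left5, pairs$left5 + rl,
                  pairs$chrom, pairs$left5 + pairs$isize - rl,
                  pairs$left5 + pairs$isize, seq_len(nrow(pairs)))
    writeLines(ln, path)
    invisible(path)
}

#' @rdname writePairsBedpe
#' @export
writePairsSam <- function(pairs, path, seqlengths, readLength = 36L) {
    hdr <- c("@HD\tVN:1.6\tSO:unsorted",
             sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                     as.integer(seqlengths)))
    if (nrow(pairs)) {
        rl <- pmin(as.integer(readLength), pairs$isize)
        qn <- sprintf("pair%d", seq_len(nrow(pairs)))
        cig <- sprintf("%dM", rl)
        p1 <- pairs$left5 + 1L
        p2 <- pairs$left5 + pairs$isize - rl + 1L
        r1 <- sprintf("%s\t99\t%s\t%d\t42\t%s\t=\t%d\t%d\t*\t*",
                      qn, pairs$chrom, p1, cig, p2, pairs$isize)
        r2 <- sprintf("%s\t147\t%s\t%d\t42\t%s\t=\t%d\t%d\t*\t*",
                      qn, pairs$chrom, p2, cig, p1, -pairs$isize)
        body <- as.vector(rbind(r1, r2))
    } else body <- character()
    writeLines(c(hdr, body), path)
    invisible(path)
}

#' Write / read single-end tags as BED6
#'
#' Tags are width-1 intervals at the 0-based 5' coordinate.
#'
#' @param tags data.frame with columns `chrom`, `pos5`, `strand`.
#' @param path file path.
#' @return `writeTagsBed` returns `path` invisibly; `readTagsBed` returns
#'   a tag data.frame.
#' @export
writeTagsBed <- function(tags, path) {
    ln <- sprintf("%s\t%d\t%d\ttag%d\t0\t%s", tags$chrom, tags$pos5,
                  tags$pos5 + 1L, seq_len(nrow(tags)), tags$strand)
    writeLines(ln, path)
    invisible(path)
}

#' @rdname writeTagsBed
#' @export
readTagsBed <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    ln <- readLines(path)
    ln <- ln[nzchar(ln) & !startsWith(ln, "track") & !startsWith(ln, "#")]
    if (!length(ln))
        return(data.frame(chrom = character(), pos5 = integer(),
                          strand = character()))
    f <- strsplit(ln, "\t", fixed = TRUE)
    nf <- vapply(f, length, integer(1))
    if (any(nf < 6L))
        stop("malformed BED6 record at line ", which(nf < 6L)[1L])
    data.frame(chrom = vapply(f, `[`, character(1), 1L),
               pos5 = as.integer(vapply(f, `[`, character(1), 2L)),
               strand = vapply(f, `[`, character(1), 6L),
               stringsAsFactors = FALSE)
}
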