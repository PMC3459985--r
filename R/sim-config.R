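#' Create a synthetic-study configuration
#'
#' Builds a validated [SimConfig-class].  The defaults describe the study
#' conditions the rest of the package is exercised under: a two-chromosome
#' 60 kb mini-genome with regularly spaced nucleosome arrays (repeat length
#' 165 bp), promoter nucleosome-depleted regions, one 125 bp centromeric
#' core particle per chromosome, a tri-modal insert-size mixture with mono-,
#' di- and tri-nucleosome peaks at 150/300/450 bp, 195 sequenced pairs per
#' unit-occupancy nucleosome, locus-specific ChIP enrichment (strongest over
#' centromeres), and a mutant genotype whose centromere-flanking nucleosomes
#' are shifted by 30 bp, whose core-particle occupancy is halved, and whose
#' H2A.Z-like ChIP signal is redistributed from promoters into gene bodies.
#'
#' @param nChromosomes,chromLength,nGenesPerChrom genome geometry.
#' @param nucleosomeSpacing,ndrWidth,cenCoreWidth chromatin architecture
#'   (bases).
#' @param isizeMeans,isizeSd,isizeClassWeights insert-size mixture of the
#'   simulated MNase digest.
#' @param pairsPerNucleosome expected pairs per unit-occupancy nucleosome.
#' @param dyadJitter half-width (bases) of the uniform jitter on observed
#'   pair centers.
#' @param cenCoreOccupancy occupancy weight of the centromeric core
#'   particle.
#' @param chipEnrichment nested list target -> genotype -> named fold
#'   vector; `NULL` selects the built-in defaults (see Details).
#' @param chipTagCount,inputTagCount tags per simulated ChIP / input
#'   library.
#' @param mutantFlankShift,mutantCoreHeightFactor,mutantCenSubset mutant
#'   centromere perturbations; an empty `mutantCenSubset` perturbs every
#'   centromere.
#' @param deFraction,deRatioUp,deRatioDown planted expression changes.
#' @param exprMeanLog,exprSdLog,exprDispersion expression count model.
#' @param lowExprElevation optional true ratio applied to the weakly
#'   expressed quartile (1 = off); emulates elevated mutant/wild-type
#'   ratios among near-silent genes.
#' @param utrMissingFraction fraction of genes emitted without UTR
#'   annotation (exercises the no-UTR intergenic-region fallback).
#' @param seed integer master seed; all generator sub-streams derive from
#'   it deterministically.
#'
#' @details The default `chipEnrichment` defines three targets:
#' \describe{
#'   \item{Fun30-like}{a remodeler-style factor, most enriched over
#'     centromeres (fold 8) and over tRNA/snoRNA/snRNA/ARS/LTR/telomere
#'     features and 3' intergenic regions, depleted within ORFs;
#'     identical in both genotypes.}
#'   \item{Htz1-like}{an H2A.Z-style histone variant, promoter-enriched in
#'     the wild type; in the mutant the promoter fold drops and the
#'     gene-body fold rises (promoter-to-gene-body redistribution).}
#'   \item{H3-like}{bulk nucleosomal histone, mildly ORF-enriched.}
#' }
#'
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(seed = 7)
#' cfg
#' @export
simConfig <- function(nChromosomes = 2L,
                      chromLength = 60000L,
                      nGenesPerChrom = 20L,
                      nucleosomeSpacing = 165L,
                      ndrWidth = 140L,
                      cenCoreWidth = 125L,
                      isizeMeans = c(150, 300, 450),
                      isizeSd = 10,
                      isizeClassWeights = c(0.6, 0.25, 0.15),
                      pairsPerNucleosome = 195,
                      dyadJitter = 10L,
                      cenCoreOccupancy = 0.5,
                      chipEnrichment = NULL,
                      chipTagCount = 200000L,
                      inputTagCount = 200000L,
                      mutantFlankShift = 30L,
                      mutantCoreHeightFactor = 0.5,
                      mutantCenSubset = integer(0),
                      deFraction = 0.1,
                      deRatioUp = 2,
                      deRatioDown = 0.5,
                      exprMeanLog = log(300),
                      exprSdLog = 1,
                      exprDispersion = 0.02,
                      lowExprElevation = 1,
                      utrMissingFraction = 0.2,
                      seed = 1L) {
    if (is.null(chipEnrichment))
        chipEnrichment <- .defaultChipEnrichment()
    cfg <- new("SimConfig",
        nChromosomes = as.integer(nChromosomes),
        chromLength = as.integer(chromLength),
        nGenesPerChrom = as.integer(nGenesPerChrom),
        nucleosomeSpacing = as.integer(nucleosomeSpacing),
        ndrWidth = as.integer(ndrWidth),
        cenCoreWidth = as.integer(cenCoreWidth),
        isizeMeans = as.numeric(isizeMeans),
        isizeSd = as.numeric(isizeSd),
        isizeClassWeights = as.numeric(isizeClassWeights),
        pairsPerNucleosome = as.numeric(pairsPerNucleosome),
        dyadJitter = as.integer(dyadJitter),
        cenCoreOccupancy = as.numeric(cenCoreOccupancy),
        chipEnrichment = chipEnrichment,
        chipTagCount = as.integer(chipTagCount),
        inputTagCount = as.integer(inputTagCount),
        mutantFlankShift = as.integer(mutantFlankShift),
        mutantCoreHeightFactor = as.numeric(mutantCoreHeightFactor),
        mutantCenSubset = as.integer(mutantCenSubset),
        deFraction = as.numeric(deFraction),
        deRatioUp = as.numeric(deRatioUp),
        deRatioDown = as.numeric(deRatioDown),
        exprMeanLog = as.numeric(exprMeanLog),
        exprSdLog = as.numeric(exprSdLog),
        exprDispersion = as.numeric(exprDispersion),
        lowExprElevation = as.numeric(lowExprElevation),
        utrMissingFraction = as.numeric(utrMissingFraction),
        seed = as.integer(seed))
    validObject(cfg)
    cfg
}

.defaultChipEnrichment <- function() {
    fun30 <- c(CEN = 8, tRNA = 4, snoRNA = 4, snRNA = 4, ARS = 3, LTR = 3,
               telomere = 3, igr3 = 3, promoter = 1.5, gene_body = 0.5)
    htz1.wt  <- c(promoter = 6, gene_body = 0.7, CEN = 2)
    htz1.mut <- c(promoter = 1.5, gene_body = 2.2, CEN = 2)
    h3 <- c(promoter = 0.5, gene_body = 1.5)
    list(
        "Fun30-like" = list(wt = fun30, mutant = fun30),
        "Htz1-like"  = list(wt = htz1.wt, mutant = htz1.mut),
        "H3-like"    = list(wt = h3, mutant = h3)
    )
}

#' @rdname simConfig
#' @param object a `SimConfig`.
#' @export
setMethod("show", "SimConfig", function(object) {
    cat(sprintf(
        "SimConfig: %d chromosome(s) x %d bp, %d genes/chrom, seed %d\n",
        object@nChromosomes, object@chromLength, object@nGenesPerChrom,
        object@seed))
    cat(sprintf("  nucleosome spacing %d bp, NDR %d bp, CEN core %d bp\n",
                object@nucleosomeSpacing, object@ndrWidth,
                object@cenCoreWidth))
    cat(sprintf("  ISIZE mixture: means %s, sd %.3g, weights %s\n",
                paste(object@isizeMeans, collapse = "/"), object@isizeSd,
                paste(object@isizeClassWeights, collapse = "/")))
    cat(sprintf("  %g pairs/nucleosome, jitter +/-%d bp\n",
                object@pairsPerNucleosome, object@dyadJitter))
    cat(sprintf(
        "  mutant: flank shift %+d bp, core height x%.3g, CEN subset %s\n",
        object@mutantFlankShift, object@mutantCoreHeightFactor,
        if (length(object@mutantCenSubset))
            paste(object@mutantCenSubset, collapse = ",") else "all"))
    invisible(NULL)
})

## Deterministic sub-stream seeding: each generator module draws from its
## own stream so that adding one simulation never perturbs another.
.STREAM_OFFSETS <- c(genome = 1L, pairs.wt = 11L, pairs.mutant = 12L,
                     chip = 100L, expression = 31L, background = 57L)

.setStreamSeed <- function(config, stream, extra = 0L) {
    base <- .STREAM_OFFSETS[[stream]] + as.integer(extra)
    ## keep derived seeds well inside 32-bit integer range
    s <- (as.numeric(config@seed) %% 2097143) * 1021 + base
    set.seed(as.integer(s %% .Machine$integer.max))
    invisible(NULL)
}

#' Write / read a flat key-value simulator configuration file
#'
#' Scalar and vector fields are serialized one per line as
#' `key = value[,value...]`; the ChIP enrichment map is flattened to
#' `chipEnrichment.<target>.<genotype>.<class> = fold`.
#'
#' @param config a [SimConfig-class].
#' @param path file path.
#' @return `writeSimConfig` returns `path` invisibly; `readSimConfig`
#'   returns a [SimConfig-class].
#' @export
writeSimConfig <- function(config, path) {
    stopifnot(is(config, "SimConfig"))
    ln <- character()
    for (nm in slotNames(config)) {
        v <- slot(config, nm)
        if (nm == "chipEnrichment") {
            for (tg in names(v)) for (gt in names(v[[tg]])) {
                fv <- v[[tg]][[gt]]
                for (cl in names(fv))
                    ln <- c(ln, sprintf("chipEnrichment.%s.%s.%s = %.15g",
                                        tg, gt, cl, fv[[cl]]))
            }
        } else {
            ln <- c(ln, sprintf("%s = %s", nm,
                                paste(format(v, digits = 15), collapse = ",")))
        }
    }
    writeLines(ln, path)
    invisible(path)
}

#' @rdname writeSimConfig
#' @export
readSimConfig <- function(path) {
    ln <- readLines(path)
    ln <- ln[nzchar(trimws(ln)) & !startsWith(trimws(ln), "#")]
    kv <- regmatches(ln, regexec("^\\s*([^=]+?)\\s*=\\s*(.*)$", ln))
    bad <- which(vapply(kv, length, integer(1)) != 3L)
    if (length(bad))
        stop("malformed configuration line ", bad[1L], ": ", ln[bad[1L]])
    keys <- vapply(kv, `[`, character(1), 2L)
    vals <- vapply(kv, `[`, character(1), 3L)
    args <- list()
    chip <- list()
    proto <- simConfig()
    for (i in seq_along(keys)) {
        k <- keys[i]
        if (startsWith(k, "chipEnrichment.")) {
            parts <- strsplit(sub("^chipEnrichment\\.", "", k), ".",
                              fixed = TRUE)[[1]]
            if (length(parts) != 3L)
                stop("malformed chipEnrichment key: ", k)
            chip[[parts[1]]][[parts[2]]][parts[3]] <- as.numeric(vals[i])
        } else {
            v <- strsplit(vals[i], ",", fixed = TRUE)[[1]]
            args[[k]] <- as.numeric(trimws(v))
        }
    }
    if (length(chip)) args$chipEnrichment <- chip
    known <- names(formals(simConfig))
    unknown <- setdiff(names(args), known)
    if (length(unknown))
        stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
    do.call(simConfig, args)
}
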