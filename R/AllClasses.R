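#' @import methods
#' @importFrom GenomeInfoDb seqnames seqlengths
#' @importFrom BiocGenerics start end width strand
#' @importFrom GenomicRanges GRanges
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors isSingleNumber isSingleString mcols `mcols<-`
#'   metadata `metadata<-`
#' @importFrom stats rnorm runif rpois rnbinom rlnorm qnorm pnorm phyper dhyper
#'   quantile median sd
#' @importFrom utils read.table write.table head tail packageVersion
NULL

setClassUnion("numericOrNULL", c("numeric", "NULL"))

#' BinnedTrack: fixed-width binned genome signal
#'
#' A per-chromosome vector of values on a fixed bin grid anchored at
#' coordinate 0: bin `i` (0-based) covers the half-open interval
#' `[i * binWidth, (i + 1) * binWidth)`.  The value semantics are carried in
#' the `valueType` slot so that downstream operations can refuse to mix,
#' e.g., a log2-enrichment track with a raw frequency track.
#'
#' @slot values named list of numeric vectors, one per chromosome; element
#'   `i` of a vector is the value of 0-based bin `i - 1`.
#' @slot binWidth single integer, bin width in bases.
#' @slot seqlengths named integer vector of chromosome lengths (bases).
#' @slot valueType one of `"frequency"`, `"log2-enrichment"`,
#'   `"linear-occupancy"`, `"difference"`, `"normalized"`.
#'
#' @seealso [BinnedTrack()] for the constructor, [binDyads()], [binTags()].
#' @export
setClass("BinnedTrack",
    representation(
        values    = "list",
        binWidth  = "integer",
        seqlengths = "integer",
        valueType = "character"
    )
)

.VALUE_TYPES <- c("frequency", "log2-enrichment", "linear-occupancy",
                  "difference", "normalized")

setValidity("BinnedTrack", function(object) {
    msg <- character()
    if (length(object@binWidth) != 1L || is.na(object@binWidth) ||
        object@binWidth < 1L)
        msg <- c(msg, "binWidth must be a single positive integer")
    if (!object@valueType %in% .VALUE_TYPES)
        msg <- c(msg, sprintf("valueType must be one of: %s",
                              paste(.VALUE_TYPES, collapse = ", ")))
    if (is.null(names(object@values)) || anyDuplicated(names(object@values)))
        msg <- c(msg, "values must be a uniquely named list")
    if (!identical(sort(names(object@values)), sort(names(object@seqlengths))))
        msg <- c(msg, "values and seqlengths must name the same chromosomes")
    for (chr in names(object@values)) {
        v <- object@values[[chr]]
        if (!is.numeric(v))
            msg <- c(msg, sprintf("values[['%s']] is not numeric", chr))
        else {
            want <- ceiling(object@seqlengths[[chr]] / object@binWidth)
            if (length(v) != want)
                msg <- c(msg, sprintf(
                    "values[['%s']] has %d bins, expected ceiling(%d / %d) = %d",
                    chr, length(v), object@seqlengths[[chr]],
                    object@binWidth, want))
        }
    }
    if (length(msg)) msg else TRUE
})

#' SimConfig: synthetic mini-genome study configuration
#'
#' Holds every tunable of the synthetic-data generator: genome geometry,
#' nucleosome array structure, the insert-size mixture of the simulated
#' MNase digest, ChIP enrichment folds per feature class and genotype,
#' the mutant-genotype chromatin perturbations, and the expression model.
#' Construct with [simConfig()], which validates and fills defaults.
#'
#' @slot nChromosomes number of chromosomes.
#' @slot chromLength length of every chromosome (bases).
#' @slot nGenesPerChrom protein-coding genes placed per chromosome.
#' @slot nucleosomeSpacing nucleosome repeat length (bases).
#' @slot ndrWidth width of the promoter nucleosome-depleted region (bases).
#' @slot cenCoreWidth width of the centromeric core particle (bases).
#' @slot isizeMeans mean insert size of the mono-, di-, tri-nucleosome
#'   classes (bases).
#' @slot isizeSd within-class insert-size standard deviation (bases).
#' @slot isizeClassWeights mixture weights of the size classes (sum to 1).
#' @slot pairsPerNucleosome expected sequenced pairs per unit-occupancy
#'   nucleosome.
#' @slot dyadJitter half-width of the uniform jitter on observed pair
#'   centers (bases).
#' @slot cenCoreOccupancy occupancy weight of the centromeric core particle
#'   relative to a bulk nucleosome.
#' @slot chipEnrichment nested list: target -> genotype -> named fold vector
#'   over feature classes.
#' @slot chipTagCount,inputTagCount tags sampled per ChIP / input library.
#' @slot mutantFlankShift displacement (bases) applied in the mutant to the
#'   nucleosomes immediately flanking each perturbed centromere.
#' @slot mutantCoreHeightFactor multiplier on the mutant core-particle
#'   occupancy at perturbed centromeres.
#' @slot mutantCenSubset indices of the centromeres carrying the mutant
#'   perturbation (`integer(0)` means all of them).
#' @slot deFraction fraction of genes given a true expression change at or
#'   beyond the fold cutoff.
#' @slot deRatioUp,deRatioDown true mutant/wild-type ratios planted in the
#'   changed genes.
#' @slot exprMeanLog,exprSdLog log-normal parameters of per-gene mean
#'   expression (natural-log scale).
#' @slot exprDispersion negative-binomial overdispersion (variance =
#'   mu + dispersion * mu^2).
#' @slot lowExprElevation optional true mutant/wild-type ratio applied to
#'   the weakly expressed quartile (1 = off).
#' @slot utrMissingFraction fraction of genes emitted without UTR
#'   annotation.
#' @slot seed integer seed; all generator sub-streams derive from it.
#' @export
setClass("SimConfig",
    representation(
        nChromosomes      = "integer",
        chromLength       = "integer",
        nGenesPerChrom    = "integer",
        nucleosomeSpacing = "integer",
        ndrWidth          = "integer",
        cenCoreWidth      = "integer",
        isizeMeans        = "numeric",
        isizeSd           = "numeric",
        isizeClassWeights = "numeric",
        pairsPerNucleosome = "numeric",
        dyadJitter        = "integer",
        cenCoreOccupancy  = "numeric",
        chipEnrichment    = "list",
        chipTagCount      = "integer",
        inputTagCount     = "integer",
        mutantFlankShift  = "integer",
        mutantCoreHeightFactor = "numeric",
        mutantCenSubset   = "integer",
        deFraction        = "numeric",
        deRatioUp         = "numeric",
        deRatioDown       = "numeric",
        exprMeanLog       = "numeric",
        exprSdLog         = "numeric",
        exprDispersion    = "numeric",
        lowExprElevation  = "numeric",
        utrMissingFraction = "numeric",
        seed              = "integer"
    )
)

setValidity("SimConfig", function(object) {
    msg <- character()
    chk_pos <- function(x, nm) {
        if (length(x) != 1L || is.na(x) || x <= 0)
            sprintf("%s must be a single positive value", nm)
        else character()
    }
    msg <- c(msg,
        chk_pos(object@nChromosomes, "nChromosomes"),
        chk_pos(object@chromLength, "chromLength"),
        chk_pos(object@nGenesPerChrom, "nGenesPerChrom"),
        chk_pos(object@nucleosomeSpacing, "nucleosomeSpacing"),
        chk_pos(object@ndrWidth, "ndrWidth"),
        chk_pos(object@cenCoreWidth, "cenCoreWidth"),
        chk_pos(object@isizeSd, "isizeSd"),
        chk_pos(object@pairsPerNucleosome, "pairsPerNucleosome"),
        chk_pos(object@cenCoreOccupancy, "cenCoreOccupancy"),
        chk_pos(object@chipTagCount, "chipTagCount"),
        chk_pos(object@inputTagCount, "inputTagCount"))
    if (length(object@isizeMeans) < 1L || any(object@isizeMeans <= 0))
        msg <- c(msg, "isizeMeans must be positive")
    if (length(object@isizeClassWeights) != length(object@isizeMeans))
        msg <- c(msg, "isizeClassWeights must match isizeMeans in length")
    else if (any(object@isizeClassWeights < 0) ||
             abs(sum(object@isizeClassWeights) - 1) > 1e-9)
        msg <- c(msg, "isizeClassWeights must be non-negative and sum to 1 (tolerance 1e-9)")
    if (object@cenCoreWidth >= 2L * object@nucleosomeSpacing)
        msg <- c(msg, "cenCoreWidth must be < 2 * nucleosomeSpacing")
    if (object@dyadJitter < 0L)
        msg <- c(msg, "dyadJitter must be >= 0")
    if (is.na(object@deFraction) || object@deFraction < 0 ||
        object@deFraction > 1)
        msg <- c(msg, "deFraction must lie in [0, 1]")
    if (object@utrMissingFraction < 0 || object@utrMissingFraction > 1)
        msg <- c(msg, "utrMissingFraction must lie in [0, 1]")
    if (object@mutantCoreHeightFactor <= 0)
        msg <- c(msg, "mutantCoreHeightFactor must be > 0")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "seed must be a single integer")
    if (length(msg)) msg else TRUE
})

#' TruthSet: simulator ground truth
#'
#' Ground-truth chromatin and expression state for the two simulated
#' genotypes, against which pipeline recovery is scored.
#'
#' @slot dyads data.frame with columns `genotype`, `chrom`, `pos` (0-based
#'   dyad coordinate), `occupancy`, `is_core` (logical flag for the
#'   centromeric core particle).
#' @slot cens [GenomicRanges::GRanges] of centromere intervals (1-based,
#'   one per chromosome, metadata column `id`).
#' @slot genes [GenomicRanges::GRanges] of gene ORFs with UTR/identity
#'   metadata.
#' @slot features [GenomicRanges::GRanges] of all annotated feature
#'   intervals (ORF, CEN, tRNA, snoRNA, snRNA, ARS, LTR, telomere).
#' @slot enrichment nested list: target -> genotype -> named fold vector.
#' @slot deGenes data.frame with columns `gene_id`, `true_ratio` for every
#'   gene whose true mutant/wild-type ratio is at or beyond the 1.5-fold
#'   cutoff.
#' @slot exprTruth data.frame with per-gene true mean and ratio.
#' @slot seqlengths named integer vector of chromosome lengths.
#' @slot config the [SimConfig-class] that produced this truth.
#' @export
setClass("TruthSet",
    representation(
        dyads      = "data.frame",
        cens       = "GRanges",
        genes      = "GRanges",
        features   = "GRanges",
        enrichment = "list",
        deGenes    = "data.frame",
        exprTruth  = "data.frame",
        seqlengths = "integer",
        config     = "SimConfig"
    )
)

setValidity("TruthSet", function(object) {
    msg <- character()
    need <- c("genotype", "chrom", "pos", "occupancy", "is_core")
    if (!all(need %in% names(object@dyads)))
        msg <- c(msg, sprintf("dyads must have columns: %s",
                              paste(need, collapse = ", ")))
    ## every centromere carries exactly one core-particle dyad per genotype
    if (all(need %in% names(object@dyads)) && length(object@cens)) {
        core <- object@dyads[object@dyads$is_core, , drop = FALSE]
        for (gt in unique(object@dyads$genotype)) {
            cg <- core[core$genotype == gt, , drop = FALSE]
            cen.chr <- as.character(GenomeInfoDb::seqnames(object@cens))
            lo <- BiocGenerics::start(object@cens) - 1L
            hi <- BiocGenerics::end(object@cens)
            hits <- vapply(seq_along(object@cens), function(i) {
                sum(cg$chrom == cen.chr[i] & cg$pos >= lo[i] & cg$pos < hi[i])
            }, integer(1))
            if (!all(hits == 1L))
                msg <- c(msg, sprintf(
                    "genotype '%s': every CEN interval must contain exactly one core dyad", gt))
        }
    }
    if (length(msg)) msg else TRUE
})

#' CenChromatinReport: per-centromere genotype comparison
#'
#' One row per centromere summarising core-particle detection in both
#' genotypes, the core height ratio, matched flanking-nucleosome peak
#' shifts, and the resulting qualitative calls.
#'
#' @slot table data.frame, one row per centromere (see [cenReport()]).
#' @slot matches data.frame of per-peak flank matches.
#' @slot params list of the thresholds used.
#' @export
setClass("CenChromatinReport",
    representation(
        table   = "data.frame",
        matches = "data.frame",
        params  = "list"
    )
)
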