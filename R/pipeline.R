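#' Run the full synthetic-data analysis pipeline
#'
#' Executes every stage end to end on one synthetic study:
#' `simulate` (genome, annotation, truth, reads, tags, counts),
#' `map-particles` (nucleosome-class dyad tracks for both genotypes, plus
#' the insert-size spectrum), `chip-track` (input-normalized enrichment,
#' occupancy and difference tracks with per-feature-class statistics),
#' `metagene` (expression-stratified anchored profile), `expression`
#' (normalized values and fold-change lists), `cen-report` (per-centromere
#' genotype comparison) and `overlap` (hypergeometric overlap of the
#' called against the planted up-regulated genes).  All outputs are plain
#' text (.fasta/.gff3/.bedpe/.bed/.sgr/.tsv) under `outdir`, and a
#' `manifest.json` records stages, parameters, seed and package version.
#' A failing stage aborts with its name; the manifest then flags the
#' partial output.
#'
#' @param config a [SimConfig-class]; `seed` overrides its seed.
#' @param outdir output directory (created if needed).
#' @param seed optional integer overriding `config@seed`.
#' @return invisibly, a list with the manifest and the key in-memory
#'   results (`truth`, `tracks`, `report`, `foldChange`, `overlap`).
#' @examples
#' \donttest{
#' res <- runPipeline(simConfig(nChromosomes = 1L, chromLength = 30000L,
#'                              nGenesPerChrom = 8L, seed = 2),
#'                    outdir = tempfile("demo"))
#' }
#' @export
runPipeline <- function(config = simConfig(), outdir, seed = NULL) {
    stopifnot(is(config, "SimConfig"))
    if (!is.null(seed)) config@seed <- as.integer(seed)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    manifest <- list(
        package = "chromParticles",
        version = as.character(packageVersion("chromParticles")),
        seed = config@seed,
        parameters = list(sizeClassTarget = 150, windowFraction = 0.2,
                          dyadBin = 15, chipBin = 10, probe = 25,
                          foldCutoff = 1.5, flank = 5000),
        stages = list())
    state <- new.env(parent = emptyenv())
    stages <- list(
        simulate = .stageSimulate, `map-particles` = .stageMapParticles,
        `chip-track` = .stageChipTrack, metagene = .stageMetagene,
        expression = .stageExpression, `cen-report` = .stageCenReport,
        overlap = .stageOverlap)
    for (nm in names(stages)) {
        res <- tryCatch(stages[[nm]](config, outdir, state),
                        error = function(e) e)
        if (inherits(res, "error")) {
            manifest$stages[[nm]] <- list(status = "failed",
                                          error = conditionMessage(res))
            .writeManifest(manifest, outdir, complete = FALSE)
            stop("pipeline stage '", nm, "' failed: ",
                 conditionMessage(res))
        }
        manifest$stages[[nm]] <- list(status = "complete", outputs = res)
    }
    .writeManifest(manifest, outdir, complete = TRUE)
    invisible(list(manifest = manifest, truth = state$truth,
                   tracks = state$tracks, report = state$report,
                   foldChange = state$fc, overlap = state$overlap))
}

.writeManifest <- function(manifest, outdir, complete) {
    manifest$complete <- complete
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

.out <- function(outdir, ...) file.path(outdir, ...)

.stageSimulate <- function(config, outdir, state) {
    g <- makeGenome(config)
    state$genome <- g
    state$truth <- g$truth
    writeGenomeFasta(g$sequence, .out(outdir, "genome.fasta"))
    writeAnnotationGff(g$annotation, .out(outdir, "annotation.gff3"))
    writeSimConfig(config, .out(outdir, "sim-config.txt"))
    writeTsv(truthDyads(g$truth), .out(outdir, "truth-dyads.tsv"))
    writeTsv(truthExpr(g$truth), .out(outdir, "truth-expression.tsv"))
    state$pairs <- list(
        wt = simulateMnasePairs(g$truth, config, "wt"),
        mutant = simulateMnasePairs(g$truth, config, "mutant"))
    for (gt in names(state$pairs))
        writePairsBedpe(state$pairs[[gt]],
                        .out(outdir, paste0("pairs-", gt, ".bedpe")))
    state$tags <- list(
        fun30 = simulateChipTags(g$truth, config, "Fun30-like", "wt"),
        htz1.wt = simulateChipTags(g$truth, config, "Htz1-like", "wt"),
        htz1.mut = simulateChipTags(g$truth, config, "Htz1-like",
                                    "mutant"))
    writeTagsBed(state$tags$fun30$chip, .out(outdir, "chip-fun30.bed"))
    writeTagsBed(state$tags$fun30$input, .out(outdir, "input.bed"))
    c("genome.fasta", "annotation.gff3", "sim-config.txt",
      "truth-dyads.tsv", "truth-expression.tsv", "pairs-wt.bedpe",
      "pairs-mutant.bedpe", "chip-fun30.bed", "input.bed")
}

.stageMapParticles <- function(config, outdir, state) {
    sl <- state$truth@seqlengths
    state$tracks <- list()
    for (gt in names(state$pairs)) {
        tr <- mapParticles(state$pairs[[gt]], seqlengths = sl)
        state$tracks[[paste0("nuc.", gt)]] <- tr
        writeSgr(tr, .out(outdir, paste0("nuc-", gt, ".sgr")))
    }
    spec <- isizeSpectrum(state$pairs$wt)
    writeTsv(spec, .out(outdir, "isize-spectrum.tsv"))
    c("nuc-wt.sgr", "nuc-mutant.sgr", "isize-spectrum.tsv")
}

.stageChipTrack <- function(config, outdir, state) {
    sl <- state$truth@seqlengths
    bt <- function(tags) binTags(tags, binWidth = 10L, seqlengths = sl)
    fun30 <- smooth3(log2Enrichment(bt(state$tags$fun30$chip),
                                    bt(state$tags$fun30$input)))
    htz1.wt <- linearOccupancy(bt(state$tags$htz1.wt$chip),
                               bt(state$tags$htz1.wt$input))
    htz1.mut <- linearOccupancy(bt(state$tags$htz1.mut$chip),
                                bt(state$tags$htz1.mut$input))
    state$tracks$chip.fun30 <- fun30
    state$tracks$htz1.diff <- differenceTrack(htz1.mut, htz1.wt)
    writeSgr(fun30, .out(outdir, "chip-fun30-log2.sgr"))
    writeBedgraph(fun30, .out(outdir, "chip-fun30-log2.bedgraph"),
                  name = "fun30_log2")
    writeSgr(state$tracks$htz1.diff, .out(outdir, "htz1-diff.sgr"))
    stats <- featureBoxStats(fun30, state$genome$annotation)
    writeTsv(stats, .out(outdir, "feature-stats.tsv"))
    state$featureStats <- stats
    c("chip-fun30-log2.sgr", "chip-fun30-log2.bedgraph", "htz1-diff.sgr",
      "feature-stats.tsv")
}

.stageMetagene <- function(config, outdir, state) {
    tab <- assignIgrs(geneTable(truthGenes(state$truth)),
                      neighbors = state$genome$annotation,
                      seqlengths = state$truth@seqlengths)
    tab <- classifyOrientation(tab, neighbors = state$genome$annotation)
    counts <- simulateExpression(state$truth, config)
    state$counts <- counts
    lens <- tab$orf_end - tab$orf_start
    names(lens) <- tab$id
    expr <- quantifyExpression(
        structure(counts$wt_count, names = counts$gene_id),
        lens[counts$gene_id])
    cats <- expressionCategories(expr)
    tab$expression_category <- as.character(cats[tab$id])
    state$geneTable <- tab
    writeTsv(tab, .out(outdir, "gene-table.tsv"))
    prof <- anchoredProfile(state$tracks$chip.fun30, tab, anchor = "tss5",
                            strata = cats)
    writeTsv(prof, .out(outdir, "metagene-tss.tsv"))
    c("gene-table.tsv", "metagene-tss.tsv")
}

.stageExpression <- function(config, outdir, state) {
    counts <- state$counts
    writeTsv(counts, .out(outdir, "counts.tsv"))
    lens <- state$geneTable$orf_end - state$geneTable$orf_start
    names(lens) <- state$geneTable$id
    wt <- quantifyExpression(
        structure(counts$wt_count, names = counts$gene_id),
        lens[counts$gene_id])
    mut <- quantifyExpression(
        structure(counts$mutant_count, names = counts$gene_id),
        lens[counts$gene_id])
    fc <- foldChangeLists(wt, mut)
    state$fc <- fc
    writeLines(fc$up, .out(outdir, "genes-up.txt"))
    writeLines(fc$down, .out(outdir, "genes-down.txt"))
    c("counts.tsv", "genes-up.txt", "genes-down.txt")
}

.stageCenReport <- function(config, outdir, state) {
    rep <- cenReport(state$tracks$nuc.wt, state$tracks$nuc.mutant,
                     truthCens(state$truth))
    state$report <- rep
    writeTsv(cenReportTable(rep), .out(outdir, "cen-report.tsv"))
    "cen-report.tsv"
}

.stageOverlap <- function(config, outdir, state) {
    truth.up <- truthDeGenes(state$truth)
    truth.up <- truth.up$gene_id[truth.up$true_ratio > 1]
    called.up <- state$fc$up
    universe <- nrow(state$geneTable)
    ov <- hypergeomOverlap(universe, length(truth.up), length(called.up),
                           length(intersect(truth.up, called.up)))
    state$overlap <- ov
    writeTsv(data.frame(N = ov$N, m = ov$m, n = ov$n, k = ov$k,
                        p_value = ov$p_value, direction = ov$direction),
             .out(outdir, "overlap.tsv"))
    "overlap.tsv"
}
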