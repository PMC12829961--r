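# End-to-end orchestration: parse -> filter -> orient/coverage ->
# compress/log -> MODWT -> p-values -> boundaries -> bin/balance ->
# pair -> donut anchors -> diamond refine -> score -> write.

#' Pipeline configuration
#'
#' Collects every tunable of the calling pipeline with its default:
#' insert window 500 bp - 5 Mb, mapq 30, boundary alpha 0.05, TAD size
#' window 40 kb - 5 Mb, donut geometry pw 2 / w 5 with alpha 0.1, at
#' least 10 observed contacts and 1.5-fold enrichment, and a resolution
#' ladder of 5/10/25/50 kb (1 kb added for genomes under 500 Mb). The
#' pipeline is deterministic: no seed.
#'
#' @param resolutions bin sizes in bp, ascending; NULL picks the ladder
#'   from the genome size.
#' @param alpha boundary significance level on Holm-adjusted p-values.
#' @param minInsert,maxInsert insert filter (bp).
#' @param minMapq mapping-quality filter.
#' @param minSize,maxSize TAD/loop span window (bp).
#' @param donutAlpha,pw,w,minObs,minRatio donut parameters.
#' @param J maximum wavelet scale (NULL: automatic).
#' @param outDir output directory (NULL: no files written).
#' @return a \code{waveTADConfig} list.
#' @export
waveTADConfig <- function(resolutions = NULL, alpha = 0.05,
                          minInsert = 500, maxInsert = 5e6, minMapq = 30,
                          minSize = 4e4, maxSize = 5e6, donutAlpha = 0.1,
                          pw = 2, w = 5, minObs = 10, minRatio = 1.5,
                          J = NULL, outDir = NULL) {
  stopifnot(alpha > 0, minInsert > 0, maxInsert >= minInsert,
            minSize > 0, maxSize >= minSize, donutAlpha > 0, w > pw)
  if (!is.null(resolutions)) resolutions <- sort(resolutions)
  structure(list(resolutions = resolutions, alpha = alpha,
                 minInsert = minInsert, maxInsert = maxInsert,
                 minMapq = minMapq, minSize = minSize, maxSize = maxSize,
                 donutAlpha = donutAlpha, pw = pw, w = w, minObs = minObs,
                 minRatio = minRatio, J = J, outDir = outDir),
            class = "waveTADConfig")
}

.defaultResolutions <- function(genomeSize) {
  if (genomeSize < 5e8) c(1e3, 5e3, 1e4, 2.5e4, 5e4)
  else c(5e3, 1e4, 2.5e4, 5e4)
}

#' Run the full TAD/loop calling pipeline
#'
#' Executes the complete flow per chromosome and, when
#' \code{config$outDir} is set, writes \code{tads.tsv} (scored calls),
#' \code{boundaries.bed}, \code{anchors.bedpe} and a structured
#' \code{log.json} of per-stage record counts. Identical inputs and
#' configuration produce identical outputs; per-chromosome results are
#' independent and sorted.
#'
#' @param pairs a \code{\link{ContactPairs}} object, or a path to a pairs
#'   file (parsed with \code{\link{parseContacts}}).
#' @param config a \code{\link{waveTADConfig}}.
#' @param chromSizes optional named sizes when \code{pairs} is a path.
#' @return (invisibly) list with \code{tads} (GRanges),
#'   \code{boundaries} (GRanges), \code{anchors} (data.frame) and
#'   \code{log} (per-chromosome stage counts).
#' @export
runWaveTAD <- function(pairs, config = waveTADConfig(), chromSizes = NULL) {
  if (is.character(pairs))
    pairs <- parseContacts(pairs, chromSizes = chromSizes)
  stopifnot(is(pairs, "ContactPairs"))
  filtered <- filterPairs(pairs, minInsert = config$minInsert,
                          maxInsert = config$maxInsert,
                          minMapq = config$minMapq)
  sizes <- chromSizes(filtered)
  resolutions <- config$resolutions
  if (is.null(resolutions)) resolutions <- .defaultResolutions(sum(sizes))
  chroms <- sort(intersect(names(sizes), unique(pairsTable(filtered)$chrom1)))

  allTads <- list()
  allBounds <- list()
  allAnchors <- list()
  logRec <- list()
  for (chrom in chroms) {
    stage <- list(chrom = chrom, pairs = sum(pairsTable(filtered)$chrom1 == chrom))
    cov <- orientAndCoverage(filtered, chrom)
    left <- trackBoundaries(compressLog(cov$five_prime), alpha = config$alpha,
                            J = config$J, maxSize = config$maxSize)
    right <- trackBoundaries(compressLog(cov$three_prime), alpha = config$alpha,
                             J = config$J, maxSize = config$maxSize)
    stage$leftBoundaries <- length(left)
    stage$rightBoundaries <- length(right)
    allBounds[[chrom]] <- c(left, right)
    if (!length(left) || !length(right)) {
      warning("no ", if (length(left)) "right" else "left",
              " boundaries on ", chrom, "; empty output for it")
      logRec[[chrom]] <- stage
      next
    }
    cands <- pairBoundaries(left, right, minSize = config$minSize,
                            maxSize = config$maxSize)
    stage$candidates <- nrow(cands)
    usable <- resolutions[resolutions < sizes[[chrom]] / (2 * config$w + 1)]
    mats <- lapply(usable, function(res)
      balanceMatrix(binContacts(filtered, chrom, res)))
    anch <- scanAnchors(cands, mats, donutAlpha = config$donutAlpha,
                        pw = config$pw, w = config$w, minObs = config$minObs,
                        minRatio = config$minRatio,
                        maxDistance = config$maxSize)
    stage$anchored <- nrow(anch$candidates)
    refined <- diamondRefine(anch$candidates, mats, w = config$w)
    stage$refined <- nrow(refined)
    allTads[[chrom]] <- scoreTADs(refined)
    if (nrow(anch$anchors))
      allAnchors[[chrom]] <- cbind(chrom = chrom, anch$anchors)
    logRec[[chrom]] <- stage
  }
  tads <- if (length(allTads)) sort(do.call(c, unname(allTads)))
          else scoreTADs(data.frame(chrom = character(0), start = numeric(0),
                                    end = numeric(0), Lp = numeric(0),
                                    Rp = numeric(0), ANCp = numeric(0),
                                    anchorRes = numeric(0)))
  bounds <- if (length(allBounds)) sort(do.call(c, unname(allBounds)))
            else GenomicRanges::GRanges()
  anchors <- if (length(allAnchors)) do.call(rbind, unname(allAnchors))
             else data.frame()

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    writeCalls(tads, file.path(config$outDir, "tads.tsv"))
    exportBoundariesBED(bounds, file.path(config$outDir, "boundaries.bed"))
    .writeAnchorsBedpe(anchors, file.path(config$outDir, "anchors.bedpe"))
    jsonlite::write_json(
      list(parameters = unclass(config)[!vapply(config, is.null, TRUE)],
           stages = logRec),
      file.path(config$outDir, "log.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(list(tads = tads, boundaries = bounds, anchors = anchors,
                 log = logRec))
}

.writeAnchorsBedpe <- function(anchors, path) {
  if (!nrow(anchors)) {
    file.create(path)
    return(invisible(path))
  }
  tab <- data.frame(
    chrom1 = anchors$chrom,
    start1 = anchors$binI * anchors$resolution,
    end1 = (anchors$binI + 1) * anchors$resolution,
    chrom2 = anchors$chrom,
    start2 = anchors$binJ * anchors$resolution,
    end2 = (anchors$binJ + 1) * anchors$resolution,
    score = round(-log10(pmax(anchors$p, 1e-100)), 4))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
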