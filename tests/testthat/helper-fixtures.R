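# Shared fixtures, memoized so expensive end-to-end runs happen once per
# test session (several files assert on the same runs).

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

# a CompressedSignal over 0..(n-1) from a plain vector
asSignal <- function(x, orientation = "five_prime") {
  new("CompressedSignal", values = as.numeric(x),
      indexMap = as.numeric(seq_along(x) - 1L),
      chrom = "chrT", orientation = orientation)
}

# a CoverageTrack from a plain depth vector
asTrack <- function(depth, chrom = "chrT", orientation = "five_prime") {
  new("CoverageTrack", chrom = chrom, orientation = orientation,
      depth = S4Vectors::Rle(as.integer(depth)),
      chromLength = length(depth))
}

# ContactPairs built directly from end positions (table dialect)
makePairs <- function(pos1, pos2, chrom = "chrT", len = 1e6,
                      chrom2 = chrom, mapq = 60, readLength = 50) {
  tab <- data.frame(chrom1 = chrom, pos1 = pos1, strand1 = "+",
                    mapq1 = mapq, chrom2 = chrom2, pos2 = pos2,
                    strand2 = "-", mapq2 = mapq, stringsAsFactors = FALSE)
  sizes <- setNames(rep(len, length(unique(c(chrom, chrom2)))),
                    unique(c(chrom, chrom2)))
  new("ContactPairs", pairs = tab, chromSizes = sizes,
      readLength = readLength, provenance = list(source = "test"))
}

# --- memoized end-to-end runs (the study conditions) -------------------

# 2 Mb chromosome, 4 planted non-nested TADs, 0.1M pairs/Mb
recoveryFixture <- function() {
  memo("recovery", {
    spec <- simSpec(
      chromLength = 2e6,
      tads = data.frame(start = c(1e5, 5.5e5, 1.0e6, 1.6e6),
                        end = c(4e5, 8.5e5, 1.45e6, 1.85e6)),
      nPairs = 2e5, seed = 42)
    sim <- simulateContacts(spec)
    run <- suppressWarnings(runWaveTAD(sim$pairs, waveTADConfig()))
    list(spec = spec, sim = sim, run = run)
  })
}

# 400 kb TAD containing a 100 kb subTAD
nestedFixture <- function() {
  memo("nested", {
    spec <- simSpec(
      chromLength = 1.2e6,
      tads = data.frame(start = c(3e5, 4.5e5), end = c(7e5, 5.5e5)),
      nPairs = 1.5e5, seed = 11)
    sim <- simulateContacts(spec)
    run <- suppressWarnings(runWaveTAD(sim$pairs, waveTADConfig()))
    list(spec = spec, sim = sim, run = run)
  })
}

# one planted TAD present in a fraction of cells
fractionFixture <- function(fraction) {
  memo(paste0("fraction_", fraction), {
    spec <- simSpec(
      chromLength = 1e6,
      tads = data.frame(start = 3e5, end = 7e5, fraction = fraction),
      nPairs = 1e5, seed = 5)
    sim <- simulateContacts(spec)
    run <- suppressWarnings(runWaveTAD(sim$pairs, waveTADConfig()))
    list(spec = spec, sim = sim, run = run)
  })
}

# small end-to-end smoke fixture (two TADs on 1 Mb)
smokeFixture <- function() {
  memo("smoke", {
    spec <- simSpec(
      chromLength = 1e6,
      tads = data.frame(start = c(2e5, 6e5), end = c(4.5e5, 8.5e5)),
      nPairs = 1e5, seed = 7)
    sim <- simulateContacts(spec)
    outDir <- file.path(tempdir(), "waveTAD-smoke")
    run <- suppressWarnings(
      runWaveTAD(sim$pairs, waveTADConfig(outDir = outDir)))
    list(spec = spec, sim = sim, run = run, outDir = outDir)
  })
}

uniqueBoundaries <- function(tads) {
  unique(c(GenomicRanges::start(tads) - 1, GenomicRanges::end(tads)))
}
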