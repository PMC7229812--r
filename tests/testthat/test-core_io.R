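test_that("FASTQ reading handles identity cases and decodes Phred+33", {
    f <- withr::local_tempfile(fileext = ".fastq")
    file.create(f)
    expect_length(readNanoporeFastq(f), 0)

    writeLines(c("@r1", "ACGT", "+", "!!!!"), f)
    rs <- readNanoporeFastq(f)
    expect_equal(readIDs(rs), "r1")
    expect_equal(as.integer(phredScores(rs)[[1]]), c(0L, 0L, 0L, 0L))

    # header descriptions are dropped from the id; 'I' encodes phred 40
    writeLines(c("@r2 ch=1 start=7", "ACGTN", "+", "IIIII"), f)
    rs <- readNanoporeFastq(f)
    expect_equal(readIDs(rs), "r2")
    expect_equal(as.integer(phredScores(rs)[[1]]), rep(40L, 5))
})

test_that("malformed FASTQ records are hard errors naming the record", {
    f <- withr::local_tempfile(fileext = ".fastq")
    writeLines(c("@ok", "ACGT", "+", "IIII", "@broken", "ACGTA", "+", "III"),
               f)
    expect_error(readNanoporeFastq(f), "broken")
    writeLines(c("@ok", "ACGT", "+"), f)
    expect_error(readNanoporeFastq(f), "multiple of 4")
    expect_error(readNanoporeFastq(tempfile()), "no such file")
})

test_that("simulated reads round-trip byte-identically through FASTQ", {
    cfg <- simulationConfig(seed = 42, n_reads = 100,
                            genome_length = 30000, segment_length = 6000,
                            pre_range = c(500L, 3000L),
                            tail_range = c(200L, 800L),
                            read_length_range = c(1000L, 3000L),
                            background_read_fraction = 0.5)
    sim <- simulateReads(cfg)
    f1 <- withr::local_tempfile(fileext = ".fastq")
    writeNanoporeFastq(sim$reads, f1)
    back <- readNanoporeFastq(f1)
    expect_equal(readIDs(back), readIDs(sim$reads))
    expect_equal(as.character(readSequences(back)),
                 as.character(readSequences(sim$reads)))
    expect_identical(lapply(phredScores(back), as.integer),
                     lapply(phredScores(sim$reads), as.integer))
    f2 <- withr::local_tempfile(fileext = ".fastq")
    writeNanoporeFastq(back, f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("split alignments load with hand-computed coordinates", {
    # primary 5000M then 3000S at chr1:10000 (+); supplementary of the
    # clipped tail at chr1:12000 (-), stored 3000M5000S. Expected (hand
    # CIGAR arithmetic, 0-based half-open):
    #   primary  ref [9999, 14999)   read [0, 5000)
    #   suppl    ref [11999, 14999)  read [5000, 8000)
    f <- withr::local_tempfile(fileext = ".sam")
    writeLines(c(
        "@HD\tVN:1.6",
        "@SQ\tSN:chr1\tLN:100000",
        paste("split", 0, "chr1", 10000, 60, "5000M3000S", "*", 0, 0, "*",
              "*", "SA:Z:chr1,12000,-,3000M5000S,60,0;", sep = "\t"),
        paste("split", 2064, "chr1", 12000, 60, "3000M5000S", "*", 0, 0,
              "*", "*", "SA:Z:chr1,10000,+,5000M3000S,60,0;", sep = "\t"),
        paste("plain", 0, "chr1", 500, 60, "100M", "*", 0, 0, "*", "*",
              sep = "\t"),
        paste("lost", 4, "*", 0, 0, "*", "*", 0, 0, "*", "*", sep = "\t"),
        paste("plain", 256, "chr1", 900, 0, "100M", "*", 0, 0, "*", "*",
              sep = "\t")), f)
    aln <- readSplitAlignments(f)
    seg <- alignmentSegments(aln)
    expect_false("lost" %in% seg$read_id)       # unmapped excluded
    expect_equal(sum(seg$read_id == "plain"), 1) # secondary excluded
    sp <- seg[seg$read_id == "split", ]
    expect_equal(sp$read_start, c(0L, 5000L))
    expect_equal(sp$read_end, c(5000L, 8000L))   # intervals abut at 5000
    expect_equal(sp$ref_start, c(9999L, 11999L))
    expect_equal(sp$ref_end, c(14999L, 14999L))
    expect_equal(sp$strand, c("+", "-"))
    expect_equal(sp$is_primary, c(TRUE, FALSE))
    expect_equal(referenceLengths(aln), c(chr1 = 100000L))
})

test_that("headerless SAM is rejected; stray SA promises only warn", {
    f <- withr::local_tempfile(fileext = ".sam")
    writeLines(paste("r", 0, "chr1", 100, 60, "50M", "*", 0, 0, "*", "*",
                     sep = "\t"), f)
    expect_error(readSplitAlignments(f), "header")

    writeLines(c(
        "@SQ\tSN:chr1\tLN:100000",
        paste("r", 0, "chr1", 100, 60, "50M", "*", 0, 0, "*", "*",
              "SA:Z:chr1,900,-,20M30S,60,0;", sep = "\t")), f)
    expect_warning(aln <- readSplitAlignments(f), "SA tag")
    expect_equal(nrow(alignmentSegments(aln)), 1)
})

test_that("simulator alignments survive the SAM round trip and match an
           independent CIGAR walker", {
    cfg <- simulationConfig(seed = 9, n_reads = 120,
                            genome_length = 40000, segment_length = 6000,
                            pre_range = c(500L, 3000L),
                            tail_range = c(200L, 800L),
                            read_length_range = c(1000L, 4000L),
                            background_read_fraction = 0.6)
    sim <- simulateReads(cfg)
    f <- withr::local_tempfile(fileext = ".sam")
    nanoJunction:::.writeSAM(sim$sam, cfg, f)
    aln <- readSplitAlignments(f)
    a <- alignmentSegments(aln)
    b <- alignmentSegments(sim$alignments)
    ord <- function(d) {
        d <- d[order(d$read_id, d$read_start, d$ref_start), ]
        rownames(d) <- NULL
        d
    }
    expect_equal(ord(a), ord(b))

    skip_if_not_installed("GenomicAlignments")
    set.seed(1)
    cig <- sample(b$cigar, 100)
    expect_equal(vapply(cig, cigarRefSpan, integer(1), USE.NAMES = FALSE),
                 GenomicAlignments::cigarWidthAlongReferenceSpace(cig))
    expect_equal(
        vapply(cig, cigarReadSpan, integer(1), USE.NAMES = FALSE),
        GenomicAlignments::cigarWidthAlongQuerySpace(
            cig, after.soft.clipping = TRUE))
})

test_that("signal TSV round-trips and rejects non-monotone base indices", {
    tr <- SignalTraceSet(list(a = c(90.12, 91, 89.5, 130.25, 129)),
                         list(a = c(0L, 2L)), 4000)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeSignalTraces(tr, f)
    back <- readSignalTraces(f)
    expect_equal(readIDs(back), "a")
    expect_equal(as.numeric(signalSamples(back)[[1]]),
                 as.numeric(signalSamples(tr)[[1]]))
    expect_equal(as.integer(baseIndex(back)[[1]]), c(0L, 2L))

    writeLines(c("bad\t4000", "1,2,3,4,5,6,7,8,9,10", "5,0", ""), f)
    expect_error(readSignalTraces(f), "non-monotone")
    expect_error(SignalTraceSet(list(a = 1:10), list(a = c(5L, 0L))),
                 "non-decreasing")
    expect_error(SignalTraceSet(list(a = 1:3), list(a = c(0L, 5L))),
                 "exceeds")
})

test_that("simulated signal traces round-trip losslessly", {
    sim <- cachedSim("small60", function() {
        simulateReads(simulationConfig(
            seed = 5, n_reads = 60, genome_length = 30000,
            segment_length = 6000, pre_range = c(500L, 3000L),
            tail_range = c(200L, 800L), read_length_range = c(1000L, 3000L),
            background_read_fraction = 0.5))
    })
    sig <- simulateSignal(sim)
    f <- withr::local_tempfile(fileext = ".tsv")
    writeSignalTraces(sig$traces, f)
    back <- readSignalTraces(f)
    expect_equal(readIDs(back), readIDs(sig$traces))
    expect_equal(lapply(signalSamples(back), as.numeric),
                 lapply(signalSamples(sig$traces), as.numeric))
    expect_equal(lapply(baseIndex(back), as.integer),
                 lapply(baseIndex(sig$traces), as.integer))
    expect_equal(unname(sampleRate(back)), unname(sampleRate(sig$traces)))
})
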