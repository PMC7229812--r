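test_that("uplift detection finds a planted step and matches a naive
           reimplementation", {
    # constant trace: nothing exceeds the baseline
    flat <- SignalTraceSet(list(f = rep(90, 2000)), list(f = 0L))
    expect_equal(nrow(detectUplift(flat)), 0)

    set.seed(44)
    x <- c(rnorm(20000, 90, 2), rnorm(5000, 130, 2), rnorm(25000, 90, 2))
    tr <- SignalTraceSet(list(s = round(x, 2)), list(s = 0L))
    up <- detectUplift(tr, window = 250)
    expect_equal(nrow(up), 1)
    expect_lt(abs(up$sample_start - 20000), 250)
    expect_lt(abs(up$sample_end - 25000), 250)
    expect_gt(up$mean_current, up$baseline_current)

    naive <- naiveUplift(round(x, 2), window = 250L)
    expect_equal(cbind(up$sample_start, up$sample_end), unname(naive))

    # invariances: shifting or rescaling the current moves baseline and
    # threshold together
    shifted <- SignalTraceSet(list(s = round(x, 2) + 1000), list(s = 0L))
    scaled <- SignalTraceSet(list(s = round(x, 2) * 3), list(s = 0L))
    for (other in list(shifted, scaled)) {
        up2 <- detectUplift(other, window = 250)
        expect_equal(up2[, c("sample_start", "sample_end")],
                     up[, c("sample_start", "sample_end")])
    }

    short <- SignalTraceSet(list(t = rnorm(100, 90, 2)), list(t = 0L))
    expect_warning(none <- detectUplift(short, window = 250), "skipped")
    expect_equal(nrow(none), 0)
})

test_that("expected bases walk the CIGAR and bridge unaligned gaps", {
    plain <- manualSplitAlignments(data.frame(
        read_id = "r", chrom = "chr1", ref_start = 1000L, ref_end = 2000L,
        read_start = 0L, read_end = 1000L, strand = "+", is_primary = TRUE,
        cigar = "1000M", stringsAsFactors = FALSE))
    expect_equal(expectedBasesForRegion(plain, "r", 0, 1000), 1000L)

    # deletions inside the region count; a deletion at its edge does not
    del <- manualSplitAlignments(data.frame(
        read_id = "r", chrom = "chr1", ref_start = 1000L, ref_end = 2002L,
        read_start = 0L, read_end = 1000L, strand = "+", is_primary = TRUE,
        cigar = "500M2D500M", stringsAsFactors = FALSE))
    expect_equal(expectedBasesForRegion(del, "r", 0, 1000), 1002L)
    expect_equal(expectedBasesForRegion(del, "r", 0, 500), 500L)
    expect_equal(expectedBasesForRegion(del, "r", 0, 501), 503L)

    # unaligned gap between segments whose read-adjacent reference
    # coordinates are 15000 (+, ref_end) and 13000 (-, ref_end)
    gap <- manualSplitAlignments(rbind(
        data.frame(read_id = "g", chrom = "chr1", ref_start = 10000L,
                   ref_end = 15000L, read_start = 0L, read_end = 5000L,
                   strand = "+", is_primary = TRUE,
                   cigar = "5000M2300S", stringsAsFactors = FALSE),
        data.frame(read_id = "g", chrom = "chr1", ref_start = 11000L,
                   ref_end = 13000L, read_start = 5300L, read_end = 7300L,
                   strand = "-", is_primary = FALSE,
                   cigar = "2000M5300S", stringsAsFactors = FALSE)))
    expect_equal(expectedBasesForRegion(gap, "g", 5000, 5300), 2000L)
    # half the gap implies half the span
    expect_equal(expectedBasesForRegion(gap, "g", 5000, 5150), 1000L)

    # a region beyond all alignments is undefined
    expect_error(expectedBasesForRegion(gap, "g", 7100, 7400),
                 "flanking alignment")
})

test_that("segment rates divide sensor samples by expected bases", {
    aln <- manualSplitAlignments(data.frame(
        read_id = "r", chrom = "chr1", ref_start = 0L, ref_end = 300L,
        read_start = 0L, read_end = 300L, strand = "+", is_primary = TRUE,
        cigar = "300M", stringsAsFactors = FALSE))
    counts <- rep.int(c(10L, 6L, 10L), c(100L, 100L, 100L))
    bidx <- cumsum(counts) - counts
    tr <- SignalTraceSet(list(r = rnorm(sum(counts), 90, 5)),
                         list(r = bidx))

    r1 <- segmentRate(tr, aln, "r", 0, 100)
    expect_equal(r1$expected_bases, 100L)
    expect_equal(r1$n_samples, 1000L)
    expect_equal(r1$samples_per_base, 10)
    expect_equal(segmentRate(tr, aln, "r", 100, 200)$samples_per_base, 6)
    # region running to the read end is clamped to the trace length
    expect_equal(segmentRate(tr, aln, "r", 200, 300)$samples_per_base, 10)
    expect_error(segmentRate(tr, aln, "r", 50, 50), "zero read length")

    # rates depend only on the base index, not the current values
    tr2 <- SignalTraceSet(list(r = rnorm(sum(counts), 90, 5) * 7 + 11),
                          list(r = bidx))
    expect_equal(segmentRate(tr2, aln, "r", 0, 100)$samples_per_base, 10)

    reg <- data.frame(read_id = "r", start = 100L, end = 200L,
                      length = 100L, median_phred = 5, bounded = TRUE)
    cmp <- compareRegionRates(tr, aln, reg, c(r = 300L))
    expect_equal(cmp$per_read$normal_rate, 10)
    expect_equal(cmp$per_read$low_rate, 6)
    expect_equal(cmp$n_lower, 1L)
})

test_that("disjoint segment samples never exceed the trace total", {
    sim <- cachedSim("small60", function() {
        simulateReads(simulationConfig(
            seed = 5, n_reads = 60, genome_length = 30000,
            segment_length = 6000, pre_range = c(500L, 3000L),
            tail_range = c(200L, 800L), read_length_range = c(1000L, 3000L),
            background_read_fraction = 0.5))
    })
    sig <- simulateSignal(sim)
    tr <- sig$traces
    for (id in head(readIDs(tr), 5)) {
        L <- unname(readLengths(sim$reads)[[id]])
        thirds <- unique(c(0L, as.integer(L %/% 3), as.integer(2 * L %/% 3),
                           L))
        tot <- sum(vapply(seq_len(3), function(k)
            segmentRate(tr, sim$alignments, id, thirds[k],
                        thirds[k + 1])$n_samples, integer(1)))
        expect_lte(tot, length(signalSamples(tr)[[id]]))
    }
})

test_that("planted translocation rates are recovered within tolerance", {
    sim <- cachedSim("small60", function() {
        simulateReads(simulationConfig(
            seed = 5, n_reads = 60, genome_length = 30000,
            segment_length = 6000, pre_range = c(500L, 3000L),
            tail_range = c(200L, 800L), read_length_range = c(1000L, 3000L),
            background_read_fraction = 0.5))
    })
    sig <- simulateSignal(sim)
    tr <- sim$truth[sim$truth$spans_junction & sim$truth$bounded, ]
    reg <- data.frame(read_id = tr$read_id,
                      start = tr$preceding_length,
                      end = tr$preceding_length + tr$low_region_length,
                      length = tr$low_region_length,
                      median_phred = 5, bounded = TRUE)
    cmp <- compareRegionRates(sig$traces, sim$alignments, reg,
                              readLengths(sim$reads))
    expect_equal(nrow(cmp$per_read), nrow(tr))
    expect_true(all(cmp$per_read$low_rate < cmp$per_read$normal_rate))
    big <- tr$preceding_length >= 500
    expect_true(all(abs(cmp$per_read$normal_rate[big] - 10) / 10 < 0.05))
    expect_true(all(abs(cmp$per_read$low_rate[big] - 6) / 6 < 0.05))
    expect_lt(cmp$sign_test_p, 0.05)
})

test_that("equal planted rates leave the sign test non-significant", {
    cfg <- simulationConfig(seed = 6, n_reads = 44,
                            genome_length = 30000, segment_length = 6000,
                            pre_range = c(500L, 3000L),
                            tail_range = c(200L, 800L),
                            background_read_fraction = 0.5,
                            uplift_rate = c(10, 1),
                            uplift_current = c(90, 8),
                            unbounded_fraction = 0)
    sim <- simulateReads(cfg)
    sig <- simulateSignal(sim)
    tr <- sim$truth[sim$truth$spans_junction, ]
    reg <- data.frame(read_id = tr$read_id,
                      start = tr$preceding_length,
                      end = tr$preceding_length + tr$low_region_length,
                      length = tr$low_region_length,
                      median_phred = 5, bounded = TRUE)
    cmp <- compareRegionRates(sig$traces, sim$alignments, reg,
                              readLengths(sim$reads))
    expect_gt(cmp$sign_test_p, 0.05)
})
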