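# helper: segment row with a CIGAR consistent with its coordinates
segRow <- function(read_id, chrom, ref_start, ref_end, read_start, read_end,
                   strand, is_primary, read_len) {
    m <- read_end - read_start
    stopifnot(ref_end - ref_start == m)  # pure-M segments in these fixtures
    lead <- if (strand == "+") read_start else read_len - read_end
    trail <- read_len - m - lead
    cig <- paste0(if (lead) paste0(lead, "S") else "", m, "M",
                  if (trail) paste0(trail, "S") else "")
    data.frame(read_id = read_id, chrom = chrom, ref_start = ref_start,
               ref_end = ref_end, read_start = read_start,
               read_end = read_end, strand = strand,
               is_primary = is_primary, cigar = cig,
               stringsAsFactors = FALSE)
}

test_that("boundary pairs require same-chromosome opposite-strand splits", {
    # same strand: tandem-style split, no inversion signature
    same <- manualSplitAlignments(rbind(
        segRow("t", "chr1", 10000, 15000, 0, 5000, "+", TRUE, 8000),
        segRow("t", "chr1", 7000, 10000, 5000, 8000, "+", FALSE, 8000)))
    expect_equal(nrow(extractBoundaryPairs(same)), 0)

    # different chromosomes: rejected
    cross <- manualSplitAlignments(rbind(
        segRow("x", "chr1", 10000, 15000, 0, 5000, "+", TRUE, 8000),
        segRow("x", "chr2", 12000, 15000, 5000, 8000, "-", FALSE, 8000)))
    expect_equal(nrow(extractBoundaryPairs(cross)), 0)

    # hand-traced inverted-duplicate split:
    # +segment read-adjacent end = ref_end = 15000; -segment read-adjacent
    # end = ref_end = 15000
    inv <- manualSplitAlignments(rbind(
        segRow("r", "chr1", 10000, 15000, 0, 5000, "+", TRUE, 8000),
        segRow("r", "chr1", 12000, 15000, 5000, 8000, "-", FALSE, 8000)))
    bp <- extractBoundaryPairs(inv)
    expect_equal(nrow(bp), 1)
    expect_equal(bp$coord_a, 15000L)
    expect_equal(bp$coord_b, 15000L)
    expect_equal(c(bp$strand_a, bp$strand_b), c("+", "-"))
    expect_equal(bp$read_split_pos, 5000L)
})

test_that("greedy resolution clusters within tolerance, deterministically", {
    empty <- extractBoundaryPairs(manualSplitAlignments(
        nanoJunction:::.emptySegments()))
    expect_equal(nrow(resolvePairsGreedy(empty)), 0)

    one <- data.frame(read_id = "r1", chrom = "chr1", coord_a = 5000L,
                      coord_b = 5000L, strand_a = "+", strand_b = "-",
                      read_split_pos = 100L, stringsAsFactors = FALSE)
    call1 <- resolvePairsGreedy(one, tolerance = 100)
    expect_equal(call1$support, 1L)
    expect_equal(call1$position, 5000L)

    # 15000 and 15010 cluster at tolerance 100; 15990 stands alone
    mk <- function(id, x) data.frame(read_id = id, chrom = "chr1",
                                     coord_a = x, coord_b = x,
                                     strand_a = "+", strand_b = "-",
                                     read_split_pos = 0L,
                                     stringsAsFactors = FALSE)
    pairs <- rbind(mk("a", 15000L), mk("b", 15010L), mk("c", 15990L))
    calls <- resolvePairsGreedy(pairs, tolerance = 100)
    expect_equal(calls$support, c(2L, 1L))
    expect_equal(calls$position, c(15005L, 15990L))

    # near-tolerance pairs falling in adjacent bins still merge
    adj <- rbind(mk("a", 15099L), mk("b", 15101L))
    expect_equal(resolvePairsGreedy(adj, tolerance = 100)$support, 2L)

    # permutation invariance of the full result
    set.seed(99)
    many <- do.call(rbind, lapply(1:30, function(i)
        mk(paste0("r", i), 20000L + sample(c(0L, 25L, 4000L, 4030L), 1))))
    ref <- resolvePairsGreedy(many, tolerance = 200)
    for (k in 1:10) {
        shuf <- many[sample(nrow(many)), ]
        got <- resolvePairsGreedy(shuf, tolerance = 200)
        expect_equal(got[, c("chrom", "position", "support")],
                     ref[, c("chrom", "position", "support")])
    }
    # every member lies within tolerance of its call; no pair is assigned
    # twice
    expect_equal(sum(vapply(ref$members, nrow, integer(1))), nrow(many))
    for (i in seq_len(nrow(ref))) {
        m <- ref$members[[i]]
        expect_true(all(abs(m$coord_a - ref$position[i]) <= 200 + 25))
    }
})

test_that("depth enrichment compares the junction window with the
           chromosome median", {
    flat <- list(chr1 = S4Vectors::Rle(20L, 100000L))
    call <- data.frame(chrom = "chr1", position = 50000L, support = 5L,
                       depth_ratio = NA_real_, passed_depth = NA)
    got <- depthEnrichment(call, flat)
    expect_equal(got$depth_ratio, 1.0)
    expect_false(got$passed_depth)

    # depth doubled over a 10 kb window containing the junction
    bump <- list(chr1 = S4Vectors::Rle(c(20L, 40L, 20L),
                                       c(45000L, 10000L, 45000L)))
    expect_equal(depthEnrichment(call, bump)$depth_ratio, 2.0)

    # a junction within one flank of the contig edge truncates the window
    edge <- data.frame(chrom = "chr1", position = 500L, support = 1L,
                       depth_ratio = NA_real_, passed_depth = NA)
    trunc <- list(chr1 = S4Vectors::Rle(c(60L, 20L),
                                        c(2500L, 97500L)))
    # window [0, 2500): all at 60; median 20 -> ratio 3
    expect_equal(depthEnrichment(edge, trunc)$depth_ratio, 3.0)

    zero <- list(chr1 = S4Vectors::Rle(0L, 100000L))
    expect_error(depthEnrichment(call, zero), "chr1")
})

test_that("junction calling is empty without split reads and blind to
           tandem duplications", {
    bg <- simulateReads(simulationConfig(
        seed = 3, n_reads = 60, genome_length = 30000,
        segment_length = 6000, cnv_type = "none",
        read_length_range = c(1000L, 3000L)))
    expect_equal(nrow(callJunctions(bg$alignments)), 0)

    tandem <- simulateReads(simulationConfig(
        seed = 4, n_reads = 80, genome_length = 30000,
        segment_length = 6000, cnv_type = "tandem",
        pre_range = c(500L, 3000L), tail_range = c(200L, 800L),
        read_length_range = c(1000L, 3000L),
        background_read_fraction = 0.5))
    # split reads exist, but all same-strand
    seg_per_read <- table(alignmentSegments(tandem$alignments)$read_id)
    expect_gt(sum(seg_per_read > 1), 10)
    expect_equal(nrow(callJunctions(tandem$alignments)), 0)
})

test_that("junction calls recover the planted ODIRA junctions", {
    sim <- cachedSim("odira400", function()
        simulateReads(simulationConfig(seed = 7, n_reads = 400)))
    calls <- callJunctions(sim$alignments)
    truth <- sort(unname(sim$genome$junctions))
    expect_equal(nrow(calls), 2)
    expect_true(all(abs(sort(calls$position) - truth) <= 100))
    expect_true(all(calls$support >= 5))
    expect_true(all(calls$depth_ratio > 1.5))
    expect_true(all(calls$passed_depth))
    # support conservation: member pairs partition the input pairs
    pairs <- extractBoundaryPairs(sim$alignments)
    expect_equal(sum(vapply(calls$members, nrow, integer(1))), nrow(pairs))
})
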