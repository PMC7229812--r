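#' Configuration for the synthetic nanopore data generator
#'
#' Bundles every knob of the generator with defaults chosen to emulate the
#' inverted-duplicate failure phenotype at desk scale: a read spanning a
#' junction is called normally up to the junction, then produces a low-phred
#' region slightly shorter than the preceding region (missed bases realized
#' as deletions, miscalled bases as substitutions), with elevated current
#' and fewer samples per nucleotide while the inverted copy translocates.
#'
#' @param seed Integer seed; all outputs are deterministic given it.
#' @param genome_length,segment_length Reference length and duplicated-unit
#'   length in bp (`3 * segment_length < genome_length`).
#' @param n_reads Total reads; `round(n_reads * (1 -
#'   background_read_fraction))` of them span a junction.
#' @param background_read_fraction Fraction of reads drawn from the
#'   reference with normal quality throughout (default 0.95: junction-
#'   spanning molecules are rare in a whole-genome sample with one CNV
#'   locus).
#' @param read_length_range Background read length range (bp).
#' @param pre_range Range of the pre-junction (preceding) length of
#'   spanning reads.
#' @param tail_range Range of the recovered tail length after the low
#'   region.
#' @param degrade_ratio,degrade_sd Low-region length over preceding length
#'   (mean, between-read SD); `degrade_ratio <= 1` since bases are missed,
#'   not gained.
#' @param normal_phred,low_phred `(mean, sd)` of per-base phred scores in
#'   normal and collapsed regions.
#' @param normal_rate,uplift_rate `(mean, sd)` samples per nucleotide
#'   outside and inside the uplifted region (fewer samples = faster
#'   translocation).
#' @param normal_current,uplift_current `(mean, sd)` current in pA.
#' @param substitution_rate Fraction of retained low-region bases miscalled.
#' @param unbounded_fraction Fraction of spanning reads ending inside the
#'   low region (region never recovers; excluded from length statistics).
#' @param boundary_jitter_sd SD (bp) of the split-boundary mapping jitter,
#'   realized by trimming/extending the primary alignment (clamped to
#'   +/- 30 bp).
#' @param cnv_type `"odira"` (triplication with inverted middle copy, two
#'   inverted-duplicate junctions), `"tandem"` (same-orientation duplication
#'   control) or `"none"`.
#' @param failure Emit the failure phenotype on spanning reads (set FALSE
#'   for a clean-spanning-read negative control).
#' @param sample_rate_hz Sampling rate metadata for signal traces.
#' @param chrom Reference sequence name.
#' @return A validated `SimulationConfig` (a classed list).
#' @export
simulationConfig <- function(seed = 1L,
                             genome_length = 200000L,
                             segment_length = 5000L,
                             n_reads = 500L,
                             background_read_fraction = 0.95,
                             read_length_range = c(2000L, 8000L),
                             pre_range = c(500L, 3800L),
                             tail_range = c(200L, 1000L),
                             degrade_ratio = 0.9,
                             degrade_sd = 0.015,
                             normal_phred = c(30, 3),
                             low_phred = c(5, 2),
                             normal_rate = c(10, 1),
                             uplift_rate = c(6, 1),
                             normal_current = c(90, 8),
                             uplift_current = c(125, 8),
                             substitution_rate = 0.3,
                             unbounded_fraction = 0.05,
                             boundary_jitter_sd = 8,
                             cnv_type = c("odira", "tandem", "none"),
                             failure = TRUE,
                             sample_rate_hz = 4000,
                             chrom = "chr1") {
    cnv_type <- match.arg(cnv_type)
    cfg <- list(seed = as.integer(seed),
                genome_length = as.integer(genome_length),
                segment_length = as.integer(segment_length),
                n_reads = as.integer(n_reads),
                background_read_fraction = background_read_fraction,
                read_length_range = as.integer(read_length_range),
                pre_range = as.integer(pre_range),
                tail_range = as.integer(tail_range),
                degrade_ratio = degrade_ratio, degrade_sd = degrade_sd,
                normal_phred = normal_phred, low_phred = low_phred,
                normal_rate = normal_rate, uplift_rate = uplift_rate,
                normal_current = normal_current,
                uplift_current = uplift_current,
                substitution_rate = substitution_rate,
                unbounded_fraction = unbounded_fraction,
                boundary_jitter_sd = boundary_jitter_sd,
                cnv_type = cnv_type, failure = isTRUE(failure),
                sample_rate_hz = sample_rate_hz, chrom = chrom)
    class(cfg) <- "SimulationConfig"
    .validateConfig(cfg)
    cfg
}

.validateConfig <- function(cfg) {
    with(cfg, {
        if (3L * segment_length >= genome_length)
            stop("need 3 * segment_length < genome_length")
        if (degrade_ratio <= 0 || degrade_ratio > 1)
            stop("degrade_ratio must be in (0, 1]")
        sds <- c(degrade_sd, normal_phred[2], low_phred[2], normal_rate[2],
                 uplift_rate[2], normal_current[2], uplift_current[2])
        if (any(sds < 0)) stop("all sds must be >= 0")
        if (normal_rate[1] <= 0 || uplift_rate[1] <= 0)
            stop("rates must be > 0")
        if (background_read_fraction < 0 || background_read_fraction > 1)
            stop("background_read_fraction must be in [0, 1]")
        if (pre_range[2] + tail_range[2] > segment_length - 10L)
            stop("pre_range + tail_range must fit inside the duplicated ",
                 "segment (pre_range[2] + tail_range[2] <= segment_length",
                 " - 10)")
    })
    invisible(cfg)
}

#' @export
print.SimulationConfig <- function(x, ...) {
    cat(sprintf(
        "SimulationConfig: %s, %d kb genome, %d bp segment, %d reads (%.0f%% background), seed %d\n",
        x$cnv_type, x$genome_length %/% 1000L, x$segment_length, x$n_reads,
        100 * x$background_read_fraction, x$seed))
    invisible(x)
}

#' Simulated reference genome and CNV allele
#'
#' Draws a uniform random reference sequence and builds the CNV allele: for
#' `cnv_type = "odira"` a chosen segment `S` is replaced by
#' `S . revcomp(S) . S` (a triplication whose middle copy is inverted, hence
#' two inverted-duplicate junctions); `"tandem"` replaces it by `S . S`;
#' `"none"` leaves the reference unchanged. The segment is centered on the
#' reference.
#'
#' @param config A [simulationConfig()].
#' @return A list: `reference`, `allele` ([Biostrings::DNAString]),
#'   `seg_start`, `seg_end` (0-based half-open segment interval),
#'   `junctions` (named vector of reference junction coordinates: for odira
#'   `jA = seg_end`, `jB = seg_start`), `chrom`.
#' @export
makeGenome <- function(config) {
    set.seed(config$seed)
    gl <- config$genome_length
    L <- config$segment_length
    ref_chr <- paste(sample(c("A", "C", "G", "T"), gl, replace = TRUE),
                     collapse = "")
    reference <- Biostrings::DNAString(ref_chr)
    seg_start <- (gl - L) %/% 2L
    seg_end <- seg_start + L
    S <- Biostrings::subseq(reference, seg_start + 1L, seg_end)
    allele <- switch(config$cnv_type,
        odira = Biostrings::xscat(
            Biostrings::subseq(reference, 1L, seg_end),
            Biostrings::reverseComplement(S), S,
            Biostrings::subseq(reference, seg_end + 1L, gl)),
        tandem = Biostrings::xscat(
            Biostrings::subseq(reference, 1L, seg_end), S,
            Biostrings::subseq(reference, seg_end + 1L, gl)),
        none = reference)
    junctions <- switch(config$cnv_type,
        odira = c(jA = seg_end, jB = seg_start),
        tandem = c(jT = seg_end),
        none = setNames(integer(), character()))
    list(reference = reference, allele = allele,
         seg_start = seg_start, seg_end = seg_end,
         junctions = junctions, chrom = config$chrom)
}

.clampPhred <- function(x) {
    x <- as.integer(round(x))
    x[x < 0L] <- 0L
    x[x > 93L] <- 93L
    x
}

.rphred <- function(n, ms) .clampPhred(rnorm(n, ms[1], ms[2]))

.DNA <- c("A", "C", "G", "T")

# uniform integer in [lo, hi] (sample() treats a scalar as 1:n)
.sampleInt <- function(lo, hi) lo + as.integer(floor(runif(1) * (hi - lo + 1L)))

# substitute each selected position with a uniformly chosen different base
.substituteBases <- function(chars, idx) {
    if (!length(idx)) return(chars)
    cur <- chars[idx]
    off <- sample.int(3L, length(idx), replace = TRUE)
    chars[idx] <- .DNA[(match(cur, .DNA) - 1L + off) %% 4L + 1L]
    chars
}

# run-length encode a retained-base mask into CIGAR blocks (TRUE -> M,
# FALSE -> D), optionally reversed for minus-strand storage order
.maskCigar <- function(mask, reverse = FALSE) {
    if (reverse) mask <- rev(mask)
    r <- rle(mask)
    paste0(r$lengths, ifelse(r$values, "M", "D"), collapse = "")
}

.cig <- function(...) {
    parts <- list(...)
    paste0(vapply(parts, function(p) {
        if (is.character(p)) p
        else if (p[1] > 0) paste0(p[1], names(p)) else ""
    }, character(1)), collapse = "")
}

#' Simulate nanopore reads with the junction failure phenotype
#'
#' Junction-spanning reads are drawn from the CNV allele around a junction:
#' normal phred before it; after it, a low-phred region of length
#' `round(degrade_ratio * preceding_length)` (plus between-read noise) whose
#' bases are randomly substituted and down-sampled, the length deficit
#' realized as deletions; then (for bounded reads) a normal-quality tail.
#' Matching primary + supplementary alignment records with consistent CIGARs
#' and mutual SA tags are emitted directly. Background reads are drawn from
#' the reference with normal phred throughout.
#'
#' @param config A [simulationConfig()].
#' @param genome Result of [makeGenome()] (recomputed when NULL).
#' @return A list:
#'   `reads` ([NanoporeReadSet]), `alignments` ([SplitAlignments]),
#'   `sam` (data.frame of raw SAM record fields),
#'   `truth` (per-read ground truth: `read_id`, `spans_junction`,
#'   `junction_side`, `junction_ref`, `junction_read_pos`,
#'   `preceding_length`, `molecule_low_length`, `low_region_length`,
#'   `tail_length`, `bounded`, `jitter`), and
#'   `masks` (retained-base masks of the failure regions, by read id).
#' @export
simulateReads <- function(config, genome = NULL) {
    if (is.null(genome)) genome <- makeGenome(config)
    set.seed(config$seed + 1L)
    n_span <- if (config$cnv_type == "none") 0L else
        as.integer(round(config$n_reads *
                         (1 - config$background_read_fraction)))
    n_bg <- config$n_reads - n_span
    ids <- sprintf("r%06d", seq_len(config$n_reads))
    span_ids <- if (n_span) ids[seq_len(n_span)] else character()

    seqs <- character(config$n_reads)
    phred <- vector("list", config$n_reads)
    seg_rows <- list()
    sam_rows <- list()
    truth_rows <- vector("list", config$n_reads)
    masks <- list()

    for (i in seq_len(n_span)) {
        r <- .simulateSpanningRead(config, genome, ids[i],
                                   side_idx = i)
        seqs[i] <- r$seq
        phred[[i]] <- r$phred
        seg_rows[[length(seg_rows) + 1L]] <- r$segments
        sam_rows[[length(sam_rows) + 1L]] <- r$sam
        truth_rows[[i]] <- r$truth
        if (!is.null(r$mask)) masks[[ids[i]]] <- r$mask
    }
    gl <- config$genome_length
    bg_phred <- IRanges::IntegerList()
    if (n_bg) {
        idx <- n_span + seq_len(n_bg)
        bids <- ids[idx]
        rng <- config$read_length_range
        len <- rng[1] + as.integer(floor(runif(n_bg) * (rng[2] - rng[1] + 1L)))
        s0 <- as.integer(floor(runif(n_bg) * (gl - len + 1L)))
        minus <- runif(n_bg) < 0.5
        frag <- Biostrings::extractAt(genome$reference,
                                      IRanges::IRanges(s0 + 1L, s0 + len))
        if (any(minus))
            frag[minus] <- Biostrings::reverseComplement(frag[minus])
        seqs[idx] <- as.character(frag)
        bg_phred <- IRanges::relist(
            .clampPhred(rnorm(sum(len), config$normal_phred[1],
                              config$normal_phred[2])),
            IRanges::PartitioningByWidth(len))
        cig <- paste0(len, "M")
        seg_rows[[length(seg_rows) + 1L]] <- data.frame(
            read_id = bids, chrom = config$chrom, ref_start = s0,
            ref_end = s0 + len, read_start = 0L, read_end = len,
            strand = ifelse(minus, "-", "+"), is_primary = TRUE,
            cigar = cig, stringsAsFactors = FALSE)
        sam_rows[[length(sam_rows) + 1L]] <- data.frame(
            qname = bids, flag = ifelse(minus, 16L, 0L),
            rname = config$chrom, pos = s0 + 1L, mapq = 60L, cigar = cig,
            sa = NA_character_, stringsAsFactors = FALSE)
        truth_rows[[n_span + 1L]] <- data.frame(
            read_id = bids, spans_junction = FALSE,
            junction_side = NA_character_, junction_ref = NA_integer_,
            junction_read_pos = NA_integer_, preceding_length = NA_integer_,
            molecule_low_length = NA_integer_,
            low_region_length = NA_integer_, tail_length = NA_integer_,
            bounded = NA, jitter = NA_integer_, stringsAsFactors = FALSE)
    }

    all_phred <- c(IRanges::IntegerList(phred[seq_len(n_span)]), bg_phred)
    reads <- NanoporeReadSet(
        Biostrings::DNAStringSet(setNames(seqs, ids)), all_phred)
    seg <- do.call(rbind, seg_rows)
    aln <- SplitAlignments(
        if (is.null(seg)) .emptySegments() else seg,
        setNames(config$genome_length, config$chrom))
    list(reads = reads, alignments = aln,
         sam = do.call(rbind, sam_rows),
         truth = do.call(rbind, truth_rows), masks = masks,
         genome = genome, config = config)
}

# One junction-spanning read. Alternates between the two junctions of the
# ODIRA allele (a tandem allele has a single same-strand junction).
.simulateSpanningRead <- function(config, genome, id, side_idx) {
    L <- config$segment_length
    seg_start <- genome$seg_start
    seg_end <- genome$seg_end
    allele <- genome$allele
    tandem <- config$cnv_type == "tandem"
    side <- if (tandem) "T" else if (side_idx %% 2L == 1L) "A" else "B"
    p <- .sampleInt(config$pre_range[1], config$pre_range[2])
    unbounded <- config$failure && !tandem &&
        runif(1) < config$unbounded_fraction
    t_len <- if (unbounded) 0L else
        .sampleInt(config$tail_range[1], config$tail_range[2])
    failure <- config$failure && !tandem

    m_low <- if (unbounded) max(150L, as.integer(round(p * runif(1, 0.3, 0.8))))
             else p
    if (failure) {
        l <- as.integer(round(m_low * rnorm(1, config$degrade_ratio,
                                            config$degrade_sd)))
        l <- min(max(l, 10L), m_low)
        mask <- rep(TRUE, m_low)
        n_del <- m_low - l
        if (n_del > 0)
            mask[sample(2:(m_low - 1L), n_del)] <- FALSE
    } else {
        l <- m_low
        mask <- NULL
    }

    # allele coordinate of the junction (0-based)
    # allele = ref[0,seg_end) . revcomp(S) . S . ref[seg_end,):
    # junction A at the S|revcomp(S) boundary, B at revcomp(S)|S
    aJ <- switch(side, A = seg_end, B = seg_end + L, T = seg_end)
    pre <- as.character(Biostrings::subseq(allele, aJ - p + 1L, aJ))
    post <- as.character(Biostrings::subseq(allele, aJ + 1L,
                                            aJ + m_low + t_len))
    low_mol <- substr(post, 1L, m_low)
    tail_seq <- if (t_len) substr(post, m_low + 1L, m_low + t_len) else ""
    if (failure) {
        chars <- strsplit(low_mol, "", fixed = TRUE)[[1]][mask]
        subs <- which(runif(l) < config$substitution_rate)
        low_called <- paste(.substituteBases(chars, subs), collapse = "")
    } else {
        low_called <- low_mol
    }
    read_seq <- paste0(pre, low_called, tail_seq)
    phred <- c(.rphred(p, config$normal_phred),
               if (failure) .rphred(l, config$low_phred)
               else .rphred(l, config$normal_phred),
               .rphred(t_len, config$normal_phred))
    read_len <- p + l + t_len

    j <- as.integer(round(rnorm(1, 0, config$boundary_jitter_sd)))
    j <- max(min(j, 30L, p - 50L), -30L, -(l - 1L))

    # primary covers the pre-junction region, trimmed/extended by j
    emit_suppl <- !unbounded
    if (side == "A") {
        pri <- list(strand = "+", flag = 0L,
                    ref_start = seg_end - p, ref_end = seg_end - j,
                    read_start = 0L, read_end = p - j,
                    cigar = .cig(c(M = p - j), c(S = read_len - (p - j))))
        sup <- list(strand = "-", flag = 2064L,
                    ref_start = seg_end - m_low - t_len, ref_end = seg_end,
                    read_start = p, read_end = read_len,
                    cigar = paste0(
                        .cig(c(M = t_len)),
                        if (failure) .maskCigar(mask, reverse = TRUE)
                        else paste0(m_low, "M"),
                        .cig(c(S = p))))
    } else if (side == "B") {
        pri <- list(strand = "-", flag = 16L,
                    ref_start = seg_start + j, ref_end = seg_start + p,
                    read_start = 0L, read_end = p - j,
                    cigar = .cig(c(S = read_len - (p - j)), c(M = p - j)))
        sup <- list(strand = "+", flag = 2048L,
                    ref_start = seg_start, ref_end = seg_start + m_low + t_len,
                    read_start = p, read_end = read_len,
                    cigar = paste0(
                        .cig(c(S = p)),
                        if (failure) .maskCigar(mask)
                        else paste0(m_low, "M"),
                        .cig(c(M = t_len))))
    } else { # tandem: same strand on both sides of the back-jump
        pri <- list(strand = "+", flag = 0L,
                    ref_start = seg_end - p, ref_end = seg_end - j,
                    read_start = 0L, read_end = p - j,
                    cigar = .cig(c(M = p - j), c(S = read_len - (p - j))))
        sup <- list(strand = "+", flag = 2048L,
                    ref_start = seg_start, ref_end = seg_start + m_low + t_len,
                    read_start = p, read_end = read_len,
                    cigar = .cig(c(S = p), c(M = m_low + t_len)))
    }
    mk_seg <- function(x, primary) data.frame(
        read_id = id, chrom = config$chrom, ref_start = x$ref_start,
        ref_end = x$ref_end, read_start = x$read_start,
        read_end = x$read_end, strand = x$strand, is_primary = primary,
        cigar = x$cigar, stringsAsFactors = FALSE)
    sa_of <- function(x) sprintf("%s,%d,%s,%s,60,0;", config$chrom,
                                 x$ref_start + 1L, x$strand, x$cigar)
    mk_sam <- function(x, other) data.frame(
        qname = id, flag = x$flag, rname = config$chrom,
        pos = x$ref_start + 1L, mapq = 60L, cigar = x$cigar,
        sa = if (emit_suppl) sa_of(other) else NA_character_,
        stringsAsFactors = FALSE)
    segments <- mk_seg(pri, TRUE)
    sam <- mk_sam(pri, sup)
    if (emit_suppl) {
        segments <- rbind(segments, mk_seg(sup, FALSE))
        sam <- rbind(sam, mk_sam(sup, pri))
    }
    junction_ref <- switch(side, A = seg_end, B = seg_start, T = seg_end)
    list(
        seq = read_seq, phred = phred, segments = segments, sam = sam,
        mask = if (failure) mask else NULL,
        truth = data.frame(
            read_id = id, spans_junction = TRUE, junction_side = side,
            junction_ref = junction_ref, junction_read_pos = p,
            preceding_length = p, molecule_low_length = m_low,
            low_region_length = l, tail_length = t_len,
            bounded = !unbounded, jitter = j, stringsAsFactors = FALSE))
}

#' Simulate raw signal traces for simulated reads
#'
#' Samples are generated per *molecule* base: the inverted copy translocates
#' through the pore even where base-calling drops bases, so missed bases
#' still contribute samples. Each molecule base draws its sample count from
#' `normal_rate` (outside the failure region) or `uplift_rate` (inside) and
#' its currents from the corresponding current distribution (rounded to
#' 0.01 pA so traces round-trip exactly through the TSV dialect). The
#' signal-to-base index maps each *called* base to the first sample of its
#' molecule base.
#'
#' @param sim Result of [simulateReads()].
#' @param read_ids Which reads to generate traces for (default: all
#'   junction-spanning reads).
#' @return A list: `traces` ([SignalTraceSet]) and `signal_truth`
#'   (data.frame `read_id`, `uplift_sample_start`, `uplift_sample_end`,
#'   `n_samples`, planted `normal_rate` / `uplift_rate` means).
#' @export
simulateSignal <- function(sim, read_ids = NULL) {
    config <- sim$config
    truth <- sim$truth
    set.seed(config$seed + 2L)
    if (is.null(read_ids))
        read_ids <- truth$read_id[truth$spans_junction]
    samples <- list()
    bidx <- list()
    st_rows <- list()
    read_len <- readLengths(sim$reads)
    for (id in read_ids) {
        tr <- truth[truth$read_id == id, ]
        failure <- isTRUE(tr$spans_junction) && config$failure &&
            !is.na(tr$molecule_low_length) && tr$junction_side != "T"
        if (failure) {
            p <- tr$preceding_length
            m_low <- tr$molecule_low_length
            t_len <- tr$tail_length
            n_mol <- p + m_low + t_len
            region <- rep.int(c(1L, 2L, 1L), c(p, m_low, t_len))
            mask <- sim$masks[[id]]
            called <- c(rep(TRUE, p), mask, rep(TRUE, t_len))
        } else {
            n_mol <- unname(read_len[[id]])
            region <- rep.int(1L, n_mol)
            called <- rep(TRUE, n_mol)
        }
        rate_ms <- rbind(config$normal_rate, config$uplift_rate)
        cur_ms <- rbind(config$normal_current, config$uplift_current)
        counts <- pmax(1L, as.integer(round(
            rnorm(n_mol, rate_ms[region, 1], rate_ms[region, 2]))))
        total <- sum(counts)
        cur <- round(rnorm(total, rep.int(cur_ms[region, 1], counts),
                           rep.int(cur_ms[region, 2], counts)), 2)
        starts <- cumsum(counts) - counts  # 0-based first sample per base
        samples[[id]] <- cur
        bidx[[id]] <- starts[called]
        st_rows[[length(st_rows) + 1L]] <- data.frame(
            read_id = id,
            uplift_sample_start = if (failure) starts[p + 1L] else
                NA_integer_,
            uplift_sample_end = if (failure) {
                if (t_len > 0) starts[p + m_low + 1L] else total
            } else NA_integer_,
            n_samples = total,
            planted_normal_rate = config$normal_rate[1],
            planted_uplift_rate = if (failure) config$uplift_rate[1]
                else NA_real_,
            stringsAsFactors = FALSE)
    }
    list(traces = SignalTraceSet(samples, bidx, config$sample_rate_hz),
         signal_truth = do.call(rbind, st_rows))
}

#' Simulate a complete dataset and write it to disk
#'
#' Runs [makeGenome()], [simulateReads()] and [simulateSignal()] and writes
#' `reference.fa`, `allele.fa`, `reads.fastq`, `alignments.sam`,
#' `signal.tsv` and `truth.json` under `dir`.
#'
#' @param config A [simulationConfig()].
#' @param dir Output directory (created if needed).
#' @param signal_reads `"spanning"` (default), `"all"` or `"none"`.
#' @return Invisibly, a list with the in-memory objects plus `paths`.
#' @export
simulateDataset <- function(config, dir,
                            signal_reads = c("spanning", "all", "none")) {
    signal_reads <- match.arg(signal_reads)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    genome <- makeGenome(config)
    sim <- simulateReads(config, genome)
    paths <- list(
        reference = file.path(dir, "reference.fa"),
        allele = file.path(dir, "allele.fa"),
        fastq = file.path(dir, "reads.fastq"),
        sam = file.path(dir, "alignments.sam"),
        truth = file.path(dir, "truth.json"))
    Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(setNames(list(genome$reference),
                                          config$chrom)), paths$reference)
    Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(setNames(list(genome$allele),
                                          paste0(config$chrom, "_allele"))),
        paths$allele)
    writeNanoporeFastq(sim$reads, paths$fastq)
    .writeSAM(sim$sam, config, paths$sam)
    signal <- NULL
    if (signal_reads != "none") {
        ids <- if (signal_reads == "all") readIDs(sim$reads) else NULL
        signal <- simulateSignal(sim, read_ids = ids)
        paths$signal <- file.path(dir, "signal.tsv")
        writeSignalTraces(signal$traces, paths$signal)
    }
    jsonlite::write_json(
        list(config = unclass(config),
             junctions = as.list(genome$junctions),
             truth = sim$truth,
             signal_truth = if (is.null(signal)) NULL else
                 signal$signal_truth),
        paths$truth, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(c(sim, list(signal = signal, paths = paths)))
}

.writeSAM <- function(sam, config, path) {
    con <- file(path, "wt")
    on.exit(close(con))
    writeLines(c("@HD\tVN:1.6\tSO:unknown",
                 sprintf("@SQ\tSN:%s\tLN:%d", config$chrom,
                         config$genome_length)), con)
    if (!is.null(sam) && nrow(sam)) {
        tags <- ifelse(is.na(sam$sa), "", paste0("\tSA:Z:", sam$sa))
        writeLines(sprintf("%s\t%d\t%s\t%d\t%d\t%s\t*\t0\t0\t*\t*%s",
                           sam$qname, sam$flag, sam$rname, sam$pos,
                           sam$mapq, sam$cigar, tags), con)
    }
    invisible(path)
}
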