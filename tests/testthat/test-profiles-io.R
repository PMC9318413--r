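test_that("TSV matrix and labels load into a sorted CNProfileSet", {
    dir <- withr::local_tempdir()
    m <- file.path(dir, "m.tsv"); l <- file.path(dir, "l.tsv")
    # deliberately unsorted rows and an X chromosome
    write.table(data.frame(ProbeID = c("b", "a", "c"),
                           Chrom = c("X", "1", "1"),
                           Arm = c("q", "q", "q"),
                           Position = c(5, 20, 10),
                           s1 = c(0.10, -0.25, 0.00),
                           s2 = c(0.30, 0.00, 0.125)),
                m, sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(data.frame(PatientID = c("s1", "s2"),
                           Subtype = c("A", "B")),
                l, sep = "\t", row.names = FALSE, quote = FALSE)
    ps <- loadProfiles(m, l)
    expect_s4_class(ps, "CNProfileSet")
    expect_identical(dim(ps), c(3L, 2L))
    pd <- probeData(ps)
    expect_identical(pd$Chrom, c(1L, 1L, 23L))      # X normalised to 23
    expect_identical(pd$ProbeID, c("c", "a", "b"))  # sorted by position
    expect_identical(unname(subtypes(ps)), c("A", "B"))
})

test_that("write/load round trip reproduces values exactly", {
    ps <- makeToyProfileSet(seed = 3)
    dir <- withr::local_tempdir()
    m <- file.path(dir, "m.tsv"); l <- file.path(dir, "l.tsv")
    writeProfiles(ps, m, l)
    ps2 <- loadProfiles(m, l)
    expect_identical(unname(SummarizedExperiment::assay(ps2)),
                     unname(SummarizedExperiment::assay(ps)))
    expect_identical(subtypes(ps2), subtypes(ps))
})

test_that("loading fails informatively on bad input", {
    dir <- withr::local_tempdir()
    m <- file.path(dir, "m.tsv"); l <- file.path(dir, "l.tsv")
    write.table(data.frame(ProbeID = "a", Chrom = 1, Arm = "q",
                           Position = 1, s1 = 0.1, s2 = "oops"),
                m, sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(data.frame(PatientID = c("s1", "s2"), Subtype = "A"),
                l, sep = "\t", row.names = FALSE, quote = FALSE)
    expect_error(loadProfiles(m, l), "non-numeric.*s2")
    write.table(data.frame(ProbeID = "a", Chrom = 1, Arm = "q",
                           Position = 1, s1 = 0.1, s2 = 0.2),
                m, sep = "\t", row.names = FALSE, quote = FALSE)
    write.table(data.frame(PatientID = "s1", Subtype = "A"),
                l, sep = "\t", row.names = FALSE, quote = FALSE)
    expect_error(loadProfiles(m, l), "s2")
})

test_that("segmentation follows the 20/10 rule with end anchoring", {
    s40 <- segmentArm(40)
    expect_identical(s40$start, c(0L, 10L, 20L))
    expect_identical(s40$end, c(20L, 30L, 40L))
    s35 <- segmentArm(35)          # final window anchored to the arm end
    expect_identical(s35$start, c(0L, 10L, 15L))
    expect_identical(s35$end, c(20L, 30L, 35L))
    s20 <- segmentArm(20)
    expect_identical(nrow(s20), 1L)
    expect_false(s20$short)
    s12 <- segmentArm(12)          # short arm: one flagged short segment
    expect_identical(s12$length, 12L)
    expect_true(s12$short)
    expect_error(segmentArm(0), "positive")
    expect_error(segmentArm(30, segLen = 10, overlap = 10), "overlap")
})

test_that("segments cover every arm probe and keep fixed length", {
    for (L in c(20L, 23L, 31L, 40L, 57L, 100L)) {
        seg <- segmentArm(L)
        covered <- sort(unique(unlist(Map(function(s, e) (s + 1):e,
                                          seg$start, seg$end))))
        expect_identical(covered, 1:L)
        expect_true(all(seg$length == 20L))
    }
})

test_that("armSegments enumerates per-arm segments with paper-style names", {
    ps <- makeToyProfileSet()
    seg <- armSegments(ps)
    expect_identical(seg$Name[1:2], c("1qs1", "1qs2"))
    expect_identical(sum(seg$Chrom == 1), 2L)  # 25 probes -> 2 windows
    expect_identical(seg$Length[seg$Chrom == 2], 8L)
    expect_true(seg$Short[seg$Chrom == 2])
    # global indices point into the right arm
    pd <- probeData(ps)
    expect_true(all(pd$Chrom[seg$FirstProbe] == seg$Chrom))
})

test_that("test/control split is disjoint, exhaustive, and honours exclusions", {
    ps <- makeToyProfileSet()
    lab <- subtypes(ps)
    sp <- splitTestControl(ps, "Case")
    expect_length(intersect(sp$test, sp$control), 0)
    expect_setequal(c(sp$test, sp$control), colnames(ps))
    # exclusion keeps excluded patients out of both groups
    lab[1:2] <- "Other"
    ps2 <- CNProfileSet(SummarizedExperiment::assay(ps), probeData(ps), lab)
    sp2 <- splitTestControl(ps2, "Case", exclude = "Other")
    expect_false(any(names(lab)[lab == "Other"] %in%
                     c(sp2$test, sp2$control)))
    expect_error(splitTestControl(ps, "NoSuch"), "not present")
    expect_error(splitTestControl(ps, "Case", exclude = "Case"), "exclude")
})
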