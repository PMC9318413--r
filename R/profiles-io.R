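#' @importFrom utils read.delim write.table head
NULL

## "X"/"23" -> 23L etc.; anything outside 1..23 errors.
normalizeChrom <- function(x) {
    x <- as.character(x)
    x[toupper(x) == "X"] <- "23"
    n <- suppressWarnings(as.integer(x))
    bad <- is.na(n) | n < 1L | n > 23L
    if (any(bad))
        stop("unrecognized chromosome value(s): ",
             paste(unique(x[bad]), collapse = ", "))
    n
}

#' Read a copy-number matrix and phenotype labels from TSV files
#'
#' The matrix file has one header row and columns \code{ProbeID},
#' \code{Chrom}, \code{Arm}, \code{Position} followed by one log2-ratio
#' column per patient. The labels file has columns \code{PatientID} and
#' \code{Subtype}. Chromosome "X" is normalised to 23 and probes are sorted
#' by (chromosome, arm, position).
#'
#' @param matrixPath path to the probe-by-patient TSV matrix.
#' @param labelsPath path to the patient label TSV.
#' @return A \linkS4class{CNProfileSet}.
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' m <- file.path(dir, "m.tsv"); l <- file.path(dir, "l.tsv")
#' write.table(data.frame(ProbeID = c("a", "b"), Chrom = c("1", "X"),
#'     Arm = "q", Position = c(1, 2), p1 = c(0.1, -0.2), p2 = c(0, 0.3)),
#'     m, sep = "\t", row.names = FALSE, quote = FALSE)
#' write.table(data.frame(PatientID = c("p1", "p2"), Subtype = c("A", "B")),
#'     l, sep = "\t", row.names = FALSE, quote = FALSE)
#' loadProfiles(m, l)
#' @export
loadProfiles <- function(matrixPath, labelsPath) {
    tab <- read.delim(matrixPath, check.names = FALSE,
                      stringsAsFactors = FALSE)
    need <- c("ProbeID", "Chrom", "Arm", "Position")
    if (!all(need %in% colnames(tab)))
        stop("matrix file must have coordinate columns: ",
             paste(need, collapse = ", "))
    patients <- setdiff(colnames(tab), need)
    if (!length(patients)) stop("matrix file has no patient columns")
    raw <- tab[, patients, drop = FALSE]
    vals <- suppressWarnings(
        vapply(raw,
               function(v) if (is.numeric(v)) v
                           else as.numeric(as.character(v)),
               numeric(nrow(tab))))
    vals <- matrix(vals, nrow = nrow(tab),
                   dimnames = list(NULL, patients))
    bad <- which(is.na(vals), arr.ind = TRUE)
    if (nrow(bad))
        stop(sprintf("non-numeric copy-number value at row %d, column '%s'",
                     bad[1, 1], patients[bad[1, 2]]))
    labels <- read.delim(labelsPath, stringsAsFactors = FALSE)
    if (!all(c("PatientID", "Subtype") %in% colnames(labels)))
        stop("labels file must have columns PatientID and Subtype")
    lab <- stats::setNames(as.character(labels$Subtype),
                           as.character(labels$PatientID))
    unlabelled <- setdiff(patients, names(lab))
    if (length(unlabelled))
        stop("no phenotype label for patient(s): ",
             paste(unlabelled, collapse = ", "))
    CNProfileSet(vals, probes = tab[, need], subtype = lab[patients])
}

#' Write a CNProfileSet back to TSV files
#'
#' Inverse of [loadProfiles()]; values are written with full precision so a
#' write/load round trip reproduces finite decimals exactly.
#'
#' @param pset a \linkS4class{CNProfileSet}.
#' @param matrixPath,labelsPath output paths.
#' @return Invisibly, the two paths.
#' @export
writeProfiles <- function(pset, matrixPath, labelsPath) {
    rd <- probeData(pset)
    vals <- as.data.frame(assay(pset), check.names = FALSE)
    vals[] <- lapply(vals, function(v) sprintf("%.17g", v))  # bit-exact round trip
    out <- cbind(rd[, c("ProbeID", "Chrom", "Arm", "Position")], vals)
    write.table(out, matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(data.frame(PatientID = colnames(pset),
                           Subtype = unname(subtypes(pset))),
                labelsPath, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(c(matrixPath, labelsPath))
}

#' Cut a chromosome arm into overlapping fixed-length probe segments
#'
#' Segments start at offsets 0, segLen - overlap, 2(segLen - overlap), ...
#' and all have exactly \code{segLen} probes: when the arm length is not a
#' multiple of the step, the final segment is anchored to the arm end (it
#' may overlap its predecessor by more than \code{overlap}). Arms with fewer
#' than \code{segLen} probes yield a single short segment covering the whole
#' arm, flagged in the \code{short} column.
#'
#' @param armProbeCount number of probes on the arm.
#' @param segLen segment length in probes (default 20).
#' @param overlap probes shared by consecutive segments (default 10).
#' @return data.frame with columns \code{ordinal} (1-based), \code{start}
#'   and \code{end} (0-based half-open probe indices into the arm),
#'   \code{length} and \code{short}.
#' @examples
#' segmentArm(35) # last window anchored at [15, 35)
#' @export
segmentArm <- function(armProbeCount, segLen = 20L, overlap = 10L) {
    armProbeCount <- as.integer(armProbeCount)
    segLen <- as.integer(segLen); overlap <- as.integer(overlap)
    if (armProbeCount < 1L) stop("armProbeCount must be positive")
    if (segLen < 1L) stop("segLen must be positive")
    if (overlap < 0L || overlap >= segLen)
        stop("need segLen > overlap >= 0")
    if (armProbeCount <= segLen) {
        return(data.frame(ordinal = 1L, start = 0L, end = armProbeCount,
                          length = armProbeCount,
                          short = armProbeCount < segLen))
    }
    step <- segLen - overlap
    starts <- seq.int(0L, armProbeCount - segLen, by = step)
    if (starts[length(starts)] != armProbeCount - segLen)
        starts <- c(starts, armProbeCount - segLen)
    data.frame(ordinal = seq_along(starts), start = starts,
               end = starts + segLen, length = segLen, short = FALSE)
}

#' Enumerate the segments of every arm of a profile set
#'
#' @param pset a \linkS4class{CNProfileSet}.
#' @param segLen,overlap see [segmentArm()].
#' @return data.frame with one row per segment: \code{Chrom}, \code{Arm},
#'   \code{Ordinal}, a paper-style abbreviation \code{Name} (e.g.
#'   \code{"17qs2"}), global 1-based probe row indices \code{FirstProbe},
#'   \code{LastProbe} (inclusive), \code{Length}, \code{Short}.
#' @export
armSegments <- function(pset, segLen = 20L, overlap = 10L) {
    rd <- probeData(pset)
    keys <- paste0(rd$Chrom, rd$Arm)
    out <- lapply(unique(keys), function(k) {
        idx <- which(keys == k)
        seg <- segmentArm(length(idx), segLen, overlap)
        data.frame(Chrom = rd$Chrom[idx[1]], Arm = rd$Arm[idx[1]],
                   Ordinal = seg$ordinal,
                   Name = paste0(rd$Chrom[idx[1]], rd$Arm[idx[1]], "s",
                                 seg$ordinal),
                   FirstProbe = idx[1] + seg$start,
                   LastProbe = idx[1] + seg$end - 1L,
                   Length = seg$length, Short = seg$short)
    })
    do.call(rbind, out)
}

#' Split a cohort into test and control patient sets
#'
#' The test set is every patient with the given phenotype; the control set
#' is every other patient, optionally minus excluded phenotypes (used when a
#' subtype shares aberrations with a control subtype).
#'
#' @param pset a \linkS4class{CNProfileSet}.
#' @param phenotype subtype defining the test group.
#' @param exclude character phenotypes dropped from the control group.
#' @return list with character vectors \code{test} and \code{control} of
#'   patient ids.
#' @export
splitTestControl <- function(pset, phenotype, exclude = character(0)) {
    lab <- subtypes(pset)
    if (!phenotype %in% lab)
        stop("phenotype not present in labels: ", phenotype)
    if (phenotype %in% exclude)
        stop("cannot exclude the test phenotype itself")
    list(test = names(lab)[lab == phenotype],
         control = names(lab)[lab != phenotype & !(lab %in% exclude)])
}
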