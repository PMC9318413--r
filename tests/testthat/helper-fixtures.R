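# Shared fixtures, all generated in code.

# small cohort on two arms (1q: 25 probes, 2p: 8 probes) with an optional
# planted gain on 1q for the "Case" patients
makeToyProfileSet <- function(nCase = 6L, nCtrl = 6L, gain = 0,
                              seed = 1L) {
    set.seed(seed)
    nProbes <- 33L
    probes <- data.frame(
        ProbeID = sprintf("P%02d", seq_len(nProbes)),
        Chrom = c(rep(1L, 25), rep(2L, 8)),
        Arm = c(rep("q", 25), rep("p", 8)),
        Position = c(seq_len(25), seq_len(8)))
    n <- nCase + nCtrl
    vals <- matrix(rnorm(nProbes * n, 0, 0.2), nProbes, n)
    if (gain != 0)
        vals[6:15, seq_len(nCase)] <- vals[6:15, seq_len(nCase)] + gain
    colnames(vals) <- sprintf("pt%02d", seq_len(n))
    CNProfileSet(vals, probes,
                 subtype = stats::setNames(
                     rep(c("Case", "Ctrl"), c(nCase, nCtrl)),
                     colnames(vals)))
}

randomDiagram <- function(nPairs, scale = 1) {
    b <- runif(nPairs, 0, scale)
    d <- b + runif(nPairs, 0, scale)
    PersistenceDiagram(cbind(b, d), dimension = 0L, reduced = TRUE)
}

# independent dim-0 oracle: single-linkage merge heights
singleLinkageDeaths <- function(cloud) {
    sort(stats::hclust(stats::dist(cloud), method = "single")$height)
}
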