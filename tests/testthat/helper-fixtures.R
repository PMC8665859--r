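# Small programmatic fixtures shared across test files.

# beta matrix with given dimensions and dimnames
mkBeta <- function(values, nProbes, nSamples,
                   probes = sprintf("cg%03d", seq_len(nProbes)),
                   samples = sprintf("s%02d", seq_len(nSamples))) {
  matrix(values, nProbes, nSamples, dimnames = list(probes, samples))
}

# minimal annotated BetaSet with a block of X-linked promoter probes
# belonging to one gene, built from explicit per-sex beta rows
mkXGeneSet <- function(maleBeta, femaleBeta, gene = "GENE1",
                       density = "HC", feature = "promoter") {
  nP <- nrow(maleBeta)
  stopifnot(nrow(femaleBeta) == nP)
  b <- cbind(maleBeta, femaleBeta)
  rownames(b) <- sprintf("cgX%02d", seq_len(nP))
  colnames(b) <- c(sprintf("m%02d", seq_len(ncol(maleBeta))),
                   sprintf("f%02d", seq_len(ncol(femaleBeta))))
  ss <- data.frame(sample_id = colnames(b),
                   sex = rep(c("M", "F"),
                             c(ncol(maleBeta), ncol(femaleBeta))))
  an <- data.frame(probe_id = rownames(b), chrom = "X",
                   pos = seq_len(nP) * 100L, genes = gene,
                   feature = feature, dist_to_tss = -100L,
                   promoter_density = density,
                   platform_450k = TRUE, platform_epic = TRUE)
  BetaSet(b, sampleSheet = ss, probeAnnotation = an)
}

# write a beta matrix in the interchange TSV format
writeBetaTSV <- function(b, path) {
  df <- data.frame(probe_id = rownames(b), b, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
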