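# Shared fixture builders and independent oracles. Everything here is
# deliberately naive plain R, kept separate from the package's own code
# paths so it can serve as a second opinion.

toyGenome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

randomSeq <- function(len, seed) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

naiveRevcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s)
           paste(rev(strsplit(s, "")[[1]]), collapse = ""), character(1),
           USE.NAMES = FALSE))
}

# Independent haplotype construction: splice each variant's alt over its
# ref footprint, walking the sorted record table.
naiveHaplotypeStr <- function(chromStr, tab) {
  tab <- tab[order(tab$pos), , drop = FALSE]
  out <- character(0)
  cur <- 1L
  for (i in seq_len(nrow(tab))) {
    p <- tab$pos[i]
    out <- c(out, substring(chromStr, cur, p - 1L), tab$alt[i])
    cur <- p + nchar(tab$ref[i])
  }
  paste(c(out, substring(chromStr, cur, nchar(chromStr))), collapse = "")
}

# Lift a reference coordinate interval [a, b] (containing no partial
# variant overlaps) into naive-haplotype coordinates and return the slice.
naiveHaplotypeSlice <- function(chromStr, tab, a, b) {
  hap <- naiveHaplotypeStr(chromStr, tab)
  net <- nchar(tab$alt) - nchar(tab$ref)
  footEnd <- tab$pos + nchar(tab$ref) - 1L
  shiftBefore <- sum(net[footEnd < a])
  shiftThrough <- sum(net[footEnd <= b])
  substring(hap, a + shiftBefore, b + shiftThrough)
}

# Independent all-positions in-silico PCR scan.
naivePcrSites <- function(chromStr, primer, role, maxMis, exact3p) {
  L <- nchar(primer)
  n <- nchar(chromStr)
  pat <- if (role == "plus") primer else naiveRevcomp(primer)
  pchars <- strsplit(pat, "")[[1]]
  hits <- list()
  for (s in seq_len(max(n - L + 1L, 0L))) {
    w <- strsplit(substring(chromStr, s, s + L - 1L), "")[[1]]
    mp <- which(w != pchars)
    clampOk <- if (role == "plus") all(mp <= L - exact3p) else all(mp > exact3p)
    if (length(mp) <= maxMis && clampOk)
      hits[[length(hits) + 1L]] <- c(start = s, end = s + L - 1L,
                                     mis = length(mp))
  }
  if (!length(hits)) return(NULL)
  as.data.frame(do.call(rbind, hits))
}

naivePcrScan <- function(genome, fwdSeq, revSeq, maxMis = 2L, exact3p = 5L,
                         maxScan = 2000L) {
  out <- list()
  for (chrom in names(genome)) {
    chromStr <- as.character(genome[[chrom]])
    plus <- list(F = naivePcrSites(chromStr, fwdSeq, "plus", maxMis, exact3p),
                 R = naivePcrSites(chromStr, revSeq, "plus", maxMis, exact3p))
    minus <- list(F = naivePcrSites(chromStr, fwdSeq, "minus", maxMis, exact3p),
                  R = naivePcrSites(chromStr, revSeq, "minus", maxMis, exact3p))
    for (pRole in c("F", "R")) for (mRole in c("F", "R")) {
      a <- plus[[pRole]]; b <- minus[[mRole]]
      if (is.null(a) || is.null(b)) next
      for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
        if (b$start[j] > a$end[i] && b$end[j] - a$start[i] + 1L <= maxScan)
          out[[length(out) + 1L]] <- data.frame(
            chrom = chrom, start = a$start[i], end = b$end[j],
            productLen = b$end[j] - a$start[i] + 1L,
            fwdMismatches = a$mis[i], revMismatches = b$mis[j],
            orientation = paste0(pRole, ">", mRole))
      }
    }
  }
  if (!length(out)) return(NULL)
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$end), , drop = FALSE]
}

# A 2-kb single-locus genome with one centred 17-bp deletion, the standard
# primer-design playground.
singleIndelLocus <- function(seed = 42) {
  chromStr <- randomSeq(2000, seed)
  genome <- Biostrings::DNAStringSet(c(chr1 = chromStr))
  ref <- substring(chromStr, 1000, 1017)
  target <- polymorphismTrack("chr1", 1000, ref, substring(ref, 1, 1),
                              "d17", inbredName = "Mo17", genome = genome)
  list(genome = genome, target = target, chromStr = chromStr)
}

# Minimal VCF writer used only to create test inputs.
writeTestVcf <- function(path, chrom, pos, id, ref, alt) {
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", chrom, pos, id, ref, alt)),
             path)
  path
}
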