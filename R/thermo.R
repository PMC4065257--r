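## Unified nearest-neighbor parameters for DNA duplex formation
## (SantaLucia & Hicks 2004): enthalpy kcal/mol, entropy cal/(mol K),
## one entry per top-strand dinucleotide.
NN_DH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
           CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0,
           TT = -7.9, TG = -8.5, AC = -8.4, AG = -7.8, TC = -8.2,
           CC = -8.0)
NN_DS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
           CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           TT = -22.2, TG = -22.7, AC = -22.4, AG = -21.0, TC = -22.2,
           CC = -19.9)
## Duplex initiation with a terminal A:T vs G:C pair, and the symmetry
## correction for self-complementary oligos.
INIT_AT <- c(dh = 2.3, ds = 4.1)
INIT_GC <- c(dh = 0.1, ds = -2.8)
SYM_DS <- -1.4
GAS_CONSTANT <- 1.987  # cal/(mol K)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Nearest-neighbor primer melting temperature
#'
#' Duplex melting temperature from the unified nearest-neighbor
#' thermodynamic model: Tm = 1000 dH / (dS + R ln CT) - 273.15, with
#' dH/dS summed over stacked dinucleotides plus terminal-initiation terms,
#' an entropic salt correction of `0.368 (N-1) ln[Na+]`, and
#' CT the effective oligo concentration (half the per-strand concentration,
#' or the full concentration for self-complementary sequences, which also
#' receive the symmetry entropy correction). Deterministic; no ambiguity
#' codes are accepted.
#'
#' @param seq character vector of primer sequences (A/C/G/T only,
#'   >= 8 nt).
#' @param saltMolar monovalent cation concentration (mol/L; default 0.05).
#' @param primerNanomolar per-strand oligo concentration (nM; default 25).
#' @return numeric vector of Tm in degrees C.
#' @examples
#' meltingTemperature("ACGTACGTACGTACGTACGT")
#' @export
meltingTemperature <- function(seq, saltMolar = 0.05, primerNanomolar = 25) {
  seq <- toupper(seq)
  if (!length(seq)) return(numeric())
  if (any(nchar(seq) < 8L))
    stop("sequences must be at least 8 nt for the nearest-neighbor model")
  if (any(grepl("[^ACGT]", seq)))
    stop("ambiguous or non-ACGT base in primer sequence")
  selfcomp <- seq == revcomp(seq)
  n <- nchar(seq)
  terminalAT <- (substring(seq, 1L, 1L) %in% c("A", "T")) +
    (substring(seq, n, n) %in% c("A", "T"))
  stacks <- vapply(seq, function(s) {
    dinucs <- substring(s, 1:(nchar(s) - 1L), 2:nchar(s))
    c(sum(NN_DH[dinucs]), sum(NN_DS[dinucs]))
  }, numeric(2), USE.NAMES = FALSE)
  dh <- stacks[1L, ] + terminalAT * INIT_AT[["dh"]] +
    (2L - terminalAT) * INIT_GC[["dh"]]
  ds <- stacks[2L, ] + terminalAT * INIT_AT[["ds"]] +
    (2L - terminalAT) * INIT_GC[["ds"]] + ifelse(selfcomp, SYM_DS, 0) +
    0.368 * (n - 1L) * log(saltMolar)
  ct <- ifelse(selfcomp, primerNanomolar, primerNanomolar / 2) * 1e-9
  1000 * dh / (ds + GAS_CONSTANT * log(ct)) - 273.15
}

#' GC content of primer sequences
#'
#' @param seq character vector of A/C/G/T sequences.
#' @return numeric vector, percent GC.
#' @export
gcContent <- function(seq) {
  seq <- toupper(seq)
  100 * nchar(gsub("[AT]", "", seq)) / nchar(seq)
}

## Longest single-base run in each sequence.
maxHomopolymerRun <- function(seq) {
  vapply(seq, function(s) {
    m <- gregexpr("(.)\\1*", s, perl = TRUE)[[1]]
    max(attr(m, "match.length"))
  }, integer(1), USE.NAMES = FALSE)
}

## Longest k such that the 3'-terminal k nt of `a` are reverse-complementary
## to the 3'-terminal k nt of `b` (primer-dimer heuristic). Since
## revcomp(suffix_k(b)) == prefix_k(revcomp(b)), the run is the longest k
## with suffix_k(a) == prefix_k(revcomp(b)). Capped at `kmax`: a 3' duplex
## longer than 8 nt is disqualifying no matter its exact length.
cross3pRun <- function(a, b, kmax = 8L) {
  cross3pRunMany(a, revcomp(b), kmax)
}

## Vectorised core: `a` and `rcB` (already reverse-complemented) are
## parallel vectors.
cross3pRunMany <- function(a, rcB, kmax = 8L) {
  kmax <- pmin(kmax, nchar(a), nchar(rcB))
  run <- integer(length(a))
  for (k in seq_len(max(kmax, 0L))) {
    hit <- k <= kmax &
      substring(a, nchar(a) - k + 1L, nchar(a)) == substring(rcB, 1L, k)
    run[hit] <- k
  }
  run
}

## Base-4 integer encoding of 8-mers (A=0, C=1, G=2, T=3; first character
## most significant), for arithmetic-only dimer-run computation over many
## primer pairs.
encode8 <- function(x) {
  m <- matrix(match(unlist(strsplit(x, "", fixed = TRUE)),
                    c("A", "C", "G", "T")) - 1L, nrow = 8L)
  as.integer(colSums(m * 4^(7:0)))
}

## Dimer run from encodings: fCode encodes the 3'-terminal 8-mer of the
## forward primer, rCode the first 8-mer of revcomp(reverse primer); the
## run is the largest k whose low-k digits of fCode equal the high-k
## digits of rCode. Equivalent to cross3pRunMany() for primers >= 8 nt.
dimerRunFromCodes <- function(fCode, rCode) {
  run <- integer(length(fCode))
  for (k in 1:8) {
    hit <- (fCode %% 4^k) == (rCode %/% 4^(8L - k))
    run[hit] <- k
  }
  run
}
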