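#' Read a reference genome from FASTA
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that normalises
#' case, trims FASTA descriptions to the first word (chromosome name) and
#' enforces the A/C/G/T/N alphabet.
#'
#' @param path path to a FASTA file.
#' @return a `DNAStringSet`, one element per chromosome.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  genome <- tryCatch(Biostrings::readDNAStringSet(path),
                     error = function(e)
                       stop("malformed FASTA '", path, "': ",
                            conditionMessage(e), call. = FALSE))
  if (!length(genome)) stop("FASTA '", path, "' contains no sequences")
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome)))
    stop("duplicate chromosome names in ", path)
  af <- Biostrings::alphabetFrequency(genome)
  extra <- rowSums(af) - rowSums(af[, c("A", "C", "G", "T", "N"), drop = FALSE])
  if (any(extra > 0))
    stop("non-ACGTN characters in sequence(s): ",
         paste(names(genome)[extra > 0], collapse = ", "))
  genome
}

#' Read a polymorphism track from VCF or a browser-track TSV export
#'
#' The VCF route uses [VariantAnnotation::readVcf()] and splits
#' multi-allelic rows into biallelic records. The TSV dialect emulates a
#' genome-browser polymorphism-track export: tab-separated, five columns
#' (`chrom`, `pos`, `ref`, `alt`, `id`), no header row, lines starting with
#' `#` ignored; a comma-separated `alt` is split into one record per
#' allele. Records come back sorted by (chrom, pos) with `netLength`
#' computed.
#'
#' @param path input file.
#' @param dialect `"vcf"`, `"tsv"`, or `"auto"` (by file extension).
#' @param inbredName inbred the track describes; defaults to the file's
#'   base name.
#' @param genome optional `DNAStringSet` used to validate REF alleles.
#' @return a [PolymorphismTrack-class].
#' @seealso [writeTrack()], [filterIndels()]
#' @export
readTrack <- function(path, dialect = c("auto", "vcf", "tsv"),
                      inbredName = NULL, genome = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  if (dialect == "auto")
    dialect <- if (grepl("\\.vcf(\\.gz|\\.bgz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  if (is.null(inbredName))
    inbredName <- sub("\\.(vcf|tsv|txt)(\\.gz|\\.bgz)?$", "", basename(path),
                      ignore.case = TRUE)
  if (dialect == "vcf") {
    vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "ref"))
    nAlt <- S4Vectors::elementNROWS(VariantAnnotation::alt(vcf))
    ids <- rep(names(SummarizedExperiment::rowRanges(vcf)), nAlt)
    multi <- rep(nAlt, nAlt) > 1L
    ids[multi] <- paste0(ids[multi], ".", sequence(nAlt)[multi])
    evcf <- VariantAnnotation::expand(vcf)
    rr <- SummarizedExperiment::rowRanges(evcf)
    tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(rr)),
                      pos = GenomicRanges::start(rr),
                      ref = as.character(VariantAnnotation::ref(evcf)),
                      alt = as.character(VariantAnnotation::alt(evcf)),
                      id = ids, stringsAsFactors = FALSE)
  } else {
    tab <- tryCatch(
      utils::read.table(path, sep = "\t", comment.char = "#",
                        header = FALSE, stringsAsFactors = FALSE,
                        col.names = c("chrom", "pos", "ref", "alt", "id"),
                        colClasses = c("character", "integer", "character",
                                       "character", "character")),
      error = function(e)
        stop("malformed track TSV '", path, "': ", conditionMessage(e),
             call. = FALSE))
    ## split multi-allelic rows (comma-separated alt) into biallelic records
    altList <- strsplit(tab$alt, ",", fixed = TRUE)
    nAlt <- lengths(altList)
    if (any(nAlt > 1L)) {
      idx <- rep(seq_len(nrow(tab)), nAlt)
      sub <- sequence(nAlt)
      tab <- tab[idx, ]
      tab$alt <- unlist(altList)
      multi <- nAlt[idx] > 1L
      tab$id[multi] <- paste0(tab$id[multi], ".", sub[multi])
    }
  }
  if (!nrow(tab)) stop("track '", path, "' contains no records")
  polymorphismTrack(tab$chrom, tab$pos, tab$ref, tab$alt, tab$id,
                    inbredName = inbredName, genome = genome)
}

#' Write a polymorphism track
#'
#' `dialect = "vcf"` emits a minimal VCF 4.2 (sites only: CHROM POS ID REF
#' ALT QUAL FILTER INFO with `.` placeholders); `dialect = "tsv"` emits the
#' five-column browser-track dialect read by [readTrack()]. Both round-trip
#' record count and all fields.
#'
#' @param track a [PolymorphismTrack-class].
#' @param path output file.
#' @param dialect `"vcf"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeTrack <- function(track, path, dialect = c("vcf", "tsv")) {
  dialect <- match.arg(dialect)
  tb <- trackTable(track)
  if (dialect == "vcf") {
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##source=IndelMarkers_%s", utils::packageVersion("IndelMarkers")),
             sprintf("##inbred=%s", inbredName(track)),
             "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
    body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.",
                    tb$chrom, tb$pos, tb$id, tb$ref, tb$alt)
    writeLines(c(hdr, body), path)
  } else {
    writeLines(c(sprintf("# polymorphism track: %s", inbredName(track)),
                 "# chrom\tpos\tref\talt\tid"), path)
    utils::write.table(tb[, c("chrom", "pos", "ref", "alt", "id")], path,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE, append = TRUE)
  }
  invisible(path)
}

#' Write marker positions as BED
#'
#' Exports the reference footprints of a track (or any `GRanges`) as BED6
#' via [rtracklayer::export()]; record ids become BED names. BED is 0-based
#' half-open; the conversion is rtracklayer's.
#'
#' @param x a [PolymorphismTrack-class] or `GRanges`.
#' @param path output `.bed` file.
#' @return `path`, invisibly.
#' @export
writeBed <- function(x, path) {
  gr <- if (is(x, "PolymorphismTrack")) trackRecords(x) else x
  names(gr) <- S4Vectors::mcols(gr)$id
  S4Vectors::mcols(gr) <- NULL
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
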