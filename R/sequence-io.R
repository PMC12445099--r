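## Reading/writing the standard formats the pipeline touches (GenBank
## flat files, FASTA, TSV) and the coordinate convention: GRanges
## (1-based inclusive) inside GenomeRecord objects, 0-based half-open on
## the forward axis in every tabular interface. Strand is stored
## separately; "complement(a..b)" spans keep forward-axis start/end.

#' @importFrom GenomicRanges GRanges seqnames start end strand
#' @importFrom IRanges IRanges
NULL

.BACTERIAL_CODE <- Biostrings::getGeneticCode("11")
.START_CODONS <- c("ATG", "GTG", "TTG")
.STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Translate a CDS nucleotide sequence (bacterial code)
#'
#' Translation under genetic code table 11 with bacterial start-codon
#' convention: ATG/GTG/TTG as the first codon translate to M. Codons
#' containing N translate to X. A trailing stop codon is dropped; an
#' internal stop raises a warning and truncates the protein at the first
#' stop.
#'
#' @param dna character string of A/C/G/T/N, length divisible by 3.
#' @return amino-acid string (no stop symbol).
#' @export
translateCds <- function(dna) {
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n %% 3L != 0L) stop("CDS length must be divisible by 3", call. = FALSE)
  codons <- substring(dna, seq(1L, n, 3L), seq(3L, n, 3L))
  aa <- unname(.BACTERIAL_CODE[codons])
  aa[is.na(aa)] <- "X"                       # any N-containing codon
  if (length(aa) && codons[1] %in% .START_CODONS) aa[1] <- "M"
  if (length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  stops <- which(aa == "*")
  if (length(stops)) {
    warning("internal stop codon; protein truncated at first stop",
            call. = FALSE)
    aa <- aa[seq_len(stops[1] - 1L)]
  }
  paste(aa, collapse = "")
}

#' Reverse complement of a DNA string
#' @param dna character string over A/C/G/T/N.
#' @return reverse-complemented string.
#' @export
revcomp <- function(dna) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(dna)))
}

.newGenomeRecord <- function(genomeId, speciesLabel, contigs, features) {
  methods::new("GenomeRecord", genomeId = genomeId,
               speciesLabel = speciesLabel, contigs = contigs,
               features = features)
}

#' Construct a GenomeRecord from 0-based half-open feature coordinates
#'
#' @param genomeId,speciesLabel identifiers.
#' @param contigSeqs named character vector or `DNAStringSet`.
#' @param featureTable data.frame with columns `feature_id`, `contig_id`,
#'   `start`, `end` (0-based half-open, forward axis), `strand` ("+"/"-"),
#'   `protein`, `product`. May have zero rows.
#' @return a [GenomeRecord].
#' @export
makeGenomeRecord <- function(genomeId, speciesLabel, contigSeqs,
                             featureTable = NULL) {
  if (!methods::is(contigSeqs, "DNAStringSet"))
    contigSeqs <- Biostrings::DNAStringSet(contigSeqs)
  if (is.null(featureTable) || nrow(featureTable) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      feature_id = character(0), protein = character(0),
      product = character(0))
  } else {
    gr <- GenomicRanges::GRanges(
      seqnames = featureTable$contig_id,
      ranges = IRanges::IRanges(start = featureTable$start + 1L,
                                end = featureTable$end),
      strand = featureTable$strand)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      feature_id = featureTable$feature_id,
      protein = featureTable$protein,
      product = featureTable$product)
  }
  .newGenomeRecord(genomeId, speciesLabel, contigSeqs, gr)
}

#' CDS feature table of a genome (0-based half-open coordinates)
#'
#' @param genome a [GenomeRecord].
#' @return data.frame with columns `feature_id`, `contig_id`, `start`,
#'   `end` (0-based half-open on the forward axis), `strand`, `protein`,
#'   `product`, ordered by contig then start.
#' @export
featureTable <- function(genome) {
  gr <- cdsFeatures(genome)
  df <- data.frame(
    feature_id = S4Vectors::mcols(gr)$feature_id,
    contig_id = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    protein = S4Vectors::mcols(gr)$protein,
    product = S4Vectors::mcols(gr)$product,
    stringsAsFactors = FALSE)
  df[order(df$contig_id, df$start), , drop = FALSE]
}

#' Extract the proteome of a genome
#'
#' One protein record per CDS feature. Proteins embedded in the
#' annotation are used verbatim; features without a stored translation
#' are translated in silico (bacterial code, start-codon convention).
#' The stop codon is never part of the protein sequence.
#'
#' @param genome a [GenomeRecord].
#' @return data.frame with columns `protein_id`, `genome_id`,
#'   `contig_id`, `start`, `end` (0-based half-open), `strand`,
#'   `sequence`.
#' @export
extractProteome <- function(genome) {
  ft <- featureTable(genome)
  if (nrow(ft) == 0L)
    return(data.frame(protein_id = character(0), genome_id = character(0),
                      contig_id = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      sequence = character(0), stringsAsFactors = FALSE))
  seqs <- as.character(contigs(genome))
  prot <- vapply(seq_len(nrow(ft)), function(i) {
    p <- ft$protein[i]
    if (!is.na(p) && nzchar(p)) return(p)
    cds <- substr(seqs[[ft$contig_id[i]]], ft$start[i] + 1L, ft$end[i])
    if (ft$strand[i] == "-") cds <- revcomp(cds)
    translateCds(cds)
  }, character(1))
  data.frame(protein_id = ft$feature_id, genome_id = genomeId(genome),
             contig_id = ft$contig_id, start = ft$start, end = ft$end,
             strand = ft$strand, sequence = prot, stringsAsFactors = FALSE)
}

## ---- GenBank flat files ----------------------------------------------

.wrapQualifier <- function(text, width = 58L) {
  if (nchar(text) <= width) return(text)
  substring(text, seq(1L, nchar(text), width),
            pmin(seq(width, nchar(text) + width - 1L, width), nchar(text)))
}

#' Write genomes as a GenBank flat file
#'
#' Minimal GenBank writer: one LOCUS record per contig, the genome id in
#' ACCESSION, species in the source feature's /organism, CDS features
#' with 1-based inclusive spans (`complement(a..b)` for the minus
#' strand) and /locus_tag, /product, /translation qualifiers.
#'
#' @param genomes a [GenomeRecord] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeGenBank <- function(genomes, path) {
  if (methods::is(genomes, "GenomeRecord")) genomes <- list(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) {
    ft <- featureTable(g)
    for (ci in names(contigs(g))) {
      seq <- as.character(contigs(g)[[ci]])
      len <- nchar(seq)
      writeLines(sprintf("LOCUS       %-16s %10d bp    DNA     linear   BCT 01-JAN-2026",
                         ci, len), con)
      writeLines(sprintf("DEFINITION  %s %s.", genomeId(g), speciesLabel(g)), con)
      writeLines(sprintf("ACCESSION   %s", genomeId(g)), con)
      writeLines("FEATURES             Location/Qualifiers", con)
      writeLines(sprintf("     source          1..%d", len), con)
      writeLines(sprintf("                     /organism=\"%s\"", speciesLabel(g)), con)
      fk <- ft[ft$contig_id == ci, , drop = FALSE]
      for (i in seq_len(nrow(fk))) {
        span <- sprintf("%d..%d", fk$start[i] + 1L, fk$end[i])
        if (fk$strand[i] == "-") span <- sprintf("complement(%s)", span)
        writeLines(sprintf("     CDS             %s", span), con)
        writeLines(sprintf("                     /locus_tag=\"%s\"", fk$feature_id[i]), con)
        if (!is.na(fk$product[i]) && nzchar(fk$product[i]))
          writeLines(sprintf("                     /product=\"%s\"", fk$product[i]), con)
        if (!is.na(fk$protein[i]) && nzchar(fk$protein[i])) {
          chunks <- .wrapQualifier(fk$protein[i])
          q <- sprintf("/translation=\"%s", chunks[1])
          if (length(chunks) == 1L) q <- paste0(q, "\"")
          writeLines(paste0("                     ", q), con)
          if (length(chunks) > 1L) {
            body <- chunks[-1]
            body[length(body)] <- paste0(body[length(body)], "\"")
            writeLines(paste0("                     ", body), con)
          }
        }
      }
      writeLines("ORIGIN", con)
      starts <- seq(1L, len, 60L)
      for (s in starts) {
        line <- substr(seq, s, min(s + 59L, len))
        groups <- substring(line, seq(1L, nchar(line), 10L),
                            pmin(seq(10L, nchar(line) + 9L, 10L), nchar(line)))
        writeLines(sprintf("%9d %s", s, tolower(paste(groups, collapse = " "))), con)
      }
      writeLines("//", con)
    }
  }
  invisible(path)
}

#' Read a GenBank flat file
#'
#' Parses the subset of the GenBank flat-file format produced by RefSeq
#' `_genomic.gbff` files that the pipeline needs: LOCUS records with CDS
#' features (forward `a..b` and `complement(a..b)` spans), /locus_tag,
#' /product and /translation qualifiers, and the ORIGIN sequence.
#' Consecutive LOCUS records sharing an ACCESSION are grouped into one
#' genome. CDS features without a /translation are translated in silico
#' (bacterial code). Spans are converted from 1-based inclusive to the
#' package's 0-based half-open tabular convention; complement features
#' get strand "-" with start/end kept on the forward axis.
#'
#' @param path GenBank flat file.
#' @return list of [GenomeRecord] objects.
#' @export
readGenBank <- function(path) {
  lines <- readLines(path)
  recs <- list()       # per-LOCUS: contig_id, accession, organism, seq, feats
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    if (!startsWith(lines[i], "LOCUS")) { i <- i + 1L; next }
    locus <- strsplit(trimws(sub("^LOCUS", "", lines[i])), "\\s+")[[1]]
    contig_id <- locus[1]
    accession <- NA_character_; organism <- NA_character_
    feats <- list()
    seqchars <- character(0)
    i <- i + 1L
    while (i <= n && !startsWith(lines[i], "//")) {
      line <- lines[i]
      if (startsWith(line, "ACCESSION")) {
        accession <- trimws(sub("^ACCESSION", "", line))
      } else if (grepl("^\\s{5}\\S", line)) {
        key <- trimws(substr(line, 1, 20))
        loc <- trimws(substr(line, 21, nchar(line)))
        quals <- character(0)
        i <- i + 1L
        while (i <= n && grepl("^\\s{21}", lines[i])) {
          quals <- c(quals, trimws(lines[i]))
          i <- i + 1L
        }
        ## join continuation lines of qualifiers
        merged <- character(0)
        for (q in quals) {
          if (startsWith(q, "/")) merged <- c(merged, q)
          else if (length(merged))
            merged[length(merged)] <- paste0(merged[length(merged)], q)
          else loc <- paste0(loc, q)
        }
        getq <- function(name) {
          hit <- grep(paste0("^/", name, "="), merged, value = TRUE)
          if (!length(hit)) return(NA_character_)
          gsub("\"", "", sub(paste0("^/", name, "="), "", hit[1]))
        }
        if (key == "source") {
          org <- getq("organism")
          if (!is.na(org)) organism <- org
        } else if (key == "CDS") {
          strand <- if (grepl("^complement\\(", loc)) "-" else "+"
          span <- regmatches(loc, regexpr("[0-9]+\\.\\.[0-9]+", loc))
          if (!length(span))
            stop("malformed CDS location in locus '", contig_id, "': ", loc,
                 call. = FALSE)
          ab <- as.integer(strsplit(span, "\\.\\.")[[1]])
          feats[[length(feats) + 1L]] <- list(
            start = ab[1] - 1L, end = ab[2], strand = strand,
            locus_tag = getq("locus_tag"), product = getq("product"),
            translation = getq("translation"))
        }
        next
      } else if (startsWith(line, "ORIGIN")) {
        i <- i + 1L
        while (i <= n && !startsWith(lines[i], "//")) {
          seqchars <- c(seqchars, gsub("[^A-Za-z]", "", lines[i]))
          i <- i + 1L
        }
        next
      }
      i <- i + 1L
    }
    i <- i + 1L    # skip //
    seq <- toupper(paste(seqchars, collapse = ""))
    if (!nchar(seq))
      stop("locus '", contig_id, "' has no ORIGIN sequence", call. = FALSE)
    recs[[length(recs) + 1L]] <- list(contig_id = contig_id,
      accession = accession, organism = organism, seq = seq, feats = feats)
  }
  if (!length(recs)) return(list())
  acc <- vapply(recs, `[[`, character(1), "accession")
  genomes <- lapply(split(recs, factor(acc, levels = unique(acc))), function(rs) {
    contig_seqs <- stats::setNames(
      vapply(rs, `[[`, character(1), "seq"),
      vapply(rs, `[[`, character(1), "contig_id"))
    fts <- do.call(rbind, lapply(rs, function(r) {
      if (!length(r$feats)) return(NULL)
      do.call(rbind, lapply(r$feats, function(f) {
        prot <- f$translation
        if (is.na(prot)) {
          cds <- substr(r$seq, f$start + 1L, f$end)
          if (f$strand == "-") cds <- revcomp(cds)
          prot <- translateCds(cds)
        }
        data.frame(feature_id = f$locus_tag, contig_id = r$contig_id,
                   start = f$start, end = f$end, strand = f$strand,
                   protein = prot,
                   product = ifelse(is.na(f$product), "", f$product),
                   stringsAsFactors = FALSE)
      }))
    }))
    makeGenomeRecord(rs[[1]]$accession,
                     rs[[1]]$organism, contig_seqs, fts)
  })
  unname(genomes)
}

## ---- FASTA and TSV ----------------------------------------------------

#' Read / write FASTA
#'
#' Thin wrappers over Biostrings readers/writers: lossless for sequences
#' and ids, 60-column wrapping on output, error on duplicate ids.
#'
#' @param path file path.
#' @param type `"AA"` or `"DNA"`.
#' @return `readFasta`: named character vector of sequences.
#' @export
readFasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate FASTA ids: ", paste(dup, collapse = ", "), call. = FALSE)
  out <- stats::setNames(as.character(set), names(set))
  out
}

#' @rdname readFasta
#' @param records named character vector (names become headers) or an
#'   `XStringSet`.
#' @export
writeFasta <- function(records, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  if (is.character(records)) {
    dup <- unique(names(records)[duplicated(names(records))])
    if (length(dup))
      stop("duplicate FASTA ids: ", paste(dup, collapse = ", "), call. = FALSE)
    records <- if (type == "AA") Biostrings::AAStringSet(records)
               else Biostrings::DNAStringSet(records)
  }
  Biostrings::writeXStringSet(records, path, width = 60L)
  invisible(path)
}

#' Read / write TSV tables
#'
#' UTF-8, header row, tab separated, no quoting.
#'
#' @param path file path.
#' @return `readTsv`: a data.frame.
#' @export
readTsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, fileEncoding = "UTF-8")
}

#' @rdname readTsv
#' @param df data.frame to write.
#' @export
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
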