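#' @importFrom GenomicRanges GRanges mcols mcols<- seqnames start end strand
#' @importFrom IRanges IRanges
#' @importFrom Biostrings readDNAStringSet readAAStringSet DNAStringSet
#'   writeXStringSet
NULL

.tmError <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "tm_error")))
}

#' Read a gene annotation (GFF3) with family labels
#'
#' Reads gene-type records from a GFF3 file and attaches family labels from
#' a two/three-column tab-separated map (\code{gene_id}, \code{family},
#' optional \code{subfamily}). Coordinates are kept 1-based inclusive, the
#' GFF3 native convention. Genes absent from the map get family
#' \code{"unassigned"} with a warning.
#'
#' @param gffPath path to a GFF3 file containing gene records with ID
#'   attributes.
#' @param familyMap path to a TSV file, or a data.frame, mapping
#'   \code{gene_id} to \code{family} (and optionally \code{subfamily}).
#' @return a [GenomicRanges::GRanges] with metadata columns
#'   \code{gene_id}, \code{family}, \code{subfamily}.
#' @export
readAnnotation <- function(gffPath, familyMap = NULL) {
  if (!file.exists(gffPath))
    .tmError(paste("file not found:", gffPath), "tm_parse_error")
  lines <- readLines(gffPath, warn = FALSE)
  body <- !startsWith(lines, "#") & nzchar(trimws(lines))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf != 9L)) {
    bad <- which(body)[which(nf != 9L)[1L]]
    .tmError(paste0("malformed GFF3 line ", bad, ": expected 9 tab-separated ",
                    "fields, found ", nf[which(nf != 9L)[1L]]),
             "tm_parse_error")
  }
  gr <- rtracklayer::import(gffPath, format = "gff3")
  gr <- gr[!is.na(gr$type) & as.character(gr$type) == "gene"]
  if (length(gr) == 0L)
    .tmError("no gene-type records in GFF3", "tm_parse_error")
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(!nzchar(ids)))
    .tmError("gene record without ID attribute", "tm_parse_error")
  if (anyDuplicated(ids))
    .tmError(paste("duplicate gene IDs:",
                   paste(unique(ids[duplicated(ids)]), collapse = ", ")),
             "tm_parse_error")
  if (is.character(familyMap))
    familyMap <- utils::read.delim(familyMap, comment.char = "#",
                                   stringsAsFactors = FALSE)
  fam <- rep("unassigned", length(ids))
  subfam <- rep(NA_character_, length(ids))
  if (!is.null(familyMap)) {
    m <- match(ids, familyMap$gene_id)
    fam[!is.na(m)] <- familyMap$family[m[!is.na(m)]]
    if ("subfamily" %in% colnames(familyMap))
      subfam[!is.na(m)] <- familyMap$subfamily[m[!is.na(m)]]
    if (anyNA(m))
      warning(sum(is.na(m)), " gene(s) missing from family map; ",
              "assigned family 'unassigned'")
  }
  out <- GenomicRanges::GRanges(
    seqnames = GenomicRanges::seqnames(gr),
    ranges = IRanges::IRanges(GenomicRanges::start(gr),
                              GenomicRanges::end(gr)),
    strand = GenomicRanges::strand(gr))
  GenomicRanges::mcols(out) <- S4Vectors::DataFrame(
    gene_id = ids, family = fam, subfamily = subfam)
  names(out) <- ids
  out
}

#' Write a gene annotation back to GFF3 plus a family map TSV
#'
#' Inverse of [readAnnotation()]: coordinates and families round-trip
#' exactly.
#'
#' @param loci GRanges with \code{gene_id}, \code{family}, \code{subfamily}
#'   metadata columns.
#' @param gffPath output GFF3 path.
#' @param familyPath optional output TSV path for the family map.
#' @return invisibly, \code{gffPath}.
#' @export
writeAnnotation <- function(loci, gffPath, familyPath = NULL) {
  gr <- loci
  GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
    source = "taxmine", type = "gene", ID = loci$gene_id,
    Name = loci$gene_id)
  rtracklayer::export(gr, gffPath, format = "gff3")
  if (!is.null(familyPath)) {
    df <- data.frame(gene_id = loci$gene_id, family = loci$family,
                     subfamily = loci$subfamily)
    utils::write.table(df, familyPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(gffPath)
}

#' Read a two-sequence codon alignment from FASTA
#'
#' The FASTA file must contain exactly two gapless sequences of equal
#' length divisible by three. Codon columns containing gaps, N or other
#' ambiguity codes are either rejected (default) or dropped.
#'
#' @param path FASTA path.
#' @param dropAmbiguous drop codon columns containing non-ACGT characters
#'   in either sequence instead of erroring.
#' @return a [CodonPairAlignment-class].
#' @export
readCodonAlignment <- function(path, dropAmbiguous = FALSE) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) != 2L)
    .tmError(paste("expected exactly 2 records, found", length(seqs)),
             "tm_parse_error")
  a <- toupper(as.character(seqs[[1L]]))
  b <- toupper(as.character(seqs[[2L]]))
  if (nchar(a) != nchar(b))
    .tmError("sequence length mismatch", "tm_length_error")
  if (nchar(a) %% 3L != 0L)
    .tmError(paste0("not codon-multiple: length ", nchar(a)),
             "tm_length_error")
  splitCodons <- function(x)
    substring(x, seq(1L, nchar(x), 3L), seq(3L, nchar(x), 3L))
  ca <- splitCodons(a)
  cb <- splitCodons(b)
  amb <- grepl("[^ACGT]", ca) | grepl("[^ACGT]", cb)
  if (any(amb)) {
    if (!dropAmbiguous)
      .tmError(paste("alignment contains gap/ambiguity characters;",
                     "set dropAmbiguous = TRUE to drop those codon columns"),
               "tm_parse_error")
    ca <- ca[!amb]
    cb <- cb[!amb]
  }
  if (any(ca %in% .STOP_CODONS) || any(cb %in% .STOP_CODONS))
    .tmError("internal stop codon in coding sequence", "tm_stop_codon_error")
  CodonPairAlignment(ca, cb)
}

#' Write a codon pair alignment as two-record FASTA
#' @param pair a [CodonPairAlignment-class].
#' @param path output FASTA path.
#' @param names record names.
#' @return invisibly, \code{path}.
#' @export
writeCodonAlignment <- function(pair, path, names = c("seqA", "seqB")) {
  seqs <- Biostrings::DNAStringSet(c(paste(pair@codonsA, collapse = ""),
                                     paste(pair@codonsB, collapse = "")))
  names(seqs) <- names
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read paired LTR terminal repeats from FASTA
#'
#' Records are paired by the naming convention \code{<id>_5LTR} /
#' \code{<id>_3LTR}; both members must be present and of equal aligned
#' length.
#'
#' @param path FASTA path.
#' @return list of [LTRElement-class] objects, named by element id.
#' @export
readLtrPairs <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  nm <- names(seqs)
  is5 <- grepl("_5LTR$", nm)
  is3 <- grepl("_3LTR$", nm)
  if (!all(is5 | is3))
    .tmError("records must be named <id>_5LTR / <id>_3LTR", "tm_parse_error")
  ids5 <- sub("_5LTR$", "", nm[is5])
  ids3 <- sub("_3LTR$", "", nm[is3])
  ids <- sort(unique(c(ids5, ids3)))
  if (!setequal(ids5, ids3))
    .tmError("unpaired LTR records", "tm_parse_error")
  out <- lapply(ids, function(id) {
    LTRElement(id,
               as.character(seqs[[which(nm == paste0(id, "_5LTR"))]]),
               as.character(seqs[[which(nm == paste0(id, "_3LTR"))]]))
  })
  names(out) <- ids
  out
}

#' Write LTR elements to FASTA with the 5LTR/3LTR suffix convention
#' @param elements list of [LTRElement-class] objects.
#' @param path output FASTA path.
#' @return invisibly, \code{path}.
#' @export
writeLtrPairs <- function(elements, path) {
  seqs <- unlist(lapply(elements, function(e) c(e@ltr5, e@ltr3)))
  ids <- vapply(elements, function(e) e@elementId, character(1))
  sset <- Biostrings::DNAStringSet(seqs)
  names(sset) <- as.vector(rbind(paste0(ids, "_5LTR"), paste0(ids, "_3LTR")))
  Biostrings::writeXStringSet(sset, path)
  invisible(path)
}

#' Read an all-vs-all protein similarity table
#'
#' Tab-separated with columns \code{query}, \code{subject},
#' \code{bitscore}, \code{evalue}, \code{aln_length} (header required,
#' '#' comments allowed).
#'
#' @param path TSV path.
#' @return data.frame of similarity hits.
#' @export
readSimilarityHits <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("query", "subject", "bitscore", "evalue", "aln_length")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    .tmError(paste("missing columns:", paste(miss, collapse = ", ")),
             "tm_parse_error")
  if (any(df$bitscore < 0) || any(df$aln_length < 0))
    .tmError("bitscore and aln_length must be non-negative",
             "tm_parse_error")
  df
}

#' Write detected gene groups as a BED-like TSV
#'
#' Output columns: \code{chrom}, \code{start} (0-based half-open),
#' \code{end}, \code{label}, \code{n_members}, \code{member_ids}
#' (comma-separated), sorted by chromosome then start. An empty group set
#' yields a header-only file.
#'
#' @param groups GRanges from [detectGroups()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeGroups <- function(groups, path) {
  df <- data.frame(chrom = character(), start = integer(), end = integer(),
                   label = character(), n_members = integer(),
                   member_ids = character())
  if (length(groups)) {
    df <- data.frame(
      chrom = as.character(GenomicRanges::seqnames(groups)),
      start = GenomicRanges::start(groups) - 1L,   # 0-based half-open out
      end = GenomicRanges::end(groups),
      label = groups$label,
      n_members = groups$n_members,
      member_ids = vapply(groups$member_ids, paste, character(1),
                          collapse = ","))
    df <- df[order(df$chrom, df$start), , drop = FALSE]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a JSON run configuration
#'
#' Records every tunable parameter and seed of a run as a JSON object so
#' analyses can be replayed exactly.
#'
#' @param config named list of parameters.
#' @param path JSON path.
#' @return \code{writeRunConfig} returns \code{path} invisibly;
#'   \code{readRunConfig} returns the named list.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Minimal leveled plain-text logger
#'
#' @param level one of DEBUG, INFO, WARN, ERROR.
#' @param ... message parts, pasted.
#' @param file connection or path ("" = stdout).
#' @return invisibly, the formatted line.
#' @export
tmLog <- function(level = c("INFO", "DEBUG", "WARN", "ERROR"), ...,
                  file = "") {
  level <- match.arg(level)
  line <- sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                  paste0(..., collapse = ""))
  cat(line, "\n", file = file, append = TRUE)
  invisible(line)
}
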