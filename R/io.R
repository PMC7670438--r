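# Standard-format I/O.  FASTA/FASTQ parsing is delegated to Biostrings;
# records are plain data.frames (id, taxon, moltype, seq) so downstream
# string algorithms stay transparent.

.normalise_seq <- function(seq) {
  seq <- toupper(seq)
  bad <- grepl("[^ACGTN-]", seq)
  if (any(bad)) {
    warning("IUPAC ambiguity codes other than N mapped to N in ",
            sum(bad), " sequence(s)")
    seq[bad] <- gsub("[^ACGTN-]", "N", seq[bad])
  }
  seq
}

#' Read sequence records from FASTA
#'
#' One record per entry; the header token before the first whitespace
#' becomes the id; the taxon is parsed from a `taxon=...` field in the
#' header description and set to `"unknown"` (with a warning) when absent.
#' Sequences are upper-cased; ambiguity codes other than `N` are mapped to
#' `N` with a warning.
#'
#' @param path FASTA file.
#' @param moltype One of `"dna_cds"`, `"dna_genomic"`, `"protein"`.
#' @return `data.frame` with columns `id`, `taxon`, `moltype`, `seq`.
#' @export
read_fasta <- function(path, moltype = "dna_genomic") {
  moltype <- match.arg(moltype, c("dna_cds", "dna_genomic", "protein"))
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(data.frame(id = character(), taxon = character(),
                      moltype = character(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  ss <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  headers <- names(ss)
  ids <- sub("\\s.*$", "", headers)
  taxon <- rep(NA_character_, length(headers))
  has <- grepl("taxon=", headers)
  taxon[has] <- sub(".*taxon=([^ ]+).*", "\\1", headers[has])
  if (any(!has)) {
    warning(sum(!has), " FASTA header(s) without a taxon field; ",
            "taxon set to 'unknown'")
    taxon[!has] <- "unknown"
  }
  seqs <- as.character(ss)
  if (moltype != "protein") seqs <- .normalise_seq(seqs)
  else seqs <- toupper(seqs)
  out <- data.frame(id = ids, taxon = taxon, moltype = moltype, seq = seqs,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (moltype == "dna_cds") invisible(lapply(out$seq, .as_codons))
  out
}

#' Write sequence records to FASTA
#'
#' Inverse of [read_fasta()]: headers are `id taxon=<taxon>`.
#'
#' @param records `data.frame` with `id`, `taxon`, `seq` (as from
#'   [read_fasta()]), or a named character vector of sequences.
#' @param path Output file.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), taxon = "unknown",
                          seq = unname(records), stringsAsFactors = FALSE)
  }
  ss <- Biostrings::BStringSet(records$seq)
  names(ss) <- paste0(records$id, " taxon=", records$taxon)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a short-read set from FASTQ
#'
#' Quality strings are parsed (and validated against sequence lengths by the
#' underlying parser) but ignored downstream.
#'
#' @param path FASTQ file.
#' @param library_id Library identifier (default: file name).
#' @return List of class `read_set`: `reads` (data.frame `id`, `seq`,
#'   `library_id`) and `library_size`.
#' @export
read_fastq <- function(path, library_id = basename(path)) {
  ss <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) stop("malformed FASTQ in ", path, ": ",
                             conditionMessage(e), call. = FALSE))
  # quality strings are parsed but ignored downstream; still validate their
  # lengths (4-line dialect), which the fast parser does not
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) %% 4 == 0L) {
    seqlen <- nchar(lines[seq(2, length(lines), by = 4)])
    quallen <- nchar(lines[seq(4, length(lines), by = 4)])
    if (any(seqlen != quallen)) {
      bad <- which(seqlen != quallen)[1]
      stop("FASTQ sequence/quality length mismatch at record ", bad,
           " (", sub("^@", "", lines[4 * bad - 3]), ")", call. = FALSE)
    }
  }
  ids <- sub("\\s.*$", "", names(ss))
  list(reads = data.frame(id = ids, seq = as.character(ss),
                          library_id = library_id, stringsAsFactors = FALSE),
       library_size = length(ss))
}

#' Write a read set to FASTQ (uniform dummy qualities)
#'
#' @param read_set As returned by [read_fastq()] or
#'   [generate_read_library()].
#' @param path Output file.
#' @export
write_fastq <- function(read_set, path) {
  r <- read_set$reads
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", r$id, "\n", r$seq, "\n+\n",
                    vapply(nchar(r$seq), function(n) {
                      paste(rep("I", n), collapse = "")
                    }, character(1))), con)
  invisible(path)
}

#' Write a report (or any list) as JSON
#'
#' @param report A list.
#' @param path Output file.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a JSON report back
#' @param path JSON file.
#' @export
read_report_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Write a data.frame as TSV
#' @param x data.frame.
#' @param path Output file.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path File path.
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE)
}

#' Reverse complement of DNA strings
#' @param seq Character vector of DNA sequences.
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Translate coding sequences to protein
#'
#' Terminal stop codons are dropped; internal stops (present only in
#' degenerate inputs) translate to `*`.
#'
#' @param cds Character vector of coding sequences.
#' @export
translate_cds <- function(cds) {
  vapply(cds, function(s) {
    cods <- .split_codons(s)
    aa <- vapply(cods, function(cd) {
      if (grepl("[^ACGT]", cd)) "X" else .aa(cd)
    }, character(1))
    if (length(aa) > 0L && aa[length(aa)] == "*") aa <- aa[-length(aa)]
    paste0(aa, collapse = "")
  }, character(1), USE.NAMES = !is.null(names(cds)))
}
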