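# Read-count expression assay: a read is counted for a gene when the two
# share an exact common substring of at least `min_perfect` nt on either
# strand; counts are normalised to counts per million (CPM).

#' Count reads sharing a perfect match with a gene
#'
#' A read is counted once if it shares with the gene (on either strand) at
#' least one exact common substring of length `min_perfect` or more.
#' Duplicate reads count individually via their multiplicities.
#' Implemented by hashing the gene's `min_perfect`-mers (both strands) and
#' streaming each read's `min_perfect`-mers against the hash; a common
#' substring of length `>= min_perfect` exists iff some `min_perfect`-mer
#' is shared.
#'
#' @param gene Gene sequence (string), at least `min_perfect` nt.
#' @param reads Read set (list with `reads` data.frame), data.frame with
#'   `seq`, or character vector; an optional `multiplicity` column is
#'   honoured.
#' @param min_perfect Minimum exact-match length in nt (default 60).
#' @return Integer raw count.
#' @export
count_matching_reads <- function(gene, reads, min_perfect = 60) {
  if (min_perfect < 1) stop("min_perfect must be >= 1", call. = FALSE)
  gene <- toupper(gene)
  if (nchar(gene) < min_perfect) {
    stop("gene shorter than min_perfect (", min_perfect, " nt)",
         call. = FALSE)
  }
  mult <- NULL
  if (is.list(reads) && !is.data.frame(reads) && !is.null(reads$reads)) {
    reads <- reads$reads
  }
  if (is.data.frame(reads)) {
    if (!is.null(reads$multiplicity)) mult <- reads$multiplicity
    reads <- reads$seq
  }
  if (is.null(mult)) mult <- rep(1L, length(reads))
  reads <- toupper(reads)
  k <- min_perfect
  index <- new.env(hash = TRUE, parent = emptyenv())
  for (g in c(gene, revcomp(gene))) {
    L <- nchar(g)
    if (L >= k) {
      for (km in substring(g, 1:(L - k + 1L), k:L)) assign(km, TRUE, index)
    }
  }
  total <- 0L
  for (i in seq_along(reads)) {
    r <- reads[i]
    L <- nchar(r)
    if (L < k) next
    for (pos in 1:(L - k + 1L)) {
      if (exists(substr(r, pos, pos + k - 1L), index)) {
        total <- total + mult[i]
        break
      }
    }
  }
  total
}

#' Counts-per-million normalisation
#'
#' @param raw_count Raw read count(s).
#' @param library_size Total reads in the originating library (> 0).
#' @return `raw_count / library_size * 1e6`.
#' @export
cpm_normalize <- function(raw_count, library_size) {
  if (any(library_size <= 0)) stop("library_size must be > 0", call. = FALSE)
  raw_count / library_size * 1e6
}

#' Expression table across genes and labelled libraries
#'
#' One record per gene and library; genes below the limit of detection get
#' a raw count of 0.
#'
#' @param genes Named character vector of gene sequences.
#' @param libraries List of libraries, each a list with `reads` (read set,
#'   data.frame, or character vector), `library_size`, `sample_id`,
#'   `tissue`, and `status` (`"E_plus"`, `"E_minus"`, or
#'   `"not_applicable"`).
#' @param min_perfect Minimum exact-match length (default 60).
#' @return `data.frame` with `gene`, `sample`, `tissue`, `status`,
#'   `raw_count`, `cpm`.
#' @export
expression_table <- function(genes, libraries, min_perfect = 60) {
  keys <- unlist(lapply(libraries, function(l) {
    paste(names(genes), l$sample_id)
  }))
  if (anyDuplicated(keys)) {
    stop("duplicate (gene, sample) pairs in libraries", call. = FALSE)
  }
  rows <- list()
  for (lib in libraries) {
    rd <- lib$reads
    if (is.list(rd) && !is.data.frame(rd) && !is.null(rd$reads)) rd <- rd$reads
    n_reads <- if (is.data.frame(rd)) nrow(rd) else length(rd)
    if (n_reads == 0L) {
      warning("library '", lib$sample_id, "' is empty; all-zero counts")
    }
    for (g in names(genes)) {
      cnt <- if (n_reads == 0L) 0L else {
        count_matching_reads(genes[[g]], rd, min_perfect)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, sample = lib$sample_id, tissue = lib$tissue,
        status = lib$status, raw_count = cnt,
        cpm = cpm_normalize(cnt, max(lib$library_size, 1)),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
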