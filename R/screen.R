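# Similarity screening: exact-word seeding on both strands, banded gapped
# extension to a local optimum, Karlin-Altschul E-values, and rule-based
# triage of hits into the four examination categories.

#' Collapse reads to unique sequences
#'
#' Exact-string deduplication with multiplicity bookkeeping; output order is
#' stable by first occurrence.
#'
#' @param reads A read set (as from [read_fastq()] or
#'   [generate_read_library()]), a data.frame with a `seq` column, or a
#'   character vector of read sequences.
#' @return `data.frame` of class `unique_read_set` with columns `id` (first
#'   occurrence id, when available), `seq`, `multiplicity`; attributes
#'   `n_input` and `library_id`.
#' @export
collapse_unique_reads <- function(reads) {
  lib <- NA_character_
  ids <- NULL
  if (is.list(reads) && !is.data.frame(reads) && !is.null(reads$reads)) {
    reads <- reads$reads
  }
  if (is.data.frame(reads)) {
    seqs <- reads$seq
    if (!is.null(reads$id)) ids <- reads$id
    if (!is.null(reads$library_id)) lib <- unique(reads$library_id)[1]
  } else {
    seqs <- as.character(reads)
  }
  if (is.null(ids)) ids <- sprintf("read%06d", seq_along(seqs))
  first <- !duplicated(seqs)
  uniq <- seqs[first]
  mult <- as.integer(table(factor(seqs, levels = uniq)))
  out <- data.frame(id = ids[first], seq = uniq, multiplicity = mult,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("unique_read_set", "data.frame"),
            n_input = length(seqs), library_id = lib)
}

#' Solve for the Karlin-Altschul lambda of a match/mismatch scheme
#'
#' `lambda` is the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s(i,j)) = 1` for the match/mismatch scoring
#' scheme under the given base frequencies, found numerically to 1e-9.  The
#' scheme must have negative expected score and a positive match score.  `K`
#' is a configurable constant (default 0.3), not estimated.
#'
#' @param match Match score (> 0).
#' @param mismatch Mismatch score.
#' @param base_freqs Base frequencies (length 4, summing to 1).
#' @param K Karlin-Altschul K constant.
#' @return List with `lambda` and `K`.
#' @export
solve_karlin_lambda <- function(match, mismatch,
                                base_freqs = rep(0.25, 4), K = 0.3) {
  p_match <- sum(base_freqs^2)
  exp_score <- p_match * match + (1 - p_match) * mismatch
  if (match <= 0 || exp_score >= 0) {
    stop("invalid scoring scheme: match must be > 0 and expected score < 0",
         call. = FALSE)
  }
  f <- function(l) p_match * exp(l * match) + (1 - p_match) * exp(l * mismatch) - 1
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  lambda <- uniroot(f, c(1e-12, hi), tol = 1e-12)$root
  list(lambda = lambda, K = K)
}

#' Search parameters for the local-alignment screen
#'
#' @param word_size Exact seed length (default 28; 64 supported).
#' @param match,mismatch Match/mismatch scores.
#' @param gap Linear gap penalty per gap character.
#' @param e_value_threshold Report hits with `E <=` this value.
#' @param K Karlin-Altschul K constant.
#' @param band Half-width of the banded gapped extension.
#' @param x_drop Terminate extension when the running best within a row
#'   falls this many score units below the overall best.
#' @param base_freqs Background base frequencies.
#' @return List of class `screen_params`.
#' @export
screen_params <- function(word_size = 28, match = 1, mismatch = -2,
                          gap = 4, e_value_threshold = 1e-10, K = 0.3,
                          band = 16, x_drop = 20,
                          base_freqs = rep(0.25, 4)) {
  structure(as.list(environment()), class = "screen_params")
}

# k-mer index of one subject: named list kmer -> start positions (1-based)
.kmer_index <- function(seq, w) {
  L <- nchar(seq)
  if (L < w) return(list())
  kmers <- substring(seq, 1:(L - w + 1), w:L)
  split(seq_len(L - w + 1L), kmers)
}

# banded local alignment around diagonal d0 (= spos - qpos of the seed).
# Linear gap penalty; returns NULL when nothing scores above 0.
.banded_sw <- function(q, s, d0, band, match, mismatch, gap, x_drop = Inf) {
  m <- nchar(q)
  n <- nchar(s)
  qv <- strsplit(q, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  W <- 2L * band + 1L
  H <- matrix(0, nrow = m + 1L, ncol = W)
  best <- 0
  best_cell <- c(0L, 0L)
  for (i in seq_len(m)) {
    j_lo <- i + d0 - band
    cols <- seq_len(W)
    js <- j_lo + cols - 1L
    valid <- js >= 1L & js <= n
    sub <- rep(-Inf, W)
    sub[valid] <- ifelse(qv[i] == sv[js[valid]], match, mismatch)
    diag_prev <- H[i, ]                      # (i-1, j-1) lives in same column
    up_prev <- c(H[i, -1L], -Inf)            # (i-1, j) is column + 1
    h <- pmax(0, diag_prev + sub, up_prev - gap)
    h[!valid] <- 0
    for (c in 2:W) {                          # left moves within the row
      cand <- h[c - 1L] - gap
      if (cand > h[c] && valid[c]) h[c] <- cand
    }
    H[i + 1L, ] <- h
    row_best <- max(h)
    if (row_best > best) {
      best <- row_best
      best_cell <- c(i, which.max(h))
    }
    if (is.finite(x_drop) && i > best_cell[1] && row_best < best - x_drop) {
      break
    }
  }
  if (best <= 0) return(NULL)
  # traceback with move re-derivation
  i <- best_cell[1]
  c <- best_cell[2]
  matches <- 0L; mismatches <- 0L; gaps <- 0L; gapopen <- 0L; len <- 0L
  in_gap <- FALSE
  qend <- i; send <- i + d0 - band + c - 1L
  repeat {
    val <- H[i + 1L, c]
    if (val <= 0) break
    j <- i + d0 - band + c - 1L
    sub <- if (qv[i] == sv[j]) match else mismatch
    if (i >= 1L && H[i, c] + sub == val) {
      len <- len + 1L
      if (qv[i] == sv[j]) matches <- matches + 1L else mismatches <- mismatches + 1L
      in_gap <- FALSE
      i <- i - 1L
    } else if (c < 2L * band + 1L && H[i, c + 1L] - gap == val) {
      len <- len + 1L; gaps <- gaps + 1L
      if (!in_gap) gapopen <- gapopen + 1L
      in_gap <- TRUE
      i <- i - 1L; c <- c + 1L
    } else if (c > 1L && H[i + 1L, c - 1L] - gap == val) {
      len <- len + 1L; gaps <- gaps + 1L
      if (!in_gap) gapopen <- gapopen + 1L
      in_gap <- TRUE
      c <- c - 1L
    } else {
      break
    }
  }
  qstart <- i + 1L
  sstart <- i + d0 - band + c
  list(score = best, qstart = qstart, qend = qend,
       sstart = sstart, send = send, length = len,
       matches = matches, mismatches = mismatches,
       gaps = gaps, gapopen = gapopen)
}

#' Seeded local-alignment search with E-value thresholding
#'
#' Exact `word_size` seeds are sought on both strands of each query against
#' every subject, deduplicated by diagonal, and extended with a banded
#' gapped dynamic program to a local optimum.  Raw scores are converted to
#' bit scores and E-values via the Karlin-Altschul relation
#' `E = K * m * n * exp(-lambda * score)` with `m` the query length and `n`
#' the total subject length.  Hits with `E <=` the threshold are returned
#' sorted by E-value.
#'
#' @param queries,subjects Named character vectors of DNA sequences (a
#'   data.frame with `id` and `seq` columns is also accepted).
#' @param params [screen_params()].
#' @return `data.frame` with columns `query_id`, `subject_id`, `strand`,
#'   `qstart`, `qend`, `sstart`, `send` (0-based half-open, plus strand of
#'   each sequence), `aligned_len`, `identity`, `mismatches`, `gapopen`,
#'   `raw_score`, `bit_score`, `e_value`.
#' @export
local_search <- function(queries, subjects, params = screen_params()) {
  queries <- .as_named_seqs(queries)
  subjects <- .as_named_seqs(subjects)
  if (any(grepl("[^ACGTN]", c(queries, subjects)))) {
    stop("queries and subjects must be DNA over {A,C,G,T,N}", call. = FALSE)
  }
  w <- params$word_size
  ka <- solve_karlin_lambda(params$match, params$mismatch,
                            params$base_freqs, params$K)
  n_total <- sum(nchar(subjects))
  idx <- lapply(subjects, .kmer_index, w = w)
  rows <- list()
  for (qname in names(queries)) {
    qplus <- queries[[qname]]
    m <- nchar(qplus)
    if (m < w) {
      warning("query '", qname, "' shorter than word size: no hits")
      next
    }
    for (strand in c("+", "-")) {
      q <- if (strand == "+") qplus else revcomp(qplus)
      qk <- substring(q, 1:(m - w + 1L), w:m)
      for (sname in names(subjects)) {
        sidx <- idx[[sname]]
        if (length(sidx) == 0L) next
        hitpos <- sidx[qk]
        qpos <- rep(seq_along(qk), lengths(hitpos))
        spos <- unlist(hitpos, use.names = FALSE)
        if (length(spos) == 0L) next
        diags <- spos - qpos
        keep <- !duplicated(diags)          # leftmost seed per diagonal
        seeds <- unique(data.frame(d = diags[keep], q = qpos[keep]))
        aligns <- list()
        for (r in seq_len(nrow(seeds))) {
          al <- .banded_sw(q, subjects[[sname]], seeds$d[r], params$band,
                           params$match, params$mismatch, params$gap,
                           params$x_drop)
          if (!is.null(al)) aligns[[length(aligns) + 1L]] <- al
        }
        if (length(aligns) == 0L) next
        aligns <- .dedupe_alignments(aligns)
        for (al in aligns) {
          e <- ka$K * m * n_total * exp(-ka$lambda * al$score)
          if (e > params$e_value_threshold) next
          qs <- al$qstart; qe <- al$qend
          if (strand == "-") {              # map back to plus-strand query
            qs <- m - al$qend + 1L
            qe <- m - al$qstart + 1L
          }
          rows[[length(rows) + 1L]] <- data.frame(
            query_id = qname, subject_id = sname, strand = strand,
            qstart = qs - 1L, qend = qe,
            sstart = al$sstart - 1L, send = al$send,
            aligned_len = al$length,
            identity = 100 * al$matches / al$length,
            mismatches = al$mismatches, gapopen = al$gapopen,
            raw_score = al$score,
            bit_score = (ka$lambda * al$score - log(ka$K)) / log(2),
            e_value = e, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(query_id = character(), subject_id = character(),
                      strand = character(), qstart = integer(),
                      qend = integer(), sstart = integer(), send = integer(),
                      aligned_len = integer(), identity = numeric(),
                      mismatches = integer(), gapopen = integer(),
                      raw_score = numeric(), bit_score = numeric(),
                      e_value = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$e_value, -out$raw_score, out$query_id,
                   out$subject_id, out$qstart, out$sstart), , drop = FALSE]
  out <- out[!duplicated(out[, c("query_id", "subject_id", "strand",
                                 "qstart", "qend", "sstart", "send")]), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

.as_named_seqs <- function(x) {
  if (is.data.frame(x)) {
    out <- toupper(x$seq)
    names(out) <- x$id
    return(out)
  }
  if (is.null(names(x))) names(x) <- sprintf("seq%04d", seq_along(x))
  toupper(x)
}

# drop alignments fully contained in a higher-scoring one
.dedupe_alignments <- function(aligns) {
  if (length(aligns) <= 1L) return(aligns)
  sc <- vapply(aligns, `[[`, numeric(1), "score")
  ord <- order(-sc)
  aligns <- aligns[ord]
  keep <- rep(TRUE, length(aligns))
  for (i in seq_along(aligns)[-1L]) {
    for (j in seq_len(i - 1L)) {
      if (!keep[j]) next
      a <- aligns[[i]]; b <- aligns[[j]]
      if (a$qstart >= b$qstart && a$qend <= b$qend &&
          a$sstart >= b$sstart && a$send <= b$send) {
        keep[i] <- FALSE
        break
      }
    }
  }
  aligns[keep]
}

#' Write similarity hits in 12-column tabular format
#'
#' The de-facto "outfmt 6" layout (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore), with 1-based inclusive
#' coordinates; subject coordinates are reversed on minus-strand hits.
#'
#' @param hits As returned by [local_search()].
#' @param path Output file.
#' @export
write_hits_tsv <- function(hits, path) {
  sstart <- ifelse(hits$strand == "-", hits$send, hits$sstart + 1L)
  send <- ifelse(hits$strand == "-", hits$sstart + 1L, hits$send)
  tab <- data.frame(hits$query_id, hits$subject_id,
                    sprintf("%.3f", hits$identity), hits$aligned_len,
                    hits$mismatches, hits$gapopen,
                    hits$qstart + 1L, hits$qend, sstart, send,
                    format(hits$e_value, digits = 3, scientific = TRUE),
                    sprintf("%.1f", hits$bit_score))
  write.table(tab, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Triage parameters for hit classification
#'
#' @param min_identity Minimum percent identity below which a hit is
#'   `low_similarity` (default 60).
#' @param min_len Minimum aligned length in nt (default 50).
#' @param microbiome_identity Identity at or above which a donor hit with no
#'   host-assembly support is `microbiome` (default 98).
#' @param e_value_threshold Threshold for panel co-hits.
#' @param search_params [screen_params()] used for the panel searches.
#' @export
classify_params <- function(min_identity = 60, min_len = 50,
                            microbiome_identity = 98,
                            e_value_threshold = 1e-10,
                            search_params = screen_params()) {
  structure(as.list(environment()), class = "classify_params")
}

#' Classify similarity hits into examination categories
#'
#' Operationalises the manual examination of candidate hits.  Rules are
#' applied in fixed order: `low_similarity` when identity or aligned length
#' falls below the thresholds; `conserved_eukaryote` when the query also
#' hits the outgroup-plant panel at the E threshold; `microbiome` when the
#' hit identity is at least `microbiome_identity` and the query has no match
#' in the host genome assembly; otherwise `hgt_candidate`.  A missing panel
#' skips its rule with a prominent warning.
#'
#' @param hits Hits of host queries against the donor set
#'   ([local_search()] output).
#' @param queries The query sequences behind `hits` (named vector or
#'   data.frame).
#' @param panels List with elements `outgroup` (outgroup-plant sequences),
#'   `host_assembly` (host genome/transcriptome sequences); either may be
#'   `NULL`.
#' @param params [classify_params()].
#' @return `data.frame`: the hit columns plus `category` and `evidence`;
#'   attribute `counts` holds the per-category totals.
#' @export
classify_hits <- function(hits, queries, panels, params = classify_params()) {
  queries <- .as_named_seqs(queries)
  if (nrow(hits) == 0L) {
    out <- cbind(hits, category = character(0), evidence = character(0))
    attr(out, "counts") <- list(total = 0L, low_similarity = 0L,
                                conserved_eukaryote = 0L, microbiome = 0L,
                                hgt_candidate = 0L)
    return(out)
  }
  qids <- unique(hits$query_id)
  qseqs <- queries[qids]
  sp <- params$search_params
  sp$e_value_threshold <- params$e_value_threshold
  outgroup_hit <- setNames(rep(FALSE, length(qids)), qids)
  if (!is.null(panels$outgroup) && length(panels$outgroup) > 0L) {
    oh <- local_search(qseqs, panels$outgroup, sp)
    outgroup_hit[unique(oh$query_id)] <- TRUE
  } else {
    warning("outgroup panel missing: conserved-gene rule skipped",
            immediate. = TRUE)
    outgroup_hit[] <- NA
  }
  host_hit <- setNames(rep(FALSE, length(qids)), qids)
  if (!is.null(panels$host_assembly) && length(panels$host_assembly) > 0L) {
    hh <- local_search(qseqs, panels$host_assembly, sp)
    host_hit[unique(hh$query_id)] <- TRUE
  } else {
    warning("host assembly panel missing: microbiome rule skipped",
            immediate. = TRUE)
    host_hit[] <- NA
  }
  category <- character(nrow(hits))
  evidence <- character(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    if (h$identity < params$min_identity || h$aligned_len < params$min_len) {
      category[i] <- "low_similarity"
      evidence[i] <- sprintf("identity %.1f%% / aligned %d nt below thresholds",
                             h$identity, h$aligned_len)
    } else if (isTRUE(outgroup_hit[[h$query_id]])) {
      category[i] <- "conserved_eukaryote"
      evidence[i] <- "query co-hits outgroup-plant panel at E threshold"
    } else if (h$identity >= params$microbiome_identity &&
               isFALSE(host_hit[[h$query_id]])) {
      category[i] <- "microbiome"
      evidence[i] <- sprintf("identity %.1f%% to donor, no host-assembly support",
                             h$identity)
    } else {
      category[i] <- "hgt_candidate"
      evidence[i] <- ""
    }
  }
  out <- cbind(hits, category = category, evidence = evidence,
               stringsAsFactors = FALSE)
  cnt <- function(k) sum(category == k)
  attr(out, "counts") <- list(
    total = nrow(hits),
    low_similarity = cnt("low_similarity"),
    conserved_eukaryote = cnt("conserved_eukaryote"),
    microbiome = cnt("microbiome"),
    hgt_candidate = cnt("hgt_candidate"))
  out
}

#' Per-donor-gene candidate summary
#'
#' Collapses `hgt_candidate` hits by subject gene, reporting the supporting
#' hit count, best identity, and total subject coverage (merged aligned
#' subject intervals, nt).
#'
#' @param classified Output of [classify_hits()].
#' @return `data.frame` with `subject_id`, `n_hits`, `best_identity`,
#'   `coverage_nt`.
#' @export
candidate_summary <- function(classified) {
  cand <- classified[classified$category == "hgt_candidate", , drop = FALSE]
  if (nrow(cand) == 0L) {
    return(data.frame(subject_id = character(), n_hits = integer(),
                      best_identity = numeric(), coverage_nt = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, lapply(split(cand, cand$subject_id), function(g) {
    iv <- g[order(g$sstart), c("sstart", "send")]
    cov <- 0L
    cur_s <- iv$sstart[1]; cur_e <- iv$send[1]
    if (nrow(iv) > 1L) for (k in 2:nrow(iv)) {
      if (iv$sstart[k] <= cur_e) cur_e <- max(cur_e, iv$send[k])
      else { cov <- cov + (cur_e - cur_s); cur_s <- iv$sstart[k]; cur_e <- iv$send[k] }
    }
    cov <- cov + (cur_e - cur_s)
    data.frame(subject_id = g$subject_id[1], n_hits = nrow(g),
               best_identity = max(g$identity), coverage_nt = cov,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
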