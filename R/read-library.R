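# Short-read library simulation with controlled duplication and
# contamination, emitting per-read truth labels.

#' Generate a synthetic short-read library
#'
#' Reads are drawn from the host transcript pool at uniformly sampled
#' lengths and positions; a controlled fraction of reads are duplicates of
#' earlier reads (to exercise read collapsing); contaminant reads are drawn
#' verbatim from donor sequences (microbiome) and from slow-evolving
#' conserved genes (conserved).  Each read carries exactly one truth label.
#'
#' @param host_pool Named character vector of host source sequences; names
#'   are gene ids.
#' @param microbiome_pool,conserved_pool Named character vectors of
#'   contaminant source sequences (may be empty).
#' @param n_reads Total reads to emit.
#' @param read_len_range Length range in nt (default `c(140, 150)`).
#' @param dup_fraction Fraction of reads emitted as duplicates of earlier
#'   reads (default 0.3).
#' @param microbiome_frac,conserved_frac Contaminant fractions of the fresh
#'   reads (each in `[0,1]`, sum with host fraction `<= 1`).
#' @param host_origins Optional named character vector mapping host gene id
#'   to its truth origin (default: every host gene `"vertical"`).
#' @param weights Optional named sampling weights over host genes (relative
#'   expression); default uniform.
#' @param library_id Library identifier.
#' @param seed Optional integer seed.
#' @return List with `reads` (data.frame `id`, `seq`, `library_id`),
#'   `library_size`, and `truth` (data.frame `id`, `origin`, `source`).
#' @export
generate_read_library <- function(host_pool,
                                  microbiome_pool = character(),
                                  conserved_pool = character(),
                                  n_reads = 2000,
                                  read_len_range = c(140, 150),
                                  dup_fraction = 0.3,
                                  microbiome_frac = 0,
                                  conserved_frac = 0,
                                  host_origins = NULL,
                                  weights = NULL,
                                  library_id = "lib1",
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (length(host_pool) == 0L) stop("host_pool is empty", call. = FALSE)
  stopifnot(microbiome_frac >= 0, conserved_frac >= 0,
            microbiome_frac + conserved_frac <= 1, dup_fraction >= 0,
            dup_fraction < 1)
  max_len <- read_len_range[2]
  usable <- function(pool, what) {
    short <- nchar(pool) < max_len
    if (any(short)) {
      warning(sum(short), " ", what,
              " source(s) shorter than the maximum read length: skipped")
      pool <- pool[!short]
    }
    pool
  }
  host_pool <- usable(host_pool, "host")
  microbiome_pool <- usable(microbiome_pool, "microbiome")
  conserved_pool <- usable(conserved_pool, "conserved")
  if (length(host_pool) == 0L) stop("no usable host source sequences",
                                    call. = FALSE)
  if (is.null(host_origins)) {
    host_origins <- setNames(rep("vertical", length(host_pool)),
                             names(host_pool))
  }
  if (is.null(weights)) weights <- setNames(rep(1, length(host_pool)),
                                            names(host_pool))
  weights <- weights[names(host_pool)]
  n_fresh <- max(1L, round(n_reads * (1 - dup_fraction)))
  n_mic <- if (length(microbiome_pool) > 0L) round(n_fresh * microbiome_frac) else 0L
  n_con <- if (length(conserved_pool) > 0L) round(n_fresh * conserved_frac) else 0L
  n_host <- n_fresh - n_mic - n_con
  draw <- function(pool, n, w = NULL, origin = NA_character_) {
    if (n == 0L) return(data.frame(seq = character(), source = character(),
                                   origin = character(),
                                   stringsAsFactors = FALSE))
    src <- if (is.null(w)) sample(names(pool), n, replace = TRUE)
           else sample(names(pool), n, replace = TRUE, prob = w)
    len <- sample(seq(read_len_range[1], read_len_range[2]), n,
                  replace = TRUE)
    start <- vapply(seq_len(n), function(i) {
      sample.int(nchar(pool[[src[i]]]) - len[i] + 1L, 1L)
    }, integer(1))
    data.frame(seq = substr(pool[src], start, start + len - 1L),
               source = src, origin = origin, stringsAsFactors = FALSE)
  }
  fresh <- rbind(
    draw(host_pool, n_host, weights),
    draw(microbiome_pool, n_mic, origin = "microbiome"),
    draw(conserved_pool, n_con, origin = "conserved")
  )
  hostrows <- is.na(fresh$origin)
  fresh$origin[hostrows] <- host_origins[fresh$source[hostrows]]
  # shuffle, then append duplicates of already-emitted reads
  fresh <- fresh[sample.int(nrow(fresh)), , drop = FALSE]
  n_dup <- n_reads - nrow(fresh)
  if (n_dup > 0L) {
    dup_idx <- sample.int(nrow(fresh), n_dup, replace = TRUE)
    fresh <- rbind(fresh, fresh[dup_idx, , drop = FALSE])
  }
  ids <- sprintf("%s_read%06d", library_id, seq_len(nrow(fresh)))
  list(
    reads = data.frame(id = ids, seq = toupper(fresh$seq),
                       library_id = library_id, stringsAsFactors = FALSE),
    library_size = nrow(fresh),
    truth = data.frame(id = ids, origin = fresh$origin,
                       source = fresh$source, stringsAsFactors = FALSE)
  )
}
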