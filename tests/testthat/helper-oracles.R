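# Independent oracles used to check the package's own implementations.
# These deliberately re-derive everything from first principles (standard
# genetic code via Biostrings, plain dynamic programs, recursive
# enumeration) and share no code with the package internals.

GC_ORACLE <- Biostrings::GENETIC_CODE

oracle_translate <- function(codon) unname(GC_ORACLE[codon])

# all orderings of a vector, by recursive insertion
oracle_permutations <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in oracle_permutations(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

# pathway-averaged (Sd, Nd) between two sense codons, stop-paths excluded
oracle_pathway <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  pos <- which(av != bv)
  if (length(pos) == 0L) return(c(0, 0))
  acc <- list()
  for (ord in oracle_permutations(pos)) {
    cur <- av
    sd_ <- 0
    nd_ <- 0
    bad <- FALSE
    for (p in ord) {
      nxt <- cur
      nxt[p] <- bv[p]
      c1 <- paste0(cur, collapse = "")
      c2 <- paste0(nxt, collapse = "")
      if (oracle_translate(c2) == "*" && c2 != b) bad <- TRUE
      if (oracle_translate(c1) == oracle_translate(c2)) sd_ <- sd_ + 1
      else nd_ <- nd_ + 1
      cur <- nxt
    }
    if (!bad) acc[[length(acc) + 1L]] <- c(sd_, nd_)
  }
  if (length(acc) == 0L) return(NULL)   # all pathways stop-crossing
  colMeans(do.call(rbind, acc))
}

# fractional site counts of a sense codon (stop targets nonsynonymous)
oracle_sites <- function(codon) {
  syn <- 0
  for (p in 1:3) {
    for (nt in setdiff(c("A", "C", "G", "T"), substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- nt
      if (oracle_translate(mut) != "*" &&
          oracle_translate(mut) == oracle_translate(codon)) {
        syn <- syn + 1
      }
    }
  }
  S <- 3 * syn / 9
  c(S = S, N = 3 - S)
}

# full-enumeration Nei-Gojobori on a short aligned pair
oracle_nei_gojobori <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    if (grepl("[^ACGT]", ca[i]) || grepl("[^ACGT]", cb[i])) next
    if (oracle_translate(ca[i]) == "*" || oracle_translate(cb[i]) == "*") next
    sa <- oracle_sites(ca[i])
    sb <- oracle_sites(cb[i])
    S <- S + (sa["S"] + sb["S"]) / 2
    N <- N + (sa["N"] + sb["N"]) / 2
    d <- oracle_pathway(ca[i], cb[i])
    Sd <- Sd + d[1]
    Nd <- Nd + d[2]
  }
  ps <- unname(Sd / S)
  pn <- unname(Nd / N)
  list(S = unname(S), N = unname(N), Sd = unname(Sd), Nd = unname(Nd),
       ps = ps, pn = pn,
       Ks = -0.75 * log(1 - 4 * ps / 3),
       Ka = -0.75 * log(1 - 4 * pn / 3))
}

# full (unbanded) Smith-Waterman best local score, linear gap penalty
oracle_smith_waterman <- function(q, s, match = 1, mismatch = -2, gap = 4) {
  qv <- strsplit(q, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  m <- length(qv)
  n <- length(sv)
  H <- matrix(0, m + 1, n + 1)
  best <- 0
  for (i in 1:m) {
    sub <- ifelse(qv[i] == sv, match, mismatch)
    for (j in 1:n) {
      H[i + 1, j + 1] <- max(0, H[i, j] + sub[j],
                             H[i, j + 1] - gap, H[i + 1, j] - gap)
    }
    best <- max(best, max(H[i + 1, ]))
  }
  best
}

# longest common substring length of two strings, plain DP
oracle_lcs_length <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  prev <- integer(length(bv))
  best <- 0L
  for (i in seq_along(av)) {
    cur <- integer(length(bv))
    eq <- av[i] == bv
    cur[eq] <- c(0L, prev)[which(eq)] + 1L
    best <- max(best, cur)
    prev <- cur
  }
  best
}

oracle_revcomp <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(x, function(s) {
           paste(rev(strsplit(s, "")[[1]]), collapse = "")
         }, character(1), USE.NAMES = FALSE))
}

# memoised demo pipeline report, shared across test files
demo_report_env <- new.env()
demo_report <- function() {
  if (is.null(demo_report_env$report)) {
    demo_report_env$bundle_seed <- 1L
    demo_report_env$report <- suppressWarnings(suppressMessages(run_pipeline()))
  }
  demo_report_env$report
}
demo_bundle <- function() {
  if (is.null(demo_report_env$bundle)) {
    demo_report_env$bundle <-
      suppressWarnings(simulate_hgt_bundle(simulation_config(seed = 1L)))
  }
  demo_report_env$bundle
}
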