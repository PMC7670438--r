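# Read collapsing, Karlin-Altschul solving, the seeded local-alignment
# search (against a full Smith-Waterman oracle), and hit triage.

test_that("read collapsing keeps multiplicities and first-occurrence order", {
  u <- collapse_unique_reads(c("ACGT", "ACGT", "ACGA"))
  expect_equal(u$seq, c("ACGT", "ACGA"))
  expect_equal(u$multiplicity, c(2L, 1L))
  all_distinct <- collapse_unique_reads(c("AA", "AC", "AG", "AT"))
  expect_equal(nrow(all_distinct), 4L)
  expect_true(all(all_distinct$multiplicity == 1L))
  expect_equal(sum(u$multiplicity), attr(u, "n_input"))
})

test_that("Karlin lambda solves the transcendental equation", {
  ka <- solve_karlin_lambda(1, -2)
  # independent root of 0.25 e^l + 0.75 e^(-2l) = 1
  f <- function(l) 0.25 * exp(l) + 0.75 * exp(-2 * l) - 1
  l_oracle <- uniroot(f, c(1e-6, 5), tol = 1e-12)$root
  expect_equal(ka$lambda, l_oracle, tolerance = 1e-9)
  # doubling the scores roughly halves lambda
  ka2 <- solve_karlin_lambda(2, -4)
  expect_equal(ka2$lambda, ka$lambda / 2, tolerance = 1e-9)
  # invalid schemes are rejected
  expect_error(solve_karlin_lambda(1, 1), "invalid scoring scheme")
  expect_error(solve_karlin_lambda(-1, -2), "invalid scoring scheme")
})

test_that("a verbatim embedded query yields one perfect low-E hit on both strands", {
  set.seed(21)
  subject <- paste0(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                    collapse = "")
  query <- substr(subject, 4001, 4300)
  hits <- local_search(c(q1 = query), c(s1 = subject))
  plus <- hits[hits$strand == "+", ]
  expect_equal(nrow(plus), 1L)
  expect_equal(plus$identity, 100)
  expect_equal(plus$aligned_len, 300L)
  expect_equal(plus$sstart, 4000L)   # 0-based half-open
  expect_equal(plus$send, 4300L)
  expect_lte(plus$e_value, 1e-10)
  # reverse-complemented query: same subject interval, minus strand, same score
  hits_rc <- local_search(c(q1 = revcomp(query)), c(s1 = subject))
  minus <- hits_rc[hits_rc$strand == "-", ]
  expect_equal(nrow(minus), 1L)
  expect_equal(minus$raw_score, plus$raw_score)
  expect_equal(minus$sstart, plus$sstart)
  expect_equal(minus$send, plus$send)
})

test_that("unrelated random sequences produce no hits at the 1e-10 threshold", {
  set.seed(77)
  n_hits <- 0L
  for (i in 1:100) {
    q <- paste0(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
                collapse = "")
    s <- paste0(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
                collapse = "")
    n_hits <- n_hits + nrow(local_search(c(q = q), c(s = s)))
  }
  expect_equal(n_hits, 0L)
})

test_that("word size longer than the query warns and yields nothing", {
  expect_warning(h <- local_search(c(q = "ACGTACGT"),
                                   c(s = strrep("ACGT", 100))),
                 "shorter than word size")
  expect_equal(nrow(h), 0L)
  expect_error(local_search(c(q = "ACGU"), c(s = "ACGT")), "DNA")
})

test_that("search score equals the Smith-Waterman optimum when a seed exists", {
  set.seed(31)
  sp <- screen_params(word_size = 8, e_value_threshold = 1e300)
  for (rep in 1:12) {
    s <- paste0(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
                collapse = "")
    a <- sample(30:160, 1)
    q <- substr(s, a, a + 29)
    qv <- strsplit(q, "")[[1]]
    n_mut <- sample(0:2, 1)
    if (n_mut > 0) {
      # confine mutations to the tail so an intact 8-mer seed survives
      idx <- sample(12:30, n_mut)
      qv[idx] <- vapply(qv[idx], function(ch) {
        sample(setdiff(c("A", "C", "G", "T"), ch), 1)
      }, character(1))
    }
    q <- paste0(qv, collapse = "")
    hits <- local_search(c(q = q), c(s = s), sp)
    expect_gt(nrow(hits), 0L)
    expect_equal(max(hits$raw_score), oracle_smith_waterman(q, s))
  }
})

test_that("gapped alignments within the band reach the Smith-Waterman optimum", {
  set.seed(33)
  s <- paste0(sample(c("A", "C", "G", "T"), 200, replace = TRUE),
              collapse = "")
  # query = subject segment with a 2-nt deletion in the middle
  q <- paste0(substr(s, 50, 79), substr(s, 82, 111))
  sp <- screen_params(word_size = 10, e_value_threshold = 1e300)
  hits <- local_search(c(q = q), c(s = s), sp)
  expect_gt(nrow(hits), 0L)
  expect_equal(max(hits$raw_score), oracle_smith_waterman(q, s))
  best <- hits[which.max(hits$raw_score), ]
  expect_gte(best$gapopen, 1L)
})

test_that("lowering the E threshold never adds hits", {
  set.seed(41)
  s <- paste0(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
              collapse = "")
  qs <- c(q1 = substr(s, 101, 250), q2 = substr(s, 1001, 1100))
  loose <- local_search(qs, c(s = s),
                        screen_params(e_value_threshold = 1e300))
  strict <- local_search(qs, c(s = s),
                         screen_params(e_value_threshold = 1e-10))
  key <- function(h) paste(h$query_id, h$subject_id, h$strand, h$qstart,
                           h$sstart)
  expect_true(all(key(strict) %in% key(loose)))
  expect_lte(nrow(strict), nrow(loose))
})

test_that("triage rules fire in order and partition every hit", {
  set.seed(51)
  donor_gene <- random_cds(300, terminal_stop = FALSE)
  # ~96% identical host copy (present in host assembly, absent elsewhere)
  hv <- strsplit(donor_gene, "")[[1]]
  idx <- sample(seq_along(hv), round(length(hv) * 0.04))
  hv[idx] <- vapply(hv[idx], function(ch) {
    sample(setdiff(c("A", "C", "G", "T"), ch), 1)
  }, character(1))
  host_copy <- paste0(hv, collapse = "")
  conserved <- random_cds(300, terminal_stop = FALSE)
  donor_only <- random_cds(300, terminal_stop = FALSE)
  queries <- c(hgt_query = host_copy,
               conserved_query = conserved,
               microbiome_query = donor_only)   # verbatim donor-only gene
  subjects <- c(donor_g1 = donor_gene, donor_cons = conserved,
                donor_g2 = donor_only)
  sp <- screen_params(word_size = 12)
  hits <- local_search(queries, subjects, sp)
  cl <- classify_hits(hits, queries,
                      panels = list(
                        outgroup = c(out_cons = conserved),
                        host_assembly = c(host_g1 = host_copy)),
                      params = classify_params(search_params = sp))
  cats <- setNames(cl$category, cl$query_id)
  expect_equal(unname(cats[["hgt_query"]]), "hgt_candidate")
  expect_equal(unname(cats[["conserved_query"]]), "conserved_eukaryote")
  expect_equal(unname(cats[["microbiome_query"]]), "microbiome")
  counts <- attr(cl, "counts")
  expect_equal(counts$total,
               counts$low_similarity + counts$conserved_eukaryote +
                 counts$microbiome + counts$hgt_candidate)
  expect_true(all(nzchar(cl$evidence[cl$category != "hgt_candidate"])))
})

test_that("a missing panel skips its rule with a warning", {
  set.seed(52)
  g <- random_cds(200, terminal_stop = FALSE)
  hits <- local_search(c(q = g), c(s = g), screen_params(word_size = 12))
  w <- capture_warnings(
    cl <- classify_hits(hits, c(q = g),
                        panels = list(outgroup = NULL, host_assembly = NULL)))
  expect_true(any(grepl("outgroup panel missing", w)))
  expect_true(any(grepl("host assembly panel missing", w)))
  # verbatim donor match would be microbiome, but the rule is disabled
  expect_equal(cl$category, "hgt_candidate")
})

test_that("candidate summary collapses hits per donor gene", {
  cl <- data.frame(
    query_id = c("r1", "r2", "r3", "r4", "r5"),
    subject_id = c("gA", "gA", "gB", "gC", "gC"),
    sstart = c(0L, 50L, 10L, 0L, 200L),
    send = c(100L, 150L, 110L, 100L, 300L),
    identity = c(95, 97, 91, 88, 93),
    category = c("hgt_candidate", "hgt_candidate", "hgt_candidate",
                 "hgt_candidate", "hgt_candidate"),
    stringsAsFactors = FALSE)
  cs <- candidate_summary(cl)
  expect_equal(nrow(cs), 3L)
  gA <- cs[cs$subject_id == "gA", ]
  expect_equal(gA$n_hits, 2L)
  expect_equal(gA$best_identity, 97)
  expect_equal(gA$coverage_nt, 150L)   # merged overlapping intervals
  gC <- cs[cs$subject_id == "gC", ]
  expect_equal(gC$coverage_nt, 200L)   # disjoint intervals add up
  empty <- candidate_summary(cl[cl$category == "none", ])
  expect_equal(nrow(empty), 0L)
})

test_that("hits table writes the 12-column 1-based tabular layout", {
  set.seed(61)
  s <- paste0(sample(c("A", "C", "G", "T"), 2000, replace = TRUE),
              collapse = "")
  q <- substr(s, 501, 650)
  hits <- local_search(c(q = q), c(s = s))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_hits_tsv(hits, f)
  tab <- read.delim(f, header = FALSE)
  expect_equal(ncol(tab), 12L)
  plus <- tab[1, ]
  expect_equal(plus$V7, 1L)      # qstart, 1-based
  expect_equal(plus$V9, 501L)    # sstart, 1-based
  expect_equal(plus$V10, 650L)
})
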