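# Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction, group summaries
# with divergence-age-normalised rates, codon usage profiles, and percent
# identity.

.split_codons <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) %% 3 != 0) {
    stop("sequence length not divisible by 3", call. = FALSE)
  }
  substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
}

#' Nei-Gojobori Ka/Ks for an aligned pair of coding sequences
#'
#' Counting-based estimator: fractional synonymous/nonsynonymous site counts
#' are summed over the codons of both sequences and averaged; pathway-averaged
#' synonymous/nonsynonymous differences are summed over codon pairs; the
#' proportions `ps = Sd/S` and `pn = Nd/N` are Jukes-Cantor corrected to give
#' `Ks` and `Ka`.  Codons containing a gap (`-`) or ambiguous base in either
#' sequence, and stop codons, are skipped.
#'
#' @param seq_a,seq_b Aligned coding sequences of equal length (strings).
#' @param id_a,id_b Optional sequence identifiers.
#' @return Object of class `pairwise_kaks`: list with fields `S`, `N`, `Sd`,
#'   `Nd`, `ps`, `pn`, `Ks`, `Ka`, `ratio`, `n_codons`, and saturation flags.
#'   `ratio` is `Ka/Ks` when `Ks > 0`, `Inf` (flagged) when `Ks = 0 < Ka`,
#'   and `NA` when both are 0 or either distance is saturated.
#' @export
nei_gojobori <- function(seq_a, seq_b, id_a = "seq_a", id_b = "seq_b") {
  seq_a <- toupper(seq_a)
  seq_b <- toupper(seq_b)
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  ca <- .split_codons(seq_a)
  cb <- .split_codons(seq_b)
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ok[ok] <- !.is_stop(ca[ok]) & !.is_stop(cb[ok])
  if (!any(ok)) stop("no countable codons in alignment", call. = FALSE)
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in which(ok)) {
    sa <- .codon_tables$sites[[ca[i]]]
    sb <- .codon_tables$sites[[cb[i]]]
    S <- S + (sa["S"] + sb["S"]) / 2
    N <- N + (sa["N"] + sb["N"]) / 2
    if (ca[i] != cb[i]) {
      d <- count_pathway_differences(ca[i], cb[i])
      Sd <- Sd + d["Sd"]
      Nd <- Nd + d["Nd"]
    }
  }
  ps <- unname(Sd / S)
  pn <- unname(Nd / N)
  jc <- function(p) {
    tryCatch(jukes_cantor_correct(p),
             xenolog_saturation = function(e) NA_real_)
  }
  Ks <- jc(ps)
  Ka <- jc(pn)
  saturated_s <- is.na(Ks)
  saturated_n <- is.na(Ka)
  ratio <- if (saturated_s || saturated_n) {
    NA_real_
  } else if (Ks > 0) {
    Ka / Ks
  } else if (Ka > 0) {
    Inf
  } else {
    NA_real_
  }
  structure(
    list(id_a = id_a, id_b = id_b,
         S = unname(S), N = unname(N), Sd = unname(Sd), Nd = unname(Nd),
         ps = ps, pn = pn, Ks = Ks, Ka = Ka, ratio = ratio,
         n_codons = sum(ok),
         saturated_s = saturated_s, saturated_n = saturated_n),
    class = "pairwise_kaks"
  )
}

#' @export
print.pairwise_kaks <- function(x, ...) {
  cat(sprintf("Nei-Gojobori %s vs %s: Ks=%.4f Ka=%.4f Ka/Ks=%s (%d codons)\n",
              x$id_a, x$id_b, x$Ks, x$Ka, format(x$ratio, digits = 4),
              x$n_codons))
  invisible(x)
}

#' Group Ka/Ks summary with age-normalised substitution rates
#'
#' Averages pairwise Nei-Gojobori estimates over a group of sequence pairs
#' and normalises the averages by the divergence age of the group:
#' `Ks_rate = Ks_avg / T` and `Ka_rate = Ka_avg / T` (the age is divided in
#' once, following the convention of the summary table this reproduces; see
#' the methods vignette).  Standard deviations are population standard
#' deviations.  The group ratio is `Ka_avg / Ks_avg` by default; per-pair
#' ratio averaging is available via `ratio_mode`.
#'
#' @param pairs List of `pairwise_kaks` objects.
#' @param T Divergence age of the group, in MYA (> 0).
#' @param label Combination label.
#' @param ratio_mode `"ratio_of_averages"` (default) or `"average_of_ratios"`.
#' @return Object of class `group_kaks`: list with `label`, `T`, `Ks_avg`,
#'   `Ks_sdv`, `Ks_rate`, `Ka_avg`, `Ka_sdv`, `Ka_rate`, `ratio`, `n_pairs`.
#' @export
group_kaks <- function(pairs, T, label = "group",
                       ratio_mode = c("ratio_of_averages",
                                      "average_of_ratios")) {
  ratio_mode <- match.arg(ratio_mode)
  usable <- Filter(function(p) !p$saturated_s && !p$saturated_n, pairs)
  if (length(usable) == 0L) {
    stop("all pairs saturated; no usable Ka/Ks estimates", call. = FALSE)
  }
  ks <- vapply(usable, `[[`, numeric(1), "Ks")
  ka <- vapply(usable, `[[`, numeric(1), "Ka")
  kaks_summary(label = label, T = T,
               Ks_avg = mean(ks), Ks_sdv = .pop_sd(ks),
               Ka_avg = mean(ka), Ka_sdv = .pop_sd(ka),
               ratio = if (ratio_mode == "average_of_ratios") {
                 mean(vapply(usable, `[[`, numeric(1), "ratio"))
               } else NULL,
               n_pairs = length(usable))
}

#' Group summary arithmetic from precomputed averages
#'
#' Computes the derived cells of a group Ka/Ks summary row — the
#' age-normalised rates `Ks_avg/T`, `Ka_avg/T` and the ratio
#' `Ka_avg/Ks_avg` — from the group averages.  Used both by [group_kaks()]
#' and directly when the averages come from a published table.
#'
#' @param label Combination label.
#' @param T Divergence age in MYA (> 0).
#' @param Ks_avg,Ka_avg Group average synonymous/nonsynonymous distances.
#' @param Ks_sdv,Ka_sdv Standard deviations (optional).
#' @param ratio Override for the group ratio; default `Ka_avg/Ks_avg`.
#' @param n_pairs Number of pairs behind the averages (optional).
#' @return Object of class `group_kaks`.
#' @export
kaks_summary <- function(label, T, Ks_avg, Ka_avg,
                         Ks_sdv = NA_real_, Ka_sdv = NA_real_,
                         ratio = NULL, n_pairs = NA_integer_) {
  if (!is.numeric(T) || T <= 0) stop("divergence age T must be > 0",
                                     call. = FALSE)
  structure(
    list(label = label, T = T,
         Ks_avg = Ks_avg, Ks_sdv = Ks_sdv, Ks_rate = Ks_avg / T,
         Ka_avg = Ka_avg, Ka_sdv = Ka_sdv, Ka_rate = Ka_avg / T,
         ratio = if (is.null(ratio)) Ka_avg / Ks_avg else ratio,
         n_pairs = n_pairs),
    class = "group_kaks"
  )
}

.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' @export
print.group_kaks <- function(x, ...) {
  cat(sprintf(
    "%s (T=%g MYA): Ks %.4f (rate %.4f/MY), Ka %.4f (rate %.4f/MY), Ka/Ks %.4f\n",
    x$label, x$T, x$Ks_avg, x$Ks_rate, x$Ka_avg, x$Ka_rate, x$ratio))
  invisible(x)
}

#' Format group Ka/Ks summaries as a table
#'
#' @param groups List of `group_kaks` objects.
#' @return `data.frame` with one row per group (combination, T, Ks_avg,
#'   Ks_sdv, Ks_rate, Ka_avg, Ka_sdv, Ka_rate, ratio).
#' @export
kaks_table <- function(groups) {
  do.call(rbind, lapply(groups, function(g) {
    data.frame(combination = g$label, T = g$T,
               Ks_avg = g$Ks_avg, Ks_sdv = g$Ks_sdv, Ks_rate = g$Ks_rate,
               Ka_avg = g$Ka_avg, Ka_sdv = g$Ka_sdv, Ka_rate = g$Ka_rate,
               ratio = g$ratio, stringsAsFactors = FALSE)
  }))
}

#' Codon usage profile of a coding-sequence set
#'
#' For each of the 18 amino acids encoded by more than one codon, the usage
#' ratio of every synonymous codon among that amino acid's occurrences pooled
#' over the set; plus the termination signal, profiled over the terminal stop
#' codons (`TAA`/`TAG`/`TGA`).  Methionine and tryptophan (single codon) are
#' excluded.  A CDS lacking a terminal stop codon contributes no termination
#' observation and triggers a warning.
#'
#' @param cds_set Character vector of coding sequences (terminal stop codons
#'   expected), optionally named.
#' @return `data.frame` with columns `amino_acid` (one-letter code, `*` for
#'   the termination signal), `codon`, `count`, `ratio`.  Ratios within each
#'   amino acid sum to 1 whenever the amino acid occurs.
#' @export
codon_usage_profile <- function(cds_set) {
  cds_set <- toupper(cds_set)
  counts <- setNames(integer(length(.gc)), names(.gc))
  term <- setNames(integer(3), .stop_codons)
  for (s in cds_set) {
    cods <- .split_codons(s)
    last <- cods[length(cods)]
    if (!grepl("[^ACGT]", last) && .is_stop(last)) {
      term[last] <- term[last] + 1L
      cods <- cods[-length(cods)]
    } else {
      warning("CDS lacks a terminal stop codon; termination signal omitted")
    }
    cods <- cods[!grepl("[^ACGT]", cods)]
    cods <- cods[!.is_stop(cods)]
    tab <- table(cods)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  rows <- list()
  aas <- sort(unique(.gc[.gc != "*"]))
  for (aa in aas) {
    cods <- names(.gc)[.gc == aa]
    if (length(cods) < 2L) next   # Met, Trp
    tot <- sum(counts[cods])
    rows[[aa]] <- data.frame(
      amino_acid = aa, codon = cods, count = unname(counts[cods]),
      ratio = if (tot > 0) unname(counts[cods]) / tot else NA_real_,
      stringsAsFactors = FALSE)
  }
  ttot <- sum(term)
  rows[["*"]] <- data.frame(
    amino_acid = "*", codon = .stop_codons, count = unname(term),
    ratio = if (ttot > 0) unname(term) / ttot else NA_real_,
    stringsAsFactors = FALSE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Percent identity of an aligned sequence pair
#'
#' Matching columns divided by the number of columns that are not
#' gap-versus-gap, times 100.
#'
#' @param a,b Aligned sequences of equal length (strings; `-` for gaps).
#' @return Percent identity in `[0, 100]`.
#' @export
percent_identity <- function(a, b) {
  a <- strsplit(toupper(a), "")[[1]]
  b <- strsplit(toupper(b), "")[[1]]
  if (length(a) != length(b)) {
    stop("aligned sequences must have equal length", call. = FALSE)
  }
  keep <- !(a == "-" & b == "-")
  if (!any(keep)) stop("no countable columns", call. = FALSE)
  100 * sum(a[keep] == b[keep]) / sum(keep)
}
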