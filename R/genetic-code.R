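#' @importFrom stats rexp runif sd setNames uniroot as.dist reorder
#' @importFrom utils head read.delim write.table modifyList
NULL

.bases <- c("A", "C", "G", "T")

# standard nuclear code; stops translate to "*"
.gc <- Biostrings::GENETIC_CODE

.aa <- function(codon) unname(.gc[codon])

.is_stop <- function(codon) .aa(codon) == "*"

.stop_codons <- names(.gc)[.gc == "*"]

.check_codon <- function(codon, allow_stop = FALSE) {
  if (!is.character(codon) || length(codon) != 1L || nchar(codon) != 3L ||
      grepl("[^ACGT]", codon)) {
    stop("not a valid codon over {A,C,G,T}: ", codon, call. = FALSE)
  }
  if (!allow_stop && .is_stop(codon)) {
    stop("stop codon not permitted here: ", codon, call. = FALSE)
  }
  invisible(codon)
}

# the 9 single-nucleotide neighbours of a codon
.codon_neighbours <- function(codon) {
  out <- character(9)
  k <- 0L
  for (p in 1:3) {
    for (b in .bases[.bases != substr(codon, p, p)]) {
      k <- k + 1L
      mut <- codon
      substr(mut, p, p) <- b
      out[k] <- mut
    }
  }
  out
}

# per-codon lookup tables, built once at load: fractional site counts and,
# for the simulator, the admissible single-nucleotide changes with their
# selective class
.codon_tables <- local({
  sense <- names(.gc)[.gc != "*"]
  sites <- list()
  changes <- list()
  for (cd in names(.gc)) {
    nb <- .codon_neighbours(cd)
    if (cd %in% sense) {
      syn <- sum(!.is_stop(nb) & .aa(nb) == .aa(cd))
      S <- 3 * syn / 9
      sites[[cd]] <- c(S = S, N = 3 - S)
      keep <- !.is_stop(nb)   # changes creating stop codons are rejected
      changes[[cd]] <- data.frame(
        to = nb[keep],
        syn = .aa(nb[keep]) == .aa(cd),
        stringsAsFactors = FALSE
      )
    } else {
      # a terminal stop codon wanders only among the three stop codons
      keep <- .is_stop(nb)
      changes[[cd]] <- data.frame(to = nb[keep], syn = TRUE,
                                  stringsAsFactors = FALSE)
    }
  }
  list(sites = sites, changes = changes, sense = sense)
})

#' Synonymous and nonsynonymous site counts of a codon
#'
#' Counts, over the nine possible single-nucleotide changes of a sense codon,
#' the fraction that are synonymous under the standard genetic code.  Changes
#' that create a stop codon are counted as nonsynonymous.  The synonymous
#' site count is `S = 3 * (synonymous fraction)` and `N = 3 - S`, so that
#' `S + N = 3` for every sense codon.
#'
#' @param codon A single sense codon over `{A,C,G,T}`.
#' @return Named numeric vector with elements `S` and `N`.
#' @examples
#' count_sites("TTT")  # S = 1/3: only TTT -> TTC is synonymous
#' count_sites("TGG")  # S = 0: tryptophan has no synonymous neighbour
#' @export
count_sites <- function(codon) {
  .check_codon(codon)
  .codon_tables$sites[[codon]]
}

#' Pathway-averaged synonymous and nonsynonymous differences between codons
#'
#' For two sense codons differing at 1, 2 or 3 positions, enumerates every
#' minimal mutational pathway (1, 2 or 6 orderings of the differing
#' positions), classifies each step as synonymous or nonsynonymous, and
#' averages the step counts over pathways.  Pathways passing through an
#' intermediate stop codon are excluded; if every pathway is excluded the
#' average falls back to all pathways with a warning.
#'
#' @param codon_a,codon_b Sense codons over `{A,C,G,T}`.
#' @return Named numeric vector with elements `Sd` and `Nd`.
#' @examples
#' count_pathway_differences("TTT", "GTA")  # (0.5, 1.5): two pathways
#' @export
count_pathway_differences <- function(codon_a, codon_b) {
  .check_codon(codon_a)
  .check_codon(codon_b)
  if (codon_a == codon_b) return(c(Sd = 0, Nd = 0))
  a <- strsplit(codon_a, "")[[1]]
  b <- strsplit(codon_b, "")[[1]]
  pos <- which(a != b)
  perms <- .perms(pos)
  keep <- matrix(NA_real_, nrow = length(perms), ncol = 2)
  viable <- logical(length(perms))
  for (i in seq_along(perms)) {
    cur <- codon_a
    sd_ <- 0
    nd_ <- 0
    through_stop <- FALSE
    for (p in perms[[i]]) {
      nxt <- cur
      substr(nxt, p, p) <- b[p]
      if (.is_stop(nxt) && nxt != codon_b) through_stop <- TRUE
      if (.aa(cur) == .aa(nxt)) sd_ <- sd_ + 1 else nd_ <- nd_ + 1
      cur <- nxt
    }
    keep[i, ] <- c(sd_, nd_)
    viable[i] <- !through_stop
  }
  if (!any(viable)) {
    warning("all mutational pathways between ", codon_a, " and ", codon_b,
            " pass through a stop codon; averaging over all pathways")
    viable[] <- TRUE
  }
  m <- colMeans(keep[viable, , drop = FALSE])
  c(Sd = m[1], Nd = m[2])
}

# all orderings of a set of 1-3 positions
.perms <- function(x) {
  n <- length(x)
  if (n == 1L) return(list(x))
  if (n == 2L) return(list(x, x[2:1]))
  idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
              c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  lapply(idx, function(i) x[i])
}

#' Jukes-Cantor multiple-hit correction
#'
#' Corrects an observed proportion of differences `p` for multiple
#' substitutions: `d = -(3/4) * log(1 - (4/3) * p)`.  Defined for
#' `0 <= p < 0.75`; at or beyond 0.75 the distance is saturated and an error
#' of class `xenolog_saturation` is signalled.
#'
#' @param p Proportion(s) of differing sites, in `[0, 0.75)`.
#' @return Corrected distance(s), same length as `p`.
#' @export
jukes_cantor_correct <- function(p) {
  if (any(!is.finite(p)) || any(p < 0)) {
    stop("p must be finite and non-negative", call. = FALSE)
  }
  if (any(p >= 0.75)) {
    stop(structure(
      class = c("xenolog_saturation", "error", "condition"),
      list(message = "proportion of differences >= 0.75: distance saturated",
           call = sys.call(-1))
    ))
  }
  -0.75 * log(1 - 4 * p / 3)
}
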