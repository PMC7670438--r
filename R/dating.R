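# Presence/absence evidence, Dollo (single-gain) dating of gene
# acquisitions on the calibrated host tree, donor-side age constraints, and
# in-silico PCR.

#' Build a presence/absence matrix from mixed evidence
#'
#' Combines in-silico (database) and PCR screening calls per (taxon, gene).
#' PCR evidence overrides conflicting in-silico evidence in either
#' direction; concordant calls are recorded with evidence `both`; a cell
#' with no evidence is `not_analysed`.  An in-silico absence with no PCR
#' backing is kept but flagged low-confidence.
#'
#' @param insilico,pcr `data.frame`s with columns `taxon`, `gene`, `call`
#'   (`"present"`/`"absent"`); either may be `NULL`.
#' @param taxa,genes Taxa and genes spanning the matrix (defaults: union of
#'   the evidence).
#' @return `data.frame` of class `presence_matrix` with one row per cell:
#'   `taxon`, `gene`, `call`, `evidence`, `conflict`, `low_confidence`.
#' @export
build_presence_matrix <- function(insilico = NULL, pcr = NULL,
                                  taxa = NULL, genes = NULL) {
  get_call <- function(df, tx, g) {
    if (is.null(df)) return(NA_character_)
    i <- which(df$taxon == tx & df$gene == g)
    if (length(i) == 0L) return(NA_character_)
    df$call[i[1]]
  }
  if (is.null(taxa)) taxa <- unique(c(insilico$taxon, pcr$taxon))
  if (is.null(genes)) genes <- unique(c(insilico$gene, pcr$gene))
  rows <- list()
  for (g in genes) for (tx in taxa) {
    is_call <- get_call(insilico, tx, g)
    pcr_call <- get_call(pcr, tx, g)
    if (is.na(is_call) && is.na(pcr_call)) {
      rows[[length(rows) + 1L]] <- data.frame(
        taxon = tx, gene = g, call = "not_analysed", evidence = NA_character_,
        conflict = FALSE, low_confidence = FALSE, stringsAsFactors = FALSE)
      next
    }
    conflict <- !is.na(is_call) && !is.na(pcr_call) && is_call != pcr_call
    call <- if (!is.na(pcr_call)) pcr_call else is_call
    evidence <- if (!is.na(is_call) && !is.na(pcr_call)) "both"
                else if (!is.na(pcr_call)) "pcr" else "in_silico"
    low_conf <- is.na(pcr_call) && identical(is_call, "absent")
    rows[[length(rows) + 1L]] <- data.frame(
      taxon = tx, gene = g, call = call, evidence = evidence,
      conflict = conflict, low_confidence = low_conf,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  structure(out, class = c("presence_matrix", "data.frame"))
}

#' Write a presence/absence matrix as TSV
#'
#' Taxa as rows, genes as columns, cells `+`/`-`/`NA` with an evidence
#' suffix (`:is`, `:pcr`, `:both`).
#'
#' @param pm `presence_matrix`.
#' @param path Output file.
#' @export
write_presence_tsv <- function(pm, path) {
  sym <- c(present = "+", absent = "-", not_analysed = "NA")
  suf <- c(in_silico = ":is", pcr = ":pcr", both = ":both")
  cell <- ifelse(pm$call == "not_analysed", "NA",
                 paste0(sym[pm$call], suf[pm$evidence]))
  wide <- tapply(cell, list(pm$taxon, pm$gene), identity)
  df <- data.frame(taxon = rownames(wide), wide, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Infer the time window of a single gene-gain event
#'
#' Under the Dollo single-gain model, the gain branch is the branch above
#' the MRCA of all taxa calling the gene present (`not_analysed` cells are
#' ignored).  The window lower bound is the MRCA's age and the upper bound
#' the age of its parent node — the split from the nearest absent lineage.
#' A donor-side constraint, when given, caps the upper bound.  Under the
#' default strict no-loss policy an absent taxon inside the presence clade
#' is an error.  The `dollo_losses` policy instead reports the implied
#' losses and widens the window: since any absence above the MRCA may
#' itself be a loss, the host-side upper bound relaxes to the root age and
#' only the donor constraint (when given) caps it.
#'
#' @param pm `presence_matrix` (or data.frame with `taxon`, `gene`, `call`).
#' @param host_tree `calibrated_tree`.
#' @param gene Gene to date.
#' @param donor_constraint_mya Optional donor-side upper bound in MYA.
#' @param loss_policy `"strict"` (default) or `"dollo_losses"`.
#' @return Object of class `transfer_window`: list with `gene`,
#'   `lower_mya`, `upper_mya`, `gain_branch` (child-node label),
#'   `host_constraint` (MRCA and parent labels), `donor_constraint_mya`,
#'   `implied_losses`.
#' @export
infer_transfer_window <- function(pm, host_tree, gene,
                                  donor_constraint_mya = NULL,
                                  loss_policy = c("strict", "dollo_losses")) {
  loss_policy <- match.arg(loss_policy)
  cells <- pm[pm$gene == gene, , drop = FALSE]
  tips <- tree_tips(host_tree)
  cells <- cells[cells$taxon %in% tips, , drop = FALSE]
  present <- cells$taxon[cells$call == "present"]
  absent <- cells$taxon[cells$call == "absent"]
  if (length(present) == 0L) {
    stop("no taxa call gene '", gene, "' present", call. = FALSE)
  }
  phy <- host_tree$phylo
  m <- if (length(present) == 1L) {
    match(present, phy$tip.label)
  } else {
    ape::getMRCA(phy, present)
  }
  clade_tips <- .tips_below(host_tree, m)
  losses <- intersect(absent, clade_tips)
  if (length(losses) > 0L && loss_policy == "strict") {
    stop("absent taxa inside the presence clade under the strict ",
         "single-gain model: ", paste(losses, collapse = ", "),
         call. = FALSE)
  }
  lower <- host_tree$ages[m]
  par <- .parent_of(host_tree, m)
  upper <- if (loss_policy == "dollo_losses") {
    # with losses allowed, any absence above the MRCA may be a loss, so the
    # presence pattern no longer bounds the gain below the root
    max(host_tree$ages)
  } else if (is.na(par)) {
    Inf
  } else {
    host_tree$ages[par]
  }
  if (!is.null(donor_constraint_mya)) upper <- min(upper, donor_constraint_mya)
  if (lower > upper) {
    stop("inconsistent constraints: lower bound ", lower,
         " exceeds upper bound ", upper, call. = FALSE)
  }
  structure(
    list(gene = gene, lower_mya = lower, upper_mya = upper,
         gain_branch = .node_label(host_tree, m),
         host_constraint = c(mrca = .node_label(host_tree, m),
                             parent = if (is.na(par)) NA_character_
                                      else .node_label(host_tree, par)),
         donor_constraint_mya = donor_constraint_mya %||% NA_real_,
         implied_losses = losses),
    class = "transfer_window")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.transfer_window <- function(x, ...) {
  cat(sprintf("transfer window for %s: %.4g - %.4g MYA (gain above %s)\n",
              x$gene, x$lower_mya, x$upper_mya, x$gain_branch))
  if (length(x$implied_losses) > 0L) {
    cat("  implied losses:", paste(x$implied_losses, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Donor-side divergence constraint for a transfer window
#'
#' The upper bound contributed by the donor phylogeny: a transferred gene
#' nesting inside the donor crown group must have left after the crown
#' radiation (crown age); one attaching to the stem may be as old as the
#' stem divergence (stem age).
#'
#' @param donor_tree `calibrated_tree`.
#' @param placement `"nested_in_crown"` or `"sister_to_crown"` (typically
#'   from [clade_nesting_check()]).
#' @param crown_node Label of the donor crown node (default `"Epichloe"`).
#' @return Age in MYA.
#' @export
donor_divergence_constraint <- function(donor_tree,
                                        placement = c("nested_in_crown",
                                                      "sister_to_crown"),
                                        crown_node = "Epichloe") {
  placement <- match.arg(placement)
  crown <- .node_number(donor_tree, crown_node)
  if (placement == "nested_in_crown") {
    donor_tree$ages[crown]
  } else {
    par <- .parent_of(donor_tree, crown)
    if (is.na(par)) stop("crown node has no parent in donor tree",
                         call. = FALSE)
    donor_tree$ages[par]
  }
}

#' In-silico PCR
#'
#' The forward primer is matched exactly on either strand; the reverse
#' primer's reverse complement is matched downstream on the same strand.
#' The product is the inclusive span from the 5' end of the forward site to
#' the 3' end of the reverse site; products longer than `max_product_len`
#' are suppressed.  Zero products on a template is an absence call.
#'
#' @param forward,reverse Primer sequences (15-35 nt DNA).
#' @param templates Named character vector of template sequences.
#' @param max_product_len Maximum reported product length in bp
#'   (default 250).
#' @return `data.frame` with `template`, `strand`, `start`, `end` (0-based
#'   half-open on the plus strand of the template), `product_len`.
#' @export
insilico_pcr <- function(forward, reverse, templates, max_product_len = 250) {
  forward <- toupper(forward)
  reverse <- toupper(reverse)
  for (p in c(forward, reverse)) {
    if (nchar(p) < 15 || nchar(p) > 35 || grepl("[^ACGT]", p)) {
      stop("primers must be 15-35 nt over {A,C,G,T}", call. = FALSE)
    }
  }
  templates <- .as_named_seqs(templates)
  find_all <- function(pat, s) {
    out <- integer(0)
    from <- 1L
    repeat {
      i <- regexpr(pat, substr(s, from, nchar(s)), fixed = TRUE)
      if (i < 0) break
      out <- c(out, from + i - 1L)
      from <- from + i
    }
    out
  }
  rows <- list()
  for (tx in names(templates)) {
    tpl <- templates[[tx]]
    for (strand in c("+", "-")) {
      s <- if (strand == "+") tpl else revcomp(tpl)
      f_pos <- find_all(forward, s)
      r_pos <- find_all(revcomp(reverse), s)
      for (f in f_pos) for (r in r_pos) {
        end <- r + nchar(reverse) - 1L
        if (end <= f) next
        len <- end - f + 1L
        if (len <= nchar(forward) + nchar(reverse)) next
        if (len > max_product_len) next
        if (strand == "+") {
          start0 <- f - 1L; end0 <- end
        } else {
          start0 <- nchar(tpl) - end; end0 <- nchar(tpl) - f + 1L
        }
        rows[[length(rows) + 1L]] <- data.frame(
          template = tx, strand = strand, start = start0, end = end0,
          product_len = len, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(template = character(), strand = character(),
                      start = integer(), end = integer(),
                      product_len = integer(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Presence calls from in-silico PCR over a set of taxa
#'
#' @param forward,reverse Primer sequences.
#' @param taxa_seqs Named list: taxon -> named character vector of that
#'   taxon's sequences.
#' @param gene Gene name for the resulting calls.
#' @param max_product_len Passed to [insilico_pcr()].
#' @return `data.frame` with `taxon`, `gene`, `call` suitable for
#'   [build_presence_matrix()].
#' @export
pcr_presence_calls <- function(forward, reverse, taxa_seqs, gene,
                               max_product_len = 250) {
  do.call(rbind, lapply(names(taxa_seqs), function(tx) {
    seqs <- taxa_seqs[[tx]]
    amp <- if (length(seqs) > 0L) {
      insilico_pcr(forward, reverse, seqs, max_product_len)
    } else NULL
    data.frame(taxon = tx, gene = gene,
               call = if (!is.null(amp) && nrow(amp) > 0L) "present"
                      else "absent",
               stringsAsFactors = FALSE)
  }))
}
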