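# Codon-level sequence-evolution simulator.  Sequences evolve along dated
# trees under a Nei-Gojobori-style process: every admissible single-
# nucleotide codon change is classified synonymous or nonsynonymous under
# the standard code; synonymous changes occur at a per-change rate mu_s and
# nonsynonymous at omega * mu_s.  With mu_s = syn_rate_per_my / 3 the
# expected number of synonymous substitutions per synonymous site per
# million years equals syn_rate_per_my.  Changes creating stop codons are
# rejected; a terminal stop codon wanders only among {TAA, TAG, TGA}.

.chg_syn_n <- vapply(.codon_tables$changes, function(d) sum(d$syn), numeric(1))
.chg_non_n <- vapply(.codon_tables$changes, function(d) sum(!d$syn), numeric(1))

# Gillespie per codon along one branch of duration t (million years)
.evolve_branch <- function(cods, t, mu_s, omega) {
  if (t < 0) stop("negative branch duration", call. = FALSE)
  if (t == 0 || length(cods) == 0L) return(cods)
  tot <- mu_s * (.chg_syn_n[cods] + omega * .chg_non_n[cods])
  first <- rep(Inf, length(cods))
  pos <- tot > 0
  first[pos] <- rexp(sum(pos), rate = tot[pos])
  for (i in which(first < t)) {
    elapsed <- first[i]
    cod <- cods[i]
    repeat {
      ch <- .codon_tables$changes[[cod]]
      r <- ifelse(ch$syn, mu_s, mu_s * omega)
      cod <- if (nrow(ch) == 1L) ch$to else sample(ch$to, 1L, prob = r)
      tot_i <- mu_s * (.chg_syn_n[cod] + omega * .chg_non_n[cod])
      if (tot_i <= 0) break
      elapsed <- elapsed + rexp(1L, rate = tot_i)
      if (elapsed >= t) break
    }
    cods[i] <- cod
  }
  cods
}

.as_codons <- function(seq) {
  cods <- .split_codons(seq)
  internal <- head(cods, -1L)
  if (any(.is_stop(internal))) {
    stop("CDS contains an internal in-frame stop codon", call. = FALSE)
  }
  cods
}

# preorder traversal evolving codon states down a calibrated tree, with
# optional state captures at (branch, time) points
.evolve_tree <- function(ct, root_codons, mu_s, omega, captures = list()) {
  phy <- ct$phylo
  ntip <- ape::Ntip(phy)
  states <- vector("list", ntip + phy$Nnode)
  states[[ntip + 1L]] <- root_codons
  edge <- stats::reorder(phy, "cladewise")$edge
  cap_out <- list()
  for (k in seq_len(nrow(edge))) {
    par <- edge[k, 1]
    chi <- edge[k, 2]
    t_par <- ct$ages[par]
    t_chi <- ct$ages[chi]
    lab <- .node_label(ct, chi)
    s <- states[[par]]
    br_caps <- Filter(function(cp) identical(cp$branch, lab), captures)
    if (length(br_caps) > 0L) {
      ts <- vapply(br_caps, `[[`, numeric(1), "t")
      if (any(ts > t_par | ts < t_chi)) {
        stop("capture/event time outside branch interval above '", lab,
             "' (", t_chi, ", ", t_par, "]", call. = FALSE)
      }
      cur <- t_par
      for (tv in sort(ts, decreasing = TRUE)) {
        s <- .evolve_branch(s, cur - tv, mu_s, omega)
        cap_out[[paste0(lab, "@", format(tv))]] <- s
        cur <- tv
      }
      s <- .evolve_branch(s, cur - t_chi, mu_s, omega)
    } else {
      s <- .evolve_branch(s, t_par - t_chi, mu_s, omega)
    }
    states[[chi]] <- s
  }
  tips <- setNames(
    vapply(seq_len(ntip), function(i) paste0(states[[i]], collapse = ""),
           character(1)),
    phy$tip.label)
  list(tips = tips, captures = cap_out)
}

#' Evolve a coding sequence along a calibrated tree
#'
#' Runs the continuous-time per-codon substitution process from a root CDS
#' down every branch of a dated tree, for the branch's duration in million
#' years, and returns the sequences at the tips.
#'
#' @param tree `calibrated_tree`.
#' @param root_cds Root coding sequence (string; length divisible by 3, no
#'   internal stop codon; terminal stop allowed).
#' @param syn_rate_per_my Expected synonymous substitutions per synonymous
#'   site per million years (default 0.015).
#' @param omega Target Ka/Ks: nonsynonymous changes occur at `omega` times
#'   the synonymous per-change rate.
#' @param seed Optional integer seed.
#' @return Named character vector of tip sequences (taxon -> CDS).
#' @export
evolve_codon_sequences <- function(tree, root_cds, syn_rate_per_my = 0.015,
                                   omega = 0.2, seed = NULL) {
  if (syn_rate_per_my <= 0) stop("syn_rate_per_my must be > 0", call. = FALSE)
  if (omega < 0) stop("omega must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  cods <- .as_codons(root_cds)
  .evolve_tree(tree, cods, syn_rate_per_my / 3, omega)$tips
}

#' Random coding sequence
#'
#' Uniform sense codons (no internal stops) with an optional terminal stop
#' codon drawn from the supplied stop-codon weights.
#'
#' @param n_codons Number of sense codons.
#' @param terminal_stop Append a terminal stop codon (default `TRUE`).
#' @param stop_weights Sampling weights for `TAA`, `TAG`, `TGA`.
#' @return A CDS string.
#' @export
random_cds <- function(n_codons, terminal_stop = TRUE,
                       stop_weights = c(TAA = 1, TAG = 1, TGA = 1)) {
  body <- sample(.codon_tables$sense, n_codons, replace = TRUE)
  if (terminal_stop) {
    stp <- sample(.stop_codons, 1L, prob = stop_weights[.stop_codons])
    body <- c(body, stp)
  }
  paste0(body, collapse = "")
}

#' Plant a horizontal gene transfer event
#'
#' Simulates one gene's full history: the gene evolves down the donor tree;
#' at time `t_mya` on the named donor branch its state is copied onto the
#' named host branch, after which the copy evolves under the host
#' substitution regime; every host tip descending from that branch carries
#' the transferred gene, every other host tip lacks it.
#'
#' @param host_tree,donor_tree `calibrated_tree`s.
#' @param root_cds Root CDS at the donor root.
#' @param event List with `gene_id`, `donor_branch` (child-node label of the
#'   donor branch), `host_branch` (child-node label of the host branch), and
#'   `t_mya` (transfer time, inside both branch intervals).
#' @param syn_rate_per_my Synonymous rate per site per MY.
#' @param omega_donor,omega_host Ka/Ks targets on the donor and host side.
#' @param seed Optional integer seed.
#' @return List: `host_tips` (named sequences, carrier tips only),
#'   `donor_tips` (all donor tips), `carriers` (host taxa carrying the
#'   gene), `truth` (data.frame of taxon, gene, origin, t_mya).
#' @export
insert_hgt_event <- function(host_tree, donor_tree, root_cds, event,
                             syn_rate_per_my = 0.015,
                             omega_donor = 0.35, omega_host = 0.3,
                             seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  t <- event$t_mya
  # validate host branch interval
  chi <- .node_number(host_tree, event$host_branch)
  par <- .parent_of(host_tree, chi)
  if (is.na(par)) stop("host branch must not be the root", call. = FALSE)
  if (t > host_tree$ages[par] || t < host_tree$ages[chi]) {
    stop("event time ", t, " outside host branch interval (",
         host_tree$ages[chi], ", ", host_tree$ages[par], "]", call. = FALSE)
  }
  mu <- syn_rate_per_my / 3
  donor <- .evolve_tree(donor_tree, .as_codons(root_cds), mu, omega_donor,
                        captures = list(list(branch = event$donor_branch,
                                             t = t)))
  transferred <- donor$captures[[1]]
  host_env <- new.env()
  .evolve_down(host_tree, chi, transferred, t, mu, omega_host, host_env)
  host_tips <- unlist(as.list(host_env))
  carriers <- names(host_tips)
  truth <- rbind(
    data.frame(taxon = carriers, gene = event$gene_id, origin = "hgt",
               t_mya = t, stringsAsFactors = FALSE),
    data.frame(taxon = tree_tips(donor_tree), gene = event$gene_id,
               origin = "vertical", t_mya = NA_real_,
               stringsAsFactors = FALSE)
  )
  list(host_tips = host_tips, donor_tips = donor$tips,
       carriers = carriers, truth = truth)
}

.evolve_down <- function(ct, node, state, from_time, mu_s, omega, out) {
  s <- .evolve_branch(state, from_time - ct$ages[node], mu_s, omega)
  if (node <= ape::Ntip(ct$phylo)) {
    assign(.node_label(ct, node), paste0(s, collapse = ""), envir = out)
  } else {
    for (k in .children_of(ct, node)) {
      .evolve_down(ct, k, s, ct$ages[node], mu_s, omega, out)
    }
  }
  invisible(out)
}
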