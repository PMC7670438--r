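# End-to-end synthetic study bundle: dated host and donor clades, genes of
# every truth class (vertical, horizontally transferred, conserved,
# donor-specific), and a contaminated short-read library, so the whole
# screening/dating/characterisation pipeline can run against known truth.

#' Simulation configuration
#'
#' Defaults define the study conditions the package emulates: a dated grass
#' tree (Brachypodieae split at 39 MYA, Triticeae-Poeae at 21 MYA) and a
#' dated fungal tree (Claviceps-Epichloe 58.8 MYA, Epichloe crown 7.2 MYA);
#' codon sequences under purifying selection (host Ka/Ks 0.3, donor 0.35);
#' two planted transfer events (an old one into the Triticeae+Poeae ancestor
#' at 30 MYA, a recent one into the Loliinae ancestor at 6 MYA); and a read
#' library of 140-150 nt reads with 30% duplication and 5% + 5%
#' microbiome/conserved contamination.
#'
#' @param host_tree,donor_tree Optional `calibrated_tree`s (defaults:
#'   [build_template_trees()]).
#' @param n_genes Host vertical (plant-specific) genes.
#' @param gene_len_codons Gene length in codons (default 300).
#' @param syn_rate_per_my Synonymous rate per synonymous site per MY.
#' @param omega_host,omega_donor Ka/Ks targets for host and donor lineages.
#' @param hgt_events List of events (`gene_id`, `donor_branch`,
#'   `host_branch`, `t_mya`).
#' @param n_conserved Conserved-gene confounders shared by all taxa.
#' @param conserved_syn_rate,conserved_omega Slow rates for conserved genes.
#' @param n_donor_specific Donor-only genes (microbiome read source).
#' @param contamination Named fractions `microbiome` and `conserved`.
#' @param dup_fraction Duplicate-read fraction of the library.
#' @param read_len_range,n_reads Read length range (nt) and library size.
#' @param focal_taxon Host taxon whose transcriptome is screened.
#' @param seed Integer master seed.
#' @return Object of class `simulation_config` (a list).
#' @export
simulation_config <- function(host_tree = NULL, donor_tree = NULL,
                              n_genes = 6, gene_len_codons = 300,
                              syn_rate_per_my = 0.015,
                              omega_host = 0.3, omega_donor = 0.35,
                              hgt_events = list(
                                list(gene_id = "FTRL_like",
                                     donor_branch = "Epichloe",
                                     host_branch = "TriticeaePoeae",
                                     t_mya = 30),
                                list(gene_id = "DUF3632_like",
                                     donor_branch = "EpichloeCore",
                                     host_branch = "Loliinae",
                                     t_mya = 6)),
                              n_conserved = 2,
                              conserved_syn_rate = 3e-4,
                              conserved_omega = 0.05,
                              n_donor_specific = 2,
                              contamination = c(microbiome = 0.05,
                                                conserved = 0.05),
                              dup_fraction = 0.3,
                              read_len_range = c(140, 150),
                              n_reads = 2000,
                              focal_taxon = "Lolium",
                              seed = 1L) {
  if (omega_host <= 0 || omega_donor <= 0) {
    stop("omega targets must be > 0", call. = FALSE)
  }
  if (any(contamination < 0) || sum(contamination) > 1) {
    stop("contamination fractions must lie in [0,1] and sum to <= 1",
         call. = FALSE)
  }
  structure(as.list(environment()), class = "simulation_config")
}

# stable per-gene child seed below 2^31, derived from the master seed
.gene_seed <- function(seed, gene_id) {
  h <- sum(utf8ToInt(gene_id) * seq_len(nchar(gene_id)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483647)
}

#' Simulate a full synthetic study bundle
#'
#' Builds the host/donor trees, evolves every gene class, plants the
#' configured transfer events, assembles per-taxon sequence sets, and emits
#' the screening read library with truth labels.
#'
#' @param config `simulation_config`.
#' @return List of class `hgt_bundle` with elements `host_tree`,
#'   `donor_tree`, `taxa_seqs` (taxon -> named vector of gene sequences),
#'   `truth_genes`, `reads` (list: `reads`, `library_size`, `truth`),
#'   `focal_taxon`, `carriers` (gene -> host carrier taxa), and `config`.
#' @export
simulate_hgt_bundle <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.null(config$host_tree) || is.null(config$donor_tree)) {
    tt <- build_template_trees()
    if (is.null(config$host_tree)) config$host_tree <- tt$host
    if (is.null(config$donor_tree)) config$donor_tree <- tt$donor
  }
  host <- config$host_tree
  donor <- config$donor_tree
  host_taxa <- tree_tips(host)
  donor_taxa <- tree_tips(donor)
  taxa_seqs <- setNames(
    lapply(c(host_taxa, donor_taxa), function(x) character()),
    c(host_taxa, donor_taxa))
  add_seq <- function(taxon, gene, seq) {
    taxa_seqs[[taxon]][[gene]] <<- seq
  }
  truth <- list()
  carriers <- list()

  # host vertical genes, present across the whole plant tree
  for (i in seq_len(config$n_genes)) {
    g <- sprintf("plant_gene_%02d", i)
    set.seed(.gene_seed(config$seed, g))
    tips <- evolve_codon_sequences(host, random_cds(config$gene_len_codons),
                                   config$syn_rate_per_my, config$omega_host)
    for (tx in names(tips)) add_seq(tx, g, tips[[tx]])
    truth[[g]] <- data.frame(gene = g, origin = "vertical",
                             t_mya = NA_real_, stringsAsFactors = FALSE)
  }

  # horizontally transferred genes
  for (ev in config$hgt_events) {
    set.seed(.gene_seed(config$seed, ev$gene_id))
    res <- insert_hgt_event(host, donor, random_cds(config$gene_len_codons),
                            ev, config$syn_rate_per_my,
                            config$omega_donor, config$omega_host)
    for (tx in names(res$host_tips)) add_seq(tx, ev$gene_id, res$host_tips[[tx]])
    for (tx in names(res$donor_tips)) add_seq(tx, ev$gene_id, res$donor_tips[[tx]])
    carriers[[ev$gene_id]] <- res$carriers
    truth[[ev$gene_id]] <- data.frame(gene = ev$gene_id, origin = "hgt",
                                      t_mya = ev$t_mya,
                                      stringsAsFactors = FALSE)
  }

  # conserved-gene confounders: one ancestral CDS, slow evolution on both
  # trees, so host copies cross-hit the donor panel and outgroup plants
  for (i in seq_len(config$n_conserved)) {
    g <- sprintf("conserved_gene_%02d", i)
    set.seed(.gene_seed(config$seed, g))
    root <- random_cds(config$gene_len_codons)
    tips_h <- evolve_codon_sequences(host, root, config$conserved_syn_rate,
                                     config$conserved_omega)
    tips_d <- evolve_codon_sequences(donor, root, config$conserved_syn_rate,
                                     config$conserved_omega)
    for (tx in names(tips_h)) add_seq(tx, g, tips_h[[tx]])
    for (tx in names(tips_d)) add_seq(tx, g, tips_d[[tx]])
    truth[[g]] <- data.frame(gene = g, origin = "conserved",
                             t_mya = NA_real_, stringsAsFactors = FALSE)
  }

  # donor-specific genes: the microbiome read source
  for (i in seq_len(config$n_donor_specific)) {
    g <- sprintf("fungal_gene_%02d", i)
    set.seed(.gene_seed(config$seed, g))
    tips <- evolve_codon_sequences(donor, random_cds(config$gene_len_codons),
                                   config$syn_rate_per_my, config$omega_donor)
    for (tx in names(tips)) add_seq(tx, g, tips[[tx]])
    truth[[g]] <- data.frame(gene = g, origin = "microbiome",
                             t_mya = NA_real_, stringsAsFactors = FALSE)
  }

  truth_genes <- do.call(rbind, truth)
  rownames(truth_genes) <- NULL

  focal <- config$focal_taxon
  focal_seqs <- unlist(taxa_seqs[[focal]])
  genes_focal <- names(focal_seqs)
  origin_of <- setNames(truth_genes$origin, truth_genes$gene)
  host_pool <- focal_seqs[origin_of[genes_focal] %in% c("vertical", "hgt")]
  conserved_pool <- focal_seqs[origin_of[genes_focal] == "conserved"]
  donor_rep <- "Epichloe_festucae"
  donor_seqs <- unlist(taxa_seqs[[donor_rep]])
  microbiome_pool <- donor_seqs[origin_of[names(donor_seqs)] == "microbiome"]
  host_origins <- setNames(origin_of[names(host_pool)], names(host_pool))

  set.seed(.gene_seed(config$seed, "read_library"))
  reads <- generate_read_library(
    host_pool, microbiome_pool, conserved_pool,
    n_reads = config$n_reads, read_len_range = config$read_len_range,
    dup_fraction = config$dup_fraction,
    microbiome_frac = config$contamination[["microbiome"]],
    conserved_frac = config$contamination[["conserved"]],
    host_origins = host_origins,
    library_id = paste0(focal, "_nonpolyA"))

  structure(
    list(host_tree = host, donor_tree = donor, taxa_seqs = taxa_seqs,
         truth_genes = truth_genes, reads = reads, focal_taxon = focal,
         donor_reference = donor_rep, carriers = carriers, config = config),
    class = "hgt_bundle")
}

#' @export
print.hgt_bundle <- function(x, ...) {
  cat(sprintf(
    "synthetic HGT bundle: %d host taxa, %d donor taxa, %d genes, %d reads\n",
    ape::Ntip(x$host_tree$phylo), ape::Ntip(x$donor_tree$phylo),
    nrow(x$truth_genes), x$reads$library_size))
  invisible(x)
}
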