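# End-to-end orchestration: simulate (or load) the inputs, collapse reads,
# screen against the donor transcriptome, triage hits, build
# presence/absence evidence, date the gain events, and characterise the
# candidates (Ka/Ks, codon usage, expression).  Every stage logs its counts
# and the whole run is deterministic given the seed.

#' Load a run configuration
#'
#' YAML with the analysis defaults pre-filled so the packaged demo runs
#' with zero edits.  Recognised blocks: `seed`, `simulate` (passed to
#' [simulation_config()]), `screen` (thresholds), `dating`, `expression`,
#' `output`.
#'
#' @param path YAML file; `NULL` loads the packaged demo configuration.
#' @return List of class `run_config`.
#' @export
load_run_config <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "demo_config.yaml", package = "xenolog")
  }
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_run_config(), user)
  if (cfg$screen$e_value_threshold <= 0) {
    stop("e_value_threshold must be > 0", call. = FALSE)
  }
  if (cfg$expression$min_perfect < 1) {
    stop("min_perfect must be >= 1", call. = FALSE)
  }
  structure(cfg, class = "run_config")
}

#' Default run configuration
#' @return List with all pipeline defaults.
#' @export
default_run_config <- function() {
  list(
    seed = 1L,
    simulate = list(),
    screen = list(e_value_threshold = 1e-10, word_size = 28,
                  min_identity = 60, min_len = 50,
                  microbiome_identity = 98),
    dating = list(loss_policy = "strict"),
    expression = list(
      min_perfect = 60,
      libraries = list(
        list(sample_id = "leaf_tip_Eminus", tissue = "leaf_tip",
             status = "E_minus", n_reads = 800),
        list(sample_id = "leaf_blade_Eminus", tissue = "leaf_blade",
             status = "E_minus", n_reads = 800),
        list(sample_id = "sheath_Eplus", tissue = "sheath",
             status = "E_plus", n_reads = 800))),
    max_amplicon_len = 250,
    output = NULL
  )
}

.log_stage <- function(log, stage, ...) {
  entry <- list(stage = stage, ...)
  message(sprintf("[%s] %s", stage,
                  paste(names(entry)[-1], unlist(entry[-1]),
                        sep = "=", collapse = " ")))
  c(log, list(entry))
}

#' Run the full discovery/dating/characterisation pipeline
#'
#' Orchestrates all stages on a synthetic study bundle: read collapsing,
#' similarity screening of the unique reads and the focal transcriptome
#' against the donor set, hit triage, per-candidate presence/absence and
#' Dollo dating with the donor-side constraint from the phylogram nesting
#' test, group Ka/Ks with age-normalised rates, codon usage, and read-count
#' expression.  Deterministic given `config$seed`.
#'
#' @param config A `run_config` (from [load_run_config()]), a path to a
#'   YAML configuration, or `NULL` for the packaged demo.
#' @return List of class `pipeline_report`.
#' @export
run_pipeline <- function(config = NULL) {
  if (is.null(config) || is.character(config)) {
    config <- load_run_config(config)
  }
  set.seed(config$seed)
  log <- list()

  sim_args <- config$simulate
  sim_args$seed <- config$seed
  bundle <- do.call(simulation_config, sim_args)
  bundle <- simulate_hgt_bundle(bundle)
  log <- .log_stage(log, "simulate",
                    genes = nrow(bundle$truth_genes),
                    reads = bundle$reads$library_size)

  uniq <- collapse_unique_reads(bundle$reads)
  log <- .log_stage(log, "collapse", input = attr(uniq, "n_input"),
                    unique = nrow(uniq))

  donor_panel <- unlist(bundle$taxa_seqs[[bundle$donor_reference]])
  focal_seqs <- unlist(bundle$taxa_seqs[[bundle$focal_taxon]])
  sp <- screen_params(word_size = config$screen$word_size,
                      e_value_threshold = config$screen$e_value_threshold)
  queries <- c(setNames(uniq$seq, uniq$id), focal_seqs)
  hits <- local_search(queries, donor_panel, sp)
  log <- .log_stage(log, "screen", queries = length(queries),
                    subjects = length(donor_panel), hits = nrow(hits))

  host_taxa <- tree_tips(bundle$host_tree)
  outgroups <- setdiff(host_taxa,
                       .tips_below(bundle$host_tree,
                                   .node_number(bundle$host_tree,
                                                "TriticeaePoeae")))
  outgroup_panel <- unlist(lapply(outgroups, function(tx) {
    s <- bundle$taxa_seqs[[tx]]
    setNames(s, paste0(tx, ".", names(s)))
  }))
  cp <- classify_params(min_identity = config$screen$min_identity,
                        min_len = config$screen$min_len,
                        microbiome_identity = config$screen$microbiome_identity,
                        e_value_threshold = config$screen$e_value_threshold,
                        search_params = sp)
  classified <- classify_hits(hits, queries,
                              panels = list(outgroup = outgroup_panel,
                                            host_assembly = focal_seqs),
                              params = cp)
  counts <- attr(classified, "counts")
  log <- .log_stage(log, "triage",
                    total = counts$total,
                    low_similarity = counts$low_similarity,
                    conserved = counts$conserved_eukaryote,
                    microbiome = counts$microbiome,
                    candidates = counts$hgt_candidate)

  cands <- candidate_summary(classified)
  donor_taxa <- tree_tips(bundle$donor_tree)
  epichloe <- grep("^Epichloe", donor_taxa, value = TRUE)
  claviceps <- setdiff(donor_taxa, epichloe)

  windows <- list()
  kaks_groups <- list()
  usage <- list()
  presence <- list()
  for (g in cands$subject_id) {
    taxon_has <- vapply(host_taxa, function(tx) {
      g %in% names(bundle$taxa_seqs[[tx]])
    }, logical(1))
    # in-silico presence: search the donor gene against each host taxon
    insilico <- do.call(rbind, lapply(host_taxa, function(tx) {
      seqs <- bundle$taxa_seqs[[tx]]
      hh <- if (length(seqs) > 0L) {
        local_search(donor_panel[g], seqs, sp)
      } else NULL
      data.frame(taxon = tx, gene = g,
                 call = if (!is.null(hh) && nrow(hh) > 0L) "present"
                        else "absent",
                 stringsAsFactors = FALSE)
    }))
    pm <- build_presence_matrix(insilico = insilico, taxa = host_taxa,
                                genes = g)
    presence[[g]] <- pm
    present_taxa <- pm$taxon[pm$call == "present"]
    if (length(present_taxa) == 0L) next

    # phylogram placement -> donor-side constraint
    copies <- c(
      setNames(vapply(present_taxa,
                      function(tx) bundle$taxa_seqs[[tx]][[g]], character(1)),
               present_taxa),
      setNames(vapply(donor_taxa,
                      function(tx) bundle$taxa_seqs[[tx]][[g]], character(1)),
               donor_taxa))
    prot <- translate_cds(copies)
    placement <- tryCatch(
      clade_nesting_check(nj_tree(p_distance_matrix(prot)),
                          focal_taxa = present_taxa,
                          reference_taxa = epichloe,
                          outgroup_taxa = claviceps),
      error = function(e) "other")
    donor_constraint <- if (placement %in% c("nested_in_crown",
                                             "sister_to_crown")) {
      donor_divergence_constraint(bundle$donor_tree, placement)
    } else NULL
    windows[[g]] <- tryCatch(
      infer_transfer_window(pm, bundle$host_tree, g, donor_constraint,
                            loss_policy = config$dating$loss_policy),
      error = function(e) list(gene = g, error = conditionMessage(e)))

    # group Ka/Ks with age-normalised rates
    kaks_groups[[g]] <- .candidate_kaks(bundle, g, present_taxa,
                                        epichloe, claviceps)
    # codon usage, host vs donor copies
    usage[[g]] <- list(
      host = codon_usage_profile(copies[present_taxa]),
      donor = codon_usage_profile(copies[intersect(donor_taxa,
                                                   names(copies))]))
  }
  log <- .log_stage(log, "dating", candidates = length(windows))

  expr <- .expression_stage(bundle, cands$subject_id, config)
  log <- .log_stage(log, "expression",
                    libraries = length(config$expression$libraries))

  report <- structure(
    list(config = unclass(config),
         stage_log = log,
         collapse = list(input_reads = attr(uniq, "n_input"),
                         unique_reads = nrow(uniq)),
         triage_counts = counts,
         candidates = cands,
         presence = lapply(presence, as.data.frame),
         transfer_windows = lapply(windows, unclass),
         kaks = lapply(kaks_groups, function(gl) kaks_table(gl)),
         codon_usage = usage,
         expression = expr,
         truth = list(genes = bundle$truth_genes,
                      carriers = bundle$carriers)),
    class = "pipeline_report")
  if (!is.null(config$output)) {
    dir.create(config$output, recursive = TRUE, showWarnings = FALSE)
    write_report_json(.report_for_json(report),
                      file.path(config$output, "report.json"))
    write_hits_tsv(hits, file.path(config$output, "hits.tsv"))
  }
  report
}

# group Ka/Ks combinations for one candidate gene: host-side pairs across
# the two basal carrier clades, donor crown pairs, and cross-taxon pairs
.candidate_kaks <- function(bundle, g, present_taxa, epichloe, claviceps) {
  seq_of <- function(tx) bundle$taxa_seqs[[tx]][[g]]
  pairs_between <- function(A, B) {
    out <- list()
    for (a in A) for (b in B) {
      out[[length(out) + 1L]] <- nei_gojobori(seq_of(a), seq_of(b), a, b)
    }
    out
  }
  groups <- list()
  if (length(present_taxa) >= 2L) {
    m <- ape::getMRCA(bundle$host_tree$phylo, present_taxa)
    kids <- .children_of(bundle$host_tree, m)
    A <- intersect(.tips_below(bundle$host_tree, kids[1]), present_taxa)
    B <- intersect(unlist(lapply(kids[-1], function(k) {
      .tips_below(bundle$host_tree, k)
    })), present_taxa)
    if (length(A) > 0L && length(B) > 0L) {
      groups$host_crown <- group_kaks(pairs_between(A, B),
                                      T = bundle$host_tree$ages[m],
                                      label = "host carrier crown")
    }
  }
  gans <- grep("gansuensis", epichloe, value = TRUE)
  others <- setdiff(epichloe, gans)
  if (length(gans) > 0L && length(others) > 0L) {
    groups$donor_crown <- group_kaks(
      pairs_between(gans, others),
      T = node_age(bundle$donor_tree, "Epichloe"),
      label = "E. gansuensis vs other Epichloe")
  }
  if (length(claviceps) > 0L) {
    stem_T <- node_age(bundle$donor_tree, "ClavicepsEpichloe")
    groups$claviceps_epichloe <- group_kaks(
      pairs_between(claviceps, epichloe), T = stem_T,
      label = "Claviceps vs Epichloe")
    groups$claviceps_plants <- group_kaks(
      pairs_between(claviceps, present_taxa), T = stem_T,
      label = "Claviceps vs plants")
  }
  groups
}

.expression_stage <- function(bundle, candidate_genes, config) {
  focal_seqs <- unlist(bundle$taxa_seqs[[bundle$focal_taxon]])
  donor_seqs <- unlist(bundle$taxa_seqs[[bundle$donor_reference]])
  genes <- focal_seqs[intersect(candidate_genes, names(focal_seqs))]
  if (length(genes) == 0L) return(NULL)
  donor_copies <- donor_seqs[intersect(candidate_genes, names(donor_seqs))]
  names(donor_copies) <- paste0("donor_", names(donor_copies))
  genes <- c(genes, donor_copies)
  libs <- lapply(config$expression$libraries, function(lc) {
    pool <- focal_seqs
    if (identical(lc$status, "E_plus")) {
      extra <- donor_seqs
      names(extra) <- paste0("donor_", names(extra))
      pool <- c(pool, extra)
    }
    weights <- setNames(rep(1, length(pool)), names(pool))
    if (!is.null(lc$gene_weights)) {
      for (nm in names(lc$gene_weights)) {
        weights[names(weights) == nm] <- lc$gene_weights[[nm]]
      }
    }
    rl <- generate_read_library(
      pool, n_reads = lc$n_reads %||% 800,
      read_len_range = bundle$config$read_len_range,
      dup_fraction = 0, weights = weights,
      library_id = lc$sample_id,
      seed = .gene_seed(config$seed, paste0("expr_", lc$sample_id)))
    list(reads = rl$reads, library_size = rl$library_size,
         sample_id = lc$sample_id, tissue = lc$tissue, status = lc$status)
  })
  expression_table(genes, libs, min_perfect = config$expression$min_perfect)
}

.report_for_json <- function(report) {
  r <- unclass(report)
  r$presence <- lapply(r$presence, function(df) as.list(as.data.frame(df)))
  r
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("pipeline report\n")
  cat(sprintf("  reads: %d input, %d unique\n",
              x$collapse$input_reads, x$collapse$unique_reads))
  tc <- x$triage_counts
  cat(sprintf("  hits: %d total = %d low-similarity + %d conserved + %d microbiome + %d candidates\n",
              tc$total, tc$low_similarity, tc$conserved_eukaryote,
              tc$microbiome, tc$hgt_candidate))
  if (nrow(x$candidates) > 0L) {
    cat("  candidate genes:", paste(x$candidates$subject_id, collapse = ", "),
        "\n")
  }
  for (w in x$transfer_windows) {
    if (!is.null(w$lower_mya)) {
      cat(sprintf("  %s transfer window: %.4g - %.4g MYA\n",
                  w$gene, w$lower_mya, w$upper_mya))
    }
  }
  invisible(x)
}
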