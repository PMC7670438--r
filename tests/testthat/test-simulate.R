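# Template trees, the codon-evolution process, planted transfers and the
# read-library generator.

test_that("template trees carry the published calibrations", {
  tt <- build_template_trees()
  expect_gt(max(tt$host$ages), 39)
  expect_equal(node_age(tt$host, "TriticeaePoeae"), 21)
  expect_equal(node_age(tt$host, "Pooideae"), 39)     # Brachypodieae split
  expect_equal(node_age(tt$donor, "Epichloe"), 7.2)   # crown radiation
  expect_equal(node_age(tt$donor, "ClavicepsEpichloe"), 58.8)
})

test_that("age overrides move nodes and invalid orderings are rejected", {
  tt <- build_template_trees(host_overrides = list(Pooideae = 35))
  expect_equal(node_age(tt$host, "Pooideae"), 35)
  expect_equal(node_age(tt$host, "TriticeaePoeae"), 21)
  expect_error(build_template_trees(host_overrides = list(Pooideae = 10)),
               "ordering")
  expect_error(build_template_trees(host_overrides = list(NoSuchNode = 5)),
               "unknown")
})

test_that("trees are ultrametric: tips at zero, every parent older than its child", {
  tt <- build_template_trees()
  for (ct in tt) {
    expect_true(all(ct$ages[seq_len(ape::Ntip(ct$phylo))] == 0))
    e <- ct$phylo$edge
    expect_true(all(ct$ages[e[, 1]] > ct$ages[e[, 2]]))
  }
})

test_that("omega = 0 keeps all tip proteins identical to the root protein", {
  tt <- build_template_trees()
  set.seed(5)
  root <- random_cds(60)
  tips <- evolve_codon_sequences(tt$host, root, syn_rate_per_my = 0.02,
                                 omega = 0, seed = 5)
  root_prot <- translate_cds(root)
  for (s in tips) expect_equal(unname(translate_cds(s)), unname(root_prot))
})

test_that("vanishing substitution opportunity returns the ancestor unchanged", {
  set.seed(2)
  root <- random_cds(100)
  # rate * duration ~ 0 must leave the sequence untouched at every tip
  tips <- evolve_codon_sequences(read_newick(text = "(A:10,B:10);"),
                                 root, 1e-12, 0.3, seed = 2)
  expect_equal(unname(tips[["A"]]), root)
  expect_equal(unname(tips[["B"]]), root)
})

test_that("pairwise Ks over T = 21 MY recovers 2 x T x rate within simulation error", {
  tr <- read_newick(text = "(A:21,B:21);")
  ks <- vapply(1:6, function(s) {
    set.seed(s)
    tips <- evolve_codon_sequences(tr, random_cds(1000), 0.015, 0.35)
    nei_gojobori(tips[["A"]], tips[["B"]])$Ks
  }, numeric(1))
  # expectation 2 * 21 * 0.015 = 0.63; allow 3 simulation SDs (~0.03/rep)
  expect_lt(abs(mean(ks) - 0.63), 3 * 0.03 / sqrt(length(ks)) + 0.02)
})

test_that("internal-stop root CDS is rejected", {
  tr <- read_newick(text = "(A:10,B:10);")
  expect_error(evolve_codon_sequences(tr, "ATGTAAAAATTT", 0.01, 0.3),
               "stop codon")
})

test_that("a transfer into the Triticeae+Poeae ancestor reaches exactly those tips", {
  tt <- build_template_trees()
  res <- insert_hgt_event(tt$host, tt$donor, random_cds(100),
                          list(gene_id = "g", donor_branch = "Epichloe",
                               host_branch = "TriticeaePoeae", t_mya = 30),
                          seed = 4)
  expect_setequal(res$carriers, c("Triticum", "Hordeum", "Lolium",
                                  "Festuca", "Dactylis", "Phalaris"))
  expect_false("Brachypodium" %in% res$carriers)
  expect_setequal(names(res$donor_tips), tree_tips(tt$donor))
})

test_that("a transfer into the Loliinae ancestor reaches only Loliinae tips", {
  tt <- build_template_trees()
  res <- insert_hgt_event(tt$host, tt$donor, random_cds(100),
                          list(gene_id = "g", donor_branch = "EpichloeCore",
                               host_branch = "Loliinae", t_mya = 6),
                          seed = 4)
  expect_setequal(res$carriers, c("Lolium", "Festuca"))
})

test_that("transfer at the branch start equals a gain at the parent node; bad times error", {
  tt <- build_template_trees()
  ok <- insert_hgt_event(tt$host, tt$donor, random_cds(50),
                         list(gene_id = "g", donor_branch = "Epichloe",
                              host_branch = "TriticeaePoeae", t_mya = 39),
                         seed = 1)
  expect_setequal(ok$carriers, c("Triticum", "Hordeum", "Lolium",
                                 "Festuca", "Dactylis", "Phalaris"))
  expect_error(
    insert_hgt_event(tt$host, tt$donor, random_cds(50),
                     list(gene_id = "g", donor_branch = "Epichloe",
                          host_branch = "TriticeaePoeae", t_mya = 45),
                     seed = 1),
    "outside")
})

test_that("read library honours duplication, contamination and determinism", {
  set.seed(1)
  pool <- setNames(vapply(1:4, function(i) random_cds(300), character(1)),
                   paste0("g", 1:4))
  mic <- setNames(vapply(1:2, function(i) random_cds(300), character(1)),
                  paste0("m", 1:2))
  lib <- generate_read_library(pool, microbiome_pool = mic,
                               n_reads = 1000, dup_fraction = 0.3,
                               microbiome_frac = 0.1, seed = 10)
  expect_equal(lib$library_size, 1000L)
  uniq <- collapse_unique_reads(lib)
  expect_gt(nrow(uniq), 600)
  expect_lt(nrow(uniq), 760)   # ~700 unique under 30% duplication
  expect_equal(sum(uniq$multiplicity), 1000L)
  expect_true(any(lib$truth$origin == "microbiome"))
  # no contamination requested -> no contaminant labels
  clean <- generate_read_library(pool, n_reads = 200, microbiome_frac = 0,
                                 conserved_frac = 0, seed = 11)
  expect_false(any(clean$truth$origin %in% c("microbiome", "conserved")))
  # same seed twice -> identical reads
  again <- generate_read_library(pool, microbiome_pool = mic,
                                 n_reads = 1000, dup_fraction = 0.3,
                                 microbiome_frac = 0.1, seed = 10)
  expect_identical(lib$reads, again$reads)
})

test_that("every emitted read carries exactly one truth label", {
  b <- demo_bundle()
  tr <- b$reads$truth
  expect_equal(nrow(tr), b$reads$library_size)
  expect_equal(anyDuplicated(tr$id), 0L)
  expect_true(all(tr$origin %in% c("vertical", "hgt", "microbiome",
                                   "conserved")))
})
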