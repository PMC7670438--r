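# Presence/absence evidence combination, Dollo single-gain dating, the
# donor-side constraint, and in-silico PCR.

make_pm <- function(present, absent, gene = "g") {
  build_presence_matrix(
    insilico = data.frame(taxon = c(present, absent), gene = gene,
                          call = rep(c("present", "absent"),
                                     c(length(present), length(absent))),
                          stringsAsFactors = FALSE))
}

test_that("PCR evidence overrides conflicting in-silico evidence", {
  insilico <- data.frame(taxon = c("Phalaris", "Lolium"), gene = "FTRL",
                         call = c("absent", "present"),
                         stringsAsFactors = FALSE)
  pcr <- data.frame(taxon = c("Phalaris", "Lolium"), gene = "FTRL",
                    call = c("present", "present"), stringsAsFactors = FALSE)
  pm <- build_presence_matrix(insilico, pcr, taxa = c("Phalaris", "Lolium",
                                                      "Dactylis"))
  harding <- pm[pm$taxon == "Phalaris", ]
  expect_equal(harding$call, "present")     # the harding-grass case
  expect_equal(harding$evidence, "both")
  expect_true(harding$conflict)
  concordant <- pm[pm$taxon == "Lolium", ]
  expect_equal(concordant$call, "present")
  expect_equal(concordant$evidence, "both")
  expect_false(concordant$conflict)
  expect_equal(pm$call[pm$taxon == "Dactylis"], "not_analysed")
})

test_that("in-silico absence without PCR backing is flagged low-confidence", {
  pm <- make_pm(present = "Lolium", absent = "Oryza")
  expect_true(pm$low_confidence[pm$taxon == "Oryza"])
  expect_false(pm$low_confidence[pm$taxon == "Lolium"])
})

test_that("the Triticeae+Poeae presence pattern dates the gain to (21, 39) MYA", {
  tt <- build_template_trees()
  pm <- make_pm(present = c("Triticum", "Hordeum", "Lolium", "Festuca",
                            "Dactylis", "Phalaris"),
                absent = c("Brachypodium", "Oryza", "Sorghum", "Zea",
                           "Arabidopsis"))
  w <- infer_transfer_window(pm, tt$host, "g")
  expect_equal(w$lower_mya, 21)
  expect_equal(w$upper_mya, 39)
  expect_equal(unname(w$host_constraint["mrca"]), "TriticeaePoeae")
})

test_that("the donor constraint caps the upper bound for a Loliinae-only gene", {
  tt <- build_template_trees()
  pm <- make_pm(present = c("Lolium", "Festuca"),
                absent = setdiff(tree_tips(tt$host), c("Lolium", "Festuca")))
  w <- infer_transfer_window(pm, tt$host, "g", donor_constraint_mya = 7.2)
  expect_equal(w$lower_mya, 5)
  expect_equal(w$upper_mya, 7.2)   # host parent (15 MYA) is older
  w2 <- infer_transfer_window(pm, tt$host, "g")
  expect_equal(w2$upper_mya, 15)
})

test_that("a single present tip dates between zero and its parent node", {
  tt <- build_template_trees()
  pm <- make_pm(present = "Lolium",
                absent = setdiff(tree_tips(tt$host), "Lolium"))
  w <- infer_transfer_window(pm, tt$host, "g")
  expect_equal(w$lower_mya, 0)
  expect_equal(w$upper_mya, 5)   # Loliinae crown
})

test_that("strict policy rejects absences inside the clade; loss mode reports them", {
  tt <- build_template_trees()
  pm <- make_pm(present = c("Triticum", "Lolium", "Festuca"),
                absent = c("Hordeum", "Brachypodium", "Oryza"))
  expect_error(infer_transfer_window(pm, tt$host, "g"), "Hordeum")
  w <- infer_transfer_window(pm, tt$host, "g", loss_policy = "dollo_losses")
  expect_equal(w$implied_losses, "Hordeum")
  expect_equal(w$lower_mya, 21)
  # losses allowed: absences above the MRCA no longer bound the gain, so
  # the host-side upper bound is the root age unless the donor caps it
  expect_equal(w$upper_mya, max(tt$host$ages))
  wd <- infer_transfer_window(pm, tt$host, "g", donor_constraint_mya = 58.8,
                              loss_policy = "dollo_losses")
  expect_equal(wd$upper_mya, 58.8)
  empty <- make_pm(present = character(), absent = "Lolium")
  expect_error(infer_transfer_window(empty, tt$host, "g"), "no taxa")
})

test_that("growing the presence set never narrows past the MRCA: window is monotone", {
  tt <- build_template_trees()
  presence_sets <- list(
    c("Lolium", "Festuca"),                                    # Loliinae
    c("Lolium", "Festuca", "Dactylis", "Phalaris"),            # Poeae
    c("Lolium", "Festuca", "Dactylis", "Phalaris",
      "Triticum", "Hordeum"))                                  # Trit.+Poeae
  prev_lower <- -Inf
  for (present in presence_sets) {
    pm <- make_pm(present = present,
                  absent = setdiff(tree_tips(tt$host), present))
    w <- infer_transfer_window(pm, tt$host, "g")
    expect_lte(w$lower_mya, w$upper_mya)
    expect_gte(w$lower_mya, prev_lower)   # MRCA can only get older
    prev_lower <- w$lower_mya
  }
})

test_that("planted gain times always fall inside the inferred window (noise-free)", {
  tt <- build_template_trees()
  phy <- tt$host$phylo
  edges <- phy$edge
  set.seed(100)
  for (rep in 1:100) {
    e <- edges[sample.int(nrow(edges), 1), ]
    child_label <- if (e[2] <= ape::Ntip(phy)) phy$tip.label[e[2]]
                   else phy$node.label[e[2] - ape::Ntip(phy)]
    lo <- tt$host$ages[e[2]]
    hi <- tt$host$ages[e[1]]
    t_true <- runif(1, lo, hi)
    carriers <- if (e[2] <= ape::Ntip(phy)) phy$tip.label[e[2]]
                else ape::extract.clade(phy, e[2])$tip.label
    pm <- make_pm(present = carriers,
                  absent = setdiff(tree_tips(tt$host), carriers))
    w <- infer_transfer_window(pm, tt$host, "g")
    expect_gte(t_true, w$lower_mya)
    expect_lte(t_true, w$upper_mya)
  }
})

test_that("the donor tree supplies crown and stem constraints by placement", {
  tt <- build_template_trees()
  expect_equal(donor_divergence_constraint(tt$donor, "nested_in_crown"), 7.2)
  expect_equal(donor_divergence_constraint(tt$donor, "sister_to_crown"), 58.8)
  tt2 <- build_template_trees(donor_overrides = list(Epichloe = 10))
  expect_equal(donor_divergence_constraint(tt2$donor, "nested_in_crown"), 10)
  expect_error(donor_divergence_constraint(tt$donor, "elsewhere"))
})

test_that("in-silico PCR finds flanked products and applies the length cap", {
  set.seed(71)
  fwd <- paste0(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                collapse = "")
  rev <- paste0(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                collapse = "")
  middle <- paste0(sample(c("A", "C", "G", "T"), 140, replace = TRUE),
                   collapse = "")
  pad <- function(n) paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  tpl180 <- paste0(pad(30), fwd, middle, revcomp(rev), pad(30))
  amp <- insilico_pcr(fwd, rev, c(t1 = tpl180))
  expect_equal(nrow(amp), 1L)
  expect_equal(amp$product_len, 180L)
  # same template reversed: product found on the minus strand
  amp_rc <- insilico_pcr(fwd, rev, c(t1 = revcomp(tpl180)))
  expect_equal(amp_rc$product_len, 180L)
  expect_equal(amp_rc$strand, "-")
  # 400-bp span exceeds the 250-bp cap
  tpl400 <- paste0(pad(30), fwd, pad(360), revcomp(rev), pad(30))
  expect_equal(nrow(insilico_pcr(fwd, rev, c(t1 = tpl400))), 0L)
  # missing reverse site: no amplification (the rice lane)
  tpl_norev <- paste0(pad(30), fwd, pad(200))
  expect_equal(nrow(insilico_pcr(fwd, rev, c(rice = tpl_norev))), 0L)
  expect_error(insilico_pcr("ACGT", rev, c(t1 = tpl180)), "15-35")
})

test_that("PCR presence calls feed the matrix and agree with direct amplification", {
  set.seed(72)
  fwd <- paste0(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                collapse = "")
  rev <- paste0(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                collapse = "")
  tpl <- paste0(strrep("A", 20), fwd, strrep("AC", 50), revcomp(rev),
                strrep("T", 20))
  calls <- pcr_presence_calls(fwd, rev,
                              list(Lolium = c(g = tpl),
                                   Oryza = c(g = strrep("ACGT", 100))),
                              gene = "g")
  expect_equal(calls$call[calls$taxon == "Lolium"], "present")
  expect_equal(calls$call[calls$taxon == "Oryza"], "absent")
  pm <- build_presence_matrix(pcr = calls)
  expect_equal(pm$call[pm$taxon == "Lolium"], "present")
  expect_equal(pm$evidence[pm$taxon == "Lolium"], "pcr")
})
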