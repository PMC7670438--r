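# Template host (grass) and donor (fungal) calibrated trees.  The printed
# calibrations that matter downstream are fixed: the Brachypodieae split
# from the rest of the core Pooideae carried at the older end (39 MYA) of
# its 32-39 MYA interval, the Triticeae-Poeae split at 21 MYA, the
# Claviceps-Epichloe divergence at 58.8 MYA and the crown radiation of
# modern Epichloe at 7.2 MYA.  Remaining node ages are field-standard
# placeholders (see the methods vignette).

.host_topology <- list(Root = list(
  "Arabidopsis",
  Poaceae = list(
    "Oryza",
    BOP_PACMAD = list(
      Panicoideae = list("Sorghum", "Zea"),
      Pooideae = list(
        "Brachypodium",
        TriticeaePoeae = list(
          Triticeae = list("Triticum", "Hordeum"),
          Poeae = list(
            Loliinae = list("Lolium", "Festuca"),
            Dactylidinae = list("Dactylis", "Phalaris")
          )
        )
      )
    )
  )
))

.host_ages_default <- c(
  Root = 160, Poaceae = 50, BOP_PACMAD = 45, Panicoideae = 12,
  Pooideae = 39, TriticeaePoeae = 21, Triticeae = 11,
  Poeae = 15, Loliinae = 5, Dactylidinae = 10
)

.donor_topology <- list(ClavicepsEpichloe = list(
  "Claviceps_purpurea",
  Epichloe = list(
    "Epichloe_gansuensis",
    EpichloeCore = list(
      "Epichloe_festucae",
      EpichloeInner = list("Epichloe_typhina", "Epichloe_elymi")
    )
  )
))

.donor_ages_default <- c(
  ClavicepsEpichloe = 58.8, Epichloe = 7.2, EpichloeCore = 4,
  EpichloeInner = 2
)

.topo_to_newick <- function(name, node, ages, parent_age) {
  if (is.character(node)) {
    return(sprintf("%s:%s", node, format(parent_age, trim = TRUE)))
  }
  age <- ages[[name]]
  if (is.null(age) || is.na(age)) stop("missing age for node ", name,
                                       call. = FALSE)
  kids <- vapply(seq_along(node), function(i) {
    nm <- names(node)[i]
    if (is.null(nm) || !nzchar(nm)) nm <- ""
    .topo_to_newick(nm, node[[i]], ages, age)
  }, character(1))
  body <- sprintf("(%s)%s", paste(kids, collapse = ","), name)
  if (is.na(parent_age)) paste0(body, ";")
  else sprintf("%s:%s", body, format(parent_age - age, trim = TRUE))
}

.build_tree <- function(topology, ages, overrides = NULL) {
  if (!is.null(overrides)) {
    unknown <- setdiff(names(overrides), names(ages))
    if (length(unknown) > 0L) {
      stop("unknown node(s) in age overrides: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    ages[names(overrides)] <- unlist(overrides)
  }
  root <- names(topology)[1]
  txt <- .topo_to_newick(root, topology[[1]], as.list(ages), NA_real_)
  ct <- tryCatch(read_newick(text = txt), error = function(e) {
    stop("age override violates parent > child ordering: ",
         conditionMessage(e), call. = FALSE)
  })
  ct
}

#' Build the template host and donor calibrated trees
#'
#' The host tree holds outgroup angiosperms (Arabidopsis, rice, sorghum,
#' maize analogues), a Brachypodieae analogue splitting from the
#' Triticeae+Poeae lineage (default 39 MYA, the older end of the 32-39 MYA
#' calibration interval), Triticeae and Poeae clades splitting at 21 MYA,
#' and a Loliinae subclade.  The donor tree holds a Claviceps analogue
#' splitting 58.8 MYA from an Epichloe clade whose crown radiation is
#' 7.2 MYA.
#'
#' @param host_overrides,donor_overrides Named lists of node-age overrides
#'   (internal node label -> age in MYA).  An override violating the
#'   parent-older-than-child ordering is rejected.
#' @return List with elements `host` and `donor`, both `calibrated_tree`.
#' @examples
#' tt <- build_template_trees()
#' node_age(tt$host, "TriticeaePoeae")  # 21
#' node_age(tt$donor, "Epichloe")       # 7.2
#' @export
build_template_trees <- function(host_overrides = NULL,
                                 donor_overrides = NULL) {
  list(
    host = .build_tree(.host_topology, .host_ages_default, host_overrides),
    donor = .build_tree(.donor_topology, .donor_ages_default, donor_overrides)
  )
}
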