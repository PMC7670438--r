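# Distance-based phylograms for candidate genes: pairwise p-distances over
# a protein alignment, canonical neighbour-joining, and the clade-nesting
# test that decides the donor-side dating constraint.

#' Pairwise p-distance matrix of a protein (or DNA) alignment
#'
#' Proportion of mismatching columns among columns without a gap in either
#' sequence, for every pair.
#'
#' @param aln Named character vector of equal-length aligned sequences.
#' @return Symmetric `dist`-compatible numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(aln) {
  aln <- .as_named_seqs(aln)
  n <- length(aln)
  if (n < 2L) stop("need at least two sequences", call. = FALSE)
  L <- unique(nchar(aln))
  if (length(L) != 1L) stop("sequences must be aligned (equal length)",
                            call. = FALSE)
  chars <- lapply(aln, function(s) strsplit(s, "")[[1]])
  D <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    a <- chars[[i]]; b <- chars[[j]]
    keep <- a != "-" & b != "-"
    if (!any(keep)) stop("no comparable columns between ", names(aln)[i],
                         " and ", names(aln)[j], call. = FALSE)
    D[i, j] <- D[j, i] <- mean(a[keep] != b[keep])
  }
  D
}

#' Neighbour-joining phylogram from a distance matrix
#'
#' Canonical neighbour-joining (via `ape::nj`); negative branch lengths are
#' clamped to zero with the negative amount transferred to the sibling
#' branch, preserving tip-to-tip path lengths through the parent.
#'
#' @param D Symmetric nonnegative distance matrix with zero diagonal
#'   (asymmetry beyond 1e-9 is rejected).
#' @return Unrooted `phylo` tree with branch lengths.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least three taxa", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-9) stop("distance matrix is not symmetric",
                                      call. = FALSE)
  if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero",
                              call. = FALSE)
  phy <- ape::nj(as.dist(D))
  # clamp negative branch lengths, moving the deficit to the sibling edge
  neg <- which(phy$edge.length < 0)
  for (e in neg) {
    amount <- -phy$edge.length[e]
    phy$edge.length[e] <- 0
    parent <- phy$edge[e, 1]
    sibs <- which(phy$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    if (length(sibs) > 0L) {
      phy$edge.length[sibs[1]] <- phy$edge.length[sibs[1]] + amount
    }
  }
  phy
}

#' Placement of focal taxa relative to a reference crown group
#'
#' Roots the tree with the outgroup, then asks where the smallest clade
#' containing the focal taxa sits: `nested_in_crown` when the focal tips
#' fall inside the reference crown group; `sister_to_crown` when the focal
#' clade attaches on the stem branch of the reference crown; `other`
#' otherwise (e.g. polyphyletic focal taxa).
#'
#' @param phy `phylo` tree (typically from [nj_tree()]).
#' @param focal_taxa Tips whose placement is tested (e.g. the plant copies
#'   of a candidate gene).
#' @param reference_taxa Tips of the reference crown group (e.g. the donor
#'   genus).
#' @param outgroup_taxa Tips used to root the tree.
#' @return One of `"nested_in_crown"`, `"sister_to_crown"`, `"other"`.
#' @export
clade_nesting_check <- function(phy, focal_taxa, reference_taxa,
                                outgroup_taxa) {
  all_taxa <- c(focal_taxa, reference_taxa, outgroup_taxa)
  missing <- setdiff(all_taxa, phy$tip.label)
  if (length(missing) > 0L) {
    stop("taxa absent from tree: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  phy <- ape::root(phy, outgroup = outgroup_taxa, resolve.root = TRUE)
  tips_of <- function(node) {
    if (node <= ape::Ntip(phy)) return(phy$tip.label[node])
    ape::extract.clade(phy, node)$tip.label
  }
  mrca_of <- function(taxa) {
    if (length(taxa) == 1L) match(taxa, phy$tip.label)
    else ape::getMRCA(phy, taxa)
  }
  focal_clade <- tips_of(mrca_of(focal_taxa))
  if (!all(focal_clade %in% c(focal_taxa, reference_taxa))) return("other")
  ref_crown <- tips_of(mrca_of(reference_taxa))
  if (all(focal_taxa %in% ref_crown)) return("nested_in_crown")
  joint <- tips_of(mrca_of(c(focal_taxa, reference_taxa)))
  if (setequal(joint, c(focal_taxa, reference_taxa)) &&
      setequal(focal_clade, focal_taxa) &&
      setequal(ref_crown, reference_taxa)) {
    return("sister_to_crown")
  }
  "other"
}
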