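# Dated, rooted species trees: an ape phylo plus absolute node ages in MYA.
# Ages drive both the sequence-evolution simulator and gain-event dating.

#' Construct a calibrated tree
#'
#' Wraps a rooted `ape::phylo` with absolute node ages (million years ago).
#' If ages are not supplied they are derived from the branch lengths under
#' the assumption that the tree is ultrametric with all tips at age 0.
#'
#' @param phy Rooted `phylo` object.
#' @param ages Optional numeric vector of ages indexed by ape node number
#'   (tips `1..Ntip`, then internal nodes).
#' @return Object of class `calibrated_tree`: list with elements `phylo` and
#'   `ages`.
#' @export
calibrated_tree <- function(phy, ages = NULL) {
  if (!inherits(phy, "phylo")) stop("phy must be an ape phylo", call. = FALSE)
  if (!ape::is.rooted(phy)) stop("tree must be rooted", call. = FALSE)
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  if (is.null(ages)) {
    if (is.null(phy$edge.length)) {
      stop("no branch lengths and no ages given", call. = FALSE)
    }
    depth <- ape::node.depth.edgelength(phy)
    root_age <- max(depth)
    ages <- root_age - depth
    if (any(abs(ages[seq_len(ntip)]) > 1e-6 * max(root_age, 1))) {
      stop("tree is not ultrametric; supply node ages explicitly",
           call. = FALSE)
    }
    ages[seq_len(ntip)] <- 0
  }
  if (length(ages) != ntip + nnode) {
    stop("ages must have one entry per node", call. = FALSE)
  }
  ct <- structure(list(phylo = phy, ages = ages), class = "calibrated_tree")
  .validate_calibrated_tree(ct)
  ct
}

.validate_calibrated_tree <- function(ct) {
  phy <- ct$phylo
  ntip <- ape::Ntip(phy)
  if (any(abs(ct$ages[seq_len(ntip)]) > 1e-9)) {
    stop("tip ages must all be 0", call. = FALSE)
  }
  parent_age <- ct$ages[phy$edge[, 1]]
  child_age <- ct$ages[phy$edge[, 2]]
  if (any(parent_age <= child_age)) {
    bad <- which(parent_age <= child_age)[1]
    stop("parent age must exceed child age (violated above node ",
         .node_label(ct, phy$edge[bad, 2]), ")", call. = FALSE)
  }
  if (anyDuplicated(phy$tip.label)) {
    stop("tip labels must be unique", call. = FALSE)
  }
  invisible(ct)
}

.node_number <- function(ct, label) {
  phy <- ct$phylo
  i <- match(label, phy$tip.label)
  if (!is.na(i)) return(i)
  j <- match(label, phy$node.label)
  if (!is.na(j)) return(ape::Ntip(phy) + j)
  stop("no node labelled '", label, "' in tree", call. = FALSE)
}

.node_label <- function(ct, num) {
  phy <- ct$phylo
  ntip <- ape::Ntip(phy)
  if (num <= ntip) phy$tip.label[num]
  else if (!is.null(phy$node.label) && nzchar(phy$node.label[num - ntip])) {
    phy$node.label[num - ntip]
  } else paste0("node", num)
}

.parent_of <- function(ct, num) {
  e <- ct$phylo$edge
  p <- e[e[, 2] == num, 1]
  if (length(p) == 0L) NA_integer_ else p
}

.children_of <- function(ct, num) {
  e <- ct$phylo$edge
  e[e[, 1] == num, 2]
}

.tips_below <- function(ct, num) {
  phy <- ct$phylo
  ntip <- ape::Ntip(phy)
  if (num <= ntip) return(phy$tip.label[num])
  kids <- .children_of(ct, num)
  unlist(lapply(kids, function(k) .tips_below(ct, k)))
}

#' Age of a labelled node
#'
#' @param ct `calibrated_tree`.
#' @param label Tip or internal node label.
#' @return Age in MYA.
#' @export
node_age <- function(ct, label) {
  ct$ages[.node_number(ct, label)]
}

#' Labels of all tips of a calibrated tree
#' @param ct `calibrated_tree`.
#' @export
tree_tips <- function(ct) ct$phylo$tip.label

#' @export
print.calibrated_tree <- function(x, ...) {
  cat(sprintf("calibrated tree: %d tips, root age %.4g MYA\n",
              ape::Ntip(x$phylo), max(x$ages)))
  invisible(x)
}

#' Read a calibrated tree from Newick
#'
#' Supports node ages either as `[&age=X]` annotations (after a tip label or
#' a closing parenthesis) or derived from branch lengths of an ultrametric
#' tree with tips at age 0.  With partial annotation, branch lengths fill in
#' the remaining ages relative to annotated nodes; a tree with neither
#' branch lengths nor full annotation is rejected.
#'
#' @param path Path to a Newick file (or a Newick string via `text`).
#' @param text Newick string, used instead of `path` when given.
#' @return `calibrated_tree`.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) text <- paste(readLines(path), collapse = "")
  # fold [&age=X] annotations into labels so ape can carry them through
  text2 <- gsub("\\[&age=([0-9eE.+-]+)\\]", "__AGE_\\1", text)
  phy <- ape::read.tree(text = text2)
  if (is.null(phy)) stop("malformed Newick input", call. = FALSE)
  extract <- function(labels) {
    has <- grepl("__AGE_", labels)
    age <- rep(NA_real_, length(labels))
    age[has] <- as.numeric(sub(".*__AGE_", "", labels[has]))
    list(labels = sub("__AGE_.*", "", labels), age = age)
  }
  tl <- extract(phy$tip.label)
  phy$tip.label <- tl$labels
  ann <- tl$age
  if (!is.null(phy$node.label)) {
    nl <- extract(phy$node.label)
    phy$node.label <- nl$labels
    ann <- c(ann, nl$age)
  } else {
    ann <- c(ann, rep(NA_real_, phy$Nnode))
  }
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  if (!is.null(phy$edge.length) && anyNA(phy$edge.length)) {
    phy$edge.length <- NULL   # partial branch lengths: rely on annotations
  }
  if (all(is.na(ann))) {
    return(calibrated_tree(phy))   # ultrametric branch-length route
  }
  if (is.null(phy$edge.length)) {
    ann[seq_len(ntip)][is.na(ann[seq_len(ntip)])] <- 0   # tips default to 0
    if (any(is.na(ann))) {
      stop("age annotation required on every internal node when branch ",
           "lengths are absent", call. = FALSE)
    }
    ages <- ann
  } else {
    depth <- ape::node.depth.edgelength(phy)
    root_age <- if (!is.na(ann[root])) ann[root] else {
      # anchor on any annotated node
      k <- which(!is.na(ann))[1]
      ann[k] + depth[k]
    }
    ages <- root_age - depth
    ages[!is.na(ann)] <- ann[!is.na(ann)]
    ages[seq_len(ntip)][abs(ages[seq_len(ntip)]) < 1e-6 * max(root_age, 1)] <- 0
  }
  calibrated_tree(phy, ages)
}

#' Write a calibrated tree to Newick
#'
#' Branch lengths are written as age differences (parent minus child), so an
#' ultrametric tree round-trips; node ages are also emitted as `[&age=X]`
#' annotations when `annotate = TRUE`.
#'
#' @param ct `calibrated_tree`.
#' @param path Output file; when `NULL` the Newick string is returned.
#' @param annotate Emit `[&age=X]` on internal nodes (default `TRUE`).
#' @export
write_newick <- function(ct, path = NULL, annotate = TRUE) {
  phy <- ct$phylo
  phy$edge.length <- ct$ages[phy$edge[, 1]] - ct$ages[phy$edge[, 2]]
  if (annotate) {
    ntip <- ape::Ntip(phy)
    nl <- if (is.null(phy$node.label)) rep("", phy$Nnode) else phy$node.label
    phy$node.label <- paste0(nl, "__AGE_",
                             format(ct$ages[ntip + seq_len(phy$Nnode)],
                                    trim = TRUE))
  }
  txt <- ape::write.tree(phy)
  txt <- gsub("__AGE_([0-9eE.+-]+)", "[\\&age=\\1]", txt)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}
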