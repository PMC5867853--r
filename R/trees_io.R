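## Reading, writing and structural editing of newick trees.
## Trees are ape "phylo" objects; gene tree collections are "multiPhylo".

#' Read a species tree from a newick file or string
#'
#' A thin wrapper around [ape::read.tree()] that validates the tree for use
#' as a species tree: leaf labels must be unique and at least four taxa are
#' required for any internal branch to define quartets.
#'
#' @param file path to a newick file containing a single tree.
#' @param text newick string; overrides `file` when given.
#' @return a `phylo` object. Internal node labels, if present, are kept
#'   verbatim (they are treated as names/annotations, not support values).
#' @export
#' @examples
#' sp <- read_species_tree(text = "((a:1,b:1):0.5,(c:1,d:1):0.5);")
read_species_tree <- function(file = NULL, text = NULL) {
  phy <- if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file)
  if (is.null(phy)) stop("could not parse newick species tree")
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L)
      stop("species tree input must contain exactly one tree, found ", length(phy))
    phy <- phy[[1L]]
  }
  .check_tip_labels(phy, "species tree")
  phy
}

#' Read gene trees from a newick file (one tree per line)
#'
#' Each non-empty line must hold one well-formed newick tree. Gene trees may
#' be incomplete (missing taxa) and multifurcating; internal node labels are
#' interpreted as branch support values (see [contract_low_support()]).
#'
#' @param file path to a newick file, one tree per line.
#' @param text newick string(s), newline-separated; overrides `file`.
#' @return a `multiPhylo` object.
#' @export
read_gene_trees <- function(file = NULL, text = NULL) {
  lines <- if (!is.null(text)) strsplit(text, "\n", fixed = TRUE)[[1L]]
           else readLines(file)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx)) stop("no gene trees found in input")
  trees <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    ln <- idx[k]
    phy <- tryCatch(
      ape::read.tree(text = lines[ln]),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(phy))
      stop(sprintf("malformed newick at line %d of gene tree input", ln))
    .check_tip_labels(phy, sprintf("gene tree at line %d", ln))
    trees[[k]] <- phy
  }
  class(trees) <- "multiPhylo"
  trees
}

.check_tip_labels <- function(phy, what) {
  dup <- unique(phy$tip.label[duplicated(phy$tip.label)])
  if (length(dup))
    stop(sprintf("duplicate leaf labels in %s: %s", what,
                 paste(dup, collapse = ", ")))
  invisible(TRUE)
}

#' Branch support values of a tree
#'
#' Internal node labels that parse as numbers are interpreted as support for
#' the edge above the node. Returns one value per edge of `phy$edge` (NA for
#' terminal edges, the root edge, and non-numeric labels).
#'
#' @param phy a `phylo` object.
#' @return numeric vector along the rows of `phy$edge`.
#' @export
support_values <- function(phy) {
  ntip <- length(phy$tip.label)
  out <- rep(NA_real_, nrow(phy$edge))
  if (is.null(phy$node.label)) return(out)
  child <- phy$edge[, 2L]
  internal <- child > ntip
  lab <- phy$node.label[child[internal] - ntip]
  lab[!nzchar(lab)] <- NA_character_
  out[internal] <- suppressWarnings(as.numeric(lab))
  out
}

#' Contract low-support branches
#'
#' Contracts every internal edge whose support is at or below `threshold`,
#' producing polytomies. Edges without a (numeric) support value are never
#' contracted. Support scale is auto-detected: if all support values are
#' <= 1 they are taken as fractions, otherwise as percentages; a threshold
#' given on the other scale is converted.
#'
#' @param phy a `phylo` object with support values as internal node labels.
#' @param threshold non-negative support threshold ("at or below" semantics).
#' @return a `phylo` object with the same leaf set.
#' @export
#' @examples
#' g <- ape::read.tree(text = "(((a:1,b:1)20:1,c:1)80:1,(d:1,e:1)5:1,f:1);")
#' contract_low_support(g, 20)   # contracts the 20- and 5-support edges
contract_low_support <- function(phy, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold))
    stop("threshold must be a single number")
  if (threshold < 0) stop("threshold must be non-negative")
  sup <- support_values(phy)
  if (all(is.na(sup))) return(phy)
  fractional <- max(sup, na.rm = TRUE) <= 1
  if (fractional && threshold > 1) threshold <- threshold / 100
  if (!fractional && threshold <= 1 && threshold > 0) {
    ## percent-scale supports with a fractional threshold
    threshold <- threshold * 100
  }
  contract_edges(phy, which(!is.na(sup) & sup <= threshold))
}

#' Contract a set of edges of a tree
#'
#' Removes the given internal edges by merging each edge's child node into
#' its parent. The leaf set is unchanged; contracting k edges around a node
#' yields a polytomy.
#'
#' @param phy a `phylo` object.
#' @param edges integer indices into the rows of `phy$edge`; each indexed
#'   edge must be internal (its child must not be a tip).
#' @return a `phylo` object.
#' @export
contract_edges <- function(phy, edges) {
  edges <- unique(as.integer(edges))
  if (!length(edges)) return(phy)
  ntip <- length(phy$tip.label)
  E <- phy$edge
  if (any(edges < 1L | edges > nrow(E))) stop("edge index out of range")
  if (any(E[edges, 2L] <= ntip)) stop("cannot contract a terminal edge")
  removed <- E[edges, 2L]
  ## map each removed node to its (possibly also removed) parent
  up <- integer(max(E))
  up[E[, 2L]] <- E[, 1L]
  resolve <- function(v) { while (v %in% removed) v <- up[v]; v }
  keep <- setdiff(seq_len(nrow(E)), edges)
  newE <- E[keep, , drop = FALSE]
  newE[, 1L] <- vapply(newE[, 1L], resolve, integer(1L))
  ## renumber surviving internal nodes consecutively after the tips
  surv <- sort(unique(c(newE[, 1L], newE[newE[, 2L] > ntip, 2L])))
  surv <- surv[surv > ntip]
  map <- integer(max(E))
  map[seq_len(ntip)] <- seq_len(ntip)
  map[surv] <- ntip + seq_along(surv)
  newE[] <- map[newE]
  out <- list(edge = newE, Nnode = length(surv), tip.label = phy$tip.label)
  if (!is.null(phy$edge.length)) out$edge.length <- phy$edge.length[keep]
  if (!is.null(phy$node.label)) out$node.label <- phy$node.label[surv - ntip]
  class(out) <- "phylo"
  attr(out, "order") <- NULL
  ape::reorder.phylo(out, "cladewise")
}

#' Resolve polytomies into an arbitrary binary refinement
#'
#' Every polytomy is replaced by a random sequence of bifurcations joined by
#' zero-length edges, so the output displays every bipartition of the input.
#' Deterministic for a given `seed`.
#'
#' @param phy a `phylo` object, possibly multifurcating.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a binary `phylo` object refining `phy`.
#' @export
resolve_arbitrarily <- function(phy, seed = NULL) {
  if (ape::is.binary(phy)) return(phy)
  if (!is.null(seed)) {
    old <- .save_rng()
    on.exit(.restore_rng(old))
    set.seed(seed)
  }
  out <- ape::multi2di(phy, random = TRUE)
  ## multi2di assigns 0 length to new edges when edge lengths exist
  out
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
  invisible(NULL)
}

#' Collapse branches not rejected by the polytomy test
#'
#' Given a [polytomy_test()] result, contracts every internal branch whose
#' p-value exceeds `alpha` or whose test is not applicable (effective number
#' of genes below 10), turning the retained null hypotheses into polytomies.
#'
#' @param test a `polytomy_test` object.
#' @param alpha significance level in (0, 1).
#' @param use_adjusted if `TRUE` and adjusted p-values are present, collapse
#'   on those instead of the raw p-values.
#' @return a `phylo` object (the tested, unrooted species tree with
#'   non-rejected branches contracted).
#' @export
collapse_nonrejected <- function(test, alpha = 0.05, use_adjusted = FALSE) {
  stopifnot(inherits(test, "polytomy_test"))
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number in (0, 1)")
  tab <- test$table
  p <- if (use_adjusted && !all(is.na(tab$adjusted_p))) tab$adjusted_p
       else tab$p_value
  drop <- !tab$applicable | is.na(p) | p > alpha
  contract_edges(test$tree, tab$edge[drop])
}

#' Write the per-branch test table as TSV
#'
#' Columns: branch_id, clade (comma-separated taxa below the branch), n1,
#' n2, n3, effective_n, chi2, p_value, applicable, adjusted_p.
#'
#' @param test a `polytomy_test` object (or the tally table from
#'   [tally_branches()]).
#' @param file output path or connection (`""` prints to stdout).
#' @return `invisible(test)`.
#' @export
write_branch_table <- function(test, file = "") {
  tab <- if (inherits(test, "polytomy_test")) test$table else test
  drop <- intersect("edge", names(tab))
  out <- tab[, setdiff(names(tab), drop), drop = FALSE]
  num <- vapply(out, is.numeric, logical(1L)) & names(out) != "effective_n"
  out[num] <- lapply(out[num], signif, digits = 6L)
  write.table(out, file = file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(test)
}

#' Write the species tree with p-values as internal node annotations
#'
#' The tested (unrooted) species tree is written in newick format with each
#' tested branch's p-value stored as the label of the branch's child node,
#' in the style of per-branch support annotations.
#'
#' @param test a `polytomy_test` object.
#' @param file output path (`""` returns/prints the newick string).
#' @param digits significant digits for p-values.
#' @return the newick string, invisibly.
#' @export
write_annotated_tree <- function(test, file = "", digits = 6L) {
  stopifnot(inherits(test, "polytomy_test"))
  phy <- test$tree
  ntip <- length(phy$tip.label)
  lab <- rep("", phy$Nnode)
  child <- phy$edge[test$table$edge, 2L]
  lab[child - ntip] <- sprintf("%.*g", digits, test$table$p_value)
  phy$node.label <- lab
  txt <- ape::write.tree(phy)
  if (nzchar(file)) writeLines(txt, file)
  invisible(txt)
}
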