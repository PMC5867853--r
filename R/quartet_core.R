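## Aggregated quartet-topology frequencies around species-tree branches.
##
## For an internal branch B of the species tree, a quartet (a, b, c, d) is
## "around B" when a and b come from the two subtrees below the branch and
## c and d from the two subtrees on the other side (the sister subtree and
## the rest). In a gene tree, the quartet has topology t1 = ab|cd,
## t2 = ac|bd, t3 = ad|bc, or is unresolved/missing. Per-branch tallies
## n1, n2, n3 sum, over gene trees, each gene's fraction of resolved
## present quartets having each topology; genes with no present resolved
## quartet around the branch are discarded for that branch.

#' Four-set contexts for every internal branch of a species tree
#'
#' The species tree is internally unrooted (the test concerns unrooted
#' topology). For each internal edge, the four disjoint taxon sets around
#' the edge are extracted: the two subtrees below the child node and the
#' two subtrees on the parent side. When a node adjacent to the edge is a
#' polytomy, the first component is used for the near set and the remaining
#' components are pooled into the far set, so the sets stay disjoint and
#' every quartet drawn from them has its middle path on the focal edge.
#'
#' @param species_tree a `phylo` object with at least 4 taxa; may be rooted
#'   (unrooted internally) and may contain polytomies.
#' @return a list of class `branch_contexts`: one element per internal edge,
#'   each a list with `edge` (row in the unrooted tree's edge matrix),
#'   `child` (child node id), `length` (branch length, NA if absent),
#'   `clade` (comma-separated sorted taxa below the edge) and taxon sets
#'   `A`, `B`, `C`, `D`. The unrooted tree is stored in attribute `tree`.
#' @export
branch_contexts <- function(species_tree) {
  stopifnot(inherits(species_tree, "phylo"))
  .check_tip_labels(species_tree, "species tree")
  ntip <- length(species_tree$tip.label)
  if (ntip < 4L)
    stop("species tree must have at least 4 taxa to define quartets")
  phy <- ape::unroot(species_tree)
  phy <- ape::reorder.phylo(phy, "postorder")
  E <- phy$edge
  root <- E[nrow(E), 1L]
  labs <- phy$tip.label
  ## descendant tip sets per node
  desc <- vector("list", ntip + phy$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- i
  for (i in seq_len(nrow(E)))
    desc[[E[i, 1L]]] <- c(desc[[E[i, 1L]]], desc[[E[i, 2L]]])
  kids <- split(E[, 2L], E[, 1L])
  internal <- which(E[, 2L] > ntip)
  ctx <- vector("list", length(internal))
  for (k in seq_along(internal)) {
    i <- internal[k]
    u <- E[i, 1L]; v <- E[i, 2L]
    below <- kids[[as.character(v)]]
    setA <- desc[[below[1L]]]
    setB <- unlist(desc[below[-1L]])
    sibs <- setdiff(kids[[as.character(u)]], v)
    if (u == root) {
      setC <- desc[[sibs[1L]]]
      setD <- unlist(desc[sibs[-1L]])
    } else {
      setC <- desc[[sibs[1L]]]
      rest <- setdiff(seq_len(ntip), c(desc[[u]]))
      setD <- c(unlist(desc[sibs[-1L]]), rest)
    }
    ctx[[k]] <- list(
      edge = i, child = v,
      length = if (is.null(phy$edge.length)) NA_real_ else phy$edge.length[i],
      clade = paste(sort(labs[desc[[v]]]), collapse = ","),
      A = labs[setA], B = labs[setB], C = labs[setC], D = labs[setD])
  }
  attr(ctx, "tree") <- phy
  class(ctx) <- "branch_contexts"
  ctx
}

#' Induced topology of a quartet in a gene tree
#'
#' @param gene_tree a `phylo` object.
#' @param taxa character vector of four distinct taxon labels
#'   `c(a, b, c, d)`.
#' @return one of `"t1"` (ab|cd), `"t2"` (ac|bd), `"t3"` (ad|bc),
#'   `"unresolved"` (the induced quartet is a star), or `"missing"` (some
#'   taxon absent from the gene tree).
#' @export
#' @examples
#' g <- ape::read.tree(text = "((a,b),(c,d));")
#' quartet_topology(g, c("a", "b", "c", "d"))  # "t1"
quartet_topology <- function(gene_tree, taxa) {
  if (length(taxa) != 4L || anyDuplicated(taxa))
    stop("a quartet requires four distinct taxa")
  if (!all(taxa %in% gene_tree$tip.label)) return("missing")
  dm <- .unit_dist(gene_tree, taxa)
  s <- c(dm[1L, 2L] + dm[3L, 4L],
         dm[1L, 3L] + dm[2L, 4L],
         dm[1L, 4L] + dm[2L, 3L])
  m <- min(s)
  if (sum(s == m) > 1L) "unresolved" else c("t1", "t2", "t3")[which.min(s)]
}

## topological (unit-edge-length) distances between the given tips
.unit_dist <- function(phy, taxa) {
  phy$edge.length <- rep(1, nrow(phy$edge))
  idx <- match(taxa, phy$tip.label)
  d <- ape::dist.nodes(phy)[idx, idx, drop = FALSE]
  d
}

## ---------------------------------------------------------------------------
## Counting engine.
##
## For one gene tree and all branch contexts at once, counts the number of
## present resolved quartets of each topology by inclusion-exclusion over
## the gene tree's edges and vertices: a quartet ab|cd is displayed by the
## tree iff some edge separates {a,b} from {c,d}; the edges doing so form a
## path whose interior vertices each see {a,b} together in one adjacent
## component and {c,d} together in another. Summing edge counts and
## subtracting interior-vertex counts scores each displayed quartet exactly
## once. All terms are products of per-subtree membership counts, computed
## in one postorder pass, so the cost is O(gene size x branches) rather
## than O(N^4).

## M: ntaxa x 4B matrix of set memberships, column blocks A | B | C | D
.quartet_counts <- function(gene, M, taxa, nb) {
  g <- if (ape::is.rooted(gene)) ape::unroot(gene) else gene
  g <- ape::reorder.phylo(g, "postorder")
  ntip <- length(g$tip.label)
  nn <- ntip + g$Nnode
  idx <- match(g$tip.label, taxa)
  if (anyNA(idx))
    stop("gene tree contains taxa absent from the species tree: ",
         paste(g$tip.label[is.na(idx)], collapse = ", "))
  iA <- seq_len(nb); iB <- nb + iA; iC <- 2L * nb + iA; iD <- 3L * nb + iA
  Cc <- matrix(0, nn, 4L * nb)
  Cc[seq_len(ntip), ] <- M[idx, , drop = FALSE]
  E <- g$edge
  for (i in seq_len(nrow(E)))
    Cc[E[i, 1L], ] <- Cc[E[i, 1L], ] + Cc[E[i, 2L], ]
  root <- E[nrow(E), 1L]
  Tot <- Cc[root, ]
  TA <- Tot[iA]; TB <- Tot[iB]; TC <- Tot[iC]; TD <- Tot[iD]

  ch <- E[, 2L]
  aS <- Cc[ch, iA, drop = FALSE]; bS <- Cc[ch, iB, drop = FALSE]
  cS <- Cc[ch, iC, drop = FALSE]; dS <- Cc[ch, iD, drop = FALSE]
  rA <- sweep(-aS, 2L, TA, "+"); rB <- sweep(-bS, 2L, TB, "+")
  rC <- sweep(-cS, 2L, TC, "+"); rD <- sweep(-dS, 2L, TD, "+")

  E1 <- aS * bS * rC * rD + rA * rB * cS * dS
  E2 <- aS * cS * rB * rD + rA * rC * bS * dS
  E3 <- aS * dS * rB * rC + rA * rD * bS * cS

  grp <- E[, 1L]
  Sab <- rowsum(aS * bS, grp); Scd <- rowsum(cS * dS, grp)
  Sac <- rowsum(aS * cS, grp); Sbd <- rowsum(bS * dS, grp)
  Sad <- rowsum(aS * dS, grp); Sbc <- rowsum(bS * cS, grp)
  Sq  <- rowsum(aS * bS * cS * dS, grp)
  vids <- as.integer(rownames(Sab))
  nonroot <- vids != root
  if (any(nonroot)) {
    v <- vids[nonroot]
    ra <- sweep(-Cc[v, iA, drop = FALSE], 2L, TA, "+")
    rb <- sweep(-Cc[v, iB, drop = FALSE], 2L, TB, "+")
    rc <- sweep(-Cc[v, iC, drop = FALSE], 2L, TC, "+")
    rd <- sweep(-Cc[v, iD, drop = FALSE], 2L, TD, "+")
    Sab[nonroot, ] <- Sab[nonroot, ] + ra * rb
    Scd[nonroot, ] <- Scd[nonroot, ] + rc * rd
    Sac[nonroot, ] <- Sac[nonroot, ] + ra * rc
    Sbd[nonroot, ] <- Sbd[nonroot, ] + rb * rd
    Sad[nonroot, ] <- Sad[nonroot, ] + ra * rd
    Sbc[nonroot, ] <- Sbc[nonroot, ] + rb * rc
    Sq[nonroot, ]  <- Sq[nonroot, ]  + ra * rb * rc * rd
  }
  N1 <- colSums(E1) - colSums(Sab * Scd - Sq)
  N2 <- colSums(E2) - colSums(Sac * Sbd - Sq)
  N3 <- colSums(E3) - colSums(Sad * Sbc - Sq)
  rbind(N1, N2, N3, present = TA * TB * TC * TD)
}

.context_membership <- function(ctx, taxa) {
  nb <- length(ctx)
  M <- matrix(0, length(taxa), 4L * nb)
  for (k in seq_len(nb)) {
    M[match(ctx[[k]]$A, taxa), k] <- 1
    M[match(ctx[[k]]$B, taxa), nb + k] <- 1
    M[match(ctx[[k]]$C, taxa), 2L * nb + k] <- 1
    M[match(ctx[[k]]$D, taxa), 3L * nb + k] <- 1
  }
  M
}

#' Quartet frequency tallies for every internal branch
#'
#' For each internal branch of the species tree, aggregates gene-tree
#' quartet topology frequencies around the branch. With `method = "mean"`
#' (the default) each gene tree j contributes its fraction
#' `f[i,j] = n[i,j] / (n[1,j] + n[2,j] + n[3,j])` of present resolved
#' quartets having topology i, and `n[i] = sum_j f[i,j]`. Gene trees with no
#' present resolved quartet around a branch are discarded for that branch,
#' so the effective number of genes varies across branches.
#'
#' `method = "single"` scores one fixed quartet per branch (the
#' alphabetically first taxon of each of the four sets); `method = "median"`
#' enumerates all quartets around the branch and takes, for each topology,
#' the median across quartets of the per-quartet gene counts (O(N^4)
#' enumeration; small trees only).
#'
#' @param species_tree a `phylo` object (>= 4 taxa) or a
#'   [branch_contexts()] object.
#' @param gene_trees a `multiPhylo` (or list of `phylo`); leaf labels must
#'   be a subset of the species tree taxa.
#' @param method aggregation across quartets around each branch.
#' @param fractions if `TRUE`, attach the per-gene fraction array
#'   (3 x genes x branches) as attribute `"fractions"` for diagnostics.
#' @return a data.frame with one row per internal branch: `branch_id`,
#'   `edge`, `clade`, `length`, `n1`, `n2`, `n3`, `effective_n`. The
#'   unrooted species tree is in attribute `"tree"`, the contexts in
#'   attribute `"contexts"`.
#' @export
tally_branches <- function(species_tree, gene_trees,
                           method = c("mean", "single", "median"),
                           fractions = FALSE) {
  method <- match.arg(method)
  ctx <- if (inherits(species_tree, "branch_contexts")) species_tree
         else branch_contexts(species_tree)
  phy <- attr(ctx, "tree")
  taxa <- phy$tip.label
  gene_trees <- .as_multiphylo(gene_trees)
  ng <- length(gene_trees)
  nb <- length(ctx)
  if (nb == 0L) stop("species tree has no internal branch to test")

  tal <- matrix(0, 3L, nb)
  eff <- integer(nb)
  frac <- if (fractions) array(NA_real_, c(3L, ng, nb)) else NULL

  if (method == "mean") {
    M <- .context_membership(ctx, taxa)
    for (j in seq_len(ng)) {
      if (length(gene_trees[[j]]$tip.label) < 4L) next
      cnt <- .quartet_counts(gene_trees[[j]], M, taxa, nb)
      m <- cnt[1L, ] + cnt[2L, ] + cnt[3L, ]
      use <- m > 0
      if (any(use)) {
        f <- sweep(cnt[1:3, use, drop = FALSE], 2L, m[use], "/")
        tal[, use] <- tal[, use] + f
        eff[use] <- eff[use] + 1L
        if (fractions) frac[, j, use] <- f
      }
    }
  } else if (method == "single") {
    quarts <- lapply(ctx, function(cx)
      c(sort(cx$A)[1L], sort(cx$B)[1L], sort(cx$C)[1L], sort(cx$D)[1L]))
    for (j in seq_len(ng)) {
      g <- gene_trees[[j]]
      .check_gene_taxa(g, taxa)
      for (k in seq_len(nb)) {
        top <- quartet_topology(g, quarts[[k]])
        i <- match(top, c("t1", "t2", "t3"))
        if (!is.na(i)) {
          tal[i, k] <- tal[i, k] + 1
          eff[k] <- eff[k] + 1L
          if (fractions) { frac[, j, k] <- 0; frac[i, j, k] <- 1 }
        }
      }
    }
  } else { # median
    for (k in seq_len(nb)) {
      med <- .median_tally(ctx[[k]], gene_trees, taxa)
      tal[, k] <- med$n
      eff[k] <- med$effective_n
    }
  }

  out <- data.frame(
    branch_id = seq_len(nb),
    edge = vapply(ctx, `[[`, integer(1L), "edge"),
    clade = vapply(ctx, `[[`, character(1L), "clade"),
    length = vapply(ctx, `[[`, numeric(1L), "length"),
    n1 = tal[1L, ], n2 = tal[2L, ], n3 = tal[3L, ],
    effective_n = eff,
    stringsAsFactors = FALSE)
  attr(out, "tree") <- phy
  attr(out, "contexts") <- ctx
  if (fractions) attr(out, "fractions") <- frac
  out
}

#' Quartet tally for a single branch context
#'
#' @param context one element of a [branch_contexts()] list.
#' @param gene_trees a `multiPhylo` or list of `phylo`.
#' @param method see [tally_branches()].
#' @return a list with `n1`, `n2`, `n3`, `effective_n`.
#' @export
tally_branch <- function(context, gene_trees,
                         method = c("mean", "single", "median")) {
  method <- match.arg(method)
  gene_trees <- .as_multiphylo(gene_trees)
  taxa <- sort(unique(c(context$A, context$B, context$C, context$D)))
  fake <- structure(list(context), tree = list(tip.label = taxa),
                    class = "branch_contexts")
  if (method == "median") {
    med <- .median_tally(context, gene_trees, taxa)
    return(list(n1 = med$n[1L], n2 = med$n[2L], n3 = med$n[3L],
                effective_n = med$effective_n))
  }
  nb <- 1L
  tal <- numeric(3L); eff <- 0L
  if (method == "mean") {
    M <- .context_membership(fake, taxa)
    for (g in gene_trees) {
      gg <- if (all(g$tip.label %in% taxa)) g
            else ape::keep.tip(g, intersect(g$tip.label, taxa))
      if (length(gg$tip.label) < 4L) next
      cnt <- .quartet_counts(gg, M, taxa, nb)
      m <- sum(cnt[1:3, 1L])
      if (m > 0) { tal <- tal + cnt[1:3, 1L] / m; eff <- eff + 1L }
    }
  } else {
    q <- c(sort(context$A)[1L], sort(context$B)[1L],
           sort(context$C)[1L], sort(context$D)[1L])
    for (g in gene_trees) {
      i <- match(quartet_topology(g, q), c("t1", "t2", "t3"))
      if (!is.na(i)) { tal[i] <- tal[i] + 1; eff <- eff + 1L }
    }
  }
  list(n1 = unname(tal[1L]), n2 = unname(tal[2L]), n3 = unname(tal[3L]),
       effective_n = eff)
}

## all-quartets enumeration used by the median method
.median_tally <- function(context, gene_trees, taxa) {
  combos <- expand.grid(a = context$A, b = context$B, c = context$C,
                        d = context$D, stringsAsFactors = FALSE)
  if (nrow(combos) > 50000L)
    stop("median method enumerates all quartets; too many for this branch (",
         nrow(combos), "); use method = 'mean'")
  m <- matrix(0, 3L, nrow(combos))
  eff <- 0L
  for (g in gene_trees) {
    pres <- g$tip.label
    ok <- combos$a %in% pres & combos$b %in% pres &
          combos$c %in% pres & combos$d %in% pres
    if (!any(ok)) next
    ut <- g
    ut$edge.length <- rep(1, nrow(ut$edge))
    dm <- ape::dist.nodes(ut)
    ix <- function(u, v) cbind(match(u, g$tip.label), match(v, g$tip.label))
    s1 <- dm[ix(combos$a[ok], combos$b[ok])] + dm[ix(combos$c[ok], combos$d[ok])]
    s2 <- dm[ix(combos$a[ok], combos$c[ok])] + dm[ix(combos$b[ok], combos$d[ok])]
    s3 <- dm[ix(combos$a[ok], combos$d[ok])] + dm[ix(combos$b[ok], combos$c[ok])]
    t1 <- s1 < s2 & s1 < s3; t2 <- s2 < s1 & s2 < s3; t3 <- s3 < s1 & s3 < s2
    m[1L, ok] <- m[1L, ok] + t1
    m[2L, ok] <- m[2L, ok] + t2
    m[3L, ok] <- m[3L, ok] + t3
    if (any(t1 | t2 | t3)) eff <- eff + 1L
  }
  list(n = apply(m, 1L, stats::median), effective_n = eff)
}

.as_multiphylo <- function(x) {
  if (inherits(x, "phylo")) x <- list(x)
  if (!length(x)) stop("empty gene tree set")
  class(x) <- "multiPhylo"
  x
}

.check_gene_taxa <- function(gene, taxa) {
  bad <- setdiff(gene$tip.label, taxa)
  if (length(bad))
    stop("gene tree contains taxa absent from the species tree: ",
         paste(bad, collapse = ", "))
  invisible(TRUE)
}
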