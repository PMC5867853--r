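## Independent brute-force oracle: explicit O(N^4) enumeration of all
## quartets around a branch, classifying each by the four-point condition
## on unit-edge-length path distances.

unit_distances <- function(phy) {
  phy$edge.length <- rep(1, nrow(phy$edge))
  d <- ape::dist.nodes(phy)[seq_along(phy$tip.label), seq_along(phy$tip.label)]
  dimnames(d) <- list(phy$tip.label, phy$tip.label)
  d
}

## per-gene quartet counts (n1, n2, n3, present) for one branch context
brute_gene_counts <- function(gene, ctx) {
  tl <- gene$tip.label
  A <- intersect(ctx$A, tl); B <- intersect(ctx$B, tl)
  C <- intersect(ctx$C, tl); D <- intersect(ctx$D, tl)
  if (!length(A) || !length(B) || !length(C) || !length(D))
    return(c(0, 0, 0, 0))
  dm <- unit_distances(gene)
  q <- expand.grid(a = A, b = B, c = C, d = D, stringsAsFactors = FALSE)
  s1 <- dm[cbind(q$a, q$b)] + dm[cbind(q$c, q$d)]
  s2 <- dm[cbind(q$a, q$c)] + dm[cbind(q$b, q$d)]
  s3 <- dm[cbind(q$a, q$d)] + dm[cbind(q$b, q$c)]
  c(sum(s1 < s2 & s1 < s3), sum(s2 < s1 & s2 < s3), sum(s3 < s1 & s3 < s2),
    nrow(q))
}

## Eq.-style mean aggregation computed entirely by brute force
brute_tally <- function(ctx, genes) {
  tal <- numeric(3)
  eff <- 0L
  for (g in genes) {
    cnt <- brute_gene_counts(g, ctx)
    m <- sum(cnt[1:3])
    if (m > 0) { tal <- tal + cnt[1:3] / m; eff <- eff + 1L }
  }
  list(n1 = tal[1], n2 = tal[2], n3 = tal[3], effective_n = eff)
}

## random binary gene trees on a taxon subset
random_genes <- function(taxa, n, drop_max = 0) {
  out <- vector("list", n)
  for (j in seq_len(n)) {
    keep <- taxa
    if (drop_max > 0) {
      k <- sample(0:drop_max, 1)
      if (k > 0 && length(taxa) - k >= 4) keep <- sample(taxa, length(taxa) - k)
    }
    out[[j]] <- ape::rtree(length(keep), tip.label = sample(keep))
  }
  class(out) <- "multiPhylo"
  out
}

## sorted bipartition (clade) strings of an unrooted tree, for topology
## comparison independent of rooting/node numbering
bipart_strings <- function(phy) {
  phy <- ape::unroot(phy)
  ntip <- length(phy$tip.label)
  pp <- ape::prop.part(phy)
  labs <- attr(pp, "labels")
  all_t <- sort(labs)
  out <- vapply(pp, function(idx) {
    cl <- sort(labs[idx])
    other <- setdiff(all_t, cl)
    ## canonical side: lexicographically smaller string
    s1 <- paste(cl, collapse = ",")
    s2 <- paste(other, collapse = ",")
    if (s1 < s2) s1 else s2
  }, character(1))
  ## drop trivial splits (whole taxon set / single tips)
  sizes <- lengths(pp)
  sort(unique(out[sizes >= 2 & sizes <= ntip - 2]))
}
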