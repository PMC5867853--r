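## Coalescent simulation of gene trees within a species tree, directly in
## coalescent units (CU): within a species-tree edge of length x carrying k
## gene lineages, successive coalescences occur after Exp(k*(k-1)/2) waiting
## times until the edge is exhausted; lineages surviving past the root
## coalesce freely. Zero-length edges and multifurcations both yield hard
## polytomies (no time for within-branch coalescence).

## precompute traversal structures for repeated simulation
.prep_sptree <- function(sp) {
  stopifnot(inherits(sp, "phylo"))
  if (is.null(sp$edge.length))
    stop("species tree must have branch lengths (coalescent units)")
  if (any(sp$edge.length < 0)) stop("negative branch length in species tree")
  if (!ape::is.rooted(sp))
    stop("the coalescent simulator requires a rooted species tree")
  sp <- ape::reorder.phylo(sp, "postorder")
  ntip <- length(sp$tip.label)
  nn <- ntip + sp$Nnode
  E <- sp$edge
  root <- E[nrow(E), 1L]
  depth <- numeric(nn)
  for (i in rev(seq_len(nrow(E))))
    depth[E[i, 2L]] <- depth[E[i, 1L]] + sp$edge.length[i]
  age <- max(depth[seq_len(ntip)]) - depth
  elen <- numeric(nn); elen[root] <- Inf
  children <- vector("list", nn)
  for (i in seq_len(nrow(E))) {
    children[[E[i, 1L]]] <- c(children[[E[i, 1L]]], E[i, 2L])
    elen[E[i, 2L]] <- sp$edge.length[i]
  }
  list(ntip = ntip, nn = nn, root = root, age = age, elen = elen,
       children = children, post = unique(E[, 1L]), tip.label = sp$tip.label)
}

.sim_gene <- function(st) {
  ntip <- st$ntip
  maxnode <- 2L * ntip - 1L
  par_ <- integer(maxnode)
  gtime <- numeric(maxnode)
  nextg <- ntip
  surv <- vector("list", st$nn)
  for (v in c(seq_len(ntip), st$post)) {
    lin <- if (v <= ntip) v else unlist(surv[st$children[[v]]])
    t0 <- st$age[v]; len <- st$elen[v]
    k <- length(lin); tcur <- 0
    while (k > 1L) {
      w <- rexp(1L, rate = k * (k - 1L) / 2)
      if (tcur + w > len) break
      tcur <- tcur + w
      pair <- sample.int(k, 2L)
      nextg <- nextg + 1L
      par_[lin[pair]] <- nextg
      gtime[nextg] <- t0 + tcur
      lin <- c(lin[-pair], nextg)
      k <- k - 1L
    }
    surv[[v]] <- lin
  }
  rootg <- nextg
  newid <- integer(maxnode)
  newid[seq_len(ntip)] <- seq_len(ntip)
  others <- setdiff((ntip + 1L):maxnode, rootg)
  newid[rootg] <- ntip + 1L
  newid[others] <- ntip + 1L + seq_along(others)
  hasp <- which(par_ > 0L)
  g <- list(edge = cbind(newid[par_[hasp]], newid[hasp]),
            edge.length = gtime[par_[hasp]] - gtime[hasp],
            Nnode = ntip - 1L,
            tip.label = st$tip.label)
  class(g) <- "phylo"
  g
}

#' Simulate gene trees under the multi-species coalescent
#'
#' @param species_tree rooted `phylo` with branch lengths in coalescent
#'   units; may be multifurcating (polytomies behave as simultaneous
#'   divergences) and may contain zero-length branches. Node ages are taken
#'   from the tree assuming it is ultrametric.
#' @param n_genes number of independent gene trees (one haploid sample per
#'   species).
#' @param seed integer seed for reproducibility; `NULL` uses the current
#'   RNG state.
#' @return a `multiPhylo` of binary rooted gene trees with coalescent-unit
#'   branch lengths.
#' @export
#' @examples
#' sp <- ape::read.tree(text = "((a:1,b:1):0.5,(c:1.5,d:1.5):0.5);")
#' gs <- simulate_gene_trees(sp, 100, seed = 1)
simulate_gene_trees <- function(species_tree, n_genes, seed = NULL) {
  if (!is.numeric(n_genes) || length(n_genes) != 1L || n_genes < 1)
    stop("n_genes must be a positive integer")
  if (!is.null(seed)) set.seed(seed)
  st <- .prep_sptree(species_tree)
  out <- vector("list", n_genes)
  for (j in seq_len(n_genes)) out[[j]] <- .sim_gene(st)
  class(out) <- "multiPhylo"
  out
}

#' Generate a Yule species tree scaled to coalescent units
#'
#' Simulates a pure-birth (Yule) tree conditioned on `n_taxa` extant tips,
#' rescales it so the root-to-tip height equals `max_height` generations,
#' and converts branch lengths to coalescent units by dividing by
#' `pop_size`.
#'
#' @param n_taxa number of tips (>= 4).
#' @param birth_rate speciation rate per generation (shapes relative branch
#'   lengths through the Yule process).
#' @param max_height tree height in generations.
#' @param pop_size haploid population size.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return an ultrametric binary `phylo` with coalescent-unit branch
#'   lengths and tips labelled `s1..sn`.
#' @export
#' @examples
#' sp <- yule_species_tree(50, 1e-6, 2e6, 2e5, seed = 1)  # height 10 CU
yule_species_tree <- function(n_taxa, birth_rate = 1e-6, max_height = 2e6,
                              pop_size = 2e5, seed = NULL) {
  if (n_taxa < 4L) stop("n_taxa must be at least 4")
  if (birth_rate <= 0 || max_height <= 0 || pop_size <= 0)
    stop("birth_rate, max_height and pop_size must be positive")
  if (!is.null(seed)) set.seed(seed)
  phy <- ape::rphylo(n_taxa, birth = birth_rate, death = 0)
  h <- max(ape::node.depth.edgelength(phy))
  phy$edge.length <- phy$edge.length * (max_height / h) / pop_size
  phy$tip.label <- paste0("s", seq_len(n_taxa))
  phy
}

#' Twelve-taxon species trees with polytomies
#'
#' Fixed 12-taxon model species trees of total height 8 coalescent units
#' used for calibration experiments. Variant `"A"` contains two hard
#' polytomies with three children each, a short 0.2 CU branch (node label
#' `P0`, the parent edge of the first polytomy) and a 1 CU branch (label
#' `P3`, a child edge of that polytomy). Variant `"B"` contains one hard
#' polytomy with five children and a 2 CU branch adjacent to it (label
#' `P7`). Node labels mark the edge above the labelled node. Branch lengths
#' other than the labelled ones are package constants chosen to keep
#' non-focal branches at least 1 CU long.
#'
#' @param variant `"A"` or `"B"`.
#' @return a rooted `phylo` with coalescent-unit branch lengths.
#' @export
s12_fixture <- function(variant = c("A", "B")) {
  variant <- match.arg(variant)
  txt <- if (variant == "A") {
    paste0("((((t1:5.8,t2:5.8)P3:1.0,(t3:5.0,t4:5.0):1.8,t5:6.8)P0:0.2,",
           "t6:7):1,((t9:5,t10:5,(t11:3.5,t12:3.5):1.5):2,",
           "(t7:4,t8:4):3):1);")
  } else {
    paste0("(((t2:5,t3:5,(t4:4,t5:4):1,(t6:3.5,t7:3.5):1.5,t8:5)P7:2,",
           "t1:7):1,((t9:5,t10:5):2,(t11:6,t12:6):1):1);")
  }
  ape::read.tree(text = txt)
}

#' Randomly subsample gene trees without replacement
#'
#' @param gene_trees a `multiPhylo`.
#' @param k subsample size; values above the number of trees are clamped.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a `multiPhylo` of `min(k, length(gene_trees))` trees.
#' @export
subsample_genes <- function(gene_trees, k, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gene_trees <- .as_multiphylo(gene_trees)
  k <- min(k, length(gene_trees))
  out <- gene_trees[sample.int(length(gene_trees), k)]
  class(out) <- "multiPhylo"
  out
}

#' Randomly perturb gene trees by nearest-neighbor interchanges
#'
#' Applies, to each gene tree independently, a Binomial(number of internal
#' edges, `rate`) number of random NNI rearrangements. This is a topological
#' noise surrogate for gene-tree estimation error: it emulates wrongly
#' resolved branches but not the length- and signal-dependent error
#' structure of real tree inference, so results under perturbation
#' characterise robustness to random error only.
#'
#' @param gene_trees a `multiPhylo` of binary gene trees.
#' @param rate expected fraction of internal edges rearranged, in `[0, 1]`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return a `multiPhylo`.
#' @export
perturb_gene_trees <- function(gene_trees, rate, seed = NULL) {
  if (rate < 0 || rate > 1) stop("rate must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  gene_trees <- .as_multiphylo(gene_trees)
  out <- lapply(gene_trees, function(g) {
    n_int <- sum(g$edge[, 2] > length(g$tip.label))
    k <- stats::rbinom(1L, n_int, rate)
    if (k > 0L) phangorn::rNNI(g, moves = k) else g
  })
  class(out) <- "multiPhylo"
  out
}

#' Replicated simulation and per-branch rejection records
#'
#' Runs the full simulation-test pipeline: per replicate, gene trees are
#' simulated under the MSC along `species_tree`; polytomies (if any) are
#' first resolved into one fixed arbitrary binary refinement whose new
#' branches have length zero; for each requested gene count a random
#' subsample is tested with [polytomy_test()] and per-branch outcomes are
#' recorded. True branch lengths in the records are those of the resolved
#' tree, so zero marks a branch resolving a hard polytomy.
#'
#' @param species_tree rooted `phylo` with coalescent-unit branch lengths.
#' @param n_genes number of gene trees simulated per replicate.
#' @param gene_counts gene counts at which the test is run (each a random
#'   subsample of the simulated genes; values above `n_genes` are clamped).
#' @param n_replicates number of independent replicates.
#' @param alpha significance level.
#' @param seed integer seed governing all randomness; `NULL` uses the
#'   current RNG state.
#' @param method quartet aggregation method, see [tally_branches()].
#' @return a data.frame with columns `replicate`, `gene_count`, `branch_id`,
#'   `clade`, `length`, `effective_n`, `chi2`, `p_value`, `applicable`,
#'   `rejected`. The resolved species tree is in attribute
#'   `"resolved_tree"`.
#' @export
run_rejection_experiment <- function(species_tree, n_genes = 1000,
                                     gene_counts = n_genes,
                                     n_replicates = 50, alpha = 0.05,
                                     seed = NULL, method = "mean") {
  if (!is.null(seed)) set.seed(seed)
  gene_counts <- pmin(sort(unique(gene_counts)), n_genes)
  resolved <- resolve_arbitrarily(species_tree)
  res <- vector("list", n_replicates * length(gene_counts))
  i <- 0L
  for (r in seq_len(n_replicates)) {
    genes <- simulate_gene_trees(species_tree, n_genes)
    for (k in gene_counts) {
      sub <- if (k == n_genes) genes else subsample_genes(genes, k)
      tst <- polytomy_test(resolved, sub, alpha = alpha, method = method)
      tab <- tst$table[, c("branch_id", "clade", "length", "effective_n",
                           "chi2", "p_value", "applicable", "rejected")]
      tab <- cbind(replicate = r, gene_count = k, tab)
      i <- i + 1L
      res[[i]] <- tab
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "resolved_tree") <- resolved
  out
}

#' Summarise rejection records
#'
#' Aggregates the output of [run_rejection_experiment()] either per branch
#' (`by = "branch"`) or by binning true branch lengths on the log scale into
#' equal-width bins (`by = "bin"`, zero-length branches get their own bin).
#'
#' @param records data.frame from [run_rejection_experiment()] (or rows of
#'   several, concatenated).
#' @param by aggregation mode.
#' @param n_bins number of log-scale length bins when `by = "bin"`.
#' @param breaks optional explicit bin breaks on the CU (not log) scale;
#'   overrides `n_bins`.
#' @return a data.frame with one row per (group, gene_count): the group
#'   label, `gene_count`, `n_branches`, and `rejected_frac`.
#' @export
rejection_summary <- function(records, by = c("branch", "bin"), n_bins = 20,
                              breaks = NULL) {
  by <- match.arg(by)
  if (by == "branch") {
    grp <- interaction(records$clade, records$gene_count, drop = TRUE)
    agg <- do.call(rbind, lapply(split(records, grp), function(d)
      data.frame(clade = d$clade[1L], length = d$length[1L],
                 gene_count = d$gene_count[1L], n_branches = nrow(d),
                 rejected_frac = mean(d$rejected))))
  } else {
    pos <- records$length > 0
    if (is.null(breaks)) {
      lx <- log(records$length[pos])
      breaks <- exp(seq(min(lx), max(lx), length.out = n_bins + 1L))
      breaks[1L] <- breaks[1L] * (1 - 1e-9)
    }
    records$.bin <- "zero"
    records$.bin[pos] <- as.character(cut(records$length[pos], breaks,
                                          include.lowest = TRUE))
    grp <- interaction(records$.bin, records$gene_count, drop = TRUE)
    agg <- do.call(rbind, lapply(split(records, grp), function(d)
      data.frame(bin = d$.bin[1L],
                 gene_count = d$gene_count[1L], n_branches = nrow(d),
                 mean_length = mean(d$length),
                 rejected_frac = mean(d$rejected))))
    agg <- agg[order(agg$mean_length, agg$gene_count), ]
  }
  rownames(agg) <- NULL
  agg
}
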