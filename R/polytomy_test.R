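## Chi-squared goodness-of-fit test of the equal-frequency polytomy null.
##
## Null hypothesis: the internal branch has length zero, i.e. the gene-tree
## quartets around the branch support the three NNI-equivalent topologies
## in equal numbers (expected frequency n/3 each). The statistic
##   chi2 = sum_i (n_i - n/3)^2 / (n/3),   n = n1 + n2 + n3,
## is asymptotically chi-squared with 2 degrees of freedom; the chi-squared
## approximation for three equiprobable outcomes is adequate for n >= 10,
## so branches with a smaller effective number of genes are flagged as not
## applicable rather than tested.

#' Chi-squared statistic for a quartet frequency tally
#'
#' @param n1,n2,n3 quartet topology tallies (fractional values allowed).
#'   `n1` may also be a list or data.frame holding `n1`, `n2`, `n3` (e.g. a
#'   [tally_branch()] result or [tally_branches()] rows), in which case the
#'   other arguments are ignored.
#' @return the goodness-of-fit statistic against equal expected frequencies
#'   `(n1+n2+n3)/3`; zero iff the three tallies are equal.
#' @export
#' @examples
#' chi2_statistic(150, 75, 75)  # 37.5
chi2_statistic <- function(n1, n2 = NULL, n3 = NULL) {
  if (is.list(n1)) { n2 <- n1$n2; n3 <- n1$n3; n1 <- n1$n1 }
  if (length(n1) != length(n2) || length(n1) != length(n3))
    stop("n1, n2, n3 must have equal length")
  if (any(is.na(c(n1, n2, n3))) || any(c(n1, n2, n3) < 0))
    stop("tallies must be non-negative numbers")
  n <- n1 + n2 + n3
  if (any(n == 0)) stop("all-zero tally: no resolved quartets to test")
  e <- n / 3
  (n1 - e)^2 / e + (n2 - e)^2 / e + (n3 - e)^2 / e
}

#' p-value of the polytomy test statistic
#'
#' Upper-tail probability of a chi-squared distribution with 2 degrees of
#' freedom, which has the closed form `exp(-chi2 / 2)`.
#'
#' @param chi2 non-negative statistic (vectorised).
#' @return p-value(s) in `[0, 1]`.
#' @export
polytomy_pvalue <- function(chi2) {
  if (any(is.na(chi2)) || any(chi2 < 0))
    stop("chi2 must be non-negative")
  pchisq(chi2, df = 2, lower.tail = FALSE)
}

#' Test every internal branch of a species tree for a polytomy
#'
#' Tallies quartet topology frequencies around each internal branch of the
#' species tree across the gene trees (see [tally_branches()]) and applies
#' the chi-squared test. Branches whose effective number of genes is below
#' 10 are reported but flagged `applicable = FALSE`: the chi-squared
#' approximation is unreliable there and downstream collapsing treats them
#' as non-rejections.
#'
#' @param species_tree a `phylo` object with at least four taxa.
#' @param gene_trees a `multiPhylo`; taxa must be a subset of the species
#'   tree's taxa. Gene trees may be incomplete and multifurcating.
#' @param alpha significance level recorded in the result (used by
#'   [collapse_nonrejected()] and the `rejected` column).
#' @param correction multiple-testing correction applied across applicable
#'   branches: `"none"` (default), `"bonferroni"`, or `"bh"`
#'   (Benjamini-Hochberg FDR).
#' @param method quartet aggregation method, see [tally_branches()].
#' @return an object of class `polytomy_test`: a list with `table` (one row
#'   per internal branch: `branch_id`, `edge`, `clade`, `length`, `n1`,
#'   `n2`, `n3`, `effective_n`, `chi2`, `p_value`, `applicable`,
#'   `adjusted_p`, `rejected`), `tree` (the unrooted species tree the edge
#'   indices refer to), `alpha`, `method`, and `n_genes`.
#' @export
#' @examples
#' sp <- ape::read.tree(text = "((a,b),(c,d));")
#' gs <- rep(c(ape::read.tree(text = "((a,b),(c,d));")), 10)
#' polytomy_test(sp, gs)
polytomy_test <- function(species_tree, gene_trees, alpha = 0.05,
                          correction = c("none", "bonferroni", "bh"),
                          method = c("mean", "single", "median")) {
  correction <- match.arg(correction)
  method <- match.arg(method)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number in (0, 1)")
  gene_trees <- .as_multiphylo(gene_trees)
  taxa <- species_tree$tip.label
  for (g in gene_trees) .check_gene_taxa(g, taxa)

  tab <- tally_branches(species_tree, gene_trees, method = method)
  n <- tab$n1 + tab$n2 + tab$n3
  ok <- n > 0
  tab$chi2 <- NA_real_
  tab$chi2[ok] <- chi2_statistic(tab$n1[ok], tab$n2[ok], tab$n3[ok])
  tab$p_value <- NA_real_
  tab$p_value[ok] <- polytomy_pvalue(tab$chi2[ok])
  tab$applicable <- tab$effective_n >= 10L
  tab$adjusted_p <- NA_real_
  if (correction != "none") {
    meth <- c(bonferroni = "bonferroni", bh = "BH")[[correction]]
    app <- tab$applicable & !is.na(tab$p_value)
    tab$adjusted_p[app] <- p.adjust(tab$p_value[app], method = meth)
  }
  p_eff <- if (correction == "none") tab$p_value else tab$adjusted_p
  tab$rejected <- tab$applicable & !is.na(p_eff) & p_eff <= alpha

  out <- list(table = tab, tree = attr(tab, "tree"), alpha = alpha,
              method = method, correction = correction,
              n_genes = length(gene_trees))
  class(out) <- "polytomy_test"
  out
}

#' @export
print.polytomy_test <- function(x, ...) {
  tab <- x$table
  cat(sprintf(
    "Polytomy test: %d internal branches, %d gene trees (method: %s)\n",
    nrow(tab), x$n_genes, x$method))
  cat(sprintf("effective n across branches: min %d / median %g / max %d\n",
              min(tab$effective_n), stats::median(tab$effective_n),
              max(tab$effective_n)))
  cat(sprintf("rejected at alpha = %g: %d of %d applicable branches\n",
              x$alpha, sum(tab$rejected), sum(tab$applicable)))
  show <- tab[, c("branch_id", "clade", "length", "n1", "n2", "n3",
                  "effective_n", "chi2", "p_value", "applicable")]
  show$clade <- ifelse(nchar(show$clade) > 28,
                       paste0(substr(show$clade, 1, 25), "..."), show$clade)
  num <- vapply(show, is.numeric, logical(1L))
  show[num] <- lapply(show[num], signif, digits = 4L)
  print(show, row.names = FALSE)
  invisible(x)
}
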