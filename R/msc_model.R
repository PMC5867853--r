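## Closed-form multi-species coalescent (MSC) quartet probabilities, power
## analysis, and deviation models (skewed alternate frequencies; gene flow).
##
## For an unrooted quartet species tree ab|cd whose internal branch has
## length x in coalescent units (CU; generations divided by the haploid
## population size), a gene tree matches the species tree topology with
## probability p1 = 1 - (2/3) exp(-x) and each alternative with
## p2 = p3 = (1/3) exp(-x). At x = 0 all three topologies are equally
## likely, which is the null hypothesis of the polytomy test.

#' MSC quartet topology probabilities
#'
#' @param x internal branch length in coalescent units (>= 0, vectorised).
#' @return a data.frame with columns `x`, `p1`, `p2`, `p3` where
#'   `p1 = 1 - (2/3) exp(-x)` and `p2 = p3 = (1/3) exp(-x)`.
#' @export
#' @examples
#' quartet_probs(0)    # 1/3, 1/3, 1/3
#' quartet_probs(0.1)  # p1 ~ 0.3968
quartet_probs <- function(x) {
  if (any(is.na(x)) || any(x < 0))
    stop("branch length x must be non-negative (coalescent units)")
  p2 <- exp(-x) / 3
  data.frame(x = x, p1 = 1 - 2 * p2, p2 = p2, p3 = p2)
}

#' Hoeffding bound on quartet frequency deviation
#'
#' Upper bound `2 exp(-2 eps^2 n)` (capped at 1) on the probability that an
#' observed quartet topology frequency deviates from its expectation by more
#' than `eps` over `n` gene trees.
#'
#' @param eps deviation, in (0, 1].
#' @param n number of gene trees (>= 1).
#' @return the bound, in `[0, 1]`.
#' @export
hoeffding_bound <- function(eps, n) {
  if (any(eps <= 0) || any(eps > 1)) stop("eps must be in (0, 1]")
  if (any(n < 1)) stop("n must be >= 1")
  pmin(1, 2 * exp(-2 * eps^2 * n))
}

#' Expected chi-squared statistic when observations match MSC expectations
#'
#' Evaluates the test statistic at `n_i = n * p_i(x)`, which simplifies to
#' `2 n (1 - exp(-x))^2`.
#'
#' @param x branch length in coalescent units (>= 0).
#' @param n number of genes (>= 1).
#' @return the statistic (vectorised over `x` and/or `n`).
#' @export
expected_chi2 <- function(x, n) {
  if (any(x < 0)) stop("branch length x must be non-negative")
  if (any(n < 1)) stop("n must be >= 1")
  2 * n * (1 - exp(-x))^2
}

#' Minimum number of genes needed to reject a polytomy
#'
#' The smallest integer n for which the polytomy test yields
#' `p <= alpha` when the observed quartet frequencies exactly equal the MSC
#' expectations for a branch of length `x`: the closed form is
#' `ceiling(qchisq(1 - alpha, df = 2) / (2 (1 - exp(-x))^2))`.
#'
#' @param x branch length in coalescent units (> 0).
#' @param alpha significance level in (0, 1).
#' @return integer number of genes (vectorised over `x`).
#' @export
#' @examples
#' min_genes_to_reject(0.1)   # 331
#' min_genes_to_reject(0.02)  # 7641
min_genes_to_reject <- function(x, alpha = 0.05) {
  if (any(x <= 0))
    stop("a zero-length branch can never be rejected; x must be > 0")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  crit <- qchisq(1 - alpha, df = 2)
  n <- ceiling(crit / (2 * (1 - exp(-x))^2))
  ## guard against an exact boundary landing a hair above alpha
  adj <- polytomy_pvalue(expected_chi2(x, n)) > alpha
  as.integer(n + adj)
}

#' Required-genes table over a grid of branch lengths
#'
#' @param x branch lengths in coalescent units (> 0).
#' @param alpha one or more significance levels.
#' @return data.frame with columns `x`, `alpha`, `n_genes`.
#' @export
power_table <- function(x = signif(10^seq(log10(0.01), log10(0.3),
                                          length.out = 25), 3),
                        alpha = c(0.05, 0.01)) {
  out <- expand.grid(x = x, alpha = alpha)
  out$n_genes <- mapply(function(xx, aa) min_genes_to_reject(xx, aa),
                        out$x, out$alpha)
  out
}

#' Quartet frequencies with skewed alternate topologies
#'
#' A deviation from the MSC in which the discordant mass `(2/3) exp(-x)` is
#' split between the two alternate topologies in ratio `skew : 1` instead of
#' equally; `skew = 1.2` makes the second topology 20% more frequent than
#' the third (the 6/11 vs 5/11 split).
#'
#' @param x branch length in coalescent units (>= 0).
#' @param skew ratio `p2 / p3` (> 0); `skew = 1` recovers [quartet_probs()].
#' @return data.frame with columns `x`, `p1`, `p2`, `p3`.
#' @export
skewed_probs <- function(x, skew = 1.2) {
  if (any(x < 0)) stop("branch length x must be non-negative")
  if (!is.numeric(skew) || any(skew <= 0)) stop("skew must be > 0")
  disc <- 2 * exp(-x) / 3
  data.frame(x = x,
             p1 = 1 - disc,
             p2 = disc * skew / (1 + skew),
             p3 = disc / (1 + skew))
}

#' Quartet frequencies under MSC with gene flow
#'
#' Mixture model for a quartet species tree with a hybridization at its
#' base: a fraction `lambda` of gene lineages follows the gene-flow edge.
#' The species-topology frequency is
#' \deqn{p_1 = (1-\lambda)^2 (1 - \tfrac23 e^{-x})
#'   + 2\lambda(1-\lambda)(1 - e^{-x/2} + \tfrac13 e^{-(x+4)})
#'   + \lambda^2 (1 - \tfrac23 e^{-x/2})}
#' and the two alternates split the rest equally,
#' `p2 = p3 = (1 - p1) / 2`. The constant 4 in the middle exponent is the
#' (fixed) length contribution of the network branches in the source model
#' and can be overridden via `network_const`.
#'
#' For short branches, combined ILS and gene flow can push `p1` to exactly
#' 1/3, a regime the polytomy test cannot distinguish from a true polytomy.
#'
#' @param x branch length in coalescent units (>= 0).
#' @param lambda inheritance probability in `[0, 1]`; `lambda = 0` recovers
#'   [quartet_probs()].
#' @param network_const additive constant in the middle term's exponent.
#' @return data.frame with columns `x`, `lambda`, `p1`, `p2`, `p3`.
#' @export
gene_flow_probs <- function(x, lambda, network_const = 4) {
  if (any(x < 0)) stop("branch length x must be non-negative")
  if (any(lambda < 0) || any(lambda > 1)) stop("lambda must be in [0, 1]")
  p1 <- (1 - lambda)^2 * (1 - 2 / 3 * exp(-x)) +
    2 * lambda * (1 - lambda) *
      (1 - exp(-x / 2) + exp(-(x + network_const)) / 3) +
    lambda^2 * (1 - 2 / 3 * exp(-x / 2))
  if (any(p1 < 0 | p1 > 1))
    stop("mis-parameterization: p1 outside [0, 1]")
  data.frame(x = x, lambda = lambda, p1 = p1,
             p2 = (1 - p1) / 2, p3 = (1 - p1) / 2)
}

#' Convert between generations and coalescent units
#'
#' A coalescent unit is the number of generations divided by the haploid
#' population size. These helpers are never applied implicitly.
#'
#' @param generations branch length in generations.
#' @param cu branch length in coalescent units.
#' @param pop_size haploid population size.
#' @return converted length(s).
#' @export
generations_to_cu <- function(generations, pop_size) {
  if (any(pop_size <= 0)) stop("pop_size must be positive")
  generations / pop_size
}

#' @rdname generations_to_cu
#' @export
cu_to_generations <- function(cu, pop_size) {
  if (any(pop_size <= 0)) stop("pop_size must be positive")
  cu * pop_size
}
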