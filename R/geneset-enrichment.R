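# Family / cluster over-representation engine: contingency construction,
# Fisher's exact test, the enrichment-ratio statistic, and the
# random-sampling permutation test with Monte-Carlo P, OR and CI.

#' Build the contingency counts for one family-enrichment test
#'
#' From a DEG set, a gene family and the background universe, computes
#' `a` = family genes among the DEGs, `m` = family genes in the background,
#' `k` = DEGs in the background, `N` = background size.  DEGs not present
#' in the background are dropped with a warning; the family is intersected
#' with the background silently.
#'
#' @param degs character vector of DEG symbols.
#' @param family character vector of family member symbols.
#' @param background character vector: the gene universe.
#' @return a list of class `contingency`: `a`, `m`, `k`, `N`.
#' @export
build_contingency <- function(degs, family, background) {
  background <- unique(background)
  if (!length(background)) stop("empty background", call. = FALSE)
  degs <- unique(degs)
  outside <- setdiff(degs, background)
  if (length(outside)) {
    warning(length(outside), " DEG(s) not in background dropped: ",
            paste(utils::head(outside, 5L), collapse = ", "),
            call. = FALSE)
    degs <- intersect(degs, background)
  }
  fam <- intersect(unique(family), background)
  contingency(a = length(intersect(degs, fam)), m = length(fam),
              k = length(degs), N = length(background))
}

#' Construct a contingency object from raw counts
#'
#' @param a family genes among the DEGs.
#' @param m family size within the background.
#' @param k number of DEGs.
#' @param N background size.
#' @return a list of class `contingency`.
#' @export
contingency <- function(a, m, k, N) {
  a <- as.integer(a); m <- as.integer(m); k <- as.integer(k); N <- as.integer(N)
  if (any(c(a, m, k, N) < 0) || a > min(m, k) || m > N || k > N) {
    stop("invalid contingency counts: need 0 <= a <= min(m, k), m <= N, ",
         "k <= N", call. = FALSE)
  }
  structure(list(a = a, m = m, k = k, N = N), class = "contingency")
}

#' Fisher's exact test for family over-representation
#'
#' Two-sided exact test on the 2x2 table
#' `[[a, m - a], [k - a, N - m - (k - a)]]` via [stats::fisher.test()].
#' The reported point estimate is the sample odds ratio
#' `a (N - m - k + a) / ((m - a)(k - a))`, with the conventions 0 when
#' `a = 0` and infinite when a zero cell makes the ratio diverge; the CI is
#' the exact conditional interval from `fisher.test`.
#'
#' @param tab a [contingency()] object.
#' @return a list: `p_value`, `sample_or`, `ci_lower`, `ci_upper`.
#' @export
fisher_enrichment <- function(tab) {
  stopifnot(inherits(tab, "contingency"))
  a <- tab$a; b <- tab$m - tab$a; c <- tab$k - tab$a
  d <- tab$N - tab$m - tab$k + tab$a
  ft <- stats::fisher.test(matrix(c(a, c, b, d), nrow = 2L))
  sample_or <- if (a == 0L) {
    0
  } else if (b == 0L || c == 0L) {
    Inf
  } else {
    (a * d) / (b * c)
  }
  list(p_value = ft$p.value, sample_or = sample_or,
       ci_lower = ft$conf.int[1L], ci_upper = ft$conf.int[2L])
}

#' Enrichment ratio: DEG fraction inside vs outside the family
#'
#' `(a / m) / ((k - a) / (N - m))` — the proportion of family genes that
#' are differential, divided by the proportion of non-family background
#' genes that are differential.  Returns 0 when `a = 0`, `Inf` when every
#' DEG is a family gene (`k = a`, `a > 0`), and `NA` (not evaluable) when
#' the family has no background representation (`m = 0`).
#'
#' @param tab a [contingency()] object.
#' @return a single numeric ratio.
#' @export
enrichment_ratio <- function(tab) {
  stopifnot(inherits(tab, "contingency"))
  if (tab$m == 0L) return(NA_real_)
  if (tab$a == 0L) return(0)
  if (tab$k == tab$a) return(Inf)
  (tab$a / tab$m) / ((tab$k - tab$a) / (tab$N - tab$m))
}

#' Random-sampling permutation test for family enrichment
#'
#' Simulates `reps` datasets, each drawing the same number of DEGs (`k`)
#' uniformly without replacement from the `N` background genes, and records
#' how many fall in the family.  The Monte-Carlo P is the fraction of
#' simulated family counts at least as large as the observed `a` (raw
#' count / reps estimator; a zero count is reported as the bound
#' `"< 1/reps"` in `p_label`).  The permutation odds ratio is the observed
#' count over the mean simulated count, with a normal-approximation CI from
#' the standard error of that mean.
#'
#' Drawing the family-overlap count from the hypergeometric law is
#' mathematically identical to sampling k-subsets and is the default;
#' `mode = "subset"` performs literal subset sampling for validation at
#' small `reps`.
#'
#' @param tab a [contingency()] object.
#' @param reps number of simulated datasets (>= 1000).
#' @param seed integer seed; results are deterministic per seed.
#' @param mode `"hypergeometric"` (default) or `"subset"`.
#' @param alternative `"greater"` (enrichment, default) or `"less"`
#'   (depletion).
#' @return a list: `p_value`, `p_label`, `or`, `ci_lower`, `ci_upper`,
#'   `mean_count`, `reps`, `seed`.
#' @export
permutation_enrichment <- function(tab, reps = 1e6, seed = 1L,
                                   mode = c("hypergeometric", "subset"),
                                   alternative = c("greater", "less")) {
  stopifnot(inherits(tab, "contingency"))
  mode <- match.arg(mode)
  alternative <- match.arg(alternative)
  if (reps < 1000) stop("`reps` must be at least 1000", call. = FALSE)
  if (tab$m == 0L || tab$k == 0L) {
    stop("not evaluable: family or DEG set has no background overlap",
         call. = FALSE)
  }
  set.seed(seed)
  counts <- if (mode == "hypergeometric") {
    stats::rhyper(reps, m = tab$m, n = tab$N - tab$m, k = tab$k)
  } else {
    replicate(reps, {
      draw <- sample.int(tab$N, tab$k)
      sum(draw <= tab$m)  # first m background indices are the family
    })
  }
  hits <- if (alternative == "greater") sum(counts >= tab$a)
          else sum(counts <= tab$a)
  p <- hits / reps
  p_label <- if (hits == 0L) sprintf("< %g", 1 / reps) else format(p)
  mean_count <- mean(counts)
  se <- stats::sd(counts) / sqrt(reps)
  or <- tab$a / mean_count
  ci <- if (tab$a == 0L) {
    c(0, 0)
  } else {
    c(tab$a / (mean_count + 1.96 * se), tab$a / (mean_count - 1.96 * se))
  }
  list(p_value = p, p_label = p_label, or = or,
       ci_lower = ci[1L], ci_upper = ci[2L],
       mean_count = mean_count, reps = as.integer(reps),
       seed = as.integer(seed))
}

#' Family enrichment over several DEG lists and gene sets
#'
#' Runs [build_contingency()], [fisher_enrichment()], [enrichment_ratio()]
#' and [permutation_enrichment()] for every (DEG list, family) pair and
#' assembles one results table, one row per pair, in input order.
#'
#' @param deg_sets named list of DEG character vectors (one per DE method).
#' @param gene_sets named list of family character vectors (e.g. from
#'   [read_gmt()]).
#' @param background the gene universe.
#' @param reps permutation replicates.
#' @param seed root seed; each pair uses a distinct derived seed so rows
#'   are reproducible independently of evaluation order.
#' @return a data frame with columns `deg_list`, `family`, `m`, `a`, `k`,
#'   `N`, `fisher_p`, `enrichment_ratio`, `fisher_ci_lower`,
#'   `fisher_ci_upper`, `perm_p`, `perm_p_label`, `perm_or`,
#'   `perm_ci_lower`, `perm_ci_upper`.
#' @export
enrich_families <- function(deg_sets, gene_sets, background,
                            reps = 1e6, seed = 1L) {
  if (!length(deg_sets) || !length(gene_sets)) {
    stop("need at least one DEG list and one gene set", call. = FALSE)
  }
  if (is.null(names(deg_sets)) || is.null(names(gene_sets))) {
    stop("`deg_sets` and `gene_sets` must be named", call. = FALSE)
  }
  rows <- list()
  i <- 0L
  for (dn in names(deg_sets)) {
    for (fn in names(gene_sets)) {
      i <- i + 1L
      tab <- build_contingency(deg_sets[[dn]], gene_sets[[fn]], background)
      fi <- fisher_enrichment(tab)
      er <- enrichment_ratio(tab)
      pe <- if (tab$m > 0L && tab$k > 0L) {
        permutation_enrichment(tab, reps = reps, seed = seed + i)
      } else {
        list(p_value = NA_real_, p_label = NA_character_, or = NA_real_,
             ci_lower = NA_real_, ci_upper = NA_real_)
      }
      rows[[i]] <- data.frame(
        deg_list = dn, family = fn,
        m = tab$m, a = tab$a, k = tab$k, N = tab$N,
        fisher_p = fi$p_value, enrichment_ratio = er,
        fisher_ci_lower = fi$ci_lower, fisher_ci_upper = fi$ci_upper,
        perm_p = pe$p_value, perm_p_label = pe$p_label,
        perm_or = pe$or, perm_ci_lower = pe$ci_lower,
        perm_ci_upper = pe$ci_upper,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
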