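# Threshold-based DEG calling on a normalized expression matrix:
# expressed-gene filter, low-expression exclusion, equal-variance t-test
# on log2(x + 1) with a |log2FC| cut.

.check_expr <- function(expr) {
  if (is.null(expr$values) || !is.matrix(expr$values) ||
      nrow(expr$values) == 0L || ncol(expr$values) == 0L) {
    stop("empty or malformed expression matrix", call. = FALSE)
  }
  if (anyDuplicated(rownames(expr$values)) ||
      anyDuplicated(colnames(expr$values))) {
    stop("duplicate gene or sample identifiers", call. = FALSE)
  }
  if (any(expr$values < 0)) {
    stop("expression values must be nonnegative", call. = FALSE)
  }
  invisible(TRUE)
}

#' Keep genes expressed in more than 20% of samples
#'
#' A gene counts as expressed when its normalized value is greater than 0
#' in strictly more than `min_frac` of all samples (default 20%); a gene
#' positive in exactly 20% of samples is removed.
#'
#' @param expr a list with `values` (genes x samples matrix) and `group`
#'   (two-level factor per sample), as from [simulate_expression()] or
#'   [read_expression()].
#' @param min_frac expressed-fraction threshold (strict).
#' @return `expr` with non-expressed genes removed.
#' @export
filter_expressed <- function(expr, min_frac = 0.20) {
  .check_expr(expr)
  frac_pos <- rowMeans(expr$values > 0)
  expr$values <- expr$values[frac_pos > min_frac, , drop = FALSE]
  expr
}

#' Exclude genes with low expression in both groups
#'
#' Removes genes whose mean normalized expression is below `min_level`
#' (strictly) in both groups; one group at or above the level suffices to
#' retain the gene.  Low-level genes carry little statistical credibility
#' in the downstream t-test.
#'
#' @param expr expression list with a two-level `group` factor.
#' @param min_level group-mean threshold, default 5.
#' @return `expr` with low-level genes removed.
#' @export
filter_min_level <- function(expr, min_level = 5) {
  .check_expr(expr)
  g <- .two_groups(expr)
  mean_a <- rowMeans(expr$values[, g$a, drop = FALSE])
  mean_b <- rowMeans(expr$values[, g$b, drop = FALSE])
  keep <- !(mean_a < min_level & mean_b < min_level)
  expr$values <- expr$values[keep, , drop = FALSE]
  expr
}

.two_groups <- function(expr) {
  group <- factor(expr$group)
  if (nlevels(group) != 2L) {
    stop("`group` must have exactly two levels", call. = FALSE)
  }
  lev <- levels(group)
  list(a = group == lev[1], b = group == lev[2], levels = lev)
}

#' Call differentially expressed genes between two groups
#'
#' Classical equal-variance two-sample t-test (two-tailed) per gene on
#' log2(value + 1), with the fold change computed from raw group means with
#' a pseudocount of 1: `log2fc = log2((mean_A + 1) / (mean_B + 1))`.  A
#' gene passes when `p_value <= max_p` and `|log2fc| >= min_abs_log2fc`
#' (defaults 0.05 and 1).  No multiple-testing correction is applied; the
#' threshold pair is the decision rule.
#'
#' @param expr filtered expression list (both groups need >= 2 samples).
#' @param max_p raw P-value threshold.
#' @param min_abs_log2fc absolute log2 fold-change threshold.
#' @return a data frame sorted by `p_value`: `gene`, `log2fc`, `p_value`,
#'   `direction` (`"up"` when group A exceeds group B), `passed`.
#' @export
call_degs <- function(expr, max_p = 0.05, min_abs_log2fc = 1) {
  .check_expr(expr)
  g <- .two_groups(expr)
  if (sum(g$a) < 2L || sum(g$b) < 2L) {
    stop("each group needs at least two samples", call. = FALSE)
  }
  la <- log2(expr$values[, g$a, drop = FALSE] + 1)
  lb <- log2(expr$values[, g$b, drop = FALSE] + 1)
  na <- ncol(la); nb <- ncol(lb)
  ma <- rowMeans(la); mb <- rowMeans(lb)
  va <- apply(la, 1L, stats::var); vb <- apply(lb, 1L, stats::var)
  sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(abs(tstat), df = na + nb - 2, lower.tail = FALSE)
  p[!is.finite(tstat)] <- NA_real_
  p[se == 0 & ma == mb] <- 1  # identical constant gene: no evidence
  log2fc <- log2((rowMeans(expr$values[, g$a, drop = FALSE]) + 1) /
                   (rowMeans(expr$values[, g$b, drop = FALSE]) + 1))
  out <- data.frame(
    gene = rownames(expr$values),
    log2fc = unname(log2fc),
    p_value = unname(p),
    direction = ifelse(log2fc >= 0, "up", "down"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out$passed <- !is.na(out$p_value) & out$p_value <= max_p &
    abs(out$log2fc) >= min_abs_log2fc
  out[order(out$p_value), , drop = FALSE]
}

#' Read an externally produced DEG list
#'
#' Accepts either a plain one-gene-per-line file or a TSV whose first
#' column is the gene symbol (e.g. a rank-based DE caller's output).
#' Duplicates are removed with a warning; order of first appearance is
#' preserved.
#'
#' @param path path to the gene-list file.
#' @return character vector of unique gene symbols.
#' @export
read_deg_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty DEG list: ", path, call. = FALSE)
  genes <- vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, "", 1L)
  if (anyDuplicated(genes)) {
    warning(sum(duplicated(genes)), " duplicate gene(s) removed from ",
            basename(path), call. = FALSE)
    genes <- genes[!duplicated(genes)]
  }
  genes
}
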