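# Unprocessed 18S/28S rRNA fractions from qPCR Ct tables.
#
# Each rRNA species is measured by one "total" amplicon and two
# spacer-containing "unprocessed" amplicons; at 100% amplification
# efficiency the relative quantity of amplicon X over amplicon Y is
# 2^(Ct_Y - Ct_X), and the unprocessed fraction of a species is the mean
# of its two unprocessed-over-total ratios.

#' Relative quantity of one amplicon over another from Ct values
#'
#' Replicate Cts are averaged per amplicon before ratioing; the ratio is
#' `efficiency^(mean_ct_den - mean_ct_num)` (default efficiency 2, i.e.
#' a perfect doubling per cycle).
#'
#' @param ct_num replicate Ct values of the numerator amplicon.
#' @param ct_den replicate Ct values of the denominator amplicon.
#' @param efficiency per-cycle amplification factor.
#' @return the relative quantity ratio (numerator over denominator).
#' @export
amplicon_ratio <- function(ct_num, ct_den, efficiency = 2) {
  if (!length(ct_num) || !length(ct_den)) {
    stop("missing Ct values for an amplicon", call. = FALSE)
  }
  efficiency^(mean(ct_den) - mean(ct_num))
}

#' Unprocessed rRNA fraction for one sample and species
#'
#' For 18S the fraction is the mean of the quantity ratios
#' pair_4_3/pair_2_1 and pair_6_5/pair_2_1 (unprocessed over total); for
#' 28S, pair_d_c/pair_b_a and pair_f_e/pair_b_a.  The result is invariant
#' to any additive Ct shift applied to all of a sample's amplicons, so no
#' reference-gene normalization is needed.
#'
#' @param ct_table long-format Ct table with columns `sample`, `species`,
#'   `amplicon`, `ct` (as from [simulate_qpcr()] or [read_ct_table()]).
#' @param sample sample identifier.
#' @param species `"18S"` or `"28S"`.
#' @param efficiency per-cycle amplification factor.
#' @return a list of class `processing_rate`: `sample`, `species`,
#'   `unprocessed_fraction`, `component_ratios` (the two
#'   unprocessed-over-total ratios).
#' @export
unprocessed_fraction <- function(ct_table, sample, species = c("18S", "28S"),
                                 efficiency = 2) {
  species <- match.arg(species)
  amps <- QPCR_AMPLICONS[[species]]
  sub <- ct_table[ct_table$sample == sample & ct_table$species == species, ]
  get_ct <- function(amp) {
    ct <- sub$ct[sub$amplicon == amp]
    if (!length(ct)) {
      stop("missing amplicon \"", amp, "\" for sample ", sample, " (",
           species, ")", call. = FALSE)
    }
    ct
  }
  ct_total <- get_ct(amps$total)
  ratios <- vapply(amps$unprocessed, function(amp) {
    amplicon_ratio(get_ct(amp), ct_total, efficiency = efficiency)
  }, numeric(1))
  structure(list(
    sample = sample, species = species,
    unprocessed_fraction = mean(ratios),
    component_ratios = ratios
  ), class = "processing_rate")
}

#' Unprocessed fractions for every (sample, species) in a Ct table
#'
#' @param ct_table long-format Ct table.
#' @param efficiency per-cycle amplification factor.
#' @return a data frame: `sample`, `species`, `unprocessed_fraction`,
#'   `ratio_1`, `ratio_2`.
#' @export
processing_rates <- function(ct_table, efficiency = 2) {
  combos <- unique(ct_table[c("sample", "species")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    r <- unprocessed_fraction(ct_table, combos$sample[i],
                              combos$species[i], efficiency = efficiency)
    data.frame(sample = r$sample, species = r$species,
               unprocessed_fraction = r$unprocessed_fraction,
               ratio_1 = unname(r$component_ratios[1L]),
               ratio_2 = unname(r$component_ratios[2L]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Normalize unprocessed fractions to a control group
#'
#' Divides each sample's unprocessed fraction by the mean fraction of the
#' control group (per species), so the control mean normalizes to 1 —
#' the usual condition-vs-control fold-change presentation.
#'
#' @param rates data frame from [processing_rates()] plus a `group` column.
#' @param control_label the control group label.
#' @return `rates` with an added `fold_change` column.
#' @export
fold_change_vs_control <- function(rates, control_label) {
  if (!"group" %in% names(rates)) {
    stop("`rates` needs a `group` column", call. = FALSE)
  }
  if (!any(rates$group == control_label)) {
    stop("control group \"", control_label, "\" is empty", call. = FALSE)
  }
  out <- rates
  out$fold_change <- NA_real_
  for (sp in unique(rates$species)) {
    in_sp <- rates$species == sp
    ctrl_mean <- mean(rates$unprocessed_fraction[in_sp &
                                                   rates$group == control_label])
    if (!is.finite(ctrl_mean) || ctrl_mean == 0) {
      stop("control-group mean fraction is zero for ", sp, call. = FALSE)
    }
    out$fold_change[in_sp] <- rates$unprocessed_fraction[in_sp] / ctrl_mean
  }
  out
}
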