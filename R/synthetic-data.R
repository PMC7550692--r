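# Synthetic cohort / expression / qPCR generators with planted structure.
# Every downstream stage of the pipeline can be exercised against these
# without any external patient-level data.

DRIVER_GENES <- c("KRAS", "TP53", "SMAD4", "CDKN2A")

#' Parameters for the synthetic PDAC cohort generator
#'
#' Defaults for the marginal driver-mutation frequencies are the values
#' observed in the combined TCGA / PACA-AU / PACA-CA PDAC cohort
#' (KRAS 90.43%, TP53 69.13%, SMAD4 23.21%, CDKN2A 20.66%).  Hazard ratios,
#' the co-occurrence log-odds and the baseline/censoring hazards are
#' simulation knobs: the defaults plant the qualitative structure in which
#' TP53 mutation doubles the event hazard while SMAD4 and CDKN2A are
#' prognostically neutral but co-occur with TP53, so that their marginal
#' survival association is confounding, not causation.
#'
#' @param n_patients number of patients to simulate.
#' @param freq_kras,freq_tp53,freq_smad4,freq_cdkn2a marginal mutation
#'   probabilities in `[0, 1]`.
#' @param co_occurrence_logodds log-odds shift applied to the SMAD4 and
#'   CDKN2A mutation probability in TP53-mutant patients.  The intercept is
#'   recalibrated so the requested marginal frequency is preserved.
#' @param hr_tp53,hr_smad4,hr_cdkn2a multiplicative hazard ratios (> 0) for
#'   each mutated gene.
#' @param baseline_hazard event hazard per month for a patient with no
#'   hazard-modifying mutation.
#' @param censor_rate hazard per month of independent exponential censoring.
#' @param seed integer seed; fixed seed gives bit-identical cohorts.
#' @return an object of class `cohort_params`.
#' @export
cohort_params <- function(n_patients = 762,
                          freq_kras = 0.9043,
                          freq_tp53 = 0.6913,
                          freq_smad4 = 0.2321,
                          freq_cdkn2a = 0.2066,
                          co_occurrence_logodds = 1.5,
                          hr_tp53 = 2,
                          hr_smad4 = 1,
                          hr_cdkn2a = 1,
                          baseline_hazard = 0.04,
                          censor_rate = 0.015,
                          seed = 1L) {
  p <- list(
    n_patients = n_patients,
    freq_kras = freq_kras, freq_tp53 = freq_tp53,
    freq_smad4 = freq_smad4, freq_cdkn2a = freq_cdkn2a,
    co_occurrence_logodds = co_occurrence_logodds,
    hr_tp53 = hr_tp53, hr_smad4 = hr_smad4, hr_cdkn2a = hr_cdkn2a,
    baseline_hazard = baseline_hazard, censor_rate = censor_rate,
    seed = as.integer(seed)
  )
  if (!is.numeric(n_patients) || length(n_patients) != 1L ||
      n_patients < 1 || n_patients != round(n_patients)) {
    stop("`n_patients` must be a positive integer", call. = FALSE)
  }
  freqs <- c(freq_kras, freq_tp53, freq_smad4, freq_cdkn2a)
  if (any(!is.finite(freqs)) || any(freqs < 0) || any(freqs > 1)) {
    stop("mutation frequencies must lie in [0, 1]", call. = FALSE)
  }
  hrs <- c(hr_tp53, hr_smad4, hr_cdkn2a)
  if (any(!is.finite(hrs)) || any(hrs <= 0)) {
    stop("hazard ratios must be strictly positive", call. = FALSE)
  }
  if (baseline_hazard <= 0 || censor_rate <= 0) {
    stop("`baseline_hazard` and `censor_rate` must be > 0", call. = FALSE)
  }
  structure(p, class = "cohort_params")
}

# Intercept b such that E_tp53[ plogis(b + logodds * tp53) ] = target,
# with tp53 ~ Bernoulli(p_tp53).  Keeps the marginal frequency of a
# co-occurring gene at its requested value while inducing dependence.
.cooccurrence_intercept <- function(target, logodds, p_tp53) {
  if (target <= 0) return(-Inf)
  if (target >= 1) return(Inf)
  f <- function(b) {
    (1 - p_tp53) * stats::plogis(b) + p_tp53 * stats::plogis(b + logodds) - target
  }
  stats::uniroot(f, lower = -50, upper = 50, tol = 1e-12)$root
}

#' Simulate a PDAC-like cohort of mutations and survival outcomes
#'
#' Draws per-patient driver-mutation statuses with the requested marginal
#' frequencies (KRAS independent; SMAD4 and CDKN2A conditioned on TP53
#' status through a logistic link), then survival times from an exponential
#' proportional-hazards model whose rate is `baseline_hazard` times the
#' product of the hazard ratios of the patient's mutated genes, with
#' independent exponential censoring.
#'
#' @param params a [cohort_params()] object.
#' @return a list with elements `mutations` (one row per mutation event:
#'   `patient_id`, `gene`, `region`, `effect`) and `clinical` (one row per
#'   patient: `patient_id`, `time`, `event`, `age`, `gender`, `cohort`).
#' @examples
#' cohort <- simulate_cohort(cohort_params(n_patients = 100, seed = 7))
#' head(cohort$clinical)
#' @export
simulate_cohort <- function(params = cohort_params()) {
  stopifnot(inherits(params, "cohort_params"))
  set.seed(params$seed)
  n <- params$n_patients
  ids <- sprintf("P%04d", seq_len(n))

  kras <- stats::rbinom(n, 1L, params$freq_kras)
  tp53 <- stats::rbinom(n, 1L, params$freq_tp53)
  b_smad4 <- .cooccurrence_intercept(params$freq_smad4,
                                     params$co_occurrence_logodds,
                                     params$freq_tp53)
  b_cdkn2a <- .cooccurrence_intercept(params$freq_cdkn2a,
                                      params$co_occurrence_logodds,
                                      params$freq_tp53)
  smad4 <- stats::rbinom(n, 1L, stats::plogis(
    b_smad4 + params$co_occurrence_logodds * tp53))
  cdkn2a <- stats::rbinom(n, 1L, stats::plogis(
    b_cdkn2a + params$co_occurrence_logodds * tp53))

  rate <- params$baseline_hazard *
    params$hr_tp53^tp53 * params$hr_smad4^smad4 * params$hr_cdkn2a^cdkn2a
  t_event <- stats::rexp(n, rate)
  t_cens <- stats::rexp(n, params$censor_rate)
  time <- pmin(t_event, t_cens)
  event <- as.integer(t_event <= t_cens)

  status <- cbind(KRAS = kras, TP53 = tp53, SMAD4 = smad4, CDKN2A = cdkn2a)
  mut_idx <- which(status == 1L, arr.ind = TRUE)
  mutations <- data.frame(
    patient_id = ids[mut_idx[, "row"]],
    gene = DRIVER_GENES[mut_idx[, "col"]],
    region = "exonic",
    effect = "nonsynonymous",
    stringsAsFactors = FALSE
  )
  mutations <- mutations[order(mutations$patient_id, mutations$gene), ]
  rownames(mutations) <- NULL

  clinical <- data.frame(
    patient_id = ids,
    time = time,
    event = event,
    age = round(pmin(pmax(stats::rnorm(n, 65, 10), 30), 95)),
    gender = sample(c("female", "male"), n, replace = TRUE),
    cohort = sample(c("TCGA", "PACA-AU", "PACA-CA"), n, replace = TRUE,
                    prob = c(154, 461, 308) / 923),
    stringsAsFactors = FALSE
  )
  list(mutations = mutations, clinical = clinical)
}

#' Parameters for the synthetic expression-matrix generator
#'
#' @param n_genes total number of genes.
#' @param n_family_genes number of genes belonging to the planted family
#'   (must not exceed `n_genes`).
#' @param family_shift_log2 mean log2 expression shift of family genes in
#'   the TP53-mutant group.
#' @param noise_sd_log2 per-observation Gaussian noise SD on the log2 scale.
#' @param baseline_log2_mean,baseline_log2_sd distribution of per-gene
#'   baseline log2 means.
#' @param frac_zero probability that an observation is replaced by a
#'   dropout zero.
#' @param seed integer seed.
#' @return an object of class `expression_sim_params`.
#' @export
expression_sim_params <- function(n_genes = 2000,
                                  n_family_genes = 40,
                                  family_shift_log2 = 2,
                                  noise_sd_log2 = 0.3,
                                  baseline_log2_mean = 5,
                                  baseline_log2_sd = 1,
                                  frac_zero = 0.02,
                                  seed = 1L) {
  if (n_family_genes > n_genes) {
    stop("`n_family_genes` must not exceed `n_genes`", call. = FALSE)
  }
  if (!is.numeric(noise_sd_log2) || noise_sd_log2 <= 0) {
    stop("`noise_sd_log2` must be > 0", call. = FALSE)
  }
  if (frac_zero < 0 || frac_zero > 1) {
    stop("`frac_zero` must lie in [0, 1]", call. = FALSE)
  }
  structure(list(
    n_genes = n_genes, n_family_genes = n_family_genes,
    family_shift_log2 = family_shift_log2, noise_sd_log2 = noise_sd_log2,
    baseline_log2_mean = baseline_log2_mean,
    baseline_log2_sd = baseline_log2_sd,
    frac_zero = frac_zero, seed = as.integer(seed)
  ), class = "expression_sim_params")
}

#' Simulate a normalized expression matrix with a planted family shift
#'
#' Expression is log-normal: each gene has a baseline log2 mean, each
#' observation adds Gaussian log2 noise, and the designated family genes
#' gain `family_shift_log2` in TP53-mutant samples.  Dropout zeros are
#' injected at rate `frac_zero`.
#'
#' @param params an [expression_sim_params()] object.
#' @param groups a data frame with columns `patient_id` and `tp53_mut`
#'   (logical or 0/1), e.g. the profiles from [build_profiles()].
#' @return a list with `values` (genes x samples matrix of nonnegative
#'   normalized values), `group` (factor `TP53_mut` / `TP53_wt` per sample)
#'   and `family_genes` (character vector of planted family gene ids).
#' @export
simulate_expression <- function(params, groups) {
  stopifnot(inherits(params, "expression_sim_params"))
  if (!all(c("patient_id", "tp53_mut") %in% names(groups))) {
    stop("`groups` must have columns `patient_id` and `tp53_mut`",
         call. = FALSE)
  }
  set.seed(params$seed)
  n_s <- nrow(groups)
  tp53 <- as.integer(as.logical(groups$tp53_mut))
  n_fam <- params$n_family_genes
  genes <- c(sprintf("SNOFAM%03d", seq_len(n_fam)),
             sprintf("GENE%05d", seq_len(params$n_genes - n_fam)))
  base <- stats::rnorm(params$n_genes, params$baseline_log2_mean,
                       params$baseline_log2_sd)
  shift <- matrix(0, params$n_genes, n_s)
  if (n_fam > 0) {
    shift[seq_len(n_fam), ] <- rep(params$family_shift_log2 * tp53,
                                   each = n_fam)
  }
  log2val <- base + shift +
    matrix(stats::rnorm(params$n_genes * n_s, 0, params$noise_sd_log2),
           params$n_genes, n_s)
  values <- 2^log2val
  drop <- matrix(stats::runif(params$n_genes * n_s) < params$frac_zero,
                 params$n_genes, n_s)
  values[drop] <- 0
  dimnames(values) <- list(genes, groups$patient_id)
  list(
    values = values,
    group = factor(ifelse(tp53 == 1L, "TP53_mut", "TP53_wt"),
                   levels = c("TP53_mut", "TP53_wt")),
    family_genes = genes[seq_len(n_fam)]
  )
}

# Amplicon labels follow the primer-pair naming of the rRNA processing
# assay: one "total" amplicon and two "unprocessed" (spacer-containing)
# amplicons per rRNA species.
QPCR_AMPLICONS <- list(
  `18S` = list(total = "pair_2_1", unprocessed = c("pair_4_3", "pair_6_5")),
  `28S` = list(total = "pair_b_a", unprocessed = c("pair_d_c", "pair_f_e"))
)

#' Parameters for the synthetic qPCR Ct-table generator
#'
#' @param true_unprocessed_fraction named numeric vector (names `18S`,
#'   `28S`) of planted unprocessed-over-total quantity ratios in `(0, 1]`;
#'   a single unnamed value is recycled to both species.
#' @param ct_total_mean noise-free Ct of the total amplicon, in cycles.
#' @param ct_noise_sd Gaussian noise SD added to every Ct, in cycles.
#' @param n_replicates technical replicates per amplicon.
#' @param sample_ids sample labels to simulate.
#' @param seed integer seed.
#' @return an object of class `qpcr_sim_params`.
#' @export
qpcr_sim_params <- function(true_unprocessed_fraction = c(`18S` = 0.3, `28S` = 0.3),
                            ct_total_mean = 20,
                            ct_noise_sd = 0,
                            n_replicates = 3,
                            sample_ids = "S1",
                            seed = 1L) {
  fr <- true_unprocessed_fraction
  if (length(fr) == 1L && is.null(names(fr))) {
    fr <- c(`18S` = unname(fr), `28S` = unname(fr))
  }
  if (!all(c("18S", "28S") %in% names(fr))) {
    stop("`true_unprocessed_fraction` needs entries for 18S and 28S",
         call. = FALSE)
  }
  if (any(fr <= 0) || any(fr > 1)) {
    stop("unprocessed fractions must lie in (0, 1]", call. = FALSE)
  }
  if (ct_noise_sd < 0) stop("`ct_noise_sd` must be >= 0", call. = FALSE)
  if (n_replicates < 1) stop("`n_replicates` must be >= 1", call. = FALSE)
  structure(list(
    true_unprocessed_fraction = fr, ct_total_mean = ct_total_mean,
    ct_noise_sd = ct_noise_sd, n_replicates = as.integer(n_replicates),
    sample_ids = sample_ids, seed = as.integer(seed)
  ), class = "qpcr_sim_params")
}

#' Simulate a qPCR Ct table with a planted unprocessed rRNA fraction
#'
#' At 100% amplification efficiency one Ct cycle equals a two-fold quantity
#' difference, so the noise-free unprocessed amplicon is placed at
#' `Ct_total - log2(fraction)` cycles, which makes the downstream
#' unprocessed-over-total quantity ratio exactly the planted fraction.
#'
#' @param params a [qpcr_sim_params()] object.
#' @return a long-format data frame with columns `sample`, `species`,
#'   `amplicon`, `replicate`, `ct`.
#' @export
simulate_qpcr <- function(params = qpcr_sim_params()) {
  stopifnot(inherits(params, "qpcr_sim_params"))
  set.seed(params$seed)
  rows <- list()
  for (s in params$sample_ids) {
    for (sp in names(QPCR_AMPLICONS)) {
      amps <- QPCR_AMPLICONS[[sp]]
      fr <- params$true_unprocessed_fraction[[sp]]
      for (amp in c(amps$total, amps$unprocessed)) {
        ct0 <- if (amp == amps$total) {
          params$ct_total_mean
        } else {
          params$ct_total_mean - log2(fr)
        }
        rows[[length(rows) + 1L]] <- data.frame(
          sample = s, species = sp, amplicon = amp,
          replicate = seq_len(params$n_replicates),
          ct = ct0 + stats::rnorm(params$n_replicates, 0, params$ct_noise_sd),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
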