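# Per-patient driver-gene profiles from annotated somatic-mutation records.

REGION_LEVELS <- c("exonic", "intronic", "UTR5", "UTR3", "splicing",
                   "intergenic", "other")
EFFECT_LEVELS <- c("nonsynonymous", "synonymous", "stopgain", "stoploss",
                   "frameshift", "nonframeshift", "unknown")

#' Read an annotated somatic-mutation table
#'
#' Expects a tab-separated file with columns `patient_id`, `gene`, `region`
#' and `effect` (pre-annotated region and functional-effect classes, as
#' produced by ANNOVAR-style annotation).  Region and effect values are
#' case-folded against the closed vocabularies; unknown values are mapped
#' to `"other"` / `"unknown"` with a warning naming the offending lines.
#'
#' @param path path to the TSV file.
#' @return a data frame of mutation records.
#' @export
read_mutations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("patient_id", "gene", "region", "effect")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("mutation table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df <- df[required]
  bad <- which(!nzchar(trimws(df$patient_id)) | !nzchar(trimws(df$gene)))
  if (length(bad)) {
    stop("empty patient_id or gene at line(s): ",
         paste(bad + 1L, collapse = ", "), call. = FALSE)
  }
  df$region <- .normalize_vocab(df$region, REGION_LEVELS, "other", "region")
  df$effect <- .normalize_vocab(df$effect, EFFECT_LEVELS, "unknown", "effect")
  df
}

.normalize_vocab <- function(x, levels, fallback, what) {
  idx <- match(tolower(trimws(x)), tolower(levels))
  unknown <- is.na(idx)
  if (any(unknown)) {
    warning(sum(unknown), " unrecognized ", what, " value(s) mapped to \"",
            fallback, "\": ", paste(unique(x[unknown]), collapse = ", "),
        call. = FALSE)
  }
  out <- levels[idx]
  out[unknown] <- fallback
  out
}

#' Keep exonic mutations only
#'
#' Restricts records to the exon region (strict region match: splicing
#' variants are excluded).  Synonymous variants are kept by default and can
#' be dropped with `drop_synonymous`.  Record order is preserved and the
#' filter is idempotent.
#'
#' @param records mutation records as from [read_mutations()].
#' @param drop_synonymous also remove records with effect `"synonymous"`.
#' @return the filtered records.
#' @export
filter_exonic <- function(records, drop_synonymous = FALSE) {
  keep <- records$region == "exonic"
  if (drop_synonymous) keep <- keep & records$effect != "synonymous"
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build per-patient driver-gene profiles
#'
#' Joins exonic-filtered mutation records to the clinical table and flags,
#' for each patient, whether each driver gene carries at least one
#' surviving mutation record.  `n_driver_mut` counts mutated genes (not
#' variants).  Every clinical patient yields a profile (all-wildtype when
#' no records survive); mutation records without a clinical row are dropped
#' with a message, never silently.
#'
#' @param records mutation records (already exonic-filtered).
#' @param clinical clinical table with columns `patient_id`, `time`,
#'   `event` and optionally `age`, `gender`, `cohort`.
#' @param driver_genes genes to profile; defaults to the four PDAC drivers.
#' @return a data frame with one row per clinical patient: logical flags
#'   `<gene>_mut`, `n_driver_mut`, and the clinical columns.
#' @export
build_profiles <- function(records, clinical,
                           driver_genes = DRIVER_GENES) {
  if (anyDuplicated(clinical$patient_id)) {
    stop("duplicate patient_id in clinical table: ",
         paste(unique(clinical$patient_id[duplicated(clinical$patient_id)]),
               collapse = ", "), call. = FALSE)
  }
  orphans <- setdiff(unique(records$patient_id), clinical$patient_id)
  if (length(orphans)) {
    message(length(orphans),
            " patient(s) with mutation data but no clinical row dropped: ",
            paste(utils::head(orphans, 5L), collapse = ", "),
            if (length(orphans) > 5L) ", ..." else "")
    records <- records[!records$patient_id %in% orphans, , drop = FALSE]
  }
  profiles <- clinical
  for (g in driver_genes) {
    mutated <- unique(records$patient_id[records$gene == g])
    profiles[[paste0(tolower(g), "_mut")]] <- profiles$patient_id %in% mutated
  }
  flag_cols <- paste0(tolower(driver_genes), "_mut")
  profiles$n_driver_mut <- as.integer(rowSums(profiles[flag_cols]))
  no_mut <- sum(profiles$n_driver_mut == 0L &
                  !profiles$patient_id %in% records$patient_id)
  if (no_mut) {
    message(no_mut, " clinical patient(s) have no mutation records; ",
            "profiled as all-wildtype")
  }
  profiles[c("patient_id", flag_cols, "n_driver_mut",
             setdiff(names(clinical), "patient_id"))]
}

#' Cohort-level mutation-frequency summary
#'
#' Reports per-gene mutation frequencies (percent, with numerator and
#' denominator), the distribution of per-patient driver-mutation counts,
#' the fraction of multi-mutant patients (two or more mutated driver
#' genes), and the fraction of those multi-mutant patients carrying KRAS.
#'
#' @param profiles profiles from [build_profiles()].
#' @return a list with components `gene_freq` (data frame), `count_dist`
#'   (table of n_driver_mut), `multi_mutant_pct` and
#'   `multi_mutant_kras_pct`.
#' @export
frequency_summary <- function(profiles) {
  if (is.null(profiles) || nrow(profiles) == 0L) {
    stop("no profiles to summarize", call. = FALSE)
  }
  n <- nrow(profiles)
  flag_cols <- setdiff(grep("_mut$", names(profiles), value = TRUE),
                       "n_driver_mut")
  counts <- vapply(profiles[flag_cols], sum, integer(1))
  gene_freq <- data.frame(
    gene = toupper(sub("_mut$", "", flag_cols)),
    n_mutant = as.integer(counts),
    n_total = n,
    pct = 100 * counts / n,
    row.names = NULL, stringsAsFactors = FALSE
  )
  multi <- profiles$n_driver_mut >= 2L
  multi_kras_pct <- if (any(multi)) {
    100 * sum(profiles$kras_mut[multi]) / sum(multi)
  } else {
    NA_real_
  }
  list(
    gene_freq = gene_freq,
    count_dist = table(n_driver_mut = profiles$n_driver_mut),
    multi_mutant_pct = 100 * sum(multi) / n,
    multi_mutant_kras_pct = multi_kras_pct
  )
}

#' Define a mutation-combination stratum
#'
#' A stratum is the set of patients whose driver-gene status is mutant for
#' every gene in `mutant` and wildtype for every gene in `wildtype`; genes
#' in neither set are unconstrained.
#'
#' @param name stratum label.
#' @param mutant,wildtype character vectors of driver-gene symbols.
#' @return an object of class `stratum`.
#' @export
stratum <- function(name, mutant = character(), wildtype = character()) {
  if (length(intersect(mutant, wildtype))) {
    stop("stratum \"", name, "\": a gene cannot be required both mutant ",
         "and wildtype", call. = FALSE)
  }
  structure(list(name = name, mutant = mutant, wildtype = wildtype),
            class = "stratum")
}

# All 16 driver-status combinations, as a logical matrix, for exclusivity
# validation.
.status_grid <- function(genes = DRIVER_GENES) {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), length(genes)))
  names(grid) <- genes
  grid
}

.stratum_matches <- function(s, status) {
  # status: named logical vector of driver flags
  all(status[s$mutant]) && !any(status[s$wildtype])
}

#' Validate that strata are mutually exclusive
#'
#' Checks, over all 16 driver-status combinations, that no two strata can
#' both match the same combination.
#'
#' @param strata list of [stratum()] objects.
#' @param genes driver genes spanning the combination space.
#' @return invisibly `TRUE`; errors on overlap.
#' @export
validate_strata <- function(strata, genes = DRIVER_GENES) {
  grid <- .status_grid(genes)
  for (i in seq_len(nrow(grid))) {
    status <- unlist(grid[i, ])
    hits <- vapply(strata, .stratum_matches, logical(1), status = status)
    if (sum(hits) > 1L) {
      stop("strata overlap on driver combination {",
           paste(genes[status], collapse = ", "), "}: ",
           paste(vapply(strata[hits], `[[`, "", "name"), collapse = " / "),
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Assign each patient to a mutation-combination stratum
#'
#' @param profiles profiles from [build_profiles()].
#' @param strata list of [stratum()] objects, validated for mutual
#'   exclusivity.
#' @return character vector of stratum labels, `"unassigned"` where no
#'   stratum matches.
#' @export
assign_strata <- function(profiles, strata) {
  validate_strata(strata)
  genes <- DRIVER_GENES
  flags <- as.matrix(profiles[paste0(tolower(genes), "_mut")])
  colnames(flags) <- genes
  vapply(seq_len(nrow(flags)), function(i) {
    status <- flags[i, ]
    for (s in strata) if (.stratum_matches(s, status)) return(s$name)
    "unassigned"
  }, character(1))
}
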