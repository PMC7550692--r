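# Shared readers/writers and the end-to-end synthetic pipeline runner.

#' Write a data frame as TSV
#'
#' @param df data frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV into a data frame
#'
#' @param path input path.
#' @return data frame.
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read gene sets from a GMT file
#'
#' Standard tab-delimited gene-set format: set name, description, then
#' member genes.  Parsing is delegated to [fgsea::gmtPathways()].
#'
#' @param path path to the `.gmt` file.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sets <- fgsea::gmtPathways(path)
  lapply(sets, unique)
}

#' Write gene sets to a GMT file
#'
#' @param gene_sets named list of character vectors.
#' @param path output path.
#' @param description description field (recycled).
#' @return invisibly, `path`.
#' @export
write_gmt <- function(gene_sets, path, description = "na") {
  lines <- vapply(names(gene_sets), function(n) {
    paste(c(n, description, gene_sets[[n]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a clinical table
#'
#' @param path TSV with at least `patient_id`, `time`, `event`.
#' @return data frame.
#' @export
read_clinical <- function(path) {
  df <- read_tsv(path)
  required <- c("patient_id", "time", "event")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("clinical table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Read a normalized expression matrix with group labels
#'
#' @param path TSV with genes as rows (first column = gene id) and samples
#'   as columns.
#' @param group factor/character of group labels aligned with the sample
#'   columns.
#' @return an expression list (`values`, `group`) as used by the DEG
#'   functions.
#' @export
read_expression <- function(path, group) {
  df <- read_tsv(path)
  values <- as.matrix(df[, -1L, drop = FALSE])
  rownames(values) <- df[[1L]]
  if (length(group) != ncol(values)) {
    stop("`group` length must match the number of sample columns",
         call. = FALSE)
  }
  expr <- list(values = values, group = factor(group))
  .check_expr(expr)
  expr
}

#' Read a qPCR Ct table
#'
#' @param path TSV with columns `sample`, `species`, `amplicon`,
#'   `replicate`, `ct`.
#' @return data frame.
#' @export
read_ct_table <- function(path) {
  df <- read_tsv(path)
  required <- c("sample", "species", "amplicon", "replicate", "ct")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("Ct table is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Pipeline run configuration
#'
#' Collects the analysis thresholds (all defaults are the published
#' decision rules: DEG P <= 0.05, |log2FC| >= 1, expressed in > 20% of
#' samples, group mean >= 5), the permutation replicate count and the root
#' seed from which every stage's seed is derived.
#'
#' @param deg_p DEG P-value threshold.
#' @param deg_abs_log2fc DEG absolute log2 fold-change threshold.
#' @param expressed_frac expressed-gene sample fraction (strict).
#' @param min_level low-expression group-mean level (strict).
#' @param reps permutation replicates (>= 1000).
#' @param seed root seed.
#' @param cohort a [cohort_params()] object (its seed is overridden by the
#'   derived stage seed).
#' @param expression an [expression_sim_params()] object (seed likewise
#'   derived).
#' @return an object of class `run_config`.
#' @export
run_config <- function(deg_p = 0.05, deg_abs_log2fc = 1,
                       expressed_frac = 0.20, min_level = 5,
                       reps = 1e6, seed = 1L,
                       cohort = cohort_params(),
                       expression = expression_sim_params()) {
  if (deg_p <= 0 || deg_abs_log2fc <= 0 || expressed_frac <= 0 ||
      min_level <= 0) {
    stop("all thresholds must be positive", call. = FALSE)
  }
  if (reps < 1000) stop("`reps` must be at least 1000", call. = FALSE)
  structure(list(
    deg_p = deg_p, deg_abs_log2fc = deg_abs_log2fc,
    expressed_frac = expressed_frac, min_level = min_level,
    reps = reps, seed = as.integer(seed),
    cohort = cohort, expression = expression
  ), class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys override [run_config()] defaults; `cohort:` and
#' `expression:` sub-maps override the corresponding simulator defaults.
#'
#' @param path YAML file.
#' @return a `run_config` object.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cohort <- do.call(cohort_params, y$cohort %||% list())
  expression <- do.call(expression_sim_params, y$expression %||% list())
  top <- y[setdiff(names(y), c("cohort", "expression"))]
  do.call(run_config, c(top, list(cohort = cohort, expression = expression)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Stage seeds derived from the root seed; offsets keep everything well
# below .Machine$integer.max.
.stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 101L, expression = 202L, enrichment = 303L,
               qpcr = 404L)
  as.integer(seed) * 1000L + offsets[[stage]]
}

#' Run the full synthetic pipeline
#'
#' Executes simulate -> profiles -> survival battery -> DEG calling ->
#' family enrichment on a synthetic cohort, writing each stage's TSV plus
#' a JSON manifest recording parameters, seeds and MD5 checksums of every
#' output.  Rerunning with the same configuration reproduces every file
#' byte for byte, which the manifest checksums make verifiable.
#'
#' @param config a [run_config()] object.
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
full_run <- function(config = run_config(), out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  cp <- config$cohort
  cp$seed <- .stage_seed(config$seed, "cohort")
  cohort <- simulate_cohort(cp)
  paths["mutations"] <- write_tsv(cohort$mutations,
                                  file.path(out_dir, "mutations.tsv"))
  paths["clinical"] <- write_tsv(cohort$clinical,
                                 file.path(out_dir, "clinical.tsv"))

  records <- filter_exonic(cohort$mutations)
  profiles <- build_profiles(records, cohort$clinical)
  paths["profiles"] <- write_tsv(profiles, file.path(out_dir, "profiles.tsv"))

  battery <- driver_battery(profiles)
  paths["battery"] <- write_tsv(battery, file.path(out_dir, "survival_battery.tsv"))

  ep <- config$expression
  ep$seed <- .stage_seed(config$seed, "expression")
  expr <- simulate_expression(ep, profiles)
  expr <- filter_expressed(expr, min_frac = config$expressed_frac)
  expr <- filter_min_level(expr, min_level = config$min_level)
  degs <- call_degs(expr, max_p = config$deg_p,
                    min_abs_log2fc = config$deg_abs_log2fc)
  paths["degs"] <- write_tsv(degs, file.path(out_dir, "degs.tsv"))

  deg_genes <- degs$gene[degs$passed]
  background <- rownames(expr$values)
  gene_sets <- list(planted_family = intersect(expr$family_genes, background))
  enrich <- enrich_families(list(t_test = deg_genes), gene_sets, background,
                            reps = config$reps,
                            seed = .stage_seed(config$seed, "enrichment"))
  paths["enrichment"] <- write_tsv(enrich, file.path(out_dir, "enrichment.tsv"))

  manifest <- list(
    seed = config$seed,
    parameters = list(
      deg_p = config$deg_p, deg_abs_log2fc = config$deg_abs_log2fc,
      expressed_frac = config$expressed_frac, min_level = config$min_level,
      reps = config$reps,
      cohort = unclass(config$cohort),
      expression = unclass(config$expression)
    ),
    outputs = as.list(unname(vapply(paths, basename, character(1)))),
    checksums = as.list(tools::md5sum(unname(paths)))
  )
  names(manifest$checksums) <- basename(names(manifest$checksums))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)

  invisible(list(cohort = cohort, profiles = profiles, battery = battery,
                 degs = degs, enrichment = enrich, manifest = manifest,
                 paths = c(paths, manifest = manifest_path)))
}
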