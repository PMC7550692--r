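write_mut_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write_tsv(df, path)
  path
}

test_that("mutation tables are parsed and vocabularies normalized", {
  path <- write_mut_tsv(data.frame(
    patient_id = c("P1", "P1", "P2"),
    gene = c("KRAS", "TP53", "KRAS"),
    region = c("Exonic", "intronic", "exonic"),
    effect = c("nonsynonymous", "unknown", "Stopgain")))
  rec <- read_mutations(path)
  expect_equal(nrow(rec), 3L)
  expect_equal(rec$region, c("exonic", "intronic", "exonic"))
  expect_equal(rec$effect[3], "stopgain")
})

test_that("unknown vocabulary values are mapped with a warning", {
  path <- write_mut_tsv(data.frame(
    patient_id = "P1", gene = "KRAS", region = "weird", effect = "odd"))
  expect_warning(expect_warning(rec <- read_mutations(path), "region"),
                 "effect")
  expect_equal(rec$region, "other")
  expect_equal(rec$effect, "unknown")
})

test_that("a missing required column is a format error naming it", {
  path <- write_mut_tsv(data.frame(patient_id = "P1", region = "exonic",
                                   effect = "unknown"))
  expect_error(read_mutations(path), "gene")
})

test_that("the exonic filter keeps exon-region records only", {
  rec <- data.frame(
    patient_id = c("P1", "P1", "P2", "P2"),
    gene = c("KRAS", "TP53", "SMAD4", "KRAS"),
    region = c("exonic", "intronic", "splicing", "exonic"),
    effect = c("nonsynonymous", "unknown", "unknown", "synonymous"),
    stringsAsFactors = FALSE)
  kept <- filter_exonic(rec)
  expect_equal(kept$region, c("exonic", "exonic"))
  expect_identical(filter_exonic(kept), kept)  # idempotent
  expect_equal(nrow(filter_exonic(rec, drop_synonymous = TRUE)), 1L)
  expect_equal(nrow(filter_exonic(rec[0, ])), 0L)
})

test_that("profiles collapse records to per-gene flags", {
  rec <- data.frame(
    patient_id = c("P1", "P1", "P1"),
    gene = c("KRAS", "KRAS", "TP53"),
    region = "exonic", effect = "nonsynonymous", stringsAsFactors = FALSE)
  clin <- data.frame(patient_id = c("P1", "P2"), time = c(10, 20),
                     event = c(1, 0), stringsAsFactors = FALSE)
  pr <- suppressMessages(build_profiles(rec, clin))
  expect_true(pr$kras_mut[1] && pr$tp53_mut[1])
  expect_equal(pr$n_driver_mut, c(2L, 0L))
  expect_false(any(unlist(pr[2, c("kras_mut", "tp53_mut", "smad4_mut",
                                  "cdkn2a_mut")])))
})

test_that("duplicate clinical ids and orphan mutations are handled", {
  rec <- data.frame(patient_id = "P9", gene = "KRAS", region = "exonic",
                    effect = "nonsynonymous", stringsAsFactors = FALSE)
  clin_dup <- data.frame(patient_id = c("P1", "P1"), time = c(1, 2),
                         event = c(1, 1))
  expect_error(build_profiles(rec, clin_dup), "duplicate patient_id")
  clin <- data.frame(patient_id = "P1", time = 1, event = 1)
  expect_message(pr <- build_profiles(rec, clin), "no clinical row")
  expect_equal(nrow(pr), 1L)
  expect_false(pr$kras_mut)
})

test_that("frequency summary arithmetic and invariances hold", {
  rec <- data.frame(
    patient_id = c("P1", "P2", "P2", "P3", "P3", "P3"),
    gene = c("KRAS", "KRAS", "TP53", "KRAS", "TP53", "SMAD4"),
    region = "exonic", effect = "nonsynonymous", stringsAsFactors = FALSE)
  clin <- data.frame(patient_id = c("P1", "P2", "P3", "P4"),
                     time = 1:4, event = 1)
  pr <- suppressMessages(build_profiles(rec, clin))
  fs <- frequency_summary(pr)
  expect_equal(fs$multi_mutant_pct, 50)     # counts {1,2,3,0}
  expect_equal(fs$gene_freq$pct[fs$gene_freq$gene == "KRAS"], 75)
  expect_equal(fs$multi_mutant_kras_pct, 100)
  # duplicated identical records change nothing
  pr2 <- suppressMessages(build_profiles(rbind(rec, rec), clin))
  expect_equal(frequency_summary(pr2)$gene_freq, fs$gene_freq)
  expect_error(frequency_summary(pr[0, ]), "no profiles")
})

test_that("strata match exact mutation combinations", {
  strata <- list(
    stratum("KRAS-only", mutant = "KRAS",
            wildtype = c("TP53", "SMAD4", "CDKN2A")),
    stratum("KRAS+TP53-only", mutant = c("KRAS", "TP53"),
            wildtype = c("SMAD4", "CDKN2A")),
    stratum("no driver",
            wildtype = c("KRAS", "TP53", "SMAD4", "CDKN2A")))
  pr <- make_profiles(3)
  pr[c("kras_mut", "tp53_mut", "smad4_mut", "cdkn2a_mut")] <-
    data.frame(kras = c(TRUE, FALSE, FALSE),
               tp53 = c(TRUE, TRUE, FALSE),
               smad4 = FALSE, cdkn2a = FALSE)
  expect_equal(assign_strata(pr, strata),
               c("KRAS+TP53-only", "unassigned", "no driver"))
})

test_that("overlapping strata are rejected at validation time", {
  overlapping <- list(
    stratum("any KRAS", mutant = "KRAS"),
    stratum("KRAS+TP53", mutant = c("KRAS", "TP53")))
  expect_error(validate_strata(overlapping), "overlap")
  expect_error(stratum("bad", mutant = "KRAS", wildtype = "KRAS"),
               "both mutant")
})

test_that("exhaustive exclusive strata partition the cohort", {
  co <- simulate_cohort(cohort_params(n_patients = 300, seed = 14))
  pr <- suppressMessages(build_profiles(filter_exonic(co$mutations),
                                        co$clinical))
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 4))
  genes <- c("KRAS", "TP53", "SMAD4", "CDKN2A")
  strata <- lapply(seq_len(nrow(grid)), function(i) {
    on <- unlist(grid[i, ])
    stratum(paste0("combo", i), mutant = genes[on], wildtype = genes[!on])
  })
  labels <- assign_strata(pr, strata)
  expect_false(any(labels == "unassigned"))
  expect_equal(sum(table(labels)), nrow(pr))
})
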