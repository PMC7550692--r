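test_that("contingency construction is plain set arithmetic", {
  background <- sprintf("g%02d", 1:20)
  family <- background[1:4]
  degs <- background[c(1, 2, 10, 11, 12)]
  tab <- build_contingency(degs, family, background)
  expect_equal(unclass(tab)[c("a", "m", "k", "N")],
               list(a = 2L, m = 4L, k = 5L, N = 20L))

  disjoint <- build_contingency(degs, c("x1", "x2"), background)
  expect_equal(disjoint$m, 0L)
  expect_true(is.na(enrichment_ratio(disjoint)))

  expect_warning(tab2 <- build_contingency(c(degs, "offworld"), family,
                                           background), "not in background")
  expect_equal(tab2$k, 5L)
  expect_error(build_contingency(degs, family, character()), "empty")
  expect_error(contingency(5, 4, 5, 20), "invalid contingency")
})

test_that("two-sided Fisher P matches brute-force enumeration", {
  expect_equal(fisher_enrichment(contingency(2, 4, 5, 20))$p_value,
               0.24871, tolerance = 1e-4)
  set.seed(61)
  for (i in 1:50) {
    tab <- random_contingency(60)
    expect_equal(fisher_enrichment(tab)$p_value,
                 fisher_oracle(tab$a, tab$m, tab$k, tab$N),
                 tolerance = 1e-10,
                 info = paste(tab$a, tab$m, tab$k, tab$N))
  }
})

test_that("sample odds ratio follows the zero-cell conventions", {
  expect_equal(fisher_enrichment(contingency(0, 4, 5, 20))$sample_or, 0)
  expect_equal(fisher_enrichment(contingency(4, 4, 5, 20))$sample_or, Inf)
  fi <- fisher_enrichment(contingency(2, 4, 5, 20))
  expect_equal(fi$sample_or, (2 * 13) / (2 * 3))
  expect_true(fi$ci_lower <= fi$sample_or)
})

test_that("enrichment ratio handles its boundary cases", {
  expect_equal(enrichment_ratio(contingency(10, 28, 90, 11789)),
               (10 / 28) / (80 / 11761))
  expect_equal(enrichment_ratio(contingency(0, 7, 90, 16859)), 0)
  expect_equal(enrichment_ratio(contingency(5, 10, 5, 100)), Inf)
})

test_that("permutation P converges to the hypergeometric upper tail", {
  set.seed(67)
  for (i in 1:10) {
    tab <- random_contingency(60)
    pe <- permutation_enrichment(tab, reps = 1e5, seed = 100 + i)
    exact <- stats::phyper(tab$a - 1L, tab$m, tab$N - tab$m, tab$k,
                           lower.tail = FALSE)
    mc_se <- sqrt(exact * (1 - exact) / 1e5)
    expect_lt(abs(pe$p_value - exact), 4 * mc_se + 1e-12)
  }
})

test_that("permutation OR converges to a*N/(k*m) with a covering CI", {
  tab <- contingency(4, 48, 90, 16859)
  pe <- permutation_enrichment(tab, reps = 1e6, seed = 71)
  expect_equal(pe$or, 4 * 16859 / (90 * 48), tolerance = 0.01)
  expect_true(pe$ci_lower <= pe$or && pe$or <= pe$ci_upper)
})

test_that("a zero observed count gives exact p = 1 and or = 0", {
  pe <- permutation_enrichment(contingency(0, 7, 90, 16859),
                               reps = 1000, seed = 73)
  expect_identical(pe$p_value, 1)
  expect_identical(pe$or, 0)
  expect_equal(c(pe$ci_lower, pe$ci_upper), c(0, 0))
})

test_that("literal subset sampling agrees with hypergeometric draws", {
  tab <- contingency(2, 6, 8, 30)
  ph <- permutation_enrichment(tab, reps = 20000, seed = 79)
  ps <- permutation_enrichment(tab, reps = 20000, seed = 79, mode = "subset")
  exact_mean <- tab$k * tab$m / tab$N
  expect_equal(ph$mean_count, exact_mean, tolerance = 0.05)
  expect_equal(ps$mean_count, exact_mean, tolerance = 0.05)
  expect_equal(ph$p_value, ps$p_value, tolerance = 0.03)
})

test_that("permutation and Fisher P are monotone in the observed count", {
  m <- 10L; k <- 15L; N <- 100L
  p_fisher <- p_perm <- numeric()
  for (a in 0:min(m, k)) {
    tab <- contingency(a, m, k, N)
    p_fisher <- c(p_fisher, fisher_enrichment(tab)$p_value)
    p_perm <- c(p_perm,
                permutation_enrichment(tab, reps = 5000, seed = 83)$p_value)
  }
  # upper-tail permutation P strictly ordered; Fisher two-sided P
  # non-increasing once past the mode
  expect_true(all(diff(p_perm) <= 0))
  mode_at <- which.max(stats::dhyper(0:min(m, k), m, N - m, k))
  expect_true(all(diff(p_fisher[mode_at:length(p_fisher)]) <= 1e-12))
})

test_that("reps below the floor and empty families are rejected", {
  tab <- contingency(2, 4, 5, 20)
  expect_error(permutation_enrichment(tab, reps = 10), "at least 1000")
  expect_error(permutation_enrichment(contingency(0, 0, 5, 20),
                                      reps = 1000), "not evaluable")
})

test_that("family batteries give one row per (DEG list, family) pair", {
  background <- sprintf("g%03d", 1:200)
  sets <- list(famA = background[1:10], famB = background[11:14],
               famC = background[15:40], famD = background[41:45])
  degs <- list(t_test = background[c(1:6, 100:110)],
               rankcomp = background[c(2:4, 120:135)])
  res <- enrich_families(degs, sets, background, reps = 2000, seed = 89)
  expect_equal(nrow(res), 8L)
  expect_equal(res$deg_list, rep(c("t_test", "rankcomp"), each = 4))
  res2 <- enrich_families(degs, sets, background, reps = 2000, seed = 89)
  expect_identical(res, res2)
  # famA is the planted enriched family for the t-test list
  t_rows <- res[res$deg_list == "t_test", ]
  expect_equal(t_rows$family[which.min(t_rows$perm_p)], "famA")
})
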