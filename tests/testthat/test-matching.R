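# A small cohort with known proband profiles for pool logic:
#   A: {incomplete_pcom, a1_asymmetry}   B: {classical}
#   C: {incomplete_pcom}                 D: {fetal_pc}
pool_df <- function() {
  row <- function(fid, mid, role, profile) {
    flags <- as.integer(c("classical", "a1_asymmetry", "incomplete_pcom",
                          "fetal_pc") %in% profile)
    data.frame(family_id = fid, member_id = mid, role = role,
               classical = flags[1], a1_asymmetry = flags[2],
               incomplete_pcom = flags[3], fetal_pc = flags[4])
  }
  rbind(row("A", "p", "proband", c("incomplete_pcom", "a1_asymmetry")),
        row("A", "r", "fdr", "incomplete_pcom"),
        row("B", "p", "proband", "classical"),
        row("B", "r", "fdr", "classical"),
        row("C", "p", "proband", "incomplete_pcom"),
        row("C", "r", "fdr", "fetal_pc"),
        row("D", "p", "proband", "fetal_pc"),
        row("D", "r", "fdr", "incomplete_pcom"))
}

test_that("comparison pools require disjoint proband profiles", {
  coh <- read_cohort(pool_df())
  expect_named(comparison_pool(coh, "A"), c("B", "D"))   # C shares a variant
  expect_named(comparison_pool(coh, "C"), c("B", "D"))
  expect_named(comparison_pool(coh, "B"), c("A", "C", "D"))
  # not-identical rule admits overlapping but different sets
  expect_named(comparison_pool(coh, "A", pool_rule = "not_identical"),
               c("B", "C", "D"))
  expect_error(comparison_pool(coh, "Z"), "unknown")
})

test_that("an unsatisfiable matching constraint is surfaced as an error", {
  df <- pool_df()[pool_df()$family_id %in% c("A", "C"), ]
  coh <- read_cohort(df)
  expect_error(comparison_pool(coh, "A"), "empty comparison pool")
  expect_error(draw_matching(coh), "empty comparison pool")
  expect_error(run_resampling(coh, n_iterations = 3, seed = 1),
               "empty comparison pool")
})

test_that("matching draws with replacement and is seed-reproducible", {
  coh <- read_cohort(pool_df())
  set.seed(31); m1 <- draw_matching(coh)
  set.seed(31); m2 <- draw_matching(coh)
  expect_identical(m1, m2)
  expect_named(m1, c("A", "B", "C", "D"))
  # two families with the same singleton pool both match it
  df <- rbind(pool_df()[pool_df()$family_id %in% c("A", "C"), ],
              data.frame(family_id = "B", member_id = c("p", "r"),
                         role = c("proband", "fdr"), classical = c(1L, 1L),
                         a1_asymmetry = 0L, incomplete_pcom = 0L,
                         fetal_pc = 0L))
  coh2 <- read_cohort(df)
  set.seed(32)
  m <- draw_matching(coh2)
  expect_identical(unname(m[c("A", "C")]), c("B", "B"))
})

test_that("iterate_once reproduces the worked two-family strata", {
  coh <- read_cohort(table1_df())
  it <- iterate_once(coh, outcomes = c("any", "incomplete_pcom",
                                       "a1_asymmetry"),
                     matching = c(index = "comparison",
                                  comparison = "index"))
  s <- it$any$strata
  idx <- s[s$family_id == "index", ]
  expect_equal(idx$index_events, 3); expect_equal(idx$index_trials, 5)
  expect_equal(idx$comparison_events, 2); expect_equal(idx$comparison_trials, 4)
  s2 <- it$incomplete_pcom$strata
  expect_equal(s2[s2$family_id == "index", ]$comparison_events, 1)
  # the a1-asymmetry column only has the index family (comparison proband
  # is classical, so that family contributes no stratum of its own)
  expect_equal(it$a1_asymmetry$strata$family_id, "index")
})

test_that("an outcome no proband carries yields zero strata, not an error", {
  coh <- read_cohort(pool_df())
  it <- iterate_once(coh, outcomes = c("classical", "any"),
                     matching = c(A = "B", B = "A", C = "D", D = "C"))
  # only B's proband is classical, so 'classical' has one stratum; a
  # cohort without classical probands has none
  expect_equal(it$classical$strata$family_id, "B")
  no_cl <- coh
  no_cl$families <- coh$families[c("A", "C", "D")]
  it2 <- iterate_once(no_cl, outcomes = c("classical", "any"),
                      matching = c(A = "D", C = "D", D = "A"))
  expect_null(it2$classical$strata)
  expect_true(is.na(it2$classical$index_concordance))
  expect_false(is.null(it2$any$strata))

  # and run_resampling reports such an outcome as an all-NA row
  big <- generate_cohort(sim_params(n_families = 60, seed = 19))
  big$families <- Filter(function(f)
    identical(f$proband$profile, "incomplete_pcom") ||
      identical(f$proband$profile, "fetal_pc"), big$families)
  agg <- suppressWarnings(run_resampling(big,
                                         outcomes = c("classical", "any"),
                                         n_iterations = 3, seed = 2))
  expect_equal(agg$n_index_families[agg$outcome == "classical"], 0L)
  expect_true(is.na(agg$median_or[agg$outcome == "classical"]))
  expect_false(is.na(agg$median_or[agg$outcome == "any"]))
})

test_that("families with an empty proband profile are excluded, warned", {
  df <- rbind(pool_df(),
              data.frame(family_id = "E", member_id = c("p", "r"),
                         role = c("proband", "fdr"), classical = 0L,
                         a1_asymmetry = 0L, incomplete_pcom = c(0L, 1L),
                         fetal_pc = 0L))
  coh <- read_cohort(df)
  expect_warning(agg <- run_resampling(coh, outcomes = "any",
                                       n_iterations = 3, seed = 9),
                 "no named variant")
  expect_equal(agg$n_index_families, 4L)
})

test_that("the index arm is fixed; only the comparison arm resamples", {
  coh <- generate_cohort(sim_params(n_families = 30, seed = 5))
  cohf <- suppressWarnings(run_resampling(coh, outcomes = "any",
                                          n_iterations = 1, seed = 1))
  set.seed(41); it1 <- suppressWarnings(iterate_once(coh, "any"))
  set.seed(99); it2 <- suppressWarnings(iterate_once(coh, "any"))
  expect_identical(it1$any$strata$index_events, it2$any$strata$index_events)
  expect_identical(it1$any$index_concordance, it2$any$index_concordance)
  expect_equal(cohf$median_index_concordance, it1$any$index_concordance)
})

test_that("run_resampling is reproducible and median-of-one is the draw", {
  coh <- generate_cohort(sim_params(n_families = 40, seed = 6))
  a1 <- suppressWarnings(run_resampling(coh, n_iterations = 11, seed = 7))
  a2 <- suppressWarnings(run_resampling(coh, n_iterations = 11, seed = 7))
  expect_identical(a1, a2)
  a3 <- suppressWarnings(run_resampling(coh, n_iterations = 11, seed = 8))
  expect_false(identical(a1$median_or, a3$median_or))

  one <- suppressWarnings(run_resampling(coh, outcomes = "any",
                                         n_iterations = 1, seed = 7))
  set.seed(7)
  iter_seed <- sample.int(2147483646L, 1)
  set.seed(iter_seed)
  m <- suppressWarnings(draw_matching(coh))
  it <- suppressWarnings(iterate_once(coh, "any", matching = m))
  expect_equal(one$median_or, it$any$fit$or_hat)
  expect_equal(one$median_comparison_concordance,
               it$any$comparison_concordance)
})
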