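test_that("default parameters encode the reference cohort design", {
  p <- default_params_from_table1()
  expect_equal(p$n_ads, 29L)
  expect_equal(p$n_controls, 17L)
  expect_equal(p$n_amci, 12L)
  expect_equal(unname(p$atrophy_effect[c("CA2", "CA3")]), c(0, 0))
  expect_true(all(p$atrophy_effect[c("CA1", "DG", "SUB")] > 0))
  # per-hemisphere control means sum to half the bilateral target
  expect_equal(sum(p$subfield_means), 1455 / 2)
})

test_that("generation is deterministic given (params, seed)", {
  p <- small_params(seed = 31)
  a <- generate_cohort(p)
  b <- generate_cohort(p)
  expect_identical(as.data.frame(a), as.data.frame(b))
  c2 <- generate_cohort(p, seed = 32)
  expect_false(identical(a$icv_mm3, c2$icv_mm3))
  # provenance distinguishes same-seed, different-params cohorts
  p2 <- small_params(seed = 31, suvr_mean = 2)
  d <- generate_cohort(p2)
  expect_false(identical(attr(a, "provenance")$params,
                         attr(d, "provenance")$params))
})

test_that("generated cohorts respect the record invariants", {
  ch <- generate_cohort(small_params(seed = 5))
  expect_equal(nrow(ch), 20)
  expect_false(anyDuplicated(ch$id) > 0)
  expect_setequal(ch$subgroup[ch$group == "ADS"], c("aMCI", "AD"))
  expect_true(all(is.na(ch$subgroup[ch$group == "control"])))
  expect_true(all(is.na(ch$amyloid_suvr[ch$group == "control"])))
  expect_true(all(!is.na(ch$amyloid_suvr[ch$group == "ADS"])))
  vols <- unlist(ch[, c(volume_columns(), "whole_hipp_l_mm3",
                        "whole_hipp_r_mm3")])
  expect_true(all(vols > 0))
  expect_true(all(ch$mmse >= 0 & ch$mmse <= 30))
  expect_true(all(ch$moca >= 0 & ch$moca <= 30))
  expect_true(all(ch$mmse == round(ch$mmse)))
  # whole-hippocampus columns are the subfield totals
  expect_equal(ch$whole_hipp_l_mm3,
               rowSums(ch[, volume_column(hids_subfields(), "L")]))
})

test_that("invalid parameters fail naming the offending field", {
  expect_error(cohort_params(n_ads = 1), "n_ads",
               class = "hids_parameter_error")
  expect_error(cohort_params(icv_sd = -1), "icv_sd")
  expect_error(cohort_params(
    atrophy_effect = setNames(c(1.2, 0, 0, 0, 0), hids_subfields())
  ), "atrophy_effect")
  expect_error(cohort_params(missing_rate = 1.5), "missing_rate")
  expect_error(generate_cohort(list(n_ads = 5)),
               class = "hids_parameter_error")
})

test_that("zero-effect parameters give exchangeable groups in expectation", {
  p <- null_params(seed = 1, n_ads = 2000, n_controls = 2000)
  ch <- generate_cohort(p)
  for (col in c("ca1_l_mm3", "whole_hipp_r_mm3", "mmse", "imm_recall")) {
    tt <- t.test(ch[[col]] ~ ch$group)
    expect_lt(abs(tt$statistic), 4)
  }
})

test_that("control whole-hippocampal mean matches the configured 1455 mm^3 at n = 10,000", {
  p <- cohort_params(n_ads = 2, n_controls = 10000, seed = 77)
  ch <- generate_cohort(p)
  w <- ch$whole_hipp_l_mm3[ch$group == "control"] +
    ch$whole_hipp_r_mm3[ch$group == "control"]
  # SE of the mean is 257/100 = 2.57; allow ~4 SE
  expect_lt(abs(mean(w) - 1455), 10)
  expect_lt(abs(sd(w) - 257), 12)
})

test_that("MMSE group difference has near-total power at reference effect sizes", {
  p <- default_params_from_table1()
  rejections <- vapply(1:100, function(s) {
    ch <- generate_cohort(p, seed = 1000 + s)
    t.test(ch$mmse ~ ch$group)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(rejections), 0.99)
})

test_that("increasing CA1 atrophy strictly increases expected CA1 degeneration scores", {
  mean_ca1_hids <- function(a, seed) {
    eff <- setNames(numeric(5), hids_subfields())
    eff["CA1"] <- a
    p <- cohort_params(n_ads = 400, n_controls = 100,
                       atrophy_effect = eff, seed = seed)
    adj <- icv_adjust(generate_cohort(p))
    mean(subfield_hids(adj, "CA1")$hids)
  }
  levels <- c(0, 0.2, 0.4, 0.6)
  scores <- vapply(levels, mean_ca1_hids, numeric(1), seed = 42)
  expect_true(all(diff(scores) > 0))
})

test_that("missing-at-random dropout hits only the requested fields", {
  p <- cohort_params(n_ads = 200, n_controls = 100,
                     missing_rate = 0.3,
                     missing_fields = c("moca", "imm_recall"), seed = 9)
  ch <- generate_cohort(p)
  expect_gt(sum(is.na(ch$moca)), 0)
  expect_gt(sum(is.na(ch$imm_recall)), 0)
  expect_false(anyNA(ch$mmse))
  expect_false(anyNA(ch$ca1_l_mm3))
})
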