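test_that("profiles carry the canonical label order and length", {
  ch <- generate_cohort(small_params(seed = 1))
  adj <- icv_adjust(ch)
  whole <- build_profiles(adj)
  expect_equal(colnames(whole), whole_labels())
  expect_equal(ncol(whole), 10)
  ca1 <- build_profiles(adj, "CA1")
  expect_equal(colnames(ca1), c("CA1_L", "CA1_R"))
  expect_error(build_profiles(adj, character()),
               class = "hids_parameter_error")
})

test_that("subjects with missing requested volumes are excluded, not imputed", {
  ch <- generate_cohort(small_params(seed = 2))
  adj <- icv_adjust(ch)
  adj$ca3_r_mm3[4] <- NA
  expect_message(prof <- build_profiles(adj), "excluded")
  expect_false(adj$id[4] %in% rownames(prof))
  excluded <- attr(prof, "excluded")
  expect_equal(excluded$id, adj$id[4])
  expect_match(excluded$reason, "CA3_R")
  # a CA1-only request is unaffected by the missing CA3 value
  expect_equal(nrow(build_profiles(adj, "CA1")), nrow(adj))
})

test_that("distance_matrix matches hand geometry and rejects misalignment", {
  lab <- c("CA1_L", "CA1_R")
  p <- matrix(c(0, 0), 1, dimnames = list("p1", lab))
  ctl <- matrix(c(3, 6, 4, 8), 2, dimnames = list(c("c1", "c2"), lab))
  dm <- distance_matrix(p, ctl)
  expect_equal(unname(dm[1, ]), c(5, 10))
  # identical profiles -> zero
  expect_equal(unname(distance_matrix(ctl, ctl)[1, 1]), 0)
  swapped <- ctl[, c(2, 1)]
  expect_error(distance_matrix(p, swapped), class = "hids_alignment_error")
  expect_error(distance_matrix(p[0, , drop = FALSE], ctl),
               class = "hids_parameter_error")
})

test_that("distance_matrix equals the brute-force oracle on random instances", {
  withr::with_seed(99, {
    for (rep in 1:100) {
      n <- sample(1:6, 1)
      m <- sample(1:6, 1)
      pats <- random_profiles(n, whole_labels(), "p")
      ctls <- random_profiles(m, whole_labels(), "c")
      fast <- distance_matrix(pats, ctls)
      slow <- oracle_distance_matrix(pats, ctls)
      expect_equal(fast, slow, tolerance = 1e-12)
    }
  })
})

test_that("transposing roles transposes the matrix; translation leaves it unchanged", {
  withr::with_seed(5, {
    a <- random_profiles(4, whole_labels(), "a")
    b <- random_profiles(3, whole_labels(), "b")
    expect_equal(distance_matrix(a, b), t(distance_matrix(b, a)))
    shift <- matrix(rnorm(10), nrow(a), 10, byrow = TRUE)[1, ]
    a2 <- sweep(a, 2, -shift)
    b2 <- sweep(b, 2, -shift)
    expect_equal(distance_matrix(a2, b2), distance_matrix(a, b),
                 tolerance = 1e-9)
  })
})

test_that("degeneration scores are mean distances with expected invariances", {
  lab <- c("CA1_L", "CA1_R")
  p <- matrix(c(0, 0), 1, dimnames = list("p1", lab))
  ctl <- matrix(c(3, 6, 4, 8), 2, dimnames = list(c("c1", "c2"), lab))
  h <- hids_from_matrix(distance_matrix(p, ctl))
  expect_equal(h$hids, 7.5) # mean of 5 and 10
  # single control: HiDs equals that one distance
  h1 <- hids_from_matrix(distance_matrix(p, ctl[1, , drop = FALSE]))
  expect_equal(h1$hids, 5)
  # identical to every control: zero
  same <- matrix(c(3, 3, 4, 4), 2, dimnames = list(c("c1", "c2"), lab))
  expect_equal(hids_from_matrix(distance_matrix(same[1, , drop = FALSE],
                                                same))$hids, 0)
  # scale equivariance: c * profiles -> c * HiDs
  expect_equal(hids_from_matrix(distance_matrix(3 * p, 3 * ctl))$hids,
               3 * h$hids)
  # homogeneity: doubling the deviation from identical controls doubles HiDs
  cc <- matrix(c(1, 1, 2, 2), 2, dimnames = list(c("c1", "c2"), lab))
  p1 <- matrix(c(1 + 3, 2 + 4), 1, dimnames = list("p", lab))
  p2 <- matrix(c(1 + 6, 2 + 8), 1, dimnames = list("p", lab))
  expect_equal(hids_from_matrix(distance_matrix(p2, cc))$hids,
               2 * hids_from_matrix(distance_matrix(p1, cc))$hids)
})

test_that("per-subfield squared distances decompose the whole-profile distance", {
  withr::with_seed(11, {
    ch <- generate_cohort(small_params(seed = 11))
    adj <- icv_adjust(ch)
    one_ctl <- adj[adj$group == "control", ][1, ]
    pat <- adj[adj$group == "ADS", ][1:3, ]
    pair <- rbind(pat, one_ctl)
    whole_d <- distance_matrix(
      build_profiles(pat), build_profiles(one_ctl)
    )
    sq_sum <- Reduce(`+`, lapply(hids_subfields(), function(sf) {
      distance_matrix(build_profiles(pat, sf),
                      build_profiles(one_ctl, sf))^2
    }))
    expect_equal(whole_d^2, sq_sum, tolerance = 1e-9)
  })
})

test_that("subfield_hids reproduces a hand-computed 2x2 toy example", {
  ch <- generate_cohort(cohort_params(n_ads = 2, n_controls = 2, seed = 3))
  adj <- icv_adjust(ch)
  adj$ca1_l_mm3 <- c(0, 1, 3, 0)
  adj$ca1_r_mm3 <- c(0, 1, 4, 0)
  sc <- subfield_hids(adj, "CA1")
  # patient 1 at origin: mean of 5 and 0; patient 2 at (1,1)
  d21 <- sqrt((1 - 3)^2 + (1 - 4)^2)
  d22 <- sqrt(2)
  expect_equal(sc$hids, c((5 + 0) / 2, (d21 + d22) / 2), tolerance = 1e-12)
  expect_true(all(sc$scope == "CA1"))
})

test_that("ADS degeneration exceeds the leave-one-out control reference under atrophy", {
  higher <- vapply(1:30, function(s) {
    ch <- generate_cohort(default_params_from_table1(), seed = 5000 + s)
    adj <- icv_adjust(ch)
    mean(compute_hids(adj)$hids) > mean(control_pseudo_hids(adj)$hids)
  }, logical(1))
  expect_true(all(higher))
})

test_that("optional z-scaled variant changes units but not the patient ordering drastically", {
  ch <- generate_cohort(default_params_from_table1(), seed = 21)
  adj <- icv_adjust(ch)
  raw <- compute_hids(adj)
  scaled <- compute_hids(adj, scale = TRUE)
  expect_gt(cor(raw$hids, scaled$hids, method = "spearman"), 0.7)
})
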