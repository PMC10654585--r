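test_that("half-up rounding differs from banker's rounding where it must", {
  expect_equal(round_half_up(56.25, 1), 56.3)
  expect_equal(round_half_up(2.5, 0), 3)
  expect_equal(round_half_up(-2.5, 0), -3)
  expect_equal(round_half_up(60.4166667, 2), 60.42)
  expect_equal(round_half_up(0.345, 2), 0.35)  # guards against fp error
})

test_that("prevalence uses all examined hosts as denominator", {
  ds <- fixture_dataset()
  pt <- prevalence_table(ds)
  am <- pt$taxa[pt$taxa$taxon == "Amerodectes molothrus", ]
  expect_equal(am$n_records, 87)
  expect_equal(am$prevalence_pct, 60.42)
  sub <- pt$subtotals[pt$subtotals$category == "specific", ]
  expect_equal(sub$n_specimens, 985)
  expect_equal(sub$abundance_share_pct, round_half_up(985 / 1246 * 100, 1))
  expect_equal(sub$record_share_pct, 74.8)
  al <- pt$subtotals[pt$subtotals$category == "alien", ]
  expect_equal(al$n_specimens, 214)
  expect_equal(al$abundance_share_pct, 17.2)
  expect_equal(sum(pt$taxa$n_records), 365)

  ## ten symbiont-free hosts give an all-zero table
  empty <- occurrence_dataset(
    data.frame(id = sprintf("h%02d", 1:10), species = "x"),
    data.frame(name = "t", genus = "G", family = "F",
               ecological_group = "vane", category = "alien"),
    data.frame())
  pe <- prevalence_table(empty)
  expect_true(all(pe$taxa$prevalence_pct == 0))

  ## zero hosts cannot form a denominator
  none <- empty; none$hosts <- none$hosts[0, ]
  expect_error(prevalence_table(none), class = "hostspec_denominator_error")
})

test_that("co-occurrence combinations partition hosts exhaustively", {
  ds <- fixture_dataset()
  cc <- cooccurrence_table(ds)
  expect_equal(sum(cc$host_counts), 144)
  hc <- cc$host_counts
  expect_equal(sum(hc[c("S", "A", "Q")]), 81)   # single-category hosts
  expect_equal(sum(hc[c("S+A", "S+Q", "A+Q", "S+A+Q")]), 58)
  expect_equal(hc[["none"]], 5)
  expect_equal(sum(cc$record_counts), 365)

  ## one host with one specific record
  one <- occurrence_dataset(
    data.frame(id = "h1", species = "x"),
    data.frame(name = "t", genus = "G", family = "F",
               ecological_group = "vane", category = "specific"),
    data.frame(host_id = "h1", taxon = "t", abundance = 3L))
  cc1 <- cooccurrence_table(one)
  expect_equal(cc1$host_counts[["S"]], 1)
  expect_equal(sum(cc1$host_counts) - cc1$host_counts[["S"]], 0)

  ## unassigned categories are refused
  ds$taxa$category[1] <- "unassigned"
  expect_error(cooccurrence_table(ds), class = "hostspec_coverage_error")
})

test_that("co-occurrence tabulation matches a naive per-host scan", {
  for (seed in 1:60) {
    sim <- simulate_transmission(transmission_sim_config(
      25, 3, 2, 3, q_vi = 0.4, q_hc = 0.15, q_hi = 0.1,
      n_contacts_conspecific = 4, n_contacts_interspecific = 3, seed = seed))
    ds <- sim$dataset
    ## flip a few taxa to qsm so all three categories appear
    qsm_taxa <- ds$taxa$name[seq(1, nrow(ds$taxa), by = 5)]
    ds$taxa$ecological_group[ds$taxa$name %in% qsm_taxa] <- "quill_skin"
    ds$taxa$category[ds$taxa$name %in% qsm_taxa] <- "qsm"
    cc <- cooccurrence_table(ds)

    ## oracle: direct per-host set enumeration
    oracle <- c(S = 0, A = 0, Q = 0, `S+A` = 0, `S+Q` = 0, `A+Q` = 0,
                `S+A+Q` = 0, none = 0)
    for (h in ds$hosts$id) {
      cats <- sort(unique(
        ds$taxa$category[match(ds$records$taxon[ds$records$host_id == h],
                               ds$taxa$name)]))
      key <- paste(c(if ("specific" %in% cats) "S",
                     if ("alien" %in% cats) "A",
                     if ("qsm" %in% cats) "Q"), collapse = "+")
      if (key == "") key <- "none"
      oracle[key] <- oracle[key] + 1
    }
    expect_equal(unname(cc$host_counts), unname(oracle[names(cc$host_counts)]))
  }
})

test_that("the rate estimator reproduces shares, point ratio and bounds", {
  est <- estimate_transmission(c(specific = 273, alien = 69, qsm = 23))
  expect_equal(est$share_specific_pct, 74.8)
  expect_equal(est$share_alien_pct, 18.9)
  expect_equal(est$share_qsm_pct, 6.3)
  expect_equal(est$ratio_point, 273 / 69)
  expect_equal(est$ratio_lower, 3.0)
  expect_equal(est$ratio_upper, 4.3)
  expect_equal(unname(coef(est)["ratio"]), 273 / 69)
  ci <- confint(est)
  expect_equal(unname(ci[1, ]), c(3.0, 4.3))

  sym <- estimate_transmission(c(specific = 10, alien = 10, qsm = 0))
  expect_equal(sym$share_specific_pct, 50)
  expect_equal(sym$ratio_point, 1)
  expect_equal(sym$ratio_lower, 1)
  expect_equal(sym$ratio_upper, 1)

  deg <- estimate_transmission(c(specific = 5, alien = 0, qsm = 0))
  expect_true(is.infinite(deg$ratio_point))
  expect_true(is.infinite(deg$ratio_upper))

  expect_error(estimate_transmission(c(specific = -1, alien = 2, qsm = 0)),
               class = "hostspec_validation_error")
})

test_that("shares sum to 100 and bounds bracket the point on random counts", {
  set.seed(4)
  for (i in 1:200) {
    counts <- c(specific = sample(1:400, 1), alien = sample(20:400, 1),
                qsm = sample(0:200, 1))
    est <- estimate_transmission(counts)
    expect_lt(abs(est$share_specific_pct + est$share_alien_pct +
                  est$share_qsm_pct - 100), 0.1 + 1e-9)
    ## oracle: extreme-assignment bounds computed directly from the counts
    exact_lower <- counts[["specific"]] / (counts[["alien"]] + counts[["qsm"]])
    exact_upper <- (counts[["specific"]] + counts[["qsm"]]) / counts[["alien"]]
    expect_lte(exact_lower, est$ratio_point)
    expect_lte(est$ratio_point, exact_upper)
    ## the rounded-share bounds track the exact ones up to rounding effects
    expect_lt(abs(est$ratio_lower_raw - exact_lower),
              0.1 + 0.1 * exact_lower)
    expect_lt(abs(est$ratio_upper_raw - exact_upper),
              0.1 + 0.1 * exact_upper)
    if (counts[["qsm"]] > 0) expect_lte(est$ratio_lower, est$ratio_upper)
  }
})
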