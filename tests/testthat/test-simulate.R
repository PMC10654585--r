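test_that("single-route configurations produce single-category records", {
  ## no conspecific contact: every record is alien
  sim <- simulate_transmission(transmission_sim_config(
    50, 5, 2, 4, q_vi = 0.5, q_hc = 0, q_hi = 0,
    n_contacts_conspecific = 10, n_contacts_interspecific = 0, seed = 2))
  cats <- sim$dataset$taxa$category[match(sim$dataset$records$taxon,
                                          sim$dataset$taxa$name)]
  expect_true(all(cats == "alien"))

  ## conspecific route only: estimator sees a zero alien share
  sim <- simulate_transmission(transmission_sim_config(
    50, 5, 2, 4, q_vi = 0, q_hc = 0.2, q_hi = 0,
    n_contacts_conspecific = 10, n_contacts_interspecific = 5, seed = 2))
  cats <- sim$dataset$taxa$category[match(sim$dataset$records$taxon,
                                          sim$dataset$taxa$name)]
  expect_true(all(cats == "specific"))
  est <- estimate_transmission(cooccurrence_table(sim$dataset))
  expect_equal(est$share_alien_pct, 0)
  expect_true(is.infinite(est$ratio_point))
})

test_that("simulators are deterministic under a fixed seed", {
  cfg <- transmission_sim_config(30, 4, 2, 3, q_vi = 0.3, q_hc = 0.1,
                                 q_hi = 0.05, seed = 7)
  s1 <- simulate_transmission(cfg)
  s2 <- simulate_transmission(cfg)
  expect_identical(s1$dataset$records, s2$dataset$records)
  cfg2 <- transmission_sim_config(30, 4, 2, 3, q_vi = 0.3, q_hc = 0.1,
                                  q_hi = 0.05, seed = 8)
  expect_false(identical(simulate_transmission(cfg2)$dataset$records,
                         s1$dataset$records))

  c1 <- simulate_cophylogeny(cophylo_sim_config(6, seed = 5))
  c2 <- simulate_cophylogeny(cophylo_sim_config(6, seed = 5))
  expect_identical(write_newick(c1$tanglegram$symbiont_tree),
                   write_newick(c2$tanglegram$symbiont_tree))
  expect_identical(c1$events, c2$events)
})

test_that("brood-parasite mode and invalid configs are enforced", {
  expect_error(transmission_sim_config(10, q_vc = 0.2),
               class = "hostspec_config_error")
  expect_error(transmission_sim_config(0), class = "hostspec_config_error")
  expect_error(transmission_sim_config(10, q_hc = 1.2),
               class = "hostspec_config_error")
})

test_that("a zero-distance pair is identical and bad ts/tv is refused", {
  pair <- simulate_k2p_pair(0, 2, 200, seed = 3)
  expect_identical(pair[["seq_a"]], pair[["seq_b"]])
  expect_error(simulate_k2p_pair(0.05, Inf, 100),
               class = "hostspec_config_error")
  expect_error(simulate_k2p_pair(-0.1, 2, 100),
               class = "hostspec_config_error")
})

test_that("the K2P generator is unbiased for the estimator", {
  for (d in c(0.05)) {
    est <- vapply(1:60, function(s) {
      pair <- simulate_k2p_pair(d, 2, 1000, seed = s)
      k2p_distance(pair["seq_a"], pair["seq_b"])$d
    }, numeric(1))
    se <- stats::sd(est) / sqrt(length(est))
    expect_lt(abs(mean(est) - d), 3 * se)
  }
})

test_that("the estimator recovers a configured specific:alien ratio of 3", {
  ## q_hi = 0, q_vi = 0.2, pool 3 of 10 fosters: E[alien records] = 0.6/host;
  ## solve 5 (1 - (1 - q_hc)^10) = 1.8 for the conspecific rate
  q_hc <- 1 - (1 - 3 * 0.6 / 5)^(1 / 10)
  cfg <- function(s) transmission_sim_config(
    500, 10, 3, 5, q_vi = 0.2, q_hc = q_hc, q_hi = 0,
    n_contacts_conspecific = 10, n_contacts_interspecific = 0, seed = s)
  expect_equal(expected_record_counts(cfg(1))$ratio, 3, tolerance = 1e-12)
  ratios <- vapply(1:20, function(s) {
    sim <- simulate_transmission(cfg(s))
    estimate_transmission(cooccurrence_table(sim$dataset))$ratio_point
  }, numeric(1))
  se <- stats::sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - 3), 3 * se)
})

test_that("cophylogeny extremes produce the expected tanglegrams", {
  ## pure cospeciation tracks the host tree exactly
  sim <- simulate_cophylogeny(cophylo_sim_config(
    7, p_cospeciate = 1, rate_switch = 0, rate_loss = 0, seed = 9))
  rec <- reconcile(sim$tanglegram)
  expect_equal(rec$total_cost, 0)
  expect_equal(rec$counts[["cospeciation"]], 6)
  expect_equal(ape::Ntip(sim$tanglegram$symbiont_tree), 7)

  ## rate_switch = 0: the true history never contains a switch, and the
  ## switch-free reconciliation (cospeciations + losses) prices every
  ## replicate, bounding the parsimony optimum from above
  for (s in 1:10) {
    sim <- simulate_cophylogeny(cophylo_sim_config(
      6, p_cospeciate = 0.85, rate_switch = 0, rate_loss = 0.05, seed = s))
    expect_equal(sim$events[["switch"]], 0)
    expect_equal(sim$events[["duplication"]], 0)
    rec <- reconcile(sim$tanglegram)
    true_cost <- sum(sim$events * event_costs()[names(sim$events)])
    expect_lte(rec$total_cost, true_cost)
    ## under costs that penalise switches beyond any loss chain, parsimony
    ## recovers the switch-free explanation exactly
    deep <- reconcile(sim$tanglegram,
                      event_costs(0, 1, 100, 1))
    expect_equal(deep$counts[["switch"]], 0)
  }
})

test_that("parsimony never prices a replicate above its true history", {
  costs <- event_costs()
  mpr_sw <- true_sw <- numeric(0)
  for (s in 1:40) {
    sim <- simulate_cophylogeny(cophylo_sim_config(
      8, p_cospeciate = 0.8, rate_switch = 0.08, rate_loss = 0.05, seed = s))
    rec <- reconcile(sim$tanglegram, costs)
    true_cost <- sum(sim$events *
                     costs[c("cospeciation", "duplication", "switch", "loss")])
    expect_lte(rec$total_cost, true_cost)
    mpr_sw <- c(mpr_sw, rec$counts[["switch"]])
    true_sw <- c(true_sw, sim$events[["switch"]])
  }
  ## inferred switch counts track the simulated truth
  expect_gt(stats::cor(mpr_sw, true_sw), 0.5)
})
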