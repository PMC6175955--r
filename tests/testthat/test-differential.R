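# Differential statistics: RFU, delta-HDX, thresholds, classification

test_that("relative fractional uptake reproduces Y / (MaxUptake x D)", {
  expect_equal(relative_fractional_uptake(0, 10), 0)
  expect_equal(relative_fractional_uptake(9.5, 10, 0.95), 1)
  expect_equal(relative_fractional_uptake(2.0, 10, 0.95), 2 / 9.5)
  expect_error(relative_fractional_uptake(1, 0), class = "hdx_rfu_error")
  expect_error(relative_fractional_uptake(-1, 5),
               class = "hdx_parameter_error")
})

test_that("delta_uptake matches a brute-force mean/variance oracle", {
  pep <- one_peptide()
  vals <- list(control = c(1.0, 1.1, 0.9), variant = c(1.2, 1.3, 1.1))
  mk <- function(st) manual_dataset(pep, st, c(30, 300, 1800),
                                    uptake = function(row)
                                      vals[[row$state]][row$replicate])
  d <- delta_uptake(mk("control"), mk("variant"))
  expect_equal(nrow(d), 3)
  expect_equal(d$delta_da, rep(0.2, 3), tolerance = 1e-12)
  # independent SE formula, written out by hand
  se <- sqrt(sum((vals$variant - mean(vals$variant))^2) / 2 / 3 +
             sum((vals$control - mean(vals$control))^2) / 2 / 3)
  expect_equal(d$se_da, rep(se, 3), tolerance = 1e-12)

  # identical sets -> zero; constant separation -> exact delta, zero SE
  same <- flat_pair(1, 1)
  expect_equal(delta_uptake(same$control, same$variant)$delta_da, rep(0, 3))
  sep <- flat_pair(1, 2)
  ds <- delta_uptake(sep$control, sep$variant)
  expect_equal(ds$delta_da, rep(1, 3))
  expect_equal(ds$se_da, rep(0, 3))

  # randomized oracle sweep
  set.seed(101)
  for (i in 1:20) {
    cv <- runif(3, 0, 4); vv <- runif(3, 0, 4)
    vals2 <- list(control = cv, variant = vv)
    mk2 <- function(st) manual_dataset(pep, st, 30,
                                       uptake = function(row)
                                         vals2[[row$state]][row$replicate])
    r <- delta_uptake(mk2("control"), mk2("variant"))
    expect_equal(r$delta_da, mean(vv) - mean(cv), tolerance = 1e-12)
    expect_equal(r$se_da,
                 sqrt(stats::var(vv) / 3 + stats::var(cv) / 3),
                 tolerance = 1e-12)
  }
})

test_that("Houde threshold matches its closed form and scales linearly", {
  pep <- one_peptide()
  a <- 0.2  # per-group replicate SD by construction: {m - a, m, m + a}
  mk <- function(st, a) manual_dataset(
    pep, st, c(30, 300, 1800),
    uptake = function(row) 2 + a * (row$replicate - 2))
  th <- houde_threshold(mk("control", a), mk("variant", a))
  # closed form: 6 groups, each sd = a, n = 3, k = 3, df = 12
  expect_equal(th$pooled_sd, a, tolerance = 1e-12)
  expect_equal(th$df, 12)
  expect_equal(th$summed_ci,
               qt(0.995, 12) * sqrt(3) * sqrt(2) * a / sqrt(3),
               tolerance = 1e-12)

  # zero replicate SDs -> zero threshold
  flat <- flat_pair(1, 1)
  expect_equal(houde_threshold(flat$control, flat$variant)$summed_ci, 0)

  # doubling every replicate SD doubles the threshold
  th2 <- houde_threshold(mk("control", 2 * a), mk("variant", 2 * a))
  expect_equal(th2$summed_ci, 2 * th$summed_ci, tolerance = 1e-12)
})

test_that("t-test p-values match an independent textbook implementation", {
  pep <- one_peptide()
  set.seed(2024)
  worst <- 0
  for (i in 1:100) {
    cv <- runif(3, 1, 4); vv <- runif(3, 1, 4)
    vals <- list(control = cv, variant = vv)
    mk <- function(st) manual_dataset(pep, st, c(30, 300, 1800),
                                      uptake = function(row)
                                        vals[[row$state]][row$replicate] / 3)
    d <- run_differential(mk("control"), mk("variant"))
    # textbook pooled two-sample t on per-replicate summed uptake
    sa <- vv; sb <- cv  # each timepoint contributes value/3, summed = value
    sp2 <- (2 * stats::var(sa) + 2 * stats::var(sb)) / 4
    t_manual <- (mean(sa) - mean(sb)) / sqrt(sp2 * (2 / 3))
    p_manual <- 2 * pt(-abs(t_manual), 4)
    worst <- max(worst, abs(d$records$p_value - p_manual))
    expect_equal(d$records$t_statistic, t_manual, tolerance = 1e-10)
  }
  expect_lt(worst, 1e-10)
})

test_that("classification requires both the CI gate and the t-test gate", {
  # identical datasets: none, p = 1
  same <- flat_pair(1.5, 1.5)
  d0 <- run_differential(same$control, same$variant)
  expect_equal(d0$records$classification, "none")
  expect_equal(d0$records$p_value, 1)

  # huge separation, tiny variance: positive
  pep <- one_peptide()
  mk <- function(st, m) manual_dataset(
    pep, st, c(30, 300, 1800),
    uptake = function(row) m + 0.01 * (row$replicate - 2))
  dpos <- run_differential(mk("control", 1), mk("variant", 2.5))
  expect_equal(dpos$records$classification, "positive")

  # borderline: summed delta above the CI but p ~ 0.026 -> none
  ctrl <- manual_dataset(pep, "control", c(30, 300, 1800), uptake = 1)
  vari <- manual_dataset(
    pep, "variant", c(30, 300, 1800),
    uptake = function(row)
      if (row$exposure_s == 1800) 1.2 + 0.3 * (row$replicate - 2) else 1.2)
  db <- run_differential(ctrl, vari)
  expect_gt(db$records$summed_delta_da, db$thresholds$summed_ci)
  expect_gt(db$records$p_value, 0.01)
  expect_lt(db$records$p_value, 0.05)
  expect_equal(db$records$classification, "none")
})

test_that("run_differential recovers the simulated sign pattern by region", {
  pair <- simulated_pair("toward_IF")
  d <- run_differential(pair$control, pair$variant)
  truth <- peptide_region_majority(pair$scenario, pair$peptides)
  recs <- dplyr::left_join(
    tidy(d), truth, by = c("start", "end", "sequence", "max_uptake"))
  ic <- recs[recs$region == "intracellular", ]
  ec <- recs[recs$region == "extracellular", ]
  expect_true(all(ic$classification == "positive"))
  expect_true(all(ec$classification == "negative"))
  # peptides entirely inside transmembrane helices carry no equilibrium
  # signal (equal protection in both states) and must stay unclassified;
  # TM-majority peptides that straddle a loop may legitimately fire
  sc <- pair$scenario
  fully_tm <- vapply(seq_len(nrow(pair$peptides)), function(i) {
    pos <- hdxshift:::exchangeable_positions(pair$peptides$sequence[i],
                                             pair$peptides$start[i])
    all(sc$region_labels[pos] == "transmembrane")
  }, logical(1))
  tm_recs <- dplyr::semi_join(
    recs, pair$peptides[fully_tm, ], by = c("start", "end", "sequence"))
  expect_gte(nrow(tm_recs), 1)
  expect_true(all(tm_recs$classification == "none"))
})

test_that("swapping control and variant is exactly antisymmetric", {
  pair <- simulated_pair("toward_IF", seed = 21)
  fwd <- run_differential(pair$control, pair$variant)
  rev <- run_differential(pair$variant, pair$control)
  key <- c("start", "end", "sequence")
  m <- dplyr::inner_join(tidy(fwd), tidy(rev), by = key,
                         suffix = c("_f", "_r"))
  expect_equal(m$summed_delta_da_r, -m$summed_delta_da_f)
  expect_equal(fwd$thresholds$summed_ci, rev$thresholds$summed_ci)
  gf <- glance(fwd); gr <- glance(rev)
  expect_identical(gf$n_positive, gr$n_negative)
  expect_identical(gf$n_negative, gr$n_positive)
})

test_that("null simulations stay calibrated at the nominal level", {
  pair <- simulated_pair("none", seed = 31, min_peptides = 400,
                         n_residues = 300)
  d <- run_differential(pair$control, pair$variant)
  g <- glance(d)
  fp <- (g$n_positive + g$n_negative) / g$n_peptides
  expect_lte(fp, 0.01 + 3 * sqrt(0.01 * 0.99 / g$n_peptides))
})

test_that("structural edge cases behave as specified", {
  pair <- simulated_pair(min_peptides = 10, n_residues = 120)

  # control vs itself: everything none
  self <- run_differential(pair$control, pair$control)
  expect_true(all(self$records$classification == "none"))

  # timepoint mismatch is a hard error
  shifted <- tibble::as_tibble(pair$variant)
  shifted$exposure_s[shifted$exposure_s == 30] <- 60
  shifted <- as_hdx_dataset(shifted,
                            labeling_conditions(c(60, 300, 1800)))
  expect_error(run_differential(pair$control, shifted),
               class = "hdx_timepoint_mismatch_error")

  # row order does not matter
  scr <- tibble::as_tibble(pair$variant)
  set.seed(4)
  scr <- as_hdx_dataset(scr[sample(nrow(scr)), ],
                        attr(pair$variant, "conditions"))
  a <- run_differential(pair$control, pair$variant)
  b <- run_differential(pair$control, scr)
  expect_equal(tidy(a), tidy(b))

  # peptide present in one state only is reported as no_coverage
  ctrl_cut <- tibble::as_tibble(pair$control)
  drop_seq <- ctrl_cut$sequence[1]
  ctrl_cut <- as_hdx_dataset(ctrl_cut[ctrl_cut$sequence != drop_seq, ],
                             attr(pair$control, "conditions"))
  d2 <- run_differential(ctrl_cut, pair$variant)
  expect_true(drop_seq %in% d2$no_coverage$sequence)
  expect_false(drop_seq %in% d2$records$sequence)
})

test_that("significance count never drops as the population shift grows (noise-free)", {
  counts <- vapply(c(0.1, 0.2, 0.3, 0.4), function(dp) {
    sc <- default_transporter_scenario(200, "toward_IF", seed = 17,
                                       delta_population = dp)
    pep <- digest_in_silico(sc$sequence, 0.8, seed = 18)
    cond <- labeling_conditions("detergent")
    ctrl <- simulate_dataset(sc, pep, cond, "control", noise_model(0, 1))
    vari <- simulate_dataset(sc, pep, cond, "variant", noise_model(0, 1))
    truth <- peptide_region_majority(sc, pep)
    d <- run_differential(ctrl, vari)
    recs <- dplyr::left_join(tidy(d), truth,
                             by = c("start", "end", "sequence", "max_uptake"))
    sum(class_sign(recs$classification) == recs$expected_sign &
        recs$expected_sign != 0)
  }, numeric(1))
  expect_true(all(diff(counts) >= 0))
})
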