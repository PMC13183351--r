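test_that("counterfactual delta-P matches the closed-form logistic difference", {
  fit <- fixed_logit_fit(b_intercept = 1, b_register = 1)
  dp <- counterfactual_delta_p(fit, registers = c("CDS", "ADS"))
  expect_equal(dp$mean, stats::plogis(2) - stats::plogis(1), tolerance = 1e-9)
  expect_equal(unname(dp$ci[1]), dp$mean, tolerance = 1e-9)
  # zero register coefficient: the contrast is exactly zero
  fit0 <- fixed_logit_fit(b_intercept = 0.3, b_register = 0)
  dp0 <- counterfactual_delta_p(fit0, registers = c("CDS", "ADS"))
  expect_equal(dp0$mean, 0, tolerance = 1e-12)
  # antisymmetry under register relabelling
  dp_rev <- counterfactual_delta_p(fit, registers = c("ADS", "CDS"))
  expect_equal(dp_rev$mean, -dp$mean, tolerance = 1e-12)
  expect_equal(unname(dp_rev$ci), unname(rev(-dp$ci)), tolerance = 1e-12)
  expect_error(counterfactual_delta_p(fit, cell = list(role = "Q")),
               class = "rp_empty_cell")
})

test_that("preconditions of the hierarchical fit are enforced", {
  rec <- simulate_hier_records(n_sentences = 10, n_splits = 2, seed = 1)
  one_reg <- rec[rec$register == "CDS", ]
  expect_error(fit_hier_bernoulli(one_reg), class = "rp_need_two_registers")
  one_role <- rec[rec$role == "A", ]
  expect_error(fit_hier_bernoulli(one_role), class = "rp_need_both_roles")
  rec2 <- rec
  rec2$dup <- rec2$register
  expect_error(fit_hier_bernoulli(rec2, fixed = ~ register + dup),
               class = "rp_rank_deficient")
})

test_that("a small fit produces draws, diagnostics and calibrated PPCs", {
  rec <- simulate_hier_records(n_sentences = 60, n_splits = 4,
                               beta = c(intercept = 0.4, register = 0.8,
                                        role = -0.3, interaction = 0),
                               seed = 6)
  fit <- fit_hier_bernoulli(rec, chains = 2, n_iter = 600, n_adapt = 500,
                            seed = 2, on_nonconvergence = "warn")
  expect_s3_class(fit, "rp_hier_fit")
  s <- summary(fit)
  expect_true(all(c("rhat", "ess") %in% names(s)))
  expect_true(all(is.finite(s$rhat)))
  expect_equal(nrow(fit$draws), 2 * 600)
  # the register coefficient should at least have the right sign
  expect_gt(coef(fit)[["registerCDS"]], 0)
  # posterior predictive cell accuracies bracket the observed ones
  ppc <- fit$ppc
  covered <- ppc$observed >= ppc$rep_q2.5 & ppc$observed <= ppc$rep_q97.5
  expect_gte(mean(covered), 0.75)
  # delta-P has ordered CI bounds within [-1, 1]
  dp <- counterfactual_delta_p(fit)
  expect_lt(dp$ci[1], dp$ci[2])
  expect_gte(dp$mean, -1); expect_lte(dp$mean, 1)
  # relabelling the registers flips the sampled contrast exactly
  dp_rev <- counterfactual_delta_p(fit, registers = c("ADS", "CDS"))
  expect_equal(dp_rev$per_draw, -dp$per_draw, tolerance = 1e-12)
})

test_that("the study-2 random structure fits records with condition effects", {
  rec <- simulate_hier_records(n_sentences = 50, n_splits = 2,
                               beta = c(intercept = 0.5, register = 0.6,
                                        role = 0, interaction = 0), seed = 9)
  rec$condition <- sample(c("basic", "fronted"), nrow(rec), replace = TRUE)
  fit <- fit_hier_bernoulli(rec, fixed = ~ register * role + condition,
                            random = "study2", chains = 2, n_iter = 500,
                            n_adapt = 400, seed = 3, on_nonconvergence = "warn")
  expect_true("conditionfronted" %in% fit$beta_names)
  dp <- counterfactual_delta_p(fit, cell = list(condition = "fronted"))
  expect_s3_class(dp, "rp_delta_p")
  expect_gt(dp$n_sentences, 0)
})
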