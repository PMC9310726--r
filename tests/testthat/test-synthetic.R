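test_that("config rejects unknown fields and carries overrides", {
  expect_error(synth_config("sleep", nonsense = 1), "unknown config fields")
  cfg <- synth_config("dose", n_cats = 7L, sigma_eps = 0.05)
  expect_equal(cfg$n_cats, 7L)
  expect_equal(cfg$sigma_eps, 0.05)
  expect_equal(cfg$sessions_per_dose, 4L)
})

test_that("seeded epoch generation is bit-reproducible", {
  cfg <- synth_config("sleep")
  a <- gen_state_epoch("SWS", cfg, seed = 5)
  b <- gen_state_epoch("SWS", cfg, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a, gen_state_epoch("SWS", cfg, seed = 6)))
  expect_error(gen_state_epoch("N3", cfg), "unknown state")
})

test_that("a pure slow oscillation epoch has low complexity", {
  cfg <- synth_config("sleep")
  w <- c(slow = 1, spindle = 0, gamma = 0, broadband = 0)
  cs <- vapply(1:5, function(i)
    epoch_lz(gen_state_epoch("SWS", cfg, seed = i, weights = w))$C, numeric(1))
  expect_true(all(cs < 0.3))
})

test_that("spectral mixtures separate wake from slow-wave sleep", {
  cfg <- synth_config("sleep")
  cw <- vapply(1:12, function(i)
    epoch_lz(gen_state_epoch("W", cfg, seed = i))$C, numeric(1))
  cs <- vapply(1:12, function(i)
    epoch_lz(gen_state_epoch("SWS", cfg, seed = 100 + i))$C, numeric(1))
  expect_gt(mean(cw), mean(cs))
})

test_that("direct-value sleep datasets have the designed size and targets", {
  cfg <- synth_config("sleep")
  ds <- gen_sleep_dataset(cfg, mode = "direct")
  expect_equal(nrow(ds$complexity), 3 * 4 * 60)  # cats x states x epochs
  # zero-variance variant: per-state means equal the configured targets
  cfg0 <- synth_config("sleep", sigma_cat = 0, sigma_eps = 1e-12)
  ds0 <- gen_sleep_dataset(cfg0, mode = "direct")
  means <- tapply(ds0$complexity$C, ds0$complexity$state, mean)
  expect_equal(as.numeric(means[names(cfg0$state_targets)]),
               unname(cfg0$state_targets), tolerance = 1e-9)
})

test_that("dataset generation is deterministic given (config, seed)", {
  cfg <- synth_config("dose")
  expect_identical(gen_dose_dataset("inverted_u", cfg),
                   gen_dose_dataset("inverted_u", cfg))
  cfg2 <- synth_config("sleep")
  expect_identical(gen_sleep_dataset(cfg2, mode = "direct"),
                   gen_sleep_dataset(cfg2, mode = "direct"))
})

test_that("dose tables follow the hierarchical design", {
  cfg <- synth_config("dose")
  tab <- gen_dose_dataset("inverted_u", cfg)
  expect_equal(nrow(tab), 5 * 4 * 4 * 60)  # cats x doses x sessions x epochs
  expect_equal(sort(unique(tab$dose)), c(0, 5, 10, 15))
  expect_equal(unique(tab$dtilde), unique(tab$dose) - 7.5)
  expect_equal(length(unique(paste(tab$cat, tab$session))), 5 * 4 * 4)
  expect_error(gen_dose_dataset("banana", cfg), "'arg' should be one of")
})

test_that("noise-free inverted-U means form an exact downward parabola", {
  cfg <- synth_config("dose", sigma_cat = 0, sigma_session = 0, sigma_eps = 0)
  tab <- gen_dose_dataset("inverted_u", cfg)
  means <- tapply(tab$C, tab$dose, mean)
  dt <- as.numeric(names(means)) - 7.5
  expect_equal(as.numeric(means), 0.62 - 0.0008 * dt^2, tolerance = 1e-12)
  expect_true(names(which.max(means)) %in% c("5", "10"))
  # mirrored curvature for the U shape
  tabu <- gen_dose_dataset("u", cfg)
  expect_equal(as.numeric(tapply(tabu$C, tabu$dose, mean)),
               0.62 + 0.0008 * dt^2, tolerance = 1e-12)
})

test_that("flat-truth grand mean sits within 3 standard errors of beta0", {
  cfg <- synth_config("dose")
  tab <- gen_dose_dataset("flat", cfg)
  se <- sqrt(cfg$sigma_cat^2 / cfg$n_cats +
             cfg$sigma_session^2 / (cfg$n_cats * 16) +
             cfg$sigma_eps^2 / nrow(tab))
  expect_lt(abs(mean(tab$C) - cfg$beta0), 3 * se)
})

test_that("stimulated cells are shifted by the configured effect", {
  cfg <- synth_config("dose", sigma_cat = 0, sigma_session = 0, sigma_eps = 0)
  tab <- gen_dose_dataset("flat", cfg, include_stim = TRUE)
  expect_equal(mean(tab$C[tab$stim]) - mean(tab$C[!tab$stim]), 0.04,
               tolerance = 1e-12)
})

test_that("variance components are recoverable from a large direct dataset", {
  cfg <- synth_config("dose", n_cats = 40L, sessions_per_dose = 2L,
                      epochs_per_condition = 10L, seed = 2024L)
  tab <- gen_dose_dataset("flat", cfg)
  fit <- lme4::lmer(C ~ 1 + (1 | cat) + (1 | cat:session), data = tab,
                    REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sd_cat <- vc$sdcor[vc$grp == "cat"]
  sd_eps <- vc$sdcor[vc$grp == "Residual"]
  expect_lt(abs(sd_cat - cfg$sigma_cat) / cfg$sigma_cat, 0.25)
  expect_lt(abs(sd_eps - cfg$sigma_eps) / cfg$sigma_eps, 0.25)
})
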