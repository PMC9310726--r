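test_that("Cohen's d matches the pooled-SD formula and its symmetries", {
  a <- c(0, 0, 1, 1); b <- c(1, 1, 2, 2)
  expect_equal(cohens_d(a, b), -1 / sqrt(1 / 3))
  expect_equal(cohens_d(a, b), -1.732, tolerance = 1e-3)
  expect_equal(cohens_d(b, a), -cohens_d(a, b))
  expect_equal(cohens_d(a, a), 0)
  # location-scale invariance under common shift and positive scaling
  set.seed(21)
  x <- rnorm(30); y <- rnorm(30, 1)
  expect_equal(cohens_d(2.5 * x + 7, 2.5 * y + 7), cohens_d(x, y))
  expect_error(cohens_d(c(1, 1), c(1, 1)), "pooled standard deviation")
  expect_error(cohens_d(1, c(1, 2)), "at least 2")
})

test_that("two-group Tukey p equals the pooled t-test p", {
  set.seed(22)
  x <- rnorm(25); y <- rnorm(30, 0.4)
  at <- anova_tukey(c(x, y), rep(c("a", "b"), c(25, 30)))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(at$pairwise$p_adj, tt$p.value, tolerance = 1e-6)
  expect_equal(at$p, tt$p.value, tolerance = 1e-6)
})

test_that("well-separated groups give tiny adjusted p and huge d", {
  set.seed(23)
  v <- c(rnorm(50), rnorm(50, 5))
  g <- rep(c("lo", "hi"), each = 50)
  at <- anova_tukey(v, g)
  expect_lt(at$pairwise$p_adj, 1e-6)
  expect_gt(abs(at$pairwise$d), 3)
  expect_equal(sign(at$pairwise$d), sign(at$pairwise$mean_diff))
})

test_that("ANOVA rejects degenerate input, naming the offending group", {
  expect_error(anova_tukey(rep(1, 9), rep(c("a", "b", "c"), 3)), "degenerate")
  expect_error(anova_tukey(c(1, 2, 3), c("a", "a", "b")), "fewer than 2.*b")
  expect_error(anova_tukey(1:5, rep("a", 5)), "at least 2 groups")
})

test_that("all pairwise contrasts are produced for four states", {
  set.seed(24)
  v <- rnorm(240, rep(c(0.62, 0.48, 0.33, 0.60), each = 60), 0.03)
  g <- rep(c("W", "LS", "SWS", "REM"), each = 60)
  at <- anova_tukey(v, g)
  expect_equal(nrow(at$pairwise), 6)
  wsws <- at$pairwise[(at$pairwise$a == "W" & at$pairwise$b == "SWS") |
                      (at$pairwise$a == "SWS" & at$pairwise$b == "W"), ]
  expect_gt(abs(wsws$d), 0.8)
})

test_that("mixed fixed effects match the least-squares oracle when variances are zero", {
  cfg <- synth_config("dose", sigma_cat = 0, sigma_session = 0, seed = 31L)
  tab <- gen_dose_dataset("inverted_u", cfg)
  tab$x <- tab$dtilde
  fit <- suppressWarnings(fit_poly_mixed(tab, 2, "cat_session"))
  ols <- lm(C ~ poly(x, 2, raw = TRUE), data = tab)
  expect_equal(unname(fit$coefficients), unname(coef(ols)), tolerance = 1e-4)
  expect_true(fit$singular)  # variance components at the boundary
})

test_that("degree-0 fits return the grand mean; BIC follows its definition", {
  cfg <- synth_config("dose", seed = 32L)
  tab <- gen_dose_dataset("flat", cfg)
  tab$x <- tab$dtilde
  f0 <- fit_poly_mixed(tab, 0, "none")
  expect_equal(unname(f0$coefficients), mean(tab$C))
  for (fit in list(f0, fit_poly_mixed(tab, 1, "cat_session"))) {
    expect_equal(fit$BIC,
                 -2 * fit$loglik + fit$k_params * log(fit$n_obs),
                 tolerance = 1e-8)
  }
})

test_that("adding a polynomial term never decreases the log-likelihood", {
  cfg <- synth_config("dose", seed = 33L)
  tab <- gen_dose_dataset("inverted_u", cfg)
  tab$x <- tab$dtilde
  lls <- vapply(0:3, function(d)
    fit_poly_mixed(tab, d, "cat_session")$loglik, numeric(1))
  expect_true(all(diff(lls) >= -1e-6))
})

test_that("Bayes factors follow the BIC approximation and its algebra", {
  cfg <- synth_config("dose", seed = 34L)
  tab <- gen_dose_dataset("linear", cfg)
  tab$x <- tab$dtilde
  f1 <- fit_poly_mixed(tab, 1, "cat_session")
  f2 <- fit_poly_mixed(tab, 2, "cat_session")
  ab <- bayes_factor(f1, f2); ba <- bayes_factor(f2, f1)
  expect_equal(ab$bf, exp((f2$BIC - f1$BIC) / 2))
  expect_equal(ab$log_bf + ba$log_bf, 0, tolerance = 1e-12)
  expect_equal(ab$bf * ba$bf, 1, tolerance = 1e-9)
  same <- bayes_factor(f1, f1)
  expect_equal(same$bf, 1)
  expect_false(same$substantial)
  # a BIC gap of 2 log 5 is exactly the substantial-evidence boundary
  f_b <- f1; f_b$BIC <- f1$BIC + 2 * log(5)
  expect_equal(bayes_factor(f1, f_b)$bf, 5, tolerance = 1e-12)
  f_m <- f1; f_m$n_obs <- f1$n_obs - 1L
  expect_error(bayes_factor(f1, f_m), "not on identical data")
  f_r <- fit_poly_mixed(tab, 1, "cat_session", REML = TRUE)
  expect_error(bayes_factor(f_r, f1), "ML fits")
})

test_that("shape selection recovers the generating curve family", {
  cfg <- synth_config("dose")
  inv <- gen_dose_dataset("inverted_u", cfg); inv$x <- inv$dtilde
  sel <- select_shape(inv, degrees = 1:3, random_spec = "cat_session")
  expect_equal(sel$shape, "inverted-U")
  expect_equal(sel$preferred_degree, 2)
  expect_gt(sel$comparisons$degree2_vs_linear$log_bf, log(5))

  uu <- gen_dose_dataset("u", cfg); uu$x <- uu$dtilde
  expect_equal(select_shape(uu, degrees = 1:2,
                            random_spec = "cat_session")$shape, "U")

  lin <- gen_dose_dataset("linear", cfg); lin$x <- lin$dtilde
  sel_lin <- select_shape(lin, degrees = 1:2, random_spec = "cat_session")
  expect_equal(sel_lin$shape, "linear")
  expect_lt(sel_lin$comparisons$degree2_vs_linear$bf, 1)
})

test_that("stimulation effects are detected without a spurious interaction", {
  cfg <- synth_config("dose")
  tab <- gen_dose_dataset("inverted_u", cfg, include_stim = TRUE)
  rep_ <- stim_dose_model(tab)
  expect_equal(rep_$term, c("dose", "stim", "stim_x_dose"))
  stim_row <- rep_[rep_$term == "stim", ]
  int_row <- rep_[rep_$term == "stim_x_dose", ]
  expect_true(stim_row$reliable)
  expect_gt(stim_row$log_bf, log(5))
  expect_lt(int_row$bf, 1)
  expect_false(int_row$reliable)
  expect_lt(int_row$eta_sq, 0.01)
})

test_that("a null stimulation effect yields no substantial stim evidence", {
  cfg <- synth_config("dose", stim_effect = 0, seed = 35L)
  rep_ <- stim_dose_model(gen_dose_dataset("flat", cfg, include_stim = TRUE))
  expect_lt(rep_$bf[rep_$term == "stim_x_dose"], 1)
  expect_false(any(rep_$reliable))
})

test_that("degenerate stimulation designs raise a missing-cell error", {
  cfg <- synth_config("dose", doses = 5)
  tab <- gen_dose_dataset("flat", cfg, include_stim = TRUE)
  expect_error(stim_dose_model(tab), "2 doses")
  expect_error(stim_dose_model(data.frame(C = 1)), "missing columns")
})

test_that("cortex fixed effect is detected against the null, overflow-safe", {
  cfg <- synth_config("dose", seed = 36L)
  a <- gen_dose_dataset("flat", cfg); a$cortex <- "rPp"
  b <- a; b$cortex <- "lPp"; b$C <- b$C + 0.05
  cmp <- baseline_cortex_model(rbind(a, b))
  expect_equal(cmp$preferred, "a")
  expect_gt(cmp$log_bf, log(5))
  # identical distributions: the null wins or evidence is not substantial
  b$C <- a$C
  cmp0 <- baseline_cortex_model(rbind(a, b))
  expect_true(cmp0$preferred == "b" || !cmp0$substantial)
  # huge offset, no noise: finite overflow-safe Bayes factor
  cfg0 <- synth_config("dose", sigma_cat = 0, sigma_session = 0,
                       sigma_eps = 1e-6, seed = 37L)
  c1 <- gen_dose_dataset("flat", cfg0); c1$cortex <- "A"
  c2 <- c1; c2$cortex <- "B"; c2$C <- c2$C + 10
  cmp_inf <- suppressWarnings(baseline_cortex_model(rbind(c1, c2)))
  expect_true(is.finite(cmp_inf$bf))
  expect_error(baseline_cortex_model(a), "2 cortices")
})
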