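#' Cohen's d (pooled-SD standardized mean difference)
#'
#' `d = (mean(a) - mean(b)) / s_p`, with the pooled standard deviation
#' computed from the (n-1)-weighted sample variances. Invariant under a
#' common shift and common positive rescaling of both samples;
#' antisymmetric in its arguments.
#'
#' @param a,b Numeric vectors with at least 2 values each.
#' @return Cohen's d (unitless).
#' @export
cohens_d <- function(a, b) {
  if (length(a) < 2 || length(b) < 2)
    stop("both samples need at least 2 values")
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) stop("pooled standard deviation is zero; d is undefined")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' One-way ANOVA with Tukey HSD contrasts and effect sizes
#'
#' Omnibus F test across groups followed by all pairwise Tukey
#' honest-significant-difference comparisons (Tukey-Kramer under mild
#' imbalance, via [stats::TukeyHSD()]), each annotated with Cohen's d.
#'
#' @param values Numeric response vector.
#' @param groups Group labels (coerced to factor), same length as `values`.
#' @return A list with `F`, `p`, and `pairwise`, a data frame with one row
#'   per group pair: `a`, `b`, `mean_diff` (a minus b), `p_adj`
#'   (Tukey-adjusted), and `d`.
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 groups")
  tab <- table(groups)
  small <- names(tab)[tab < 2]
  if (length(small))
    stop("groups with fewer than 2 values: ", paste(small, collapse = ", "))
  df <- data.frame(y = values, g = groups)
  fit <- stats::aov(y ~ g, data = df)
  ss <- summary(fit)[[1]]
  ms_res <- ss[["Mean Sq"]][2]
  if (!is.finite(ms_res) ||
      ms_res <= .Machine$double.eps * (max(abs(values))^2 + 1))
    stop("degenerate within-group variance; ANOVA undefined")
  tk <- stats::TukeyHSD(fit)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairwise <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    a <- pairs[[i]][1]; b <- pairs[[i]][2]
    data.frame(a = a, b = b,
               mean_diff = unname(tk[i, "diff"]),
               p_adj = unname(tk[i, "p adj"]),
               d = cohens_d(values[groups == a], values[groups == b]),
               stringsAsFactors = FALSE)
  }))
  list(F = ss[["F value"]][1], p = ss[["Pr(>F)"]][1], pairwise = pairwise)
}

#' Fit a polynomial (mixed) model of complexity on a predictor
#'
#' Fits `C ~ poly(x, degree)` with the requested random-intercept
#' structure. Models intended for BIC/Bayes-factor comparison of fixed
#' effects are fitted by maximum likelihood (not REML), since REML
#' likelihoods are not comparable across fixed-effect structures.
#'
#' @param data Data frame with the response in `response`, the predictor in
#'   `predictor`, and (for mixed specs) `cat` and `session` columns.
#' @param degree Polynomial degree 0-3 (raw, not orthogonal, polynomials:
#'   coefficients stay interpretable on the centred-dose / state-code
#'   scale).
#' @param random_spec `"none"` (ordinary least squares), `"cat"` (random
#'   intercept per cat), or `"cat_session"` (random intercepts for cat and
#'   for session nested in cat).
#' @param predictor,response Column names (defaults `"x"` and `"C"`).
#' @param REML Fit by REML instead of ML (only for variance-component
#'   reporting; never for BIC comparison).
#' @return An `lz_model_fit` list: `degree`, `coefficients` (fixed
#'   effects), `loglik`, `BIC`, `n_obs`, `k_params`, `random_spec`,
#'   `converged`, `singular`, and the underlying `fit` object.
#' @export
fit_poly_mixed <- function(data, degree, random_spec = c("none", "cat", "cat_session"),
                           predictor = "x", response = "C", REML = FALSE) {
  random_spec <- match.arg(random_spec)
  stopifnot(degree %in% 0:3)
  if (!all(c(response, predictor) %in% names(data)) && degree > 0)
    stop("data must contain columns ", response, " and ", predictor)
  fixed <- if (degree == 0) "1" else
    sprintf("poly(%s, %d, raw = TRUE)", predictor, degree)
  converged <- TRUE
  singular <- FALSE
  if (random_spec == "none") {
    fml <- stats::as.formula(paste(response, "~", fixed))
    fit <- stats::lm(fml, data = data)
  } else {
    re <- if (random_spec == "cat") "(1 | cat)" else "(1 | cat) + (1 | cat:session)"
    fml <- stats::as.formula(paste(response, "~", fixed, "+", re))
    fit <- withCallingHandlers(
      lme4::lmer(fml, data = data, REML = REML,
                 control = lme4::lmerControl(check.conv.singular = "ignore")),
      warning = function(w) {
        converged <<- FALSE
        invokeRestart("muffleWarning")
      }
    )
    singular <- lme4::isSingular(fit)
    if (singular)
      warning("variance component at boundary (singular fit); fit retained")
  }
  ll <- stats::logLik(fit)
  n <- stats::nobs(fit)
  k <- attr(ll, "df")
  beta <- if (random_spec == "none") stats::coef(fit) else lme4::fixef(fit)
  names(beta) <- paste0("beta", seq_along(beta) - 1L)
  if (n <= k) stop("n_obs must exceed the number of parameters")
  structure(list(
    degree = degree,
    coefficients = beta,
    loglik = as.numeric(ll),
    BIC = stats::BIC(fit),
    n_obs = n,
    k_params = k,
    random_spec = random_spec,
    converged = converged,
    singular = singular,
    REML = REML,
    fit = fit
  ), class = "lz_model_fit")
}

#' BIC-approximated Bayes factor between two model fits
#'
#' `BF_ab = exp((BIC_b - BIC_a) / 2)`: the unit-information-prior
#' approximation to the Bayes factor in favour of model `a` over model
#' `b`. Values that would overflow double precision are clamped to the
#' largest representable double; `log_bf` is always exact. Evidence is
#' labelled substantial when the winning direction exceeds 5.
#'
#' @param fit_a,fit_b `lz_model_fit` objects fitted to the same data (same
#'   `n_obs`); ML fits, not REML.
#' @return An `lz_model_comparison` list: `bf` (BF_ab), `log_bf`,
#'   `preferred` (`"a"` or `"b"`), `substantial` (winning BF > 5), plus the
#'   two fits.
#' @export
bayes_factor <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "lz_model_fit"), inherits(fit_b, "lz_model_fit"))
  if (fit_a$n_obs != fit_b$n_obs)
    stop("fits are not on identical data: n_obs ", fit_a$n_obs, " vs ", fit_b$n_obs)
  if (isTRUE(fit_a$REML) || isTRUE(fit_b$REML))
    stop("Bayes factors require ML fits (REML = FALSE)")
  log_bf <- (fit_b$BIC - fit_a$BIC) / 2
  bf <- if (log_bf > log(.Machine$double.xmax)) .Machine$double.xmax
        else exp(log_bf)
  structure(list(
    model_a = fit_a, model_b = fit_b,
    bf = bf, log_bf = log_bf,
    preferred = if (log_bf >= 0) "a" else "b",
    substantial = abs(log_bf) > log(5)
  ), class = "lz_model_comparison")
}

#' Select the dose-response (or state-response) shape by Bayes factor
#'
#' Fits polynomial mixed models of the requested degrees, reports the
#' quadratic-versus-linear and (when fitted) cubic-versus-linear Bayes
#' factors, and labels the BIC-preferred shape: `"inverted-U"` when the
#' quadratic model wins with negative curvature, `"U"` when it wins with
#' positive curvature, `"cubic"` or `"linear"` otherwise.
#'
#' @inheritParams fit_poly_mixed
#' @param degrees Polynomial degrees to compare (default 1:3).
#' @return A list with `fits` (named by degree), `comparisons` (list of
#'   `lz_model_comparison`, higher degree as model a, linear as model b),
#'   `preferred_degree`, `shape`, and `table` — one row per fitted degree
#'   with `degree`, `BIC`, `BF_vs_linear`, `substantial`.
#' @export
select_shape <- function(data, degrees = 1:3,
                         random_spec = c("none", "cat", "cat_session"),
                         predictor = "x", response = "C") {
  random_spec <- match.arg(random_spec)
  stopifnot(1 %in% degrees)
  degrees <- sort(unique(degrees))
  fits <- lapply(degrees, fit_poly_mixed, data = data,
                 random_spec = random_spec, predictor = predictor,
                 response = response)
  names(fits) <- paste0("degree", degrees)
  lin <- fits[["degree1"]]
  comparisons <- list()
  bf_col <- rep(NA_real_, length(degrees))
  sub_col <- rep(NA, length(degrees))
  for (i in seq_along(degrees)) {
    if (degrees[i] == 1) next
    cmp <- bayes_factor(fits[[i]], lin)
    comparisons[[paste0("degree", degrees[i], "_vs_linear")]] <- cmp
    bf_col[i] <- cmp$bf
    sub_col[i] <- cmp$log_bf > log(5)
  }
  bics <- vapply(fits, `[[`, numeric(1), "BIC")
  preferred_degree <- degrees[which.min(bics)]
  shape <- if (preferred_degree == 2) {
    b2 <- fits[[which(degrees == 2)]]$coefficients[["beta2"]]
    if (b2 < 0) "inverted-U" else "U"
  } else if (preferred_degree == 3) "cubic" else "linear"
  list(
    fits = fits,
    comparisons = comparisons,
    preferred_degree = preferred_degree,
    shape = shape,
    table = data.frame(degree = degrees, BIC = unname(bics),
                       BF_vs_linear = bf_col, substantial = sub_col)
  )
}

# eta-squared of each fixed-effect term: SS_term / SS_total, with SS_term
# from the sequential fixed-effects decomposition of the ML fit and
# SS_total the total sum of squares of the centred response.
.eta_sq <- function(fit, response_values) {
  an <- stats::anova(fit)
  ss_total <- sum((response_values - mean(response_values))^2)
  stats::setNames(an[, "Sum Sq"] / ss_total, rownames(an))
}

#' Stimulation-by-dose effect report
#'
#' Quantifies the effect of auditory stimulation, of ketamine dose, and of
#' their interaction on per-epoch complexity, mirroring a
#' stimulated-versus-unstimulated dose-response design. Dose enters as a
#' raw quadratic polynomial in centred dose; random intercepts for cat and
#' session nested in cat. Each term is scored by a likelihood-ratio
#' p-value, a BIC-approximated Bayes factor against the model without that
#' term, and eta-squared from the full model's fixed-effects decomposition.
#' A term is labelled `reliable` only when both p < 0.01 and BF > 5.
#'
#' @param data Data frame with columns `C`, `dtilde` (centred dose),
#'   `stim` (logical), `cat`, `session`.
#' @return A data frame with one row per term (`dose`, `stim`,
#'   `stim_x_dose`): `p`, `eta_sq`, `bf`, `log_bf`, `reliable`.
#' @export
stim_dose_model <- function(data) {
  need <- c("C", "dtilde", "stim", "cat", "session")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  cells <- table(data$stim, data$dose %||% data$dtilde)
  if (nrow(cells) < 2 || ncol(cells) < 2 || any(cells == 0)) {
    bad <- if (any(cells == 0))
      paste(which(cells == 0, arr.ind = TRUE), collapse = ", ") else "entire rows/columns"
    stop("both stimulation levels must be present at >= 2 doses; missing cells: ", bad)
  }
  ml <- function(fml) lme4::lmer(stats::as.formula(fml), data = data, REML = FALSE,
                                 control = lme4::lmerControl(check.conv.singular = "ignore"))
  re <- "(1 | cat) + (1 | cat:session)"
  full     <- ml(paste("C ~ poly(dtilde, 2, raw = TRUE) * stim +", re))
  no_inter <- ml(paste("C ~ poly(dtilde, 2, raw = TRUE) + stim +", re))
  no_stim  <- ml(paste("C ~ poly(dtilde, 2, raw = TRUE) +", re))
  no_dose  <- ml(paste("C ~ stim +", re))
  lrt_p <- function(big, small) {
    dev <- 2 * (as.numeric(stats::logLik(big)) - as.numeric(stats::logLik(small)))
    df <- attr(stats::logLik(big), "df") - attr(stats::logLik(small), "df")
    stats::pchisq(pmax(dev, 0), df, lower.tail = FALSE)
  }
  bic_bf <- function(big, small) {
    log_bf <- (stats::BIC(small) - stats::BIC(big)) / 2
    c(bf = if (log_bf > log(.Machine$double.xmax)) .Machine$double.xmax else exp(log_bf),
      log_bf = log_bf)
  }
  eta <- .eta_sq(full, data$C)
  term_eta <- function(pattern) {
    hit <- grep(pattern, names(eta), value = TRUE)
    if (length(hit)) sum(eta[hit]) else NA_real_
  }
  rows <- list(
    dose = c(p = lrt_p(no_inter, no_dose), bic_bf(no_inter, no_dose),
             eta_sq = term_eta("^poly\\(dtilde, 2, raw = TRUE\\)$")),
    stim = c(p = lrt_p(no_inter, no_stim), bic_bf(no_inter, no_stim),
             eta_sq = term_eta("^stim")),
    stim_x_dose = c(p = lrt_p(full, no_inter), bic_bf(full, no_inter),
                    eta_sq = term_eta(":stim|stim.*:"))
  )
  out <- do.call(rbind, lapply(names(rows), function(nm) {
    v <- rows[[nm]]
    data.frame(term = nm, p = unname(v["p"]), eta_sq = unname(v["eta_sq"]),
               bf = unname(v["bf"]), log_bf = unname(v["log_bf"]),
               stringsAsFactors = FALSE)
  }))
  out$reliable <- out$p < 0.01 & out$log_bf > log(5)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Baseline complexity differences among cortices
#'
#' Contrasts a linear mixed model with cortex as a fixed effect (random
#' intercepts for cat and session nested in cat) against the intercept-only
#' null with the same random structure, by BIC-approximated Bayes factor.
#'
#' @param data Data frame with columns `C`, `cortex`, `cat`, `session`.
#' @return An `lz_model_comparison` with the cortex model as model a.
#' @export
baseline_cortex_model <- function(data) {
  if (!"cortex" %in% names(data)) stop("data must contain a cortex column")
  if (length(unique(data$cortex)) < 2)
    stop("need at least 2 cortices, got ", length(unique(data$cortex)))
  data$cortex <- factor(data$cortex)
  ctl <- lme4::lmerControl(check.conv.singular = "ignore")
  full <- lme4::lmer(C ~ cortex + (1 | cat) + (1 | cat:session),
                     data = data, REML = FALSE, control = ctl)
  null <- lme4::lmer(C ~ 1 + (1 | cat) + (1 | cat:session),
                     data = data, REML = FALSE, control = ctl)
  wrap <- function(fit, degree) {
    ll <- stats::logLik(fit)
    structure(list(degree = degree, coefficients = lme4::fixef(fit),
                   loglik = as.numeric(ll), BIC = stats::BIC(fit),
                   n_obs = stats::nobs(fit), k_params = attr(ll, "df"),
                   random_spec = "cat_session", converged = TRUE,
                   singular = lme4::isSingular(fit), REML = FALSE, fit = fit),
              class = "lz_model_fit")
  }
  bayes_factor(wrap(full, NA), wrap(null, 0))
}
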