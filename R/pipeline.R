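#' Read multichannel signals from long-format delimited text
#'
#' Reads the long CSV dialect
#' `cat,session,channel,condition,stim,sample_index,value` and reassembles
#' one recording per (cat, session, condition, stim) cell. `condition` is
#' either a vigilance-state label (`W`, `LS`, `SWS`, `REM`) or a numeric
#' dose in mg/kg. The sampling rate comes from `fs`, or from a JSON
#' sidecar `<path>.json` with a field `fs`.
#'
#' @param path CSV file path.
#' @param fs Sampling rate in Hz; if `NULL`, read from the sidecar.
#' @return A list of `lz_recording` objects.
#' @export
read_signals_csv <- function(path, fs = NULL) {
  if (is.null(fs)) {
    sidecar <- paste0(path, ".json")
    if (!file.exists(sidecar))
      stop("no fs given and no sidecar found at ", sidecar)
    fs <- jsonlite::read_json(sidecar)$fs
    if (is.null(fs)) stop("sidecar ", sidecar, " lacks an fs field")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cat", "session", "channel", "condition", "stim",
            "sample_index", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed header in ", path, ": missing field(s) ",
         paste(miss, collapse = ", "))
  key <- interaction(df$cat, df$session, df$condition, df$stim, drop = TRUE)
  lapply(split(df, key), function(d) {
    chans <- split(d, d$channel)
    lens <- vapply(chans, nrow, integer(1))
    if (length(unique(lens)) != 1L)
      stop("inconsistent channel lengths in ", path, " for cat=", d$cat[1],
           " session=", d$session[1], ": ",
           paste(names(lens), lens, sep = "=", collapse = ", "))
    signals <- lapply(chans, function(ch) ch$value[order(ch$sample_index)])
    cond <- d$condition[1]
    dose <- suppressWarnings(as.numeric(cond))
    recording(signals, fs = fs, cat = d$cat[1], session = d$session[1],
              state = if (is.na(dose)) cond else NA,
              dose = dose, stim = as.logical(d$stim[1]))
  })
}

#' Write recordings to long-format delimited text
#'
#' Inverse of [read_signals_csv()]; also writes the `fs` sidecar.
#'
#' @param recs A list of `lz_recording` objects (equal `fs`).
#' @param path Output CSV path.
#' @export
write_signals_csv <- function(recs, path) {
  if (inherits(recs, "lz_recording")) recs <- list(recs)
  rows <- lapply(recs, function(r) {
    do.call(rbind, lapply(names(r$signals), function(ch) {
      data.frame(cat = r$cat, session = r$session, channel = ch,
                 condition = if (!is.na(r$state)) r$state else r$dose,
                 stim = r$stim,
                 sample_index = seq_along(r$signals[[ch]]) - 1L,
                 value = r$signals[[ch]], stringsAsFactors = FALSE)
    }))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  jsonlite::write_json(list(fs = recs[[1]]$fs), paste0(path, ".json"),
                       auto_unbox = TRUE)
  invisible(path)
}

.rbind_all <- function(lst) {
  if (!length(lst)) return(NULL)
  out <- do.call(rbind, unname(lst))
  rownames(out) <- NULL
  out
}

.provenance <- function(cfg) {
  list(package = "neurolz",
       version = as.character(utils::packageVersion("neurolz")),
       seed = cfg$seed,
       config_hash = rlang::hash(unclass(cfg)))
}

#' Per-cortex sleep-state analysis
#'
#' For every cortex in a per-epoch complexity table: state means and SDs,
#' a one-way ANOVA with Tukey contrasts and Cohen's d over states, and a
#' linear-versus-quadratic mixed-model comparison (states coded 0-3 in the
#' progression W, LS, SWS, REM; random intercept per cat when more than
#' one cat contributes, ordinary least squares otherwise). A cortex
#' missing a state, or otherwise unanalysable, is skipped with a logged
#' reason rather than aborting the run.
#'
#' @param complexity Long data frame with columns `cat`, `channel`,
#'   `state`, `C` (e.g. from [gen_sleep_dataset()] or [epochs_lz()]).
#' @param cfg The `lz_synth_config` (or any list with `states` and `seed`)
#'   used for provenance; defaults to `synth_config("sleep")`.
#' @return A report bundle: `state_summary`, `pairwise`, `model_selection`
#'   (one row per cortex: n_cats, BIC linear/quadratic, BF, substantial,
#'   shape), `skipped`, `provenance`.
#' @export
run_sleep_analysis <- function(complexity, cfg = synth_config("sleep")) {
  states <- cfg$states %||% c("W", "LS", "SWS", "REM")
  summaries <- list(); pairwise <- list(); selection <- list(); skipped <- list()
  for (cortex in sort(unique(complexity$channel))) {
    d <- complexity[complexity$channel == cortex, ]
    present <- intersect(states, unique(d$state))
    if (length(present) < 2) {
      skipped[[cortex]] <- data.frame(
        cortex = cortex,
        reason = paste0("fewer than 2 states present (",
                        paste(present, collapse = ","), ")"))
      next
    }
    res <- tryCatch({
      sm <- do.call(rbind, lapply(present, function(s) {
        v <- d$C[d$state == s]
        data.frame(cortex = cortex, state = s, n_epochs = length(v),
                   mean_C = mean(v), sd_C = stats::sd(v))
      }))
      at <- anova_tukey(d$C, factor(d$state, levels = present))
      pw <- cbind(cortex = cortex, at$pairwise)
      d$x <- match(d$state, states) - 1
      n_cats <- length(unique(d$cat))
      rs <- if (n_cats > 1) "cat" else "none"
      sel <- select_shape(d, degrees = 1:2, random_spec = rs)
      cmp <- sel$comparisons$degree2_vs_linear
      ms <- data.frame(cortex = cortex, n_cats = n_cats,
                       BIC_linear = sel$table$BIC[1],
                       BIC_quadratic = sel$table$BIC[2],
                       BF_quad_vs_linear = cmp$bf,
                       substantial = cmp$log_bf > log(5),
                       shape = sel$shape)
      list(sm = sm, pw = pw, ms = ms)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[cortex]] <- data.frame(cortex = cortex,
                                      reason = conditionMessage(res))
      next
    }
    summaries[[cortex]] <- res$sm
    pairwise[[cortex]] <- res$pw
    selection[[cortex]] <- res$ms
  }
  list(state_summary = .rbind_all(summaries),
       pairwise = .rbind_all(pairwise),
       model_selection = .rbind_all(selection),
       skipped = .rbind_all(skipped),
       provenance = .provenance(cfg))
}

#' Per-cortex ketamine dose-response analysis
#'
#' For every cortex (or for a single unlabelled table): a per-dose summary
#' curve, linear/quadratic/cubic mixed-model shape selection with Bayes
#' factors (random intercepts for cat and session nested in cat), and —
#' when both stimulation levels are present — a stimulation-by-dose effect
#' report.
#'
#' @param dose_table Long data frame with columns `cat`, `session`, `dose`,
#'   `dtilde`, `stim`, `C`, optionally `channel`.
#' @param cfg Configuration used for provenance (default
#'   `synth_config("dose")`).
#' @param degrees Polynomial degrees for shape selection.
#' @return A report bundle: `dose_curve`, `model_selection` (Bayes-factor
#'   table per cortex), `shape`, `stim_report` (or NULL), `skipped`,
#'   `provenance`.
#' @export
run_dose_analysis <- function(dose_table, cfg = synth_config("dose"),
                              degrees = 1:3) {
  if (!"channel" %in% names(dose_table)) dose_table$channel <- "pooled"
  curves <- list(); selection <- list(); shapes <- list()
  stim_reports <- list(); skipped <- list()
  for (cortex in sort(unique(dose_table$channel))) {
    d <- dose_table[dose_table$channel == cortex, ]
    if (length(unique(d$dose)) < 2) {
      skipped[[cortex]] <- data.frame(cortex = cortex,
                                      reason = "fewer than 2 dose levels")
      next
    }
    res <- tryCatch({
      curve <- do.call(rbind, lapply(sort(unique(d$dose)), function(ds) {
        v <- d$C[d$dose == ds]
        data.frame(cortex = cortex, dose = ds, n_epochs = length(v),
                   mean_C = mean(v), sd_C = stats::sd(v))
      }))
      d$x <- d$dtilde
      sel <- select_shape(d, degrees = degrees, random_spec = "cat_session")
      tab <- cbind(cortex = cortex, n_cats = length(unique(d$cat)), sel$table)
      sr <- if (length(unique(d$stim)) == 2) cbind(cortex = cortex,
                                                   stim_dose_model(d)) else NULL
      list(curve = curve, tab = tab,
           shape = data.frame(cortex = cortex, shape = sel$shape,
                              preferred_degree = sel$preferred_degree),
           sr = sr)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      skipped[[cortex]] <- data.frame(cortex = cortex,
                                      reason = conditionMessage(res))
      next
    }
    curves[[cortex]] <- res$curve
    selection[[cortex]] <- res$tab
    shapes[[cortex]] <- res$shape
    if (!is.null(res$sr)) stim_reports[[cortex]] <- res$sr
  }
  list(dose_curve = .rbind_all(curves),
       model_selection = .rbind_all(selection),
       shape = .rbind_all(shapes),
       stim_report = .rbind_all(stim_reports),
       skipped = .rbind_all(skipped),
       provenance = .provenance(cfg))
}

#' Write a report bundle to disk
#'
#' Writes every data-frame component of a report bundle as CSV and a
#' `manifest.json` carrying the provenance block (package version, seed,
#' config hash), so a rerun with the same configuration and seed
#' reproduces the outputs byte for byte.
#'
#' @param bundle A report bundle from [run_sleep_analysis()] or
#'   [run_dose_analysis()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(bundle)) {
    if (is.data.frame(bundle[[nm]]))
      utils::write.csv(bundle[[nm]], file.path(dir, paste0(nm, ".csv")),
                       row.names = FALSE)
  }
  jsonlite::write_json(bundle$provenance, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
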