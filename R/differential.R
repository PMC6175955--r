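# Core differential HDX-MS statistics: relative fractional uptake,
# per-timepoint and summed delta-HDX (variant minus control), a
# Houde-style pooled-variance global confidence threshold on the summed
# difference, an unpaired two-sided t-test on per-replicate summed
# uptake, and the dual-gate per-peptide classification.

#' Relative fractional uptake (RFU)
#'
#' `RFU = Y / (MaxUptake x D)`: the deuterium uptake `Y` (Da) of a
#' peptide normalized by its count of exchangeable amides and the
#' deuterium fraction `D` of the labeling mix. A fully saturated peptide
#' has RFU 1 (in the absence of back-exchange, which is not corrected
#' for).
#'
#' @param uptake_da Uptake in Da (>= 0).
#' @param max_uptake Exchangeable amide count (>= 1).
#' @param deuterium_fraction Deuterium fraction after mixing, in (0, 1];
#'   default 0.95 (5 uL protein into 95 uL labeling buffer).
#' @return Unitless fractional uptake.
#' @examples
#' relative_fractional_uptake(9.5, 10)        # 1
#' relative_fractional_uptake(2.0, 10, 0.95)  # 0.2105...
#' @export
relative_fractional_uptake <- function(uptake_da, max_uptake,
                                       deuterium_fraction = 0.95) {
  if (any(max_uptake == 0)) {
    abort("RFU undefined: peptide has no exchangeable amides (max_uptake = 0).",
          class = "hdx_rfu_error")
  }
  if (any(uptake_da < 0)) {
    abort("`uptake_da` must be non-negative.", class = "hdx_parameter_error")
  }
  if (any(deuterium_fraction <= 0 | deuterium_fraction > 1)) {
    abort("`deuterium_fraction` must lie in (0, 1].",
          class = "hdx_parameter_error")
  }
  uptake_da / (max_uptake * deuterium_fraction)
}

pep_keys <- c("protein", "start", "end", "sequence", "max_uptake")

# replicate-level rows of complete groups only; warns once if any
# incomplete groups are dropped
usable_rows <- function(dataset, label) {
  x <- as_tibble(dataset)
  if (!"incomplete" %in% names(x)) x$incomplete <- FALSE
  if (any(x$incomplete)) {
    warn(paste0("Skipping incomplete replicate groups in the ", label,
                " dataset."))
  }
  filter(x, !.data$incomplete)
}

#' Per-timepoint uptake difference between two states
#'
#' For every peptide and exposure time present with complete replicates
#' in both datasets, computes the mean uptake difference
#' (variant minus control) and its standard error
#' `sqrt(s_v^2/n_v + s_c^2/n_c)`.
#'
#' @param control,variant Uptake datasets ([as_hdx_dataset()] tibbles)
#'   for the control and variable state.
#' @return A tibble with one row per (peptide, exposure): peptide keys,
#'   `exposure_s`, `mean_control`, `mean_variant`, `delta_da`, `se_da`,
#'   `n_control`, `n_variant`.
#' @export
delta_uptake <- function(control, variant) {
  per_group <- function(x, suffix) {
    x |>
      group_by(across(all_of(c(pep_keys, "exposure_s")))) |>
      summarise(mean = mean(.data$uptake_da),
                var = stats::var(.data$uptake_da),
                n = dplyr::n(), .groups = "drop") |>
      rename(!!paste0("mean_", suffix) := "mean",
             !!paste0("var_", suffix) := "var",
             !!paste0("n_", suffix) := "n")
  }
  inner_join(per_group(usable_rows(control, "control"), "control"),
             per_group(usable_rows(variant, "variant"), "variant"),
             by = c(pep_keys, "exposure_s")) |>
    mutate(delta_da = .data$mean_variant - .data$mean_control,
           se_da = sqrt(.data$var_variant / .data$n_variant +
                        .data$var_control / .data$n_control)) |>
    select(all_of(pep_keys), "exposure_s", "mean_control", "mean_variant",
           "delta_da", "se_da", "n_control", "n_variant") |>
    arrange(.data$start, .data$end, .data$exposure_s)
}

#' Global significance threshold for summed delta-HDX
#'
#' Houde-style pooled-variance threshold: the pooled replicate SD is the
#' root-mean-square of the per-(peptide, state, exposure) replicate SDs
#' over both datasets; the SE of one per-timepoint difference is
#' `sqrt(2) * pooled_sd / sqrt(n)`; the symmetric threshold on the
#' summed difference over `k` timepoints is
#' `t_{1 - alpha/2, df} * sqrt(k) * sqrt(2) * pooled_sd / sqrt(n)`, with
#' `df = sum(n_g - 1)` over all contributing replicate groups.
#'
#' @param control,variant Uptake datasets.
#' @param alpha Significance level (default 0.01, i.e. a 99% confidence
#'   threshold).
#' @return An object of class `hdx_thresholds`: `alpha`, `pooled_sd`
#'   (Da), `se_delta` (Da), `summed_ci` (Da), `df`, `n`, `k_timepoints`.
#' @export
houde_threshold <- function(control, variant, alpha = 0.01) {
  groups <- bind_rows(usable_rows(control, "control"),
                      usable_rows(variant, "variant")) |>
    group_by(across(all_of(c(pep_keys, "state", "exposure_s")))) |>
    summarise(sd = sd(.data$uptake_da), n = dplyr::n(), .groups = "drop")
  if (nrow(groups) == 0) {
    abort("No usable replicate groups for threshold estimation.",
          class = "hdx_insufficient_data_error")
  }
  pooled_sd <- sqrt(mean(groups$sd^2))
  df <- sum(groups$n - 1)
  n <- round(mean(groups$n))
  k <- length(union(unique(as_tibble(control)$exposure_s),
                    unique(as_tibble(variant)$exposure_s)))
  se_delta <- sqrt(2) * pooled_sd / sqrt(n)
  summed_ci <- qt(1 - alpha / 2, df) * sqrt(k) * se_delta
  structure(
    list(alpha = alpha, pooled_sd = pooled_sd, se_delta = se_delta,
         summed_ci = summed_ci, df = df, n = n, k_timepoints = k),
    class = "hdx_thresholds"
  )
}

#' @export
print.hdx_thresholds <- function(x, ...) {
  cat(sprintf(
    "<hdx_thresholds> alpha = %g | pooled SD = %.4g Da | summed-dHDX threshold = +/- %.4g Da (df = %d, k = %d)\n",
    x$alpha, x$pooled_sd, x$summed_ci, x$df, x$k_timepoints))
  invisible(x)
}

#' Differential HDX-MS analysis of two states
#'
#' The full peptide-level differential workflow. For every peptide
#' present with complete replicates in both datasets and at every
#' exposure time: per-timepoint mean difference and SE
#' ([delta_uptake()]); the summed difference over timepoints; an
#' unpaired two-sided t-test comparing per-replicate summed uptake
#' (sum over timepoints within a replicate) between states; and the
#' dual-gate classification - `positive` if the summed difference
#' exceeds the +[houde_threshold()] and `p <= alpha`, `negative` for the
#' mirrored case, `none` otherwise. Peptides covered in only one state
#' are reported separately (`no_coverage`). Both states must have been
#' measured at identical exposure times; a mismatch is an error, never a
#' silent intersection.
#'
#' @param control,variant Uptake datasets ([as_hdx_dataset()] tibbles).
#' @param alpha Significance level for both gates (default 0.01).
#' @param var_equal Equal-variance (pooled) t-test, the convention for
#'   n = 3 HDX replicates; set `FALSE` for Welch.
#' @param p_adjust Multiple-testing correction passed to
#'   [stats::p.adjust()]; `"none"` by default (the conventional choice
#'   for peptide-level HDX significance maps).
#' @return An object of class `hdx_differential`: a list with `records`
#'   (one row per shared peptide: keys, per-timepoint deltas in nested
#'   column `per_timepoint`, `summed_delta_da`, `summed_se_da`, `rfu_*`
#'   auxiliaries, `t_statistic`, `df`, `p_value`, `classification`),
#'   `thresholds`, `no_coverage` (peptides in one state only), `alpha`,
#'   and the labeling metadata.
#' @export
run_differential <- function(control, variant, alpha = 0.01,
                             var_equal = TRUE, p_adjust = "none") {
  cond <- hdx_conditions_of(control) %||% hdx_conditions_of(variant)
  D <- if (!is.null(cond)) cond$deuterium_fraction else 0.95

  tc <- sort(unique(as_tibble(control)$exposure_s))
  tv <- sort(unique(as_tibble(variant)$exposure_s))
  if (!identical(tc, tv)) {
    abort(paste0(
      "Exposure-time mismatch between states: control has {",
      paste(tc, collapse = ", "), "} s, variant has {",
      paste(tv, collapse = ", "), "} s."),
      class = "hdx_timepoint_mismatch_error")
  }
  k <- length(tc)

  cpep <- distinct(as_tibble(control)[pep_keys])
  vpep <- distinct(as_tibble(variant)[pep_keys])
  shared <- inner_join(cpep, vpep, by = pep_keys)
  no_cov <- bind_rows(
    anti_join(cpep, vpep, by = pep_keys) |> mutate(missing_in = "variant"),
    anti_join(vpep, cpep, by = pep_keys) |> mutate(missing_in = "control")
  )
  if (nrow(shared) == 0) {
    warn("Control and variant share no peptides; result is empty.")
    return(structure(list(records = tibble(), thresholds = NULL,
                          no_coverage = no_cov, alpha = alpha,
                          deuterium_fraction = D),
                     class = "hdx_differential"))
  }

  thresholds <- houde_threshold(control, variant, alpha = alpha)
  deltas <- delta_uptake(control, variant)

  summed <- deltas |>
    group_by(across(all_of(pep_keys))) |>
    summarise(
      summed_delta_da = sum(.data$delta_da),
      summed_se_da = sqrt(sum(.data$se_da^2)),
      n_timepoints = dplyr::n(),
      mean_uptake_control = sum(.data$mean_control),
      mean_uptake_variant = sum(.data$mean_variant),
      .groups = "drop") |>
    filter(.data$n_timepoints == k)

  # per-replicate summed uptake (sum across timepoints within replicate)
  rep_sums <- function(x) {
    usable_rows(x, "dataset") |>
      group_by(across(all_of(c(pep_keys, "replicate")))) |>
      summarise(summed = sum(.data$uptake_da),
                n_t = dplyr::n(), .groups = "drop") |>
      filter(.data$n_t == k)
  }
  sc <- rep_sums(control)
  sv <- rep_sums(variant)
  tests <- summed |>
    select(all_of(pep_keys)) |>
    mutate(.test = pmap(list(.data$protein, .data$start, .data$end,
                             .data$sequence), function(pr, s, e, sq) {
      a <- sv$summed[sv$protein == pr & sv$start == s & sv$end == e &
                     sv$sequence == sq]
      b <- sc$summed[sc$protein == pr & sc$start == s & sc$end == e &
                     sc$sequence == sq]
      if (length(a) < 2 || length(b) < 2) {
        return(tibble(t_statistic = NA_real_, df = NA_real_,
                      p_value = NA_real_))
      }
      if (sd(a) == 0 && sd(b) == 0) {
        # degenerate: identical replicates; difference is exact
        eq <- isTRUE(all.equal(mean(a), mean(b)))
        return(tibble(t_statistic = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                      df = length(a) + length(b) - 2,
                      p_value = if (eq) 1 else 0))
      }
      tt <- t.test(a, b, var.equal = var_equal)
      tibble(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
             p_value = tt$p.value)
    })) |>
    unnest(".test")

  records <- summed |>
    left_join(tests, by = pep_keys) |>
    mutate(
      p_value = p.adjust(.data$p_value, method = p_adjust),
      rfu_control = dplyr::if_else(
        .data$max_uptake > 0,
        .data$mean_uptake_control / k / (.data$max_uptake * D), NA_real_),
      rfu_variant = dplyr::if_else(
        .data$max_uptake > 0,
        .data$mean_uptake_variant / k / (.data$max_uptake * D), NA_real_),
      classification = dplyr::case_when(
        is.na(.data$p_value) ~ "none",
        .data$summed_delta_da > thresholds$summed_ci &
          .data$p_value <= alpha ~ "positive",
        .data$summed_delta_da < -thresholds$summed_ci &
          .data$p_value <= alpha ~ "negative",
        TRUE ~ "none")
    ) |>
    left_join(tidyr::nest(deltas, per_timepoint = !all_of(pep_keys)),
              by = pep_keys) |>
    select(all_of(pep_keys), "per_timepoint", "summed_delta_da",
           "summed_se_da", "rfu_control", "rfu_variant", "t_statistic",
           "df", "p_value", "classification") |>
    arrange(.data$start, .data$end)

  structure(
    list(records = records, thresholds = thresholds, no_coverage = no_cov,
         alpha = alpha, deuterium_fraction = D,
         timepoints_s = tc),
    class = "hdx_differential"
  )
}

#' @export
print.hdx_differential <- function(x, ...) {
  counts <- table(factor(x$records$classification,
                         levels = c("positive", "negative", "none")))
  cat(sprintf(
    "<hdx_differential> %d peptides | positive %d, negative %d, none %d | %d without paired coverage\n",
    nrow(x$records), counts[["positive"]], counts[["negative"]],
    counts[["none"]], nrow(x$no_coverage)))
  if (!is.null(x$thresholds)) print(x$thresholds)
  invisible(x)
}

#' @describeIn run_differential One row per peptide with test statistics
#'   and classification (per-timepoint deltas unnested on request via
#'   `per_timepoint = TRUE`).
#' @param x An `hdx_differential` object.
#' @param per_timepoint Return one row per (peptide, exposure) instead.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.hdx_differential <- function(x, per_timepoint = FALSE, ...) {
  if (per_timepoint) {
    x$records |>
      select(all_of(pep_keys), "per_timepoint", "classification") |>
      unnest("per_timepoint")
  } else {
    select(x$records, -"per_timepoint")
  }
}

#' @describeIn run_differential One-row summary: peptide and class
#'   counts, pooled SD, threshold, alpha.
#' @exportS3Method generics::glance
glance.hdx_differential <- function(x, ...) {
  counts <- table(factor(x$records$classification,
                         levels = c("positive", "negative", "none")))
  tibble(
    n_peptides = nrow(x$records),
    n_positive = unname(counts[["positive"]]),
    n_negative = unname(counts[["negative"]]),
    n_none = unname(counts[["none"]]),
    n_no_coverage = nrow(x$no_coverage),
    pooled_sd_da = x$thresholds$pooled_sd %||% NA_real_,
    summed_ci_da = x$thresholds$summed_ci %||% NA_real_,
    alpha = x$alpha
  )
}

#' Write differential results as TSV
#'
#' One row per peptide: keys, per-timepoint deltas in wide columns
#' (`delta_<t>s`), summed delta, SE, t, df, p, classification, and the
#' threshold used.
#'
#' @param diff An `hdx_differential` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_differential_tsv <- function(diff, path) {
  wide <- tidy(diff, per_timepoint = TRUE) |>
    select(all_of(pep_keys), "exposure_s", "delta_da") |>
    mutate(exposure_s = paste0("delta_", .data$exposure_s, "s")) |>
    pivot_wider(names_from = "exposure_s", values_from = "delta_da")
  out <- tidy(diff) |>
    left_join(wide, by = pep_keys) |>
    mutate(summed_ci_da = diff$thresholds$summed_ci %||% NA_real_)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
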