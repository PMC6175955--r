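# Two-state (OF/IF) Linderstrom-Lang exchange-kinetics simulator.
#
# The generator emulates the diagnostic geometry of a 12-TM MFS
# transporter probed by differential HDX-MS: intracellular loops are
# closed (protected) in the outward-facing state and open in the
# inward-facing state, extracellular loops the converse, transmembrane
# helices equally protected in both. Under fast conformational exchange
# (EX2) the observed per-residue rate is the population-weighted mixture
# k_obs = k_int * (f_IF / P_IF + (1 - f_IF) / P_OF).

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Default two-state transporter scenario
#'
#' Builds a per-residue ground-truth model of a 12-helix-like membrane
#' transporter: residues are partitioned into alternating
#' intracellular-loop / transmembrane / extracellular-loop blocks
#' (termini intracellular, as in the MFS fold); intracellular residues
#' are more protected in the outward-facing (OF) state than the
#' inward-facing (IF) state, extracellular residues the converse, and
#' transmembrane residues equally protected in both. The control
#' condition sits at a 50/50 OF/IF equilibrium; the variant is shifted
#' by `delta_population` toward the requested state.
#'
#' Protection factors are log10 units: loops have baseline
#' `log10_protection_loop` with the affected state raised by
#' `protection_contrast`; transmembrane residues use
#' `log10_protection_tm` in both states. Intrinsic amide exchange rates
#' are drawn log-uniformly from `intrinsic_rate_range` (per minute),
#' spanning a 30 s - 150 min observation window; supply
#' `intrinsic_rates` to override (e.g. sequence-specific reference
#' rates).
#'
#' @param n_residues Protein length (>= 50).
#' @param shift Direction of the variant's equilibrium shift:
#'   `"toward_IF"`, `"toward_OF"`, or `"none"`.
#' @param seed Integer seed; the scenario is fully deterministic given
#'   the seed and parameters.
#' @param delta_population Population shift of the variant (default 0.3).
#' @param protection_contrast OF-vs-IF protection difference in affected
#'   loop regions, log10 units (default 1.0).
#' @param log10_protection_loop,log10_protection_tm Baseline log10
#'   protection factors for loop and transmembrane residues.
#' @param intrinsic_rate_range Range (per minute) for log-uniform
#'   intrinsic-rate sampling.
#' @param intrinsic_rates Optional per-residue intrinsic rates (per
#'   minute), length `n_residues`.
#' @param n_helices Number of transmembrane helices (default 12).
#' @return An object of class `hdx_scenario`: a list with `sequence`,
#'   `log10_protection_OF`, `log10_protection_IF`,
#'   `intrinsic_rates_per_min`, `region_labels`
#'   (`"intracellular"`/`"transmembrane"`/`"extracellular"`),
#'   `population_IF_control`, `population_IF_variant`, `shift`.
#' @export
default_transporter_scenario <- function(n_residues,
                                         shift = c("toward_IF", "toward_OF", "none"),
                                         seed = 1L,
                                         delta_population = 0.3,
                                         protection_contrast = 1.0,
                                         log10_protection_loop = 2.0,
                                         log10_protection_tm = 4.0,
                                         intrinsic_rate_range = c(1, 1000),
                                         intrinsic_rates = NULL,
                                         n_helices = 12L) {
  shift <- match.arg(shift)
  n_residues <- as.integer(n_residues)
  tm_len <- 14L
  min_loop <- 4L
  n_helices <- as.integer(n_helices)
  while (n_helices > 2 &&
         n_helices * tm_len + (n_helices + 1) * min_loop > n_residues) {
    n_helices <- n_helices - 2L
  }
  if (n_helices * tm_len + (n_helices + 1) * min_loop > n_residues) {
    abort("`n_residues` too small to hold one block of each region type.",
          class = "hdx_parameter_error")
  }

  # loops alternate in/out starting and ending intracellular (even helix
  # count); spread leftover residues evenly across loops
  n_loops <- n_helices + 1L
  loop_total <- n_residues - n_helices * tm_len
  loop_len <- rep(loop_total %/% n_loops, n_loops)
  extra <- loop_total %% n_loops
  if (extra > 0) loop_len[seq_len(extra)] <- loop_len[seq_len(extra)] + 1L
  loop_side <- rep(c("intracellular", "extracellular"), length.out = n_loops)

  region <- character(0)
  for (i in seq_len(n_helices)) {
    region <- c(region, rep(loop_side[i], loop_len[i]),
                rep("transmembrane", tm_len))
  }
  region <- c(region, rep(loop_side[n_loops], loop_len[n_loops]))
  stopifnot(length(region) == n_residues)

  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
    code
  }
  out <- withr_seed({
    sequence <- paste(sample(AA20, n_residues, replace = TRUE,
                             prob = c(rep(1, 12), 0.6, rep(1, 7))),
                      collapse = "")
    rates <- intrinsic_rates %||%
      10^runif(n_residues, log10(intrinsic_rate_range[1]),
               log10(intrinsic_rate_range[2]))
    list(sequence = sequence, rates = rates)
  })
  if (length(out$rates) != n_residues || any(out$rates <= 0)) {
    abort("`intrinsic_rates` must be positive and of length `n_residues`.",
          class = "hdx_parameter_error")
  }

  pOF <- pIF <- rep(log10_protection_loop, n_residues)
  tm <- region == "transmembrane"
  pOF[tm] <- pIF[tm] <- log10_protection_tm
  ic <- region == "intracellular"
  ec <- region == "extracellular"
  pOF[ic] <- log10_protection_loop + protection_contrast  # closed inside
  pIF[ec] <- log10_protection_loop + protection_contrast  # closed outside

  f_control <- 0.5
  f_variant <- switch(shift,
    toward_IF = f_control + delta_population,
    toward_OF = f_control - delta_population,
    none = f_control
  )
  if (f_variant < 0 || f_variant > 1) {
    abort("`delta_population` pushes the variant population outside [0, 1].",
          class = "hdx_parameter_error")
  }

  structure(
    list(sequence = out$sequence,
         log10_protection_OF = pOF,
         log10_protection_IF = pIF,
         intrinsic_rates_per_min = out$rates,
         region_labels = region,
         population_IF_control = f_control,
         population_IF_variant = f_variant,
         shift = shift,
         seed = as.integer(seed)),
    class = "hdx_scenario"
  )
}

#' @export
print.hdx_scenario <- function(x, ...) {
  cat(sprintf(
    "<hdx_scenario> %d residues | shift: %s | f_IF control/variant: %.2f/%.2f\n",
    nchar(x$sequence), x$shift, x$population_IF_control,
    x$population_IF_variant))
  print(table(x$region_labels))
  invisible(x)
}

#' Per-residue deuterium uptake fraction under EX2 kinetics
#'
#' Closed-form uptake of a single amide after exposure time `time_s`,
#' assuming fast conformational exchange between the OF and IF states:
#' `1 - exp(-k_obs * t)` with
#' `k_obs = k_int * (f_IF / P_IF + (1 - f_IF) / P_OF)`.
#' Vectorized over `residue_index` and `time_s` (recycled).
#'
#' @param scenario An [default_transporter_scenario()] object.
#' @param residue_index 1-based residue indices.
#' @param state_population_IF Fraction of molecules in the IF state.
#' @param time_s Exposure time(s) in seconds.
#' @return Uptake fractions in [0, 1].
#' @export
residue_uptake_fraction <- function(scenario, residue_index,
                                    state_population_IF, time_s) {
  if (any(time_s < 0)) {
    abort("`time_s` must be non-negative.", class = "hdx_parameter_error")
  }
  if (state_population_IF < 0 || state_population_IF > 1) {
    abort("`state_population_IF` must lie in [0, 1].",
          class = "hdx_parameter_error")
  }
  k_int <- scenario$intrinsic_rates_per_min[residue_index]
  P_OF <- 10^scenario$log10_protection_OF[residue_index]
  P_IF <- 10^scenario$log10_protection_IF[residue_index]
  k_obs <- k_int * (state_population_IF / P_IF +
                    (1 - state_population_IF) / P_OF)
  1 - exp(-k_obs * time_s / 60)
}

#' In-silico digestion with a coverage target
#'
#' Draws overlapping peptides with random start positions and lengths
#' uniform in `length_range`, accumulating until the fraction of
#' residues covered by at least one peptide reaches `target_coverage`
#' (and, optionally, at least `min_peptides` peptides exist) or a
#' bounded attempt count is exhausted; in the latter case a warning is
#' raised and the partial result returned. Duplicate spans are
#' discarded. Deterministic given `seed`.
#'
#' @param sequence Protein sequence (one-letter codes).
#' @param target_coverage Fraction of residues that must be covered.
#' @param length_range Peptide length window (default `c(5, 25)`,
#'   the conventional bottom-up filter).
#' @param seed Integer seed.
#' @param min_peptides Keep drawing until at least this many peptides
#'   exist (0 = coverage target only).
#' @param max_attempts Attempt bound.
#' @return A tibble of peptides (`start`, `end`, `sequence`,
#'   `max_uptake`) with attribute `achieved_coverage`.
#' @export
digest_in_silico <- function(sequence, target_coverage = 0.8,
                             length_range = c(5, 25), seed = 1L,
                             min_peptides = 0L, max_attempts = 10000L) {
  if (target_coverage <= 0 || target_coverage > 1) {
    abort("`target_coverage` must lie in (0, 1].",
          class = "hdx_parameter_error")
  }
  n <- nchar(sequence)
  if (n < length_range[1]) {
    abort("Sequence shorter than the minimum peptide length.",
          class = "hdx_parameter_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)

  covered <- logical(n)
  starts <- integer(0); ends <- integer(0)
  attempts <- 0L
  repeat {
    cov <- mean(covered)
    if ((cov >= target_coverage && length(starts) >= min_peptides) ||
        attempts >= max_attempts) break
    attempts <- attempts + 1L
    len <- sample(seq(length_range[1], min(length_range[2], n)), 1)
    s <- sample(seq_len(n - len + 1), 1)
    e <- s + len - 1L
    if (any(starts == s & ends == e)) next
    starts <- c(starts, s); ends <- c(ends, e)
    covered[s:e] <- TRUE
  }
  achieved <- mean(covered)
  if (achieved < target_coverage || length(starts) < min_peptides) {
    warn(sprintf(
      "Digestion stopped after %d attempts with coverage %.3f (target %.3f) and %d peptides; returning partial result.",
      attempts, achieved, target_coverage, length(starts)))
  }
  seqs <- substring(sequence, starts, ends)
  out <- tibble(start = starts, end = ends, sequence = seqs,
                max_uptake = compute_max_uptake(seqs)) |>
    arrange(.data$start, .data$end)
  attr(out, "achieved_coverage") <- achieved
  out
}

#' Noise model for simulated replicates
#'
#' @param replicate_sd Gaussian replicate standard deviation in Da
#'   (default 0.05, typical instrument repeatability); replicate values
#'   are truncated at zero.
#' @param seed Integer seed.
#' @return A list of class `hdx_noise`.
#' @export
noise_model <- function(replicate_sd = 0.05, seed = 1L) {
  if (replicate_sd < 0) {
    abort("`replicate_sd` must be non-negative.",
          class = "hdx_parameter_error")
  }
  structure(list(replicate_sd = replicate_sd, seed = as.integer(seed)),
            class = "hdx_noise")
}

#' Simulate a peptide uptake dataset from a scenario
#'
#' For each peptide and exposure time, the noise-free uptake is the
#' deuterium fraction times the sum of [residue_uptake_fraction()] over
#' the peptide's exchangeable amides (first residue and prolines
#' excluded); replicates add i.i.d. Gaussian noise truncated at zero.
#' Back-exchange is deliberately not simulated, matching uncorrected
#' relative uptake data.
#'
#' @param scenario An [default_transporter_scenario()] object.
#' @param peptides Peptide tibble from [digest_in_silico()] (columns
#'   `start`, `end`, `sequence`, `max_uptake`).
#' @param conditions A [labeling_conditions()] object.
#' @param which Simulate the `"control"` or `"variant"` condition (sets
#'   the IF population).
#' @param noise A [noise_model()]; its seed is combined with `which` so
#'   the two conditions get independent noise.
#' @param protein_id Protein identifier written into the table.
#' @param state_label State label; defaults to `which`.
#' @return An [as_hdx_dataset()] tibble.
#' @export
simulate_dataset <- function(scenario, peptides, conditions,
                             which = c("control", "variant"),
                             noise = noise_model(),
                             protein_id = "SYNTH",
                             state_label = NULL) {
  which <- match.arg(which)
  n <- nchar(scenario$sequence)
  if (any(peptides$start < 1) || any(peptides$end > n)) {
    abort("Peptide span outside the scenario sequence.",
          class = "hdx_parameter_error")
  }
  f_IF <- if (which == "control") scenario$population_IF_control
          else scenario$population_IF_variant
  state_label <- state_label %||% which

  # residue x timepoint noise-free uptake fractions, computed once
  frac <- vapply(conditions$timepoints_s, function(t)
    residue_uptake_fraction(scenario, seq_len(n), f_IF, t),
    numeric(n))

  grid <- tidyr::crossing(
    peptides |> mutate(.pep = dplyr::row_number()),
    tibble(exposure_s = conditions$timepoints_s)
  )
  noiseless <- purrr::map2_dbl(grid$.pep, grid$exposure_s, function(i, t) {
    pos <- exchangeable_positions(peptides$sequence[i], peptides$start[i])
    ti <- match(t, conditions$timepoints_s)
    conditions$deuterium_fraction * sum(frac[pos, ti])
  })

  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(noise$seed + ifelse(which == "variant", 1000003L, 0L))

  out <- grid |>
    mutate(noiseless = noiseless) |>
    tidyr::crossing(tibble(replicate = seq_len(conditions$n_replicates))) |>
    arrange(.data$.pep, .data$exposure_s, .data$replicate) |>
    mutate(
      uptake_da = pmax(0, .data$noiseless +
                         rnorm(dplyr::n(), 0, noise$replicate_sd)),
      protein = protein_id, state = state_label
    ) |>
    select("protein", "start", "end", "sequence", "state", "exposure_s",
           "max_uptake", "replicate", "uptake_da")
  as_hdx_dataset(out, conditions = conditions)
}

#' Assign each peptide to its majority region
#'
#' A peptide is assigned to the scenario region (intracellular,
#' extracellular, transmembrane) that holds a strict majority (> 50%) of
#' its exchangeable amides; peptides with no majority are labeled
#' `"mixed"`. Used to build ground-truth sidecars for simulated runs.
#'
#' @param scenario An [default_transporter_scenario()] object.
#' @param peptides Peptide tibble (`start`, `end`, `sequence`).
#' @return The peptide tibble with columns `region` and
#'   `expected_sign` (+1/-1/0: the summed-dHDX sign this region should
#'   show for the scenario's shift direction).
#' @export
peptide_region_majority <- function(scenario, peptides) {
  region <- map_chr(seq_len(nrow(peptides)), function(i) {
    pos <- exchangeable_positions(peptides$sequence[i], peptides$start[i])
    tab <- table(scenario$region_labels[pos])
    top <- names(tab)[which.max(tab)]
    if (max(tab) > sum(tab) / 2) top else "mixed"
  })
  dir <- sign(scenario$population_IF_variant - scenario$population_IF_control)
  expected <- dplyr::case_when(
    region == "intracellular" ~ 1 * dir,
    region == "extracellular" ~ -1 * dir,
    TRUE ~ 0
  )
  peptides |> mutate(region = region, expected_sign = expected)
}
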