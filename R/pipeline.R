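# Command-level orchestration: each hdx_cmd_* function realizes one
# pipeline subcommand (simulate / diff / map / gate) on files, logging
# to stderr and writing its fully-resolved configuration as YAML next
# to the outputs so every run is reproducible from the artifacts alone.

log_msg <- function(...) {
  message(sprintf("[hdxshift %s] ", format(Sys.time(), "%H:%M:%S")),
          sprintf(...))
}

resolve_config <- function(defaults, file_config = NULL, overrides = list()) {
  cfg <- defaults
  for (src in list(file_config, overrides)) {
    if (is.null(src)) next
    for (nm in names(src)) if (!is.null(src[[nm]])) cfg[[nm]] <- src[[nm]]
  }
  cfg
}

dump_config <- function(cfg, out_dir, name) {
  cfg$package_version <- as.character(utils::packageVersion("hdxshift"))
  path <- file.path(out_dir, paste0(name, ".resolved.yaml"))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

read_config_file <- function(path) {
  if (is.null(path)) return(NULL)
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "hdx_io_error")
  }
  yaml::read_yaml(path)
}

#' Simulate a control/variant uptake-table pair
#'
#' Generates a two-state transporter scenario, digests it in silico,
#' simulates both conditions, and writes two dialect-conformant uptake
#' tables plus a ground-truth sidecar (per-residue region labels and
#' populations; per-peptide majority region and expected sign) and the
#' resolved configuration.
#'
#' @param out_dir Output directory (created if needed).
#' @param config Named list overriding the defaults: `n_residues` (300),
#'   `shift` ("toward_IF"), `seed` (drawn and logged when `NULL`),
#'   `delta_population` (0.3), `scheme` ("detergent" or "nanodisc"),
#'   `n_replicates` (3), `replicate_sd` (0.05), `target_coverage` (0.8),
#'   `min_peptides` (0), `dialect` ("long_tsv").
#' @param config_file Optional YAML file with the same keys; explicit
#'   `config` entries win.
#' @return Invisibly, a list with the written paths and the resolved
#'   config.
#' @export
hdx_cmd_simulate <- function(out_dir, config = list(), config_file = NULL) {
  cfg <- resolve_config(
    list(n_residues = 300L, shift = "toward_IF", seed = NULL,
         delta_population = 0.3, scheme = "detergent", n_replicates = 3L,
         replicate_sd = 0.05, target_coverage = 0.8, min_peptides = 0L,
         dialect = "long_tsv"),
    read_config_file(config_file), config)
  if (is.null(cfg$seed)) {
    cfg$seed <- sample.int(.Machine$integer.max, 1)
    log_msg("No seed supplied; generated seed %d.", cfg$seed)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  scenario <- default_transporter_scenario(
    cfg$n_residues, shift = cfg$shift, seed = cfg$seed,
    delta_population = cfg$delta_population)
  conditions <- labeling_conditions(cfg$scheme,
                                    n_replicates = cfg$n_replicates)
  peptides <- digest_in_silico(scenario$sequence,
                               target_coverage = cfg$target_coverage,
                               seed = cfg$seed + 1L,
                               min_peptides = cfg$min_peptides)
  noise <- noise_model(cfg$replicate_sd, seed = cfg$seed + 2L)
  ctrl <- simulate_dataset(scenario, peptides, conditions, "control", noise)
  vari <- simulate_dataset(scenario, peptides, conditions, "variant", noise)

  ext <- if (cfg$dialect == "long_tsv") "tsv" else "csv"
  p_ctrl <- file.path(out_dir, paste0("control.", ext))
  p_vari <- file.path(out_dir, paste0("variant.", ext))
  write_uptake_table(ctrl, p_ctrl, cfg$dialect)
  write_uptake_table(vari, p_vari, cfg$dialect)

  truth <- peptide_region_majority(scenario, peptides)
  p_truth <- file.path(out_dir, "ground_truth_peptides.tsv")
  readr::write_tsv(truth, p_truth, progress = FALSE)
  p_res <- file.path(out_dir, "ground_truth_residues.tsv")
  readr::write_tsv(tibble(residue = seq_len(nchar(scenario$sequence)),
                          region = scenario$region_labels,
                          log10_protection_OF = scenario$log10_protection_OF,
                          log10_protection_IF = scenario$log10_protection_IF,
                          population_IF_control = scenario$population_IF_control,
                          population_IF_variant = scenario$population_IF_variant),
                   p_res, progress = FALSE)
  cfg$achieved_coverage <- attr(peptides, "achieved_coverage")
  dump_config(cfg, out_dir, "simulate")
  log_msg("Simulated %d peptides (coverage %.1f%%), shift %s, into %s.",
          nrow(peptides), 100 * cfg$achieved_coverage, cfg$shift, out_dir)
  invisible(list(control = p_ctrl, variant = p_vari,
                 ground_truth = p_truth, config = cfg))
}

#' Differential analysis of two uptake tables
#'
#' Reads control and variant tables, runs [run_differential()], and
#' writes the differential TSV, the Woods-plot table, and a thresholds
#' report.
#'
#' @param control_path,variant_path Input uptake tables.
#' @param out_dir Output directory.
#' @param config Overrides: `dialect` ("long_tsv"), `alpha` (0.01),
#'   `var_equal` (TRUE), `p_adjust` ("none").
#' @param config_file Optional YAML config.
#' @return Invisibly, the `hdx_differential` object.
#' @export
hdx_cmd_diff <- function(control_path, variant_path, out_dir,
                         config = list(), config_file = NULL) {
  cfg <- resolve_config(
    list(dialect = "long_tsv", alpha = 0.01, var_equal = TRUE,
         p_adjust = "none"),
    read_config_file(config_file), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ctrl <- read_uptake_table(control_path, cfg$dialect)
  vari <- read_uptake_table(variant_path, cfg$dialect)
  diff <- run_differential(ctrl, vari, alpha = cfg$alpha,
                           var_equal = cfg$var_equal,
                           p_adjust = cfg$p_adjust)
  write_differential_tsv(diff, file.path(out_dir, "differential.tsv"))
  readr::write_tsv(woods_plot_data(diff),
                   file.path(out_dir, "woods_plot.tsv"), progress = FALSE)
  g <- glance(diff)
  readr::write_tsv(g, file.path(out_dir, "thresholds.tsv"), progress = FALSE)
  dump_config(cfg, out_dir, "diff")
  log_msg("Differential: %d peptides | +%d / -%d / none %d | threshold %.4g Da.",
          g$n_peptides, g$n_positive, g$n_negative, g$n_none, g$summed_ci_da)
  invisible(diff)
}

#' Map differential classifications onto a structure
#'
#' Consolidates a differential TSV to residues and writes the annotated
#' PDB plus the per-residue TSV.
#'
#' @param diff_tsv Differential table written by [hdx_cmd_diff()].
#' @param pdb_in Input structure.
#' @param out_dir Output directory.
#' @param config Overrides: `protein_length` (inferred as max peptide
#'   end when `NULL`), `chain` (NULL = all), `residue_offset` (0).
#' @param config_file Optional YAML config.
#' @return Invisibly, the residue map.
#' @export
hdx_cmd_map <- function(diff_tsv, pdb_in, out_dir, config = list(),
                        config_file = NULL) {
  cfg <- resolve_config(
    list(protein_length = NULL, chain = NULL, residue_offset = 0L),
    read_config_file(config_file), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- readr::read_tsv(diff_tsv, show_col_types = FALSE,
                             progress = FALSE)
  need <- c("start", "end", "classification")
  if (length(setdiff(need, names(records))) > 0) {
    abort(paste0("Differential table missing column(s): ",
                 paste(setdiff(need, names(records)), collapse = ", ")),
          class = "hdx_format_error")
  }
  protein_length <- cfg$protein_length %||% max(records$end)
  map <- consolidate_to_residues(records, protein_length)
  write_structure_annotation(
    map, pdb_in, file.path(out_dir, "annotated.pdb"),
    tsv_out = file.path(out_dir, "residue_classes.tsv"),
    chain = cfg$chain, residue_offset = cfg$residue_offset)
  write_coloring_macro(file.path(out_dir, "color_by_class.pml"))
  dump_config(cfg, out_dir, "map")
  tab <- table(map$label)
  log_msg("Residue map: positive %d | negative %d | none %d | no_coverage %d.",
          tab[["positive"]], tab[["negative"]], tab[["none"]],
          tab[["no_coverage"]])
  invisible(map)
}

#' Gate-distance analysis of a trajectory
#'
#' Reads a multi-model PDB (or plain-text frames table), computes the
#' gate-distance time trace and the trailing-window distribution, and
#' writes both as TSV.
#'
#' @param frames_path Trajectory path.
#' @param out_dir Output directory.
#' @param config Overrides: `format` ("pdb" or "table"), `group1` /
#'   `group2` (compact range strings; defaults are the XylE
#'   intracellular gate), `dt_ns` / `times_ns` (frame times),
#'   `window_ns` (200), `binwidth_A` (0.25).
#' @param config_file Optional YAML config.
#' @return Invisibly, a list with the trace and histogram tibbles.
#' @export
hdx_cmd_gate <- function(frames_path, out_dir, config = list(),
                         config_file = NULL) {
  cfg <- resolve_config(
    list(format = "pdb", group1 = "75-80,149-154,160-165",
         group2 = "332-337,391-397,404-410", dt_ns = NULL, times_ns = NULL,
         window_ns = 200, binwidth_A = 0.25),
    read_config_file(config_file), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  frames <- if (cfg$format == "pdb") {
    read_frames_pdb(frames_path, times_ns = cfg$times_ns, dt_ns = cfg$dt_ns)
  } else {
    read_frames_table(frames_path, dt_ns = cfg$dt_ns)
  }
  gate <- gate_definition(cfg$group1, cfg$group2)
  trace <- distance_trace(frames, gate)
  window <- min(cfg$window_ns, max(trace$time_ns) - min(trace$time_ns))
  hist <- trailing_distribution(trace, window_ns = window,
                                binwidth_A = cfg$binwidth_A)
  readr::write_tsv(trace, file.path(out_dir, "gate_trace.tsv"),
                   progress = FALSE)
  readr::write_tsv(hist, file.path(out_dir, "gate_distribution.tsv"),
                   progress = FALSE)
  cfg$window_ns_used <- window
  dump_config(cfg, out_dir, "gate")
  log_msg("Gate trace: %d frames | trailing %.4g ns window | modal distance %.2f A.",
          nrow(trace), window, hist$bin_mid_A[which.max(hist$density)])
  invisible(list(trace = trace, distribution = hist))
}
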