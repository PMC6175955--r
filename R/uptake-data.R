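# Data model and I/O for peptide-level deuterium uptake tables.
#
# A dataset is a tidy tibble with one row per replicate measurement:
#   protein, start, end, sequence, state, exposure_s, max_uptake,
#   replicate, uptake_da  (+ optional logical columns incomplete,
#   reconstructed)
# Labeling metadata (deuterium fraction, timepoints, replicate count)
# travels in attributes set by `labeling_conditions()` /
# `as_hdx_dataset()`; all computations also accept a plain tibble with
# the same columns.

#' Labeling conditions for an HDX experiment
#'
#' Bundles the deuterium fraction after mixing, the exposure-time scheme
#' and the nominal replicate count. Two presets match common bottom-up
#' HDX designs for membrane proteins: the detergent-micelle scheme
#' (30 s, 5 min, 30 min) and the lipid-nanodisc scheme
#' (5 min, 30 min, 150 min).
#'
#' @param timepoints_s Strictly increasing positive exposure times in
#'   seconds, or one of `"detergent"` / `"nanodisc"` for the presets.
#' @param deuterium_fraction Fraction of deuterium in the labeling mix,
#'   in (0, 1]. The default 0.95 corresponds to diluting 5 uL of protein
#'   into 95 uL of deuterated buffer.
#' @param n_replicates Nominal number of technical replicates (>= 2).
#' @return An object of class `hdx_conditions` (a named list).
#' @examples
#' labeling_conditions("detergent")
#' labeling_conditions(c(300, 1800, 9000), deuterium_fraction = 0.95)
#' @export
labeling_conditions <- function(timepoints_s = "detergent",
                                deuterium_fraction = 0.95,
                                n_replicates = 3L) {
  if (is.character(timepoints_s)) {
    timepoints_s <- switch(match.arg(timepoints_s, c("detergent", "nanodisc")),
      detergent = c(30, 300, 1800),
      nanodisc  = c(300, 1800, 9000)
    )
  }
  timepoints_s <- as.numeric(timepoints_s)
  if (length(timepoints_s) < 1 || any(timepoints_s <= 0) ||
      is.unsorted(timepoints_s, strictly = TRUE)) {
    abort("`timepoints_s` must be strictly increasing and positive.",
          class = "hdx_parameter_error")
  }
  if (!is.numeric(deuterium_fraction) || deuterium_fraction <= 0 ||
      deuterium_fraction > 1) {
    abort("`deuterium_fraction` must lie in (0, 1].",
          class = "hdx_parameter_error")
  }
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 2) {
    abort("`n_replicates` must be at least 2.", class = "hdx_parameter_error")
  }
  structure(
    list(timepoints_s = timepoints_s,
         deuterium_fraction = deuterium_fraction,
         n_replicates = n_replicates),
    class = "hdx_conditions"
  )
}

#' @export
print.hdx_conditions <- function(x, ...) {
  cat("<hdx_conditions>\n")
  cat("  timepoints (s):    ", paste(x$timepoints_s, collapse = ", "), "\n")
  cat("  deuterium fraction:", x$deuterium_fraction, "\n")
  cat("  replicates:        ", x$n_replicates, "\n")
  invisible(x)
}

#' Maximum theoretical deuterium uptake of a peptide
#'
#' Counts the backbone amides of a peptide that can retain deuterium in a
#' bottom-up HDX experiment: every residue except the N-terminal one
#' (whose amide back-exchanges essentially instantly) and except prolines
#' (no amide hydrogen). This is the DynamX-compatible MaxUptake
#' convention: `length - 1 - #prolines at positions 2..length`.
#'
#' @param sequence Character vector of peptide sequences in standard
#'   one-letter code.
#' @return Integer vector of exchangeable-amide counts.
#' @examples
#' compute_max_uptake("GASPLK")     # 4
#' compute_max_uptake("AAAAAAAAAA") # 9
#' @export
compute_max_uptake <- function(sequence) {
  if (length(sequence) == 0 || any(!nzchar(sequence))) {
    abort("`sequence` must be non-empty.", class = "hdx_validation_error")
  }
  bad <- grepl("[^ACDEFGHIKLMNPQRSTVWY]", toupper(sequence))
  if (any(bad)) {
    abort(
      paste0("Unknown residue letter(s) in sequence(s): ",
             paste(sequence[bad], collapse = ", ")),
      class = "hdx_validation_error"
    )
  }
  vapply(toupper(sequence), function(s) {
    aa <- strsplit(s, "")[[1]]
    length(aa) - 1L - sum(aa[-1] == "P")
  }, integer(1), USE.NAMES = FALSE)
}

# exchangeable positions of a peptide spanning start..end: global residue
# indices that carry a reporting amide (skip first residue and prolines)
exchangeable_positions <- function(sequence, start) {
  aa <- strsplit(toupper(sequence), "")[[1]]
  idx <- seq_along(aa)[-1]
  start + idx[aa[idx] != "P"] - 1L
}

required_cols <- c("protein", "start", "end", "sequence", "state",
                   "exposure_s", "max_uptake", "replicate", "uptake_da")

#' Construct/validate an HDX uptake dataset
#'
#' Validates a tidy replicate-level measurement table and attaches
#' labeling metadata. Checks residue-coordinate consistency, the
#' MaxUptake convention, non-negative uptake, an upper uptake bound of
#' `max_uptake * D * (1 + tolerance)`, uniqueness of
#' (peptide, state, exposure, replicate), and flags (peptide, state,
#' exposure) groups whose replicate count differs from the nominal one
#' (column `incomplete`); downstream statistics skip flagged groups with
#' a warning rather than failing.
#'
#' @param x Data frame with columns `protein`, `start`, `end`,
#'   `sequence`, `state`, `exposure_s`, `max_uptake`, `replicate`,
#'   `uptake_da`.
#' @param conditions An [labeling_conditions()] object; if `NULL`,
#'   inferred from the data (timepoints = sorted unique exposures,
#'   replicate count = modal group size, D = 0.95).
#' @param tolerance Allowed fractional excess of uptake over the
#'   theoretical maximum, to accommodate replicate noise.
#' @return The validated tibble with class `hdx_dataset` and attribute
#'   `conditions`.
#' @export
as_hdx_dataset <- function(x, conditions = NULL, tolerance = 0.15) {
  x <- as_tibble(x)
  missing_cols <- setdiff(required_cols, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "hdx_format_error")
  }
  if (nrow(x) == 0) {
    abort("no measurements", class = "hdx_format_error")
  }
  if (is.null(conditions)) {
    sizes <- dplyr::count(x, .data$protein, .data$sequence, .data$start,
                          .data$state, .data$exposure_s)$n
    conditions <- labeling_conditions(
      sort(unique(x$exposure_s)),
      deuterium_fraction = 0.95,
      n_replicates = as.integer(names(sort(table(sizes),
                                           decreasing = TRUE))[1])
    )
  }
  with_bad_span <- x$end < x$start | nchar(x$sequence) != x$end - x$start + 1
  if (any(with_bad_span)) {
    abort("Peptide span inconsistent with sequence length.",
          class = "hdx_validation_error")
  }
  expected_mu <- compute_max_uptake(unique(x$sequence))
  names(expected_mu) <- unique(x$sequence)
  if (any(x$max_uptake != expected_mu[x$sequence])) {
    abort("`max_uptake` disagrees with the length-1-minus-prolines convention.",
          class = "hdx_validation_error")
  }
  if (any(x$uptake_da < 0, na.rm = TRUE)) {
    abort("Negative uptake values.", class = "hdx_validation_error")
  }
  cap <- x$max_uptake * conditions$deuterium_fraction * (1 + tolerance)
  if (any(x$uptake_da > cap, na.rm = TRUE)) {
    abort("Uptake exceeds max_uptake x D beyond the noise tolerance.",
          class = "hdx_validation_error")
  }
  dup <- duplicated(x[c("protein", "sequence", "start", "state",
                        "exposure_s", "replicate")])
  if (any(dup)) {
    abort("Duplicate (peptide, state, exposure, replicate) entries.",
          class = "hdx_integrity_error")
  }
  x <- x |>
    group_by(.data$protein, .data$sequence, .data$start, .data$end,
             .data$state, .data$exposure_s) |>
    mutate(incomplete = dplyr::n() != conditions$n_replicates) |>
    ungroup() |>
    arrange(.data$protein, .data$start, .data$end, .data$state,
            .data$exposure_s, .data$replicate)
  if (any(x$incomplete)) {
    warn("Some (peptide, state, exposure) groups have an incomplete replicate set; they are flagged and skipped by downstream statistics.")
  }
  structure(x, class = c("hdx_dataset", class(tibble())),
            conditions = conditions)
}

#' @export
print.hdx_dataset <- function(x, ...) {
  cond <- attr(x, "conditions")
  cat(sprintf(
    "<hdx_dataset> %d measurements | %d peptides | states: %s | timepoints (s): %s | D = %s\n",
    nrow(x), nrow(distinct(as_tibble(x), .data$sequence, .data$start)),
    paste(unique(x$state), collapse = ", "),
    paste(cond$timepoints_s, collapse = ", "),
    cond$deuterium_fraction))
  NextMethod()
}

hdx_conditions_of <- function(x, default = NULL) {
  attr(x, "conditions") %||% default
}

# ---- exposure parsing ------------------------------------------------------

# Accepts "30 s", "0.5 min", "30s", "5min", or bare numbers. Bare numbers
# are minutes for cluster_csv (DynamX convention) and seconds for long_tsv.
parse_exposure <- function(x, bare_unit = c("min", "s")) {
  bare_unit <- match.arg(bare_unit)
  x <- trimws(as.character(x))
  out <- numeric(length(x))
  for (i in seq_along(x)) {
    v <- x[[i]]
    if (grepl("min$", v)) {
      out[i] <- as.numeric(sub("min$", "", v)) * 60
    } else if (grepl("s(ec)?$", v)) {
      out[i] <- as.numeric(sub("s(ec)?$", "", v))
    } else {
      num <- suppressWarnings(as.numeric(v))
      if (is.na(num)) {
        abort(paste0("Cannot parse exposure value '", v, "'."),
              class = "hdx_parse_error")
      }
      out[i] <- if (bare_unit == "min") num * 60 else num
    }
  }
  if (anyNA(out)) {
    abort("Cannot parse exposure value(s).", class = "hdx_parse_error")
  }
  out
}

# ---- reading ---------------------------------------------------------------

dialect_spec <- list(
  cluster_csv = list(
    delim = ",",
    cols = c(protein = "Protein", start = "Start", end = "End",
             sequence = "Sequence", state = "State", exposure = "Exposure",
             maxuptake = "MaxUptake", uptake = "Uptake"),
    bare_exposure_unit = "min"
  ),
  long_tsv = list(
    delim = "\t",
    cols = c(protein = "protein", start = "start", end = "end",
             sequence = "sequence", state = "state", exposure = "exposure",
             maxuptake = "max_uptake", replicate = "replicate",
             uptake = "uptake"),
    bare_exposure_unit = "s"
  )
)

#' Read a peptide uptake table
#'
#' Reads delimited-text uptake tables in one of two dialects.
#' `"cluster_csv"` is a DynamX-like wide CSV with one row per
#' (peptide, state, exposure): columns `Protein, Start, End, Sequence,
#' State, Exposure, MaxUptake, Uptake` plus either `Uptake SD`
#' (mean + SD export; replicates are reconstructed as
#' `mean + sd * sqrt(3/2) * {-1, 0, +1}` so the reconstructed sample SD
#' equals the stated SD, and flagged in the `reconstructed` column) or
#' replicate columns `Uptake 1..n`. `"long_tsv"` is a tidy TSV with one
#' row per replicate (lower-case column names, `replicate` column).
#' Exposures accept `"s"`/`"min"` suffixes; bare numbers are minutes in
#' `cluster_csv` (DynamX convention) and seconds in `long_tsv`.
#'
#' @param path Path to the file.
#' @param dialect `"cluster_csv"` or `"long_tsv"`.
#' @param apply_length_filter Drop peptides outside the 5-25 residue
#'   length window (the conventional DynamX filter); exclusions are
#'   reported via a message.
#' @param conditions Optional [labeling_conditions()]; inferred from the
#'   file when `NULL`.
#' @return An [as_hdx_dataset()] tibble.
#' @export
read_uptake_table <- function(path,
                              dialect = c("cluster_csv", "long_tsv"),
                              apply_length_filter = TRUE,
                              conditions = NULL) {
  dialect <- match.arg(dialect)
  spec <- dialect_spec[[dialect]]
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "hdx_io_error")
  }
  raw <- readr::read_delim(path, delim = spec$delim, show_col_types = FALSE,
                           progress = FALSE, trim_ws = TRUE,
                           col_types = readr::cols(.default = readr::col_character()))
  need <- spec$cols[setdiff(names(spec$cols), "replicate")]
  missing_cols <- setdiff(unname(need), names(raw))
  # cluster_csv carries replicates either as "Uptake SD" or "Uptake 1..n"
  if (dialect == "cluster_csv") {
    has_sd <- "Uptake SD" %in% names(raw)
    rep_cols <- grep("^Uptake [0-9]+$", names(raw), value = TRUE)
    if (!has_sd && length(rep_cols) == 0) {
      missing_cols <- union(missing_cols, "Uptake SD")
    }
  }
  if (length(missing_cols) > 0) {
    abort(paste0("Input table is missing required column(s) for dialect '",
                 dialect, "': ", paste(missing_cols, collapse = ", ")),
          class = "hdx_format_error")
  }
  if (nrow(raw) == 0) {
    abort("no measurements", class = "hdx_format_error")
  }

  num <- function(col, what) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) & nzchar(raw[[col]]))
    if (length(bad) > 0) {
      abort(paste0("Non-numeric ", what, " in column '", col, "' at data row(s) ",
                   paste(head(bad, 5), collapse = ", "), "."),
            class = "hdx_parse_error")
    }
    v
  }

  base <- tibble(
    protein = raw[[need[["protein"]]]],
    start = as.integer(num(need[["start"]], "start")),
    end = as.integer(num(need[["end"]], "end")),
    sequence = toupper(raw[[need[["sequence"]]]]),
    state = raw[[need[["state"]]]],
    exposure_s = parse_exposure(raw[[need[["exposure"]]]],
                                bare_unit = spec$bare_exposure_unit),
    max_uptake = as.integer(num(need[["maxuptake"]], "max uptake"))
  )

  if (dialect == "long_tsv") {
    base$replicate <- as.integer(num(spec$cols[["replicate"]], "replicate index"))
    base$uptake_da <- num(spec$cols[["uptake"]], "uptake")
    base$reconstructed <- FALSE
    out <- base
  } else {
    rep_cols <- grep("^Uptake [0-9]+$", names(raw), value = TRUE)
    if (length(rep_cols) > 0) {
      for (rc in rep_cols) raw[[rc]] <- num(rc, "uptake")
      out <- base |>
        mutate(!!!setNames(lapply(rep_cols, function(rc) raw[[rc]]), rep_cols)) |>
        pivot_longer(all_of(rep_cols), names_to = "replicate",
                     values_to = "uptake_da") |>
        mutate(replicate = as.integer(sub("^Uptake ", "", .data$replicate)),
               reconstructed = FALSE) |>
        filter(!is.na(.data$uptake_da))
    } else {
      mu <- num(need[["uptake"]], "uptake")
      sdv <- num("Uptake SD", "uptake SD")
      # reconstruct three placeholder replicates whose sample SD matches
      warn("cluster_csv file carries mean + SD only; replicate values reconstructed as placeholders (flagged `reconstructed`).")
      # offsets {-1, 0, +1} have unit sample SD, so the reconstructed
      # triplet reproduces the stated mean and SD exactly
      k <- 1
      out <- base |>
        mutate(.mu = mu, .sd = sdv) |>
        tidyr::crossing(tibble(replicate = 1:3, .off = c(-k, 0, k))) |>
        mutate(uptake_da = pmax(0, .data$.mu + .data$.off * .data$.sd),
               reconstructed = TRUE) |>
        select(-".mu", -".sd", -".off")
    }
  }

  if (apply_length_filter) {
    len <- nchar(out$sequence)
    drop <- len < 5 | len > 25
    if (any(drop)) {
      dropped <- unique(out$sequence[drop])
      inform(paste0("Excluded ", length(dropped),
                    " peptide(s) outside the 5-25 length window: ",
                    paste(head(dropped, 10), collapse = ", ")))
      out <- out[!drop, , drop = FALSE]
    }
    if (nrow(out) == 0) {
      abort("no measurements", class = "hdx_format_error")
    }
  }
  as_hdx_dataset(out, conditions = conditions)
}

#' Write a peptide uptake table
#'
#' Inverse of [read_uptake_table()]. `long_tsv` writes one row per
#' replicate; `cluster_csv` writes one row per (peptide, state,
#' exposure) with replicate columns `Uptake 1..n` (incomplete groups get
#' explicit blank cells, with a warning). Numbers are written with 6
#' significant digits, locale-independent decimal point; round-tripping
#' through [read_uptake_table()] reproduces the dataset to that
#' precision.
#'
#' @param dataset An [as_hdx_dataset()] tibble.
#' @param path Output file path.
#' @param dialect `"cluster_csv"` or `"long_tsv"`.
#' @return `path`, invisibly.
#' @export
write_uptake_table <- function(dataset, path,
                               dialect = c("cluster_csv", "long_tsv")) {
  dialect <- match.arg(dialect)
  x <- as_tibble(dataset)
  fmt <- function(v) ifelse(is.na(v), "", formatC(v, digits = 6,
                                                  format = "g"))
  dir_ok <- dir.exists(dirname(path))
  if (!dir_ok) {
    abort(paste0("Cannot write to '", path, "': directory does not exist."),
          class = "hdx_io_error")
  }
  if (dialect == "long_tsv") {
    out <- tibble(
      protein = x$protein, start = x$start, end = x$end,
      sequence = x$sequence, state = x$state,
      exposure = paste0(fmt(x$exposure_s), " s"),
      max_uptake = x$max_uptake, replicate = x$replicate,
      uptake = fmt(x$uptake_da)
    )
    readr::write_tsv(out, path, progress = FALSE)
  } else {
    if (any(x$incomplete %||% FALSE)) {
      warn("Dataset contains incomplete replicate groups; written with explicit blank cells.")
    }
    n_rep <- max(x$replicate)
    means <- x |>
      group_by(.data$protein, .data$start, .data$end, .data$sequence,
               .data$state, .data$exposure_s) |>
      summarise(Uptake = mean(.data$uptake_da), .groups = "drop")
    wide <- x |>
      select("protein", "start", "end", "sequence", "state",
             "exposure_s", "max_uptake", "replicate", "uptake_da") |>
      mutate(uptake_da = fmt(.data$uptake_da)) |>
      pivot_wider(names_from = "replicate", values_from = "uptake_da",
                  names_prefix = "Uptake ", values_fill = "") |>
      left_join(means, by = c("protein", "start", "end", "sequence",
                              "state", "exposure_s"))
    rep_cols <- paste("Uptake", seq_len(n_rep))
    for (rc in setdiff(rep_cols, names(wide))) wide[[rc]] <- ""
    out <- wide |>
      mutate(Exposure = paste0(fmt(.data$exposure_s / 60), " min"),
             Uptake = fmt(.data$Uptake)) |>
      select(Protein = "protein", Start = "start", End = "end",
             Sequence = "sequence", State = "state", "Exposure",
             MaxUptake = "max_uptake", "Uptake", all_of(rep_cols))
    readr::write_csv(out, path, progress = FALSE)
  }
  invisible(path)
}
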