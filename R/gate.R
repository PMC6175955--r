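# Intracellular gate-distance metric on coordinate trajectories:
# center-of-mass (COM) distance between two Calpha residue groups, the
# per-frame time trace, and the normalized distribution over a trailing
# time window (conventionally the last 200 ns of a simulation).

# standard atomic masses (u) for the elements seen in protein backbones
ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   P = 30.974, S = 32.06, SE = 78.971)

#' Parse compact residue-range syntax
#'
#' `"75-80,149-154,160-165"` -> the vector of all residue ids in those
#' ranges.
#'
#' @param spec Character scalar in compact range syntax.
#' @return Integer vector of residue ids.
#' @export
parse_residue_ranges <- function(spec) {
  parts <- strsplit(gsub("\\s", "", spec), ",")[[1]]
  out <- unlist(lapply(parts, function(p) {
    if (grepl("-", p)) {
      ab <- as.integer(strsplit(p, "-")[[1]])
      if (length(ab) != 2 || anyNA(ab) || ab[2] < ab[1]) {
        abort(paste0("Bad residue range '", p, "'."),
              class = "hdx_parameter_error")
      }
      ab[1]:ab[2]
    } else {
      v <- as.integer(p)
      if (is.na(v)) abort(paste0("Bad residue id '", p, "'."),
                          class = "hdx_parameter_error")
      v
    }
  }))
  sort(unique(out))
}

#' Gate definition: two disjoint Calpha residue groups
#'
#' The default corresponds to the intracellular gate of the xylose
#' transporter XylE: group 1 spans the cytoplasmic ends of TM2/TM3
#' (residues 75-80, 149-154, 160-165), group 2 those of TM10/TM11
#' (332-337, 391-397, 404-410). The gate metric is the center-of-mass
#' distance between the Calpha atoms of the two groups.
#'
#' @param group1,group2 Residue ids, as integer vectors or compact
#'   range strings (see [parse_residue_ranges()]).
#' @return A list of class `hdx_gate`.
#' @export
gate_definition <- function(group1 = "75-80,149-154,160-165",
                            group2 = "332-337,391-397,404-410") {
  if (is.character(group1)) group1 <- parse_residue_ranges(group1)
  if (is.character(group2)) group2 <- parse_residue_ranges(group2)
  if (length(group1) == 0 || length(group2) == 0) {
    abort("Gate groups must be non-empty.", class = "hdx_parameter_error")
  }
  if (length(intersect(group1, group2)) > 0) {
    abort("Gate groups must be disjoint.", class = "hdx_parameter_error")
  }
  structure(list(group1 = as.integer(group1), group2 = as.integer(group2),
                 atom_selector = "CA"),
            class = "hdx_gate")
}

#' @export
print.hdx_gate <- function(x, ...) {
  cat(sprintf("<hdx_gate> Calpha COM distance | group1: %d residues | group2: %d residues\n",
              length(x$group1), length(x$group2)))
  invisible(x)
}

#' Mass-weighted center of mass
#'
#' @param coordinates Numeric matrix, one row per atom, columns x/y/z
#'   (Angstrom).
#' @param masses Atomic masses (u), one per atom; all positive.
#' @return Length-3 numeric vector.
#' @export
center_of_mass <- function(coordinates, masses) {
  coordinates <- rbind(coordinates)
  if (nrow(coordinates) == 0) {
    abort("Empty atom selection.", class = "hdx_selection_error")
  }
  if (length(masses) != nrow(coordinates) || any(masses <= 0)) {
    abort("`masses` must be positive, one per atom.",
          class = "hdx_parameter_error")
  }
  colSums(coordinates * masses) / sum(masses)
}

#' Read a trajectory from a multi-model PDB
#'
#' Reads MODEL/ENDMDL frames and extracts, per frame, the coordinates
#' of all atoms together with residue ids, atom names and element-based
#' masses. Frame times are never guessed: supply either explicit
#' `times_ns` or a constant frame interval `dt_ns` (times then start at
#' 0).
#'
#' @param path Multi-model PDB path.
#' @param times_ns Explicit per-frame times (ns).
#' @param dt_ns Constant frame interval (ns).
#' @return A list of class `hdx_frames`: `coords` (array
#'   frames x atoms x 3), `resno`, `atom_name`, `element`, `mass`,
#'   `times_ns`.
#' @export
read_frames_pdb <- function(path, times_ns = NULL, dt_ns = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
                  error = function(e) {
                    abort(paste0("Cannot parse trajectory PDB '", path, "': ",
                                 conditionMessage(e)),
                          class = "hdx_format_error")
                  })
  xyz <- pdb$xyz                      # frames x (3*atoms)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)
  n_atoms <- ncol(xyz) / 3
  coords <- array(NA_real_, dim = c(n_frames, n_atoms, 3))
  coords[, , 1] <- xyz[, seq(1, ncol(xyz), by = 3)]
  coords[, , 2] <- xyz[, seq(2, ncol(xyz), by = 3)]
  coords[, , 3] <- xyz[, seq(3, ncol(xyz), by = 3)]
  elem <- toupper(trimws(pdb$atom$elesy %||% ""))
  if (all(!nzchar(elem))) {
    elem <- toupper(substr(trimws(pdb$atom$elety), 1, 1))
  }
  as_frames(coords,
            resno = pdb$atom$resno,
            atom_name = trimws(pdb$atom$elety),
            element = elem,
            times_ns = times_ns, dt_ns = dt_ns)
}

#' Read a trajectory from a plain-text frames table
#'
#' TSV with one row per atom per frame and columns `frame`, `time_ns`
#' (optional if `dt_ns` given), `resno`, `atom_name`, `element`, `x`,
#' `y`, `z` (Angstrom). Atom order must be identical in every frame.
#'
#' @param path TSV path.
#' @param dt_ns Constant frame interval (ns), used when the table has no
#'   `time_ns` column.
#' @return An `hdx_frames` object (see [read_frames_pdb()]).
#' @export
read_frames_table <- function(path, dt_ns = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("frame", "resno", "atom_name", "element", "x", "y", "z")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols) > 0) {
    abort(paste0("Frames table missing column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "hdx_format_error")
  }
  frames <- sort(unique(tab$frame))
  n_atoms <- sum(tab$frame == frames[1])
  if (any(table(tab$frame) != n_atoms)) {
    abort("Atom count differs between frames.", class = "hdx_format_error")
  }
  tab <- arrange(tab, .data$frame)
  coords <- array(NA_real_, dim = c(length(frames), n_atoms, 3))
  for (i in seq_along(frames)) {
    sub <- tab[tab$frame == frames[i], ]
    coords[i, , ] <- as.matrix(sub[, c("x", "y", "z")])
  }
  first <- tab[tab$frame == frames[1], ]
  times <- if ("time_ns" %in% names(tab)) {
    vapply(frames, function(f) tab$time_ns[tab$frame == f][1], numeric(1))
  } else NULL
  as_frames(coords, resno = first$resno, atom_name = first$atom_name,
            element = toupper(first$element), times_ns = times,
            dt_ns = dt_ns)
}

as_frames <- function(coords, resno, atom_name, element,
                      times_ns = NULL, dt_ns = NULL) {
  n_frames <- dim(coords)[1]
  if (is.null(times_ns)) {
    if (is.null(dt_ns)) {
      abort("Frame times unknown: supply `times_ns` or `dt_ns` (they are never guessed).",
            class = "hdx_parameter_error")
    }
    times_ns <- (seq_len(n_frames) - 1) * dt_ns
  }
  if (length(times_ns) != n_frames || is.unsorted(times_ns)) {
    abort("`times_ns` must match the frame count and be non-decreasing.",
          class = "hdx_parameter_error")
  }
  mass <- ATOMIC_MASSES[element]
  if (anyNA(mass)) {
    mass[is.na(mass)] <- ATOMIC_MASSES[["C"]]
  }
  structure(list(coords = coords, resno = resno, atom_name = atom_name,
                 element = element, mass = unname(mass),
                 times_ns = as.numeric(times_ns)),
            class = "hdx_frames")
}

#' @export
print.hdx_frames <- function(x, ...) {
  cat(sprintf("<hdx_frames> %d frames x %d atoms | t = %.3g .. %.3g ns\n",
              dim(x$coords)[1], dim(x$coords)[2],
              min(x$times_ns), max(x$times_ns)))
  invisible(x)
}

gate_atom_indices <- function(frames, residues) {
  idx <- which(frames$resno %in% residues & frames$atom_name == "CA")
  found <- unique(frames$resno[idx])
  absent <- setdiff(residues, found)
  if (length(absent) > 0) {
    abort(paste0("Gate residues without a Calpha atom in the trajectory: ",
                 paste(absent, collapse = ", ")),
          class = "hdx_selection_error")
  }
  idx
}

#' Gate distance in a single frame
#'
#' Euclidean distance between the mass-weighted centers of mass of the
#' Calpha atoms of the two gate groups; invariant under global rigid
#' transformations of the frame.
#'
#' @param frames An `hdx_frames` object.
#' @param gate A [gate_definition()].
#' @param frame Frame index (default 1).
#' @return Distance in Angstrom.
#' @export
gate_distance <- function(frames, gate, frame = 1L) {
  i1 <- gate_atom_indices(frames, gate$group1)
  i2 <- gate_atom_indices(frames, gate$group2)
  xyz <- frames$coords[frame, , , drop = TRUE]
  com1 <- center_of_mass(xyz[i1, , drop = FALSE], frames$mass[i1])
  com2 <- center_of_mass(xyz[i2, , drop = FALSE], frames$mass[i2])
  sqrt(sum((com1 - com2)^2))
}

#' Gate-distance time trace
#'
#' @param frames An `hdx_frames` object.
#' @param gate A [gate_definition()].
#' @return Tibble with one row per frame, in frame order: `frame`,
#'   `time_ns`, `distance_A`.
#' @export
distance_trace <- function(frames, gate) {
  i1 <- gate_atom_indices(frames, gate$group1)
  i2 <- gate_atom_indices(frames, gate$group2)
  n_frames <- dim(frames$coords)[1]
  d <- vapply(seq_len(n_frames), function(f) {
    xyz <- frames$coords[f, , , drop = TRUE]
    com1 <- center_of_mass(xyz[i1, , drop = FALSE], frames$mass[i1])
    com2 <- center_of_mass(xyz[i2, , drop = FALSE], frames$mass[i2])
    sqrt(sum((com1 - com2)^2))
  }, numeric(1))
  structure(tibble(frame = seq_len(n_frames), time_ns = frames$times_ns,
                   distance_A = d),
            class = c("hdx_gate_trace", class(tibble())))
}

#' Normalized trailing-window distance distribution
#'
#' Histogram of the gate distance over the frames whose time lies in
#' the trailing window `[t_end - window_ns, t_end]` (conventionally the
#' last 200 ns), normalized so the bin densities integrate to 1.
#'
#' @param trace A [distance_trace()] tibble.
#' @param window_ns Trailing window length (ns); must not exceed the
#'   trace span (the full span uses all frames).
#' @param binwidth_A Histogram bin width (Angstrom).
#' @return Tibble with `bin_mid_A`, `bin_lo_A`, `bin_hi_A`, `count`,
#'   `density` (per Angstrom).
#' @export
trailing_distribution <- function(trace, window_ns = 200,
                                  binwidth_A = 0.25) {
  span <- max(trace$time_ns) - min(trace$time_ns)
  if (window_ns > span && nrow(trace) > 1) {
    abort("`window_ns` exceeds the trace time span.",
          class = "hdx_parameter_error")
  }
  keep <- trace$time_ns >= max(trace$time_ns) - window_ns
  d <- trace$distance_A[keep]
  if (length(d) == 0) {
    abort("Trailing window contains no frames.",
          class = "hdx_parameter_error")
  }
  lo <- floor(min(d) / binwidth_A) * binwidth_A
  hi <- ceiling(max(d) / binwidth_A) * binwidth_A
  if (hi <= lo) hi <- lo + binwidth_A
  breaks <- seq(lo, hi, by = binwidth_A)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)
  tibble(bin_mid_A = h$mids,
         bin_lo_A = head(h$breaks, -1),
         bin_hi_A = tail(h$breaks, -1),
         count = h$counts,
         density = h$density)
}

#' Gate-distance trace plot
#'
#' @param object An `hdx_gate_trace` tibble.
#' @param ... Unused.
#' @return A ggplot of distance vs simulation time.
#' @exportS3Method ggplot2::autoplot
autoplot.hdx_gate_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_ns,
                                       y = .data$distance_A)) +
    ggplot2::geom_line(color = "#d95f02") +
    ggplot2::labs(x = "Time (ns)", y = "Intracellular gate distance (Å)") +
    ggplot2::theme_minimal()
}
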