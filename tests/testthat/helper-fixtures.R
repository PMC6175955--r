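# Fixture builders shared across the suite. Everything is generated in
# code; no stored data files.

# Replicate-level dataset for hand-constructed cases. `uptake` is a
# function(peptide_row, state, exposure_s, replicate) -> Da, or a fixed
# numeric vector recycled over rows.
manual_dataset <- function(peptides, states, exposures_s, n_replicates = 3,
                           uptake, deuterium_fraction = 0.95) {
  grid <- tidyr::crossing(peptides, state = states,
                          exposure_s = exposures_s,
                          replicate = seq_len(n_replicates))
  grid$uptake_da <- if (is.function(uptake)) {
    purrr::pmap_dbl(grid, function(...) uptake(list(...)))
  } else {
    rep_len(uptake, nrow(grid))
  }
  grid$protein <- grid$protein %||% "TEST"
  as_hdx_dataset(
    grid,
    conditions = labeling_conditions(exposures_s,
                                     deuterium_fraction = deuterium_fraction,
                                     n_replicates = n_replicates))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

one_peptide <- function(sequence = "AAAAAAAAAA", start = 1) {
  tibble::tibble(protein = "TEST", start = start,
                 end = start + nchar(sequence) - 1L, sequence = sequence,
                 max_uptake = compute_max_uptake(sequence))
}

# constant-uptake single-peptide dataset pair used by degenerate cases
flat_pair <- function(ctrl_value = 1, var_value = 1) {
  pep <- one_peptide()
  list(
    control = manual_dataset(pep, "control", c(30, 300, 1800),
                             uptake = ctrl_value),
    variant = manual_dataset(pep, "variant", c(30, 300, 1800),
                             uptake = var_value)
  )
}

# Write a toy single-model PDB with CA atoms at given residues/coords.
write_toy_pdb <- function(path, resno, xyz, elety = "CA", chain = "A") {
  n <- length(resno)
  elety <- rep_len(elety, n)
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(xyz)),
                   resno = resno,
                   resid = rep("ALA", n),
                   eleno = seq_len(n),
                   elety = elety,
                   chain = rep(chain, n))
  invisible(path)
}

# Multi-frame trajectory as an hdx_frames object built directly in code:
# one CA atom per residue, coords[frame, atom, xyz].
make_frames <- function(coords, resno, times_ns) {
  hdxshift:::as_frames(coords, resno = resno,
                       atom_name = rep("CA", length(resno)),
                       element = rep("C", length(resno)),
                       times_ns = times_ns)
}

# Random proper rotation matrix (det +1)
random_rotation <- function() {
  qr_d <- qr(matrix(rnorm(9), 3))
  R <- qr.Q(qr_d)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Default simulated control/variant pair used by several tests
simulated_pair <- function(shift = "toward_IF", seed = 7, sd = 0.05,
                           n_residues = 300, min_peptides = 60,
                           scheme = "detergent") {
  sc <- default_transporter_scenario(n_residues, shift, seed = seed)
  pep <- digest_in_silico(sc$sequence, 0.8, seed = seed + 1,
                          min_peptides = min_peptides)
  cond <- labeling_conditions(scheme)
  list(
    scenario = sc, peptides = pep, conditions = cond,
    control = simulate_dataset(sc, pep, cond, "control",
                               noise_model(sd, seed + 2)),
    variant = simulate_dataset(sc, pep, cond, "variant",
                               noise_model(sd, seed + 2))
  )
}

class_sign <- function(classification) {
  ifelse(classification == "positive", 1,
         ifelse(classification == "negative", -1, 0))
}
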