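# Shared fixture builders for the suite. All sequences are synthetic.

scaffold_u <- function() vhhkit:::default_scaffolds()$Upright

# Baseline VHH-like domain: scheme-length regions (FR 25/14/29/11,
# CDR 10/16/L3) so Kabat numbering carries no insertion codes at L3 = 8.
baseline_sequence <- function(cdr3 = "GRAYDYWA",
                              cdr1 = "GRTFSSYAMG",
                              cdr2 = "AISGSGGSTYYADSVK") {
  s <- scaffold_u()
  paste0(s["FR1"], cdr1, s["FR2"], cdr2, s["FR3"], cdr3, s["FR4"])
}

# Independent torsion oracle: bio3d cross-product/atan2 implementation,
# mapped from (-180, 180] to [0, 360).
oracle_torsion <- function(p1, p2, p3, p4) {
  th <- bio3d::torsion.xyz(c(p1, p2, p3, p4), atm.inc = 4)
  if (is.na(th)) return(NA_real_)
  if (th < 0) th <- th + 360
  th %% 360
}

# Random rigid motion (rotation + translation) applied to an n x 3 matrix.
random_rigid <- function(m, seed) {
  withr::with_seed(seed, {
    ax <- rnorm(3); ax <- ax / sqrt(sum(ax^2))
    th <- runif(1, 0, 2 * pi)
    K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3)
    R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    tr <- rnorm(3, sd = 20)
  })
  sweep(m %*% t(R), 2, tr, "+")
}

# Minimal hand-written PDB with an A/B altloc pair on one CA.
write_altloc_pdb <- function(path) {
  atom <- function(eleno, name, alt, res3, resno, x, y, z, occ) {
    sprintf("ATOM  %5d  %-3s%1s%3s A%4d    %8.3f%8.3f%8.3f%6.2f  0.00           C",
            eleno, name, alt, res3, resno, x, y, z, occ)
  }
  writeLines(c(
    "HEADER    IMMUNE SYSTEM                           01-JAN-22   ALTL",
    "EXPDTA    X-RAY DIFFRACTION",
    "REMARK   2 RESOLUTION.    1.90 ANGSTROMS.",
    atom(1, "CA", " ", "GLN", 1, 0, 0, 0, 1),
    atom(2, "CA", " ", "VAL", 2, 3.8, 0, 0, 1),
    atom(3, "CA", "A", "GLN", 3, 7.6, 0, 0, 0.4),
    atom(4, "CA", "B", "GLN", 3, 7.9, 0, 0, 0.6),
    "END"), path)
  path
}

# Two-chain complex with known inter-chain atom distances for paratope
# tests: antibody residues on the x axis, antigen atoms placed at controlled
# distances from selected antibody residues.
make_contact_model <- function(ab_contacts_at, gap = 4.0, far = 50) {
  seq_ab <- baseline_sequence()
  n <- nchar(seq_ab)
  res_ab <- data.frame(resno = seq_len(n), ins = "",
                       aa = strsplit(seq_ab, "")[[1]],
                       ca_x = 10 * seq_len(n), ca_y = 0, ca_z = 0,
                       stringsAsFactors = FALSE)
  ab <- chain_record("A", seq_ab, res_ab)
  nb <- assign_kabat(seq_ab)
  ag_xyz <- do.call(rbind, lapply(ab_contacts_at, function(kn) {
    j <- nb$seq_index[nb$kabat_num == kn & nb$kabat_ins == ""]
    c(10 * j, gap, 0)
  }))
  ag_xyz <- rbind(ag_xyz, c(-far, -far, -far))
  res_ag <- data.frame(resno = seq_len(nrow(ag_xyz)), ins = "", aa = "G",
                       ca_x = ag_xyz[, 1], ca_y = ag_xyz[, 2],
                       ca_z = ag_xyz[, 3], stringsAsFactors = FALSE)
  ag <- chain_record("B", strrep("G", nrow(ag_xyz)), res_ag)
  structure_model("cplx", "X-RAY DIFFRACTION", 2.0, list(ab, ag))
}

# Curation record table builder with sensible defaults.
make_record <- function(entry_id = "1abc", chain_id = "A",
                        method = "X-RAY DIFFRACTION", resolution = 2.0,
                        light_chain_id = NA_character_,
                        species_heavy = "lama glama",
                        species_light = NA_character_,
                        antigen_chain_ids = "B",
                        ligand_mw_max = NA_real_,
                        variable_domain_sequence = baseline_sequence()) {
  data.frame(entry_id = entry_id, chain_id = chain_id, method = method,
             resolution = resolution, light_chain_id = light_chain_id,
             species_heavy = species_heavy, species_light = species_light,
             antigen_chain_ids = antigen_chain_ids,
             ligand_mw_max = ligand_mw_max,
             variable_domain_sequence = variable_domain_sequence,
             stringsAsFactors = FALSE)
}
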