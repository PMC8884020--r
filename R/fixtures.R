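# Seeded synthetic fixtures: geometric loop traces with prescribed
# classification indices, random CDR repertoires, and planted-truth clone
# tables. Every generator is a pure function of its seed and parameters.
# Fixtures aim for plausibility (Calpha spacing ~3.8 Angstrom), not
# force-field realism.

FIXTURE_CDR1 <- "GRTFSSYAMG"                 # 10 aa, no Trp/Cys
FIXTURE_CDR2 <- "AISGSGGSTYYADSVK"          # 16 aa, no Cys

#' Build a Calpha trace realizing prescribed loop-geometry indices
#'
#' Constructs a VHH-like chain (baseline frameworks, CDR3 of the requested
#' length) whose Calpha coordinates are an analytic placement of the five
#' geometry-defining atoms -- H46, and the CDR3-anchor quad (n+1), (n),
#' (n-1), (n-2) plus (n-5) -- so that [loop_geometry()] recovers
#' `theta_target` and `d_target` exactly (within floating-point error);
#' remaining residues lie on a smooth generic trace. No optimization loop is
#' involved.
#'
#' @param theta_target pseudo-dihedral target in degrees, [0, 360).
#' @param d_target H46-to-(n-5) distance target in Angstrom, > 0.
#' @param cdr3_length CDR3 length (>= 5).
#' @param seed seed for the CDR3 sequence letters.
#' @return list: `chain` ([chain_record()]), `numbering`
#'   (`DomainNumbering`), `sequence`, `model` (a single-chain
#'   [structure_model()] ready for [write_mock_structure()]).
#' @export
make_loop_trace <- function(theta_target, d_target, cdr3_length, seed = 1) {
  if (cdr3_length < 5)
    vhh_error("vhh_construction_error", "cdr3_length must be >= 5")
  if (theta_target < 0 || theta_target >= 360)
    vhh_error("vhh_construction_error", "theta_target must be in [0, 360)")
  if (d_target <= 0)
    vhh_error("vhh_construction_error", "d_target must be > 0")

  scaff <- default_scaffolds()$Upright
  cdr3 <- withr::with_seed(seed, paste(
    sample(cdr3_alphabet17(), cdr3_length, replace = TRUE), collapse = ""))
  sequence <- paste0(scaff["FR1"], FIXTURE_CDR1, scaff["FR2"], FIXTURE_CDR2,
                     scaff["FR3"], cdr3, scaff["FR4"])
  numbering <- assign_kabat(sequence)
  n <- nchar(sequence)

  # generic smooth trace: gentle helix, ~3.8 A between neighbours
  i <- seq_len(n)
  ca <- cbind(3.5 * i, 4.0 * sin(i / 3), 4.0 * cos(i / 3))

  r_n <- which(numbering$kabat_num == 102 & numbering$kabat_ins == "")
  r46 <- which(numbering$kabat_num == 46 & numbering$kabat_ins == "")
  th <- theta_target * pi / 180
  b <- 3.8
  # torsion quad in a local frame: atoms (n+1), (n), (n-1), (n-2)
  quad <- rbind(c(0, b, 0), c(0, 0, 0), c(b, 0, 0),
                c(b, b * cos(th), b * sin(th)))
  off <- ca[numbering$seq_index[r_n], ] - quad[2, ]   # anchor quad near trace
  ca[numbering$seq_index[r_n + 1], ] <- quad[1, ] + off
  ca[numbering$seq_index[r_n], ]     <- quad[2, ] + off
  ca[numbering$seq_index[r_n - 1], ] <- quad[3, ] + off
  ca[numbering$seq_index[r_n - 2], ] <- quad[4, ] + off
  # H46 placed at the exact target distance from the (n-5) residue
  u <- c(0.48, -0.6, 0.64)                            # unit vector
  ca[numbering$seq_index[r46], ] <-
    ca[numbering$seq_index[r_n - 5], ] + d_target * u

  residues <- data.frame(resno = i, ins = "",
                         aa = strsplit(sequence, "")[[1]],
                         ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
                         stringsAsFactors = FALSE)
  chain <- chain_record("A", sequence, residues)
  model <- structure_model(sprintf("mk%02d", seed %% 100),
                           "X-RAY DIFFRACTION", 2.0, list(chain))
  list(chain = chain, numbering = numbering, sequence = sequence,
       model = model)
}

#' Generate distinct random CDR repertoires
#'
#' Stand-in for curated camelid CDR1/CDR2 repertoires: distinct random
#' sequences of the correct lengths (CDR1 spans H26-H35, hence 10 residues).
#'
#' @param cdr1_n,cdr2_n repertoire sizes.
#' @param cdr2_len CDR2 length (16 for Upright-type, 17 for Roll-type).
#' @param seed RNG seed.
#' @param alphabet amino-acid alphabet (default the full 20 letters).
#' @param cdr1_len CDR1 length (default 10).
#' @param dir optional directory: writes `cdr1.fasta` / `cdr2.fasta`.
#' @return list: `cdr1`, `cdr2` character vectors.
#' @export
make_repertoires <- function(cdr1_n, cdr2_n, cdr2_len, seed,
                             alphabet = AA20, cdr1_len = 10, dir = NULL) {
  stopifnot(cdr1_n >= 1, cdr2_n >= 1)
  gen_distinct <- function(n, len) {
    if (len * log(length(alphabet)) < log(.Machine$double.xmax) &&
        n > length(alphabet)^min(len, 30))
      vhh_error("vhh_capacity_error",
                sprintf("cannot draw %d distinct sequences of length %d over %d letters",
                        n, len, length(alphabet)))
    out <- character(0)
    while (length(out) < n) {
      need <- n - length(out)
      cand <- apply(matrix(sample(alphabet, need * len, replace = TRUE),
                           ncol = len), 1, paste, collapse = "")
      out <- unique(c(out, cand))
    }
    out[seq_len(n)]
  }
  reps <- withr::with_seed(seed, list(cdr1 = gen_distinct(cdr1_n, cdr1_len),
                                      cdr2 = gen_distinct(cdr2_n, cdr2_len)))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta_seqs(stats::setNames(reps$cdr1,
                                     sprintf("cdr1_%03d", seq_len(cdr1_n))),
                     file.path(dir, "cdr1.fasta"))
    write_fasta_seqs(stats::setNames(reps$cdr2,
                                     sprintf("cdr2_%03d", seq_len(cdr2_n))),
                     file.path(dir, "cdr2.fasta"))
  }
  reps
}

#' Generate a planted-truth clone table
#'
#' Clones are sampled from the design's sub-libraries in equal proportion;
#' a fraction are exact duplicates of earlier clones, a fraction carry a
#' single FR2 point substitution (destined for "other" in attribution), and
#' binder/non-binder status, K_D, T_m and T_agg are drawn from stated
#' distributions. The ground truth records every planted label.
#'
#' @param design a `LibraryDesign`.
#' @param n number of clones.
#' @param binder_fraction fraction with response above the 0.1 threshold.
#' @param duplicate_rate fraction duplicating an earlier clone's sequence.
#' @param mutant_rate fraction given one FR2 substitution.
#' @param kd_log10_range log10(K_D/M) range, uniform (default -12..-7).
#' @param tm_mean,tm_sd T_m normal parameters (degrees C).
#' @param seed RNG seed.
#' @param dir optional directory: writes `clones.tsv` and `truth.json`.
#' @return list: `clones` (data.frame `clone_id`, `sequence`, `response`,
#'   `kd_molar`, `tm_c`, `tagg_c`), `truth` (`clone_id`, `sublibrary`,
#'   `is_binder`, `duplicate_of`, `is_mutant`).
#' @export
make_clone_table <- function(design, n = 200, binder_fraction = 0.5,
                             duplicate_rate = 0.1, mutant_rate = 0.1,
                             kd_log10_range = c(-12, -7),
                             tm_mean = 65, tm_sd = 8, seed = 1, dir = NULL) {
  subs <- names(design$sublibraries)
  res <- withr::with_seed(seed, {
    origin <- sample(subs, n, replace = TRUE)
    seqs <- character(n)
    for (nm in subs) {
      idx <- which(origin == nm)
      if (length(idx))
        seqs[idx] <- sample_protein(design, nm, length(idx),
                                    seed = sample.int(1e6, 1))$sequence
    }
    # mutate first, then copy duplicates, so a duplicate always shares its
    # source's final sequence and mutant status
    is_mut <- runif(n) < mutant_rate
    for (j in which(is_mut)) {
      s <- design$sublibraries[[origin[j]]]
      fr2_start <- nchar(s$fr["FR1"]) + nchar(s$cdr1[1]) + 1
      pos <- fr2_start + sample.int(nchar(s$fr["FR2"]), 1) - 1
      old <- substr(seqs[j], pos, pos)
      substr(seqs[j], pos, pos) <- sample(setdiff(AA20, old), 1)
    }
    dup_of <- rep(NA_integer_, n)
    if (n >= 2) {
      cand <- 2:n
      dup <- cand[runif(length(cand)) < duplicate_rate]
      for (j in dup) {
        src <- sample.int(j - 1, 1)
        seqs[j] <- seqs[src]
        origin[j] <- origin[src]
        is_mut[j] <- is_mut[src]
        dup_of[j] <- src
      }
    }
    mut <- which(is_mut)
    is_binder <- runif(n) < binder_fraction
    response <- ifelse(is_binder, runif(n, 0.15, 2.0), runif(n, 0, 0.08))
    kd <- 10^runif(n, kd_log10_range[1], kd_log10_range[2])
    tm <- rnorm(n, tm_mean, tm_sd)
    tagg <- tm - abs(rnorm(n, 2, 2))
    list(origin = origin, seqs = seqs, dup_of = dup_of, mut = mut,
         is_binder = is_binder, response = response, kd = kd, tm = tm,
         tagg = tagg)
  })
  ids <- sprintf("clone%04d", seq_len(n))
  clones <- data.frame(clone_id = ids, sequence = res$seqs,
                       response = round(res$response, 4),
                       kd_molar = signif(res$kd, 4),
                       tm_c = round(res$tm, 2), tagg_c = round(res$tagg, 2),
                       stringsAsFactors = FALSE)
  truth <- data.frame(clone_id = ids,
                      sublibrary = ifelse(seq_len(n) %in% res$mut, "other",
                                          res$origin),
                      origin = res$origin,
                      is_binder = res$is_binder,
                      duplicate_of = ifelse(is.na(res$dup_of), NA,
                                            ids[res$dup_of]),
                      is_mutant = seq_len(n) %in% res$mut,
                      stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(clones, file.path(dir, "clones.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  list(clones = clones, truth = truth)
}
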