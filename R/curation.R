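# Structure-dataset curation: filters that reproduce the dataset-construction
# criteria (heavy-chain-only or paired entries, X-ray method, resolution
# cutoff, species, hapten exclusion), exact-duplicate removal, and the
# class/length summary statistics.

#' Curation criteria
#'
#' @param require_heavy_only keep only entries without a light chain (VHH
#'   dataset rule).
#' @param require_paired keep only entries with both heavy and light chain
#'   (VH dataset rule). Mutually exclusive with `require_heavy_only`.
#' @param method required experimental method label, or NULL to skip.
#' @param resolution_max resolution cutoff in Angstrom; "better than" is
#'   strict, so records with `resolution >= resolution_max` are rejected.
#' @param species required organism label (verbatim match), or NULL.
#' @param exclude_hapten reject complexes whose only antigen entities are
#'   small non-polymer components (all ligand MW < `hapten_mw_max`).
#' @param hapten_mw_max molecular-weight bound (Da) in the hapten heuristic.
#' @return a `CurationCriteria` list.
#' @export
curation_criteria <- function(require_heavy_only = TRUE,
                              require_paired = FALSE,
                              method = "X-RAY DIFFRACTION",
                              resolution_max = 2.8,
                              species = NULL,
                              exclude_hapten = TRUE,
                              hapten_mw_max = 1000) {
  if (require_heavy_only && require_paired)
    vhh_error("vhh_validation_error",
              "require_heavy_only and require_paired are mutually exclusive")
  if (resolution_max <= 0)
    vhh_error("vhh_validation_error", "resolution_max must be > 0")
  structure(list(require_heavy_only = require_heavy_only,
                 require_paired = require_paired, method = method,
                 resolution_max = resolution_max, species = species,
                 exclude_hapten = exclude_hapten,
                 hapten_mw_max = hapten_mw_max),
            class = "CurationCriteria")
}

# Is this record a hapten-only complex? Declared convention: no polymer
# antigen chain and at least one ligand, all ligands below the MW bound.
# A per-record `hapten` logical column overrides the heuristic.
is_hapten_record <- function(records, mw_max) {
  has_poly_ag <- !is.na(records$antigen_chain_ids) &
    nzchar(records$antigen_chain_ids)
  mw <- records$ligand_mw_max
  heur <- !has_poly_ag & !is.na(mw) & mw > 0 & mw < mw_max
  if ("hapten" %in% names(records)) {
    ov <- records$hapten
    heur[!is.na(ov)] <- ov[!is.na(ov)]
  }
  heur
}

#' Filter dataset records against curation criteria
#'
#' Records missing metadata needed by an enabled rule are rejected with
#' reason "missing-metadata", never silently kept.
#'
#' @param records data.frame with (as needed by enabled rules) columns
#'   `entry_id`, `chain_id`, `method`, `resolution`, `light_chain_id`
#'   (NA when heavy-only), `species_heavy`, `species_light`,
#'   `antigen_chain_ids` (comma-separated, "" or NA when none),
#'   `ligand_mw_max` (max MW of non-water ligands, NA when none) and an
#'   optional `hapten` logical override.
#' @param criteria a [curation_criteria()].
#' @return list with `kept` (subset), `rejections` (data.frame `entry_id`,
#'   `chain_id`, `reason`) and `log` (counts per rule).
#' @export
filter_records <- function(records, criteria = curation_criteria()) {
  n <- nrow(records)
  reason <- rep(NA_character_, n)
  need <- c("method", "resolution")
  if (criteria$require_heavy_only || criteria$require_paired)
    need <- c(need, "light_chain_id")
  if (!is.null(criteria$species))
    need <- c(need, "species_heavy",
              if (criteria$require_paired) "species_light")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols))
    vhh_error("vhh_validation_error",
              sprintf("records lack required columns: %s",
                      paste(missing_cols, collapse = ", ")))

  miss <- is.na(records$method) | is.na(records$resolution)
  if (!is.null(criteria$species)) {
    miss <- miss | is.na(records$species_heavy)
    # light-chain species only needed when a light chain is present;
    # chainless entries fall to the pairing rule instead
    if (criteria$require_paired)
      miss <- miss | (!is.na(records$light_chain_id) &
                        is.na(records$species_light))
  }
  reason[miss] <- "missing-metadata"

  ok <- is.na(reason)
  if (criteria$require_heavy_only) {
    bad <- ok & !is.na(records$light_chain_id)
    reason[bad] <- "light-chain-present"
  }
  if (criteria$require_paired) {
    bad <- ok & is.na(records$light_chain_id)
    reason[bad] <- "light-chain-absent"
  }
  ok <- is.na(reason)
  if (!is.null(criteria$method)) {
    bad <- ok & records$method != criteria$method
    reason[bad] <- "method"
  }
  ok <- is.na(reason)
  bad <- ok & records$resolution >= criteria$resolution_max
  reason[bad] <- "resolution"
  ok <- is.na(reason)
  if (!is.null(criteria$species)) {
    bad <- ok & records$species_heavy != criteria$species
    if (criteria$require_paired)
      bad <- bad | (ok & records$species_light != criteria$species)
    reason[bad] <- "species"
  }
  ok <- is.na(reason)
  if (criteria$exclude_hapten &&
      all(c("antigen_chain_ids", "ligand_mw_max") %in% names(records))) {
    bad <- ok & is_hapten_record(records, criteria$hapten_mw_max)
    reason[bad] <- "hapten"
  }

  kept <- records[is.na(reason), , drop = FALSE]
  rej <- data.frame(entry_id = records$entry_id[!is.na(reason)],
                    chain_id = if ("chain_id" %in% names(records))
                      records$chain_id[!is.na(reason)] else NA_character_,
                    reason = reason[!is.na(reason)],
                    stringsAsFactors = FALSE)
  counts <- table(rej$reason)
  log <- data.frame(rule = as.character(names(counts)),
                    n_rejected = as.integer(counts),
                    stringsAsFactors = FALSE)
  list(kept = kept, rejections = rej, log = log)
}

#' Remove exact sequence duplicates
#'
#' Redundancy removal at 100 percent identity: no two retained records share
#' an identical variable-domain sequence. The retained representative has
#' the best (smallest) resolution; ties break to the lexicographically
#' smallest `entry_id`.
#'
#' @param records data.frame with columns `variable_domain_sequence`,
#'   `resolution`, `entry_id`.
#' @return the de-duplicated subset, in original column layout.
#' @export
dedup_exact <- function(records) {
  if (!nrow(records)) return(records)
  ord <- order(records$variable_domain_sequence, records$resolution,
               records$entry_id)
  r <- records[ord, , drop = FALSE]
  r[!duplicated(r$variable_domain_sequence), , drop = FALSE]
}

#' Class and CDR-length summary statistics
#'
#' @param records data.frame with columns `class` (Upright/Roll/Half-Roll,
#'   NA = unclassified), `cdr2_length`, `cdr3_length` and `cdr3_seq`.
#' @param long_cdr3 cysteine stratification boundary (default 16: loops with
#'   16 or more residues vs shorter).
#' @return list: `cdr3_hist` (class x CDR3-length counts),
#'   `cdr2_contingency` (counts with row percentages),
#'   `cys_by_length` (fraction of CDR3s containing Cys, per stratum),
#'   `n_unclassified`.
#' @export
class_length_summary <- function(records, long_cdr3 = 16) {
  uncl <- is.na(records$class)
  r <- records[!uncl, , drop = FALSE]
  classes <- c("Upright", "Roll", "Half-Roll")
  cls <- factor(r$class, levels = classes)

  cdr3_hist <- as.data.frame(table(class = cls, cdr3_length = r$cdr3_length),
                             stringsAsFactors = FALSE)
  cdr3_hist$cdr3_length <- as.integer(cdr3_hist$cdr3_length)
  names(cdr3_hist)[3] <- "n"

  ct <- table(class = cls, cdr2_length = r$cdr2_length)
  rs <- rowSums(ct)
  pct <- sweep(ct, 1, ifelse(rs == 0, 1, rs), "/") * 100
  cdr2 <- as.data.frame(ct, stringsAsFactors = FALSE)
  names(cdr2)[3] <- "n"
  cdr2$row_pct <- as.data.frame(pct, stringsAsFactors = FALSE)$Freq
  cdr2$cdr2_length <- as.integer(cdr2$cdr2_length)

  has_cys <- grepl("C", r$cdr3_seq, fixed = TRUE)
  stratum <- ifelse(r$cdr3_length >= long_cdr3,
                    sprintf(">=%d", long_cdr3), sprintf("<%d", long_cdr3))
  cys <- do.call(rbind, lapply(unique(stratum), function(s) {
    sel <- stratum == s
    data.frame(stratum = s, n = sum(sel),
               frac_with_cys = mean(has_cys[sel]), stringsAsFactors = FALSE)
  }))

  list(cdr3_hist = cdr3_hist, cdr2_contingency = cdr2,
       cys_by_length = cys, n_unclassified = sum(uncl))
}

#' Hallmark-residue profile at FR2 positions H37/H44/H45/H47
#'
#' In classic camelid VHHs these positions are hydrophilic (e.g. F/E/R/G),
#' where human VH carries the hydrophobic VL-interface set (V/G/L/W);
#' Roll-type VHHs tend toward the VH-like tetrad.
#'
#' @param records data.frame with columns `entry_id`, `chain_id`,
#'   `sequence`; numbering is computed per record with [assign_kabat()]
#'   unless a list column `numbering` is supplied. A position absent from
#'   the numbering (or a failed numbering) yields 'X', counted separately.
#' @return list: `per_record` (tetrad per record) and `frequencies`
#'   (position x amino-acid counts).
#' @export
hallmark_profile <- function(records) {
  positions <- c(37L, 44L, 45L, 47L)
  rows <- lapply(seq_len(nrow(records)), function(i) {
    nb <- if ("numbering" %in% names(records)) records$numbering[[i]]
    else tryCatch(assign_kabat(records$sequence[i]),
                  vhh_error = function(e) NULL)
    aa <- rep("X", 4)
    if (!is.null(nb)) {
      letters1 <- strsplit(attr(nb, "sequence"), "")[[1]]
      for (k in seq_along(positions)) {
        j <- which(nb$kabat_num == positions[k] & nb$kabat_ins == "")
        if (length(j) == 1) aa[k] <- letters1[nb$seq_index[j]]
      }
    }
    data.frame(entry_id = records$entry_id[i], chain_id = records$chain_id[i],
               H37 = aa[1], H44 = aa[2], H45 = aa[3], H47 = aa[4],
               stringsAsFactors = FALSE)
  })
  per_record <- do.call(rbind, rows)
  freq <- sapply(c("H37", "H44", "H45", "H47"), function(p)
    table(factor(per_record[[p]], levels = c(AA20, "X"))))
  list(per_record = per_record, frequencies = t(freq))
}
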