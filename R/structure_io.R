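# Structure reading and the uniform internal model.
#
# Parsing of PDB / mmCIF is delegated to bio3d; this layer resolves
# alternate locations, separates polymer chains from ligands, attaches
# SEQRES-derived sequences and header metadata, and exposes a mock writer so
# the whole pipeline is testable without downloaded structures.

AA_MASS <- c(C = 12.011, N = 14.007, O = 15.999, S = 32.06, P = 30.974,
             F = 18.998, CL = 35.45, BR = 79.904, I = 126.904,
             FE = 55.845, ZN = 65.38, MG = 24.305, "NA" = 22.99, K = 39.098,
             CA = 40.078, MN = 54.938, SE = 78.971, CU = 63.546, CO = 58.933)

#' Chain record constructor
#'
#' @param chain_id single-character chain identifier.
#' @param seqres one-letter SEQRES-derived sequence (may equal the
#'   atom-derived sequence when SEQRES is absent).
#' @param residues data.frame with columns `resno`, `ins`, `aa`,
#'   `ca_x`, `ca_y`, `ca_z` (NA when no Calpha), ordered by author numbering.
#' @param atoms data.frame of heavy atoms: `resno`, `ins`, `aa`, `atom`,
#'   `x`, `y`, `z`.
#' @param species optional organism label.
#' @return an object of class `ChainRecord`.
#' @export
chain_record <- function(chain_id, seqres, residues, atoms = NULL,
                         species = NA_character_) {
  stopifnot(is.character(chain_id), nchar(chain_id) >= 1)
  stopifnot(all(c("resno", "ins", "aa", "ca_x", "ca_y", "ca_z") %in%
                  names(residues)))
  if (is.null(atoms)) {
    has_ca <- !is.na(residues$ca_x)
    atoms <- data.frame(resno = residues$resno[has_ca],
                        ins = residues$ins[has_ca],
                        aa = residues$aa[has_ca], atom = "CA",
                        x = residues$ca_x[has_ca], y = residues$ca_y[has_ca],
                        z = residues$ca_z[has_ca],
                        stringsAsFactors = FALSE)
  }
  structure(list(chain_id = chain_id, seqres = seqres, residues = residues,
                 atoms = atoms, species = species),
            class = "ChainRecord")
}

#' Structure model constructor
#'
#' @param entry_id entry identifier.
#' @param method experimental method label (e.g. "X-RAY DIFFRACTION").
#' @param resolution resolution in Angstrom, NA for non-crystallographic
#'   entries.
#' @param chains list of [chain_record()] objects.
#' @param ligands data.frame of non-polymer components (`id`, `chain`,
#'   `resno`, `n_heavy`, `mw`).
#' @return an object of class `StructureModel`.
#' @export
structure_model <- function(entry_id, method = NA_character_,
                            resolution = NA_real_, chains = list(),
                            ligands = NULL) {
  ids <- vapply(chains, function(ch) ch$chain_id, character(1))
  if (anyDuplicated(ids))
    vhh_error("vhh_validation_error", "duplicate chain identifiers in entry")
  if (!is.na(resolution) && resolution <= 0)
    vhh_error("vhh_validation_error", "resolution must be > 0 when present")
  if (is.null(ligands))
    ligands <- data.frame(id = character(0), chain = character(0),
                          resno = integer(0), n_heavy = integer(0),
                          mw = numeric(0), stringsAsFactors = FALSE)
  structure(list(entry_id = entry_id, method = method,
                 resolution = resolution,
                 chains = stats::setNames(chains, ids), ligands = ligands),
            class = "StructureModel")
}

#' @export
print.StructureModel <- function(x, ...) {
  cat(sprintf("<StructureModel %s> method=%s resolution=%s, %d chain(s), %d ligand(s)\n",
              x$entry_id, x$method,
              ifelse(is.na(x$resolution), "NA", format(x$resolution)),
              length(x$chains), nrow(x$ligands)))
  for (ch in x$chains)
    cat(sprintf("  chain %s: %d residues (%d with Calpha)\n", ch$chain_id,
                nrow(ch$residues), sum(!is.na(ch$residues$ca_x))))
  invisible(x)
}

# Resolve alternate locations: keep highest occupancy per
# (chain, resno, insert, atom name); ties broken by altloc label order.
resolve_altlocs <- function(atom) {
  alt <- ifelse(is.na(atom$alt), "", atom$alt)
  occ <- ifelse(is.na(atom$o), 1, atom$o)
  key <- paste(atom$chain, atom$resno, ifelse(is.na(atom$insert), "", atom$insert),
               atom$elety, sep = "\r")
  ord <- order(key, -occ, alt)
  atom <- atom[ord, , drop = FALSE]
  atom[!duplicated(key[ord]), , drop = FALSE]
}

parse_pdb_header <- function(lines) {
  method <- NA_character_
  resolution <- NA_real_
  entry_id <- NA_character_
  h <- grep("^HEADER", lines, value = TRUE)
  if (length(h)) {
    id <- trimws(substr(h[1], 63, 66))
    if (nzchar(id)) entry_id <- tolower(id)
  }
  e <- grep("^EXPDTA", lines, value = TRUE)
  if (length(e)) method <- trimws(substr(e[1], 11, nchar(e[1])))
  r <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(r)) {
    tail_r <- substr(r[1], 23, nchar(r[1]))
    m <- regmatches(tail_r, regexpr("[0-9]+\\.?[0-9]*", tail_r))
    if (length(m)) resolution <- suppressWarnings(as.numeric(m))
  }
  list(entry_id = entry_id, method = method, resolution = resolution)
}

parse_cif_header <- function(lines) {
  method <- NA_character_
  resolution <- NA_real_
  entry_id <- NA_character_
  grab <- function(tag) {
    l <- grep(paste0("^", tag, "\\s"), lines, value = TRUE)
    if (!length(l)) return(NA_character_)
    v <- trimws(sub(paste0("^", tag, "\\s+"), "", l[1]))
    gsub("^['\"]|['\"]$", "", v)
  }
  e <- grab("_entry.id")
  if (!is.na(e)) entry_id <- tolower(e)
  m <- grab("_exptl.method")
  if (!is.na(m)) method <- toupper(m)
  for (tag in c("_refine.ls_d_res_high", "_reflns.d_resolution_high")) {
    v <- grab(tag)
    if (!is.na(v) && grepl("^[0-9.]+$", v)) { resolution <- as.numeric(v); break }
  }
  list(entry_id = entry_id, method = method, resolution = resolution)
}

#' Read a PDB or mmCIF file into a StructureModel
#'
#' Keeps the first model of multi-model files, resolves alternate locations
#' by highest occupancy (ties by altloc label), drops hydrogens, maps
#' modified polymer residues to 'X' where no standard parent is known, and
#' collects non-water HETATM components into a ligand table with heavy-atom
#' counts and molecular weights (hydrogens ignored).
#'
#' @param path file path.
#' @param format one of "auto", "pdb", "mmcif".
#' @return a [structure_model()].
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path))
    vhh_error("vhh_io_error", sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  lines <- readLines(path, warn = FALSE)
  hdr <- if (format == "pdb") parse_pdb_header(lines) else parse_cif_header(lines)
  if (is.na(hdr$entry_id))
    hdr$entry_id <- sub("\\.[^.]+$", "", basename(path))

  pdb <- tryCatch(
    if (format == "pdb")
      bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
    else
      bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE),
    error = function(e)
      vhh_error("vhh_format_error",
                sprintf("failed to parse %s as %s: %s", path, format,
                        conditionMessage(e))))

  atom <- resolve_altlocs(pdb$atom)
  elem <- toupper(ifelse(is.na(atom$elesy) | atom$elesy == "",
                         substr(trimws(atom$elety), 1, 1), atom$elesy))
  atom <- atom[!elem %in% c("H", "D"), , drop = FALSE]
  atom$insert <- ifelse(is.na(atom$insert), "", atom$insert)
  atom$chain <- ifelse(is.na(atom$chain), "A", atom$chain)

  # polymer residue: carries a carbon CA atom (excludes calcium ions)
  elem <- toupper(ifelse(is.na(atom$elesy) | atom$elesy == "",
                         substr(trimws(atom$elety), 1, 1), atom$elesy))
  rkey <- paste(atom$chain, atom$resno, atom$insert, sep = "\r")
  ca_keys <- unique(rkey[atom$elety == "CA" & elem == "C"])
  is_poly <- rkey %in% ca_keys | atom$type == "ATOM"

  seqres3 <- pdb$seqres # named three-letter vector, possibly NULL/empty
  chains <- list()
  for (cid in unique(atom$chain[is_poly])) {
    sub <- atom[is_poly & atom$chain == cid, , drop = FALSE]
    ord <- order(sub$resno, sub$insert)
    sub <- sub[ord, , drop = FALSE]
    ridx <- !duplicated(paste(sub$resno, sub$insert, sep = "\r"))
    res3 <- sub$resid[ridx]
    aa <- suppressWarnings(bio3d::aa321(res3))
    aa[is.na(aa) | aa == "-" | !aa %in% AA20] <- "X"
    resno <- sub$resno[ridx]
    ins <- sub$insert[ridx]
    ca <- matrix(NA_real_, nrow = sum(ridx), ncol = 3)
    keym <- paste(sub$resno, sub$insert, sep = "\r")
    ukey <- keym[ridx]
    ca_rows <- which(sub$elety == "CA")
    ca[match(keym[ca_rows], ukey), ] <- cbind(sub$x[ca_rows], sub$y[ca_rows],
                                              sub$z[ca_rows])
    residues <- data.frame(resno = resno, ins = ins, aa = aa,
                           ca_x = ca[, 1], ca_y = ca[, 2], ca_z = ca[, 3],
                           stringsAsFactors = FALSE)
    atoms <- data.frame(resno = sub$resno, ins = sub$insert,
                        aa = aa[match(keym, ukey)], atom = trimws(sub$elety),
                        x = sub$x, y = sub$y, z = sub$z,
                        stringsAsFactors = FALSE)
    sq <- if (!is.null(seqres3) && any(names(seqres3) == cid)) {
      a <- suppressWarnings(bio3d::aa321(seqres3[names(seqres3) == cid]))
      a[is.na(a) | a == "-" | !a %in% AA20] <- "X"
      paste(a, collapse = "")
    } else paste(aa, collapse = "")
    chains[[cid]] <- chain_record(cid, sq, residues, atoms)
  }
  if (!length(chains))
    vhh_error("vhh_empty_structure",
              sprintf("no polymer chains found in %s", path))

  lig <- atom[!is_poly, , drop = FALSE]
  lig <- lig[!toupper(lig$resid) %in% c("HOH", "DOD", "WAT"), , drop = FALSE]
  ligands <- if (nrow(lig)) {
    key <- paste(lig$chain, lig$resno, lig$resid, sep = "\r")
    elem <- toupper(ifelse(is.na(lig$elesy) | lig$elesy == "",
                           substr(trimws(lig$elety), 1, 1), lig$elesy))
    mw <- unname(AA_MASS[elem])
    mw[is.na(mw)] <- 0
    agg <- tapply(mw, key, sum)
    cnt <- tapply(mw, key, length)
    first <- !duplicated(key)
    data.frame(id = lig$resid[first], chain = lig$chain[first],
               resno = lig$resno[first],
               n_heavy = as.integer(cnt[key[first]]),
               mw = as.numeric(agg[key[first]]), stringsAsFactors = FALSE)
  } else NULL

  structure_model(hdr$entry_id, hdr$method, hdr$resolution, chains, ligands)
}

#' Extract a chain sequence
#'
#' @param model a [structure_model()].
#' @param chain_id chain identifier.
#' @param source "seqres" for the SEQRES-derived full sequence, "atom" for
#'   the sequence over residues with coordinates (gaps omitted).
#' @return one-letter amino acid string.
#' @export
extract_chain_sequence <- function(model, chain_id,
                                   source = c("seqres", "atom")) {
  source <- match.arg(source)
  ch <- model$chains[[chain_id]]
  if (is.null(ch))
    vhh_error("vhh_lookup_error", sprintf("unknown chain id: %s", chain_id))
  if (source == "seqres") ch$seqres else paste(ch$residues$aa, collapse = "")
}

fmt_atom_name <- function(nm) {
  # element right-justified in columns 13-14 for short names
  if (nchar(nm) >= 4) substr(nm, 1, 4) else sprintf(" %-3s", nm)
}

#' Write a minimal valid PDB file for a model
#'
#' Emits HEADER, EXPDTA, REMARK 2 RESOLUTION, SEQRES, ATOM and TER records.
#' The round trip through [read_structure()] preserves chain and residue
#' counts, sequences, and Calpha coordinates to the fixed-column precision
#' (1e-3 Angstrom).
#'
#' @param model a [structure_model()] (chains may carry atoms beyond Calpha).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mock_structure <- function(model, path) {
  out <- c(sprintf("%-62s%4s", "HEADER    IMMUNE SYSTEM                           01-JAN-22",
                   toupper(model$entry_id)),
           sprintf("EXPDTA    %s", ifelse(is.na(model$method),
                                          "X-RAY DIFFRACTION", model$method)))
  if (!is.na(model$resolution))
    out <- c(out, sprintf("REMARK   2 RESOLUTION. %7.2f ANGSTROMS.",
                          model$resolution))
  for (ch in model$chains) {
    aa3 <- bio3d::aa123(strsplit(ch$seqres, "")[[1]])
    aa3[is.na(aa3)] <- "UNK"
    n <- length(aa3)
    ser <- 0
    for (i in seq(1, n, by = 13)) {
      ser <- ser + 1
      blk <- aa3[i:min(i + 12, n)]
      out <- c(out, sprintf("SEQRES %3d %s %4d  %s", ser, ch$chain_id, n,
                            paste(sprintf("%-3s", blk), collapse = " ")))
    }
  }
  eleno <- 0
  for (ch in model$chains) {
    at <- ch$atoms
    for (k in seq_len(nrow(at))) {
      eleno <- eleno + 1
      aa3 <- bio3d::aa123(at$aa[k]); if (is.na(aa3)) aa3 <- "UNK"
      out <- c(out, sprintf("ATOM  %5d %s %3s %s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                            eleno, fmt_atom_name(at$atom[k]), aa3,
                            ch$chain_id, at$resno[k],
                            ifelse(at$ins[k] == "", " ", at$ins[k]),
                            at$x[k], at$y[k], at$z[k], 1.0, 0.0,
                            toupper(substr(at$atom[k], 1, 1))))
    }
    out <- c(out, "TER")
  }
  out <- c(out, "END")
  writeLines(out, path)
  invisible(path)
}

#' Serialize / restore a StructureModel as JSON (cache format)
#' @param model a [structure_model()].
#' @param path file path.
#' @return `path` (write) or the restored model (read).
#' @export
write_model_json <- function(model, path) {
  payload <- list(entry_id = model$entry_id, method = model$method,
                  resolution = model$resolution,
                  chains = lapply(unname(model$chains), function(ch)
                    list(chain_id = ch$chain_id, seqres = ch$seqres,
                         residues = ch$residues, atoms = ch$atoms,
                         species = ch$species)),
                  ligands = model$ligands)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  fix_res <- function(df) {
    df$ins <- ifelse(is.na(df$ins), "", df$ins)
    df
  }
  chains <- lapply(seq_len(nrow(p$chains)), function(i) {
    chain_record(p$chains$chain_id[i], p$chains$seqres[i],
                 fix_res(p$chains$residues[[i]]),
                 fix_res(p$chains$atoms[[i]]),
                 species = if (!is.null(p$chains$species)) p$chains$species[i]
                 else NA_character_)
  })
  structure_model(p$entry_id,
                  ifelse(is.null(p$method), NA_character_, p$method),
                  ifelse(is.null(p$resolution), NA_real_, p$resolution),
                  chains, p$ligands)
}

#' Download a PDB entry (optional convenience helper)
#'
#' Thin wrapper around [utils::download.file()]; never used by the test
#' suite, which runs fully offline on generated fixtures.
#'
#' @param entry_id four-character PDB id.
#' @param dest destination file path.
#' @export
fetch_pdb <- function(entry_id, dest = paste0(tolower(entry_id), ".pdb")) {
  url <- sprintf("https://files.rcsb.org/download/%s.pdb", toupper(entry_id))
  utils::download.file(url, dest, quiet = TRUE)
  invisible(dest)
}
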