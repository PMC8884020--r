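# CDR3 loop-conformation classification.
#
# Two indices separate the gross CDR3 conformations of a VHH:
#   d_fr2      : Calpha distance (Angstrom) between Kabat H46 in FR2 and the
#                residue five positions before the CDR3 endpoint H102.
#   theta_base : pseudo-dihedral (degrees, [0, 360)) over the Calpha atoms of
#                residues (n+1), (n), (n-1), (n-2), with n = H102.
# Upright: theta >= 140 and d >= 15.  Roll: theta < 140 and d < 10.
# Everything else is Half-Roll; loops shorter than 5 residues are
# Indeterminate (the indices are undefined for them).

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Pseudo-dihedral angle over four points
#'
#' Standard right-handed torsion about the p2-p3 axis, mapped from
#' (-180, 180] to [0, 360) by adding 360 to negative values.
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom).
#' @return angle in degrees, in [0, 360).
#' @export
pseudo_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sqrt(sum(b1^2)) < 1e-12 || sqrt(sum(b2^2)) < 1e-12 ||
      sqrt(sum(b3^2)) < 1e-12)
    vhh_error("vhh_degenerate_torsion", "consecutive points coincide")
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-12 || sqrt(sum(n2^2)) < 1e-12)
    vhh_error("vhh_degenerate_torsion",
              "collinear points: torsion undefined")
  b2hat <- b2 / sqrt(sum(b2^2))
  theta <- atan2(sum(cross3(n1, n2) * b2hat), sum(n1 * n2)) * 180 / pi
  if (theta < 0) theta <- theta + 360
  theta %% 360
}

loop_geometry_obj <- function(d_fr2, theta_base, cdr3_length) {
  if (!is.na(d_fr2) && d_fr2 < 0)
    vhh_error("vhh_validation_error", "d_fr2 must be >= 0")
  if (!is.na(theta_base) && (theta_base < 0 || theta_base >= 360))
    vhh_error("vhh_validation_error", "theta_base must be in [0, 360)")
  structure(list(d_fr2 = d_fr2, theta_base = theta_base,
                 cdr3_length = as.integer(cdr3_length)),
            class = "LoopGeometry")
}

#' @export
print.LoopGeometry <- function(x, ...) {
  cat(sprintf("<LoopGeometry> d_fr2 = %s A, theta_base = %s deg, CDR3 length = %d\n",
              format(x$d_fr2), format(x$theta_base), x$cdr3_length))
  invisible(x)
}

ca_of <- function(chain, seq_index) {
  r <- chain$residues[seq_index, ]
  if (is.na(r$ca_x)) return(NULL)
  c(r$ca_x, r$ca_y, r$ca_z)
}

#' Compute the two loop-geometry indices for a numbered chain
#'
#' The numbering must have been computed on the chain's atom-derived
#' sequence, so that `seq_index` values index the chain's residue list.
#' Insertion-coded residues count as ordinary positions when stepping back
#' from the CDR3 endpoint.
#'
#' @param chain a [chain_record()].
#' @param numbering a `DomainNumbering` over the chain's residues.
#' @return a `LoopGeometry` (indices are NA, with `cdr3_length` set, for
#'   loops shorter than 5 residues).
#' @export
loop_geometry <- function(chain, numbering) {
  cdr3_rows <- which(numbering$kabat_num >= 95 & numbering$kabat_num <= 102)
  if (!length(cdr3_rows))
    vhh_error("vhh_missing_region", "CDR3 absent from numbering")
  L <- length(cdr3_rows)
  if (L < 5) return(loop_geometry_obj(NA_real_, NA_real_, L))

  r_n <- which(numbering$kabat_num == 102 & numbering$kabat_ins == "")
  if (length(r_n) != 1)
    vhh_error("vhh_missing_region", "CDR3 endpoint H102 absent")
  need <- c(`n+1` = r_n + 1, n = r_n, `n-1` = r_n - 1, `n-2` = r_n - 2,
            `n-5` = r_n - 5)
  if (need["n+1"] > nrow(numbering) || need["n-5"] < 1)
    vhh_error("vhh_missing_coordinate",
              "numbered chain too short around CDR3 endpoint")
  r46 <- which(numbering$kabat_num == 46 & numbering$kabat_ins == "")
  if (length(r46) != 1)
    vhh_error("vhh_missing_region", "FR2 position H46 absent")

  fetch <- function(row, what) {
    p <- ca_of(chain, numbering$seq_index[row])
    if (is.null(p)) {
      lab <- kabat_label(numbering$kabat_num[row], numbering$kabat_ins[row])
      stop(structure(
        class = c("vhh_missing_coordinate", "vhh_error", "error", "condition"),
        list(message = sprintf("missing Calpha at %s (%s)", lab, what),
             kabat = lab, call = sys.call(-1))))
    }
    p
  }
  p1 <- fetch(need["n+1"], "n+1")
  p2 <- fetch(need["n"], "n")
  p3 <- fetch(need["n-1"], "n-1")
  p4 <- fetch(need["n-2"], "n-2")
  pn5 <- fetch(need["n-5"], "n-5")
  p46 <- fetch(r46, "H46")

  loop_geometry_obj(sqrt(sum((p46 - pn5)^2)),
                    pseudo_dihedral(p1, p2, p3, p4), L)
}

# Vectorized class rule; exposed for grid-style evaluation.
loop_class_label <- function(theta, d, cdr3_length,
                             theta_cut = 140, d_upright = 15, d_roll = 10) {
  out <- rep("Half-Roll", length(theta))
  out[theta >= theta_cut & d >= d_upright] <- "Upright"
  out[theta < theta_cut & d < d_roll] <- "Roll"
  out[cdr3_length < 5] <- "Indeterminate"
  out
}

#' Classify a CDR3 loop as Upright, Roll or Half-Roll
#'
#' Upright: `theta_base >= theta_cut` and `d_fr2 >= d_upright`.
#' Roll: `theta_base < theta_cut` and `d_fr2 < d_roll` (strict).
#' Any other combination is Half-Roll. Loops shorter than 5 residues are
#' Indeterminate; an optional `manual` label (from visual inspection of the
#' structure) may then be carried through.
#'
#' @param geom a `LoopGeometry` from [loop_geometry()].
#' @param theta_cut,d_upright,d_roll class thresholds (degrees, Angstrom).
#' @param manual optional label for short (< 5 residue) loops.
#' @return character scalar: "Upright", "Roll", "Half-Roll" or
#'   "Indeterminate".
#' @export
classify_loop <- function(geom, theta_cut = 140, d_upright = 15, d_roll = 10,
                          manual = NULL) {
  if (geom$cdr3_length < 5) {
    if (!is.null(manual)) return(manual)
    return("Indeterminate")
  }
  loop_class_label(geom$theta_base, geom$d_fr2, geom$cdr3_length,
                   theta_cut, d_upright, d_roll)
}

#' Classify every requested chain of one or more structures
#'
#' Convenience driver behind the `classify` CLI subcommand: extracts each
#' chain's atom-derived sequence, numbers it, computes the loop indices and
#' the class.
#'
#' @param models list of [structure_model()] objects.
#' @param chains optional character vector of chain ids (default: all).
#' @param ... thresholds passed to [classify_loop()].
#' @return data.frame: `entry`, `chain`, `cdr3_length`, `d_fr2`,
#'   `theta_base`, `class` (class "failed:<anchor/reason>" when the chain
#'   cannot be numbered or measured).
#' @export
classify_structures <- function(models, chains = NULL, ...) {
  rows <- list()
  for (m in models) {
    ids <- if (is.null(chains)) names(m$chains)
    else intersect(chains, names(m$chains))
    for (cid in ids) {
      ch <- m$chains[[cid]]
      res <- tryCatch({
        nb <- assign_kabat(paste(ch$residues$aa, collapse = ""))
        g <- loop_geometry(ch, nb)
        list(L = g$cdr3_length, d = g$d_fr2, th = g$theta_base,
             cls = classify_loop(g, ...))
      }, vhh_error = function(e)
        list(L = NA_integer_, d = NA_real_, th = NA_real_,
             cls = paste0("failed:", conditionMessage(e))))
      rows[[length(rows) + 1]] <-
        data.frame(entry = m$entry_id, chain = cid, cdr3_length = res$L,
                   d_fr2 = res$d, theta_base = res$th, class = res$cls,
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
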