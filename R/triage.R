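# Post-screening triage arithmetic: binder calling from BLI responses,
# unique-clone accounting, attribution of clones to their sub-library of
# origin, and the affinity/stability candidate-selection window.

#' Call binders from BLI responses
#'
#' A clone is a binder iff its binding response exceeds the threshold
#' strictly (default > 0.1).
#'
#' @param clones data.frame with columns `clone_id`, `sequence`, `response`.
#' @param threshold response threshold.
#' @return list: `binders`, `nonbinders`, `unmeasured` (rows with missing
#'   response, reported rather than dropped).
#' @export
call_binders <- function(clones, threshold = 0.1) {
  unmeasured <- clones[is.na(clones$response), , drop = FALSE]
  measured <- clones[!is.na(clones$response), , drop = FALSE]
  list(binders = measured[measured$response > threshold, , drop = FALSE],
       nonbinders = measured[measured$response <= threshold, , drop = FALSE],
       unmeasured = unmeasured)
}

#' Unique-clone accounting
#'
#' Uniqueness is exact protein-sequence identity; the representative of each
#' sequence is the first clone in `clone_id` order.
#'
#' @param clones data.frame with `clone_id` and `sequence`.
#' @return list: `total`, `n_unique`, `representatives` (one row per unique
#'   sequence).
#' @export
unique_clones <- function(clones) {
  ord <- order(clones$clone_id)
  r <- clones[ord, , drop = FALSE]
  reps <- r[!duplicated(r$sequence), , drop = FALSE]
  list(total = nrow(clones), n_unique = nrow(reps), representatives = reps)
}

# Decompose one sequence against one sub-library spec; TRUE iff frameworks
# match exactly, CDR1/CDR2 are repertoire members and CDR3 has the designed
# length.
matches_spec <- function(sequence, s) {
  l1 <- nchar(s$fr["FR1"]); lc1 <- nchar(s$cdr1[1])
  l2 <- nchar(s$fr["FR2"]); lc2 <- nchar(s$cdr2[1])
  l3 <- nchar(s$fr["FR3"]); lc3 <- s$cdr3_length
  l4 <- nchar(s$fr["FR4"])
  if (nchar(sequence) != l1 + lc1 + l2 + lc2 + l3 + lc3 + l4) return(FALSE)
  at <- function(start, len) substr(sequence, start, start + len - 1)
  p <- cumsum(c(1, l1, lc1, l2, lc2, l3, lc3))
  at(p[1], l1) == s$fr["FR1"] &&
    at(p[3], l2) == s$fr["FR2"] &&
    at(p[5], l3) == s$fr["FR3"] &&
    at(p[7], l4) == s$fr["FR4"] &&
    at(p[2], lc1) %in% s$cdr1 &&
    at(p[4], lc2) %in% s$cdr2
}

#' Attribute a clone to its sub-library of origin
#'
#' The label is the unique sub-library whose frameworks match the sequence
#' exactly, whose CDR1/CDR2 are repertoire members, and whose CDR3 length
#' matches; "other" when zero (e.g. a mutation acquired during screening) or
#' several sub-libraries match.
#'
#' @param sequence one protein sequence, or a character vector.
#' @param design a `LibraryDesign`.
#' @return data.frame: `sequence`, `label`, `reason` ("" for a clean match,
#'   "no-match" or "ambiguous" for "other").
#' @export
attribute_sublibrary <- function(sequence, design) {
  out <- lapply(sequence, function(sq) {
    hits <- names(Filter(isTRUE, lapply(design$sublibraries, function(s)
      matches_spec(sq, s))))
    if (length(hits) == 1)
      data.frame(sequence = sq, label = hits, reason = "",
                 stringsAsFactors = FALSE)
    else
      data.frame(sequence = sq, label = "other",
                 reason = if (length(hits)) "ambiguous" else "no-match",
                 stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Candidate-selection window on affinity and thermal stability
#'
#' Selects clones with `K_D < kd_max` and `T_m > tm_min` (both strict).
#' Defaults follow the screening-triage convention K_D below 1 nM and T_m
#' above 60 degrees C (a stricter 65 degrees C variant is sometimes used;
#' pass `tm_min = 65`).
#'
#' @param clones data.frame with `clone_id`, `kd_molar`, `tm_c` and
#'   optionally `tagg_c`.
#' @param kd_max affinity bound in molar.
#' @param tm_min melting-temperature bound in degrees C.
#' @return list: `selected` (subset), `n_unevaluable` (missing K_D or T_m),
#'   `kd_tm` and `tm_tagg` summary tables with a `selected` flag.
#' @export
select_window <- function(clones, kd_max = 1e-9, tm_min = 60) {
  evaluable <- !is.na(clones$kd_molar) & !is.na(clones$tm_c)
  ev <- clones[evaluable, , drop = FALSE]
  sel_flag <- ev$kd_molar < kd_max & ev$tm_c > tm_min
  kd_tm <- data.frame(clone_id = ev$clone_id, kd_molar = ev$kd_molar,
                      tm_c = ev$tm_c, selected = sel_flag,
                      stringsAsFactors = FALSE)
  tm_tagg <- if ("tagg_c" %in% names(clones))
    data.frame(clone_id = ev$clone_id, tm_c = ev$tm_c, tagg_c = ev$tagg_c,
               selected = sel_flag, stringsAsFactors = FALSE)
  else NULL
  list(selected = ev[sel_flag, , drop = FALSE],
       n_unevaluable = sum(!evaluable), kd_tm = kd_tm, tm_tagg = tm_tagg)
}

#' Full triage summary of a clone table
#'
#' Binder calling, unique-clone accounting on the binders, sub-library
#' attribution of the unique clones, and the selection window.
#'
#' @param clones clone table (`clone_id`, `sequence`, `response`,
#'   `kd_molar`, `tm_c`, `tagg_c`).
#' @param design a `LibraryDesign` for attribution.
#' @param response_threshold,kd_max,tm_min thresholds.
#' @return list with `binders`, `uniques`, `attribution` (label counts),
#'   `window`.
#' @export
triage_clones <- function(clones, design, response_threshold = 0.1,
                          kd_max = 1e-9, tm_min = 60) {
  b <- call_binders(clones, response_threshold)
  u <- unique_clones(b$binders)
  att <- attribute_sublibrary(u$representatives$sequence, design)
  w <- select_window(u$representatives, kd_max, tm_min)
  list(binders = b, uniques = u,
       attribution = cbind(u$representatives["clone_id"], att),
       attribution_counts = table(att$label),
       window = w)
}
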