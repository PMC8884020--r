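# Contact-based paratope mapping of VHH-antigen complexes.
#
# A VHH residue is a paratope contact iff its minimum heavy-atom distance to
# any antigen chain is within the cutoff (default 4.5 Angstrom; hydrogens are
# ignored -- they are rarely present in X-ray models at typical resolution).

#' Contact residues between an antibody chain and antigen chains
#'
#' @param model a [structure_model()].
#' @param antibody_chain chain id of the VHH/VH domain.
#' @param antigen_chains character vector of antigen chain ids.
#' @param cutoff heavy-atom distance cutoff in Angstrom.
#' @param numbering optional `DomainNumbering` for the antibody chain
#'   (computed with [assign_kabat()] on its atom-derived sequence when NULL).
#' @return a `ContactMap` data.frame: `resno`, `ins`, `kabat_num`,
#'   `kabat_ins`, `min_distance`, `antigen_chain`, one row per contacting
#'   antibody residue; the cutoff is attached as an attribute.
#' @export
contact_residues <- function(model, antibody_chain, antigen_chains,
                             cutoff = 4.5, numbering = NULL) {
  ab <- model$chains[[antibody_chain]]
  if (is.null(ab))
    vhh_error("vhh_lookup_error",
              sprintf("unknown antibody chain: %s", antibody_chain))
  ags <- lapply(antigen_chains, function(cid) {
    ch <- model$chains[[cid]]
    if (is.null(ch))
      vhh_error("vhh_lookup_error", sprintf("unknown antigen chain: %s", cid))
    ch
  })
  if (is.null(numbering))
    numbering <- tryCatch(
      assign_kabat(paste(ab$residues$aa, collapse = "")),
      vhh_error = function(e) NULL)

  abm <- as.matrix(ab$atoms[, c("x", "y", "z")])
  ab_key <- paste(ab$atoms$resno, ab$atoms$ins, sep = "\r")
  res_key <- paste(ab$residues$resno, ab$residues$ins, sep = "\r")

  best_d <- rep(Inf, nrow(ab$residues))
  best_ag <- rep(NA_character_, nrow(ab$residues))
  for (ag in ags) {
    agm <- as.matrix(ag$atoms[, c("x", "y", "z")])
    if (!nrow(agm) || !nrow(abm)) next
    # squared distances via the expansion |a-b|^2 = |a|^2 + |b|^2 - 2 a.b
    d2 <- outer(rowSums(abm^2), rowSums(agm^2), "+") - 2 * abm %*% t(agm)
    dmin_atom <- sqrt(pmax(apply(d2, 1, min), 0))
    dmin_res <- tapply(dmin_atom, ab_key, min)
    idx <- match(names(dmin_res), res_key)
    upd <- dmin_res < best_d[idx]
    best_d[idx[upd]] <- dmin_res[upd]
    best_ag[idx[upd]] <- ag$chain_id
  }

  sel <- which(best_d <= cutoff)
  kn <- rep(NA_integer_, length(sel))
  ki <- rep(NA_character_, length(sel))
  if (!is.null(numbering)) {
    m <- match(sel, numbering$seq_index)
    kn[!is.na(m)] <- numbering$kabat_num[m[!is.na(m)]]
    ki[!is.na(m)] <- numbering$kabat_ins[m[!is.na(m)]]
  }
  out <- data.frame(resno = ab$residues$resno[sel], ins = ab$residues$ins[sel],
                    kabat_num = kn, kabat_ins = ki,
                    min_distance = best_d[sel], antigen_chain = best_ag[sel],
                    stringsAsFactors = FALSE)
  attr(out, "cutoff") <- cutoff
  class(out) <- c("ContactMap", "data.frame")
  out
}

#' Region usage of a contact map
#'
#' @param contacts a `ContactMap` from [contact_residues()].
#' @param scheme region scheme from [kabat_region_scheme()].
#' @return data.frame `region`, `n_contacts`, `fraction` (fractions sum to 1
#'   over contacts with a Kabat assignment). An empty contact map returns a
#'   zero-count table with attribute `empty = TRUE` and a warning.
#' @export
region_usage <- function(contacts, scheme = kabat_region_scheme()) {
  out <- data.frame(region = scheme$region, n_contacts = 0L, fraction = 0,
                    stringsAsFactors = FALSE)
  usable <- contacts[!is.na(contacts$kabat_num), , drop = FALSE]
  if (!nrow(usable)) {
    warning("empty contact map: no region usage to report")
    attr(out, "empty") <- TRUE
    return(out)
  }
  reg <- cut(usable$kabat_num, breaks = c(scheme$start - 0.5,
                                          scheme$end[nrow(scheme)] + 0.5),
             labels = scheme$region)
  tab <- table(reg)
  cnt <- as.integer(tab[match(out$region, names(tab))])
  cnt[is.na(cnt)] <- 0L
  out$n_contacts <- cnt
  out$fraction <- if (sum(cnt) > 0) cnt / sum(cnt) else rep(0, length(cnt))
  attr(out, "empty") <- FALSE
  out
}
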