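# Synthetic VHH library design: four sub-libraries (Upright 6, Upright 12,
# Roll 12, Roll 15) built from humanized framework scaffolds, curated
# CDR1/CDR2 repertoires, and fully randomized CDR3s over a 17-letter
# alphabet (the 20 amino acids minus Cys, Met and Pro, which are excluded to
# avoid unwanted disulfides and chemical liabilities). CDR3 randomization
# models equimolar trimer-phosphoramidite synthesis: letters are drawn iid
# uniformly per position.

#' The 17-letter CDR3 alphabet (no Cys, Met, Pro)
#' @return character vector of 17 one-letter codes.
#' @export
cdr3_alphabet17 <- function() setdiff(AA20, c("C", "M", "P"))

# Shipped framework scaffolds: synthetic DP-47 / IGHV3-23*01-flavoured
# placeholders trimmed to the package's fixed Kabat framework lengths
# (FR1 25, FR2 14, FR3 29, FR4 11). They are NOT the frameworks of any
# published library. The two FR2 variants differ at the hallmark tetrad
# H37/H44/H45/H47: camelid-like (F/E/R/F) for Upright, VH-like (V/G/L/W)
# for Roll.
default_scaffolds <- function() {
  fr1 <- "EVQLLESGGGLVQPGGSLRLSCAAS"
  fr3 <- "RFTISRDNSKNTLYLQMNSLRAEDTACAR"
  fr4 <- "WGQGTLVTVSS"
  list(
    Upright = c(FR1 = fr1, FR2 = "WFRQAPGKEREFVS", FR3 = fr3, FR4 = fr4),
    Roll    = c(FR1 = fr1, FR2 = "WVRQAPGKGLEWVS", FR3 = fr3, FR4 = fr4))
}

#' Sub-library specification
#'
#' @param name one of "Upright6", "Upright12", "Roll12", "Roll15" (other
#'   names are allowed for custom designs).
#' @param type structural type, "Upright" or "Roll".
#' @param fr named character vector FR1..FR4 of framework scaffolds.
#' @param cdr1,cdr2 character vectors: the validated CDR repertoires.
#'   Upright sub-libraries require every CDR2 of length 16, Roll of 17.
#' @param cdr3_length randomized CDR3 length (at most 15 residues; longer
#'   CDR3s favour loop-stabilizing extra cysteines, which are excluded from
#'   the design).
#' @param cdr3_alphabet amino-acid set for CDR3 randomization; must exclude
#'   C, M and P.
#' @return a validated `SubLibrarySpec`.
#' @export
sublibrary_spec <- function(name, type = c("Upright", "Roll"), fr,
                            cdr1, cdr2, cdr3_length,
                            cdr3_alphabet = cdr3_alphabet17()) {
  type <- match.arg(type)
  if (!all(c("FR1", "FR2", "FR3", "FR4") %in% names(fr)))
    vhh_error("vhh_validation_error", "fr must name FR1..FR4")
  if (!length(cdr1) || !length(cdr2))
    vhh_error("vhh_validation_error", "empty CDR repertoire")
  want <- if (type == "Upright") 16L else 17L
  bad <- which(nchar(cdr2) != want)
  if (length(bad))
    vhh_error("vhh_validation_error",
              sprintf("%s sub-library requires CDR2 length %d; offending sequence: %s",
                      type, want, cdr2[bad[1]]))
  if (any(c("C", "M", "P") %in% cdr3_alphabet))
    vhh_error("vhh_validation_error",
              "cdr3_alphabet must exclude C, M and P")
  if (!all(cdr3_alphabet %in% AA20))
    vhh_error("vhh_validation_error", "cdr3_alphabet outside amino alphabet")
  if (cdr3_length < 1 || cdr3_length > 15)
    vhh_error("vhh_validation_error", "cdr3_length must be in 1..15")
  structure(list(name = name, type = type, fr = fr,
                 cdr1 = unname(cdr1), cdr2 = unname(cdr2),
                 cdr3_length = as.integer(cdr3_length),
                 cdr3_alphabet = cdr3_alphabet),
            class = "SubLibrarySpec")
}

# Default DNA cassette elements (synthetic but functional layouts): T7
# promoter + Shine-Dalgarno 5'UTR, His6 tag, and a 3'UTR linker
# hybridization region for display-linker annealing.
default_cassette <- function() {
  list(utr5 = "TAATACGACTCACTATAGGGTTAACTTTAAGAAGGAGATATACAT",
       his_tag = "GGCGGAGGCAGCCATCACCATCACCATCAC",
       utr3 = "GGAAGCGGTTCTGGTTCTGGCAGCAAAAAA")
}

#' Default single-codon-per-amino-acid table
#'
#' One codon per residue, mirroring trimer-phosphoramidite synthesis, using
#' common expression-host-preferred codons. Fully overridable.
#' @return named character vector (names = one-letter amino acids).
#' @export
default_codon_table <- function() {
  c(A = "GCG", C = "TGC", D = "GAT", E = "GAA", F = "TTT", G = "GGC",
    H = "CAT", I = "ATT", K = "AAA", L = "CTG", M = "ATG", N = "AAC",
    P = "CCG", Q = "CAG", R = "CGT", S = "AGC", T = "ACC", V = "GTG",
    W = "TGG", Y = "TAT")
}

#' Validate a codon table against the standard genetic code
#' @param table named character vector of codons.
#' @return the table, invisibly; errors on stop codons or mistranslations.
#' @export
validate_codon_table <- function(table) {
  if (is.null(names(table)) || any(!names(table) %in% AA20))
    vhh_error("vhh_validation_error", "codon table names must be amino acids")
  if (any(nchar(table) != 3) || any(grepl("[^ACGT]", table)))
    vhh_error("vhh_validation_error", "codons must be 3-letter ACGT strings")
  gc <- Biostrings::GENETIC_CODE
  tr <- unname(gc[table])
  if (any(tr == "*"))
    vhh_error("vhh_validation_error",
              sprintf("stop codon assigned: %s", table[tr == "*"][1]))
  wrong <- tr != names(table)
  if (any(wrong))
    vhh_error("vhh_validation_error",
              sprintf("codon %s translates to %s, not %s",
                      table[wrong][1], tr[wrong][1], names(table)[wrong][1]))
  invisible(table)
}

default_enzymes <- function() c(BsmBI = "CGTCTC", BtgZI = "GCGATG")

#' Build a validated library design
#'
#' @param config list (or path to a YAML file) with elements:
#'   `scaffolds` (list `Upright`/`Roll`, each FR1..FR4), `cdr1` (character
#'   vector or FASTA path), `cdr2_upright`, `cdr2_roll` (likewise),
#'   `cdr3_lengths` (named list per sub-library), optional `cdr3_alphabet`,
#'   `cassette`, `codon_table`, `enzymes`. Missing parts fall back to the
#'   shipped defaults. `config = NULL` with `repertoires` supplied builds
#'   the default four-sub-library design.
#' @param repertoires optional list `cdr1`, `cdr2_upright`, `cdr2_roll`
#'   taking precedence over `config` (e.g. output of [make_repertoires()]).
#' @return a `LibraryDesign` with four validated sub-libraries.
#' @export
build_design <- function(config = NULL, repertoires = NULL) {
  if (is.character(config) && length(config) == 1)
    config <- yaml::read_yaml(config)
  config <- config %||% list()
  as_seqs <- function(x) {
    if (is.null(x)) return(NULL)
    if (length(x) == 1 && is.character(x) && file.exists(x))
      return(read_fasta_seqs(x))
    as.character(x)
  }
  scaff <- config$scaffolds %||% default_scaffolds()
  scaff <- lapply(scaff, function(s) unlist(s))
  cdr1 <- as_seqs(repertoires$cdr1 %||% config$cdr1)
  cdr2u <- as_seqs(repertoires$cdr2_upright %||% config$cdr2_upright)
  cdr2r <- as_seqs(repertoires$cdr2_roll %||% config$cdr2_roll)
  if (is.null(cdr1) || is.null(cdr2u) || is.null(cdr2r))
    vhh_error("vhh_validation_error",
              "design needs cdr1, cdr2_upright and cdr2_roll repertoires")
  alpha <- config$cdr3_alphabet %||% cdr3_alphabet17()
  lengths <- config$cdr3_lengths %||%
    list(Upright6 = 6, Upright12 = 12, Roll12 = 12, Roll15 = 15)
  subs <- lapply(names(lengths), function(nm) {
    type <- if (grepl("^Upright", nm)) "Upright" else "Roll"
    sublibrary_spec(nm, type, scaff[[type]], cdr1,
                    if (type == "Upright") cdr2u else cdr2r,
                    lengths[[nm]], alpha)
  })
  names(subs) <- names(lengths)
  ct <- unlist(config$codon_table %||% default_codon_table())
  validate_codon_table(ct)
  structure(list(sublibraries = subs,
                 cassette = config$cassette %||% default_cassette(),
                 codon_table = ct,
                 enzymes = unlist(config$enzymes %||% default_enzymes())),
            class = "LibraryDesign")
}

#' The default four-sub-library design with seeded synthetic repertoires
#'
#' Repertoire sizes follow the design of the four-sub-library VHH library:
#' 150 CDR1 sequences; 71 CDR2 sequences of 16 residues (Upright) and 69 of
#' 17 residues (Roll); CDR3 lengths 6/12 (Upright) and 12/15 (Roll) over the
#' 17-letter alphabet.
#'
#' @param seed seed for the synthetic repertoires (fixed default so the
#'   default design is reproducible).
#' @return a `LibraryDesign`.
#' @export
default_design <- function(seed = 101) {
  rep <- make_repertoires(cdr1_n = 150, cdr2_n = 71, cdr2_len = 16,
                          seed = seed,
                          alphabet = setdiff(AA20, c("C", "W")))
  rep_roll <- make_repertoires(cdr1_n = 1, cdr2_n = 69, cdr2_len = 17,
                               seed = seed + 1,
                               alphabet = setdiff(AA20, c("C", "W")))
  build_design(repertoires = list(cdr1 = rep$cdr1, cdr2_upright = rep$cdr2,
                                  cdr2_roll = rep_roll$cdr2))
}

#' Exact theoretical diversity of a design
#'
#' Per sub-library |CDR1| x |CDR2| x |alphabet|^L, in exact integer
#' arithmetic, plus the pooled total.
#'
#' @param design a `LibraryDesign`.
#' @return a `DiversityReport`: data.frame `per` (`name`, `diversity`
#'   exact-decimal string, `diversity_num` double approximation) and fields
#'   `total` / `total_num`.
#' @export
diversity <- function(design) {
  per <- lapply(design$sublibraries, function(s) {
    b <- big_mul(big_mul(big_from_num(length(s$cdr1)),
                         big_from_num(length(s$cdr2))),
                 big_pow(length(s$cdr3_alphabet), s$cdr3_length))
    list(name = s$name, big = b)
  })
  total <- Reduce(big_add, lapply(per, `[[`, "big"))
  report <- data.frame(
    name = vapply(per, `[[`, character(1), "name"),
    diversity = vapply(per, function(p) format(p$big), character(1)),
    diversity_num = vapply(per, function(p) big_as_num(p$big), numeric(1)),
    stringsAsFactors = FALSE)
  structure(list(per = report, total = format(total),
                 total_num = big_as_num(total)),
            class = "DiversityReport")
}

#' @export
print.DiversityReport <- function(x, ...) {
  print(x$per, row.names = FALSE)
  cat(sprintf("pooled total: %s (~%.3g)\n", x$total, x$total_num))
  invisible(x)
}

#' Sample full-length VHH protein sequences from a sub-library
#'
#' CDR1/CDR2 are drawn uniformly from the repertoires and CDR3 letters iid
#' uniformly from the 17-letter alphabet (equimolar trimer mixing).
#' Deterministic for a fixed seed.
#'
#' @param design a `LibraryDesign`.
#' @param sublib_name sub-library name.
#' @param n number of sequences.
#' @param seed RNG seed.
#' @return data.frame: `sequence`, `sublibrary`, `cdr1_index`, `cdr2_index`,
#'   `cdr3`.
#' @export
sample_protein <- function(design, sublib_name, n, seed) {
  s <- design$sublibraries[[sublib_name]]
  if (is.null(s))
    vhh_error("vhh_lookup_error",
              sprintf("unknown sub-library: %s", sublib_name))
  stopifnot(n >= 1)
  withr::with_seed(seed, {
    i1 <- sample.int(length(s$cdr1), n, replace = TRUE)
    i2 <- sample.int(length(s$cdr2), n, replace = TRUE)
    letters_mat <- matrix(sample(s$cdr3_alphabet, n * s$cdr3_length,
                                 replace = TRUE), nrow = n)
    cdr3 <- apply(letters_mat, 1, paste, collapse = "")
  })
  data.frame(
    sequence = paste0(s$fr["FR1"], s$cdr1[i1], s$fr["FR2"], s$cdr2[i2],
                      s$fr["FR3"], cdr3, s$fr["FR4"]),
    sublibrary = s$name, cdr1_index = i1, cdr2_index = i2, cdr3 = cdr3,
    stringsAsFactors = FALSE)
}

#' Reverse-translate a protein with a one-codon-per-residue table
#'
#' @param protein one-letter amino acid string.
#' @param codon_table named codon vector (validated).
#' @return DNA string of length `3 * nchar(protein)`.
#' @export
reverse_translate <- function(protein, codon_table = default_codon_table()) {
  aa <- strsplit(toupper(protein), "")[[1]]
  missing <- setdiff(unique(aa), names(codon_table))
  if (length(missing))
    vhh_error("vhh_coding_error",
              sprintf("residues missing from codon table: %s",
                      paste(missing, collapse = ", ")))
  paste(codon_table[aa], collapse = "")
}

#' Assemble the display cassette around a VHH gene
#'
#' Concatenates 5'UTR (T7 promoter + Shine-Dalgarno), the VHH coding
#' sequence, the His-tag region and the 3'UTR linker-hybridization region,
#' reporting 0-based half-open element coordinates.
#'
#' @param vhh_dna VHH coding sequence (DNA).
#' @param design a `LibraryDesign` (supplies the cassette elements).
#' @return list: `sequence`, `elements` data.frame (`element`, `start`,
#'   `end`).
#' @export
assemble_cassette <- function(vhh_dna, design) {
  cas <- design$cassette
  parts <- list(utr5 = cas$utr5, vhh = vhh_dna, his_tag = cas$his_tag,
                utr3 = cas$utr3)
  for (nm in names(parts))
    if (is.null(parts[[nm]]) || !nzchar(parts[[nm]]))
      vhh_error("vhh_assembly_error",
                sprintf("cassette element '%s' missing or empty", nm))
  lens <- vapply(parts, nchar, integer(1))
  ends <- cumsum(lens)
  list(sequence = paste(unlist(parts), collapse = ""),
       elements = data.frame(element = names(parts),
                             start = c(0L, ends[-length(ends)]),
                             end = ends, row.names = NULL,
                             stringsAsFactors = FALSE))
}

#' Restriction-site audit over both strands
#'
#' Reports every exact match of each recognition sequence on the forward
#' strand and (as the reverse-complement pattern found on the forward
#' strand) on the reverse strand, with 0-based forward-strand offsets, and
#' flags sites falling inside a coding region.
#'
#' @param dna DNA string.
#' @param enzymes named character vector of recognition sequences.
#' @param coding_region optional c(start, end), 0-based half-open, for the
#'   in-coding flag.
#' @return data.frame: `enzyme`, `strand` ("+"/"-"), `offset` (0-based
#'   start of the matched pattern on the forward strand), `in_coding`.
#' @export
restriction_audit <- function(dna, enzymes = default_enzymes(),
                              coding_region = NULL) {
  if (any(!nzchar(enzymes)))
    vhh_error("vhh_config_error", "empty recognition sequence configured")
  subj <- Biostrings::DNAString(dna)
  rows <- list()
  for (nm in names(enzymes)) {
    pat <- Biostrings::DNAString(enzymes[[nm]])
    for (strand in c("+", "-")) {
      p <- if (strand == "+") pat else Biostrings::reverseComplement(pat)
      hits <- Biostrings::matchPattern(p, subj)
      st <- Biostrings::start(hits) - 1L
      if (length(st))
        rows[[length(rows) + 1]] <-
          data.frame(enzyme = nm, strand = strand, offset = st,
                     stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(enzyme = character(0), strand = character(0),
                  offset = integer(0), stringsAsFactors = FALSE)
  out$in_coding <- if (!is.null(coding_region) && nrow(out))
    out$offset < coding_region[2] &
      (out$offset + nchar(enzymes[out$enzyme])) > coding_region[1]
  else rep(FALSE, nrow(out))
  out[order(out$enzyme, out$strand, out$offset), , drop = FALSE]
}

#' Composition QC of randomized CDR3s
#'
#' Per-position amino-acid frequencies against the equimolar design:
#' total-variation distance from uniform(1/|alphabet|) and a chi-square
#' statistic (|alphabet| - 1 degrees of freedom) per position.
#'
#' @param cdr3s character vector of CDR3 sequences (all the designed
#'   length), or a positions x letters count matrix.
#' @param alphabet design alphabet (default the 17-letter set).
#' @param length_expected expected CDR3 length (taken from the data when
#'   NULL). Sequences of the wrong length or with letters outside the
#'   alphabet are counted as violations and excluded from the statistics.
#' @return list: `counts`, `freq` (positions x letters), `tvd` per
#'   position, `chisq` data.frame (`position`, `statistic`, `df`,
#'   `p_value`), `n_used`, `n_excluded`.
#' @export
composition_qc <- function(cdr3s, alphabet = cdr3_alphabet17(),
                           length_expected = NULL) {
  if (is.matrix(cdr3s)) {
    counts <- cdr3s
    if (is.null(colnames(counts))) colnames(counts) <- alphabet
    counts <- counts[, alphabet, drop = FALSE]
    n_used <- NA_integer_; n_excluded <- NA_integer_
  } else {
    if (!length(cdr3s))
      vhh_error("vhh_empty_input", "no CDR3 sequences supplied")
    L <- length_expected %||% as.integer(names(sort(table(nchar(cdr3s)),
                                                    decreasing = TRUE))[1])
    ok_len <- nchar(cdr3s) == L
    pat <- sprintf("^[%s]*$", paste(alphabet, collapse = ""))
    ok_alpha <- grepl(pat, cdr3s)
    keep <- ok_len & ok_alpha
    n_used <- sum(keep); n_excluded <- sum(!keep)
    if (!n_used)
      vhh_error("vhh_empty_input", "no valid CDR3 sequences after exclusion")
    m <- do.call(rbind, strsplit(cdr3s[keep], ""))
    counts <- t(apply(m, 2, function(col)
      table(factor(col, levels = alphabet))))
  }
  k <- length(alphabet)
  tot <- rowSums(counts)
  freq <- sweep(counts, 1, tot, "/")
  tvd <- apply(freq, 1, function(f) 0.5 * sum(abs(f - 1 / k)))
  chisq <- t(vapply(seq_len(nrow(counts)), function(i) {
    e <- tot[i] / k
    stat <- sum((counts[i, ] - e)^2 / e)
    c(stat, k - 1, stats::pchisq(stat, k - 1, lower.tail = FALSE))
  }, numeric(3)))
  list(counts = counts, freq = freq, tvd = unname(tvd),
       chisq = data.frame(position = seq_len(nrow(counts)),
                          statistic = chisq[, 1], df = chisq[, 2],
                          p_value = chisq[, 3]),
       n_used = n_used, n_excluded = n_excluded)
}

# FASTA helpers (Biostrings-backed)
read_fasta_seqs <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

write_fasta_seqs <- function(seqs, path, dna = FALSE) {
  x <- if (dna) Biostrings::DNAStringSet(seqs) else
    Biostrings::AAStringSet(seqs)
  if (is.null(names(x))) names(x) <- sprintf("seq%05d", seq_along(x))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
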