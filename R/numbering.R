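# Kabat numbering of VH/VHH domains.
#
# The numberer anchors on four motifs that are essentially invariant across
# heavy-chain variable domains: the first framework cysteine (H22), the
# tryptophan opening FR2 (H36), the second framework cysteine (H92), and the
# FR4 W-G-x-G motif (H103). Framework lengths between anchors are fixed
# (FR1 25, FR2 14, FR3 29, FR4 11 positions); CDR length variation is
# absorbed by Kabat insertion codes (35A..., 52A..., 100A...) or by
# truncation for short loops. An external numbering table (e.g. ANARCI
# output) can be applied verbatim via apply_external_numbering() when exact
# parity with another numberer is required.

INS_ORDER <- c("", LETTERS)

kabat_key <- function(num, ins) num * 100 + match(ins, INS_ORDER) - 1

#' The seven-region Kabat-based scheme
#'
#' FR1 H1-H25, CDR1 H26-H35 (the Kabat/Chothia union), FR2 H36-H49,
#' CDR2 H50-H65, FR3 H66-H94, CDR3 H95-H102, FR4 H103-H113. A pure-Kabat
#' CDR1 (H31-H35) variant is available with `cdr1 = "kabat"`.
#'
#' @param cdr1 "union" (default) or "kabat".
#' @return data.frame with columns `region`, `start`, `end`.
#' @export
kabat_region_scheme <- function(cdr1 = c("union", "kabat")) {
  cdr1 <- match.arg(cdr1)
  c1 <- if (cdr1 == "union") 26L else 31L
  df <- data.frame(
    region = c("FR1", "CDR1", "FR2", "CDR2", "FR3", "CDR3", "FR4"),
    start = c(1L, c1, 36L, 50L, 66L, 95L, 103L),
    end = c(c1 - 1L, 35L, 49L, 65L, 94L, 102L, 113L),
    stringsAsFactors = FALSE)
  class(df) <- c("RegionScheme", "data.frame")
  df
}

new_domain_numbering <- function(seq_index, kabat_num, kabat_ins, sequence) {
  df <- data.frame(seq_index = as.integer(seq_index),
                   kabat_num = as.integer(kabat_num),
                   kabat_ins = kabat_ins, stringsAsFactors = FALSE)
  keys <- kabat_key(df$kabat_num, df$kabat_ins)
  if (any(is.na(keys)))
    vhh_error("vhh_validation_error", "invalid insertion code in numbering")
  if (any(diff(keys) <= 0))
    vhh_error("vhh_validation_error",
              "Kabat positions must be strictly increasing")
  if (any(diff(df$seq_index) != 1))
    vhh_error("vhh_validation_error",
              "numbering must cover a contiguous subsequence")
  bad <- df$kabat_ins != "" & df$kabat_num >= 95 & df$kabat_num <= 102 &
    df$kabat_num != 100
  if (any(bad))
    vhh_error("vhh_validation_error",
              "CDR3 insertion codes must attach to position 100")
  attr(df, "sequence") <- sequence
  attr(df, "domain_start") <- df$seq_index[1]
  attr(df, "domain_end") <- df$seq_index[nrow(df)]
  class(df) <- c("DomainNumbering", "data.frame")
  df
}

numbering_failure <- function(anchor, msg) {
  stop(structure(
    class = c("vhh_numbering_failure", "vhh_error", "error", "condition"),
    list(message = sprintf("Kabat numbering failed at anchor %s: %s",
                           anchor, msg),
         anchor = anchor, call = sys.call(-1))))
}

# Kabat position labels for one region of observed length L.
# Baseline span start..end; insertions lettered at insert_at; short loops
# truncate, with CDR3 keeping its final `keep_tail` positions (H101/H102).
region_positions <- function(L, start, end, insert_at, keep_tail = 0) {
  base <- end - start + 1
  if (L >= base) {
    nums <- c(start:insert_at, rep(insert_at, L - base),
              if (insert_at < end) (insert_at + 1):end)
    ins <- c(rep("", insert_at - start + 1), LETTERS[seq_len(L - base)],
             rep("", end - insert_at))
    if (L - base > 26)
      vhh_error("vhh_validation_error", "loop too long for insertion codes")
  } else if (keep_tail > 0 && L > keep_tail) {
    head_n <- L - keep_tail
    nums <- c(start:(start + head_n - 1), (end - keep_tail + 1):end)
    ins <- rep("", L)
  } else {
    nums <- start:(start + L - 1)
    ins <- rep("", L)
  }
  list(num = nums, ins = ins)
}

#' Assign Kabat numbering to a VH/VHH domain sequence
#'
#' @param sequence one-letter amino acid string, 90-160 residues.
#' @return a `DomainNumbering`: data.frame of (`seq_index`, `kabat_num`,
#'   `kabat_ins`) with the input sequence attached as an attribute.
#' @export
assign_kabat <- function(sequence) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 90 || n > 160)
    vhh_error("vhh_validation_error",
              sprintf("sequence length %d outside [90, 160]", n))
  s <- strsplit(sequence, "")[[1]]

  i22 <- which(s == "C")[1]
  if (is.na(i22)) numbering_failure("H22", "no framework cysteine found")
  w <- which(s == "W")
  i36 <- w[w >= i22 + 4][1]
  if (is.na(i36)) numbering_failure("H36", "no FR2 tryptophan after CDR1")
  cdr1_len <- i36 - i22 - 4
  if (cdr1_len < 1) numbering_failure("H36", "CDR1 region empty")
  i50 <- i36 + 14

  m <- gregexpr("WG.G", sequence)[[1]]
  m <- m[m >= i36 + 20]
  if (!length(m) || m[1] == -1)
    numbering_failure("H103", "no FR4 W-G-x-G motif found")
  i103 <- m[length(m)]

  cc <- which(s == "C")
  i92 <- cc[cc >= i50 & cc <= i103 - 4][1]
  if (is.na(i92)) numbering_failure("H92", "no second framework cysteine")
  cdr2_len <- i92 - i50 - 26
  if (cdr2_len < 1)
    numbering_failure("H92", "FR3 too short between CDR2 and cysteine")
  cdr3_len <- i103 - i92 - 3
  if (cdr3_len < 1) numbering_failure("H103", "CDR3 region empty")

  start1 <- max(1L, i22 - 21L)
  fr1_nums <- (22 - (i22 - start1)):25
  cdr1 <- region_positions(cdr1_len, 26, 35, 35)
  cdr2 <- region_positions(cdr2_len, 50, 65, 52)
  cdr3 <- region_positions(cdr3_len, 95, 102, 100, keep_tail = 2)
  end4 <- min(n, i103 + 10L)
  fr4_nums <- 103:(103 + (end4 - i103))

  nums <- c(fr1_nums, cdr1$num, 36:49, cdr2$num, 66:94, cdr3$num, fr4_nums)
  ins <- c(rep("", length(fr1_nums)), cdr1$ins, rep("", 14), cdr2$ins,
           rep("", 29), cdr3$ins, rep("", length(fr4_nums)))
  idx <- start1:end4
  stopifnot(length(idx) == length(nums))
  new_domain_numbering(idx, nums, ins, sequence)
}

#' Apply an external (e.g. ANARCI-derived) numbering table
#'
#' @param sequence one-letter amino acid string.
#' @param table a data.frame with columns `seq_index` (0-based),
#'   `kabat_number`, `insertion_code` (NA or "" for none), or a path to a
#'   CSV file with those columns.
#' @return a `DomainNumbering`.
#' @export
apply_external_numbering <- function(sequence, table) {
  if (is.character(table) && length(table) == 1)
    table <- utils::read.csv(table, stringsAsFactors = FALSE,
                             colClasses = c(insertion_code = "character"))
  need <- c("seq_index", "kabat_number", "insertion_code")
  if (!all(need %in% names(table)))
    vhh_error("vhh_validation_error",
              sprintf("numbering table must have columns: %s",
                      paste(need, collapse = ", ")))
  idx <- as.integer(table$seq_index) + 1L
  if (any(idx < 1) || any(idx > nchar(sequence)))
    vhh_error("vhh_validation_error",
              "table seq_index outside sequence bounds")
  ins <- table$insertion_code
  ins[is.na(ins)] <- ""
  new_domain_numbering(idx, table$kabat_number, toupper(trimws(ins)),
                       toupper(sequence))
}

#' Parse one row of ANARCI wide-format CSV output into a numbering table
#'
#' ANARCI's CSV output is wide: metadata columns followed by one column per
#' numbered position ("1", "2", ..., "100A", ...) holding the residue letter
#' or "-" for a gap.
#'
#' @param path CSV file path.
#' @param row row number to parse (default 1).
#' @return data.frame with `seq_index` (0-based), `kabat_number`,
#'   `insertion_code`, suitable for [apply_external_numbering()].
#' @export
read_anarci_csv <- function(path, row = 1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  pos_cols <- grep("^[0-9]+[A-Z]?$", names(df), value = TRUE)
  if (!length(pos_cols))
    vhh_error("vhh_format_error", "no position columns found in ANARCI CSV")
  start0 <- if ("seqstart_index" %in% names(df))
    as.integer(df$seqstart_index[row]) else 0L
  vals <- as.character(df[row, pos_cols])
  keep <- !is.na(vals) & vals != "-" & vals != ""
  nums <- as.integer(sub("[A-Z]$", "", pos_cols[keep]))
  ins <- sub("^[0-9]+", "", pos_cols[keep])
  data.frame(seq_index = start0 + seq_len(sum(keep)) - 1L,
             kabat_number = nums, insertion_code = ins,
             stringsAsFactors = FALSE)
}

#' Extract region slices from a numbered domain
#'
#' @param numbering a `DomainNumbering` (carries its sequence).
#' @param scheme a region scheme from [kabat_region_scheme()].
#' @return data.frame with one row per region: `region`, `kabat_start`,
#'   `kabat_end`, `length`, `sequence`. CDR3 length counts insertion-coded
#'   residues.
#' @export
extract_regions <- function(numbering, scheme = kabat_region_scheme()) {
  seq <- attr(numbering, "sequence")
  if (is.null(seq))
    vhh_error("vhh_validation_error", "numbering carries no sequence")
  letters1 <- strsplit(seq, "")[[1]]
  out <- lapply(seq_len(nrow(scheme)), function(i) {
    rows <- numbering$kabat_num >= scheme$start[i] &
      numbering$kabat_num <= scheme$end[i]
    if (!any(rows))
      vhh_error("vhh_missing_region",
                sprintf("region %s (H%d-H%d) absent from numbering",
                        scheme$region[i], scheme$start[i], scheme$end[i]))
    data.frame(region = scheme$region[i],
               kabat_start = scheme$start[i], kabat_end = scheme$end[i],
               length = sum(rows),
               sequence = paste(letters1[numbering$seq_index[rows]],
                                collapse = ""),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# Kabat label like "H100A" for (num, ins) pairs.
kabat_label <- function(num, ins = "") paste0("H", num, ins)
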