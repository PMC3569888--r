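# Fixture builders used across the suite. DSSP text is composed here with
# an sprintf layout written independently of the package's emitter, so the
# parser's column positions are cross-checked, not just round-tripped.

# one residue line of classic DSSP (columns: see format docs in the package)
fixture_residue_line <- function(idx, resnum, chain, aa, ss,
                                 lad1 = " ", bp1 = 0L, bp2 = 0L,
                                 sheet = " ") {
  sprintf("%5d%5d %1s %1s  %1s      %1s %4d%4d%1s%4d",
          idx, resnum, chain, aa, ss, lad1, bp1, bp2, sheet, 0L)
}

fixture_break_line <- function(idx) {
  sprintf("%5d        %1s", idx, "!")
}

fixture_header <- function() {
  c("==== SECONDARY STRUCTURE DEFINITION TEST FIXTURE ====",
    paste0("  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N",
           "    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI"))
}

# DSSP text for one or more chains given per-residue field vectors; a break
# line (consuming one index) is inserted wherever `brk` is TRUE
fixture_dssp_text <- function(chain, ss, aa = NULL, bp1 = NULL, bp2 = NULL,
                              lad1 = NULL, sheet = NULL, brk = NULL) {
  n <- length(ss)
  if (is.null(aa)) aa <- rep("A", n)
  if (is.null(bp1)) bp1 <- integer(n)
  if (is.null(bp2)) bp2 <- integer(n)
  if (is.null(lad1)) lad1 <- rep(" ", n)
  if (is.null(sheet)) sheet <- rep(" ", n)
  if (is.null(brk)) brk <- rep(FALSE, n)   # break *before* residue i
  # emitted dssp index of residue position i (break lines consume indices)
  pos_of <- cumsum(1L + brk)
  # bp fields refer to residue positions 1..n; remap to emitted dssp indices
  idx <- 0L
  out <- character()
  for (i in seq_len(n)) {
    if (brk[i]) {
      idx <- idx + 1L
      out <- c(out, fixture_break_line(idx))
    }
    idx <- idx + 1L
    out <- c(out, fixture_residue_line(
      idx, idx, chain[i], aa[i], ss[i], lad1[i],
      if (bp1[i] > 0L) pos_of[bp1[i]] else 0L,
      if (bp2[i] > 0L) pos_of[bp2[i]] else 0L, sheet[i]))
  }
  paste(c(fixture_header(), out, ""), collapse = "\n")
}

# a ladder of k strands (each `len` residues) wired strand i <-> strand i+1
# antiparallel-style partner slots, as one chain; returns DSSP text
fixture_ladder_text <- function(k, len = 4L, sheet = "A") {
  n_per <- len + 4L
  n <- k * n_per
  ss <- rep(" ", n)
  bp1 <- integer(n)
  bp2 <- integer(n)
  sheet_v <- rep(" ", n)
  start <- function(j) (j - 1L) * n_per + 1L
  for (j in seq_len(k)) {
    ss[start(j):(start(j) + len - 1L)] <- "E"
    sheet_v[start(j):(start(j) + len - 1L)] <- sheet
  }
  for (j in seq_len(k - 1L)) {
    for (r in seq_len(len) - 1L) {
      i1 <- start(j) + r
      i2 <- start(j + 1L) + r
      bp2[i1] <- i2   # partner in next strand
      bp1[i2] <- i1   # partner in previous strand
    }
  }
  fixture_dssp_text(chain = rep("A", n), ss = ss, bp1 = bp1, bp2 = bp2,
                    sheet = sheet_v)
}

# run the geometry pipeline on DSSP text and return the pair table
pairs_from_text <- function(text) {
  chains <- parse_dssp(text)
  pair_table(enumerate_pairs(strand_table(chains), residue_table(chains)))
}

# pipeline pair table for a list of configs / synthetic dataset, pooled over
# the rendered files in configuration order
pairs_from_configs <- function(configs) {
  texts <- render_dssp(configs)
  do.call(rbind, lapply(texts, pairs_from_text))
}

# a bare strand_pair carrying only a bridged map (orientation tests)
fixture_pair_with_map <- function(index1, index2, ladder = " ") {
  structure(list(bridged_map = data.frame(index1 = index1, index2 = index2,
                                          ladder = ladder,
                                          stringsAsFactors = FALSE),
                 SL1 = length(unique(index1)), SL2 = length(unique(index2))),
            class = "strand_pair")
}
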