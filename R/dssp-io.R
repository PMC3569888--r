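# Classic fixed-column DSSP reading/writing.
#
# Column layout of the residue table (1-based, as printed by DSSP):
#   1-5  dssp index        14    amino acid ('!' marks a chain break,
#   6-10 PDB residue no.         '*' in col 15 a chain terminator)
#   11   insertion code    17    secondary-structure state
#   12   chain id          24,25 bridge-ladder letters (lowercase = parallel)
#                          26-29 BP1   30-33 BP2   34 sheet label   35-38 ACC
# Only these columns are interpreted; everything else is padding.

DSSP_TABLE_SENTINEL <- "#  RESIDUE AA STRUCTURE BP1 BP2"

DSSP_HEADER <- c(
  "==== SECONDARY STRUCTURE DEFINITION, CLASSIC DSSP COLUMN LAYOUT ====",
  "REFERENCE SEE PACKAGE DOCUMENTATION (strandpairs)",
  paste0("  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N",
         "    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI",
         "    X-CA   Y-CA   Z-CA"))

# amino-acid one-letter codes DSSP can print for standard residues
STANDARD_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

new_chain_record <- function(chain_id, residues, break_positions = integer()) {
  structure(list(chain_id = chain_id,
                 residues = residues,
                 break_positions = as.integer(break_positions)),
            class = "chain_record")
}

#' @export
print.chain_record <- function(x, ...) {
  cat(sprintf("<chain %s: %d residues, %d break(s), %d 'E' residues>\n",
              x$chain_id, nrow(x$residues), length(x$break_positions),
              sum(x$residues$ss_state == "E")))
  invisible(x)
}

empty_residue_table <- function() {
  data.frame(dssp_index = integer(), chain_id = character(),
             pdb_resnum = integer(), insertion_code = character(),
             amino_acid = character(), ss_state = character(),
             ladder1 = character(), ladder2 = character(),
             bp1 = integer(), bp2 = integer(),
             sheet_label = character(), ss_bonded_cys = logical(),
             stringsAsFactors = FALSE)
}

# integer field parser: blank -> `blank`, non-numeric -> NA (caught by caller)
.dssp_int <- function(s, blank = NA_integer_) {
  s <- trimws(s)
  out <- suppressWarnings(as.integer(s))
  out[s == ""] <- blank
  out
}

#' Parse classic DSSP-format text into chain records
#'
#' Reads the fixed-column residue table of a DSSP file (the dialect with
#' BP1/BP2 bridge-partner and sheet-label columns) and returns one record per
#' chain. Chain-break lines (\code{!} in the amino-acid column) are not
#' residues; their positions are recorded in \code{break_positions} of the
#' enclosing chain. Lowercase amino-acid letters, which DSSP uses for
#' disulfide-bonded cysteines, are normalised to \code{"C"} with the
#' \code{ss_bonded_cys} flag set.
#'
#' @param text DSSP-format text: a single string (possibly containing
#'   newlines) or a character vector of lines.
#' @return A list of chain records. Each record is a list with elements
#'   \code{chain_id}, \code{residues} (a data frame with columns
#'   \code{dssp_index}, \code{chain_id}, \code{pdb_resnum},
#'   \code{insertion_code}, \code{amino_acid}, \code{ss_state},
#'   \code{ladder1}, \code{ladder2}, \code{bp1}, \code{bp2},
#'   \code{sheet_label}, \code{ss_bonded_cys}) and \code{break_positions}
#'   (indices \code{i} such that a chain break falls between residues
#'   \code{i} and \code{i + 1}).
#' @seealso [emit_dssp()] for the inverse operation, [read_dssp()] to read
#'   from a file.
#' @export
#' @examples
#' ch <- parse_dssp(emit_dssp(list()))   # header-only file, zero chains
#' length(ch)
parse_dssp <- function(text) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  hdr <- grep(DSSP_TABLE_SENTINEL, text, fixed = TRUE)
  if (length(hdr) == 0L) {
    stop("not a DSSP file: residue-table header ('", DSSP_TABLE_SENTINEL,
         "') not found", call. = FALSE)
  }
  hdr <- hdr[[1L]]
  lines <- if (hdr < length(text)) text[(hdr + 1L):length(text)] else character()
  keep <- nzchar(trimws(lines))
  lineno <- which(keep) + hdr        # file line numbers, for error messages
  lines <- lines[keep]
  if (length(lines) == 0L) return(structure(list(), names = character()))

  lines <- formatC(lines, width = -38L)  # pad right so substr() is total
  idx    <- .dssp_int(substr(lines, 1L, 5L))
  bad <- which(is.na(idx))
  if (length(bad)) {
    stop("malformed DSSP residue line ", lineno[bad[1L]],
         ": unreadable index field", call. = FALSE)
  }
  if (any(diff(idx) <= 0L)) {
    bad <- which(diff(idx) <= 0L)[1L] + 1L
    stop("malformed DSSP residue table at line ", lineno[bad],
         ": dssp index not strictly increasing", call. = FALSE)
  }
  aa      <- substr(lines, 14L, 14L)
  is_brk  <- aa == "!"
  resnum  <- .dssp_int(substr(lines, 6L, 10L))
  if (any(is.na(resnum) & !is_brk)) {
    bad <- which(is.na(resnum) & !is_brk)[1L]
    stop("malformed DSSP residue line ", lineno[bad],
         ": unreadable residue number", call. = FALSE)
  }
  icode   <- substr(lines, 11L, 11L)
  chain   <- substr(lines, 12L, 12L)
  ss      <- substr(lines, 17L, 17L)
  lad1    <- substr(lines, 24L, 24L)
  lad2    <- substr(lines, 25L, 25L)
  bp1     <- .dssp_int(substr(lines, 26L, 29L), blank = 0L)
  bp2     <- .dssp_int(substr(lines, 30L, 33L), blank = 0L)
  if (any(is.na(bp1) & !is_brk) || any(is.na(bp2) & !is_brk)) {
    bad <- which((is.na(bp1) | is.na(bp2)) & !is_brk)[1L]
    stop("malformed DSSP residue line ", lineno[bad],
         ": unreadable bridge-partner field", call. = FALSE)
  }
  sheet   <- substr(lines, 34L, 34L)

  res_idx <- idx[!is_brk]
  bp_all  <- c(bp1[!is_brk], bp2[!is_brk])
  bad_bp  <- setdiff(unique(bp_all), c(0L, res_idx))
  if (length(bad_bp)) {
    stop("invalid DSSP file: bridge partner index ", bad_bp[1L],
         " does not name a residue line", call. = FALSE)
  }

  lower <- !is_brk & aa %in% letters
  aa[lower] <- "C"

  res <- data.frame(dssp_index = idx, chain_id = chain, pdb_resnum = resnum,
                    insertion_code = icode, amino_acid = aa, ss_state = ss,
                    ladder1 = lad1, ladder2 = lad2, bp1 = bp1, bp2 = bp2,
                    sheet_label = sheet, ss_bonded_cys = lower,
                    stringsAsFactors = FALSE)[!is_brk, , drop = FALSE]
  rownames(res) <- NULL

  chain_ids <- unique(res$chain_id)
  chains <- lapply(chain_ids, function(cid) {
    r <- res[res$chain_id == cid, , drop = FALSE]
    rownames(r) <- NULL
    # a break line whose neighbours are both in this chain splits it
    brk_at <- integer()
    if (any(is_brk)) {
      for (p in which(is_brk)) {
        before <- which(!is_brk[seq_len(p - 1L)] & chain[seq_len(p - 1L)] == cid)
        after_all <- if (p < length(is_brk)) (p + 1L):length(is_brk) else integer()
        after <- after_all[!is_brk[after_all] & chain[after_all] == cid]
        nxt_any <- after_all[!is_brk[after_all]]
        if (length(before) && length(after) &&
            length(nxt_any) && chain[nxt_any[1L]] == cid) {
          brk_at <- c(brk_at, length(before))
        }
      }
    }
    new_chain_record(cid, r, unique(brk_at))
  })
  names(chains) <- chain_ids
  chains
}

#' Read a DSSP file
#'
#' @param path path to a classic-format DSSP file.
#' @return See [parse_dssp()].
#' @export
read_dssp <- function(path) {
  parse_dssp(readLines(path, warn = FALSE))
}

fmt_residue_lines <- function(r) {
  sprintf("%5d%5d%1s%1s %1s  %1s      %1s%1s%4d%4d%1s%4d",
          r$dssp_index, r$pdb_resnum, r$insertion_code, r$chain_id,
          r$amino_acid, r$ss_state, r$ladder1, r$ladder2,
          r$bp1, r$bp2, r$sheet_label, 0L)
}

fmt_break_line <- function(idx, terminator = FALSE) {
  sprintf("%5d     %1s%1s %1s%1s%7s%6s%4d%4d%1s%4d",
          idx, " ", " ", "!", if (terminator) "*" else " ",
          "", "", 0L, 0L, " ", 0L)
}

#' Write chain records as classic DSSP-format text
#'
#' Inverse of [parse_dssp()] for the columns the parser reads: the output
#' round-trips to field-identical residue records. Residues are written with
#' their stored \code{dssp_index}; every index missing from the stored
#' sequence is emitted as a chain-break line (\code{!}, or \code{!*} at a
#' chain boundary), which is how DSSP itself numbers break lines. Recorded
#' intra-chain break positions must therefore leave a gap in the stored
#' indices.
#'
#' @param chains list of chain records as produced by [parse_dssp()] or the
#'   synthetic generator.
#' @return A single string of DSSP-format text.
#' @export
emit_dssp <- function(chains) {
  if (length(chains) == 0L) {
    return(paste(c(DSSP_HEADER, ""), collapse = "\n"))
  }
  res <- do.call(rbind, lapply(chains, `[[`, "residues"))
  rownames(res) <- NULL
  if (any(diff(res$dssp_index) <= 0L)) {
    bad <- res$dssp_index[which(diff(res$dssp_index) <= 0L)[1L] + 1L]
    stop("cannot emit DSSP: dssp_index ", bad,
         " breaks the strictly increasing order", call. = FALSE)
  }
  bad_bp <- setdiff(unique(c(res$bp1, res$bp2)), c(0L, res$dssp_index))
  if (length(bad_bp)) {
    stop("cannot emit DSSP: bridge partner index ", bad_bp[1L],
         " names no residue", call. = FALSE)
  }
  for (ch in chains) {
    for (b in ch$break_positions) {
      if (b < 1L || b >= nrow(ch$residues) ||
          ch$residues$dssp_index[b + 1L] - ch$residues$dssp_index[b] < 2L) {
        stop("cannot emit DSSP: recorded break after position ", b,
             " of chain ", ch$chain_id,
             " leaves no dssp_index gap for the break line", call. = FALSE)
      }
    }
  }
  # chain id owning each residue row, to place '!*' at chain boundaries
  first_of_chain <- c(TRUE, res$chain_id[-1L] != res$chain_id[-nrow(res)])
  lines <- character()
  prev_idx <- res$dssp_index[1L] - 1L
  body <- fmt_residue_lines(res)
  out <- vector("list", nrow(res))
  for (i in seq_len(nrow(res))) {
    gap <- setdiff(seq(prev_idx + 1L, res$dssp_index[i]), res$dssp_index[i])
    brks <- if (length(gap)) {
      fmt_break_line(gap, terminator = first_of_chain[i] && i > 1L)
    } else character()
    out[[i]] <- c(brks, body[i])
    prev_idx <- res$dssp_index[i]
  }
  paste(c(DSSP_HEADER, unlist(out), ""), collapse = "\n")
}

#' Write chain records to a DSSP file
#'
#' @param chains list of chain records.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_dssp <- function(chains, path) {
  writeLines(sub("\n$", "", emit_dssp(chains)), path)
  invisible(path)
}

#' Chain-level dataset filters
#'
#' Policy object for [filter_chains()]. The defaults mirror the survey
#' preprocessing this package reproduces: chains without any extended-sheet
#' residue are dropped, as are chains carrying nonstandard residues
#' (amino-acid letter \code{"X"}, which DSSP prints for residues it cannot
#' map to a standard one-letter code).
#'
#' @param require_beta drop chains with no \code{'E'} residue.
#' @param reject_nonstandard drop chains containing an \code{'X'} residue.
#' @return A \code{filter_policy} list.
#' @export
filter_policy <- function(require_beta = TRUE, reject_nonstandard = TRUE) {
  structure(list(require_beta = isTRUE(require_beta),
                 reject_nonstandard = isTRUE(reject_nonstandard)),
            class = "filter_policy")
}

#' Apply chain-level filters
#'
#' Disulfide-bonded cysteines (lowercase letters in the DSSP file) are
#' standard residues and never trigger the nonstandard-residue filter; only
#' \code{"X"} does. Every removal is logged with the criterion that caused
#' it. Filtering is idempotent and never drops residues silently: a chain is
#' either retained whole or rejected whole.
#'
#' @param chains list of chain records from [parse_dssp()].
#' @param policy a [filter_policy()].
#' @return list with elements \code{retained} (chain records) and
#'   \code{rejections} (data frame with columns \code{chain_id},
#'   \code{reason}; reasons are \code{"no-beta-sheet"} and
#'   \code{"nonstandard-residue"}).
#' @export
filter_chains <- function(chains, policy = filter_policy()) {
  stopifnot(inherits(policy, "filter_policy"))
  reasons <- vapply(chains, function(ch) {
    if (policy$require_beta && !any(ch$residues$ss_state == "E")) {
      return("no-beta-sheet")
    }
    if (policy$reject_nonstandard && any(ch$residues$amino_acid == "X")) {
      return("nonstandard-residue")
    }
    NA_character_
  }, character(1))
  rej <- data.frame(chain_id = vapply(chains, `[[`, character(1), "chain_id"),
                    reason = reasons, stringsAsFactors = FALSE)
  rej <- rej[!is.na(rej$reason), , drop = FALSE]
  rownames(rej) <- NULL
  list(retained = chains[is.na(reasons)], rejections = rej)
}

#' Combined residue table of several chains
#'
#' @param chains list of chain records.
#' @return One data frame of residue records in file order.
#' @export
residue_table <- function(chains) {
  if (length(chains) == 0L) return(empty_residue_table())
  out <- do.call(rbind, lapply(chains, `[[`, "residues"))
  rownames(out) <- NULL
  out
}
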