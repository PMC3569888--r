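# Strand extraction, pair enumeration via bridge partners, and the
# registration decomposition SL1/SL2 -> PL, Et1, Et2, EL.

#' Extract beta-strands from one chain
#'
#' A strand is a maximal run of residues in the extended state \code{'E'},
#' split at chain breaks and at any discontinuity of the DSSP numbering.
#' Isolated single-residue bridges (state \code{'B'}) are not strands;
#' single-residue \code{'E'} runs are.
#'
#' @param chain a chain record from [parse_dssp()].
#' @return data frame with one row per strand: \code{chain_id},
#'   \code{strand_ordinal} (1-based order along the chain),
#'   \code{sheet_label}, \code{first_index}, \code{last_index} (DSSP
#'   indices), \code{length}.
#' @export
extract_strands <- function(chain) {
  r <- chain$residues
  empty <- data.frame(chain_id = character(), strand_ordinal = integer(),
                      sheet_label = character(), first_index = integer(),
                      last_index = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(r) == 0L) return(empty)
  is_e <- r$ss_state == "E"
  # boundary before row i: break recorded after i-1, or non-consecutive index
  boundary <- c(TRUE, diff(r$dssp_index) != 1L)
  boundary[chain$break_positions + 1L] <- TRUE
  run_start <- is_e & (boundary | !c(FALSE, is_e[-length(is_e)]))
  if (!any(is_e)) return(empty)
  run_id <- cumsum(run_start)
  run_id[!is_e] <- NA_integer_
  starts <- which(run_start)
  ends <- vapply(seq_along(starts), function(k) {
    max(which(!is.na(run_id) & run_id == k))
  }, integer(1))
  sheet <- vapply(seq_along(starts), function(k) {
    sl <- r$sheet_label[starts[k]:ends[k]]
    sl <- sl[sl != " " & sl != ""]
    if (length(sl)) sl[[1L]] else " "
  }, character(1))
  data.frame(chain_id = chain$chain_id,
             strand_ordinal = seq_along(starts),
             sheet_label = sheet,
             first_index = r$dssp_index[starts],
             last_index = r$dssp_index[ends],
             length = r$dssp_index[ends] - r$dssp_index[starts] + 1L,
             stringsAsFactors = FALSE)
}

#' Strand table of several chains
#'
#' Convenience wrapper applying [extract_strands()] to each chain and
#' row-binding the results in file order (which defines the global strand
#' order used to orient pairs).
#'
#' @param chains list of chain records.
#' @return data frame as in [extract_strands()].
#' @export
strand_table <- function(chains) {
  out <- do.call(rbind, lapply(chains, extract_strands))
  if (is.null(out)) out <- extract_strands(new_chain_record("", empty_residue_table()))
  rownames(out) <- NULL
  out
}

# orientation of a bridge ladder from its map; majority vote over the signs
# of partner progression, ladder-letter case as tie-breaker for single rungs
.orientation <- function(bm) {
  bm <- bm[order(bm$index1, bm$index2), , drop = FALSE]
  first_partner <- bm[!duplicated(bm$index1), , drop = FALSE]
  if (nrow(first_partner) >= 2L) {
    d <- sign(diff(first_partner$index2))
    up <- sum(d > 0)
    down <- sum(d < 0)
    list(orientation = if (up >= down) "parallel" else "antiparallel",
         monotonic = (up == 0L || down == 0L) && all(d != 0),
         determinate = TRUE)
  } else {
    lad <- bm$ladder[bm$ladder != " " & bm$ladder != ""]
    if (length(lad) && lad[[1L]] %in% letters) {
      list(orientation = "parallel", monotonic = TRUE, determinate = TRUE)
    } else if (length(lad) && lad[[1L]] %in% LETTERS) {
      list(orientation = "antiparallel", monotonic = TRUE, determinate = TRUE)
    } else {
      # no ladder letter recorded: fall back to the majority class
      list(orientation = "antiparallel", monotonic = TRUE, determinate = FALSE)
    }
  }
}

#' Classify the orientation of a strand pair
#'
#' Parallel if the bridge partner index increases along the first strand,
#' antiparallel if it decreases. Single-rung pairs are decided by the case
#' of the DSSP ladder letter (lowercase = parallel); if none is recorded the
#' pair is classed antiparallel (the majority class) with a warning.
#'
#' @param pair a \code{strand_pair} from [enumerate_pairs()].
#' @return \code{"parallel"} or \code{"antiparallel"}.
#' @export
classify_orientation <- function(pair) {
  stopifnot(inherits(pair, "strand_pair"))
  o <- .orientation(pair$bridged_map)
  if (!o$determinate) {
    warning("single-bridge pair with no ladder letter: orientation ",
            "indeterminate, classed antiparallel", call. = FALSE)
  }
  o$orientation
}

#' Compute the registration decomposition of a strand pair
#'
#' Fills \code{PL} (residues of the common paired part), the terminal
#' extensions \code{Et1 = SL1 - PL} and \code{Et2 = SL2 - PL}, the whole
#' length \code{EL = PL + Et1 + Et2}, and the \code{bulged} flag. A pair is
#' bulged when its bridged residues are non-contiguous in either strand,
#' when the two strands bridge different numbers of residues, or when the
#' partner progression is non-monotonic; for bulged pairs \code{PL} is the
#' smaller of the two bridged-residue counts.
#'
#' @param pair a \code{strand_pair}.
#' @return The pair with registration fields filled.
#' @export
compute_registration <- function(pair) {
  stopifnot(inherits(pair, "strand_pair"))
  bm <- pair$bridged_map
  i1 <- sort(unique(bm$index1))
  i2 <- sort(unique(bm$index2))
  contig <- function(v) length(v) == 1L || all(diff(v) == 1L)
  o <- .orientation(bm)
  bulged <- !contig(i1) || !contig(i2) || length(i1) != length(i2) ||
    !o$monotonic
  pl <- if (bulged) min(length(i1), length(i2)) else length(i1)
  pair$orientation <- o$orientation
  pair$PL <- as.integer(pl)
  pair$Et1 <- pair$SL1 - pair$PL
  pair$Et2 <- pair$SL2 - pair$PL
  pair$EL <- pair$PL + pair$Et1 + pair$Et2
  pair$bulged <- bulged
  pair
}

#' Enumerate adjacent strand pairs from bridge partners
#'
#' Two strands form a pair when at least one residue of one lists a residue
#' of the other as bridge partner (BP1 or BP2). Each unordered pair is
#' reported once, with \code{strand1} the strand appearing earlier along the
#' chain (for cross-chain pairs, earlier in file order). Bridge links that
#' point at a residue outside any strand (e.g. an isolated \code{'B'}
#' bridge) are ignored with a warning. Registration and orientation are
#' computed for every pair.
#'
#' @param strands strand table from [strand_table()] (or one or more
#'   row-bound results of [extract_strands()], in file order).
#' @param residues residue table from [residue_table()] covering the same
#'   chains.
#' @return list of \code{strand_pair} objects; see [pair_table()] for a flat
#'   view.
#' @export
enumerate_pairs <- function(strands, residues) {
  if (nrow(strands) == 0L || nrow(residues) == 0L) return(list())
  max_idx <- max(residues$dssp_index)
  sid_of <- rep(NA_integer_, max_idx)
  for (s in seq_len(nrow(strands))) {
    sid_of[strands$first_index[s]:strands$last_index[s]] <- s
  }
  e <- residues[residues$ss_state == "E", , drop = FALSE]
  links <- rbind(
    data.frame(from = e$dssp_index, to = e$bp1, ladder = e$ladder1,
               stringsAsFactors = FALSE)[e$bp1 > 0L, , drop = FALSE],
    data.frame(from = e$dssp_index, to = e$bp2, ladder = e$ladder2,
               stringsAsFactors = FALSE)[e$bp2 > 0L, , drop = FALSE])
  if (nrow(links) == 0L) return(list())
  links$from_sid <- sid_of[links$from]
  links$to_sid <- ifelse(links$to <= max_idx, sid_of[links$to], NA_integer_)
  dangling <- is.na(links$to_sid) | residues$ss_state[
    match(links$to, residues$dssp_index)] != "E"
  if (any(dangling)) {
    warning(sum(dangling), " bridge link(s) to residues outside any strand ",
            "ignored", call. = FALSE)
    links <- links[!dangling, , drop = FALSE]
  }
  links <- links[!is.na(links$from_sid) & links$from_sid != links$to_sid, ,
                 drop = FALSE]
  if (nrow(links) == 0L) return(list())
  a <- pmin(links$from_sid, links$to_sid)
  b <- pmax(links$from_sid, links$to_sid)
  index1 <- ifelse(links$from_sid == a, links$from, links$to)
  index2 <- ifelse(links$from_sid == a, links$to, links$from)
  lm <- data.frame(a = a, b = b, index1 = index1, index2 = index2,
                   ladder = links$ladder, stringsAsFactors = FALSE)
  lm <- lm[!duplicated(lm[c("a", "b", "index1", "index2")]), , drop = FALSE]
  groups <- split(seq_len(nrow(lm)), list(lm$a, lm$b), drop = TRUE)
  # deterministic order: by strand1 then strand2 position
  ord <- order(vapply(groups, function(g) lm$a[g[1L]], integer(1)),
               vapply(groups, function(g) lm$b[g[1L]], integer(1)))
  groups <- groups[ord]
  lapply(groups, function(g) {
    s1 <- lm$a[g[1L]]
    s2 <- lm$b[g[1L]]
    bm <- data.frame(index1 = lm$index1[g], index2 = lm$index2[g],
                     ladder = lm$ladder[g], stringsAsFactors = FALSE)
    bm <- bm[order(bm$index1, bm$index2), , drop = FALSE]
    rownames(bm) <- NULL
    pair <- structure(list(
      chain1 = strands$chain_id[s1], chain2 = strands$chain_id[s2],
      sheet_label = strands$sheet_label[s1],
      strand1_ordinal = strands$strand_ordinal[s1],
      strand2_ordinal = strands$strand_ordinal[s2],
      SL1 = strands$length[s1], SL2 = strands$length[s2],
      orientation = NA_character_, PL = NA_integer_, Et1 = NA_integer_,
      Et2 = NA_integer_, EL = NA_integer_, bulged = NA,
      interchain = strands$chain_id[s1] != strands$chain_id[s2],
      bridged_map = bm), class = "strand_pair")
    compute_registration(pair)
  })
}

#' @export
print.strand_pair <- function(x, ...) {
  cat(sprintf(
    "<strand pair %s:%d - %s:%d (%s%s%s): SL1=%d SL2=%d PL=%d Et1=%d Et2=%d EL=%d>\n",
    x$chain1, x$strand1_ordinal, x$chain2, x$strand2_ordinal, x$orientation,
    if (x$bulged) ", bulged" else "",
    if (x$interchain) ", interchain" else "",
    x$SL1, x$SL2, x$PL, x$Et1, x$Et2, x$EL))
  invisible(x)
}

#' Flatten strand pairs to a data frame
#'
#' @param pairs list of \code{strand_pair} objects.
#' @return data frame with columns \code{chain1}, \code{chain2},
#'   \code{sheet}, \code{strand1_ordinal}, \code{strand2_ordinal},
#'   \code{orientation}, \code{SL1}, \code{SL2}, \code{PL}, \code{Et1},
#'   \code{Et2}, \code{EL}, \code{bulged}, \code{interchain},
#'   \code{n_bridges}.
#' @export
pair_table <- function(pairs) {
  cols <- function(f, what) vapply(pairs, `[[`, f, what)
  data.frame(
    chain1 = cols(character(1), "chain1"),
    chain2 = cols(character(1), "chain2"),
    sheet = cols(character(1), "sheet_label"),
    strand1_ordinal = cols(integer(1), "strand1_ordinal"),
    strand2_ordinal = cols(integer(1), "strand2_ordinal"),
    orientation = cols(character(1), "orientation"),
    SL1 = cols(integer(1), "SL1"), SL2 = cols(integer(1), "SL2"),
    PL = cols(integer(1), "PL"), Et1 = cols(integer(1), "Et1"),
    Et2 = cols(integer(1), "Et2"), EL = cols(integer(1), "EL"),
    bulged = cols(logical(1), "bulged"),
    interchain = cols(logical(1), "interchain"),
    n_bridges = vapply(pairs, function(p) nrow(p$bridged_map), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
}
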