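# Per-pair ratio statistics and dataset-level summaries.
#
# All percentages are carried on the 0-100 scale. Internal computation is
# at full double precision; rounding to two decimals (half-up) happens only
# in the display helpers.

RATIO_VARIABLES <- c("R", "Rt1", "Rt2")

.pairs_df <- function(pairs) {
  if (is.data.frame(pairs)) return(pairs)
  pair_table(pairs)
}

#' Pairing ratio R
#'
#' \code{R = 100 * PL / EL = 100 * PL / (PL + Et1 + Et2)}: the common paired
#' part as a percentage of the whole length of the pairing.
#'
#' @param pairs a pair data frame ([pair_table()]) or list of
#'   \code{strand_pair} objects.
#' @return numeric vector of percentages in (0, 100].
#' @export
pairing_ratio <- function(pairs) {
  p <- .pairs_df(pairs)
  100 * p$PL / (p$PL + p$Et1 + p$Et2)
}

#' Per-strand ratios Rt1 and Rt2
#'
#' \code{Rt_i = 100 * PL / SL_i}: the common paired part as a percentage of
#' each strand's own length.
#'
#' @inheritParams pairing_ratio
#' @return data frame with columns \code{Rt1}, \code{Rt2}.
#' @export
strand_ratios <- function(pairs) {
  p <- .pairs_df(pairs)
  data.frame(Rt1 = 100 * p$PL / p$SL1, Rt2 = 100 * p$PL / p$SL2)
}

#' Terminal-alignment rule
#'
#' The empirical pairing rule: a strand pair conforms when
#' \code{R >= 25} and \code{Rt1 >= 40} and \code{Rt2 >= 40}, all thresholds
#' inclusive.
#'
#' @param R,Rt1,Rt2 numeric vectors of percentages (0-100 scale), recycled
#'   to a common length.
#' @return logical vector.
#' @export
check_rule <- function(R, Rt1, Rt2) {
  R >= 25 & Rt1 >= 40 & Rt2 >= 40
}

#' Per-pair ratio statistics
#'
#' Appends \code{R}, \code{Rt1}, \code{Rt2} and the rule verdict
#' \code{rule_pass} to the pair table.
#'
#' @inheritParams pairing_ratio
#' @return the pair data frame with four added columns.
#' @export
pair_stats <- function(pairs) {
  p <- .pairs_df(pairs)
  p$R <- pairing_ratio(p)
  rt <- strand_ratios(p)
  p$Rt1 <- rt$Rt1
  p$Rt2 <- rt$Rt2
  p$rule_pass <- check_rule(p$R, p$Rt1, p$Rt2)
  p
}

DIFF_BINS <- c(as.character(0:10), ">10")

#' Length-difference cross-table
#'
#' Cross-tabulates pairs by the absolute strand-length difference
#' \code{|SL1 - SL2|} (rows 0..10 and ">10") against the four
#' extension-existence cases. Row percentages of the four cases are
#' computed within each row; \code{pct_total} is the row's share of all
#' pairs. Two cells are structurally zero: equal-length pairs cannot have
#' exactly one extension (\code{Et1 - Et2 = SL1 - SL2}), and unequal-length
#' pairs cannot have none.
#'
#' @inheritParams pairing_ratio
#' @return data frame with columns \code{diff}, \code{n_pairs},
#'   \code{pct_total}, \code{pct_et1_0_et2_0}, \code{pct_et1_0_et2_pos},
#'   \code{pct_et1_pos_et2_0}, \code{pct_et1_pos_et2_pos}. Case percentages
#'   are \code{NA} for empty rows.
#' @export
length_difference_table <- function(pairs) {
  p <- .pairs_df(pairs)
  d <- abs(p$SL1 - p$SL2)
  bin <- ifelse(d > 10, ">10", as.character(d))
  bin <- factor(bin, levels = DIFF_BINS)
  case <- factor(paste0(ifelse(p$Et1 == 0, "z", "p"),
                        ifelse(p$Et2 == 0, "z", "p")),
                 levels = c("zz", "zp", "pz", "pp"))
  tab <- table(bin, case)
  n <- rowSums(tab)
  total <- sum(n)
  rowpct <- sweep(tab, 1, n, "/") * 100
  rowpct[n == 0, ] <- NA_real_
  data.frame(diff = DIFF_BINS,
             n_pairs = as.integer(n),
             pct_total = if (total > 0) 100 * n / total else rep(0, length(n)),
             pct_et1_0_et2_0 = rowpct[, "zz"],
             pct_et1_0_et2_pos = rowpct[, "zp"],
             pct_et1_pos_et2_0 = rowpct[, "pz"],
             pct_et1_pos_et2_pos = rowpct[, "pp"],
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Range, mean and standard deviation of the registration variables
#'
#' Summarises \code{SL1}, \code{SL2}, \code{PL}, \code{Et1}, \code{Et2},
#' \code{EL} over the dataset. The standard deviation uses the sample
#' (n - 1) convention (0 is reported for a single pair). By linearity,
#' \code{mean(EL) = mean(PL) + mean(Et1) + mean(Et2)} exactly.
#'
#' @inheritParams pairing_ratio
#' @return data frame with columns \code{variable}, \code{min}, \code{max},
#'   \code{mean}, \code{sd}.
#' @export
variable_summary <- function(pairs) {
  p <- .pairs_df(pairs)
  if (nrow(p) == 0L) stop("no pairs", call. = FALSE)
  vars <- c("SL1", "SL2", "PL", "Et1", "Et2", "EL")
  data.frame(variable = vars,
             min = vapply(vars, function(v) min(p[[v]]), numeric(1)),
             max = vapply(vars, function(v) max(p[[v]]), numeric(1)),
             mean = vapply(vars, function(v) mean(p[[v]]), numeric(1)),
             sd = vapply(vars, function(v) {
               if (nrow(p) == 1L) 0 else stats::sd(p[[v]])
             }, numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Histogram of a ratio variable
#'
#' Percent of pairs per right-closed bin \code{(lo, hi]} over (0, 100].
#' Exact 100-percent values land in the top bin, so every pair is counted
#' once.
#'
#' @inheritParams pairing_ratio
#' @param variable one of \code{"R"}, \code{"Rt1"}, \code{"Rt2"}.
#' @param bin_width bin width in percent points; must divide 100.
#' @return data frame with columns \code{bin_lo}, \code{bin_hi},
#'   \code{percent}.
#' @export
ratio_distribution <- function(pairs, variable = c("R", "Rt1", "Rt2"),
                               bin_width = 5) {
  variable <- match.arg(variable)
  if (bin_width <= 0 || 100 %% bin_width != 0) {
    stop("bin_width must be a positive divisor of 100", call. = FALSE)
  }
  v <- pair_stats(pairs)[[variable]]
  breaks <- seq(0, 100, by = bin_width)
  cuts <- cut(v, breaks = breaks, right = TRUE, include.lowest = FALSE)
  counts <- as.integer(table(cuts))
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
             percent = if (length(v)) 100 * counts / length(v) else
               rep(0, length(counts)),
             stringsAsFactors = FALSE)
}

#' Cumulative percentage curve of a ratio variable
#'
#' \code{CP(x) = 100 * |pairs with variable >= x| / |pairs|}: the percent of
#' pairs whose ratio equals or exceeds the abscissa. Non-increasing in
#' \code{x} with \code{CP(0) = 100}.
#'
#' @inheritParams ratio_distribution
#' @param grid abscissa values (percent).
#' @return data frame with columns \code{x}, \code{cp}.
#' @export
cumulative_curve <- function(pairs, variable = c("R", "Rt1", "Rt2"),
                             grid = seq(0, 100, by = 5)) {
  variable <- match.arg(variable)
  v <- pair_stats(pairs)[[variable]]
  cp <- vapply(grid, function(x) {
    if (length(v)) 100 * mean(v >= x) else NA_real_
  }, numeric(1))
  data.frame(x = grid, cp = cp)
}

#' Round percentages for display
#'
#' Two decimals, half-up (the convention used in printed summary tables),
#' rather than R's default round-half-even.
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  # small nudge so values that are .5 up to double rounding error go up
  sign(x) * floor(abs(x) * p + 0.5 + 1e-8) / p
}

#' Published strand-pair length-difference cross-table
#'
#' The reference cross-table from a published survey of a 2009 culled
#' nonredundant PDB chain set (25\% identity, 2.0 A resolution, R-factor
#' 0.25): pair counts by absolute strand-length difference and the
#' within-row percentages of the four terminal-extension cases. Shipped as
#' plain TSV and used for desk-scale arithmetic checks of the cross-table
#' aggregation contract; the underlying per-pair data are not
#' redistributable.
#'
#' @return data frame with the same columns as
#'   [length_difference_table()].
#' @export
reference_pair_table <- function() {
  path <- system.file("extdata", "published_pair_table.tsv",
                      package = "strandpairs", mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c(diff = "character"))
}
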