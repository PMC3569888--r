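# End-to-end orchestration: DSSP files -> pair table -> dataset summaries.

#' Analyse parsed chains
#'
#' Runs the full pipeline on already-parsed chains: chain filters, strand
#' extraction, pair enumeration, ratio statistics and the dataset
#' summaries. Bulged pairs are excluded from the summaries by default
#' (their registration is still reported in the pair table); interchain
#' pairs are included by default.
#'
#' @param chains list of chain records from [parse_dssp()] (one file's
#'   worth; use [run_analyze()] for multi-file input).
#' @param include_bulged include bulged pairs in the summaries.
#' @param include_interchain include cross-chain pairs in the summaries.
#' @param bin_width histogram bin width (percent).
#' @param grid_step abscissa step of the cumulative curves (percent).
#' @param policy chain [filter_policy()].
#' @return list with elements \code{pairs} (all pairs, with ratio columns),
#'   \code{used} (the subset entering the summaries), \code{summary} (list:
#'   \code{diff_table}, \code{var_summary}, \code{histograms},
#'   \code{cumulative}), \code{rejections}, \code{log} (named counts).
#' @export
analyze_chains <- function(chains, include_bulged = FALSE,
                           include_interchain = TRUE, bin_width = 5,
                           grid_step = 5, policy = filter_policy()) {
  filt <- filter_chains(chains, policy)
  strands <- strand_table(filt$retained)
  residues <- residue_table(filt$retained)
  pairs <- enumerate_pairs(strands, residues)
  ptab <- if (length(pairs)) pair_stats(pair_table(pairs)) else
    pair_stats(pair_table(list()))
  .summarise_pairs(ptab, filt$rejections,
                   chains_read = length(chains),
                   include_bulged = include_bulged,
                   include_interchain = include_interchain,
                   bin_width = bin_width, grid_step = grid_step)
}

.summarise_pairs <- function(ptab, rejections, chains_read, include_bulged,
                             include_interchain, bin_width, grid_step) {
  used <- ptab
  if (!include_bulged) used <- used[!used$bulged, , drop = FALSE]
  if (!include_interchain) used <- used[!used$interchain, , drop = FALSE]
  rownames(used) <- NULL
  grid <- seq(0, 100, by = grid_step)
  summary <- list(
    diff_table = length_difference_table(used),
    var_summary = if (nrow(used)) variable_summary(used) else NULL,
    histograms = stats::setNames(lapply(RATIO_VARIABLES, function(v) {
      ratio_distribution(used, v, bin_width)
    }), RATIO_VARIABLES),
    cumulative = stats::setNames(lapply(RATIO_VARIABLES, function(v) {
      cumulative_curve(used, v, grid)
    }), RATIO_VARIABLES))
  log <- c(chains_read = chains_read,
           chains_rejected = nrow(rejections),
           chains_retained = chains_read - nrow(rejections),
           pairs_total = nrow(ptab),
           pairs_bulged = sum(ptab$bulged),
           pairs_interchain = sum(ptab$interchain),
           pairs_used = nrow(used))
  list(pairs = ptab, used = used, summary = summary,
       rejections = rejections, log = log)
}

.resolve_dssp_files <- function(input) {
  files <- unlist(lapply(input, function(p) {
    if (dir.exists(p)) {
      list.files(p, pattern = "\\.dssp$", full.names = TRUE)
    } else p
  }))
  files <- files[file.exists(files)]
  if (length(files) == 0L) {
    stop("no readable DSSP input under: ", paste(input, collapse = ", "),
         call. = FALSE)
  }
  sort(files)
}

#' Analyse DSSP files end to end
#'
#' Reads one or more DSSP files (or every \code{*.dssp} file of a
#' directory), runs the pipeline per file (DSSP indices are file-scoped,
#' so bridge partners never cross files), pools the pair tables, and
#' computes the dataset summaries. Optionally writes all outputs to
#' \code{output_dir}: \code{pair_table.tsv},
#' \code{length_difference_table.tsv}, \code{variable_summary.tsv},
#' \code{histograms.json}, \code{cumulative_curves.json},
#' \code{rejections.tsv}. Outputs are deterministic given identical input
#' and configuration.
#'
#' @param input character vector of DSSP file paths and/or directories.
#' @param output_dir optional directory for the TSV/JSON outputs.
#' @inheritParams analyze_chains
#' @return As [analyze_chains()], with a \code{file} column in
#'   \code{pairs} and \code{rejections} and a \code{files} element listing
#'   the inputs.
#' @export
run_analyze <- function(input, output_dir = NULL, include_bulged = FALSE,
                        include_interchain = TRUE, bin_width = 5,
                        grid_step = 5, policy = filter_policy()) {
  files <- .resolve_dssp_files(input)
  ptabs <- list(); rejs <- list(); chains_read <- 0L
  for (f in files) {
    chains <- read_dssp(f)
    chains_read <- chains_read + length(chains)
    filt <- filter_chains(chains, policy)
    pairs <- enumerate_pairs(strand_table(filt$retained),
                             residue_table(filt$retained))
    pt <- pair_stats(pair_table(pairs))
    if (nrow(pt)) pt <- cbind(file = basename(f), pt,
                              stringsAsFactors = FALSE)
    rj <- filt$rejections
    if (nrow(rj)) rj <- cbind(file = basename(f), rj,
                              stringsAsFactors = FALSE)
    ptabs[[f]] <- pt; rejs[[f]] <- rj
  }
  ptab <- do.call(rbind, ptabs[vapply(ptabs, nrow, integer(1)) > 0])
  if (is.null(ptab)) {
    ptab <- cbind(file = character(), pair_stats(pair_table(list())))
  }
  rownames(ptab) <- NULL
  rej <- do.call(rbind, rejs[vapply(rejs, nrow, integer(1)) > 0])
  if (is.null(rej)) {
    rej <- data.frame(file = character(), chain_id = character(),
                      reason = character(), stringsAsFactors = FALSE)
  }
  rownames(rej) <- NULL
  res <- .summarise_pairs(ptab, rej, chains_read, include_bulged,
                          include_interchain, bin_width, grid_step)
  res$files <- files
  if (!is.null(output_dir)) .write_outputs(res, output_dir)
  invisible(res)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
}

.write_outputs <- function(res, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  .write_tsv(res$pairs, file.path(output_dir, "pair_table.tsv"))
  .write_tsv(res$summary$diff_table,
             file.path(output_dir, "length_difference_table.tsv"))
  if (!is.null(res$summary$var_summary)) {
    .write_tsv(res$summary$var_summary,
               file.path(output_dir, "variable_summary.tsv"))
  }
  jsonlite::write_json(res$summary$histograms,
                       file.path(output_dir, "histograms.json"),
                       dataframe = "columns", digits = NA)
  jsonlite::write_json(res$summary$cumulative,
                       file.path(output_dir, "cumulative_curves.json"),
                       dataframe = "columns", digits = NA)
  .write_tsv(res$rejections, file.path(output_dir, "rejections.tsv"))
  writeLines(paste(names(res$log), res$log, sep = "\t"),
             file.path(output_dir, "run_log.tsv"))
  invisible(output_dir)
}

#' Simulate DSSP fixtures with ground truth
#'
#' Samples a synthetic dataset, renders it as one or more DSSP files
#' (\code{fixtures_001.dssp}, ...) and writes the ground-truth table
#' (\code{truth.tsv}) alongside. Fully reproducible for a given seed.
#'
#' @param n number of strand pairs.
#' @param output_dir destination directory (created if needed).
#' @param seed integer seed.
#' @param params a [sampling_params()] object.
#' @return invisibly, list with \code{files}, \code{truth_path},
#'   \code{dataset}.
#' @export
run_simulate <- function(n, output_dir, seed = 1L,
                         params = sampling_params()) {
  ds <- sample_dataset(n, params, seed)
  texts <- render_dssp(ds)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- file.path(output_dir,
                     sprintf("fixtures_%03d.dssp", seq_along(texts)))
  for (i in seq_along(texts)) {
    writeLines(sub("\n$", "", texts[[i]]), files[[i]])
  }
  truth_path <- file.path(output_dir, "truth.tsv")
  .write_tsv(truth_table(ds), truth_path)
  invisible(list(files = files, truth_path = truth_path, dataset = ds))
}
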