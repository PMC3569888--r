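# independent run-segmentation oracle: maximal 'E' runs of a state string,
# split at break positions (break after position b)
oracle_runs <- function(ss, breaks = integer()) {
  cut <- rep(FALSE, length(ss))
  cut[breaks + 1L] <- TRUE
  lens <- integer()
  run <- 0L
  for (i in seq_along(ss)) {
    if (ss[i] == "E") {
      if (i == 1L || ss[i - 1L] != "E" || cut[i]) {
        run <- run + 1L
        lens[run] <- 0L
      }
      lens[run] <- lens[run] + 1L
    }
  }
  lens
}

test_that("strands are maximal 'E' runs, split at breaks; 'B' is excluded", {
  ch <- parse_dssp(fixture_dssp_text(chain = rep("A", 11),
                                     ss = strsplit("CCEEEECCEEC", "")[[1]]))
  st <- extract_strands(ch[[1]])
  expect_equal(st$length, c(4L, 2L))
  expect_equal(st$strand_ordinal, 1:2)

  ch_b <- parse_dssp(fixture_dssp_text(chain = rep("A", 5),
                                       ss = c("C", "B", "C", "B", "C")))
  expect_equal(nrow(extract_strands(ch_b[[1]])), 0L)

  ch_brk <- parse_dssp(fixture_dssp_text(chain = rep("A", 5),
                                         ss = rep("E", 5),
                                         brk = c(FALSE, FALSE, TRUE, FALSE,
                                                 FALSE)))
  expect_equal(extract_strands(ch_brk[[1]])$length, c(2L, 3L))
})

test_that("strand segmentation matches a brute-force oracle on random input", {
  set.seed(401)
  for (rep in 1:25) {
    n <- sample(5:40, 1)
    ss <- sample(c("E", "C", "H", "B", "T"), n, replace = TRUE,
                 prob = c(0.4, 0.3, 0.1, 0.1, 0.1))
    breaks <- sort(sample(seq_len(n - 1), sample(0:2, 1)))
    ch <- parse_dssp(fixture_dssp_text(chain = rep("A", n), ss = ss,
                                       brk = c(seq_len(n) %in% (breaks + 1L))))
    expect_equal(extract_strands(ch[[1]])$length, oracle_runs(ss, breaks),
                 info = paste(ss, collapse = ""))
  }
})

test_that("a k-strand ladder yields k-1 pairs; unlinked strands yield none", {
  for (k in c(2L, 4L, 7L)) {
    pt <- pairs_from_text(fixture_ladder_text(k))
    expect_equal(nrow(pt), k - 1L)
    expect_true(all(pt$PL == 4L))
    # brute force from the raw bridge links
    chains <- parse_dssp(fixture_ladder_text(k))
    r <- residue_table(chains)
    st <- strand_table(chains)
    sid <- function(ix) findInterval(ix, st$first_index)
    links <- rbind(cbind(r$dssp_index[r$bp1 > 0], r$bp1[r$bp1 > 0]),
                   cbind(r$dssp_index[r$bp2 > 0], r$bp2[r$bp2 > 0]))
    key <- unique(paste(pmin(sid(links[, 1]), sid(links[, 2])),
                        pmax(sid(links[, 1]), sid(links[, 2]))))
    expect_equal(nrow(pt), length(key))
  }

  no_links <- fixture_dssp_text(chain = rep("A", 12),
                                ss = rep(c("E", "E", "E", "C"), 3))
  expect_equal(nrow(pairs_from_text(no_links)), 0L)
})

test_that("a 10-strand, 3-sheet topology gives 7 pairs", {
  # sheets of 3, 4 and 3 strands as simple ladders -> 2 + 3 + 2 pairs
  texts <- vapply(c(A = 3L, B = 4L, C = 3L), fixture_ladder_text,
                  character(1), len = 4L)
  # merge into one file by concatenating chains under distinct ids
  chains <- c(parse_dssp(texts[[1]]), parse_dssp(texts[[2]]),
              parse_dssp(texts[[3]]))
  offs <- c(0L, vapply(chains, function(ch) max(ch$residues$dssp_index),
                       integer(1)))
  for (i in seq_along(chains)) {
    off <- sum(offs[seq_len(i)])
    chains[[i]]$chain_id <- LETTERS[i]
    r <- chains[[i]]$residues
    r$chain_id <- LETTERS[i]
    r$dssp_index <- r$dssp_index + off
    r$bp1[r$bp1 > 0] <- r$bp1[r$bp1 > 0] + off
    r$bp2[r$bp2 > 0] <- r$bp2[r$bp2 > 0] + off
    chains[[i]]$residues <- r
  }
  st <- strand_table(chains)
  expect_equal(nrow(st), 10L)
  pt <- pair_table(enumerate_pairs(st, residue_table(chains)))
  expect_equal(nrow(pt), 7L)
  expect_false(any(pt$interchain))
})

test_that("orientation follows partner progression along strand1", {
  par <- fixture_pair_with_map(c(10, 11, 12), c(20, 21, 22))
  anti <- fixture_pair_with_map(c(10, 11, 12), c(22, 21, 20))
  expect_equal(classify_orientation(par), "parallel")
  expect_equal(classify_orientation(anti), "antiparallel")

  # single rung: ladder-letter case decides; blank warns and defaults
  expect_equal(classify_orientation(fixture_pair_with_map(10, 20, "a")),
               "parallel")
  expect_equal(classify_orientation(fixture_pair_with_map(10, 20, "A")),
               "antiparallel")
  expect_warning(
    o <- classify_orientation(fixture_pair_with_map(10, 20, " ")),
    "indeterminate")
  expect_equal(o, "antiparallel")

  # generator ground truth is recovered for both orientations
  cfgs <- c(lapply(3:8, function(l) make_pair_config(l, l, 1, "parallel")),
            lapply(3:8, function(l) make_pair_config(l, l, 1, "antiparallel")))
  pt <- pairs_from_configs(cfgs)
  expect_equal(pt$orientation, truth_table(cfgs)$orientation)
})

test_that("registration matches the interval-overlap closed form", {
  pt <- pairs_from_configs(list(make_pair_config(4, 4, 0),
                                make_pair_config(6, 4, 0),
                                make_pair_config(5, 5, 2, "parallel")))
  expect_equal(pt$PL, c(4L, 4L, 3L))
  expect_equal(pt$Et1, c(0L, 2L, 2L))
  expect_equal(pt$Et2, c(0L, 0L, 2L))
  expect_equal(pt$EL, c(4L, 6L, 7L))

  # random spot checks against PL = min(SL1, o + SL2) - max(0, o)
  set.seed(402)
  cfgs <- replicate(40, {
    sl1 <- sample(1:12, 1); sl2 <- sample(1:12, 1)
    o <- sample(seq(-(sl2 - 1L), sl1 - 1L), 1)
    make_pair_config(sl1, sl2, o, sample(c("parallel", "antiparallel"), 1))
  }, simplify = FALSE)
  pt <- pairs_from_configs(cfgs)
  tt <- truth_table(cfgs)
  expect_equal(pt$PL, pmin(tt$SL1, tt$offset + tt$SL2) - pmax(0L, tt$offset))
  expect_equal(pt$Et1, tt$truth_Et1)
  expect_equal(pt$Et2, tt$truth_Et2)
})

test_that("registration identities hold on every enumerated pair", {
  ds <- sample_dataset(300, sampling_params(bulge_rate = 0.15), seed = 17)
  pt <- pairs_from_configs(ds)
  expect_equal(pt$EL, pt$PL + pt$Et1 + pt$Et2)
  nb <- !pt$bulged
  expect_true(any(nb))
  expect_equal(pt$Et1[nb] - pt$Et2[nb], pt$SL1[nb] - pt$SL2[nb])
  expect_true(all(pt$PL >= 1 & pt$PL <= pmin(pt$SL1, pt$SL2)))
})

test_that("bulged ladders are flagged and bridges to non-strands ignored", {
  cfg <- make_pair_config(8, 8, 0, "antiparallel",
                          bulge_spec = list(position = 4))
  pt <- pairs_from_configs(list(cfg))
  expect_true(pt$bulged)
  expect_equal(pt$SL1, 8L)

  # a bridge pointing at a coil residue is dropped with a warning
  txt <- fixture_dssp_text(chain = rep("A", 9),
                           ss = c("E", "E", "E", "C", "C", "C", "E", "E", "E"),
                           bp1 = c(9L, 8L, 7L, 0L, 0L, 0L, 3L, 2L, 5L))
  expect_warning(pt2 <- pairs_from_text(txt), "ignored")
  expect_equal(nrow(pt2), 1L)
  expect_equal(pt2$PL, 3L)
})
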