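test_that("residue table lines parse into chains, break lines into breaks", {
  # two chains, 10 table lines of which one is a '!' break -> 9 residues
  txt <- fixture_dssp_text(
    chain = c(rep("A", 5), rep("B", 4)),
    ss = c("C", "E", "E", "E", "C", "H", "H", "E", "E"),
    brk = c(rep(FALSE, 5), TRUE, rep(FALSE, 3)))
  chains <- parse_dssp(txt)
  expect_length(chains, 2L)
  expect_equal(vapply(chains, function(ch) nrow(ch$residues), integer(1)),
               c(A = 5L, B = 4L))
  expect_equal(chains[["A"]]$break_positions, integer())
  expect_equal(chains[["B"]]$break_positions, integer())

  # an intra-chain break is recorded at the position it splits
  txt2 <- fixture_dssp_text(chain = rep("A", 5), ss = rep("E", 5),
                            brk = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  ch <- parse_dssp(txt2)[["A"]]
  expect_equal(ch$break_positions, 2L)
  expect_equal(nrow(ch$residues), 5L)
})

test_that("parser reads the documented fixed columns", {
  txt <- fixture_dssp_text(chain = c("A", "A"), ss = c("E", "E"),
                           aa = c("G", "W"), bp1 = c(2L, 1L),
                           lad1 = c("A", "A"), sheet = c("Z", "Z"))
  r <- residue_table(parse_dssp(txt))
  expect_equal(r$amino_acid, c("G", "W"))
  expect_equal(r$ss_state, c("E", "E"))
  expect_equal(r$bp1, c(2L, 1L))
  expect_equal(r$bp2, c(0L, 0L))
  expect_equal(r$ladder1, c("A", "A"))
  expect_equal(r$sheet_label, c("Z", "Z"))
  expect_equal(r$dssp_index, 1:2)
})

test_that("disulfide-bonded cysteines (lowercase) normalise to C with a flag", {
  txt <- fixture_dssp_text(chain = c("A", "A", "A"), ss = c("E", "E", "E"),
                           aa = c("a", "X", "C"))
  r <- residue_table(parse_dssp(txt))
  expect_equal(r$amino_acid, c("C", "X", "C"))
  expect_equal(r$ss_bonded_cys, c(TRUE, FALSE, FALSE))
})

test_that("malformed input is rejected with a useful error", {
  expect_error(parse_dssp("just some text\nwith no table"), "header")
  # bridge partner naming no residue line
  txt <- fixture_dssp_text(chain = c("A", "A"), ss = c("E", "E"))
  bad <- sub("   0   0", "  99   0", txt)  # bp1 of first residue -> 99
  expect_error(parse_dssp(bad), "bridge partner")
  # non-increasing dssp index
  lines <- strsplit(txt, "\n")[[1]]
  lines[4] <- sub("^    2    2", "    1    2", lines[4])
  expect_error(parse_dssp(paste(lines, collapse = "\n")),
               "strictly increasing")
  # unreadable index field
  lines2 <- strsplit(txt, "\n")[[1]]
  substr(lines2[3], 1, 5) <- "  a  "
  expect_error(parse_dssp(paste(lines2, collapse = "\n")), "line 3")
})

test_that("emit/parse round trip is the identity on generator output", {
  # empty chain list -> header-only file parsing to zero chains
  expect_length(parse_dssp(emit_dssp(list())), 0L)

  # single all-'E' chain
  ds <- sample_dataset(30, sampling_params(bulge_rate = 0.2), seed = 11)
  txt <- render_dssp(ds)
  for (t in txt) {
    chains <- parse_dssp(t)
    again <- parse_dssp(emit_dssp(chains))
    expect_identical(residue_table(again), residue_table(chains))
    expect_identical(lapply(again, `[[`, "break_positions"),
                     lapply(chains, `[[`, "break_positions"))
  }

  # round trip preserves multi-chain files with breaks
  txt2 <- fixture_dssp_text(
    chain = c(rep("A", 4), rep("B", 3)),
    ss = c("E", "E", "C", "C", "E", "E", "E"),
    brk = c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE, FALSE))
  chains2 <- parse_dssp(txt2)
  expect_identical(residue_table(parse_dssp(emit_dssp(chains2))),
                   residue_table(chains2))
})

test_that("emit_dssp refuses invariant-violating records", {
  txt <- fixture_dssp_text(chain = c("A", "A"), ss = c("E", "E"))
  chains <- parse_dssp(txt)
  chains[["A"]]$residues$bp1[1] <- 42L
  expect_error(emit_dssp(chains), "42")
})

test_that("chain filters follow the survey criteria and are idempotent", {
  all_h <- parse_dssp(fixture_dssp_text(chain = rep("A", 4),
                                        ss = rep("H", 4)))[[1]]
  with_x <- parse_dssp(fixture_dssp_text(chain = rep("B", 4),
                                         ss = c("E", "E", "C", "C"),
                                         aa = c("A", "G", "X", "L")))[[1]]
  good <- parse_dssp(fixture_dssp_text(chain = rep("C", 4),
                                       ss = c("E", "E", "C", "C")))[[1]]
  b_only <- parse_dssp(fixture_dssp_text(chain = rep("D", 3),
                                         ss = c("C", "B", "C")))[[1]]
  res <- filter_chains(list(all_h, with_x, good, b_only))
  expect_equal(vapply(res$retained, `[[`, character(1), "chain_id"), "C")
  expect_equal(res$rejections$chain_id, c("A", "B", "D"))
  expect_equal(res$rejections$reason,
               c("no-beta-sheet", "nonstandard-residue", "no-beta-sheet"))

  # idempotent, and no residue silently dropped
  again <- filter_chains(res$retained)
  expect_identical(again$retained, res$retained)
  expect_equal(nrow(again$rejections), 0L)
  n_in <- sum(vapply(list(all_h, with_x, good, b_only),
                     function(ch) nrow(ch$residues), integer(1)))
  n_kept <- sum(vapply(res$retained, function(ch) nrow(ch$residues),
                       integer(1)))
  n_rej <- sum(vapply(list(all_h, with_x, b_only),
                      function(ch) nrow(ch$residues), integer(1)))
  expect_equal(n_in, n_kept + n_rej)
})
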