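# Sequence generator, block decomposition, blockiness taxonomy and CNC.

test_that("charged-site template puts 34 charges on a 100-mer, ends included", {
  pos <- charged_positions(100)
  expect_length(pos, 34)
  expect_equal(pos[1], 1)
  expect_equal(pos[length(pos)], 100)
  expect_true(all(diff(pos) %in% c(2, 3)))
  s <- generate_sequence(100, seed = 1)
  expect_equal(which(s$charges != 0), pos)
  expect_true(all(abs(s$charges[pos]) == 1))
  expect_equal(sum(s$charges), s$net_charge)
})

test_that("generator statistics match the i.i.d. fair-coin oracle", {
  set.seed(42)
  q <- replicate(4000, generate_sequence(100)$net_charge)
  # parity: 34 unit charges can never give an odd net charge
  expect_true(all(q %% 2 == 0))
  # binomial closed form: E[Q] = 0, Var(Q) = 34
  expect_lt(abs(mean(q)), 3 * sqrt(34 / length(q)))
  var_se <- 34 * sqrt(2 / (length(q) - 1)) # chi-square variance of the variance
  expect_lt(abs(var(q) - 34), 3 * var_se)
})

test_that("perfect-correlation limit yields single-sign sequences", {
  set.seed(7)
  one_block <- replicate(200, {
    s <- generate_sequence(100, correlation = 0.9999)
    length(rle(s$site_signs)$values) == 1
  })
  expect_gt(mean(one_block), 0.95)
  expect_error(generate_sequence(100, correlation = 1), "correlation")
  expect_error(generate_sequence(100, correlation = -1.2), "correlation")
})

test_that("Q-ensemble selection enforces the target and matches the exact binomial rate", {
  seqs <- select_q_ensemble(2e4, target_q = 8, seed = 3)
  expect_true(all(vapply(seqs, function(s) s$net_charge, numeric(1)) == 8))
  p_exact <- dbinom(21, 34, 0.5) # 21 plus / 13 minus charges
  acc <- attr(seqs, "acceptance_fraction")
  expect_lt(abs(acc - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 2e4))
  expect_error(select_q_ensemble(100, target_q = 7), "parity")
})

test_that("block decomposition is run-length over charged sites only", {
  signs <- c(1, 1, -1, -1, -1, rep(c(1, -1), 13), 1, 1, 1)
  s <- seq_from_signs(signs)
  dec <- decompose_blocks(s)
  expect_equal(dec$blocks$size[1:3], c(2, 3, 1))
  expect_equal(dec$blocks$sign[1:3], c(1, -1, 1))
  # signed block sizes must sum to Q (direct-summation oracle)
  expect_equal(sum(dec$blocks$sign * dec$blocks$size), s$net_charge)
  expect_error(decompose_blocks(seq_from_signs(rep(c(1, -1), 17))),
               "minority")
})

test_that("all-same-sign sequence is flagged as a degenerate single block", {
  s <- seq_from_signs(rep(1, 34))
  dec <- decompose_blocks(s)
  expect_true(dec$single_block)
  expect_equal(dec$terminal_majority_head, 34L)
  expect_equal(dec$terminal_majority_tail, 34L)
  expect_warning(cnc <- central_net_charge(dec), "single-block")
  expect_equal(cnc, 0L) # Q - the block
})

test_that("taxonomy labels follow the minority block-size rules", {
  label_of <- function(sizes) {
    # build a Q>0 sequence realizing the requested minority multiset
    n_min <- sum(sizes)
    stopifnot(n_min < 17)
    signs <- integer(0)
    for (b in sizes) signs <- c(signs, rep(1, 2), rep(-1, b))
    signs <- c(signs, rep(1, 34 - length(signs)))
    classify_group(decompose_blocks(seq_from_signs(signs)))
  }
  expect_equal(label_of(c(4, 2))$group_label, "A1")
  expect_equal(label_of(c(4, 2))$subgroup_label, "(-4)x1,(-2)xn")
  expect_equal(label_of(c(4, 3, 2))$subgroup_label, "(-4)x1,(-3)x1")
  expect_equal(label_of(c(3, 3, 3))$group_label, "B3")
  expect_equal(label_of(c(2, 2, 2, 2, 2))$group_label, "C5")
  expect_equal(label_of(c(6))$group_label, "AAA")
  expect_equal(label_of(c(5))$group_label, "AA")
  expect_equal(label_of(c(4, 4))$group_label, "A2")
  expect_equal(label_of(c(3, 2))$group_label, "B1")
  expect_equal(label_of(c(2, 2, 2, 2))$group_label, "C4")
  # outside the printed taxonomy: systematic fallback, flagged
  c2 <- label_of(c(2, 2))
  expect_equal(c2$group_label, "C2")
  expect_false(c2$in_taxonomy)
  b4 <- label_of(c(3, 3, 3, 3))
  expect_equal(b4$group_label, "B4")
  expect_false(b4$in_taxonomy)
})

test_that("central net charge subtracts exactly the terminal majority runs", {
  dec <- decompose_blocks(seq_from_signs(signs_head3_tail2))
  expect_equal(dec$net_charge, 8L)
  expect_equal(dec$terminal_majority_head, 3L)
  expect_equal(dec$terminal_majority_tail, 2L)
  expect_equal(central_net_charge(dec), 3L)

  # both termini minority-sign: CNC = Q
  signs <- c(-1, rep(1, 16), rep(c(1, -1), 8), -1)
  s <- seq_from_signs(signs)
  dec <- decompose_blocks(s)
  expect_equal(dec$terminal_majority_head, 0L)
  expect_equal(central_net_charge(dec), s$net_charge)

  # head 5, tail 4 with Q = 8 gives a negative core charge
  signs <- c(rep(1, 5), -1, rep(c(1, -1), 11), 1, -1, rep(1, 4))
  s <- seq_from_signs(signs)
  expect_equal(s$net_charge, 8L)
  dec <- decompose_blocks(s)
  expect_equal(dec$terminal_majority_head, 5L)
  expect_equal(dec$terminal_majority_tail, 4L)
  expect_equal(central_net_charge(dec), -1L)
})

test_that("taxonomy and CNC are total over random nonzero-Q sequences", {
  set.seed(99)
  for (i in 1:200) {
    s <- generate_sequence(100)
    if (s$net_charge == 0) next
    dec <- decompose_blocks(s)
    cl <- classify_group(dec)
    expect_true(nzchar(cl$group_label))
    expect_lte(cl$cnc, s$net_charge)
    both_min <- dec$terminal_majority_head == 0 &&
                dec$terminal_majority_tail == 0
    expect_equal(cl$cnc == s$net_charge, both_min)
  }
})

test_that("FASTA-like serialization round-trips sequences and descriptors", {
  seqs <- select_q_ensemble(2000, 8, seed = 5, max_keep = 10)
  path <- withr::local_tempfile(fileext = ".fa")
  write_sequences_fasta(seqs, path)
  back <- read_sequences_fasta(path)
  expect_equal(length(back), length(seqs))
  for (i in seq_along(seqs)) {
    expect_equal(back[[i]]$charges, seqs[[i]]$charges)
  }
  tab <- describe_sequences(seqs)
  expect_true(all(tab$Q == 8))
  expect_true(all(tab$cnc <= tab$Q))
})
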