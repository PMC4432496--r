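test_that("identical orthologs yield no events", {
  lib <- test_lib()
  s <- concat_labels(c("A", "B", "C", "A"))
  pair <- tibble::tibble(element_id = c("h", "c"), sequence = c(s, s))
  al <- align_pair(pair, lib)
  expect_equal(nrow(al$events), 0L)
  expect_equal(al$token_distance, 0L)
  ev <- compare_orthologs(pair, lib)
  expect_equal(nrow(as_tibble(ev)), 0L)
})

test_that("a single inserted unit is called at the token boundary", {
  lib <- test_lib()
  short <- concat_labels(c("A", "B", "C", "A"))
  long <- concat_labels(c("A", "B", "K", "C", "A"))
  pair <- tibble::tibble(element_id = c("h", "c"),
                         sequence = c(long, short))
  ev <- compare_orthologs(pair, lib)
  tb <- as_tibble(ev)
  expect_equal(nrow(tb), 1L)
  expect_equal(tb$carrier, "long")
  expect_equal(tb$length, 49L)
  expect_true(tb$token_boundary_aligned)
  expect_true("precise_ru_indel" %in% tb$labels[[1]])
  # polarity does not depend on input order
  ev2 <- compare_orthologs(pair[2:1, ], lib)
  expect_equal(as_tibble(ev2)$start, tb$start)
  expect_equal(as_tibble(ev2)$length, tb$length)
})

test_that("left-normalization is canonical and idempotent", {
  s <- "GGGACACACTTT"
  # deleting either AC copy is equivalent; both normalize to the first
  n1 <- vntrscheme:::left_normalize(s, 4, 5)
  n2 <- vntrscheme:::left_normalize(s, 6, 7)
  expect_equal(n1, n2)
  expect_equal(vntrscheme:::left_normalize(s, n1[1], n1[2]), n1)
})

test_that("planted multi-indel pairs are recovered at planted breakpoints", {
  lib <- test_lib()
  labs <- c("A", "B", "C", "A", "D", "K", "G", "C'", "B", "A", "D", "C")
  el <- elements_from_labels(list(labs), ids = "anc")
  sch <- as_tibble(segment_vntr(el, lib))
  for (seed in 1:5) {
    events <- tibble::tibble(token_from = c(3L, 6L, 9L),
                             token_to = c(3L, 7L, 9L),
                             designed_mh = c(0L, 10L, 5L))
    sim <- make_ortholog_pair(el, events, seed = seed, lib = lib,
                              tokens = sch)
    ev <- as_tibble(compare_orthologs(sim$pair, lib))
    expect_equal(nrow(ev), 3L, info = paste("seed", seed))
    got <- ev[order(ev$start), ]
    expect_equal(got$start, sim$truth$planted_start,
                 info = paste("seed", seed))
    expect_equal(got$end, sim$truth$planted_end, info = paste("seed", seed))
    expect_equal(got$mh_exact_right, sim$truth$designed_mh,
                 info = paste("seed", seed))
  }
})

test_that("microhomology measurement matches a character-scan oracle", {
  lib <- test_lib()
  el <- elements_from_labels(list(pair_template_labels()), ids = "anc")
  sch <- as_tibble(segment_vntr(el, lib))
  set.seed(99)
  for (trial in 1:10) {
    mh <- sample(0:42, 1)
    events <- tibble::tibble(token_from = 5L, token_to = 6L,
                             designed_mh = mh)
    sim <- make_ortholog_pair(el, events, seed = trial, lib = lib,
                              tokens = sch)
    al <- align_pair(sim$pair, lib)
    ev <- measure_microhomology(al)
    for (i in seq_len(nrow(ev))) {
      cs <- if (ev$carrier[i] == "long") al$seq_long else al$seq_short
      S <- substr(cs, ev$start[i], ev$end[i])
      om <- oracle_mh(S, substr(cs, 1, ev$start[i] - 1),
                      substr(cs, ev$end[i] + 1, nchar(cs)))
      expect_equal(ev$mh_exact_left[i], om$left)
      expect_equal(ev$mh_exact_right[i], om$right)
      expect_gte(ev$mh_relaxed[i], max(om$left, om$right))
    }
  }
})

test_that("designed mismatches split exact and relaxed microhomology", {
  lib <- test_lib()
  el <- elements_from_labels(list(pair_template_labels()), ids = "anc")
  sch <- as_tibble(segment_vntr(el, lib))

  # 8 bp homology with a mismatch at position 8: exact stops at 7
  sim <- make_ortholog_pair(
    el, tibble::tibble(token_from = 5L, token_to = 5L, designed_mh = 8L,
                       mismatch_at = list(8L)),
    seed = 2, lib = lib, tokens = sch
  )
  ev <- as_tibble(compare_orthologs(sim$pair, lib))
  expect_equal(ev$mh_exact_right, 7L)

  # 12 bp designed homology with one mismatch at position 6 inside a
  # 40 bp deletion: exact 5, relaxed recovers the full tract
  sim2 <- make_ortholog_pair(
    el, tibble::tibble(token_from = 5L, token_to = 5L, designed_mh = 12L,
                       mismatch_at = list(6L)),
    seed = 3, lib = lib, tokens = sch
  )
  expect_equal(sim2$truth$planted_end - sim2$truth$planted_start + 1L, 40L)
  ev2 <- as_tibble(compare_orthologs(sim2$pair, lib))
  expect_equal(ev2$mh_exact_right, 5L)
  expect_equal(ev2$mh_relaxed, 12L)

  # no designed homology, flanks forced non-matching
  sim3 <- make_ortholog_pair(
    el, tibble::tibble(token_from = 5L, token_to = 5L, designed_mh = 0L),
    seed = 4, lib = lib, tokens = sch
  )
  ev3 <- as_tibble(compare_orthologs(sim3$pair, lib))
  expect_equal(ev3$mh_exact_left, 0L)
  expect_equal(ev3$mh_exact_right, 0L)
})

test_that("mechanism labels follow the configured thresholds", {
  lib <- test_lib()
  # whole-token deletion, no homology: precise RU loss
  el <- elements_from_labels(list(pair_template_labels()), ids = "anc")
  sch <- as_tibble(segment_vntr(el, lib))
  sim <- make_ortholog_pair(
    el, tibble::tibble(token_from = 6L, token_to = 6L, designed_mh = 0L),
    seed = 5, lib = lib, tokens = sch
  )
  ev <- as_tibble(compare_orthologs(sim$pair, lib))
  expect_true("precise_ru_indel" %in% ev$labels[[1]])
  expect_true("slippage_compatible" %in% ev$labels[[1]])
  expect_false("mh_mediated" %in% ev$labels[[1]])

  # 3 bp micro indel turning an A-type unit into a C-type unit
  a <- label_seq("A")
  a_del3 <- paste0(substr(a, 1, 19), substr(a, 23, 40))
  expect_equal(a_del3, label_seq("C"))
  long <- concat_labels(c("B", "A", "D", "B"))
  short <- paste0(label_seq("B"), a_del3, label_seq("D"), label_seq("B"))
  ev2 <- as_tibble(compare_orthologs(
    tibble::tibble(element_id = c("h", "c"), sequence = c(long, short)),
    lib
  ))
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$length, 3L)
  expect_true("ru_conversion_microindel" %in% ev2$labels[[1]])
  expect_equal(ev2$converted_tokens[[1]][[1]][["from"]], "A")
  expect_equal(ev2$converted_tokens[[1]][[1]][["to"]], "C")

  # long microhomology on a long segment: compatible with both slippage
  # and homologous-recombination processing
  el2 <- elements_from_labels(list(c("A", "B", "N", "K", "L", "B", "A",
                                     "D")), ids = "anc")
  sch2 <- as_tibble(segment_vntr(el2, lib))
  sim3 <- make_ortholog_pair(
    el2, tibble::tibble(token_from = 3L, token_to = 5L, designed_mh = 34L),
    seed = 6, lib = lib, tokens = sch2
  )
  ev3 <- as_tibble(compare_orthologs(sim3$pair, lib))
  expect_equal(ev3$length, 150L)
  expect_gte(ev3$mh_relaxed, 34L)
  labs3 <- ev3$labels[[1]]
  expect_true(all(c("mh_mediated", "slippage_compatible",
                    "nahr_compatible") %in% labs3))
})

test_that("relaxed microhomology never undercuts either exact side", {
  lib <- test_lib()
  el <- elements_from_labels(list(pair_template_labels()), ids = "anc")
  sch <- as_tibble(segment_vntr(el, lib))
  set.seed(123)
  for (trial in 1:8) {
    sim <- make_ortholog_pair(
      el, tibble::tibble(token_from = 5L, token_to = 6L,
                         designed_mh = sample(0:42, 1)),
      seed = trial + 100, lib = lib, tokens = sch
    )
    ev <- as_tibble(compare_orthologs(sim$pair, lib))
    expect_true(all(ev$mh_relaxed >= pmax(ev$mh_exact_left,
                                          ev$mh_exact_right)))
    # NAHR compatibility implies microhomology mediation
    for (l in ev$labels) {
      if ("nahr_compatible" %in% l) expect_true("mh_mediated" %in% l)
    }
  }
})

test_that("mechanism configuration validates its invariants", {
  expect_error(mechanism_config(mh_min = 40, nahr_min = 34))
  expect_error(mechanism_config(slippage_window = 0))
  cfg <- mechanism_config()
  expect_equal(cfg$mh_min, 5L)
  expect_equal(cfg$nahr_min, 34L)
  expect_equal(cfg$slippage_window, 200L)
})
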