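test_that("generation is deterministic per seed and replayable", {
  lib <- test_lib()
  s1 <- generate_subfamily_set("LAVA_A", n = 5, seed = 31, lib = lib)
  s2 <- generate_subfamily_set("LAVA_A", n = 5, seed = 31, lib = lib)
  s3 <- generate_subfamily_set("LAVA_A", n = 5, seed = 32, lib = lib)
  expect_identical(s1$elements, s2$elements)
  expect_identical(s1$truth, s2$truth)
  expect_false(identical(s1$elements$sequence, s3$elements$sequence))

  # replaying recorded mutations reproduces every emitted sequence
  s4 <- generate_subfamily_set("SVA_B", n = 6, seed = 8, lib = lib,
                               mutation_rate = 0.02)
  for (i in seq_len(nrow(s4$truth))) {
    expect_identical(replay_truth(s4$truth[i, ]),
                     s4$elements$sequence[i])
  }
})

test_that("noise-free elements tokenize to their generating token string", {
  lib <- test_lib()
  sim <- generate_subfamily_set("LAVA_C1", n = 4, seed = 2, lib = lib,
                                mutation_rate = 0, indel_rate = 0)
  sch <- segment_vntr(sim$elements, lib)
  cs <- code_strings(sch)
  want <- vapply(sim$truth$generating_tokens, paste, "", collapse = "-")
  expect_equal(cs$code_string, unname(want))
})

test_that("mutation counts follow the configured rate", {
  lib <- test_lib()
  sim <- generate_subfamily_set("SVA_D", n = 10, seed = 7, lib = lib,
                                mutation_rate = 0.01, indel_rate = 0)
  total_bp <- sum(nchar(sim$truth$clean_sequence))
  n_mut <- sum(vapply(sim$truth$mutations, nrow, 0L))
  lambda <- 0.01 * total_bp
  expect_gte(n_mut, stats::qpois(0.005, lambda))
  expect_lte(n_mut, stats::qpois(0.995, lambda))
  # substitutions never keep the original base
  for (m in sim$truth$mutations) {
    if (nrow(m)) expect_true(all(m$from != m$to))
  }
})

test_that("grammar files validate tokens and round-trip", {
  lib <- test_lib()
  g <- packaged_grammars("SVA_F")
  expect_equal(paste(g$prefix, collapse = ""), "ABCAAAB'CACAAF")
  expect_equal(g$suffix, c("K", "G", "C'", "T"))
  expect_error(
    generate_subfamily_set(
      subfamily_grammar("bad", prefix = c("A", "Z9")), n = 2, lib = lib
    ),
    "unknown RU token"
  )
  # every packaged grammar is valid against the packaged library
  for (nm in names(packaged_grammars())) {
    expect_silent(vntrscheme:::validate_grammar(packaged_grammars(nm), lib))
  }
})

test_that("ortholog-pair planting honours its contracts", {
  lib <- test_lib()
  el <- elements_from_labels(list(pair_template_labels()), ids = "e")
  sch <- as_tibble(segment_vntr(el, lib))

  # no events: identical haplotypes
  sim0 <- make_ortholog_pair(el, tibble::tibble(token_from = integer(),
                                                token_to = integer(),
                                                designed_mh = integer()),
                             seed = 1, lib = lib, tokens = sch)
  expect_identical(sim0$pair$sequence[1], sim0$pair$sequence[2])

  # overlapping spans are refused
  expect_error(
    make_ortholog_pair(
      el, tibble::tibble(token_from = c(3L, 4L), token_to = c(5L, 6L),
                         designed_mh = 0L),
      seed = 1, lib = lib, tokens = sch
    ),
    "overlap"
  )

  # a deletion shortens the derived haplotype by the span length
  sim1 <- make_ortholog_pair(
    el, tibble::tibble(token_from = 6L, token_to = 6L, designed_mh = 12L),
    seed = 9, lib = lib, tokens = sch
  )
  expect_equal(nchar(sim1$pair$sequence[1]) - nchar(sim1$pair$sequence[2]),
               49L)

  # a duplication lengthens it, and the pair FASTA is written as given
  sim2 <- make_ortholog_pair(
    el, tibble::tibble(token_from = 4L, token_to = 4L, designed_mh = 0L,
                       type = "duplication"),
    seed = 9, lib = lib, tokens = sch
  )
  expect_equal(nchar(sim2$pair$sequence[2]) - nchar(sim2$pair$sequence[1]),
               40L)
  ev <- as_tibble(compare_orthologs(sim2$pair, lib))
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$length, 40L)
})
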