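test_that("conserved arrays are maximal at the support threshold", {
  # identical schemata: prefix and suffix cover the whole schema
  toks <- tokens_from_labels(rep(list(c("A", "B", "C", "A")), 5))
  ac <- consensus_arrays(toks, theta = 0.7)
  expect_equal(render_array(ac, "prefix"), "ABCA")
  expect_equal(render_array(ac, "suffix"), "ABCA")
  expect_true(all(ac$prefix$support == 1))
  expect_true(all(ac$suffix$support == 1))

  # 9/10 begin A-B-C-A; 5 continue with A: support drops below 0.7 there
  lls <- c(
    rep(list(c("A", "B", "C", "A", "A", "D")), 5),
    rep(list(c("A", "B", "C", "A", "K", "D")), 4),
    list(c("B", "C", "A", "D", "K", "D"))
  )
  ac2 <- consensus_arrays(tokens_from_labels(lls), theta = 0.7)
  expect_equal(render_array(ac2, "prefix"), "ABCA")
  expect_equal(ac2$prefix$support, rep(0.9, 4))
  # maximality: the best 5th token would have support 0.5 < theta
  expect_lt(5 / 10, 0.7)

  expect_error(consensus_arrays(toks[0, ]), "empty")
  mixed <- dplyr::bind_rows(
    tokens_from_labels(list(c("A", "B")), subfamily = "S1"),
    tokens_from_labels(list(c("A", "B")), subfamily = "S2")
  )
  expect_error(consensus_arrays(mixed), "mixed subfamily")
})

test_that("array derivation is invariant to element order", {
  set.seed(3)
  lls <- lapply(1:8, function(i) {
    c("A", "N", "B", "B", sample(c("B", "C", "D"), 6, replace = TRUE))
  })
  toks <- tokens_from_labels(lls, subfamily = "LAVA_X")
  ac1 <- consensus_arrays(toks, theta = 0.7)
  shuf <- toks[sample(nrow(toks)), ]
  ac2 <- consensus_arrays(shuf, theta = 0.7)
  expect_equal(ac1$prefix, ac2$prefix)
  expect_equal(ac1$suffix, ac2$suffix)
})

test_that("a minority 5' structure is reported alongside the consensus", {
  lls <- c(rep(list(c("A", "N", "B", "B", "C")), 6),
           rep(list(c("A", "B", "B", "D", "C")), 4))
  ac <- consensus_arrays(tokens_from_labels(lls), theta = 0.7)
  expect_equal(render_array(ac, "prefix"), "A")
  expect_equal(ac$n_alt, 4L)
  expect_equal(render_array(ac, "alt_prefix"), "ABBDC")
})

test_that("noise-free subfamily sets reproduce their generating grammar", {
  lib <- test_lib()
  sim <- generate_subfamily_set("SVA_D", n = 6, seed = 21, lib = lib,
                                mutation_rate = 0, indel_rate = 0)
  sch <- segment_vntr(sim$elements, lib)
  g <- packaged_grammars("SVA_D")
  ac <- consensus_arrays(sch, theta = 0.7)
  # derived prefix begins with the grammar's 5' array (it may extend into
  # deterministic interior positions), suffix ends with the 3' array
  expect_equal(ac$prefix$type_code[seq_along(g$prefix)],
               substr(g$prefix, 1, 1))
  pre_tags <- substr(g$prefix, 2, nchar(g$prefix))
  expect_equal(ac$prefix$variant_tag[seq_along(g$prefix)], pre_tags)
  suf <- render_array(ac, "suffix")
  expect_equal(substr(suf, nchar(suf) - nchar("KGC'T") + 1, nchar(suf)),
               "KGC'T")
  # variant-insensitive mining merges the K'-headed first array with K
  mot <- mine_internal_arrays(sch, theta = 0.7, variant_sensitive = FALSE)
  expect_true("K_nGC" %in% mot$motif)
})

test_that("LAVA-like sets keep conserved arrays short", {
  lib <- test_lib()
  sim <- generate_subfamily_set("LAVA_E", n = 10, seed = 9, lib = lib,
                                mutation_rate = 0, indel_rate = 0)
  sch <- segment_vntr(sim$elements, lib)
  ac <- consensus_arrays(sch, theta = 0.7)
  expect_lte(nrow(ac$prefix), 5L)
  expect_equal(render_array(ac, "prefix"),
               paste(packaged_grammars("LAVA_E")$prefix, collapse = ""))
})

test_that("position-specific consensus votes per column within the array", {
  lib <- test_lib()
  labs <- c("A", "B", "C", "A")
  clean <- elements_from_labels(rep(list(labs), 6))
  # four more elements with three substitutions inside the B token
  b <- label_seq("B")
  noisy_b <- b
  substr(noisy_b, 3, 3) <- "A"
  substr(noisy_b, 12, 12) <- "T"
  substr(noisy_b, 25, 25) <- "A"
  noisy_seq <- paste0(label_seq("A"), noisy_b, label_seq("C"),
                      label_seq("A"))
  noisy <- tibble::tibble(
    element_id = sprintf("TEST_n%02d", 1:4), subfamily = "TEST",
    sequence = noisy_seq
  )
  sch <- segment_vntr(dplyr::bind_rows(clean, noisy), lib)
  ps <- position_specific_consensus(sch, position = 2, side = "prefix",
                                    lib = lib)
  expect_equal(ps$consensus, b)
  expect_equal(ps$type_code, "B")
  expect_equal(ps$variant_tag, "")
  expect_error(position_specific_consensus(sch, position = 40), "outside")
})

test_that("the variant slot of a 5' array classifies to the variant", {
  lib <- test_lib()
  sim <- generate_subfamily_set("SVA_F", n = 6, seed = 4, lib = lib,
                                mutation_rate = 0, indel_rate = 0)
  sch <- segment_vntr(sim$elements, lib)
  ps <- position_specific_consensus(sch, position = 7, side = "prefix",
                                    lib = lib)
  expect_equal(ps$type_code, "B")
  expect_equal(ps$variant_tag, "'")
})

test_that("internal motif mining compresses runs and caps variability", {
  interior <- c("K", "K", "G", "C'", "K", "G", "C'", "K", "K", "K",
                "G", "C'")
  toks <- tokens_from_labels(list(interior))
  mot <- mine_internal_arrays(toks, theta = 0.7, prefix_len = 0,
                              suffix_len = 0)
  expect_equal(mot$motif[1], "K_nGC'")
  expect_equal(mot$variable_pos[1], 1L)
  expect_equal(c(mot$copy_min[1], mot$copy_max[1]), c(1L, 3L))
  expect_equal(mot$occurrences[1], 3L)

  none <- mine_internal_arrays(tokens_from_labels(list(c("A", "B", "C", "D"))),
                               theta = 0.7, prefix_len = 0, suffix_len = 0)
  expect_equal(nrow(none), 0L)

  orang <- c("Q", "C", "C", "C", "Q", "C", "C", "Q", "C", "C", "C", "C")
  mo <- mine_internal_arrays(tokens_from_labels(list(orang)), theta = 0.7,
                             prefix_len = 0, suffix_len = 0)
  expect_true("QC_n" %in% mo$motif)
  expect_equal(mo$copy_max[mo$motif == "QC_n"], 4L)
})
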