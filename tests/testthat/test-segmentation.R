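test_that("clean concatenations tokenize exactly and tile the sequence", {
  lib <- test_lib()
  el <- elements_from_labels(list(c("A", "B", "C", "A")), ids = "toy")
  sch <- segment_vntr(el, lib)
  tb <- as_tibble(sch)
  expect_equal(nrow(tb), 4L)
  expect_equal(code_strings(sch)$code_string, "A-B-C-A")
  expect_true(all(tb$edit_distance == 0L))
  expect_true(all(tb$identity == 1))
  # tokens tile the sequence with no gaps or overlaps
  expect_equal(tb$start[1], 0L)
  expect_equal(tb$end[nrow(tb)], nchar(el$sequence))
  expect_equal(tb$start[-1], tb$end[-nrow(tb)])
  # concatenating token substrings reproduces the input
  parts <- substring(el$sequence, tb$start + 1, tb$end)
  expect_equal(paste(parts, collapse = ""), el$sequence)

  # empty sequence -> zero tokens
  sch0 <- segment_vntr(tibble::tibble(element_id = "e", sequence = ""), lib)
  expect_equal(nrow(as_tibble(sch0)), 0L)
  expect_equal(code_strings(sch0)$code_string, "")
})

test_that("unmutated k-token concatenations are recovered for k up to 12", {
  lib <- test_lib()
  ent <- test_entries()
  set.seed(41)
  for (k in c(1, 3, 6, 9, 12)) {
    labs <- paste0(ent$code, ent$tag)[sample(nrow(ent), k, replace = TRUE)]
    el <- elements_from_labels(list(labs), ids = "rec")
    sch <- segment_vntr(el, lib)
    expect_equal(code_strings(sch)$code_string,
                 paste(labs, collapse = "-"),
                 info = paste("k =", k))
  }
})

test_that("DP cost equals the exhaustive tiling oracle on short sequences", {
  lib <- test_lib()
  ent <- test_entries()
  p <- seg_params()
  set.seed(42)
  for (trial in 1:20) {
    k <- sample(2:5, 1)
    units <- ent$consensus[sample(nrow(ent), k, replace = TRUE)]
    units <- vapply(units, function(u) mutate_seq(u, sample(0:2, 1)), "")
    seqq <- substr(paste(units, collapse = ""), 1, 200)
    el <- tibble::tibble(element_id = "x", sequence = seqq)
    sch <- segment_vntr(el, lib, p)
    expect_equal(tiling_cost(sch, "x", lib, p),
                 oracle_min_cost(seqq, lib, p),
                 info = paste("trial", trial))
  }
})

test_that("tokenization is robust to up to two substitutions per unit", {
  lib <- test_lib()
  ent <- test_entries()
  ok <- 0L
  n_trials <- 200L
  set.seed(7)
  eligible <- which(ent$length >= 37)
  for (trial in seq_len(n_trials)) {
    k <- sample(2:5, 1)
    idx <- sample(eligible, k, replace = TRUE)
    labs <- paste0(ent$code, ent$tag)[idx]
    units <- vapply(ent$consensus[idx], function(u) {
      mutate_seq(u, sample(0:2, 1))
    }, "")
    el <- tibble::tibble(element_id = "x",
                         sequence = paste(units, collapse = ""))
    sch <- segment_vntr(el, lib)
    got <- as_tibble(sch)$type_code
    want <- substr(labs, 1, 1)
    if (length(got) == length(want) && all(got == want)) ok <- ok + 1L
  }
  expect_gte(ok / n_trials, 0.95)
})

test_that("a short final token is matched against consensus prefixes", {
  lib <- test_lib()
  a <- label_seq("A")
  b <- label_seq("B")
  el <- tibble::tibble(element_id = "tr",
                       sequence = paste0(a, substr(b, 1, 20)))
  sch <- segment_vntr(el, lib)
  tb <- as_tibble(sch)
  expect_equal(nrow(tb), 2L)
  expect_true(tb$truncated[2])
  expect_false(tb$truncated[1])
  expect_equal(tb$end[2], nchar(el$sequence))
  expect_equal(tb$type_code[2], "B")
  expect_equal(tb$edit_distance[2], 0L)
})

test_that("assembly-gap sequences are refused, mild N content tolerated", {
  lib <- test_lib()
  a <- label_seq("A")
  gappy <- paste0(a, strrep("N", 10))  # 20% N
  expect_error(segment_vntr(tibble::tibble(element_id = "g",
                                           sequence = gappy), lib),
               "assembly-gap")
  mild <- paste0(substr(a, 1, 38), "NN", label_seq("B"))  # ~2.5% N
  sch <- segment_vntr(tibble::tibble(element_id = "m", sequence = mild), lib)
  expect_equal(nrow(as_tibble(sch)), 2L)
})

test_that("classification picks base type, then variant, with an X sink", {
  lib <- test_lib()
  expect_equal(classify_token(label_seq("B"), lib)[c(1, 2, 3)],
               list(type_code = "B", variant_tag = "", edit_distance = 0L))
  expect_equal(classify_token(label_seq("B'"), lib)[c(1, 2, 3)],
               list(type_code = "B", variant_tag = "'", edit_distance = 0L))
  # rejection-sample a 40-bp string below the identity threshold everywhere
  ent <- test_entries()
  set.seed(11)
  repeat {
    rnd <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                 collapse = "")
    d <- utils::adist(rnd, ent$consensus)[1, ]
    idy <- 1 - d / pmax(40, ent$length)
    if (all(idy < 0.75)) break
  }
  expect_equal(classify_token(rnd, lib)$type_code, "X")
  # data-frame interface agrees
  cu <- classify_units(tibble::tibble(unit = c(label_seq("B'"), rnd)), lib)
  expect_equal(cu$type_code, c("B", "X"))
})

test_that("unit discovery sorts by length and applies majority rule", {
  expect_error(discover_units(tibble::tibble(unit = character())),
               "no units")

  # identical units collapse to one fully supported cluster
  x <- strrep("ACGT", 10)
  cl <- discover_units(tibble::tibble(unit = rep(x, 10)))
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$support, 10L)
  expect_equal(cl$consensus, x)

  # 6 clean + 4 with three fixed substitutions: majority restores the clean
  y <- x
  substr(y, 5, 5) <- "T"
  substr(y, 18, 18) <- "A"
  substr(y, 35, 35) <- "C"
  cl2 <- discover_units(tibble::tibble(unit = c(rep(x, 6), rep(y, 4))))
  expect_equal(nrow(cl2), 1L)
  expect_equal(cl2$consensus, x)

  # ancestral-like mix: the two dominant clusters are 40 and 39 bp
  set.seed(5)
  a <- label_seq("A")
  b <- label_seq("B")
  units <- c(vapply(1:20, function(i) mutate_seq(a, sample(0:2, 1)), ""),
             vapply(1:20, function(i) mutate_seq(b, sample(0:2, 1)), ""))
  cl3 <- discover_units(tibble::tibble(unit = units))
  expect_setequal(cl3$length[1:2], c(40L, 39L))
  expect_equal(sum(cl3$support[1:2]), 40L)
})

test_that("cluster consensus equals the per-column mode when unique", {
  set.seed(13)
  base <- strrep("GC", 20)
  members <- vapply(1:9, function(i) mutate_seq(base, 1), "")
  cl <- discover_units(tibble::tibble(unit = members))
  m <- do.call(rbind, strsplit(cl$members[[1]], ""))
  mode_col <- apply(m, 2, function(col) {
    tab <- sort(table(col), decreasing = TRUE)
    if (length(tab) > 1 && tab[1] == tab[2]) NA_character_ else names(tab)[1]
  })
  cons <- strsplit(cl$consensus[1], "")[[1]]
  comparable <- !is.na(mode_col)
  expect_equal(cons[comparable], unname(mode_col[comparable]))
})
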