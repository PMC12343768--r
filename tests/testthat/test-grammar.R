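test_that("charge profile matches hand-enumerated window means", {
  expect_equal(charge_profile("KKKKK", 5)$value, rep(1, 5))
  expect_equal(charge_profile("GGGGG", 5)$value, rep(0, 5))
  expect_equal(
    charge_profile("KKGEE", 3)$value,
    c(2 / 3, 1 / 3, 0, -1 / 3, -2 / 3),
    tolerance = 1e-12
  )
})

test_that("charge profile agrees with the brute-force oracle on random sequences", {
  set.seed(7)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    seq <- paste(sample(c("K", "R", "D", "E", "G", "S", "P"), n, TRUE), collapse = "")
    w <- sample(2:min(9, n), 1)
    expect_equal(charge_profile(seq, w)$value, brute_charge_profile(seq, w),
      tolerance = 1e-12
    )
  }
})

test_that("charge profile at full-sequence window equals NCPR everywhere", {
  seq <- "KKDDEEGGRRSS"
  ncpr <- composition_features(seq)
  ncpr <- ncpr$value[ncpr$feature == "ncpr"]
  expect_equal(charge_profile(seq, nchar(seq))$value, rep(ncpr, nchar(seq)))
})

test_that("composition features: symmetry, extremes, direct counts, and sum-to-one", {
  f <- composition_features("EEKK")
  expect_equal(f$value[f$feature == "ncpr"], 0)
  expect_equal(f$value[f$feature == "fcr"], 1)

  f <- composition_features("EEEE")
  expect_equal(f$value[f$feature == "frac_E"], 1)
  expect_equal(f$value[f$feature == "ncpr"], -1)

  f <- composition_features("DEKRST")
  expect_equal(f$value[f$feature == "fcr"], 4 / 6)
  aa <- f$value[grepl("^frac_[A-Z]$", f$feature)]
  expect_equal(sum(aa), 1)
})

test_that("patterning delta reproduces hand-derived toy values", {
  expect_equal(patterning_delta("EEEEKKKK", "neg", "pos", windows = 5), 0.0656)
  expect_equal(patterning_delta("EKEKEKEK", "neg", "pos"), 0.0008)
  expect_equal(patterning_delta("EEEEKKKK", "neg", "pos"), mean(c(0.0656, 0.00823045)),
    tolerance = 1e-5
  )
})

test_that("patterning delta equals brute-force enumeration on random sequences", {
  set.seed(11)
  g <- residue_groups()
  for (i in 1:15) {
    n <- sample(8:40, 1)
    seq <- paste(sample(c("E", "D", "K", "R", "G", "S"), n, TRUE), collapse = "")
    if (!any(strsplit(seq, "")[[1]] %in% c("E", "D", "K", "R"))) next
    ws <- sample(3:6, sample(1:2, 1))
    expect_equal(
      patterning_delta(seq, "neg", "pos", windows = ws),
      brute_delta(seq, g$neg, g$pos, ws),
      tolerance = 1e-12
    )
  }
})

test_that("segregated arrangements beat alternating ones for every composition (exhaustive, n <= 10)", {
  # pure two-letter case: the contiguous block arrangement attains the maximum
  arr <- all_arrangements(rep(c("E", "K"), each = 4))
  deltas <- vapply(arr, patterning_delta, numeric(1), x = "neg", y = "pos", windows = 5)
  expect_equal(unname(deltas["EEEEKKKK"]), max(deltas))
  expect_equal(unname(deltas["EKEKEKEK"]), min(deltas))

  # mixed compositions: contiguous blocks always >= interleaved charges
  for (comp in list(c(E = 3, K = 3, G = 2), c(E = 2, K = 4, G = 3), c(E = 2, K = 2, G = 5))) {
    residues <- rep(names(comp), comp)
    blocky <- paste(rep(names(comp), comp), collapse = "")
    inter <- c(rbind(
      rep("E", max(comp[c("E", "K")])),
      rep("K", max(comp[c("E", "K")]))
    ))[seq_len(comp[["E"]] + comp[["K"]])]
    alternating <- paste(c(inter, rep("G", comp[["G"]])), collapse = "")
    expect_gte(
      patterning_delta(blocky, "neg", "pos", windows = 5),
      patterning_delta(alternating, "neg", "pos", windows = 5)
    )
  }
})

test_that("composition is permutation invariant, patterning is not", {
  set.seed(3)
  seq <- paste(c(rep("E", 8), rep("K", 8), rep("G", 14)), collapse = "")
  shuf <- paste(sample(strsplit(seq, "")[[1]]), collapse = "")
  expect_equal(
    composition_features(seq)$value,
    composition_features(shuf)$value
  )
  expect_false(isTRUE(all.equal(
    patterning_delta(seq, "neg", "pos"),
    patterning_delta(shuf, "neg", "pos")
  )))
})

test_that("patterning z-score: degenerate homopolymer, blocky > 2, alternating < 0", {
  z_homo <- patterning_zscore(strrep("K", 30), "pos", "neg", n_shuffles = 100, seed = 1)
  expect_true(z_homo$degenerate)
  expect_equal(z_homo$z, 0)

  blocky <- paste0(strrep("E", 5), strrep("K", 5), strrep("G", 20))
  z_b <- patterning_zscore(blocky, "neg", "pos", n_shuffles = 2000, seed = 1)
  expect_gt(z_b$z, 2)

  alt <- strrep("EK", 20)
  z_a <- patterning_zscore(alt, "neg", "pos", n_shuffles = 2000, seed = 1)
  expect_lt(z_a$z, 0)
})

test_that("z of freshly shuffled sequences is centred on 0", {
  set.seed(99)
  seq_ch <- strsplit(paste0(strrep("E", 6), strrep("K", 6), strrep("G", 18)), "")[[1]]
  zs <- vapply(1:200, function(i) {
    s <- paste(sample(seq_ch), collapse = "")
    patterning_zscore(s, "neg", "pos", n_shuffles = 200, seed = i)$z
  }, numeric(1))
  expect_lt(abs(mean(zs)), 0.2)
})

test_that("background z-scores behave: zero at the mean, degenerate on identical IDRs", {
  bg <- build_background(tibble::tibble(sequence = c("EEKKGG", "EEGGKK", "GGEEKK", "KKGGEE")))
  z <- composition_zscores("EKGEKG", bg)
  expect_equal(z$z[z$feature == "ncpr"], 0)
  expect_equal(z$z[z$feature == "fcr"], 0)

  bg2 <- build_background(tibble::tibble(sequence = c("EEKKGG", "EEKKGG")))
  z2 <- composition_zscores("EEKKGG", bg2)
  expect_true(all(z2$degenerate))
  expect_error(build_background(tibble::tibble(sequence = "EEKK")), "at least 2")
})

test_that("background recovers a planted composition shift at the right z", {
  set.seed(21)
  n_bg <- 500
  len <- 100
  fracs <- pmin(pmax(rnorm(n_bg, 0.05, 0.01), 0), 0.3)
  seqs <- vapply(fracs, function(f) {
    k <- round(f * len)
    paste(sample(c(rep("E", k), rep("G", len - k))), collapse = "")
  }, character(1))
  bg <- build_background(tibble::tibble(sequence = seqs))
  query <- paste(c(rep("E", 7), rep("G", 93)), collapse = "")
  z <- composition_zscores(query, bg)
  expect_equal(z$z[z$feature == "frac_E"], 2.0, tolerance = 0.12)
})

test_that("grammar report assembles composition and patterning with the |z|>=1 mask", {
  set.seed(5)
  bg <- sim_idrome(40, length_range = c(40L, 80L), seed = 2)
  background <- build_background(bg)
  blocky <- paste0(strrep("E", 10), strrep("G", 20), strrep("K", 5), strrep("S", 10))
  idrs <- tibble::tibble(
    idr_id = c("blocky", "allG"),
    sequence = c(blocky, strrep("G", 45))
  )
  rep <- grammar_report(idrs, background, n_shuffles = 300, seed = 7)
  expect_s3_class(rep, "grammar_report")
  expect_equal(rep$display, !is.na(rep$z) & abs(rep$z) >= 1)

  blocky_rows <- rep[rep$idr_id == "blocky" & rep$feature == "pat_pos_neg", ]
  expect_true(blocky_rows$display)

  allg <- rep[rep$idr_id == "allG", ]
  expect_true(all(allg$z[allg$feature %in% c("frac_E", "frac_K", "fcr")] <= 0))
  expect_true(all(allg$degenerate[allg$type == "patterning"]))

  # composition z identical under shuffling, patterning z not
  shuf <- paste(sample(strsplit(blocky, "")[[1]]), collapse = "")
  rep2 <- grammar_report(
    tibble::tibble(idr_id = c("wt", "shuf"), sequence = c(blocky, shuf)),
    background,
    n_shuffles = 300, seed = 7
  )
  comp <- tidyr::pivot_wider(
    rep2[rep2$type == "composition", c("idr_id", "feature", "z")],
    names_from = "idr_id", values_from = "z"
  )
  expect_equal(comp$wt, comp$shuf)
  pat <- tidyr::pivot_wider(
    rep2[rep2$type == "patterning" & !is.na(rep2$z), c("idr_id", "feature", "z")],
    names_from = "idr_id", values_from = "z"
  )
  expect_false(isTRUE(all.equal(pat$wt, pat$shuf)))
})
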