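test_that("extended iGTGT-0 fragments carry the diagnostic glycerol-monoalkyl ions", {
  fr <- predict_fragments(d_ext_iGTGT0)
  expect_true(all(c("C28H58O3", "C23H48O3") %in%
                    fr$frag_formula[fr$kind == "chain_glycerol_ion"]))
  expect_equal(fr$mz[fr$frag_formula == "C28H58O3"], 443.445,
               tolerance = 0.005)
  expect_equal(fr$mz[fr$frag_formula == "C23H48O3"], 373.367,
               tolerance = 0.005)
  # phytane loss at printed m/z, 3 decimals
  expect_identical(round_mz(fr$mz[fr$annotation == "[M-C20H40+H]+"]), 1094.104)
  # combined phytane + glycerol loss
  expect_equal(fr$mz[fr$annotation == "[M-C23H48O3+H]+"], 1002.055,
               tolerance = 0.005)
})

test_that("extended iGDGT-0 fragments show both bridging-chain losses", {
  fr <- predict_fragments(d_ext_iGDGT0)
  c40 <- fr[fr$annotation == "[M-C40H78+H]+", ]
  expect_identical(c40$frag_formula, "C51H104O6")
  expect_equal(c40$mz, 813.792, tolerance = 0.005)
  expect_equal(fr$mz[fr$annotation == "[M-C45H88+H]+"], 743.713,
               tolerance = 0.005)
})

test_that("di-extended iGTGT-0 lacks the glycerol-phytanyl ion", {
  fr <- predict_fragments(d_diext_iGTGT0)
  expect_false("C23H48O3" %in% fr$frag_formula)
  expect_true("C28H58O3" %in% fr$frag_formula)
  expect_equal(fr$mz[fr$frag_formula == "C28H58O3"], 443.445,
               tolerance = 0.005)
})

test_that("glycosidic lipids lose the hexose head group to a protonated ion", {
  fr1 <- predict_fragments(d_1G_ext_iGTGT0, adduct = "+NH4")
  hg <- fr1[fr1$kind == "headgroup_loss", ]
  expect_identical(hg$annotation, "[M-C6H10O5+H]+")
  expect_identical(hg$frag_formula, "C91H184O6")
  expect_equal(hg$mz, 1374.414, tolerance = 0.005)

  fr2 <- predict_fragments(d_1G_diext_iGTGT0, adduct = "+NH4")
  expect_equal(fr2$mz[fr2$kind == "headgroup_loss"], 1444.499,
               tolerance = 0.005)
})

test_that("symmetric lipids collapse equivalent chain losses", {
  fr <- predict_fragments(d_iGDGT0)
  expect_identical(sum(fr$kind == "chain_loss"), 1L)
  expect_identical(fr$annotation[fr$kind == "chain_loss"], "[M-C40H78+H]+")
  expect_error(predict_fragments(d_iGDGT0, adduct = "+Na"), "\\+H and \\+NH4")
})

test_that("every fragment conserves elements and sits below the precursor", {
  lib <- default_library()
  for (i in seq_len(nrow(lib))) {
    d <- lib$descriptor[[i]]
    M <- build_formula(d)
    for (adduct in c("+H", "+NH4")) {
      fr <- predict_fragments(d, adduct)
      prec <- fr$mz[fr$kind == "precursor"]
      expect_true(all(fr$mz <= prec + 1e-9), label = lib$name[i])
      for (j in seq_len(nrow(fr))) {
        recon <- formula_add(parse_formula(fr$frag_formula[j]),
                             parse_formula(fr$loss_formula[j]))
        expect_identical(format_formula(recon), format_formula(M),
                         label = paste(lib$name[i], fr$annotation[j]))
      }
    }
  }
})

test_that("spectrum matching finds diagnostic peaks within tolerance", {
  fr <- predict_fragments(d_ext_iGTGT0)
  spec <- tibble::tibble(mz = c(373.368, 443.446), intensity = c(50, 100))
  m <- match_spectrum(spec, fr, tol_ppm = 10)
  expect_setequal(m$frag_formula, c("C23H48O3", "C28H58O3"))
  expect_true(all(abs(m$ppm) < 10))

  expect_identical(nrow(match_spectrum(spec[0, ], fr)), 0L)

  displaced <- tibble::tibble(mz = 443.445 * (1 + 50e-6), intensity = 1)
  m2 <- match_spectrum(displaced, fr, tol_ppm = 10, tol_da = 0)
  expect_identical(nrow(m2), 0L)
})

test_that("fragment scoring weights diagnostic ions double", {
  frags <- tibble::tibble(
    kind = c("chain_glycerol_ion", "chain_glycerol_ion", "water_loss",
             "glycerol_loss", "combined_loss", "precursor"),
    annotation = paste0("a", 1:6),
    mz = 1:6
  )
  all_matched <- frags
  expect_identical(fragment_score(all_matched, frags), 1)
  expect_identical(fragment_score(frags[0, ], frags), 0)
  # two weight-2 ions matched out of 2x2 + 4x1 = 8 total weight
  expect_identical(fragment_score(frags[1:2, ], frags), 0.5)
  expect_error(fragment_score(frags, frags[0, ]), "empty")
})

test_that("score is monotone as peaks are added", {
  fr <- predict_fragments(d_ext_iGTGT0)
  scores <- vapply(seq_len(nrow(fr)), function(k) {
    spec <- tibble::tibble(mz = fr$mz[seq_len(k)], intensity = 1)
    fragment_score(match_spectrum(spec, fr), fr)
  }, numeric(1))
  expect_true(all(diff(scores) >= 0))
  expect_identical(scores[length(scores)], 1)
})
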