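lib <- default_library()

test_that("feature annotation matches within tolerance and ranks by ppm", {
  feats <- tibble::tibble(
    feature_id = c("F1", "F2", "F3"),
    mz = c(1302.326, 1000.000, adduct_mz("C86H172O6", "+H"))
  )
  hits <- annotate_features(feats, lib, tol_ppm = 5)
  f1 <- hits[hits$feature_id == "F1", ]
  expect_identical(f1$name, "iGDGT-0")
  expect_identical(f1$adduct, "+H")
  expect_gt(f1$ppm, 2); expect_lt(f1$ppm, 3)
  expect_false("F2" %in% hits$feature_id)
  f3 <- hits[hits$feature_id == "F3", ]
  expect_identical(f3$ppm[f3$rank == 1], 0)
  expect_error(annotate_features(feats, lib[0, ]), "non-empty")
})

test_that("the printed three-member ladder is found as one increasing C5H10 series", {
  feats <- tibble::tibble(
    feature_id = c("A", "B", "C"),
    mz = c(1304.339, 1374.416, 1444.495),
    rt_min = c(24.4, 25.3, 26.3)
  )
  s <- detect_series(feats, unit = "C5H10", tol_ppm = 15,
                     rt_direction = "increasing")
  expect_identical(nrow(s), 1L)
  expect_identical(s$members[[1]], c("A", "B", "C"))
  expect_true(s$strong)

  s_dec <- detect_series(feats, rt_direction = "decreasing")
  expect_identical(nrow(s_dec), 0L)

  expect_identical(nrow(detect_series(feats[0, ])), 0L)
})

test_that("series output is invariant under row permutation", {
  withr::with_seed(5, {
    feats <- tibble::tibble(
      feature_id = sprintf("F%02d", 1:8),
      mz = c(1304.339, 1374.416, 1444.495, 900.1, 1234.5, 800.0,
             800 + monoisotopic_mass("C5H10"), 1510.0),
      rt_min = c(24.4, 25.3, 26.3, 10, 12, 8, 9, 30)
    )
    ref <- detect_series(feats)
    for (i in 1:5) {
      perm <- feats[sample(nrow(feats)), ]
      got <- detect_series(perm)
      expect_identical(
        sort(vapply(got$members, paste, "", collapse = ">")),
        sort(vapply(ref$members, paste, "", collapse = ">"))
      )
    }
  })
})

test_that("series detection agrees with the brute-force oracle", {
  unit_mass <- monoisotopic_mass("C5H10")
  withr::with_seed(99, {
    for (rep in 1:15) {
      n_chain <- sample(2:4, 1)
      chain_mz <- 1000 + cumsum(c(0, rep(unit_mass, n_chain - 1))) *
        (1 + rnorm(n_chain, 0, 3e-6))
      n_rand <- sample(3:10, 1)
      feats <- tibble::tibble(
        feature_id = sprintf("F%02d", seq_len(n_chain + n_rand)),
        mz = c(chain_mz, runif(n_rand, 600, 1600)),
        rt_min = c(sort(runif(n_chain, 20, 25)), runif(n_rand, 5, 30))
      )
      got <- detect_series(feats, tol_ppm = 15, rt_direction = "increasing")
      want <- oracle_series(feats, tol_ppm = 15, rt_direction = "increasing")
      expect_setequal(
        vapply(got$members, paste, "", collapse = ">"),
        vapply(want, paste, "", collapse = ">")
      )
    }
  })
})

test_that("the H2 partner classifies a series root as GTGT or GDGT", {
  feats <- tibble::tibble(
    feature_id = c("A", "B", "C", "P"),
    mz = c(1304.339, 1374.416, 1444.495, 1302.326),
    rt_min = c(24.4, 25.3, 26.3, 24.3)
  )
  s <- detect_series(feats)
  expect_identical(series_class_hypothesis(s[1, ], feats), "GTGT-series")

  no_partner <- feats[feats$feature_id != "P", ]
  s2 <- detect_series(no_partner)
  expect_identical(series_class_hypothesis(s2[1, ], no_partner), "unknown")

  off <- feats
  off$mz[off$feature_id == "P"] <- 1304.339 - 2.10
  s3 <- detect_series(off)
  expect_identical(series_class_hypothesis(s3[1, ], off), "unknown")

  above <- feats
  above$mz[above$feature_id == "P"] <- 1304.339 + monoisotopic_mass("H2")
  s4 <- detect_series(above)
  expect_identical(series_class_hypothesis(s4[1, ], above), "GDGT-series")
})

test_that("a noise-free library round trip is recovered exactly", {
  mix <- tibble::tibble(name = lib$name, pct = 100 / nrow(lib))
  feats <- generate_features(mix, seed = 1, mass_sigma_ppm = 0,
                             library = lib)
  hits <- annotate_features(feats, lib, tol_ppm = 5) |>
    dplyr::filter(rank == 1)
  expect_identical(nrow(hits), nrow(feats))
  expect_identical(hits$name, hits$true_name)
  expect_identical(hits$adduct, hits$true_adduct)
  expect_true(all(abs(hits$ppm) < 1e-9))
})

test_that("1 ppm mass noise preserves recovery at 5 ppm tolerance", {
  mix <- tibble::tibble(name = lib$name, pct = 100 / nrow(lib))
  feats <- generate_features(mix, seed = 424, mass_sigma_ppm = 1,
                             library = lib)
  hits <- annotate_features(feats, lib, tol_ppm = 5) |>
    dplyr::filter(rank == 1)
  recovered <- mean(feats$feature_id %in%
                      hits$feature_id[hits$name == hits$true_name])
  expect_gte(recovered, 0.99)
})
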