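# Descriptors used across tests.

d_iGDGT0       <- lipid_descriptor("GDGT", bridges = c(40, 40))
d_iGTGT0       <- lipid_descriptor("GTGT", bridges = 40, pendants = c(20, 20))
d_ext_iGTGT0   <- lipid_descriptor("GTGT", bridges = 40, pendants = c(20, 25))
d_diext_iGTGT0 <- lipid_descriptor("GTGT", bridges = 40, pendants = c(25, 25))
d_ext_iGDGT0   <- lipid_descriptor("GDGT", bridges = c(40, 45))
d_diext_iGDGT0 <- lipid_descriptor("GDGT", bridges = c(40, 50))
d_1G_ext_iGTGT0 <- lipid_descriptor("GTGT", bridges = 40,
                                    pendants = c(20, 25), hexoses = 1)
d_1G_diext_iGTGT0 <- lipid_descriptor("GTGT", bridges = 40,
                                      pendants = c(25, 25), hexoses = 1)
d_AR <- lipid_descriptor("AR", pendants = c(20, 20))

# random valid Hill formula over the supported elements
random_formula <- function() {
  elems <- sample(names(ATOMIC_MASSES), sample(1:5, 1))
  counts <- sample(1:120, length(elems), replace = TRUE)
  stats::setNames(as.integer(counts), elems)
}

# Brute-force homolog-series oracle: enumerate every m/z-ordered feature
# subset up to `max_len`, keep those whose consecutive steps satisfy the
# repeat-unit and retention-time definition, then keep only chains that no
# single feature can extend at either end. Independent of detect_series();
# the step test is written straight from the definition, evaluated for all
# ordered pairs at once so full subset enumeration stays fast.
oracle_series <- function(features, unit = "C5H10", tol_ppm = 15,
                          rt_direction = "increasing", max_len = 5) {
  f <- features[order(features$mz), ]
  n <- nrow(f)
  if (n < 2) return(list())
  umass <- monoisotopic_mass(unit)
  dmz <- outer(f$mz, f$mz, function(a, b) b - a)       # [i, j] = mz_j - mz_i
  tol <- tol_ppm * 1e-6 * matrix(f$mz, n, n, byrow = TRUE)
  rt_ok <- if (rt_direction == "increasing") {
    outer(f$rt_min, f$rt_min, "<")
  } else {
    outer(f$rt_min, f$rt_min, ">")
  }
  S <- abs(dmz - umass) <= tol & rt_ok                 # valid step i -> j

  valid <- list()
  for (k in 2:min(max_len, n)) {
    cols <- utils::combn(n, k)
    ok <- rep(TRUE, ncol(cols))
    for (r in seq_len(k - 1)) {
      ok <- ok & S[cbind(cols[r, ], cols[r + 1, ])]
    }
    for (c in which(ok)) valid[[length(valid) + 1L]] <- cols[, c]
  }
  maximal <- Filter(function(idx) {
    !(any(S[, idx[1]]) || any(S[idx[length(idx)], ]))
  }, valid)
  lapply(maximal, function(idx) f$feature_id[idx])
}
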