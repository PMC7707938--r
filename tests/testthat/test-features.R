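make_trial <- function(nch = 4, n = 600, fs = 1000, label = "open", seed = 1) {
  set.seed(seed)
  emg_trial(matrix(rnorm(nch * n), nrow = nch), fs = fs, label = label)
}

test_that("WWPE features have channels x bands layout", {
  tr <- make_trial()
  v <- wwpe_features(tr)
  expect_length(v, 20)
  expect_equal(names(v)[1:5],
               c("ch1_a4_wpe", "ch1_d4_wpe", "ch1_d3_wpe", "ch1_d2_wpe", "ch1_d1_wpe"))
  expect_true(all(is.finite(v)))

  v1 <- wwpe_features(make_trial(nch = 1))
  expect_length(v1, 5)

  pe <- wwpe_features(tr, feature_spec("wavelet_pe"))
  expect_length(pe, 20)
  expect_equal(names(pe)[1], "ch1_a4_pe")
  expect_false(identical(unname(pe), unname(v)))
})

test_that("a constant trial yields all-zero sub-band entropies", {
  tr <- emg_trial(matrix(2, nrow = 4, ncol = 600), fs = 1000, label = "open")
  v <- suppressWarnings(wwpe_features(tr))
  expect_equal(unname(v), rep(0, 20))
})

test_that("single-band features give one entropy per channel", {
  tr <- make_trial()
  v <- subband_entropy_features(tr, "d3")
  expect_length(v, 4)
  expect_equal(names(v), paste0("ch", 1:4, "_d3_wpe"))
  # unweighted flag dispatches to plain PE
  vpe <- subband_entropy_features(tr, "d3", weighted = FALSE)
  expect_equal(names(vpe), paste0("ch", 1:4, "_d3_pe"))
  expect_false(identical(unname(vpe), unname(v)))
  # identical channels give identical entropies
  x <- rnorm(600)
  same <- emg_trial(rbind(x, x, x, x), fs = 1000, label = "open")
  vs <- subband_entropy_features(same, "d2")
  expect_equal(max(vs) - min(vs), 0)
  expect_error(subband_entropy_features(tr, "d7"), "valid bands")
})

test_that("raw entropy features skip the decomposition", {
  tr <- make_trial()
  v <- raw_entropy_features(tr, weighted = FALSE)
  expect_length(v, 4)
  expect_equal(unname(v),
               vapply(1:4, function(ch) permutation_entropy(tr$data[ch, ]), numeric(1)))
  ramps <- emg_trial(rbind(1:300, 2 * (1:300), -(1:300), 300:1),
                     fs = 1000, label = "open")
  expect_equal(unname(raw_entropy_features(ramps, weighted = FALSE)), rep(0, 4))
})

test_that("time-domain features follow the classical definitions", {
  tr3 <- emg_trial(matrix(c(1, 3, 2), nrow = 1), fs = 1000, label = "open")
  v <- time_domain_features(tr3)
  expect_equal(v[["ch1_wl"]], 3)
  const <- emg_trial(matrix(-2.5, nrow = 1, ncol = 10), fs = 1000, label = "open")
  vc <- time_domain_features(const)
  expect_equal(unname(vc), c(2.5, 2.5, 0, 0, 0))
  alt <- emg_trial(matrix(c(1, -1, 1, -1), nrow = 1), fs = 1000, label = "open")
  expect_equal(time_domain_features(alt)[["ch1_zc"]], 3)
  expect_length(time_domain_features(make_trial()), 20)
  # thresholds suppress small crossings
  tiny <- emg_trial(matrix(c(0.1, -0.1, 0.1, -0.1), nrow = 1), fs = 1000, label = "open")
  expect_equal(time_domain_features(tiny, zc_threshold = 0.5)[["ch1_zc"]], 0)
})

test_that("feature spec validates band requirements", {
  expect_error(feature_spec("subband_wpe"), "requires a `band`")
  expect_error(feature_spec("wwpe", band = "d3"), "only meaningful")
  expect_error(feature_spec("subband_pe", band = "d9"), "valid bands")
})

test_that("feature matrices carry labels and deterministic columns", {
  ds <- generate_dataset(small_config())
  fm <- build_feature_matrix(ds, feature_spec("wwpe"))
  expect_equal(dim(fm$values), c(14, 20))
  expect_equal(nlevels(fm$labels), 7)
  expect_false(anyNA(fm$values))
  fm2 <- build_feature_matrix(ds, feature_spec("wwpe"))
  expect_identical(fm$values, fm2$values)  # bit-identical rerun
  sub <- build_feature_matrix(ds, feature_spec("subband_wpe", band = "d3"))
  expect_equal(ncol(sub$values), 4)
  td <- build_feature_matrix(ds, feature_spec("time_domain"))
  expect_equal(ncol(td$values), 20)
  expect_error(build_feature_matrix(list(), feature_spec("wwpe")), "no trials")
  mixed <- list(ds$trials[[1]],
                emg_trial(matrix(rnorm(2 * 600), 2), fs = 1000, label = "open"))
  expect_error(build_feature_matrix(mixed, feature_spec("wwpe")), "heterogeneous")
})

test_that("entropy features are amplitude invariant, time-domain scale", {
  tr <- make_trial()
  scaled <- tr
  scaled$data <- 3.7 * tr$data
  expect_equal(wwpe_features(scaled), wwpe_features(tr), tolerance = 1e-10)
  td <- time_domain_features(tr)
  tds <- time_domain_features(scaled)
  amp <- c("rms", "mav", "wl")
  for (ch in paste0("ch", 1:4)) {
    expect_equal(tds[paste(ch, amp, sep = "_")],
                 3.7 * td[paste(ch, amp, sep = "_")], tolerance = 1e-12)
  }
})
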