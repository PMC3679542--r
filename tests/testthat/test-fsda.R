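test_that("wedge masks are a Hermitian partition of unity", {
  bins <- velocity_bins(v_min = 0.2)
  for (shape in list(c(64, 48), c(33, 47), c(8, 8))) {
    masks <- build_masks(bins, shape, 0.106, 0.2)
    total <- Reduce(`+`, masks)
    expect_true(all(abs(total - 1) < 1e-12))
    # Hermitian: mask at index k equals mask at index (n - k) mod n
    n_t <- shape[1]; n_s <- shape[2]
    for (m in masks) {
      conj_idx_r <- c(1L, rev(seq_len(n_t - 1L) + 1L))
      conj_idx_c <- c(1L, rev(seq_len(n_s - 1L) + 1L))
      expect_true(max(abs(m - m[conj_idx_r, conj_idx_c])) < 1e-12)
    }
  }
  expect_error(build_masks(bins, c(4, 4), 0.106, 0.2), ">= 8")
})

test_that("hard-edged masks assign pure slope frequencies to their bins", {
  bins <- velocity_bins(v_min = 0.2, softness = 0)
  masks <- build_masks(bins, c(64, 64), 0.106, 0.2)
  f_t <- iftmotion:::fft_freq(64, 0.2)
  f_s <- iftmotion:::fft_freq(64, 0.106)
  # every non-Nyquist grid frequency whose implied velocity -f_t / f_s sits
  # firmly inside a wedge belongs to that wedge's mask entirely
  hits <- 0L
  for (i in c(2:32, 34:64)) {   # skip DC and the Nyquist row/column
    for (j in c(2:32, 34:64)) {
      v <- -f_t[i] / f_s[j]
      if (v > 1 && v < 4) {
        expect_equal(masks$anterograde[i, j], 1)
        expect_equal(masks$retrograde[i, j], 0)
        hits <- hits + 1L
      } else if (v < -1 && v > -4) {
        expect_equal(masks$retrograde[i, j], 1)
        hits <- hits + 1L
      }
    }
  }
  expect_gt(hits, 50)
})

test_that("FSDA reconstruction is exact and energy fractions sum to one", {
  k <- make_ridge_kymo(c(2, -3, 0), s0 = c(1, 8, 5), noise_sd = 5)
  res <- fsda_decompose(k)
  recon <- Reduce(`+`, lapply(res$components, unclass))
  err <- max(abs(recon - unclass(res$windowed_input))) / diff(range(k))
  expect_lt(err, 1e-6)
  expect_equal(sum(res$energy$fraction), 1, tolerance = 1e-9)
  # components are real with negligible imaginary residue by construction:
  # verify directly on the masked spectrum
  Z <- stats::fft(unclass(res$windowed_input))
  masks <- build_masks(res$bins, dim(k), 0.106, 0.2)
  comp <- stats::fft(Z * masks$anterograde, inverse = TRUE) / length(Z)
  expect_lt(max(abs(Im(comp))) / diff(range(k)), 1e-9)
})

test_that("a single anterograde ridge concentrates its energy in that bin", {
  # ridge spans the kymograph corner to corner (10 um at 2 um/s in 5 s),
  # sampled fast enough that the moving profile is not temporally aliased
  k <- make_ridge_kymo(2, s0 = 0.2, n_t = 50, frame_interval = 0.1)
  res <- fsda_decompose(k)
  en <- res$energy
  non_dc <- en$fraction[en$bin != "background"]
  frac_ant <- en$fraction[en$bin == "anterograde"] / sum(non_dc)
  expect_gt(frac_ant, 0.90)
})

test_that("zero input decomposes to zero components and all-background labels", {
  k <- kymograph(matrix(0, 40, 40), 0.106, 0.2)
  res <- fsda_decompose(k)
  for (comp in res$components) expect_true(all(unclass(comp) == 0))
  vm <- velocity_colormap(k)
  expect_true(all(attr(vm, "labels")[as.vector(unclass(vm))] == "background"))
  expect_error(fsda_decompose(kymograph(matrix(NaN, 9, 9), 0.1, 0.2)),
               "non-finite")
})

test_that("a paused ridge survives in the pause component at its position", {
  paused_um <- 6
  k <- make_ridge_kymo(c(2, 0), s0 = c(0.5, paused_um))
  res <- fsda_decompose(k)
  prof <- colMeans(abs(unclass(res$components$paused)))
  peak_um <- (which.max(prof) - 1) * 0.106
  expect_lt(abs(peak_um - paused_um), 0.3)
})

test_that("velocity pseudo-coloring labels ridges by their direction", {
  k <- make_ridge_kymo(2, s0 = 0.5)
  vm <- velocity_colormap(k)
  labs <- attr(vm, "labels")
  tt <- (seq_len(nrow(k)) - 1) * 0.2
  ridge_cols <- round((0.5 + 2 * tt) / 0.106) + 1
  on_ridge <- ridge_cols >= 3 & ridge_cols <= ncol(k) - 2
  got <- labs[unclass(vm)[cbind(which(on_ridge), ridge_cols[on_ridge])]]
  expect_gt(mean(got == "anterograde"), 0.9)

  # two crossing ridges keep their own labels away from the crossing
  k2 <- make_ridge_kymo(c(2, -2), s0 = c(0, 10))
  vm2 <- velocity_colormap(k2)
  labs2 <- attr(vm2, "labels")
  a_cols <- round((0 + 2 * tt) / 0.106) + 1
  r_cols <- round((10 - 2 * tt) / 0.106) + 1
  away <- abs(a_cols - r_cols) > 12 & a_cols >= 3 & a_cols <= ncol(k2) - 2 &
    r_cols >= 3 & r_cols <= ncol(k2) - 2
  got_a <- labs2[unclass(vm2)[cbind(which(away), a_cols[away])]]
  got_r <- labs2[unclass(vm2)[cbind(which(away), r_cols[away])]]
  expect_gt(mean(got_a == "anterograde"), 0.9)
  expect_gt(mean(got_r == "retrograde"), 0.9)
})

test_that("track extraction fits ridge velocities and honours thresholds", {
  # one noiseless ridge at 2.96 um/s
  k <- make_ridge_kymo(2.96, s0 = 0.2, n_t = 30)
  tr <- extract_tracks(k, threshold = 10)
  expect_equal(nrow(tr), 1L)
  expect_equal(tr$velocity, 2.96, tolerance = 0.05 / 2.96)

  # two parallel ridges separated by more than the gate
  k2 <- make_ridge_kymo(c(1, 1), s0 = c(0.5, 6), n_t = 30)
  tr2 <- extract_tracks(k2, threshold = 10)
  expect_equal(nrow(tr2), 2L)

  # a ridge shorter than min_duration is discarded
  k3 <- make_ridge_kymo(2, s0 = 4, t0 = 2, n_t = 60)
  K3 <- unclass(k3)
  K3[-(11:12), ] <- 0   # keep two frames only
  tr3 <- extract_tracks(kymograph(K3, 0.106, 0.2), threshold = 10,
                        min_duration = 0.6)
  expect_equal(nrow(tr3), 0L)
  expect_error(extract_tracks(kymograph(matrix(numeric(0), 0, 0), 0.1, 0.1)),
               "Empty")
})

test_that("overlapping or invalid bins are rejected", {
  expect_error(velocity_bins(breaks = c(-Inf, 1, 0.5, Inf)), "increasing")
  expect_error(velocity_bins(breaks = c(-1, 0, 1)), "increasing|Inf")
  expect_error(velocity_bins(v_min = 0), "v_min")
})
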