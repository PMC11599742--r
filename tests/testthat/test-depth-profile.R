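flat_frame <- function(lower = -15, upper = 15) {
  assign_frame(
    build_scene(scene_spec(seed = 1L))$structure,
    boundaries = c(lower, upper), normal = c(0, 0, 1))
}

test_that("histogram counts are conserved and concentrated correctly", {
  f <- flat_frame()
  h <- depth_histogram(rep(0, 37), f, bin_width = 2)
  expect_identical(sum(h$counts), 37L)
  expect_identical(h$n_total, 37L)
  nz <- which(h$counts > 0)
  expect_length(nz, 1L)
  expect_equal(h$bin_centers[nz], 0)
  # depths outside the boundaries are excluded, not an error
  h2 <- depth_histogram(c(0, 99, -99), f, bin_width = 2)
  expect_identical(h2$n_total, 1L)
  # empty input gives an all-zero histogram
  h3 <- depth_histogram(numeric(0), f, bin_width = 2)
  expect_true(all(h3$counts == 0L))
  expect_length(h3$modes, 0L)
})

test_that("histograms are equivariant under shifting the z-origin", {
  f <- flat_frame()  # boundaries [-15, 15], 15 bins of 2 A
  set.seed(9)
  depths <- pmin(9, pmax(-9, stats::rnorm(500, 0, 4)))
  h <- depth_histogram(depths, f, bin_width = 2)
  # shift the origin by exactly one bin: every atom's depth drops by the
  # shift, and its bin assignment moves down by exactly one bin
  f2 <- f
  f2$z_origin <- f2$z_origin + 2
  h2 <- depth_histogram(depths - 2, f2, bin_width = 2)
  expect_identical(h2$counts[1:14], h$counts[2:15])
  expect_identical(h2$n_total, h$n_total)
  # a sub-bin shift moves every admitted depth consistently: recomputing
  # with depths expressed in the shifted frame reproduces the assignment
  delta <- 1.3
  f3 <- f
  f3$z_origin <- f3$z_origin + delta
  bin_of <- function(d, fr) {
    floor((d - fr$z_lower) / 2)
  }
  expect_identical(bin_of(depths - delta, f3) - bin_of(depths, f),
                   ifelse((depths - f$z_lower) %% 2 < delta %% 2, -1, 0))
})

test_that("mode detection matches an exhaustive local-maximum oracle", {
  # oracle: strict local maxima of the smoothed counts, plateaus to the
  # lower depth, zero-level maxima excluded
  mode_oracle <- function(counts, w) {
    n <- length(counts)
    h <- (w - 1) %/% 2
    s <- sapply(seq_len(n), function(i) mean(counts[max(1, i - h):min(n, i + h)]))
    out <- integer(0)
    for (i in seq_len(n)) {
      if (s[i] <= 0) next
      left <- if (i == 1) -Inf else s[i - 1]
      right <- if (i == n) -Inf else s[i + 1]
      if (left < s[i] && right <= s[i]) {
        # ensure the plateau eventually falls off on the right
        j <- i
        while (j < n && s[j + 1] == s[i]) j <- j + 1
        if ((j == n || s[j + 1] < s[i]) && (i == 1 || s[i - 1] < s[i])) {
          out <- c(out, i)
        }
      }
    }
    out
  }
  f <- flat_frame()
  make_h <- function(counts) {
    h <- depth_histogram(numeric(0), f, bin_width = 2)
    h$counts <- counts
    h$n_total <- sum(counts)
    h
  }
  cases <- list(
    c(0, 0, 9, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0),       # single spike
    c(0, 7, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 7, 0),       # symmetric twins
    c(0, 3, 3, 3, 0, 0, 0, 0, 5, 0, 0, 2, 2, 0, 0),       # plateaus
    c(1, 2, 3, 4, 5, 4, 3, 2, 1, 2, 3, 2, 1, 0, 0),       # two bumps
    rep(0L, 15))                                           # empty
  for (counts in cases) {
    h <- make_h(counts)
    for (w in c(1L, 3L)) {
      got <- detect_modes(h, smoothing_window = w)
      expect_equal(got, h$bin_centers[mode_oracle(counts, w)])
    }
  }
  # symmetric twin spikes give modes symmetric about zero
  tw <- detect_modes(make_h(cases[[2]]), smoothing_window = 1L)
  expect_length(tw, 2L)
  expect_equal(sum(tw), 0)
  # smoothing removes a spurious single-bin dip-maximum
  jag <- make_h(c(0, 0, 4, 9, 5, 8, 9, 4, 0, 0, 0, 0, 0, 0, 0))
  expect_gt(length(detect_modes(jag, smoothing_window = 1L)),
            length(detect_modes(jag, smoothing_window = 3L)))
  expect_length(detect_modes(jag, smoothing_window = 3L), 1L)
})

test_that("bimodal depth mixtures are recovered within one bin width", {
  set.seed(77)
  f <- flat_frame(-16, 16)
  depths <- c(stats::rnorm(1000, -10, 3), stats::rnorm(1000, 10, 3))
  h <- depth_histogram(depths, f, bin_width = 2)
  expect_length(h$modes, 2L)
  expect_lt(abs(h$modes[1] - (-10)), 2)
  expect_lt(abs(h$modes[2] - 10), 2)
})

test_that("proximal lipid atoms honour proximity, element, and boundary rules", {
  scene <- build_scene(scene_spec(
    seed = 23L, boundaries = c(-8, 8),
    lipids = list(list(class = "linear_acyl", location = "peripheral",
                       d0 = 4.0),
                  list(class = "linear_acyl", location = "peripheral",
                       d0 = 12.0))))
  prox <- proximal_lipid_atoms(scene$structure, scene$frame,
                               proximity_cutoff = 5)
  near_resno <- scene$truth$lipids$resno[scene$truth$lipids$d0_target == 4]
  far_resno <- scene$truth$lipids$resno[scene$truth$lipids$d0_target == 12]
  expect_true(all(prox$resno == near_resno))
  expect_false(any(prox$resno == far_resno))
  expect_true(all(prox$element == "C"))
  # the 16-carbon chain spans beyond the +-8 A belt: out-of-slab carbons
  # are excluded even though they are proximal
  lip_all <- scene_residue(scene, near_resno)
  expect_lt(nrow(prox), nrow(lip_all))
  expect_true(all(prox$depth >= scene$frame$z_lower &
                    prox$depth <= scene$frame$z_upper))
})

test_that("noble-gas scenes show the planted trimodal depth profile", {
  scene <- build_scene(scene_spec(
    seed = 29L,
    gas = list(weights = c(1, 1, 1) / 3, means = c(-10, 0, 10),
               sds = c(2, 2, 2), n = 3000)))
  gas <- scene$structure$atoms[scene$structure$atoms$resname == "AR", ]
  h <- depth_histogram(depths_of(gas, scene$frame), scene$frame,
                       bin_width = 2)
  expect_length(h$modes, 3L)
  expect_true(all(abs(sort(h$modes) - c(-10, 0, 10)) <= 2))
})
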