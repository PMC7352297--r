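# Micrograph synthesis and TH quantification.

test_that("optical density definition: uniform and tenfold-dimmed fields", {
  u <- matrix(200, 64, 64)
  expect_equal(as.numeric(striatal_optical_density(u)), 0)
  dim10 <- matrix(20, 64, 64)
  expect_equal(as.numeric(striatal_optical_density(dim10, background = 200)), 1)
})

test_that("saturated-black pixels are clipped at the OD ceiling and counted", {
  m <- matrix(200, 32, 32)
  m[1:4, 1:4] <- 0
  od <- striatal_optical_density(m, background = 200, od_ceiling = 3)
  expect_identical(attr(od, "n_clipped"), 16L)
  expect_lte(as.numeric(od), 3)
})

test_that("OD is additive under stacked absorbing layers", {
  bg <- 240
  a1 <- matrix(0.2, 48, 48); a2 <- matrix(0.35, 48, 48)
  i1 <- bg * 10^-a1
  i12 <- bg * 10^-(a1 + a2)
  od1 <- as.numeric(striatal_optical_density(i1, background = bg))
  od12 <- as.numeric(striatal_optical_density(i12, background = bg))
  od2 <- as.numeric(striatal_optical_density(bg * 10^-a2, background = bg))
  expect_equal(od12, od1 + od2, tolerance = 1e-10)
})

test_that("blank and empty images count zero nuclei", {
  blank <- matrix(220, 128, 128)
  expect_identical(as.integer(count_th_nuclei(blank)), 0L)
  noisy <- synthesize_histo_image(histo_image_params(
    region = "snc", n_nuclei = 0, image_size = 128, seed = 2))
  expect_identical(as.integer(count_th_nuclei(noisy)), 0L)
})

test_that("well-separated synthetic disks are counted exactly", {
  img <- synthesize_histo_image(histo_image_params(
    region = "snc", n_nuclei = 10, image_size = 128, seed = 3))
  expect_identical(as.integer(count_th_nuclei(img)), 10L)
  img2 <- synthesize_histo_image(histo_image_params(
    region = "snc", n_nuclei = 150, image_size = 384, seed = 4))
  expect_identical(as.integer(count_th_nuclei(img2)), 150L)
})

test_that("counting is 8-connected and respects the area filter", {
  m <- matrix(220, 32, 32)
  m[10:13, 10:13] <- 50          # 16-px object
  m[14, 14] <- 50                # diagonal neighbour joins it
  m[25, 25] <- 50                # isolated single pixel, below min area
  cnt <- count_th_nuclei(m, counting_params(min_object_area = 8))
  expect_identical(as.integer(cnt), 1L)
  cnt2 <- count_th_nuclei(m, counting_params(min_object_area = 1))
  expect_identical(as.integer(cnt2), 2L)
})

test_that("counting is invariant to threshold-preserving brightness shifts", {
  img <- synthesize_histo_image(histo_image_params(
    region = "snc", n_nuclei = 25, image_size = 192, seed = 5))
  base <- as.integer(count_th_nuclei(img))
  for (shift in c(-15, 10, 25)) {
    shifted <- pmin(pmax(unclass(img) + shift, 0), 255)
    expect_identical(as.integer(count_th_nuclei(shifted)), base)
  }
})

test_that("overcrowded placement errors after bounded retries", {
  expect_error(synthesize_histo_image(histo_image_params(
    region = "snc", n_nuclei = 500, nucleus_radius_px = 6,
    image_size = 64, seed = 1)), "place|fit")
})

test_that("percent reduction arithmetic and degenerate control", {
  expect_equal(as.numeric(percent_reduction(50, 100)), 50)
  expect_equal(as.numeric(percent_reduction(4:8, 4:8)), 0)
  expect_error(percent_reduction(1:3, c(-1, 0, 1)), "control mean")
})

test_that("striatal densitometry recovers a 25% fiber deficit", {
  od_c <- numeric(5); od_l <- numeric(5)
  for (s in 1:5) {
    ic <- synthesize_histo_image(histo_image_params(
      region = "striatum", fiber_density = 1, image_size = 256,
      seed = 100 + s))
    il <- synthesize_histo_image(histo_image_params(
      region = "striatum", fiber_density = 0.75, image_size = 256,
      seed = 200 + s))
    od_c[s] <- striatal_optical_density(ic)
    od_l[s] <- striatal_optical_density(il)
  }
  red <- as.numeric(percent_reduction(od_l, od_c))
  expect_lt(abs(red - 25), 3)
})
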