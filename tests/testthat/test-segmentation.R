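test_that("well-separated bright disks are recovered with high overlap", {
  sc <- make_scene(scene_spec(shape = c(96, 96), n_cells = 10,
                              radius_range = c(4, 6), seed = 23))
  imgs <- render_reporter_images(sc, noise_sd = 0.01, seed = 2)
  lab <- segment_macrophages(imgs$mcherry, threshold = 0.15, min_area = 25)
  expect_equal(max(lab), 10)
  # each recovered label overlaps exactly one true cell with Jaccard >= 0.9
  for (k in seq_len(10)) {
    truth_ids <- unique(sc$label[lab == k])
    truth_ids <- truth_ids[truth_ids > 0]
    expect_length(truth_ids, 1)
    expect_gte(jaccard(lab == k, sc$label == truth_ids), 0.9)
  }
})

test_that("segmentation is invariant to positive intensity rescaling", {
  sc <- make_scene(small_scene_spec(seed = 29))
  imgs <- render_reporter_images(sc, noise_sd = 0.01, seed = 3)
  a <- segment_macrophages(imgs$mcherry)
  b <- segment_macrophages(imgs$mcherry * 37.5)
  expect_identical(unclass(a)[seq_along(a)], unclass(b)[seq_along(b)])
})

test_that("degenerate inputs follow the rescale-by-max contract", {
  u <- matrix(5, 20, 20)
  lab <- segment_macrophages(u, threshold = 0.15, min_area = 4)
  expect_equal(max(lab), 1)
  expect_true(all(lab == 1)) # everything rescales to 1 >= threshold

  # threshold 1: only pixels equal to the max survive; small ones removed
  m <- matrix(0.2, 20, 20)
  m[5, 5] <- 1            # isolated maximum, area 1
  m[10:13, 10:13] <- 1    # 16-pixel plateau at the maximum
  lab2 <- segment_macrophages(m, threshold = 1, min_area = 2)
  expect_equal(max(lab2), 1)
  expect_equal(sum(lab2 > 0), 16)
  expect_equal(lab2[5, 5], 0L)

  expect_error(segment_macrophages(matrix(0, 8, 8)), "no signal")
  expect_error(segment_macrophages(matrix(-1, 8, 8)), "nonnegative")
})

test_that("labels are 8-connected, hole-filled, consecutive", {
  img <- matrix(0, 12, 12)
  img[2, 2] <- 1; img[3, 3] <- 1      # diagonal touch: one object
  img[6:10, 6:10] <- 1; img[8, 8] <- 0 # object with a hole
  lab <- segment_macrophages(img, threshold = 0.5, min_area = 2)
  expect_equal(max(lab), 2)
  expect_equal(lab[2, 2], lab[3, 3])
  expect_equal(lab[8, 8], lab[7, 7]) # hole filled
  expect_setequal(unique(as.vector(lab)), c(0L, 1L, 2L))
  # area bookkeeping: label areas partition the foreground
  expect_equal(sum(tabulate(lab[lab > 0])), sum(lab > 0))
})

test_that("bacteria-mask exclusion removes exactly the overlapping pixels", {
  sc <- make_scene(small_scene_spec(n_cells = 4, seed = 41))
  imgs <- render_reporter_images(sc, noise_sd = 0)
  lab <- segment_macrophages(imgs$mcherry, min_area = 5)
  n0 <- max(lab)
  areas0 <- tabulate(lab[lab > 0])

  # no-op when everything is below the threshold
  bact <- matrix(0, nrow(lab), ncol(lab))
  lab_same <- exclude_bacteria(lab, bact, bacteria_threshold = 0.5)
  expect_identical(as.integer(lab_same), as.integer(lab))

  # mask covering all of cell 1 drops it; count decreases by one
  bact[lab == 1] <- 1
  lab_drop <- exclude_bacteria(lab, bact, bacteria_threshold = 0.5)
  expect_equal(max(lab_drop), n0 - 1)

  # mask covering part of cell 2 shrinks it by exactly the overlap
  bact2 <- matrix(0, nrow(lab), ncol(lab))
  px2 <- which(lab == 2)
  overlap <- px2[seq_len(floor(length(px2) * 0.3))]
  bact2[overlap] <- 1
  lab_part <- exclude_bacteria(lab, bact2, bacteria_threshold = 0.5)
  # cell 2 keeps its label position in raster order here
  areas1 <- tabulate(lab_part[lab_part > 0])
  expect_equal(sum(areas1), sum(areas0) - length(overlap))
  expect_error(exclude_bacteria(lab, matrix(0, 2, 2)), "shape")
})

test_that("TNFa classification flags exactly the GFP-bright cells", {
  status <- c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE,
              FALSE)
  sc <- make_scene(scene_spec(shape = c(96, 96), n_cells = 10,
                              radius_range = c(4, 6), seed = 53,
                              tnfa_status = status))
  imgs <- render_reporter_images(sc, noise_sd = 0.01, seed = 4)
  lab <- segment_macrophages(imgs$mcherry)
  ann <- classify_tnfa(lab, imgs$gfp)
  # map recovered labels back to true cells to compare statuses
  for (k in seq_len(max(lab))) {
    true_id <- unique(sc$label[lab == k])
    true_id <- true_id[true_id > 0]
    expect_equal(ann$tnfa_status[ann$cell_id == k],
                 sc$cells$tnfa_status[true_id])
  }
  expect_equal(sum(ann$tnfa_status == "positive"), 3)

  # all-zero GFP: everything negative (threshold from background = 0)
  ann0 <- classify_tnfa(lab, matrix(0, 96, 96))
  expect_true(all(ann0$tnfa_status == "negative"))

  # threshold 0 with strictly positive image: everything positive
  ann1 <- classify_tnfa(lab, matrix(1, 96, 96), gfp_threshold = 0)
  expect_true(all(ann1$tnfa_status == "positive"))
  expect_error(classify_tnfa(lab, matrix(0, 3, 3)), "shape")
})

test_that("proportional TNFa area does exact pixel bookkeeping", {
  mch <- matrix(0, 20, 20)
  mch[1:10, 1:10] <- 1 # 100 macrophage pixels
  gfp <- matrix(0, 20, 20)
  gfp[1:5, 1:5] <- 1   # 25 of them GFP+
  expect_equal(tnfa_proportional_area(gfp, mch, 0.5, 0.5), 0.25)

  # GFP superset of the macrophage mask
  expect_equal(tnfa_proportional_area(matrix(1, 20, 20), mch, 0.5, 0.5), 1)

  # disjoint masks
  gfp2 <- matrix(0, 20, 20); gfp2[15:18, 15:18] <- 1
  expect_equal(tnfa_proportional_area(gfp2, mch, 0.5, 0.5), 0)

  expect_error(tnfa_proportional_area(gfp, matrix(0, 20, 20), 0.5, 0.5),
               "no macrophage")
  expect_error(tnfa_proportional_area(gfp, mch, -1, 0.5), "threshold")
})

test_that("recovered TNFa+ proportion tracks the injected proportion", {
  hits <- 0; total <- 0
  for (seed in 1:4) {
    sc <- make_scene(scene_spec(shape = c(96, 96), n_cells = 10,
                                radius_range = c(4, 6), tnfa_prop = 0.3,
                                seed = seed * 100))
    # noiseless reporter: "any GFP signal" is exact by construction
    imgs <- render_reporter_images(sc, noise_sd = 0, seed = seed)
    lab <- segment_macrophages(imgs$mcherry)
    ann <- classify_tnfa(lab, imgs$gfp)
    hits <- hits + sum(ann$tnfa_status == "positive")
    total <- total + nrow(ann)
  }
  # injected 3/10 per field exactly (round(0.3*10)); recovery must match
  expect_equal(hits / total, 0.3, tolerance = 1e-9)
})

test_that("a user-supplied mask override takes precedence", {
  sc <- make_scene(small_scene_spec(seed = 61))
  imgs <- render_reporter_images(sc, noise_sd = 0)
  override <- matrix(0L, nrow(sc$label), ncol(sc$label))
  override[1:5, 1:5] <- 7L
  lab <- segment_macrophages(imgs$mcherry, mask_override = override)
  expect_equal(max(lab), 1)
  expect_equal(sum(lab > 0), 25)
  expect_equal(attr(lab, "source"), "override")
})
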