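test_that("dice and iou match pixel-count oracles and their identity", {
  a <- matrix(FALSE, 20, 20); a[1:10, 1:10] <- TRUE    # 100 px
  b <- matrix(FALSE, 20, 20); b[6:15, 1:10] <- TRUE    # 100 px, 50 shared
  expect_equal(dice(a, b), 2 * 50 / 200)
  expect_equal(iou(a, b), 50 / 150)
  expect_equal(dice(a, a), 1)
  expect_equal(iou(a, a), 1)
  disj <- matrix(FALSE, 20, 20); disj[15:20, 15:20] <- TRUE
  expect_equal(dice(a, disj), 0)
  expect_equal(iou(a, disj), 0)
  empty <- matrix(FALSE, 20, 20)
  expect_equal(dice(empty, empty), 1)
  expect_equal(iou(empty, empty), 1)
  expect_error(dice(a, matrix(FALSE, 10, 10)), "shapes differ")
  expect_error(iou(a, matrix(FALSE, 10, 10)), "shapes differ")

  set.seed(14)
  for (i in 1:50) {
    m1 <- matrix(runif(400) < 0.4, 20, 20)
    m2 <- matrix(runif(400) < 0.4, 20, 20)
    d <- dice(m1, m2); j <- iou(m1, m2)
    expect_equal(d, 2 * j / (1 + j), tolerance = 1e-12)
    expect_gte(d, j)
    # brute-force pixel counting oracle
    expect_equal(d, 2 * sum(m1 & m2) / (sum(m1) + sum(m2)))
  }
})

test_that("tile positivity and screening metrics follow their formulas", {
  expect_false(tile_positive(matrix(FALSE, 5, 5)))
  one <- matrix(FALSE, 5, 5); one[3, 3] <- TRUE
  expect_true(tile_positive(one))
  set.seed(15)
  for (i in 1:30) {
    m <- matrix(runif(64) < 0.05, 8, 8)
    expect_identical(tile_positive(m), sum(m) > 0)
  }

  # TP=19, FN=1, FP=2
  pred <- c(rep(TRUE, 19), FALSE, TRUE, TRUE, rep(FALSE, 10))
  truth <- c(rep(TRUE, 20), rep(FALSE, 12))
  sm <- seg_screen_metrics(pred, truth)
  expect_equal(sm$sensitivity, 0.95)
  expect_equal(sm$ppv, 19 / 21)
  perfect <- seg_screen_metrics(truth, truth)
  expect_equal(perfect$sensitivity, 1)
  expect_equal(perfect$ppv, 1)
  allneg <- seg_screen_metrics(rep(FALSE, 20), truth[1:20])
  expect_equal(allneg$sensitivity, 0)
  expect_true(is.na(allneg$ppv))
  nolab <- seg_screen_metrics(pred[21:32], truth[21:32])
  expect_true(is.na(nolab$sensitivity))
})

test_that("segmenter training is seeded-deterministic and validates inputs", {
  tiles <- small_tiles()
  folds <- small_folds()
  cfg <- seg_train_config(target = "glomerulus", epochs = 1, seed = 5,
                          input_px = 64L)
  s1 <- train_segmenter(tiles, folds, cfg)
  s2 <- train_segmenter(tiles, folds, cfg)
  expect_identical(s1$metrics$global_pixel$dice,
                   s2$metrics$global_pixel$dice)
  expect_identical(s1$models[[1]]$theta, s2$models[[1]]$theta)

  expect_error(train_segmenter(tiles, folds,
                               seg_train_config(architecture = "segformer_b4")),
               "not available in this build")
  clean <- lapply(tiles, function(t) {
    t$masks$podocyte <- matrix(FALSE, 128, 128); t
  })
  expect_error(train_segmenter(clean, folds,
                               seg_train_config(target = "podocyte")),
               "empty")
})

test_that("predicted masks are deterministic and nested in the threshold", {
  tiles <- small_tiles()
  cfg <- seg_train_config(target = "glomerulus", epochs = 2, seed = 5,
                          input_px = 64L)
  seg <- train_segmenter(tiles, small_folds(), cfg)
  model <- seg$models[[1]]
  tl <- tiles[[3]]
  m50 <- predict_mask(model, tl)
  expect_identical(predict_mask(model, tl), m50)
  m40 <- predict_mask(model, tl, threshold = 0.4)
  m60 <- predict_mask(model, tl, threshold = 0.6)
  expect_identical(sum(m60 & !m50), 0L)   # higher threshold shrinks
  expect_identical(sum(m50 & !m40), 0L)
  # blank tile: valid mask, no NaN
  blank <- array(1, dim(tl$pixels))
  mb <- predict_mask(model, blank)
  expect_true(is.logical(mb) && !anyNA(mb))
  # upsampling to tile resolution preserves the area fraction
  m512 <- predict_mask(model, tl, out_px = 512L)
  expect_equal(mean(m512), mean(m50), tolerance = 0.01)
})

test_that("fold metrics exist under both aggregation conventions", {
  tiles <- small_tiles()
  seg <- train_segmenter(tiles, small_folds(),
                         seg_train_config(target = "glomerulus", epochs = 2,
                                          seed = 5, input_px = 64L))
  g <- seg$metrics$global_pixel; p <- seg$metrics$per_tile_mean
  expect_identical(g$aggregation, "global_pixel")
  expect_identical(p$aggregation, "per_tile_mean")
  expect_true(g$dice >= g$iou)
  expect_identical(g$n_tiles, length(tiles))
})
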