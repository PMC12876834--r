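test_that("case-level folds are balanced, exhaustive and deterministic", {
  f5 <- make_case_folds(paste0("c", 1:5), k = 5, seed = 1)
  expect_identical(sort(unname(f5$assignment)), 0:4)

  f77 <- make_case_folds(paste0("c", 1:77), k = 5, seed = 3)
  expect_identical(sort(as.integer(table(f77$assignment)),
                        decreasing = TRUE),
                   c(16L, 16L, 15L, 15L, 15L))
  expect_identical(make_case_folds(paste0("c", 1:77), k = 5, seed = 3),
                   f77)
  expect_error(make_case_folds(c("a", "b"), k = 5), "at least 5")
})

test_that("no case contributes tiles to both train and validation", {
  tiles <- small_tiles()
  folds <- small_folds()
  tf <- zebrascore:::tile_fold(tiles, folds)
  ids <- vapply(tiles, `[[`, character(1), "case_id")
  for (f in 0:4) {
    # exhaustive: every tile id in the held-out fold is absent from training
    expect_length(intersect(ids[tf == f], ids[tf != f]), 0)
  }
})

test_that("augmentation is label-preserving, shape-preserving and invertible", {
  set.seed(4)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  idp <- zebrascore:::identity_augment_params()
  expect_identical(apply_augment(img, idp), img)

  set.seed(5)
  prm <- draw_augment_params()
  out <- apply_augment(img, prm)
  expect_identical(dim(out), dim(img))

  rot180 <- zebrascore:::identity_augment_params()
  rot180$rot <- 180L
  expect_equal(apply_augment(apply_augment(img, rot180), rot180), img)

  flip <- zebrascore:::identity_augment_params()
  flip$flip_h <- TRUE
  expect_equal(apply_augment(apply_augment(img, flip), flip), img)

  # tile masks follow the geometric transform
  tl <- small_tiles()[[1]]
  set.seed(6)
  at <- augment_tile(tl)
  expect_identical(dim(at$pixels), dim(tl$pixels))
  expect_identical(sum(at$masks$glomerulus), sum(tl$masks$glomerulus))
})

test_that("glomerulus aggregation rules match their definitions", {
  pr <- data.frame(p_foamy = c(0.9, 0.1, 0.1),
                   predicted_label = c("foamy", "not_foamy", "not_foamy"))
  expect_identical(aggregate_glomerulus(pr, "any_positive")$label, "foamy")
  expect_identical(aggregate_glomerulus(pr, "majority")$label, "not_foamy")
  expect_equal(aggregate_glomerulus(pr, "any_positive")$score, 0.9)
  expect_equal(aggregate_glomerulus(pr, "mean_prob")$score, mean(pr$p_foamy))

  one <- pr[1, ]
  for (rule in c("any_positive", "majority", "mean_prob"))
    expect_identical(aggregate_glomerulus(one, rule)$label, "foamy")
  expect_error(aggregate_glomerulus(pr[0, ]), "no predictions")

  set.seed(7)
  for (i in 1:20) {
    n <- sample(1:8, 1)
    p <- runif(n)
    pr <- data.frame(p_foamy = p,
                     predicted_label = ifelse(p >= 0.5, "foamy", "not_foamy"))
    expect_identical(aggregate_glomerulus(pr, "any_positive")$label,
                     if (any(p >= 0.5)) "foamy" else "not_foamy")
    expect_identical(aggregate_glomerulus(pr, "majority")$label,
                     if (mean(p >= 0.5) > 0.5) "foamy" else "not_foamy")
    expect_identical(aggregate_glomerulus(pr, "mean_prob")$label,
                     if (mean(p) >= 0.5) "foamy" else "not_foamy")
  }
})

test_that("case aggregation is any-positive and monotone", {
  expect_identical(aggregate_case(rep("not_foamy", 5)), "control")
  expect_identical(aggregate_case(c(rep("not_foamy", 19), "foamy")), "FN")
  expect_error(aggregate_case(character(0)), "no region labels")
  # monotone: adding a positive region never flips a positive case
  set.seed(8)
  for (i in 1:20) {
    labs <- sample(c("foamy", "not_foamy"), sample(1:6, 1), replace = TRUE)
    if (aggregate_case(labs) == "FN")
      expect_identical(aggregate_case(c(labs, "foamy")), "FN")
  }
})

test_that("training rejects bad inputs with informative errors", {
  tiles <- small_tiles()
  folds <- small_folds()
  expect_error(train_classifier(tiles, folds,
                                train_config(backbone = "resnet18")),
               "not available in this build")
  neg <- Filter(function(t) t$label == "not_foamy", tiles)
  expect_error(train_classifier(neg, folds, train_config()), "single class")
})

test_that("the small CNN separates foamy tiles and beats a permuted null", {
  tiles <- small_tiles()
  folds <- small_folds()
  cfg <- train_config(seed = 77)
  cls <- train_classifier(tiles, folds, cfg)
  acc <- mean(cls$oof$predicted_label == cls$oof$label)
  # sanity bound for the reduced test fixture; the >= 0.90 separability
  # contract is asserted on the full-size default cohort in the acceptance
  # suite
  expect_gte(acc, 0.80)

  # chance level once labels are permuted at case level
  ids <- unique(vapply(tiles, `[[`, character(1), "case_id"))
  set.seed(99)
  perm <- setNames(sample(c(rep("foamy", 5), rep("not_foamy", 5))), ids)
  null_tiles <- lapply(tiles, function(t) { t$label <- perm[[t$case_id]]; t })
  null_cls <- train_classifier(null_tiles, folds, cfg)
  null_acc <- mean(null_cls$oof$predicted_label == null_cls$oof$label)
  expect_gte(null_acc, 0.2)
  expect_lte(null_acc, 0.8)
})

test_that("prediction is deterministic, batch-invariant and NaN-free", {
  tiles <- small_tiles()
  folds <- small_folds()
  cfg <- train_config(seed = 31, epochs = 1)
  cls <- train_classifier(tiles, folds, cfg)
  model <- cls$models[[1]]
  p1 <- predict_tiles(model, tiles[1:6])
  # duplicate tile gets an identical probability
  p2 <- predict_tiles(model, c(tiles[1:6], tiles[1]))
  expect_equal(p2$p_foamy[7], p1$p_foamy[1])
  # batch-size invariance: one-at-a-time equals all-at-once
  singles <- vapply(1:6, function(i)
    predict_tiles(model, tiles[i])$p_foamy, numeric(1))
  expect_equal(singles, p1$p_foamy)
  # an all-pad blank tile yields a valid probability
  blank <- tiles[[1]]
  blank$pixels <- array(1, dim(blank$pixels))
  pb <- predict_tiles(model, list(blank))$p_foamy
  expect_true(is.finite(pb) && pb >= 0 && pb <= 1)

  # seeded determinism of the whole CV fit
  cls2 <- train_classifier(tiles, folds, cfg)
  expect_identical(cls$oof$p_foamy, cls2$oof$p_foamy)
})

test_that("model bundles round-trip through the WSInfer-style format", {
  tiles <- small_tiles()
  cls <- train_classifier(tiles, small_folds(), train_config(seed = 31,
                                                             epochs = 1))
  dir <- withr::local_tempdir()
  save_model_bundle(cls$models[[1]], dir)
  expect_true(file.exists(file.path(dir, "config.json")))
  back <- load_model_bundle(dir)
  expect_equal(predict_tiles(back, tiles[1:4])$p_foamy,
               predict_tiles(cls$models[[1]], tiles[1:4])$p_foamy,
               tolerance = 1e-12)
  meta <- jsonlite::fromJSON(file.path(dir, "config.json"))
  expect_identical(meta$patch_size_pixels, 512L)
  expect_equal(meta$spacing_um_px, 0.5)
  expect_identical(meta$class_names, c("not_foamy", "foamy"))
})
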