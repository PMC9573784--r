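# One small training run is shared across the blocks below.
tiny <- local({
  b <- generate_carpel_batch(24, seed = 11, image_size = c(64, 64))
  cfg <- seg_config(input_size = 64, depth = 3, base_channels = 8,
                    epochs = 12, seed = 0)
  list(batch = b,
       seg = train_segmenter(b$images[1:18], b$stigma_truths[1:18], cfg),
       cfg = cfg)
})

test_that("configuration invariants are enforced", {
  expect_error(seg_config(input_size = 130, depth = 4), "divisible")
  expect_error(seg_config(val_fraction = 0), "val_fraction")
  expect_error(seg_config(binarize_threshold = 1), "binarize_threshold")
  expect_error(seg_config(n_output_channels = 3), "output")
})

test_that("training reduces the validation soft-Dice loss and logs every epoch", {
  log <- tiny$seg$training_log
  expect_equal(nrow(log), tiny$cfg$epochs)
  expect_lt(log$val_loss[nrow(log)], log$val_loss[1])
  expect_true(all(log$train_loss >= 0 & log$train_loss <= 1))
  expect_true(all(log$val_loss >= 0 & log$val_loss <= 1))
})

test_that("training is deterministic given data, config and seed", {
  b <- tiny$batch
  cfg <- seg_config(input_size = 32, depth = 2, base_channels = 4,
                    epochs = 2, seed = 5)
  s1 <- train_segmenter(b$images[1:12], b$stigma_truths[1:12], cfg)
  s2 <- train_segmenter(b$images[1:12], b$stigma_truths[1:12], cfg)
  expect_identical(s1$training_log, s2$training_log)
  expect_identical(s1$net$params, s2$net$params)
})

test_that("training rejects malformed inputs", {
  b <- tiny$batch
  expect_error(train_segmenter(b$images[1:5], b$stigma_truths[1:5],
                               tiny$cfg), "at least 10")
  cfg2 <- seg_config(input_size = 64, n_output_channels = 2)
  expect_error(train_segmenter(b$images[1:12], b$stigma_truths[1:12], cfg2),
               "output channel")
  bad <- b$stigma_truths[1:12]
  bad[[3]] <- bad[[3]][1:32, 1:32]
  expect_error(train_segmenter(b$images[1:12], bad, tiny$cfg), "dimensions")
})

test_that("prediction is deterministic, native-resolution, and better than chance", {
  img <- tiny$batch$images[[20]]
  truth <- tiny$batch$stigma_truths[[20]]
  m1 <- predict_masks(tiny$seg, img)
  m2 <- predict_masks(tiny$seg, img)
  expect_identical(m1, m2)
  expect_named(m1, "stigma")
  expect_equal(dim(m1$stigma), dim(truth))
  expect_true(all(m1$stigma %in% c(0, 1)))

  shuffled <- matrix(sample(truth), nrow(truth))
  expect_gt(dice(m1$stigma, truth), dice(m1$stigma, shuffled))

  # degenerate input still yields a valid binary grid
  black <- array(0, c(48, 48, 3))
  mb <- predict_masks(tiny$seg, black)$stigma
  expect_equal(dim(mb), c(48, 48))
  expect_true(all(mb %in% c(0, 1)))

  expect_error(predict_masks(tiny$seg, matrix(0, 32, 32)), "RGB")
})

test_that("native and network-resolution Dice agree for convex masks", {
  # prediction resized back to native vs truth resized down to the network:
  # the two evaluations must tell the same story
  b <- generate_carpel_batch(4, seed = 21, image_size = c(96, 96))
  seg <- asNamespace("carpelseg")
  S <- tiny$cfg$input_size
  for (i in 1:4) {
    truth <- b$stigma_truths[[i]]
    d_native <- dice(predict_masks(tiny$seg, b$images[[i]])$stigma, truth)
    # same prediction evaluated at the network's own resolution
    P <- seg$unet_fw(tiny$seg$net,
                     seg$pad_flat(seg$resize_rgb(b$images[[i]]$img, S, S)))$P
    pred_net <- (matrix(P[1, ], S, S) > tiny$cfg$binarize_threshold) * 1
    d_net <- dice(pred_net, (seg$resize_mat(truth, S, S) > 0.5) * 1)
    expect_lt(abs(d_native - d_net), 0.02)
  }
})

test_that("post-processing keeps the largest 8-connected component and fills holes", {
  m <- matrix(0, 40, 40)
  m[5:25, 5:25] <- 1          # 441 px blob
  m[30:33, 30:34] <- 1        # 20 px blob
  out <- postprocess_mask(m)
  expect_equal(sum(out), 441)
  expect_equal(sum(out[30:33, 30:34]), 0)

  # diagonal touching counts as connected
  m2 <- matrix(0, 10, 10)
  m2[2:4, 2:4] <- 1
  m2[5, 5] <- 1               # touches only diagonally
  m2[8, 8] <- 1               # separate single pixel
  out2 <- postprocess_mask(m2)
  expect_equal(sum(out2), 10)

  # interior hole is filled
  h <- disc_mask(30, 30, 15, 15, 10)
  holed <- h; holed[14:16, 14:16] <- 0
  expect_equal(sum(postprocess_mask(holed)), sum(h))

  e <- postprocess_mask(matrix(0, 5, 5))
  expect_equal(sum(e), 0)
  expect_true(attr(e, "empty"))
})

test_that("checkpoints round-trip through save/load", {
  f <- tempfile(fileext = ".rds")
  save_segmenter(tiny$seg, f)
  back <- load_segmenter(f)
  img <- tiny$batch$images[[19]]
  expect_identical(predict_masks(back, img), predict_masks(tiny$seg, img))
  saveRDS(list(format = "other"), f)
  expect_error(load_segmenter(f), "checkpoint")
})
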