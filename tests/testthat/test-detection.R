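# one small rendered cohort shared by the cascade tests
detection_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sp <- small_spec(noise = 0.04, blur = 1, seed = 2)
      co <- sample_cohort(24, spec = sp, seed = 6)
      cache <<- lapply(seq_len(24), function(i) {
        s <- sp; s$seed <- 600L + i
        render_radiograph(co$landmarks[[i]], s)
      })
    }
    cache
  }
})

fast_training <- function(seed = 1L) training_config(epochs = 300L, seed = seed)

test_that("mae loss matches direct arithmetic", {
  expect_equal(mae_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mae_loss(c(1, 2), c(0, 0)), 1.5)
  # asymmetric pairs: permuting labels changes the value
  expect_false(isTRUE(all.equal(mae_loss(c(1, 5), c(1, 2)),
                                mae_loss(c(1, 5), c(2, 1)))))
  expect_error(mae_loss(1:3, 1:2), "different lengths")
})

test_that("crop transforms are exact and clip as hand-computed", {
  img <- matrix(runif(50 * 40), nrow = 50, ncol = 40)
  full <- crop_roi(img, c(0, 0, 39, 49), margin = 0)
  expect_identical(full$image, img)
  expect_equal(full$offset, c(0, 0))

  roi <- crop_roi(img, c(10, 20, 10, 10), margin = 0)
  ctr <- c(15, 25)
  expect_equal(roi$to_parent(roi$to_roi(ctr)), ctr)
  expect_equal(roi$to_roi(ctr), c(5, 5))

  # box poking over the right/bottom border: clipped to the image
  clipped <- crop_roi(img, c(35, 45, 20, 20), margin = 0)
  expect_equal(clipped$offset, c(35, 45))
  expect_equal(dim(clipped$image), c(5, 5))
  # margin expands symmetrically before clipping
  expanded <- crop_roi(img, c(10, 10, 10, 10), margin = 0.1)
  expect_equal(expanded$offset, c(9, 9))
  expect_error(crop_roi(img, c(100, 100, 5, 5)), "intersect")
})

test_that("chained crop transforms compose to identity", {
  img <- matrix(0, 200, 100)
  p <- c(43.25, 157.5)
  roi1 <- crop_roi(img, c(10, 80, 80, 110), margin = 0.05)
  roi2 <- crop_roi(roi1$image, c(20, 40, 30, 50), margin = 0.1)
  q <- roi2$to_roi(roi1$to_roi(p))
  expect_equal(roi1$to_parent(roi2$to_parent(q)), p, tolerance = 1e-12)
})

test_that("an untrained regressor is the zero-output baseline", {
  set.seed(3)
  X <- matrix(rnorm(40 * 6), 40)
  Y <- matrix(runif(40 * 4), 40)
  reg <- spinesag:::fit_regressor(X, Y, lr = 0.005, epochs = 50)
  # before the first update the regressor predicts the constant 0
  expect_equal(reg$history[1], mean(abs(Y)))
  expect_lt(reg$history[51], reg$history[1])
})

test_that("cascade training reduces the loss of every head deterministically", {
  m1 <- train_cascade(detection_cohort(), training = fast_training())
  m2 <- train_cascade(detection_cohort(), training = fast_training())
  h <- m1$history
  for (head in unique(h$head)) {
    hh <- h[h$head == head, ]
    expect_lt(hh$loss[which.max(hh$epoch)], hh$loss[which.min(hh$epoch)])
  }
  expect_identical(m1$history, m2$history)
  img <- detection_cohort()[[1]]$image
  expect_identical(predict_landmarks(m1, img), predict_landmarks(m2, img))
})

test_that("the 9:1 split separates training and validation subjects", {
  m <- train_cascade(detection_cohort(), training = fast_training())
  expect_length(m$train_idx, 21)  # floor(0.9 * 24)
  expect_length(m$val_idx, 3)
  expect_length(intersect(m$train_idx, m$val_idx), 0)
})

test_that("predictions are in-bounds, complete, and repeatable", {
  m <- train_cascade(detection_cohort(), training = fast_training())
  img <- detection_cohort()[[m$val_idx[1]]]$image
  p <- predict_landmarks(m, img)
  expect_setequal(p$name, landmark_names())
  expect_true(all(p$x >= 0 & p$x <= ncol(img) - 1))
  expect_true(all(p$y >= 0 & p$y <= nrow(img) - 1))
  expect_identical(p, predict_landmarks(m, img))
  expect_error(predict_landmarks(m, matrix(0, 5, 5)), "expects")
})

test_that("a one-epoch model still yields in-bounds flagged predictions", {
  m <- train_cascade(detection_cohort(),
                     training = training_config(epochs = 1L, seed = 2))
  p <- predict_landmarks(m, detection_cohort()[[1]]$image)
  expect_true(all(p$x >= 0 & p$y >= 0))
  expect_type(p$clamped, "logical")
})

test_that("model save/load round-trips to bit-identical predictions", {
  m <- train_cascade(detection_cohort(), training = fast_training())
  f <- withr::local_tempfile(fileext = ".rds")
  save_cascade(m, f)
  m2 <- load_cascade(f)
  img <- detection_cohort()[[2]]$image
  expect_identical(predict_landmarks(m, img), predict_landmarks(m2, img))
})

test_that("held-out landmark error stays within one order-1 region width", {
  m <- train_cascade(detection_cohort(), training = fast_training())
  preds <- lapply(m$val_idx,
                  function(i) predict_landmarks(m, detection_cohort()[[i]]$image))
  truths <- lapply(m$val_idx, function(i) detection_cohort()[[i]]$landmarks)
  ev <- evaluate_detector(preds, truths)
  roi_width <- m$config$region_box[1] * m$image_dim[1]
  expect_true(all(ev$landmarks$mae_px < roi_width))
})

test_that("detector evaluation matches Pythagorean and geometric oracles", {
  truth <- generate_landmarks(small_spec(seed = 3))$landmarks
  exact <- truth
  ev0 <- evaluate_detector(list(exact), list(truth))
  expect_equal(ev0$landmarks$mae_px, rep(0, 11))
  expect_equal(ev0$parameters$mae_deg, rep(0, 12))

  shifted <- dplyr::mutate(truth,
                           x = ifelse(name == "t1_sup_ant", x + 3, x),
                           y = ifelse(name == "t1_sup_ant", y + 4, y))
  ev <- evaluate_detector(list(landmark_set(shifted)), list(truth))
  expect_equal(ev$landmarks$mae_px[ev$landmarks$landmark == "t1_sup_ant"], 5)
  expect_equal(sum(ev$landmarks$mae_px), 5)

  # angular errors agree with recomputing the parameters independently
  m_t <- measure_parameters(truth)
  m_s <- measure_parameters(landmark_set(shifted))
  for (p in names(m_t)) {
    expect_equal(ev$per_case$abs_error[ev$per_case$parameter == p],
                 abs(m_s[[p]] - m_t[[p]]))
  }
  expect_error(evaluate_detector(list(exact), list(truth, truth)),
               "different lengths")
})

test_that("cascade tidiers summarise the training history", {
  m <- train_cascade(detection_cohort(), training = fast_training())
  td <- tidy(m)
  expect_true(all(c("head", "epoch", "loss") %in% names(td)))
  gl <- glance(m)
  expect_equal(gl$n_heads, 9)
  expect_lt(gl$final_loss, gl$initial_loss)
})
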