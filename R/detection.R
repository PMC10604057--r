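# Decentralized coarse-to-fine landmark detection: three orders of
# coordinate regressors, each narrowing the region of interest for the
# next.  Order 1 finds rough region centers on the full image, order 2
# finds per-vertebra centers inside each region, order 3 localizes the
# final landmarks inside per-vertebra crops.

region_members <- function() {
  list(
    hip = c("femoral_head_1", "femoral_head_2"),
    lumbar = c("sacrum_center", "s1_sup_ant", "s1_sup_post",
               "l1_sup_ant", "l1_sup_post"),
    cervical = c("t1_sup_ant", "t1_sup_post", "c2_inf_ant", "c2_inf_post")
  )
}

vertebra_members <- function() {
  list(
    hip = c("femoral_head_1", "femoral_head_2"),
    sacrum = c("s1_sup_ant", "s1_sup_post", "sacrum_center"),
    l1 = c("l1_sup_ant", "l1_sup_post"),
    t1 = c("t1_sup_ant", "t1_sup_post"),
    c2 = c("c2_inf_ant", "c2_inf_post")
  )
}

region_of_vertebra <- function() {
  c(hip = "hip", sacrum = "lumbar", l1 = "lumbar",
    t1 = "cervical", c2 = "cervical")
}

#' Cascade configuration
#'
#' Geometry of the three detection orders: per-order feature resolutions
#' (block-mean downsampling grids), the fractional sizes of the order-2
#' region crops and order-3 vertebra crops, and the symmetric crop margin.
#' Every canonical landmark is assigned to exactly one order-3 head.
#'
#' @param o1_res,o2_res,o3_res Integer `c(nx, ny)` feature grids per order.
#' @param region_box Fractions `c(w, h)` of the image covered by an
#'   order-2 region crop.
#' @param vert_box Fractions `c(w, h)` of the image covered by an order-3
#'   vertebra crop.
#' @param margin Fractional symmetric margin added when cropping.
#' @param n_crops Number of jittered training crops drawn per image for
#'   orders 2 and 3 (crop augmentation; narrowing the ROI increases the
#'   diversity of the training set).
#' @return Object of class `cascade_config`.
#' @export
cascade_config <- function(o1_res = c(12L, 30L),
                           o2_res = c(14L, 14L),
                           o3_res = c(14L, 14L),
                           region_box = c(0.85, 0.40),
                           vert_box = c(0.50, 0.16),
                           margin = 0.10,
                           n_crops = 3L) {
  stopifnot(all(o1_res > 0), all(o2_res > 0), all(o3_res > 0),
            all(region_box > 0), all(vert_box > 0), margin >= 0, n_crops >= 1)
  structure(
    list(o1_res = as.integer(o1_res), o2_res = as.integer(o2_res),
         o3_res = as.integer(o3_res), region_box = region_box,
         vert_box = vert_box, margin = margin, n_crops = as.integer(n_crops)),
    class = "cascade_config"
  )
}

#' Training configuration
#'
#' @param lr Learning rate of the gradient-descent update (must be > 0).
#' @param epochs Number of full-batch epochs per regressor.
#' @param seed Integer seed controlling the train/validation split and the
#'   crop jitter.
#' @param split Training fraction of the cohort (default 9:1).
#' @param jitter Fractional jitter applied to training crop centers.
#' @return Object of class `training_config`.
#' @export
training_config <- function(lr = 0.005, epochs = 400L, seed = 1L,
                            split = 0.9, jitter = 0.18) {
  if (lr <= 0) abort("learning rate must be positive")
  if (split <= 0 || split >= 1) abort("split must be in (0, 1)")
  structure(
    list(lr = lr, epochs = as.integer(epochs), seed = as.integer(seed),
         split = split, jitter = jitter),
    class = "training_config"
  )
}

#' Mean absolute error loss
#'
#' `mean(|predicted - label|)` over all coordinates, the loss minimized by
#' every regressor in the cascade.
#'
#' @param predicted,label Equal-length numeric vectors or equal-dim
#'   matrices of positions.
#' @return Non-negative scalar; zero iff the inputs are identical.
#' @examples
#' mae_loss(c(1, 2), c(0, 0))
#' @export
mae_loss <- function(predicted, label) {
  predicted <- as.numeric(predicted)
  label <- as.numeric(label)
  if (length(predicted) != length(label)) {
    abort("`predicted` and `label` have different lengths")
  }
  if (length(predicted) == 0) abort("empty position lists")
  mean(abs(predicted - label))
}

#' Crop a region of interest
#'
#' Expands the box symmetrically by `margin` (a fraction of its width and
#' height), clips it to the image, extracts whole pixels, and returns the
#' exact coordinate transform between sub-image and parent frames.
#'
#' @param image Numeric matrix (rows = y, cols = x).
#' @param box Numeric `c(x, y, width, height)` in parent pixel coordinates.
#' @param margin Fractional symmetric expansion.
#' @return List with `image` (the crop), `offset` (`c(dx, dy)`; parent =
#'   sub + offset), and helpers `to_parent(p)` / `to_roi(p)`.
#' @export
crop_roi <- function(image, box, margin = 0) {
  h <- nrow(image); w <- ncol(image)
  mx <- margin * box[3]; my <- margin * box[4]
  x0 <- max(0, floor(box[1] - mx))
  y0 <- max(0, floor(box[2] - my))
  x1 <- min(w - 1, ceiling(box[1] + box[3] + mx))
  y1 <- min(h - 1, ceiling(box[2] + box[4] + my))
  if (x1 < x0 || y1 < y0) abort("ROI does not intersect the image")
  sub <- image[(y0 + 1):(y1 + 1), (x0 + 1):(x1 + 1), drop = FALSE]
  offset <- c(x0, y0)
  list(
    image = sub, offset = offset,
    to_parent = function(p) p + offset,
    to_roi = function(p) p - offset
  )
}

# Block-mean downsampling of an image to an nx-by-ny feature grid.
roi_features <- function(image, res) {
  h <- nrow(image); w <- ncol(image)
  ry <- floor((seq_len(h) - 1) * res[2] / h) + 1
  rx <- floor((seq_len(w) - 1) * res[1] / w) + 1
  m <- rowsum(image, ry) / as.vector(table(ry))
  m <- rowsum(t(m), rx) / as.vector(table(rx))
  as.numeric(m)
}

# Multi-output linear coordinate regressor trained by full-batch
# adaptive-moment gradient descent on the MAE loss.  Features are
# standardized with training moments; targets are coordinates normalized
# to [0, 1] in the crop frame.
fit_regressor <- function(X, Y, lr, epochs) {
  n <- nrow(X)
  center <- colMeans(X)
  scale <- apply(X, 2, sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  Xs <- cbind(1, sweep(sweep(X, 2, center), 2, scale, "/"))
  W <- matrix(0, ncol(Xs), ncol(Y))
  m <- W; v <- W
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  history <- numeric(epochs + 1L)
  for (ep in seq_len(epochs)) {
    pred <- Xs %*% W
    history[ep] <- mean(abs(pred - Y))
    grad <- crossprod(Xs, sign(pred - Y)) / (n * ncol(Y))
    m <- b1 * m + (1 - b1) * grad
    v <- b2 * v + (1 - b2) * grad^2
    mhat <- m / (1 - b1^ep)
    vhat <- v / (1 - b2^ep)
    W <- W - lr * mhat / (sqrt(vhat) + eps)
  }
  pred <- Xs %*% W
  history[epochs + 1L] <- mean(abs(pred - Y))
  if (!all(is.finite(W)) || !all(is.finite(history))) {
    abort("non-finite loss during training; reduce the learning rate")
  }
  structure(list(W = W, center = center, scale = scale, history = history),
            class = "mae_regressor")
}

predict_regressor <- function(reg, x) {
  xs <- c(1, (x - reg$center) / reg$scale)
  as.numeric(xs %*% reg$W)
}

landmark_matrix <- function(lms, names) {
  i <- match(names, lms$name)
  cbind(lms$x[i], lms$y[i])
}

centroid_of <- function(lms, names) colMeans(landmark_matrix(lms, names))

roi_box_around <- function(center, frac, w, h) {
  bw <- frac[1] * w; bh <- frac[2] * h
  c(min(max(center[1], 0), w - 1) - bw / 2,
    min(max(center[2], 0), h - 1) - bh / 2, bw, bh)
}

#' Train the decentralized detection cascade
#'
#' Splits the annotated cohort into training and validation sets, then
#' trains order 1 on full images (targets: the hip, lumbar and cervical
#' region centers), order 2 on region crops around the ground-truth region
#' centers with jitter (targets: per-vertebra centers), and order 3 on
#' vertebra crops (targets: the final landmarks).  All regressors minimize
#' the mean-absolute-error loss by gradient descent; the per-epoch loss of
#' every regressor is returned.
#'
#' @param cohort List of `annotated_image` objects (see
#'   [render_radiograph()]), or a `phantom_cohort` plus `spec`.
#' @param config A [cascade_config()].
#' @param training A [training_config()].
#' @param spec Optional [phantom_spec()]; required when `cohort` is a
#'   `phantom_cohort`, used to render its images.
#' @return Object of class `cascade_model` with elements `regressors`,
#'   `config`, `training`, `history` (tibble: order, head, epoch, loss),
#'   `val_idx`, `image_dim`.
#' @export
train_cascade <- function(cohort, config = cascade_config(),
                          training = training_config(), spec = NULL) {
  if (inherits(cohort, "phantom_cohort")) {
    if (is.null(spec)) abort("`spec` is required to render a phantom_cohort")
    cohort <- lapply(cohort$landmarks, render_radiograph, spec = spec)
  }
  if (!length(cohort)) abort("empty training cohort")
  stopifnot(inherits(config, "cascade_config"),
            inherits(training, "training_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(training$seed)

  h <- nrow(cohort[[1]]$image); w <- ncol(cohort[[1]]$image)
  n <- length(cohort)
  n_train <- max(1L, floor(training$split * n))
  idx <- sample.int(n)
  train_idx <- sort(idx[seq_len(n_train)])
  val_idx <- sort(setdiff(idx, train_idx))
  train_set <- cohort[train_idx]

  jit <- function(k, extent) runif(k, -training$jitter, training$jitter) * extent

  regions <- region_members()
  verts <- vertebra_members()
  histories <- list()

  # --- order 1: full image -> region centers -------------------------------
  X1 <- t(vapply(train_set, function(a) roi_features(a$image, config$o1_res),
                 numeric(prod(config$o1_res))))
  Y1 <- t(vapply(train_set, function(a) {
    unlist(lapply(regions, function(m) centroid_of(a$landmarks, m) / c(w, h)))
  }, numeric(2 * length(regions))))
  reg1 <- fit_regressor(X1, Y1, training$lr, training$epochs)
  histories[["order1"]] <- reg1$history

  # --- order 2: region crop -> vertebra centers ----------------------------
  reg2 <- list()
  for (rg in names(regions)) {
    vnames <- names(verts)[region_of_vertebra()[names(verts)] == rg]
    feats <- list(); targs <- list(); k <- 0L
    for (i in seq_along(train_set)) {
      a <- train_set[[i]]
      for (rep_ in seq_len(config$n_crops)) {
        ctr <- centroid_of(a$landmarks, regions[[rg]]) +
          c(jit(1, config$region_box[1] * w), jit(1, config$region_box[2] * h))
        roi <- crop_roi(a$image, roi_box_around(ctr, config$region_box, w, h),
                        config$margin)
        dims <- c(ncol(roi$image), nrow(roi$image))
        k <- k + 1L
        feats[[k]] <- roi_features(roi$image, config$o2_res)
        targs[[k]] <- unlist(lapply(vnames, function(v) {
          roi$to_roi(centroid_of(a$landmarks, verts[[v]])) / dims
        }))
      }
    }
    reg2[[rg]] <- fit_regressor(do.call(rbind, feats), do.call(rbind, targs),
                                training$lr, training$epochs)
    histories[[paste0("order2_", rg)]] <- reg2[[rg]]$history
  }

  # --- order 3: vertebra crop -> landmarks ---------------------------------
  reg3 <- list()
  for (v in names(verts)) {
    feats <- list(); targs <- list(); k <- 0L
    for (i in seq_along(train_set)) {
      a <- train_set[[i]]
      for (rep_ in seq_len(config$n_crops)) {
        ctr <- centroid_of(a$landmarks, verts[[v]]) +
          c(jit(1, config$vert_box[1] * w), jit(1, config$vert_box[2] * h))
        roi <- crop_roi(a$image, roi_box_around(ctr, config$vert_box, w, h),
                        config$margin)
        dims <- c(ncol(roi$image), nrow(roi$image))
        k <- k + 1L
        feats[[k]] <- roi_features(roi$image, config$o3_res)
        targs[[k]] <- as.numeric(t(sweep(
          sweep(landmark_matrix(a$landmarks, verts[[v]]), 2, roi$offset),
          2, dims, "/")))
      }
    }
    reg3[[v]] <- fit_regressor(do.call(rbind, feats), do.call(rbind, targs),
                               training$lr, training$epochs)
    histories[[paste0("order3_", v)]] <- reg3[[v]]$history
  }

  history <- dplyr::bind_rows(lapply(names(histories), function(nm) {
    tibble::tibble(head = nm, epoch = seq_along(histories[[nm]]) - 1L,
                   loss = histories[[nm]])
  }))
  history$order <- sub("_.*", "", history$head)
  structure(
    list(regressors = list(o1 = reg1, o2 = reg2, o3 = reg3),
         config = config, training = training, history = history,
         train_idx = train_idx, val_idx = val_idx, image_dim = c(w, h)),
    class = "cascade_model"
  )
}

#' @export
print.cascade_model <- function(x, ...) {
  fin <- x$history[x$history$epoch == max(x$history$epoch), ]
  cat("<cascade_model> 3 orders,", length(x$regressors$o2), "region heads,",
      length(x$regressors$o3), "vertebra heads; final mean loss",
      sprintf("%.4f", mean(fin$loss)), "\n")
  invisible(x)
}

#' Predict the 11 landmarks on an image
#'
#' Runs the cascade coarse-to-fine: order-1 region centers on the full
#' image, order-2 vertebra centers inside region crops placed at the
#' order-1 predictions, order-3 landmarks inside vertebra crops.  All
#' outputs are full-image pixel coordinates.  Predictions falling outside
#' the image are clamped to its bounds and flagged in the `clamped` column
#' rather than silently filled.
#'
#' @param model A [train_cascade()] model.
#' @param image Numeric image matrix with the dimensions the model was
#'   trained on.
#' @return Tibble with columns `name`, `x`, `y`, `clamped`.
#' @export
predict_landmarks <- function(model, image) {
  stopifnot(inherits(model, "cascade_model"))
  w <- ncol(image); h <- nrow(image)
  if (!all(c(w, h) == model$image_dim)) {
    abort(paste0("image is ", w, "x", h, " px but the model expects ",
                 model$image_dim[1], "x", model$image_dim[2]))
  }
  cfg <- model$config
  regions <- region_members(); verts <- vertebra_members()

  p1 <- predict_regressor(model$regressors$o1, roi_features(image, cfg$o1_res))
  region_ctr <- lapply(stats::setNames(seq_along(regions), names(regions)),
                       function(i) p1[c(2 * i - 1, 2 * i)] * c(w, h))

  vert_ctr <- list()
  for (rg in names(regions)) {
    roi <- crop_roi(image, roi_box_around(region_ctr[[rg]], cfg$region_box, w, h),
                    cfg$margin)
    dims <- c(ncol(roi$image), nrow(roi$image))
    vnames <- names(verts)[region_of_vertebra()[names(verts)] == rg]
    p2 <- predict_regressor(model$regressors$o2[[rg]],
                            roi_features(roi$image, cfg$o2_res))
    for (j in seq_along(vnames)) {
      vert_ctr[[vnames[j]]] <- roi$to_parent(p2[c(2 * j - 1, 2 * j)] * dims)
    }
  }

  out <- list()
  for (v in names(verts)) {
    roi <- crop_roi(image, roi_box_around(vert_ctr[[v]], cfg$vert_box, w, h),
                    cfg$margin)
    dims <- c(ncol(roi$image), nrow(roi$image))
    p3 <- predict_regressor(model$regressors$o3[[v]],
                            roi_features(roi$image, cfg$o3_res))
    for (j in seq_along(verts[[v]])) {
      out[[verts[[v]][j]]] <- roi$to_parent(p3[c(2 * j - 1, 2 * j)] * dims)
    }
  }
  nm <- landmark_names()
  xs <- vapply(nm, function(k) out[[k]][1], 0)
  ys <- vapply(nm, function(k) out[[k]][2], 0)
  clamped <- xs < 0 | xs > w - 1 | ys < 0 | ys > h - 1
  tibble::tibble(
    name = nm,
    x = pmin(pmax(xs, 0), w - 1),
    y = pmin(pmax(ys, 0), h - 1),
    clamped = clamped
  )
}

#' Evaluate detector predictions against ground truth
#'
#' Pairs predicted and true landmark sets; reports per-landmark Euclidean
#' pixel errors and per-parameter absolute angular errors obtained by
#' measuring all 12 parameters on the predicted and on the true landmarks.
#'
#' @param predictions List of prediction tibbles (from
#'   [predict_landmarks()]) or landmark sets.
#' @param truths List of [landmark_set()]s, same length.
#' @param frame A [frame_convention()].
#' @return Object of class `detector_evaluation`: list of tibbles
#'   `landmarks` (`landmark`, `mae_px`, `sd_px`), `parameters`
#'   (`parameter`, `mae_deg`, `sd_deg`), and `per_case`
#'   (`case`, `parameter`, `abs_error`).
#' @export
evaluate_detector <- function(predictions, truths, frame = frame_convention()) {
  if (length(predictions) != length(truths)) {
    abort("`predictions` and `truths` have different lengths")
  }
  if (!length(predictions)) abort("no prediction pairs")
  frame <- as_frame(frame)
  nm <- landmark_names()
  px_err <- matrix(NA_real_, length(predictions), length(nm),
                   dimnames = list(NULL, nm))
  par_rows <- list()
  for (i in seq_along(predictions)) {
    p <- predictions[[i]]; t_ <- truths[[i]]
    pm <- landmark_matrix(p, nm); tm <- landmark_matrix(t_, nm)
    px_err[i, ] <- sqrt(rowSums((pm - tm)^2))
    pars_t <- measure_parameters(t_, frame)
    pars_p <- tryCatch(measure_parameters(landmark_set(p[, c("name", "x", "y")]), frame),
                       error = function(e) NULL)
    if (!is.null(pars_p)) {
      par_rows[[i]] <- tibble::tibble(
        case = i, parameter = names(pars_t),
        abs_error = abs(as.numeric(pars_p[1, ]) - as.numeric(pars_t[1, ]))
      )
    }
  }
  per_case <- dplyr::bind_rows(par_rows)
  if (!nrow(per_case)) {
    per_case <- tibble::tibble(case = integer(), parameter = character(),
                               abs_error = numeric())
  }
  structure(
    list(
      landmarks = tibble::tibble(
        landmark = nm,
        mae_px = unname(colMeans(px_err)),
        sd_px = unname(apply(px_err, 2, sd))
      ),
      parameters = per_case |>
        dplyr::group_by(.data$parameter) |>
        dplyr::summarise(mae_deg = mean(.data$abs_error),
                         sd_deg = sd(.data$abs_error), .groups = "drop"),
      per_case = per_case
    ),
    class = "detector_evaluation"
  )
}

#' Save / load a cascade model
#'
#' Serialization round-trips produce bit-identical predictions.
#'
#' @param model A `cascade_model`.
#' @param path File path for the checkpoint archive.
#' @return `save_cascade()` returns `path` invisibly; `load_cascade()`
#'   returns the model.
#' @export
save_cascade <- function(model, path) {
  stopifnot(inherits(model, "cascade_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_cascade
#' @export
load_cascade <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cascade_model")) abort("not a cascade checkpoint")
  model
}
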