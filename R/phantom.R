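#' Phantom specification
#'
#' Target sagittal parameters plus rendering controls for one synthetic
#' subject.  The five targets PI, PT, L1I, T1I, C2I are the independent
#' angles of the measurement model; sacral slope and the six test
#' parameters follow from them deterministically.  All linear dimensions
#' default to fractions of the image height so a spec scales cleanly with
#' resolution; the default image is a 4x downscale of a 3240 x 1080 pixel
#' whole-spine film.
#'
#' @param pi_deg,pt,l1i,t1i,c2i Target pelvic incidence, pelvic tilt and
#'   L1/T1/C2 incidence angles, degrees.  (`pi_deg` avoids clashing with
#'   the constant `pi`.)
#' @param image_width,image_height Image size in pixels.
#' @param spine_length Arc length from the S1 endplate midpoint to the C2
#'   endplate midpoint, pixels.
#' @param pelvic_radius Distance from the femoral-head midpoint to the S1
#'   endplate midpoint, pixels.
#' @param head_sep Horizontal separation of the two femoral-head centers,
#'   pixels; 0 gives a perfect lateral with coincident heads.
#' @param head_radius Femoral-head disc radius, pixels (rendering).
#' @param half_widths Named numeric vector of endplate half-widths in
#'   pixels for `s1`, `l1`, `t1`, `c2`.
#' @param body_height Vertebral body height used when rendering, pixels.
#' @param noise Additive Gaussian noise level as a fraction of the
#'   intensity range (0 = none).
#' @param blur Gaussian blur standard deviation in pixels (0 = none).
#' @param anterior Frame convention anterior direction, `"+x"` or `"-x"`.
#' @param seed Integer seed; fully determines the rendered image.
#' @return An object of class `phantom_spec`.
#' @examples
#' phantom_spec(pi_deg = 52.16, pt = 14.99, seed = 1)
#' @export
phantom_spec <- function(pi_deg = 51.76, pt = 14.21, l1i = -0.56,
                         t1i = 39.07, c2i = 26.21,
                         image_width = 270, image_height = 810,
                         spine_length = 0.58 * image_height,
                         pelvic_radius = 0.065 * image_height,
                         head_sep = 0.022 * image_height,
                         head_radius = 0.02 * image_height,
                         half_widths = c(s1 = 0.030, l1 = 0.028,
                                         t1 = 0.024, c2 = 0.015) * image_height,
                         body_height = 0.026 * image_height,
                         noise = 0.05, blur = 1, anterior = "+x",
                         seed = 1L) {
  targets <- c(PI = pi_deg, PT = pt, L1I = l1i, T1I = t1i, C2I = c2i)
  if (!all(is.finite(targets))) abort("target parameters must be finite")
  if (image_width <= 0 || image_height <= 0) abort("image size must be positive")
  if (noise < 0 || blur < 0) abort("noise and blur must be non-negative")
  hw <- half_widths[c("s1", "l1", "t1", "c2")]
  if (anyNA(hw)) abort("`half_widths` needs entries s1, l1, t1, c2")
  structure(
    list(targets = targets,
         image_width = as.integer(image_width),
         image_height = as.integer(image_height),
         spine_length = spine_length, pelvic_radius = pelvic_radius,
         head_sep = head_sep, head_radius = head_radius,
         half_widths = hw, body_height = body_height,
         noise = noise, blur = blur, anterior = anterior,
         seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>", x$image_width, "x", x$image_height, "px, targets:",
      paste(names(x$targets), sprintf("%.2f", x$targets), collapse = ", "),
      "\n")
  invisible(x)
}

# Arc-length fractions of the S1->C2 centerline at which the inflection
# vertebrae sit: lumbar ~35%, thoracic ~45%, cervical ~20% of spine length.
spine_anchors <- function() c(s1 = 0, l1 = 0.35, t1 = 0.80, c2 = 1.0)

# Centerline from the S1 midpoint to C2: local travel direction follows the
# endplate perpendicular, with slope interpolated linearly in arc length
# between the anchor levels.  Because lateral position is a rendering
# choice (only endplate orientations carry the angles), the lateral drift
# is compressed about the S1 midpoint when a steep configuration would
# otherwise leave the canvas.
spine_centerline <- function(s1_mid, slopes, spec, orient, nstep = 400L) {
  rad <- function(d) d * base::pi / 180
  anch <- spine_anchors()
  tgrid <- seq(0, 1, length.out = nstep + 1L)
  sgrid <- stats::approx(anch, as.numeric(slopes), xout = tgrid)$y
  ds <- spec$spine_length / nstep
  cx <- s1_mid[1] + cumsum(orient * sin(rad(sgrid[-1])) * ds)
  cy <- s1_mid[2] + cumsum(-cos(rad(sgrid[-1])) * ds)
  pad <- max(spec$half_widths) + 2
  lo <- min(cx); hi <- max(cx)
  k <- 1
  if (hi + pad > spec$image_width - 1 && hi > s1_mid[1]) {
    k <- min(k, (spec$image_width - 1 - pad - s1_mid[1]) / (hi - s1_mid[1]))
  }
  if (lo - pad < 0 && lo < s1_mid[1]) {
    k <- min(k, (pad - s1_mid[1]) / (lo - s1_mid[1]))
  }
  k <- max(k, 0)
  if (k < 1) cx <- s1_mid[1] + k * (cx - s1_mid[1])
  list(x = cx, y = cy, sgrid = sgrid, nstep = nstep, compression = k)
}

#' Generate a landmark set from target parameters
#'
#' Forward model of the parameter definitions: places the femoral heads, S1
#' endplate and sacrum center so that the pelvic-tilt line makes angle PT
#' with the vertical and the S1 endplate makes angle SS = PI - PT with the
#' horizontal, then integrates a smooth centerline from S1 to C2 whose
#' local direction interpolates the endplate perpendiculars, and places the
#' L1/T1/C2 endplates on it at their target slopes (XI - PT).  Measuring
#' the returned landmarks recovers every target parameter to floating
#' precision; the centerline shape affects rendering only.
#'
#' @param spec A [phantom_spec()].
#' @return List with `landmarks` (a [landmark_set()]), `frame`, and
#'   `truth`, a one-row tibble of all 12 target parameter values.
#' @examples
#' ph <- generate_landmarks(phantom_spec(pi_deg = 52.16, pt = 14.99,
#'                                       l1i = 2.46, t1i = 39.77,
#'                                       c2i = 26.87, seed = 1))
#' measure_parameters(ph$landmarks, ph$frame)
#' @export
generate_landmarks <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  tg <- spec$targets
  frame <- frame_convention(spec$anterior)
  o <- frame$orient
  rad <- function(d) d * base::pi / 180
  slopes <- c(s1 = tg[["PI"]] - tg[["PT"]],
              l1 = tg[["L1I"]] - tg[["PT"]],
              t1 = tg[["T1I"]] - tg[["PT"]],
              c2 = tg[["C2I"]] - tg[["PT"]])

  w <- spec$image_width; h <- spec$image_height
  fm <- c(if (o > 0) 0.30 * w else 0.70 * w, 0.88 * h)
  # pelvic-tilt line leaves the femoral midpoint tilted PT posteriorly
  pt_dir <- c(-o * sin(rad(tg[["PT"]])), -cos(rad(tg[["PT"]])))
  s1_mid <- fm + spec$pelvic_radius * pt_dir

  eplate <- function(s) c(o * cos(rad(s)), sin(rad(s)))       # posterior->anterior
  nvec <- function(s) c(o * sin(rad(s)), -cos(rad(s)))        # endplate perpendicular, up

  cl <- spine_centerline(s1_mid, slopes, spec, o)
  anch <- spine_anchors()
  mid_at <- function(t) {
    if (t == 0) return(s1_mid)
    i <- round(t * cl$nstep)
    c(cl$x[i], cl$y[i])
  }

  hw <- spec$half_widths
  mids <- list(s1 = s1_mid, l1 = mid_at(anch[["l1"]]),
               t1 = mid_at(anch[["t1"]]), c2 = mid_at(anch[["c2"]]))
  pts <- list(
    femoral_head_1 = fm - c(spec$head_sep / 2, 0),
    femoral_head_2 = fm + c(spec$head_sep / 2, 0),
    sacrum_center = s1_mid - 0.9 * spec$body_height * nvec(slopes[["s1"]])
  )
  for (lv in names(mids)) {
    e <- eplate(slopes[[lv]])
    pr <- endplate_pairs()[[lv]]
    pts[[pr[1]]] <- mids[[lv]] - hw[[lv]] * e
    pts[[pr[2]]] <- mids[[lv]] + hw[[lv]] * e
  }
  tbl <- tibble::tibble(
    name = landmark_names(),
    x = vapply(landmark_names(), function(n) pts[[n]][1], 0),
    y = vapply(landmark_names(), function(n) pts[[n]][2], 0)
  )
  pad <- ifelse(startsWith(tbl$name, "femoral"), spec$head_radius, 2)
  out_of_bounds <- tbl$x < pad | tbl$x > w - 1 - pad |
    tbl$y < pad | tbl$y > h - 1 - pad
  if (any(out_of_bounds)) {
    abort(paste0("infeasible phantom spec: landmark(s) outside image bounds: ",
                 paste(tbl$name[out_of_bounds], collapse = ", ")),
          class = "spinesag_infeasible_spec")
  }
  truth <- dplyr::bind_cols(
    tibble::tibble(PI = tg[["PI"]], PT = tg[["PT"]], SS = tg[["PI"]] - tg[["PT"]],
                   L1I = tg[["L1I"]], T1I = tg[["T1I"]], C2I = tg[["C2I"]]),
    derive_parameters(c(PI = tg[["PI"]], PT = tg[["PT"]]),
                      c(L1I = tg[["L1I"]], T1I = tg[["T1I"]], C2I = tg[["C2I"]]))
  )
  list(landmarks = landmark_set(tbl), frame = frame, truth = truth)
}

#' Default cohort sampling configuration
#'
#' Per-parameter normal sampling moments and truncation bounds for the five
#' independent angles, anchored to a reference clinical cohort of 63
#' standing adults (mean, SD, min, max per parameter).  Sacral slope and
#' the six test parameters are always derived, never sampled, so every
#' synthetic subject satisfies the angle identities exactly.
#'
#' @return Tibble with columns `parameter`, `mean`, `sd`, `min`, `max`.
#' @export
cohort_defaults <- function() {
  tibble::tribble(
    ~parameter, ~mean, ~sd, ~min, ~max,
    "PI", 51.76, 12.47, 27.94, 80.18,
    "PT", 14.21, 8.94, -5.36, 46.55,
    "L1I", -0.56, 13.30, -23.69, 54.78,
    "T1I", 39.07, 11.74, 12.50, 64.85,
    "C2I", 26.21, 11.26, 2.76, 53.06
  )
}

sample_truncnorm <- function(n, mean, sd, lo, hi) {
  if (sd == 0) return(rep(mean, n))
  out <- numeric(0)
  while (length(out) < n) {
    draw <- rnorm(2L * (n - length(out)) + 8L, mean, sd)
    out <- c(out, draw[draw >= lo & draw <= hi])
  }
  out[seq_len(n)]
}

#' Sample a synthetic cohort of landmark sets
#'
#' Draws `n` subjects with PI, PT, L1I, T1I, C2I from independent truncated
#' normals (defaults from [cohort_defaults()]), builds each subject's
#' landmark set with [generate_landmarks()], and resamples any subject
#' whose target configuration is geometrically infeasible within the image
#' (bounded retries).
#'
#' @param n Number of subjects.
#' @param config Data frame like [cohort_defaults()]; rows for `PI`, `PT`,
#'   `L1I`, `T1I`, `C2I`.
#' @param spec Base [phantom_spec()] supplying geometry/rendering controls;
#'   its target angles are overwritten per subject.
#' @param seed Integer seed for the sampler.
#' @param max_retries Resampling attempts per subject before erroring.
#' @return Tibble of class `phantom_cohort`: one row per subject with
#'   `subject`, the 12 truth parameters, and a `landmarks` list-column.
#' @examples
#' cohort <- sample_cohort(5, seed = 42)
#' dplyr::glimpse(cohort[, 1:6])
#' @export
sample_cohort <- function(n, config = cohort_defaults(),
                          spec = phantom_spec(), seed = 1L,
                          max_retries = 50L) {
  stopifnot(n >= 0, is.data.frame(config))
  if (any(config$sd < 0)) abort("sampling SDs must be non-negative")
  rows <- match(c("PI", "PT", "L1I", "T1I", "C2I"), config$parameter)
  if (anyNA(rows)) abort("config must contain rows PI, PT, L1I, T1I, C2I")
  cfg <- config[rows, ]
  empty <- tibble::tibble(subject = integer())
  if (n == 0) {
    out <- empty
    class(out) <- c("phantom_cohort", class(out))
    return(out)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  subjects <- vector("list", n)
  for (i in seq_len(n)) {
    got <- NULL
    for (try in seq_len(max_retries)) {
      draw <- stats::setNames(
        mapply(function(m, s, lo, hi) sample_truncnorm(1, m, s, lo, hi),
               cfg$mean, cfg$sd, cfg$min, cfg$max),
        cfg$parameter
      )
      sp <- spec
      sp$targets <- c(PI = draw[["PI"]], PT = draw[["PT"]], L1I = draw[["L1I"]],
                      T1I = draw[["T1I"]], C2I = draw[["C2I"]])
      got <- tryCatch(generate_landmarks(sp),
                      spinesag_infeasible_spec = function(e) NULL)
      if (!is.null(got)) break
    }
    if (is.null(got)) {
      abort(paste0("could not draw a feasible subject after ", max_retries,
                   " attempts (subject ", i, ")"))
    }
    subjects[[i]] <- dplyr::bind_cols(
      tibble::tibble(subject = i), got$truth,
      tibble::tibble(landmarks = list(got$landmarks))
    )
  }
  out <- dplyr::bind_rows(subjects)
  class(out) <- c("phantom_cohort", class(out))
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
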