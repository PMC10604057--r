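# Rasterization of phantom radiographs: plain intensity matrices in [0, 1],
# row = y + 1, col = x + 1 (origin top-left, y down), matching the landmark
# pixel frame.

draw_disc <- function(img, cx, cy, r, val) {
  h <- nrow(img); w <- ncol(img)
  xs <- max(1L, floor(cx - r) + 1L):min(w, ceiling(cx + r) + 1L)
  ys <- max(1L, floor(cy - r) + 1L):min(h, ceiling(cy + r) + 1L)
  if (!length(xs) || !length(ys)) return(img)
  px <- outer(rep(1, length(ys)), xs - 1)
  py <- outer(ys - 1, rep(1, length(xs)))
  inside <- (px - cx)^2 + (py - cy)^2 <= r^2
  sub <- img[ys, xs, drop = FALSE]
  sub[inside] <- val
  img[ys, xs] <- sub
  img
}

# Convex quadrilateral given as 4x2 matrix of (x, y) corners in cyclic
# order (either winding): a pixel is inside when its half-plane cross
# products carry one sign for all four edges.
draw_quad <- function(img, corners, val) {
  h <- nrow(img); w <- ncol(img)
  xs <- max(1L, floor(min(corners[, 1])) + 1L):min(w, ceiling(max(corners[, 1])) + 1L)
  ys <- max(1L, floor(min(corners[, 2])) + 1L):min(h, ceiling(max(corners[, 2])) + 1L)
  if (!length(xs) || !length(ys)) return(img)
  px <- outer(rep(1, length(ys)), xs - 1)
  py <- outer(ys - 1, rep(1, length(xs)))
  pos <- TRUE; neg <- TRUE
  for (i in 1:4) {
    a <- corners[i, ]; b <- corners[if (i == 4) 1 else i + 1, ]
    cross <- (b[1] - a[1]) * (py - a[2]) - (b[2] - a[2]) * (px - a[1])
    pos <- pos & (cross >= 0)
    neg <- neg & (cross <= 0)
  }
  inside <- pos | neg
  sub <- img[ys, xs, drop = FALSE]
  sub[inside] <- val
  img[ys, xs] <- sub
  img
}

gaussian_kernel <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian blur with edge clamping.
blur_image <- function(img, sigma) {
  if (sigma <= 0) return(img)
  k <- gaussian_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  conv_cols <- function(m) {
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      idx <- pmin(pmax(seq_len(n) + (j - 1L - r), 1L), n)
      out <- out + k[j] * m[idx, , drop = FALSE]
    }
    out
  }
  t(conv_cols(t(conv_cols(img))))
}

#' Render a phantom radiograph
#'
#' Draws femoral-head discs and vertebral-body quadrilaterals along the
#' interpolated spine centerline onto a grayscale canvas, then applies
#' Gaussian blur and additive Gaussian noise per the `spec` settings.  The annotation
#' coordinates are exactly the input landmarks; intermediate (unlabeled)
#' vertebral bodies are drawn between the inflection levels for visual
#' plausibility only.
#'
#' @param landmarks A [landmark_set()] (typically from
#'   [generate_landmarks()]).
#' @param spec The [phantom_spec()] providing image size, rendering sizes,
#'   noise, blur and seed.
#' @return An object of class `annotated_image`: list with `image` (matrix
#'   in \[0, 1\], `image_height` rows by `image_width` columns), `landmarks`,
#'   `frame`, and `truth` (the [sagittal_report()] of the landmarks).
#' @examples
#' ph <- generate_landmarks(phantom_spec(seed = 5, image_width = 135,
#'                                       image_height = 405))
#' ann <- render_radiograph(ph$landmarks, phantom_spec(seed = 5,
#'   image_width = 135, image_height = 405))
#' dim(ann$image)
#' @export
render_radiograph <- function(landmarks, spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  landmarks <- as_landmarks(landmarks)
  frame <- frame_convention(spec$anterior)
  o <- frame$orient
  w <- spec$image_width; h <- spec$image_height
  oob <- landmarks$x < 0 | landmarks$x > w - 1 |
    landmarks$y < 0 | landmarks$y > h - 1
  if (any(oob)) {
    abort(paste0("landmark(s) outside image bounds: ",
                 paste(landmarks$name[oob], collapse = ", ")))
  }
  rad <- function(d) d * base::pi / 180
  img <- matrix(0.08, nrow = h, ncol = w)
  bone <- 0.85

  for (nm in c("femoral_head_1", "femoral_head_2")) {
    p <- lm_point(landmarks, nm)
    img <- draw_disc(img, p[1], p[2], spec$head_radius, bone)
  }

  pel <- pelvic_parameters(landmarks, frame)
  inc <- incidence_angles(landmarks, frame)
  slopes <- c(s1 = pel$SS, l1 = inc$L1I - pel$PT,
              t1 = inc$T1I - pel$PT, c2 = inc$C2I - pel$PT)
  eplate <- function(s) c(o * cos(rad(s)), sin(rad(s)))
  nv <- function(s) c(o * sin(rad(s)), -cos(rad(s)))

  body_quad <- function(mid, slope, half_width, height, upward) {
    e <- eplate(slope); n <- nv(slope)
    a <- mid + half_width * e; p <- mid - half_width * e
    sgn <- if (upward) 1 else -1
    rbind(p, a, a + sgn * height * n, p + sgn * height * n)
  }

  # labeled vertebrae: body on the far side of the labeled endplate
  for (lv in names(endplate_pairs())) {
    pr <- endplate_pairs()[[lv]]
    mid <- lm_mid(landmarks, pr[1], pr[2])
    hw <- spec$half_widths[[lv]]
    img <- draw_quad(img, body_quad(mid, slopes[[lv]], hw,
                                    spec$body_height, upward = lv == "c2"),
                     bone)
  }

  # intermediate bodies along the interpolated centerline (rendering only)
  s1_mid <- lm_mid(landmarks, "s1_sup_ant", "s1_sup_post")
  anch <- spine_anchors()
  cl <- spine_centerline(s1_mid, slopes, spec, o)
  cx <- cl$x; cy <- cl$y
  tmids <- setdiff(seq(0.07, 0.95, by = 0.055),
                   unlist(lapply(anch, function(a) a + c(-0.02, 0, 0.02))))
  for (t in tmids) {
    i <- max(1L, round(t * cl$nstep))
    s <- cl$sgrid[i + 1L]
    hwi <- stats::approx(anch, as.numeric(spec$half_widths), xout = t)$y
    img <- draw_quad(img, body_quad(c(cx[i], cy[i]), s, 0.9 * hwi,
                                    0.8 * spec$body_height, upward = FALSE),
                     0.75 * bone)
  }

  img <- blur_image(img, spec$blur)
  if (spec$noise > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(spec$seed)
    img <- img + matrix(rnorm(length(img), 0, spec$noise), nrow = h)
  }
  img[img < 0] <- 0
  img[img > 1] <- 1
  structure(
    list(image = img, landmarks = landmarks, frame = frame,
         truth = sagittal_report(landmarks, frame)),
    class = "annotated_image"
  )
}

#' @export
print.annotated_image <- function(x, ...) {
  cat("<annotated_image>", ncol(x$image), "x", nrow(x$image),
      "px with", nrow(x$landmarks), "landmarks\n")
  invisible(x)
}

#' Write a grayscale image to PNG
#'
#' @param image Numeric matrix in \[0, 1\] or an `annotated_image`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_radiograph <- function(image, path) {
  if (inherits(image, "annotated_image")) image <- image$image
  png::writePNG(image, target = path)
  invisible(path)
}

#' Read a grayscale image from PNG or TIFF
#'
#' Multichannel images are averaged to one gray channel.
#'
#' @param path Image file path (PNG).
#' @return Numeric matrix in \[0, 1\].
#' @export
read_radiograph <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- apply(img[, , 1:min(3, dim(img)[3]), drop = FALSE], c(1, 2), mean)
  img
}
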