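#' Signed angle between two vectors in the image plane
#'
#' The magnitude is `acos` of the normalized dot product of the two vectors;
#' the sign comes from the 2-D cross product, oriented by the frame
#' convention so that a rotation from `v1` toward the patient's anterior
#' side is positive.  Under the package's sign rules this makes an endplate
#' perpendicular lying anterior to the pelvic-tilt line a positive
#' incidence, and an endplate sloping downward anteriorly a positive slope.
#'
#' @param v1,v2 Numeric length-2 vectors in image pixel coordinates
#'   (x rightward, y downward).
#' @param frame A [frame_convention()] (or `"+x"` / `"-x"`).
#' @param what Optional label naming the landmark pair, used in error
#'   messages for degenerate (zero-length) vectors.
#' @return Signed angle in degrees, in (-180, 180].
#' @examples
#' signed_angle(c(1, 0), c(1, 1), frame_convention("+x"))
#' @export
signed_angle <- function(v1, v2, frame = frame_convention(), what = NULL) {
  frame <- as_frame(frame)
  n1 <- sqrt(sum(v1^2))
  n2 <- sqrt(sum(v2^2))
  if (n1 == 0 || n2 == 0) {
    abort(paste0("zero-length vector in angle computation",
                 if (!is.null(what)) paste0(" (", what, ")")))
  }
  # atan2(|cross|, dot) equals the arccos of the normalized dot product
  # but stays fully conditioned near 0 and 180 degrees
  dot <- sum(v1 * v2)
  cross <- v1[1] * v2[2] - v1[2] * v2[1]
  mag <- atan2(abs(cross), dot) * 180 / pi
  s <- sign(cross * frame$orient)
  ang <- if (s == 0) mag else s * mag
  if (ang <= -180) ang <- ang + 360
  ang
}

# Rotate a vector 90 degrees "toward up" under the frame: the anterior
# horizontal maps onto (0, -1).  This fixes the perpendicular branch used
# for all endplate perpendiculars.
perp_up <- function(v, frame) {
  frame <- as_frame(frame)
  if (frame$orient > 0) c(v[2], -v[1]) else c(-v[2], v[1])
}

up_vec <- function() c(0, -1)

anterior_vec <- function(frame) c(as_frame(frame)$orient, 0)

# Endplate vector, directed posterior -> anterior endpoint.
endplate_vec <- function(lms, level) {
  pr <- endplate_pairs()[[level]]
  v <- lm_point(lms, pr[2]) - lm_point(lms, pr[1])
  if (sum(v^2) == 0) {
    abort(paste0("degenerate ", toupper(level), " endplate"))
  }
  v
}

#' Pelvic-tilt line
#'
#' The vector from the midpoint of the two femoral-head centers to the
#' midpoint of the S1 superior endplate.
#'
#' @param landmarks A [landmark_set()].
#' @return Numeric length-2 vector in image pixel coordinates.
#' @export
pt_line <- function(landmarks) {
  landmarks <- as_landmarks(landmarks)
  v <- lm_mid(landmarks, "s1_sup_ant", "s1_sup_post") -
    lm_mid(landmarks, "femoral_head_1", "femoral_head_2")
  if (sum(v^2) == 0) {
    abort("degenerate pelvic-tilt line: femoral midpoint equals S1 endplate midpoint")
  }
  v
}

as_landmarks <- function(landmarks) {
  if (inherits(landmarks, "landmark_set")) landmarks else landmark_set(landmarks)
}

#' Pelvic parameters from landmarks
#'
#' Computes pelvic incidence (PI), pelvic tilt (PT) and sacral slope (SS):
#' PI is the signed angle between the pelvic-tilt line and the S1 superior
#' endplate perpendicular; PT the signed angle between the vertical and the
#' pelvic-tilt line (positive when the S1 midpoint lies posterior to the
#' femoral midpoint); SS the signed angle between the horizontal and the S1
#' endplate (positive when the endplate slopes downward anteriorly).  The
#' identity PI = PT + SS holds by construction of the sign rules.
#'
#' @inheritParams pt_line
#' @param frame A [frame_convention()].
#' @return One-row tibble with columns `PI`, `PT`, `SS` (degrees).
#' @examples
#' ph <- generate_landmarks(phantom_spec(pi_deg = 52, pt = 15, seed = 1))
#' pelvic_parameters(ph$landmarks)
#' @export
pelvic_parameters <- function(landmarks, frame = frame_convention()) {
  landmarks <- as_landmarks(landmarks)
  frame <- as_frame(frame)
  ptv <- pt_line(landmarks)
  e_s1 <- endplate_vec(landmarks, "s1")
  tibble::tibble(
    PI = signed_angle(ptv, perp_up(e_s1, frame), frame, "pt_line vs S1 perpendicular"),
    PT = signed_angle(ptv, up_vec(), frame, "pt_line vs vertical"),
    SS = signed_angle(anterior_vec(frame), e_s1, frame, "horizontal vs S1 endplate")
  )
}

#' Incidence angles of the inflection points
#'
#' The incidence angle of an inflection vertebra (L1, T1, C2) is the signed
#' angle between the pelvic-tilt line and the perpendicular of that
#' vertebra's endplate (superior endplate for L1 and T1, inferior for C2).
#' Each incidence equals the vertebra's slope plus the pelvic tilt.
#'
#' @inheritParams pelvic_parameters
#' @return One-row tibble with columns `L1I`, `T1I`, `C2I` (degrees).
#' @export
incidence_angles <- function(landmarks, frame = frame_convention()) {
  landmarks <- as_landmarks(landmarks)
  frame <- as_frame(frame)
  ptv <- pt_line(landmarks)
  inc <- function(level) {
    signed_angle(ptv, perp_up(endplate_vec(landmarks, level), frame), frame,
                 paste0("pt_line vs ", toupper(level), " perpendicular"))
  }
  tibble::tibble(L1I = inc("l1"), T1I = inc("t1"), C2I = inc("c2"))
}

#' Directly measured test parameters
#'
#' The six test parameters measured directly from landmark geometry:
#' lumbar lordosis `LL` (S1 vs L1 superior endplates), thoracic kyphosis
#' `TK` (L1 vs T1 superior endplates) and C2-C7 lordosis `C2_7L` (C2
#' inferior vs T1 superior endplates) as signed Cobb angles, plus the
#' slopes `L1S`, `T1S`, `C2S` of the named endplates against the
#' horizontal.  Lordotic (posteriorly rotated relative to the caudal
#' reference) angles are negative, kyphotic positive.
#'
#' @inheritParams pelvic_parameters
#' @return One-row tibble with columns `LL`, `TK`, `C2_7L`, `L1S`, `T1S`,
#'   `C2S` (degrees).
#' @export
direct_parameters <- function(landmarks, frame = frame_convention()) {
  landmarks <- as_landmarks(landmarks)
  frame <- as_frame(frame)
  e <- lapply(stats::setNames(nm = names(endplate_pairs())),
              function(l) endplate_vec(landmarks, l))
  a <- anterior_vec(frame)
  tibble::tibble(
    LL = signed_angle(e$s1, e$l1, frame, "S1 vs L1 endplates"),
    TK = signed_angle(e$l1, e$t1, frame, "L1 vs T1 endplates"),
    C2_7L = signed_angle(e$c2, e$t1, frame, "C2 vs T1 endplates"),
    L1S = signed_angle(a, e$l1, frame, "horizontal vs L1 endplate"),
    T1S = signed_angle(a, e$t1, frame, "horizontal vs T1 endplate"),
    C2S = signed_angle(a, e$c2, frame, "horizontal vs C2 endplate")
  )
}

#' Derive the six test parameters from pelvic parameters and incidences
#'
#' Pure arithmetic on the three pelvic parameters and the three incidence
#' angles of the inflection points:
#' lumbar lordosis = L1I - PI; thoracic kyphosis = T1I - L1I;
#' C2-C7 lordosis = T1I - C2I; L1 slope = L1I - PT;
#' T1 slope = T1I - PT; C2 slope = C2I - PT.
#'
#' Accepts either a pair of one-row tibbles (as returned by
#' [pelvic_parameters()] and [incidence_angles()]) or equal-length numeric
#' vectors, and is vectorized over rows.
#'
#' @param pelvic Data frame with columns `PI`, `PT` (and optionally `SS`),
#'   or a named numeric vector.
#' @param incidences Data frame with columns `L1I`, `T1I`, `C2I`, or a
#'   named numeric vector.
#' @return Tibble with columns `LL`, `TK`, `C2_7L`, `L1S`, `T1S`, `C2S`.
#' @examples
#' derive_parameters(
#'   tibble::tibble(PI = 52.16, PT = 14.99),
#'   tibble::tibble(L1I = 2.46, T1I = 39.77, C2I = 26.87)
#' )
#' @export
derive_parameters <- function(pelvic, incidences) {
  if (!is.data.frame(pelvic)) pelvic <- tibble::as_tibble(as.list(pelvic))
  if (!is.data.frame(incidences)) incidences <- tibble::as_tibble(as.list(incidences))
  need_p <- setdiff(c("PI", "PT"), names(pelvic))
  need_i <- setdiff(c("L1I", "T1I", "C2I"), names(incidences))
  if (length(need_p) || length(need_i)) {
    abort(paste0("missing parameter column(s): ",
                 paste(c(need_p, need_i), collapse = ", ")))
  }
  vals <- c(pelvic$PI, pelvic$PT, incidences$L1I, incidences$T1I, incidences$C2I)
  if (!all(is.finite(vals))) abort("non-finite parameter values")
  tibble::tibble(
    LL = incidences$L1I - pelvic$PI,
    TK = incidences$T1I - incidences$L1I,
    C2_7L = incidences$T1I - incidences$C2I,
    L1S = incidences$L1I - pelvic$PT,
    T1S = incidences$T1I - pelvic$PT,
    C2S = incidences$C2I - pelvic$PT
  )
}

#' Full sagittal measurement report
#'
#' Measures all 12 parameters from a landmark set: the three pelvic
#' parameters, the three incidence angles, and the six test parameters both
#' directly from landmark geometry and derived through the incidence-angle
#' equations, with the per-parameter absolute discrepancy between the two
#' routes.  On exact landmark sets the discrepancy is zero to floating
#' precision, since the derivation equations are analytic identities of the
#' sign conventions.
#'
#' @inheritParams pelvic_parameters
#' @return A tibble of class `sagittal_report` with columns `parameter`,
#'   `group` (`pelvic`, `incidence` or `test`), `direct`, `derived`,
#'   `discrepancy`.  Pelvic and incidence rows carry `NA` in `derived` and
#'   `discrepancy`.
#' @examples
#' ph <- generate_landmarks(phantom_spec(seed = 3))
#' sagittal_report(ph$landmarks)
#' @export
sagittal_report <- function(landmarks, frame = frame_convention()) {
  landmarks <- as_landmarks(landmarks)
  frame <- as_frame(frame)
  pel <- pelvic_parameters(landmarks, frame)
  inc <- incidence_angles(landmarks, frame)
  dir <- direct_parameters(landmarks, frame)
  der <- derive_parameters(pel, inc)
  test_names <- names(der)
  out <- dplyr::bind_rows(
    tibble::tibble(parameter = names(pel), group = "pelvic",
                   direct = as.numeric(pel[1, ]), derived = NA_real_),
    tibble::tibble(parameter = names(inc), group = "incidence",
                   direct = as.numeric(inc[1, ]), derived = NA_real_),
    tibble::tibble(parameter = test_names, group = "test",
                   direct = as.numeric(dir[1, ]),
                   derived = as.numeric(der[1, ]))
  )
  out$discrepancy <- abs(out$direct - out$derived)
  class(out) <- c("sagittal_report", class(out))
  out
}

#' Measure all 12 parameters as a single wide row
#'
#' Convenience wrapper around the individual measurement functions,
#' returning one row per landmark set for cohort-style pipelines.
#'
#' @inheritParams pelvic_parameters
#' @return One-row tibble with columns `PI`, `PT`, `SS`, `L1I`, `T1I`,
#'   `C2I`, `LL`, `TK`, `C2_7L`, `L1S`, `T1S`, `C2S` (directly measured).
#' @export
measure_parameters <- function(landmarks, frame = frame_convention()) {
  landmarks <- as_landmarks(landmarks)
  dplyr::bind_cols(
    pelvic_parameters(landmarks, frame),
    incidence_angles(landmarks, frame),
    direct_parameters(landmarks, frame)
  )
}
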