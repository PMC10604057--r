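#' Canonical landmark names
#'
#' The eleven anatomical landmarks used for whole-spine sagittal measurement:
#' the centers of both femoral heads, the center of the sacrum, and the
#' anterior/posterior endpoints of the S1, L1 and T1 superior endplates and
#' the C2 inferior endplate.
#'
#' @return Character vector of the 11 canonical landmark names, in order.
#' @export
landmark_names <- function() {
  c("femoral_head_1", "femoral_head_2", "sacrum_center",
    "s1_sup_ant", "s1_sup_post",
    "l1_sup_ant", "l1_sup_post",
    "t1_sup_ant", "t1_sup_post",
    "c2_inf_ant", "c2_inf_post")
}

#' Frame convention for a lateral radiograph
#'
#' Landmark coordinates are raster pixels: origin at the top-left corner,
#' x increasing rightward, y increasing downward.  "Up" is therefore the
#' negative y axis.  Whether the patient's anterior side points toward +x
#' or -x cannot be inferred from an image reliably, so it is an explicit,
#' mandatory piece of metadata carried alongside every landmark set.
#'
#' @param anterior Direction of the patient's anterior (front) side in the
#'   image frame, `"+x"` (patient faces right, the default) or `"-x"`.
#' @return An object of class `frame_convention`.
#' @examples
#' frame_convention("+x")
#' @export
frame_convention <- function(anterior = c("+x", "-x")) {
  anterior <- match.arg(anterior)
  structure(
    list(anterior = anterior, orient = if (anterior == "+x") 1 else -1),
    class = "frame_convention"
  )
}

#' @export
print.frame_convention <- function(x, ...) {
  cat("<frame_convention> anterior:", x$anterior, "(y down, up = -y)\n")
  invisible(x)
}

as_frame <- function(frame) {
  if (inherits(frame, "frame_convention")) return(frame)
  if (is.character(frame) && length(frame) == 1) return(frame_convention(frame))
  abort("`frame` must be a frame_convention or one of \"+x\", \"-x\".")
}

#' Construct a validated landmark set
#'
#' A landmark set is a tibble with columns `name`, `x`, `y` holding the 11
#' canonical landmarks exactly once each, in pixel coordinates.
#'
#' Validation enforces: all 11 canonical names present exactly once, finite
#' coordinates, distinct anterior/posterior endpoints for every endplate,
#' and a femoral-head midpoint distinct from the S1 endplate midpoint (the
#' two femoral heads themselves may coincide on a perfect lateral view).
#'
#' @param data A data frame with columns `name`, `x`, `y`.
#' @return A tibble of class `landmark_set`, rows ordered canonically.
#' @examples
#' lms <- generate_landmarks(phantom_spec(seed = 1))$landmarks
#' landmark_set(lms)
#' @export
landmark_set <- function(data) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  need <- c("name", "x", "y")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(paste0("landmark data lacks column(s): ", paste(miss, collapse = ", ")))
  }
  canon <- landmark_names()
  dup <- unique(data$name[duplicated(data$name)])
  if (length(dup)) {
    abort(paste0("duplicate landmark name(s): ", paste(dup, collapse = ", ")))
  }
  missing_names <- setdiff(canon, data$name)
  if (length(missing_names)) {
    abort(paste0("missing landmark(s): ", paste(missing_names, collapse = ", ")))
  }
  extra <- setdiff(data$name, canon)
  if (length(extra)) {
    abort(paste0("unknown landmark name(s): ", paste(extra, collapse = ", ")))
  }
  out <- tibble::as_tibble(data[match(canon, data$name), need])
  out$x <- as.numeric(out$x)
  out$y <- as.numeric(out$y)
  if (!all(is.finite(out$x)) || !all(is.finite(out$y))) {
    bad <- out$name[!is.finite(out$x) | !is.finite(out$y)]
    abort(paste0("non-finite coordinates for: ", paste(bad, collapse = ", ")))
  }
  class(out) <- c("landmark_set", class(out))
  validate_geometry(out)
  out
}

lm_point <- function(lms, name) {
  i <- match(name, lms$name)
  c(lms$x[i], lms$y[i])
}

lm_mid <- function(lms, name_a, name_b) {
  (lm_point(lms, name_a) + lm_point(lms, name_b)) / 2
}

endplate_pairs <- function() {
  list(
    s1 = c("s1_sup_post", "s1_sup_ant"),
    l1 = c("l1_sup_post", "l1_sup_ant"),
    t1 = c("t1_sup_post", "t1_sup_ant"),
    c2 = c("c2_inf_post", "c2_inf_ant")
  )
}

validate_geometry <- function(lms) {
  for (nm in names(endplate_pairs())) {
    pr <- endplate_pairs()[[nm]]
    v <- lm_point(lms, pr[2]) - lm_point(lms, pr[1])
    if (sum(v^2) == 0) {
      abort(paste0("degenerate ", toupper(nm),
                   " endplate: anterior and posterior endpoints coincide"))
    }
  }
  fm <- lm_mid(lms, "femoral_head_1", "femoral_head_2")
  s1 <- lm_mid(lms, "s1_sup_ant", "s1_sup_post")
  if (sum((s1 - fm)^2) == 0) {
    abort("degenerate pelvis: femoral-head midpoint coincides with the S1 endplate midpoint")
  }
  invisible(lms)
}
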