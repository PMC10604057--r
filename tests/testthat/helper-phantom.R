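# Shared fixtures: all phantoms are generated in code at test time.

# small rendering size keeps image tests fast; angles are scale-free
small_spec <- function(..., seed = 1L) {
  phantom_spec(image_width = 108, image_height = 324, ..., seed = seed)
}

# landmark set built from explicit points, bypassing the phantom
manual_landmarks <- function(points) {
  landmark_set(tibble::tibble(
    name = names(points),
    x = vapply(points, `[`, 0, 1),
    y = vapply(points, `[`, 0, 2)
  ))
}

# a simple valid configuration used by several geometry tests:
# vertical pelvis, horizontal S1 endplate, straight vertical spine
straight_landmarks <- function() {
  manual_landmarks(list(
    femoral_head_1 = c(-2, 110), femoral_head_2 = c(2, 110),
    sacrum_center = c(0, 105),
    s1_sup_ant = c(10, 100), s1_sup_post = c(-10, 100),
    l1_sup_ant = c(9, 70), l1_sup_post = c(-9, 70),
    t1_sup_ant = c(8, 40), t1_sup_post = c(-8, 40),
    c2_inf_ant = c(5, 20), c2_inf_post = c(-5, 20)
  ))
}

# random landmark set with non-degenerate endplates (identities must hold
# for any valid configuration, not only phantom-shaped ones)
random_landmarks <- function() {
  repeat {
    pts <- lapply(landmark_names(), function(n) runif(2, 10, 500))
    names(pts) <- landmark_names()
    lms <- tryCatch(manual_landmarks(pts), error = function(e) NULL)
    if (!is.null(lms)) return(lms)
  }
}

# random feasible phantom targets spanning the clinical ranges
random_feasible_spec <- function(base = phantom_spec()) {
  repeat {
    sp <- base
    sp$targets <- c(PI = runif(1, 30, 80), PT = runif(1, -5, 40),
                    L1I = runif(1, -20, 40), T1I = runif(1, 15, 60),
                    C2I = runif(1, 5, 50))
    ok <- tryCatch({generate_landmarks(sp); TRUE},
                   spinesag_infeasible_spec = function(e) FALSE)
    if (ok) return(sp)
  }
}

rotate_landmarks <- function(lms, angle_deg, center) {
  th <- angle_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  m <- t(R %*% t(cbind(lms$x - center[1], lms$y - center[2])))
  landmark_set(tibble::tibble(name = lms$name,
                              x = m[, 1] + center[1],
                              y = m[, 2] + center[2]))
}
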