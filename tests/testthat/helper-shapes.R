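# Shared fixtures: parametric shapes and independent plain-R oracles.

rot2 <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
}

mk_ellipse <- function(a, b, angle = 0, n = 48, center = c(0, 0)) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  v <- cbind(a * cos(t), b * sin(t)) %*% t(rot2(angle))
  contour2d(sweep(v, 2, center, `+`))
}

mk_rect <- function(w, h, angle = 0, center = c(0, 0)) {
  v <- rbind(c(-w / 2, -h / 2), c(w / 2, -h / 2), c(w / 2, h / 2), c(-w / 2, h / 2))
  contour2d(sweep(v %*% t(rot2(angle)), 2, center, `+`))
}

# L-shaped (non-convex) hexagon
mk_lshape <- function(s = 10) {
  contour2d(rbind(c(0, 0), c(2 * s, 0), c(2 * s, s), c(s, s),
                  c(s, 2 * s), c(0, 2 * s)))
}

# independent plain-R first-hit ray oracle: exhaustive edge intersection
ray_oracle <- function(contour, origin, direction) {
  v <- contour$vertices
  n <- nrow(v)
  d <- direction / sqrt(sum(direction^2))
  best <- Inf
  for (i in seq_len(n)) {
    a <- v[i, ]; b <- v[if (i == n) 1 else i + 1, ]
    e <- b - a
    den <- d[1] * e[2] - d[2] * e[1]
    if (abs(den) < 1e-14) next
    w <- a - origin
    t <- (w[1] * e[2] - w[2] * e[1]) / den
    s <- (w[1] * d[2] - w[2] * d[1]) / den
    if (t > 1e-12 && s >= -1e-12 && s <= 1 + 1e-12 && t < best) best <- t
  }
  unname(best)
}

fraction_params <- function(...) {
  model_params(spindle_length_mode = "fraction", ...)
}
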