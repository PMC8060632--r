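# Shared fixture builders: everything is generated in code at test time.

# A tiny deterministic RGB array (h x w x 3, integer 0..255).
tiny_rgb <- function(r, g, b) {
  h <- nrow(r)
  w <- ncol(r)
  img <- array(0L, c(h, w, 3))
  img[, , 1] <- r; img[, , 2] <- g; img[, , 3] <- b
  storage.mode(img) <- "integer"
  img
}

# Writes a synthetic canopy scene as a PNG and returns path + truth.
write_scene_png <- function(target_cover, seed, dir = tempdir(), ...) {
  scn <- simulate_canopy_image(
    scene_config(target_cover = target_cover, seed = seed, ...))
  path <- tempfile(tmpdir = dir, fileext = ".png")
  png::writePNG(scn$image / 255, path)
  list(path = path, scene = scn)
}

# Independent straight-line RSS via explicit normal equations (not lm).
rss_normal_equations <- function(x, y) {
  n <- length(x)
  sxx <- sum(x^2) - sum(x)^2 / n
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  syy <- sum(y^2) - sum(y)^2 / n
  syy - sxy^2 / sxx
}
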