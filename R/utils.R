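# Shared numeric helpers.

clip01 <- function(x) pmin(pmax(x, 0), 1)

# Runs `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards so library code never perturbs user randomness.
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Bilinear resize of a matrix or an H x W x C array, sampling at pixel
# centres with edge clamping.
resize_bilinear <- function(x, out_h, out_w) {
  d <- dim(x)
  h <- d[1]; w <- d[2]
  if (h == out_h && w == out_w) return(x)
  src_y <- pmin(pmax((seq_len(out_h) - 0.5) * h / out_h + 0.5, 1), h)
  src_x <- pmin(pmax((seq_len(out_w) - 0.5) * w / out_w + 0.5, 1), w)
  y0 <- floor(src_y); y1 <- pmin(y0 + 1, h); wy <- src_y - y0
  x0 <- floor(src_x); x1 <- pmin(x0 + 1, w); wx <- src_x - x0
  w00 <- outer(1 - wy, 1 - wx); w01 <- outer(1 - wy, wx)
  w10 <- outer(wy, 1 - wx); w11 <- outer(wy, wx)
  one_plane <- function(m) {
    w00 * m[y0, x0, drop = FALSE] + w01 * m[y0, x1, drop = FALSE] +
      w10 * m[y1, x0, drop = FALSE] + w11 * m[y1, x1, drop = FALSE]
  }
  if (length(d) == 2L) return(one_plane(x))
  out <- array(0, c(out_h, out_w, d[3]))
  for (ch in seq_len(d[3])) out[, , ch] <- one_plane(x[, , ch])
  out
}

# RGB triple (v = 1) for a hue in degrees and a saturation in [0, 1].
hsv_unit <- function(h_deg, s) {
  as.numeric(grDevices::col2rgb(grDevices::hsv((h_deg %% 360) / 360, s, 1))) / 255
}

# Smooth random field in [0, 1]: a coarse uniform grid upsampled bilinearly.
# Consumes (cells + 1)^2 draws from the current RNG stream.
smooth_field <- function(size, cells = 6) {
  g <- matrix(stats::runif((cells + 1)^2), cells + 1, cells + 1)
  resize_bilinear(g, size, size)
}
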