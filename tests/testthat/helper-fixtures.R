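# shared fixtures: all synthetic, built in code at test time

# a clean (noise- and blur-free) two-stomate scene for pore tests
clean_spec <- function(seed, n_stomata = 2, polarity_mix = 0.5,
                       height = 256, width = 256) {
  scene_spec(height = height, width = width, n_stomata = n_stomata,
             polarity_mix = polarity_mix, blur_sigma_range = c(0, 0),
             noise_sd = 0, vein_density = 4, artifact_rate = 0, seed = seed)
}

# brute-force Otsu oracle: try all 256 thresholds, smallest-t tie-break
otsu_oracle <- function(g) {
  v <- round(as.vector(g)); n <- length(v)
  best_t <- NA_integer_; best <- -Inf
  for (t in 0:255) {
    a <- v[v <= t]; b <- v[v > t]
    if (!length(a) || !length(b)) next
    sb <- (length(a) / n) * (length(b) / n) * (mean(a) - mean(b))^2
    if (sb > best + 1e-12) { best <- sb; best_t <- t }
  }
  best_t
}

# draw a filled ellipse mask (independent of synthgen internals)
ellipse_mask <- function(h, w, cr, cc, a, b, theta_deg = 0) {
  th <- theta_deg * pi / 180
  y <- matrix(seq_len(h), h, w) - cr
  x <- matrix(seq_len(w), h, w, byrow = TRUE) - cc
  u <- cos(th) * x + sin(th) * y
  v <- -sin(th) * x + cos(th) * y
  (u / a)^2 + (v / b)^2 <= 1
}

# minimal constant-prediction classifier stub for sliding-window tests
const_model <- function(label, window_size = 32) {
  fit <- structure(list(label = label), class = "stomapore_const_fit")
  structure(list(kind = "constant", fit = fit,
                 classes = c("background", "stomate", "vein"),
                 extractor = hog_extractor(window_size),
                 extractor_id = "const", window_size = window_size),
            class = "stomate_classifier")
}

predict.stomapore_const_fit <- function(object, newdata, ...) {
  factor(rep(object$label, nrow(newdata)),
         levels = c("background", "stomate", "vein"))
}
registerS3method("predict", "stomapore_const_fit",
                 predict.stomapore_const_fit, envir = asNamespace("stats"))
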