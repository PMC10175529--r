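# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_radrobust <- function(..., class = "radrobust_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Evaluate `expr` with a temporary RNG state seeded by `seed`, restoring the
# caller's RNG state afterwards so library functions do not clobber user seeds.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Deterministic per-scan seed derived from the master seed; all arithmetic is
# exact in doubles and the result stays below 2^31 - 1.
derive_scan_seed <- function(master, platform_id, image_type, repeat_idx) {
  type_idx <- match(image_type, c("VUE", "VMI70keV"))
  if (is.na(type_idx)) stop_radrobust("unknown image_type: ", image_type)
  h <- (as.numeric(master) %% 1e6) * 1009 +
    platform_id * 7919 + type_idx * 613 + repeat_idx * 101
  as.integer(h %% 2147483629 + 1)
}

# Separable Gaussian smoothing with replicate padding; fwhm in pixels.
smooth_gaussian <- function(m, fwhm_px) {
  if (fwhm_px <= 0) return(m)
  sigma <- fwhm_px / (2 * sqrt(2 * log(2)))
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- stats::dnorm(-r:r, sd = sigma)
  k <- k / sum(k)
  conv_cols <- function(x) {
    n <- nrow(x)
    xp <- rbind(x[rep(1L, r), , drop = FALSE], x,
                x[rep(n, r), , drop = FALSE])
    out <- stats::filter(xp, k, sides = 2)
    matrix(out[(r + 1L):(r + n), ], nrow = n)
  }
  t(conv_cols(t(conv_cols(m))))
}

image_types_all <- function() c("VUE", "VMI70keV")

check_image_type <- function(image_type) {
  if (!(is.character(image_type) && length(image_type) == 1L &&
          image_type %in% image_types_all()))
    stop_radrobust("image_type must be one of ",
                   paste(image_types_all(), collapse = ", "))
  image_type
}
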