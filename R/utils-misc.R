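# Shared internal helpers: seeded sub-streams, image plumbing, validation.

#' @useDynLib faunadetect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data %||%
#' @importFrom tibble tibble as_tibble
NULL

SEED_MOD <- 2147483647 # 2^31 - 1; keeps derived seeds in integer range

# Mix a base seed with an integer or string key into a new seed.
# Multipliers are small enough that products stay exactly representable
# in doubles, so the stream is identical across platforms.
derive_seed <- function(seed, key) {
  if (is.character(key)) {
    h <- 0
    for (code in utf8ToInt(key)) h <- (h * 131 + code) %% SEED_MOD
    key <- h
  }
  as.integer((48271 * (seed %% 44488) + 16807 * (key %% 127772) +
                (seed + key) %% SEED_MOD) %% SEED_MOD)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("`%s` must be a single integer >= %s", name, min),
         call. = FALSE)
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf,
                         closed_min = TRUE, closed_max = TRUE) {
  ok <- is.numeric(x) && length(x) == 1 && !is.na(x) &&
    (if (closed_min) x >= min else x > min) &&
    (if (closed_max) x <= max else x < max)
  if (!ok) {
    stop(sprintf("`%s` must be a single number in %s%s, %s%s", name,
                 if (closed_min) "[" else "(", format(min), format(max),
                 if (closed_max) "]" else ")"), call. = FALSE)
  }
  as.numeric(x)
}

# Images are numeric arrays [height, width, 3] with values in [0, 1]
# (the layout png::readPNG produces).
assert_image <- function(image) {
  if (!is.array(image) || length(dim(image)) != 3 || dim(image)[3] != 3 ||
      any(dim(image)[1:2] < 1)) {
    stop("`image` must be a non-empty height x width x 3 array", call. = FALSE)
  }
  invisible(image)
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Bilinear resize of an [h, w, 3] array to side x side (delegates to EBImage,
# which treats the third dimension as frames; side is square so the x/y
# order does not matter).
resize_patch <- function(patch, side) {
  if (dim(patch)[1] == side && dim(patch)[2] == side) return(clip01(patch))
  out <- EBImage::resize(patch, w = side, h = side)
  clip01(array(out, dim = c(side, side, 3)))
}

# Block-average an [h, w, 3] patch down to side x side and flatten to a
# length 3*side^2 vector (channel-major). Used as the input representation
# for the VAE and the patch classifier.
pool_patch <- function(patch, side) {
  if (dim(patch)[1] != side || dim(patch)[2] != side) {
    patch <- resize_patch(patch, side)
  }
  as.numeric(patch)
}

patches_to_matrix <- function(patches, side) {
  if (is.data.frame(patches)) patches <- patches$patch
  if (!length(patches)) stop("no patches supplied", call. = FALSE)
  t(vapply(patches, pool_patch, numeric(3 * side * side), side = side))
}

md5_file <- function(path) unname(tools::md5sum(path))
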