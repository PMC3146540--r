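# internal helpers shared across modules

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# All generators route their randomness through this so that they are pure
# functions of (spec, seed).
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Derive a stream of child seeds from one master seed, each < 2^31.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Separable Gaussian blur with reflective padding. sigma in pixels.
gaussian_blur <- function(img, sigma) {
  if (sigma <= 0) return(img)
  half <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-half, half), sd = sigma)
  k <- k / sum(k)
  blur1d <- function(m) {
    # convolve each column of m with k, reflective edges
    n <- nrow(m)
    idx <- c(rev(seq_len(half)), seq_len(n), n - seq_len(half) + 1L)
    padded <- m[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      out <- out + k[j] * padded[(j - 1L) + seq_len(n), , drop = FALSE]
    }
    out
  }
  t(blur1d(t(blur1d(img))))
}

# Otsu's threshold on a numeric matrix (256-bin histogram).
otsu_threshold <- function(img) {
  r <- range(img)
  if (r[1] == r[2]) stop("constant image: cannot threshold", call. = FALSE)
  breaks <- seq(r[1], r[2], length.out = 257L)
  h <- tabulate(findInterval(img, breaks, all.inside = TRUE), nbins = 256L)
  p <- h / sum(h)
  omega <- cumsum(p)
  mids <- (breaks[-257] + breaks[-1]) / 2
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  sigma_b <- (mu_t * omega - mu)^2 / (omega * (1 - omega))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

# Label 8-connected foreground components of a logical matrix.
# Row-run encoding + union-find; returns an integer matrix (0 = background).
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  if (!any(mask)) return(labels)

  # collect TRUE runs per column-scan? operate row-wise over columns:
  # treat each ROW as a scanline across columns.
  run_row <- integer(0); run_s <- integer(0); run_e <- integer(0)
  for (i in seq_len(nr)) {
    r <- rle(mask[i, ])
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    run_row <- c(run_row, rep.int(i, sum(keep)))
    run_s <- c(run_s, starts[keep])
    run_e <- c(run_e, ends[keep])
  }
  nrun <- length(run_row)
  parent <- seq_len(nrun)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union2 <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
  }
  # union runs on adjacent rows whose column intervals touch (8-connectivity:
  # intervals grown by 1 must overlap)
  row_index <- split(seq_len(nrun), run_row)
  rows_present <- as.integer(names(row_index))
  for (k in seq_along(rows_present)[-1]) {
    if (rows_present[k] - rows_present[k - 1L] != 1L) next
    above <- row_index[[k - 1L]]
    here <- row_index[[k]]
    for (a in here) {
      for (b in above) {
        if (run_s[a] <= run_e[b] + 1L && run_e[a] >= run_s[b] - 1L) union2(a, b)
      }
    }
  }
  roots <- vapply(seq_len(nrun), find, integer(1))
  ids <- match(roots, sort(unique(roots)))
  for (j in seq_len(nrun)) {
    labels[run_row[j], run_s[j]:run_e[j]] <- ids[j]
  }
  labels
}

# Principal-axis extents (in pixels) of a set of pixel coordinates.
# Returns c(length_px, width_px, cx, cy): extents along the major/minor axes
# of the pixel cloud, each +1 for the pixel footprint.
axis_extents <- function(rows, cols) {
  xy <- cbind(cols, rows)
  ctr <- colMeans(xy)
  if (nrow(xy) == 1L) return(c(1, 1, ctr))
  cv <- stats::cov(xy)
  ev <- eigen(cv, symmetric = TRUE)$vectors
  proj <- sweep(xy, 2, ctr) %*% ev
  ext <- apply(proj, 2, function(p) diff(range(p)) + 1)
  c(max(ext), min(ext), ctr)
}
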