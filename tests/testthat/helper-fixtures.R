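# Shared fixtures and brute-force oracles. Expensive objects are cached per
# test run.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- fn()
  .fixture_env[[name]]
}

# compact phantom used throughout the unit tests: 0.5 mm isotropic, reduced
# lateral extent so generation and feature extraction stay fast
small_params <- function(seed = 1L, ...) {
  phantom_params(grid_shape = c(64, 96, 48), shaft_radius_mm = 10,
                 plateau_width_mm = 26, seed = seed, ...)
}

small_phantom <- function(seed = 1L, oa = FALSE) {
  fixture(sprintf("phantom_%d_%d", seed, oa), function() {
    generate_tibia_phantom(small_params(seed), oa)
  })
}

# random quantized test volume for the matrix-family oracles
random_quantized <- function(seed, dims = c(5, 5, 5), G = 4,
                             mask_frac = 0.85) {
  set.seed(seed)
  vol <- array(runif(prod(dims)), dims)
  mask <- array(runif(prod(dims)) < mask_frac, dims)
  if (!any(mask)) mask[1] <- TRUE
  quantize(vol, mask, G)
}

# --- brute-force oracles (independent of the package's C++ paths) ---

glcm_bf <- function(q, offset) {
  d <- dim(q$levels)
  G <- q$G
  out <- matrix(0, G, G)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!q$mask[i, j, k]) next
    ii <- i + offset[1]; jj <- j + offset[2]; kk <- k + offset[3]
    if (ii < 1 || ii > d[1] || jj < 1 || jj > d[2] || kk < 1 || kk > d[3]) next
    if (!q$mask[ii, jj, kk]) next
    a <- q$levels[i, j, k]; b <- q$levels[ii, jj, kk]
    out[a, b] <- out[a, b] + 1
    out[b, a] <- out[b, a] + 1
  }
  out
}

glrlm_bf <- function(q, dir) {
  d <- dim(q$levels)
  G <- q$G
  maxlen <- max(d)
  out <- matrix(0, G, maxlen)
  inb <- function(i, j, k) i >= 1 && i <= d[1] && j >= 1 && j <= d[2] &&
    k >= 1 && k <= d[3]
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!q$mask[i, j, k]) next
    g <- q$levels[i, j, k]
    pi <- i - dir[1]; pj <- j - dir[2]; pk <- k - dir[3]
    if (inb(pi, pj, pk) && q$mask[pi, pj, pk] &&
        q$levels[pi, pj, pk] == g) next
    len <- 1
    ci <- i + dir[1]; cj <- j + dir[2]; ck <- k + dir[3]
    while (inb(ci, cj, ck) && q$mask[ci, cj, ck] &&
           q$levels[ci, cj, ck] == g) {
      len <- len + 1
      ci <- ci + dir[1]; cj <- cj + dir[2]; ck <- ck + dir[3]
    }
    out[g, len] <- out[g, len] + 1
  }
  out
}

# 26-connected flood fill per level; returns sorted (level, size) pairs
glszm_bf <- function(q) {
  d <- dim(q$levels)
  seen <- array(FALSE, d)
  zones <- list()
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!q$mask[i, j, k] || seen[i, j, k]) next
    g <- q$levels[i, j, k]
    queue <- list(c(i, j, k))
    seen[i, j, k] <- TRUE
    size <- 0
    while (length(queue) > 0) {
      v <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      size <- size + 1
      for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
        if (di == 0 && dj == 0 && dk == 0) next
        a <- v[1] + di; b <- v[2] + dj; cc <- v[3] + dk
        if (a < 1 || a > d[1] || b < 1 || b > d[2] || cc < 1 || cc > d[3]) next
        if (!q$mask[a, b, cc] || seen[a, b, cc]) next
        if (q$levels[a, b, cc] != g) next
        seen[a, b, cc] <- TRUE
        queue[[length(queue) + 1]] <- c(a, b, cc)
      }
    }
    zones[[length(zones) + 1]] <- c(g, size)
  }
  m <- do.call(rbind, zones)
  m[order(m[, 1], m[, 2]), , drop = FALSE]
}

ngtdm_bf <- function(q) {
  d <- dim(q$levels)
  G <- q$G
  out <- matrix(0, G, 2)
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (k in seq_len(d[3])) {
    if (!q$mask[i, j, k]) next
    g <- q$levels[i, j, k]
    nb <- c()
    for (di in -1:1) for (dj in -1:1) for (dk in -1:1) {
      if (di == 0 && dj == 0 && dk == 0) next
      a <- i + di; b <- j + dj; cc <- k + dk
      if (a < 1 || a > d[1] || b < 1 || b > d[2] || cc < 1 || cc > d[3]) next
      if (q$mask[a, b, cc]) nb <- c(nb, q$levels[a, b, cc])
    }
    if (length(nb) == 0) next
    out[g, 1] <- out[g, 1] + 1
    out[g, 2] <- out[g, 2] + abs(g - mean(nb))
  }
  out
}

# ROC AUC by explicit positive-negative pair counting (ties 0.5)
roc_auc_bf <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  tot / (length(pos) * length(neg))
}

# PR AUC by exhaustive threshold sweep over unique scores
pr_auc_bf <- function(scores, labels) {
  th <- sort(unique(scores), decreasing = TRUE)
  npos <- sum(labels == 1)
  prev_rec <- 0
  area <- 0
  for (t in th) {
    sel <- scores >= t
    prec <- sum(labels[sel] == 1) / sum(sel)
    rec <- sum(labels[sel] == 1) / npos
    area <- area + prec * (rec - prev_rec)
    prev_rec <- rec
  }
  area
}

# per-pixel riu2 LBP code for integer offsets (radius 1, P = 8, no
# interpolation ambiguity on a checkerboard)
lbp_code_bf <- function(sl, i, j, r = 1) {
  ang <- 2 * pi * (0:7) / 8
  bits <- integer(8)
  for (k in 1:8) {
    dx <- r * cos(ang[k]); dy <- r * sin(ang[k])
    x0 <- floor(dx); y0 <- floor(dy)
    fx <- dx - x0; fy <- dy - y0
    x1 <- x0 + (fx > 1e-9); y1 <- y0 + (fy > 1e-9)
    nb <- (1 - fx) * (1 - fy) * sl[i + x0, j + y0] +
      fx * (1 - fy) * sl[i + x1, j + y0] +
      (1 - fx) * fy * sl[i + x0, j + y1] +
      fx * fy * sl[i + x1, j + y1]
    bits[k] <- as.integer(nb >= sl[i, j] - 1e-12)
  }
  trans <- sum(abs(diff(c(bits, bits[1]))))
  if (trans <= 2) sum(bits) else 9L
}

# mean 3x3x3 local variance inside a mask (direct evaluation)
local_variance_bf <- function(vol, mask, stride = 1) {
  d <- dim(vol)
  mask <- array(as.logical(mask), d)
  idx <- which(mask, arr.ind = TRUE)
  idx <- idx[idx[, 1] > 1 & idx[, 1] < d[1] &
               idx[, 2] > 1 & idx[, 2] < d[2] &
               idx[, 3] > 1 & idx[, 3] < d[3], , drop = FALSE]
  idx <- idx[seq(1, nrow(idx), by = stride), , drop = FALSE]
  vals <- apply(idx, 1, function(v) {
    nb_mask <- mask[(v[1] - 1):(v[1] + 1), (v[2] - 1):(v[2] + 1),
                    (v[3] - 1):(v[3] + 1)]
    if (!all(nb_mask)) return(NA_real_)  # neighbourhood fully inside mask
    var(as.numeric(vol[(v[1] - 1):(v[1] + 1), (v[2] - 1):(v[2] + 1),
                       (v[3] - 1):(v[3] + 1)]))
  })
  mean(vals, na.rm = TRUE)
}

# independent truth-table implementation of the tibiofemoral OA rule on the
# 5 boolean-reduced inputs
tfoa_rule_bf <- function(p1, p2, s_bml, s_men, s_part) {
  nsec <- s_bml + s_men + s_part
  (p1 && p2) || ((p1 || p2) && nsec >= 2)
}

# one-row MOAKS record, all zeros, with optional overrides
moaks_row <- function(...) {
  base <- list(cart_med_tib_ant = 0L, cart_med_tib_cen = 0L,
               cart_med_tib_pos = 0L, cart_lat_tib = 0L, cart_med_fem = 0L,
               cart_lat_fem = 0L, ost_med_tib = 0L, ost_lat_tib = 0L,
               ost_med_fem = 0L, ost_lat_fem = 0L, bml_med_tib_ant = 0L,
               bml_med_tib_cen = 0L, bml_med_tib_pos = 0L, bml_lat_tib = 0L,
               cyst_grade = 0L, bml_cyst_nonattachment = FALSE,
               meniscus_degen_grade = 0L, meniscus_horizontal_tear = FALSE)
  over <- list(...)
  for (nm in names(over)) base[[nm]] <- over[[nm]]
  tibble::as_tibble(base)
}
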