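#' Quantize a volume into G grey levels inside a mask
#'
#' Equal-width binning between the in-mask minimum and maximum; the maximum
#' maps to level `G`. A constant volume maps every in-mask voxel to level 1
#' (documented convention, not an error). Voxels outside the mask get
#' level 0 (excluded).
#'
#' @param volume numeric 3-D array.
#' @param mask logical array of the same shape.
#' @param G number of grey levels (>= 2).
#' @return a `tibrad_quantized` list: `levels` (integer array, 0 outside
#'   mask), `mask`, `G`, `range`.
#' @export
quantize <- function(volume, mask, G = 16) {
  stopifnot(identical(dim(volume), dim(mask)), G >= 2)
  if (!any(mask)) stop("mask is empty")
  v <- volume[mask]
  lo <- min(v); hi <- max(v)
  q <- array(0L, dim(volume))
  if (hi == lo) {
    q[mask] <- 1L
  } else {
    lev <- pmin(as.integer(floor((v - lo) / (hi - lo) * G)) + 1L, G)
    q[mask] <- lev
  }
  structure(list(levels = q, mask = array(as.logical(mask), dim(mask)),
                 G = as.integer(G), range = c(lo, hi)),
            class = "tibrad_quantized")
}

# the 13 unique 3-D direction offsets (half of the 26-neighbourhood)
glcm_directions <- function() {
  rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1),
        c(1, 1, 0), c(1, -1, 0), c(1, 0, 1), c(1, 0, -1),
        c(0, 1, 1), c(0, 1, -1),
        c(1, 1, 1), c(1, 1, -1), c(1, -1, 1), c(1, -1, -1))
}

#' Grey-level co-occurrence matrix for one offset
#'
#' Pairs are accumulated symmetrically (each in-mask pair counted in both
#' directions) and normalized to sum 1.
#'
#' @param q a [quantize()] result.
#' @param offset integer length-3 voxel offset (non-zero).
#' @param normalize divide by the total pair count.
#' @return G x G matrix.
#' @export
glcm <- function(q, offset, normalize = TRUE) {
  stopifnot(inherits(q, "tibrad_quantized"), length(offset) == 3,
            any(offset != 0))
  m <- glcm_pairs_cpp(q$levels, q$mask, dim(q$levels), as.integer(offset), q$G)
  tot <- sum(m)
  if (tot < 1) stop("fewer than one valid voxel pair for this offset")
  if (normalize) m / tot else m
}

#' GLCM summary features
#'
#' Ten descriptors of a normalized co-occurrence matrix: contrast,
#' dissimilarity, homogeneity (inverse difference moment), energy (ASM),
#' entropy, correlation, autocorrelation, cluster shade, cluster prominence,
#' and maximum probability.
#'
#' @param P normalized G x G co-occurrence matrix (sums to 1).
#' @return named numeric vector of length 10.
#' @export
glcm_features <- function(P) {
  G <- nrow(P)
  i <- row(P); j <- col(P)
  mu_i <- sum(i * P); mu_j <- sum(j * P)
  sd_i <- sqrt(sum((i - mu_i)^2 * P)); sd_j <- sqrt(sum((j - mu_j)^2 * P))
  corr <- if (sd_i * sd_j > 0) sum((i - mu_i) * (j - mu_j) * P) / (sd_i * sd_j)
          else 0
  c(contrast = sum((i - j)^2 * P),
    dissimilarity = sum(abs(i - j) * P),
    homogeneity = sum(P / (1 + (i - j)^2)),
    energy = sum(P^2),
    entropy = -sum(P[P > 0] * log2(P[P > 0])),
    correlation = corr,
    autocorrelation = sum(i * j * P),
    cluster_shade = sum((i + j - mu_i - mu_j)^3 * P),
    cluster_prominence = sum((i + j - mu_i - mu_j)^4 * P),
    max_probability = max(P))
}

#' Grey-level run-length matrix for one direction
#'
#' Counts maximal constant-level runs of in-mask voxels along the direction;
#' runs are broken by the mask and the grid border.
#'
#' @param q a [quantize()] result.
#' @param direction integer length-3 direction (non-zero).
#' @return G x maxlen count matrix.
#' @export
glrlm <- function(q, direction) {
  stopifnot(inherits(q, "tibrad_quantized"), any(direction != 0))
  glrlm_runs_cpp(q$levels, q$mask, dim(q$levels), as.integer(direction), q$G)
}

#' GLRLM summary features
#'
#' The sixteen classical run-length descriptors (short/long run emphasis,
#' grey-level and run-length non-uniformity and their normalized versions,
#' run percentage, low/high grey-level run emphasis and the four combined
#' emphases, grey-level variance, run-length variance, run entropy).
#'
#' @param R G x maxlen run count matrix.
#' @param n_voxels number of in-mask voxels (for run percentage).
#' @return named numeric vector of length 16.
#' @export
glrlm_features <- function(R, n_voxels) {
  Nr <- sum(R)
  if (Nr == 0) stop("no runs")
  g <- row(R); l <- col(R)
  p <- R / Nr
  sre <- sum(p / l^2); lre <- sum(p * l^2)
  gln <- sum(rowSums(R)^2) / Nr; glnn <- sum(rowSums(p)^2)
  rln <- sum(colSums(R)^2) / Nr; rlnn <- sum(colSums(p)^2)
  rp <- Nr / n_voxels
  lglre <- sum(p / g^2); hglre <- sum(p * g^2)
  srlgle <- sum(p / (g^2 * l^2)); srhgle <- sum(p * g^2 / l^2)
  lrlgle <- sum(p * l^2 / g^2); lrhgle <- sum(p * g^2 * l^2)
  mu_g <- sum(p * g); mu_l <- sum(p * l)
  glv <- sum(p * (g - mu_g)^2); rlv <- sum(p * (l - mu_l)^2)
  re <- -sum(p[p > 0] * log2(p[p > 0]))
  c(sre = sre, lre = lre, gln = gln, glnn = glnn, rln = rln, rlnn = rlnn,
    rp = rp, lglre = lglre, hglre = hglre, srlgle = srlgle, srhgle = srhgle,
    lrlgle = lrlgle, lrhgle = lrhgle, glv = glv, rlv = rlv, run_entropy = re)
}

#' Grey-level size-zone matrix
#'
#' Counts 26-connected constant-level zones of in-mask voxels by level and
#' size.
#'
#' @param q a [quantize()] result.
#' @return matrix with one row per zone: columns `level`, `size`.
#' @export
glszm <- function(q) {
  stopifnot(inherits(q, "tibrad_quantized"))
  z <- glszm_zones_cpp(q$levels, q$mask, dim(q$levels), q$G)
  colnames(z) <- c("level", "size")
  z
}

#' GLSZM summary features
#'
#' Sixteen size-zone descriptors analogous to the run-length set (small/large
#' area emphasis, non-uniformities, zone percentage, grey-level emphases,
#' variances, zone entropy).
#'
#' @param zones matrix from [glszm()].
#' @param n_voxels number of in-mask voxels.
#' @param G number of grey levels.
#' @return named numeric vector of length 16.
#' @export
glszm_features <- function(zones, n_voxels, G) {
  Nz <- nrow(zones)
  if (Nz == 0) stop("no zones")
  g <- zones[, "level"]; s <- zones[, "size"]
  p <- rep(1 / Nz, Nz)
  sae <- sum(p / s^2); lae <- sum(p * s^2)
  gln <- sum(tapply(rep(1, Nz), factor(g, levels = 1:G), sum,
                    default = 0)^2) / Nz
  glnn <- gln / Nz
  szn <- sum(table(s)^2) / Nz
  sznn <- szn / Nz
  zp <- Nz / n_voxels
  lglze <- sum(p / g^2); hglze <- sum(p * g^2)
  salgle <- sum(p / (g^2 * s^2)); sahgle <- sum(p * g^2 / s^2)
  lalgle <- sum(p * s^2 / g^2); lahgle <- sum(p * g^2 * s^2)
  mu_g <- sum(p * g); mu_s <- sum(p * s)
  glv <- sum(p * (g - mu_g)^2); zv <- sum(p * (s - mu_s)^2)
  # zone entropy over the joint (level, size) distribution
  tab <- table(paste(g, s)) / Nz
  ze <- -sum(tab * log2(tab))
  c(sae = sae, lae = lae, gln = gln, glnn = glnn, szn = szn, sznn = sznn,
    zp = zp, lglze = lglze, hglze = hglze, salgle = salgle, sahgle = sahgle,
    lalgle = lalgle, lahgle = lahgle, glv = glv, zv = zv, zone_entropy = ze)
}

#' Neighbourhood grey-tone difference matrix and features
#'
#' `ngtdm()` accumulates, per grey level, the voxel count and the summed
#' absolute difference between a voxel's level and the mean level of its
#' valid 26-neighbours. `ngtdm_features()` returns the five classical
#' descriptors (coarseness, contrast, busyness, complexity, strength).
#' When the coarseness denominator is zero (a single uniform zone), the
#' feature is set to the documented large constant 1e6, never infinity.
#'
#' @param q a [quantize()] result.
#' @return `ngtdm()`: G x 2 matrix (columns `n`, `s`).
#' @export
ngtdm <- function(q) {
  stopifnot(inherits(q, "tibrad_quantized"))
  m <- ngtdm_table_cpp(q$levels, q$mask, dim(q$levels), q$G)
  colnames(m) <- c("n", "s")
  m
}

#' @rdname ngtdm
#' @param tab G x 2 matrix from `ngtdm()`.
#' @export
ngtdm_features <- function(tab) {
  G <- nrow(tab)
  n_i <- tab[, "n"]; s_i <- tab[, "s"]
  N <- sum(n_i)
  if (N == 0) stop("empty NGTDM")
  p_i <- n_i / N
  act <- which(p_i > 0)
  Ng <- length(act)
  den <- sum(p_i * s_i)
  coarseness <- if (den > 0) 1 / den else 1e6
  contrast <- if (Ng > 1) {
    (1 / (Ng * (Ng - 1))) *
      sum(outer(p_i[act], p_i[act]) * outer(act, act, "-")^2) *
      sum(s_i) / N
  } else 0
  busy_den <- sum(abs(outer(act * p_i[act], act * p_i[act], "-")))
  busyness <- if (busy_den > 0) den / busy_den else 0
  complexity <- if (Ng > 0) {
    idx <- outer(act, act, "-")
    pp <- outer(p_i[act], p_i[act], "+")
    ss <- outer(p_i[act] * s_i[act], p_i[act] * s_i[act], "+")
    sum(abs(idx) * ss / pp) / N
  } else 0
  strength_num <- sum(outer(p_i[act], p_i[act], "+") * outer(act, act, "-")^2)
  strength <- if (sum(s_i) > 0) strength_num / sum(s_i) else 0
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = complexity, strength = strength)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
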