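#' Discretize intensities into gray levels
#'
#' Fixed-bin-width, minimum-referenced discretization:
#' `level = floor((v - min(v)) / bin_width) + 1`. Adding a constant to all
#' intensities therefore leaves the levels unchanged.
#'
#' @param values numeric vector of intensities (the masked voxels).
#' @param bin_width bin width in intensity units, > 0.
#' @return list with `levels` (integer vector, >= 1) and `ng` (number of gray
#'   levels, i.e. the maximum level).
#' @export
discretize <- function(values, bin_width) {
  if (!length(values)) stop("empty value vector")
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("bin_width must be a positive scalar")
  lev <- as.integer(floor((values - min(values)) / bin_width)) + 1L
  list(levels = lev, ng = max(lev))
}

# the 13 canonical 3-D direction offsets at Chebyshev distance 1 (one of each
# +/- pair; first nonzero component positive)
direction_offsets <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[rowSums(abs(g)) > 0, ]
  keep <- apply(g, 1, function(o) o[match(TRUE, o != 0)] > 0)
  unname(g[keep, , drop = FALSE])
}

# level array: cropped 3-D integer array with NA outside the mask
level_array <- function(volume, mask, bin_width) {
  mask <- array(as.logical(mask), dim(mask))
  if (!any(mask)) stop("mask has no foreground voxels")
  dz <- discretize(volume[mask], bin_width)
  lev <- array(NA_integer_, dim(volume))
  lev[mask] <- dz$levels
  list(lev = lev, ng = dz$ng, np = sum(mask))
}

# pairs of co-occurring levels for one offset (asymmetric; caller symmetrizes)
offset_pairs <- function(lev, off) {
  d <- dim(lev)
  rng <- lapply(1:3, function(a) {
    lo <- max(1L, 1L - off[a]); hi <- min(d[a], d[a] - off[a])
    if (lo > hi) return(integer(0))
    lo:hi
  })
  if (any(!lengths(rng))) return(NULL)
  a <- lev[rng[[1]], rng[[2]], rng[[3]], drop = FALSE]
  b <- lev[rng[[1]] + off[1], rng[[2]] + off[2], rng[[3]] + off[3], drop = FALSE]
  keep <- !is.na(a) & !is.na(b)
  if (!any(keep)) return(NULL)
  cbind(a[keep], b[keep])
}

#' Gray-level co-occurrence matrix features
#'
#' Builds a symmetric, probability-normalized GLCM per direction (13 unique
#' 3-D offsets at distance 1 by default), computes the 22-feature panel per
#' direction and averages over directions with at least one valid voxel pair.
#'
#' @param volume 3-D numeric array.
#' @param mask 3-D logical/0-1 array, same dimensions.
#' @param bin_width discretization bin width.
#' @param offsets integer matrix of direction offsets (rows), default the 13
#'   canonical 3-D directions.
#' @return named numeric vector of 22 features; attribute `undefined` flags a
#'   VOI with no valid pair in any direction (all features 0).
#' @export
glcm_features <- function(volume, mask, bin_width = 25, offsets = direction_offsets()) {
  la <- level_array(volume, mask, bin_width)
  per_dir <- list()
  for (r in seq_len(nrow(offsets))) {
    pr <- offset_pairs(la$lev, offsets[r, ])
    if (is.null(pr)) next
    counts <- matrix(0, la$ng, la$ng)
    tab <- table(factor(pr[, 1], levels = 1:la$ng),
                 factor(pr[, 2], levels = 1:la$ng))
    counts <- unclass(tab) + t(unclass(tab))   # symmetrize
    per_dir[[length(per_dir) + 1L]] <- glcm_panel(counts / sum(counts))
  }
  finalize_texture(per_dir, names = feature_panels()$glcm)
}

glcm_panel <- function(p) {
  ng <- nrow(p)
  i <- row(p); j <- col(p)
  px <- rowSums(p); py <- colSums(p)
  mu_x <- sum(seq_len(ng) * px); mu_y <- sum(seq_len(ng) * py)
  sd_x <- sqrt(sum((seq_len(ng) - mu_x)^2 * px))
  sd_y <- sqrt(sum((seq_len(ng) - mu_y)^2 * py))
  # diagonal-band and anti-diagonal marginals
  k_diff <- 0:(ng - 1)
  p_diff <- vapply(k_diff, function(k) sum(p[abs(i - j) == k]), 0)
  k_sum <- 2:(2 * ng)
  p_sum <- vapply(k_sum, function(k) sum(p[(i + j) == k]), 0)
  da <- sum(k_diff * p_diff)
  hxy <- -sum(xlog2(p))
  pxpy <- outer(px, py)
  hxy1 <- -sum(ifelse(p > 0 & pxpy > 0, p * log2(pxpy), 0))
  hxy2 <- -sum(xlog2(pxpy))
  hx <- -sum(xlog2(px)); hy <- -sum(xlog2(py))
  corr <- if (sd_x * sd_y > 0) (sum(i * j * p) - mu_x * mu_y) / (sd_x * sd_y) else 1
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  c(Autocorrelation = sum(i * j * p),
    JointAverage = mu_x,
    ClusterProminence = sum((i + j - mu_x - mu_y)^4 * p),
    ClusterShade = sum((i + j - mu_x - mu_y)^3 * p),
    ClusterTendency = sum((i + j - mu_x - mu_y)^2 * p),
    Contrast = sum((i - j)^2 * p),
    Correlation = corr,
    DifferenceAverage = da,
    DifferenceEntropy = -sum(xlog2(p_diff)),
    DifferenceVariance = sum((k_diff - da)^2 * p_diff),
    JointEnergy = sum(p^2),
    JE = hxy,
    Id = sum(p / (1 + abs(i - j))),
    Idm = sum(p / (1 + (i - j)^2)),
    Idmn = sum(p / (1 + (i - j)^2 / ng^2)),
    Idn = sum(p / (1 + abs(i - j) / ng)),
    Imc1 = imc1,
    Imc2 = imc2,
    InverseVariance = sum(p[i != j] / (i - j)[i != j]^2),
    MaximumProbability = max(p),
    SumEntropy = -sum(xlog2(p_sum)),
    SumSquares = sum((i - mu_x)^2 * p))
}

#' Gray-level run-length matrix features
#'
#' Maximal runs of equal gray level along each of the 13 directions; the
#' 16-feature panel is computed per direction and averaged.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features.
#' @export
glrlm_features <- function(volume, mask, bin_width = 25, offsets = direction_offsets()) {
  la <- level_array(volume, mask, bin_width)
  d <- dim(la$lev)
  idx <- which(!is.na(la$lev))
  coords <- arrayInd(idx, d)
  levs <- la$lev[idx]
  per_dir <- list()
  for (r in seq_len(nrow(offsets))) {
    off <- offsets[r, ]
    ax <- match(TRUE, off != 0)            # first nonzero component is +1
    tpos <- coords[, ax]
    key <- coords - tpos %*% t(off)        # base point of each line
    kid <- key %*% c(1, max(d) + 2L, (max(d) + 2L)^2)
    o <- order(kid, tpos)
    k <- kid[o]; tt <- tpos[o]; l <- levs[o]
    n <- length(o)
    newrun <- if (n > 1)
      c(TRUE, k[-1] != k[-n] | tt[-1] != tt[-n] + 1L | l[-1] != l[-n]) else TRUE
    rid <- cumsum(newrun)
    rl <- tabulate(rid)
    rlev <- l[newrun]
    R <- table(factor(rlev, levels = 1:la$ng), factor(rl, levels = 1:max(rl)))
    per_dir[[length(per_dir) + 1L]] <- glrlm_panel(unclass(R), la$np)
  }
  finalize_texture(per_dir, names = feature_panels()$glrlm)
}

glrlm_panel <- function(R, np) {
  nr <- sum(R)
  i <- row(R); l <- col(R)
  p <- R / nr
  mu_i <- sum(i * p); mu_l <- sum(l * p)
  c(SRE = sum(R / l^2) / nr,
    LRE = sum(R * l^2) / nr,
    GLN = sum(rowSums(R)^2) / nr,
    GLNN = sum(rowSums(R)^2) / nr^2,
    RLN = sum(colSums(R)^2) / nr,
    RLNN = sum(colSums(R)^2) / nr^2,
    RP = nr / np,
    GLV = sum(p * (i - mu_i)^2),
    RV = sum(p * (l - mu_l)^2),
    RE = -sum(xlog2(p)),
    LGLRE = sum(R / i^2) / nr,
    HGLRE = sum(R * i^2) / nr,
    SRLGLE = sum(R / (i^2 * l^2)) / nr,
    SRHGLE = sum(R * i^2 / l^2) / nr,
    LRLGLE = sum(R * l^2 / i^2) / nr,
    LRHGLE = sum(R * i^2 * l^2) / nr)
}

#' Gray-level size-zone matrix features
#'
#' Zones are 26-connected components of equal gray level within the mask;
#' the 16-feature panel is computed from the single zone matrix.
#'
#' @inheritParams glcm_features
#' @return named numeric vector of 16 features.
#' @export
glszm_features <- function(volume, mask, bin_width = 25) {
  la <- level_array(volume, mask, bin_width)
  zones <- connected_zones(la$lev)
  S <- table(factor(zones$level, levels = 1:la$ng),
             factor(zones$size, levels = 1:max(zones$size)))
  finalize_texture(list(glszm_panel(unclass(S), la$np)),
                   names = feature_panels()$glszm)
}

glszm_panel <- function(S, np) {
  nz <- sum(S)
  i <- row(S); s <- col(S)
  p <- S / nz
  mu_i <- sum(i * p); mu_s <- sum(s * p)
  c(SAE = sum(S / s^2) / nz,
    LAE = sum(S * s^2) / nz,
    GLNU = sum(rowSums(S)^2) / nz,
    GLNUN = sum(rowSums(S)^2) / nz^2,
    SZN = sum(colSums(S)^2) / nz,
    SZNN = sum(colSums(S)^2) / nz^2,
    ZP = nz / np,
    GLV = sum(p * (i - mu_i)^2),
    ZV = sum(p * (s - mu_s)^2),
    ZE = -sum(xlog2(p)),
    LGLZE = sum(S / i^2) / nz,
    HGLZE = sum(S * i^2) / nz,
    SALGLE = sum(S / (i^2 * s^2)) / nz,
    SAHGLE = sum(S * i^2 / s^2) / nz,
    LALGLE = sum(S * s^2 / i^2) / nz,
    LAHGLE = sum(S * i^2 * s^2) / nz)
}

# 26-connected same-level components via union-find over mask voxels
connected_zones <- function(lev) {
  d <- dim(lev)
  idx <- which(!is.na(lev))
  pos <- match(seq_len(prod(d)), idx)      # linear index -> voxel rank
  parent <- seq_along(idx)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]      # path halving
      x <- parent[x]
    }
    x
  }
  offs <- direction_offsets()
  coords <- arrayInd(idx, d)
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    nb <- coords + rep(off, each = nrow(coords))
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb_lin <- (nb[, 3] - 1L) * d[1] * d[2] + (nb[, 2] - 1L) * d[1] + nb[, 1]
    nb_rank <- rep(NA_integer_, length(idx))
    nb_rank[ok] <- pos[nb_lin[ok]]
    same <- which(!is.na(nb_rank) & lev[idx] == lev[idx][nb_rank])
    for (v in same) {
      ra <- find(v); rb <- find(nb_rank[v])
      if (ra != rb) parent[ra] <- rb
    }
  }
  root <- vapply(seq_along(idx), find, 1L)
  sizes <- table(root)
  data.frame(level = lev[idx][as.integer(names(sizes))],
             size = as.integer(sizes))
}

#' Gray-level dependence matrix features
#'
#' For each mask voxel, the dependence is the number of 26-neighbours within
#' Chebyshev distance 1 whose gray level differs by at most `alpha`; the
#' matrix column index is dependence + 1 (an isolated voxel sits in column 1).
#'
#' @inheritParams glcm_features
#' @param alpha gray-level difference tolerance for dependence (default 0).
#' @return named numeric vector of 14 features.
#' @export
gldm_features <- function(volume, mask, bin_width = 25, alpha = 0) {
  la <- level_array(volume, mask, bin_width)
  d <- dim(la$lev)
  idx <- which(!is.na(la$lev))
  coords <- arrayInd(idx, d)
  dep <- integer(length(idx))
  offs <- direction_offsets()
  offs <- rbind(offs, -offs)               # both signs: full 26-neighbourhood
  for (r in seq_len(nrow(offs))) {
    off <- offs[r, ]
    nb <- coords + rep(off, each = nrow(coords))
    ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
      nb[, 3] >= 1 & nb[, 3] <= d[3]
    nb_lin <- (nb[, 3] - 1L) * d[1] * d[2] + (nb[, 2] - 1L) * d[1] + nb[, 1]
    nb_lev <- rep(NA_integer_, length(idx))
    nb_lev[ok] <- la$lev[nb_lin[ok]]
    dep <- dep + as.integer(!is.na(nb_lev) & abs(la$lev[idx] - nb_lev) <= alpha)
  }
  j <- dep + 1L
  D <- table(factor(la$lev[idx], levels = 1:la$ng),
             factor(j, levels = 1:max(j)))
  finalize_texture(list(gldm_panel(unclass(D))), names = feature_panels()$gldm)
}

gldm_panel <- function(D) {
  nz <- sum(D)
  i <- row(D); j <- col(D)
  p <- D / nz
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  c(SDE = sum(D / j^2) / nz,
    LDE = sum(D * j^2) / nz,
    GLN = sum(rowSums(D)^2) / nz,
    DN = sum(colSums(D)^2) / nz,
    DNN = sum(colSums(D)^2) / nz^2,
    GLV = sum(p * (i - mu_i)^2),
    DV = sum(p * (j - mu_j)^2),
    DE = -sum(xlog2(p)),
    LGLE = sum(D / i^2) / nz,
    HGLE = sum(D * i^2) / nz,
    SDLGLE = sum(D / (i^2 * j^2)) / nz,
    SDHGLE = sum(D * i^2 / j^2) / nz,
    LDLGLE = sum(D * j^2 / i^2) / nz,
    LDHGLE = sum(D * i^2 * j^2) / nz)
}

# average per-direction panels; empty input -> zero vector flagged undefined
finalize_texture <- function(per_dir, names) {
  if (!length(per_dir)) {
    out <- stats::setNames(rep(0, length(names)), names)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  out <- Reduce(`+`, per_dir) / length(per_dir)
  stats::setNames(as.numeric(out), names)
}

#' First-order intensity statistics
#'
#' The 18-statistic panel over masked voxel intensities. `Entropy` and
#' `Uniformity` use the same fixed-bin-width discretization as the texture
#' families; moments use population (1/N) denominators; `Skewness` and
#' `Kurtosis` of a constant sample are defined as 0 (`Kurtosis` is
#' non-excess otherwise).
#'
#' @param values numeric vector of masked intensities.
#' @param bin_width bin width for the entropy/uniformity histogram.
#' @return named numeric vector of 18 statistics.
#' @export
first_order_features <- function(values, bin_width = 25) {
  if (!length(values)) stop("empty mask: no intensity values")
  n <- length(values)
  mu <- mean(values)
  m2 <- mean((values - mu)^2)
  m3 <- mean((values - mu)^3)
  m4 <- mean((values - mu)^4)
  q <- unname(quantile(values, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7))
  robust <- values[values >= q[1] & values <= q[5]]
  pr <- tabulate(discretize(values, bin_width)$levels) / n
  c(Energy = sum(values^2),
    Entropy = -sum(xlog2(pr)),
    Minimum = min(values),
    Percentile10 = q[1],
    Percentile90 = q[5],
    Maximum = max(values),
    Mean = mu,
    Median = q[3],
    InterquartileRange = q[4] - q[2],
    Range = max(values) - min(values),
    MeanAbsoluteDeviation = mean(abs(values - mu)),
    RobustMeanAbsoluteDeviation = mean(abs(robust - mean(robust))),
    RootMeanSquared = sqrt(mean(values^2)),
    StandardDeviation = sqrt(m2),
    Variance = m2,
    Skewness = if (m2 > 0) m3 / m2^1.5 else 0,
    Kurtosis = if (m2 > 0) m4 / m2^2 else 0,
    Uniformity = sum(pr^2))
}
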