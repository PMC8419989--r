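# Brute-force texture oracles: naive loop implementations built directly from
# the matrix definitions, independent of the package's vectorized code paths.

# the 13 canonical direction offsets, written out literally
ORACLE_OFFSETS <- matrix(c(
  1, 0, 0,   0, 1, 0,   0, 0, 1,
  1, 1, 0,   1, -1, 0,  1, 0, 1,
  1, 0, -1,  0, 1, 1,   0, 1, -1,
  1, 1, 1,   1, 1, -1,  1, -1, 1,  1, -1, -1
), ncol = 3, byrow = TRUE)

oracle_levels <- function(vol, mask, bw) {
  lev <- array(NA_integer_, dim(vol))
  v <- vol[mask]
  lev[mask] <- as.integer(floor((v - min(v)) / bw)) + 1L
  lev
}

in_grid <- function(p, d) all(p >= 1) && all(p <= d)

oracle_glcm <- function(vol, mask, bw) {
  lev <- oracle_levels(vol, mask, bw)
  d <- dim(vol); ng <- max(lev, na.rm = TRUE)
  panels <- list()
  for (r in seq_len(nrow(ORACLE_OFFSETS))) {
    off <- ORACLE_OFFSETS[r, ]
    cnt <- matrix(0, ng, ng)
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      p1 <- c(i, j, k); p2 <- p1 + off
      if (!in_grid(p2, d)) next
      a <- lev[p1[1], p1[2], p1[3]]; b <- lev[p2[1], p2[2], p2[3]]
      if (is.na(a) || is.na(b)) next
      cnt[a, b] <- cnt[a, b] + 1
      cnt[b, a] <- cnt[b, a] + 1
    }
    if (sum(cnt) == 0) next
    panels[[length(panels) + 1]] <- oracle_glcm_panel(cnt / sum(cnt))
  }
  if (!length(panels)) return(NULL)
  Reduce(`+`, panels) / length(panels)
}

oracle_glcm_panel <- function(p) {
  ng <- nrow(p)
  px <- py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) { px[i] <- px[i] + p[i, j]; py[j] <- py[j] + p[i, j] }
  mux <- sum((1:ng) * px); muy <- sum((1:ng) * py)
  sx <- sqrt(sum(((1:ng) - mux)^2 * px)); sy <- sqrt(sum(((1:ng) - muy)^2 * py))
  lg <- function(x) if (x > 0) log2(x) else 0
  ac <- cp <- cs <- ct <- con <- je <- id <- idm <- idmn <- idn <- iv <- ss <- en <- 0
  hxy1 <- hxy2 <- 0
  for (i in 1:ng) for (j in 1:ng) {
    pij <- p[i, j]
    ac <- ac + i * j * pij
    cp <- cp + (i + j - mux - muy)^4 * pij
    cs <- cs + (i + j - mux - muy)^3 * pij
    ct <- ct + (i + j - mux - muy)^2 * pij
    con <- con + (i - j)^2 * pij
    je <- je - pij * lg(pij)
    id <- id + pij / (1 + abs(i - j))
    idm <- idm + pij / (1 + (i - j)^2)
    idmn <- idmn + pij / (1 + (i - j)^2 / ng^2)
    idn <- idn + pij / (1 + abs(i - j) / ng)
    if (i != j) iv <- iv + pij / (i - j)^2
    ss <- ss + (i - mux)^2 * pij
    en <- en + pij^2
    hxy1 <- hxy1 - pij * lg(px[i] * py[j])
    hxy2 <- hxy2 - px[i] * py[j] * lg(px[i] * py[j])
  }
  pd <- numeric(ng); psum <- numeric(2 * ng - 1)
  for (i in 1:ng) for (j in 1:ng) {
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + p[i, j]
    psum[i + j - 1] <- psum[i + j - 1] + p[i, j]
  }
  da <- sum((0:(ng - 1)) * pd)
  de <- -sum(vapply(pd, function(q) q * lg(q), 0))
  dv <- sum(((0:(ng - 1)) - da)^2 * pd)
  se <- -sum(vapply(psum, function(q) q * lg(q), 0))
  hx <- -sum(vapply(px, function(q) q * lg(q), 0))
  hy <- -sum(vapply(py, function(q) q * lg(q), 0))
  corr <- if (sx * sy > 0) (ac - mux * muy) / (sx * sy) else 1
  imc1 <- if (max(hx, hy) > 0) (je - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(max(0, 1 - exp(-2 * (hxy2 - je))))
  c(Autocorrelation = ac, JointAverage = mux, ClusterProminence = cp,
    ClusterShade = cs, ClusterTendency = ct, Contrast = con,
    Correlation = corr, DifferenceAverage = da, DifferenceEntropy = de,
    DifferenceVariance = dv, JointEnergy = en, JE = je, Id = id, Idm = idm,
    Idmn = idmn, Idn = idn, Imc1 = imc1, Imc2 = imc2, InverseVariance = iv,
    MaximumProbability = max(p), SumEntropy = se, SumSquares = ss)
}

oracle_glrlm <- function(vol, mask, bw) {
  lev <- oracle_levels(vol, mask, bw)
  d <- dim(vol); ng <- max(lev, na.rm = TRUE); np <- sum(mask)
  panels <- list()
  for (r in seq_len(nrow(ORACLE_OFFSETS))) {
    off <- ORACLE_OFFSETS[r, ]
    runs <- list()
    for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
      p1 <- c(i, j, k)
      a <- lev[i, j, k]
      if (is.na(a)) next
      prev <- p1 - off
      if (in_grid(prev, d) && !is.na(lev[prev[1], prev[2], prev[3]]) &&
          lev[prev[1], prev[2], prev[3]] == a) next   # not a run start
      len <- 1; cur <- p1 + off
      while (in_grid(cur, d) && !is.na(lev[cur[1], cur[2], cur[3]]) &&
             lev[cur[1], cur[2], cur[3]] == a) {
        len <- len + 1; cur <- cur + off
      }
      runs[[length(runs) + 1]] <- c(a, len)
    }
    rm_ <- do.call(rbind, runs)
    R <- matrix(0, ng, max(rm_[, 2]))
    for (q in seq_len(nrow(rm_))) R[rm_[q, 1], rm_[q, 2]] <- R[rm_[q, 1], rm_[q, 2]] + 1
    panels[[length(panels) + 1]] <- oracle_sizetype_panel(R, np, "glrlm")
  }
  Reduce(`+`, panels) / length(panels)
}

# shared naive panel over a (gray level x size) matrix; family picks names
oracle_sizetype_panel <- function(M, np, family) {
  n <- sum(M); ng <- nrow(M); ns <- ncol(M)
  lg <- function(x) if (x > 0) log2(x) else 0
  sre <- lre <- lgl <- hgl <- srl <- srh <- lrl <- lrh <- ent <- 0
  mu_i <- mu_s <- 0
  for (i in 1:ng) for (s in 1:ns) {
    m <- M[i, s]; pr <- m / n
    sre <- sre + m / s^2; lre <- lre + m * s^2
    lgl <- lgl + m / i^2; hgl <- hgl + m * i^2
    srl <- srl + m / (i^2 * s^2); srh <- srh + m * i^2 / s^2
    lrl <- lrl + m * s^2 / i^2; lrh <- lrh + m * i^2 * s^2
    ent <- ent - pr * lg(pr)
    mu_i <- mu_i + i * pr; mu_s <- mu_s + s * pr
  }
  glv <- sv <- 0
  for (i in 1:ng) for (s in 1:ns) {
    glv <- glv + (M[i, s] / n) * (i - mu_i)^2
    sv <- sv + (M[i, s] / n) * (s - mu_s)^2
  }
  gn <- sum(rowSums(M)^2); sn <- sum(colSums(M)^2)
  vals <- c(sre / n, lre / n, gn / n, gn / n^2, sn / n, sn / n^2, n / np,
            glv, sv, ent, lgl / n, hgl / n, srl / n, srh / n, lrl / n, lrh / n)
  names(vals) <- switch(family,
    glrlm = c("SRE", "LRE", "GLN", "GLNN", "RLN", "RLNN", "RP", "GLV", "RV",
              "RE", "LGLRE", "HGLRE", "SRLGLE", "SRHGLE", "LRLGLE", "LRHGLE"),
    glszm = c("SAE", "LAE", "GLNU", "GLNUN", "SZN", "SZNN", "ZP", "GLV", "ZV",
              "ZE", "LGLZE", "HGLZE", "SALGLE", "SAHGLE", "LALGLE", "LAHGLE"))
  vals
}

oracle_glszm <- function(vol, mask, bw) {
  lev <- oracle_levels(vol, mask, bw)
  d <- dim(vol); ng <- max(lev, na.rm = TRUE); np <- sum(mask)
  seen <- array(FALSE, d)
  zones <- list()
  nbhd <- rbind(ORACLE_OFFSETS, -ORACLE_OFFSETS)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    if (is.na(lev[i, j, k]) || seen[i, j, k]) next
    a <- lev[i, j, k]
    stack <- list(c(i, j, k)); seen[i, j, k] <- TRUE; size <- 0
    while (length(stack)) {
      p1 <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      size <- size + 1
      for (q in seq_len(nrow(nbhd))) {
        p2 <- p1 + nbhd[q, ]
        if (!in_grid(p2, d) || seen[p2[1], p2[2], p2[3]]) next
        if (is.na(lev[p2[1], p2[2], p2[3]]) ||
            lev[p2[1], p2[2], p2[3]] != a) next
        seen[p2[1], p2[2], p2[3]] <- TRUE
        stack[[length(stack) + 1]] <- p2
      }
    }
    zones[[length(zones) + 1]] <- c(a, size)
  }
  zm <- do.call(rbind, zones)
  S <- matrix(0, ng, max(zm[, 2]))
  for (q in seq_len(nrow(zm))) S[zm[q, 1], zm[q, 2]] <- S[zm[q, 1], zm[q, 2]] + 1
  oracle_sizetype_panel(S, np, "glszm")
}

oracle_gldm <- function(vol, mask, bw, alpha = 0) {
  lev <- oracle_levels(vol, mask, bw)
  d <- dim(vol); ng <- max(lev, na.rm = TRUE)
  nbhd <- rbind(ORACLE_OFFSETS, -ORACLE_OFFSETS)
  deps <- list()
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    a <- lev[i, j, k]
    if (is.na(a)) next
    dep <- 0
    for (q in seq_len(nrow(nbhd))) {
      p2 <- c(i, j, k) + nbhd[q, ]
      if (!in_grid(p2, d)) next
      b <- lev[p2[1], p2[2], p2[3]]
      if (!is.na(b) && abs(a - b) <= alpha) dep <- dep + 1
    }
    deps[[length(deps) + 1]] <- c(a, dep + 1)
  }
  dm <- do.call(rbind, deps)
  D <- matrix(0, ng, max(dm[, 2]))
  for (q in seq_len(nrow(dm))) D[dm[q, 1], dm[q, 2]] <- D[dm[q, 1], dm[q, 2]] + 1
  n <- sum(D); nj <- ncol(D)
  lg <- function(x) if (x > 0) log2(x) else 0
  sde <- lde <- lgl <- hgl <- sdl <- sdh <- ldl <- ldh <- ent <- mu_i <- mu_j <- 0
  for (i in 1:ng) for (s in 1:nj) {
    m <- D[i, s]; pr <- m / n
    sde <- sde + m / s^2; lde <- lde + m * s^2
    lgl <- lgl + m / i^2; hgl <- hgl + m * i^2
    sdl <- sdl + m / (i^2 * s^2); sdh <- sdh + m * i^2 / s^2
    ldl <- ldl + m * s^2 / i^2; ldh <- ldh + m * i^2 * s^2
    ent <- ent - pr * lg(pr)
    mu_i <- mu_i + i * pr; mu_j <- mu_j + s * pr
  }
  glv <- dv <- 0
  for (i in 1:ng) for (s in 1:nj) {
    glv <- glv + (D[i, s] / n) * (i - mu_i)^2
    dv <- dv + (D[i, s] / n) * (s - mu_j)^2
  }
  c(SDE = sde / n, LDE = lde / n, GLN = sum(rowSums(D)^2) / n,
    DN = sum(colSums(D)^2) / n, DNN = sum(colSums(D)^2) / n^2, GLV = glv,
    DV = dv, DE = ent, LGLE = lgl / n, HGLE = hgl / n, SDLGLE = sdl / n,
    SDHGLE = sdh / n, LDLGLE = ldl / n, LDHGLE = ldh / n)
}

# random small VOI (dimensions at most 4 x 4 x 2) with integer intensities
random_voi <- function(seed) {
  withr::with_seed(seed, {
    d <- c(sample(2:4, 1), sample(2:4, 1), sample(1:2, 1))
    vol <- array(sample(0:99, prod(d), replace = TRUE), d)
    mask <- array(stats::runif(prod(d)) < 0.8, d)
    if (sum(mask) < 2) mask[sample(prod(d), 2)] <- TRUE
    list(vol = vol, mask = mask)
  })
}

# compare every texture family against its oracle on one VOI
expect_texture_oracle_match <- function(voi, bw = 25, tol = 1e-9) {
  og <- oracle_glcm(voi$vol, voi$mask, bw)
  if (!is.null(og))
    expect_equal(as.numeric(glcm_features(voi$vol, voi$mask, bw)[names(og)]),
                 as.numeric(og), tolerance = tol)
  or <- oracle_glrlm(voi$vol, voi$mask, bw)
  expect_equal(as.numeric(glrlm_features(voi$vol, voi$mask, bw)[names(or)]),
               as.numeric(or), tolerance = tol)
  os <- oracle_glszm(voi$vol, voi$mask, bw)
  expect_equal(as.numeric(glszm_features(voi$vol, voi$mask, bw)[names(os)]),
               as.numeric(os), tolerance = tol)
  od <- oracle_gldm(voi$vol, voi$mask, bw)
  expect_equal(as.numeric(gldm_features(voi$vol, voi$mask, bw)[names(od)]),
               as.numeric(od), tolerance = tol)
}
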