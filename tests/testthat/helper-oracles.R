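# Independent brute-force oracles. These deliberately share no code with the
# package: naive loops and closed forms only.

# all 22 GLCM features by explicit double loops over (i, j)
naive_glcm_features <- function(p) {
  ng <- nrow(p)
  px <- numeric(ng); py <- numeric(ng)
  for (i in 1:ng) for (j in 1:ng) {
    px[i] <- px[i] + p[i, j]
    py[j] <- py[j] + p[i, j]
  }
  mux <- 0; muy <- 0
  for (i in 1:ng) { mux <- mux + i * px[i]; muy <- muy + i * py[i] }
  sigx <- 0; sigy <- 0
  for (i in 1:ng) {
    sigx <- sigx + (i - mux)^2 * px[i]
    sigy <- sigy + (i - muy)^2 * py[i]
  }
  sigx <- sqrt(sigx); sigy <- sqrt(sigy)
  lg <- function(x) if (x > 0) log2(x) else 0

  HXY <- 0; HXY1 <- 0; HXY2 <- 0; HX <- 0
  for (i in 1:ng) {
    HX <- HX - px[i] * lg(px[i])
    for (j in 1:ng) {
      HXY <- HXY - p[i, j] * lg(p[i, j])
      HXY1 <- HXY1 - p[i, j] * lg(px[i] * py[j])
      HXY2 <- HXY2 - px[i] * py[j] * lg(px[i] * py[j])
    }
  }
  psum <- numeric(2 * ng); pdiff <- numeric(ng)  # indices k and k+1
  for (i in 1:ng) for (j in 1:ng) {
    psum[i + j] <- psum[i + j] + p[i, j]
    pdiff[abs(i - j) + 1] <- pdiff[abs(i - j) + 1] + p[i, j]
  }
  SA <- 0; SE <- 0; DE <- 0
  for (k in 2:(2 * ng)) {
    SA <- SA + k * psum[k]
    SE <- SE - psum[k] * lg(psum[k])
  }
  SV <- 0
  for (k in 2:(2 * ng)) SV <- SV + (k - SA)^2 * psum[k]
  for (k in 0:(ng - 1)) DE <- DE - pdiff[k + 1] * lg(pdiff[k + 1])

  ac <- 0; con <- 0; ene <- 0; iv <- 0; cp <- 0; corr_num <- 0; ent <- HXY
  mp <- 0; va <- 0; cs <- 0; hom <- 0; idn <- 0; ct <- 0; dis <- 0
  hom2 <- 0; idmn <- 0
  for (i in 1:ng) for (j in 1:ng) {
    ac <- ac + i * j * p[i, j]
    con <- con + (i - j)^2 * p[i, j]
    ene <- ene + p[i, j]^2
    if (j > i) iv <- iv + 2 * p[i, j] / (i - j)^2
    cp <- cp + (i + j - mux - muy)^4 * p[i, j]
    corr_num <- corr_num + i * j * p[i, j]
    mp <- max(mp, p[i, j])
    va <- va + (i - mux)^2 * p[i, j]
    cs <- cs + (i + j - mux - muy)^3 * p[i, j]
    hom <- hom + p[i, j] / (1 + abs(i - j))
    idn <- idn + p[i, j] / (1 + abs(i - j) / ng)
    ct <- ct + (i + j - mux - muy)^2 * p[i, j]
    dis <- dis + abs(i - j) * p[i, j]
    hom2 <- hom2 + p[i, j] / (1 + (i - j)^2)
    idmn <- idmn + p[i, j] / (1 + (i - j)^2 / ng^2)
  }
  c(AutoCorrelation = ac, Contrast = con, Energy = ene,
    InformationMeasureCorr1 = if (HX > 0) (HXY - HXY1) / HX else 0,
    InverseVariance = iv, SumVariance = SV, ClusterProminence = cp,
    Correlation = if (sigx > 0 && sigy > 0)
      (corr_num - mux * muy) / (sigx * sigy) else 0,
    Entropy = ent,
    InformationMeasureCorr2 = sqrt(max(0, 1 - exp(-2 * (HXY2 - HXY)))),
    MaxProbability = mp, Variance = va, ClusterShade = cs,
    DifferenceEntropy = DE, Homogeneity = hom, InverseDiffNorm = idn,
    SumAverage = SA, ClusterTendency = ct, Dissimilarity = dis,
    Homogeneity2 = hom2, InverseDiffMomentNorm = idmn, SumEntropy = SE)
}

# random symmetric normalized GLCM
random_glcm <- function(ng) {
  m <- matrix(stats::rexp(ng * ng), ng, ng)
  m <- m + t(m)
  structure(list(p = m / sum(m), n_levels = ng), class = "glcm")
}

# MTV by explicit triple loop
naive_mtv_cc <- function(vol, mask, threshold) {
  d <- dim(vol$voxels)
  count <- 0
  for (s in 1:d[1]) for (r in 1:d[2]) for (cc in 1:d[3])
    if (mask$voxels[s, r, cc] && vol$voxels[s, r, cc] >= threshold)
      count <- count + 1
  count * vol$voxel_volume_cc
}

# max pairwise distance over ALL segmented voxel centers, O(n^2)
naive_max_diameter <- function(seg) {
  idx <- seg$voxels
  d <- seg$dim; sp <- seg$spacing
  s <- ((idx - 1) %% d[1]) + 1
  r <- (((idx - 1) %/% d[1]) %% d[2]) + 1
  cc <- ((idx - 1) %/% (d[1] * d[2])) + 1
  x <- (cc - 0.5) * sp[1]; y <- (r - 0.5) * sp[2]; z <- (s - 0.5) * sp[3]
  best <- 0
  n <- length(idx)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    best <- max(best, sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2 + (z[i] - z[j])^2))
  best
}

# AUC by explicit positive-negative pair counting, ties worth 1/2
naive_pair_auc <- function(scores, labels) {
  pos <- scores[labels]; neg <- scores[!labels]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# brute-force slice GLCM: enumerate every in-mask ordered neighbor pair
naive_glcm_slice <- function(levels, ng,
                             directions = c("0", "45", "90", "135")) {
  offs <- list("0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
               "135" = c(-1, -1))
  cnt <- matrix(0, ng, ng)
  n <- nrow(levels); m <- ncol(levels)
  for (dn in directions) {
    o <- offs[[dn]]
    for (r in 1:n) for (cc in 1:m) {
      r2 <- r + o[1]; c2 <- cc + o[2]
      if (r2 < 1 || r2 > n || c2 < 1 || c2 > m) next
      a <- levels[r, cc]; b <- levels[r2, c2]
      if (is.na(a) || is.na(b)) next
      cnt[a, b] <- cnt[a, b] + 1
      cnt[b, a] <- cnt[b, a] + 1
    }
  }
  if (sum(cnt) == 0) return(NULL)
  cnt / sum(cnt)
}

# naive O(n^3) complete-linkage agglomeration, lowest-index pair on ties
naive_complete_linkage_cut <- function(x, k) {
  n <- nrow(x)
  members <- as.list(seq_len(n))
  d <- as.matrix(stats::dist(x))
  while (length(members) > k) {
    best <- c(NA, NA); bestd <- Inf
    for (i in seq_len(length(members) - 1)) {
      for (j in (i + 1):length(members)) {
        dij <- max(d[members[[i]], members[[j]]])
        if (dij < bestd) { bestd <- dij; best <- c(i, j) }
      }
    }
    members[[best[1]]] <- c(members[[best[1]]], members[[best[2]]])
    members[[best[2]]] <- NULL
  }
  lab <- integer(n)
  for (g in seq_along(members)) lab[members[[g]]] <- g
  lab
}

# same partition up to label renaming?
same_partition <- function(a, b) {
  length(unique(paste(a, b))) == length(unique(a)) &&
    length(unique(a)) == length(unique(b))
}
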