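# Independent brute-force F computation for a balanced 2 (between) x 2 x 3
# (within) mixed design, built from explicit cell means and the classical
# stratum decomposition - no model-fitting machinery.
brute_mixed_f <- function(Y, groups) {
  ns <- nrow(Y)
  g <- as.character(groups)
  I <- rep(c("high", "low"), each = 3)
  J <- rep(c("A", "V", "AV"), 2)
  gl <- unique(g); il <- unique(I); jl <- unique(J)
  ng <- ns / length(gl)
  m <- mean(Y)
  ms <- rowMeans(Y)
  mg <- sapply(gl, function(x) mean(Y[g == x, ]))
  mi <- sapply(il, function(x) mean(Y[, I == x]))
  mj <- sapply(jl, function(x) mean(Y[, J == x]))
  mgi <- outer(gl, il, Vectorize(function(a, b) mean(Y[g == a, I == b])))
  mgj <- outer(gl, jl, Vectorize(function(a, b) mean(Y[g == a, J == b])))
  mij <- outer(il, jl, Vectorize(function(a, b) mean(Y[, I == a & J == b])))
  dimnames(mgi) <- list(gl, il); dimnames(mgj) <- list(gl, jl)
  dimnames(mij) <- list(il, jl)

  SSg <- ng * 6 * sum((mg - m)^2)
  SSsub <- 6 * sum((ms - mg[g])^2)
  SSI <- ns * 3 * sum((mi - m)^2)
  SSJ <- ns * 2 * sum((mj - m)^2)
  SSgI <- 0
  for (a in gl) for (b in il) SSgI <- SSgI + ng * 3 * (mgi[a, b] - mg[a] - mi[b] + m)^2
  SSgJ <- 0
  for (a in gl) for (b in jl) SSgJ <- SSgJ + ng * 2 * (mgj[a, b] - mg[a] - mj[b] + m)^2
  SSIJ <- 0
  for (a in il) for (b in jl) SSIJ <- SSIJ + ns * (mij[a, b] - mi[a] - mj[b] + m)^2
  SSgIJ <- 0
  for (a in gl) for (b in il) for (cc in jl) {
    mc <- mean(Y[g == a, I == b & J == cc])
    dev <- mc - mgi[a, b] - mgj[a, cc] - mij[b, cc] + mg[a] + mi[b] + mj[cc] - m
    SSgIJ <- SSgIJ + ng * dev^2
  }
  SSerrI <- 0
  for (s in seq_len(ns)) for (b in il) {
    msi <- mean(Y[s, I == b])
    SSerrI <- SSerrI + 3 * (msi - ms[s] - mgi[g[s], b] + mg[g[s]])^2
  }
  SSerrJ <- 0
  for (s in seq_len(ns)) for (b in jl) {
    msj <- mean(Y[s, J == b])
    SSerrJ <- SSerrJ + 2 * (msj - ms[s] - mgj[g[s], b] + mg[g[s]])^2
  }
  SStot <- sum((Y - m)^2)
  SSerrIJ <- SStot - (SSg + SSsub + SSI + SSgI + SSerrI + SSJ + SSgJ +
                        SSerrJ + SSIJ + SSgIJ)
  dfsub <- ns - length(gl)
  c(group = unname((SSg / 1) / (SSsub / dfsub)),
    intensity = unname((SSI / 1) / (SSerrI / dfsub)),
    "group:intensity" = unname((SSgI / 1) / (SSerrI / dfsub)),
    stim_type = unname((SSJ / 2) / (SSerrJ / (2 * dfsub))),
    "group:stim_type" = unname((SSgJ / 2) / (SSerrJ / (2 * dfsub))),
    "intensity:stim_type" = unname((SSIJ / 2) / (SSerrIJ / (2 * dfsub))),
    "group:intensity:stim_type" = unname((SSgIJ / 2) / (SSerrIJ / (2 * dfsub))))
}
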