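# Model-specific scoring and analytic gradients for the five embedding models.
#
# Parameters are stored as real matrices throughout; complex-valued models
# (RotatE, ComplEx) keep paired real/imaginary matrices, and RotatE relations
# are stored as phase angles so the unit-modulus constraint holds by
# construction. All functions are vectorised over a batch of index triples
# (hi, ri, ti). Higher score = more plausible.

KGE_MODELS <- c("TransE", "TransR", "RotatE", "ComplEx", "HolE")

# --- FFT helpers for circular correlation / convolution on matrix rows -----

row_fft <- function(X) t(stats::mvfft(t(X)))

row_ifft <- function(Xc) t(stats::mvfft(t(Xc), inverse = TRUE)) / ncol(Xc)

# circular correlation of each row pair: corr(a,b)_k = sum_i a_i b_{(i+k) mod d}
ccorr_rows <- function(A, B) Re(row_ifft(Conj(row_fft(A)) * row_fft(B)))

# circular convolution of each row pair
cconv_rows <- function(A, B) Re(row_ifft(row_fft(A) * row_fft(B)))

# O(d^2) double-loop circular correlation, kept as the reference definition
# (exercised directly by the test-suite oracle comparisons).
ccorr_slow <- function(a, b) {
  d <- length(a)
  vapply(seq_len(d) - 1L, function(k) {
    sum(a * b[((seq_len(d) - 1L + k) %% d) + 1L])
  }, numeric(1))
}

# --- parameter initialisation ----------------------------------------------

kge_init_params <- function(model, n_e, n_r, d) {
  lim <- 6 / sqrt(d)
  um <- function(n) matrix(runif(n * d, -lim, lim), nrow = n)
  switch(model,
    TransE = {
      R <- um(n_r)
      R <- R / pmax(sqrt(rowSums(R^2)), 1e-12)
      list(E = um(n_e), R = R)
    },
    TransR = {
      M <- array(0, dim = c(d, d, n_r))
      for (j in seq_len(n_r)) M[, , j] <- diag(d)
      list(E = um(n_e), R = um(n_r), M = M)
    },
    RotatE = list(E_re = um(n_e), E_im = um(n_e),
                  theta = matrix(runif(n_r * d, -pi, pi), nrow = n_r)),
    ComplEx = list(E_re = um(n_e), E_im = um(n_e),
                   R_re = um(n_r), R_im = um(n_r)),
    HolE = list(E = um(n_e), R = um(n_r)),
    abort("unknown model: %s", model))
}

# --- forward passes ---------------------------------------------------------

kge_score_batch <- function(model, params, hi, ri, ti) {
  eps <- 1e-12
  unname(switch(model,
    TransE = {
      U <- params$E[hi, , drop = FALSE] + params$R[ri, , drop = FALSE] -
        params$E[ti, , drop = FALSE]
      -sqrt(rowSums(U^2) + eps)
    },
    TransR = {
      D <- params$E[hi, , drop = FALSE] - params$E[ti, , drop = FALSE]
      out <- numeric(length(hi))
      for (rel in unique(ri)) {
        idx <- which(ri == rel)
        U <- D[idx, , drop = FALSE] %*% t(params$M[, , rel]) +
          matrix(params$R[rel, ], nrow = length(idx), ncol = ncol(D),
                 byrow = TRUE)
        out[idx] <- -rowSums(U^2)
      }
      out
    },
    RotatE = {
      cs <- cos(params$theta[ri, , drop = FALSE])
      sn <- sin(params$theta[ri, , drop = FALSE])
      Hre <- params$E_re[hi, , drop = FALSE]
      Him <- params$E_im[hi, , drop = FALSE]
      Ure <- Hre * cs - Him * sn - params$E_re[ti, , drop = FALSE]
      Uim <- Hre * sn + Him * cs - params$E_im[ti, , drop = FALSE]
      -sqrt(rowSums(Ure^2 + Uim^2) + eps)
    },
    ComplEx = {
      Hre <- params$E_re[hi, , drop = FALSE]; Him <- params$E_im[hi, , drop = FALSE]
      Tre <- params$E_re[ti, , drop = FALSE]; Tim <- params$E_im[ti, , drop = FALSE]
      Rre <- params$R_re[ri, , drop = FALSE]; Rim <- params$R_im[ri, , drop = FALSE]
      rowSums(Hre * Rre * Tre + Him * Rre * Tim +
              Hre * Rim * Tim - Him * Rim * Tre)
    },
    HolE = {
      H <- params$E[hi, , drop = FALSE]; T_ <- params$E[ti, , drop = FALSE]
      rowSums(params$R[ri, , drop = FALSE] * ccorr_rows(H, T_))
    },
    abort("unknown model: %s", model)))
}

# --- backward passes --------------------------------------------------------
# ds: dLoss/dscore per batch row. Returns dense gradients for each parameter
# (scatter-added over batch rows with rowsum).

scatter_rows <- function(G, idx, n) {
  out <- matrix(0, nrow = n, ncol = ncol(G))
  agg <- rowsum(G, group = idx)
  out[as.integer(rownames(agg)), ] <- agg
  out
}

kge_grad_batch <- function(model, params, hi, ri, ti, ds) {
  eps <- 1e-12
  switch(model,
    TransE = {
      H <- params$E[hi, , drop = FALSE]; T_ <- params$E[ti, , drop = FALSE]
      U <- H + params$R[ri, , drop = FALSE] - T_
      nrm <- sqrt(rowSums(U^2) + eps)
      G <- U * (-ds / nrm)
      n_e <- nrow(params$E)
      gE <- scatter_rows(rbind(G, -G), c(hi, ti), n_e)
      list(E = gE, R = scatter_rows(G, ri, nrow(params$R)))
    },
    TransR = {
      D <- params$E[hi, , drop = FALSE] - params$E[ti, , drop = FALSE]
      d <- ncol(D)
      gE <- matrix(0, nrow(params$E), d)
      gR <- matrix(0, nrow(params$R), d)
      gM <- array(0, dim = dim(params$M))
      for (rel in unique(ri)) {
        idx <- which(ri == rel)
        M <- params$M[, , rel]
        Di <- D[idx, , drop = FALSE]
        U <- Di %*% t(M) + matrix(params$R[rel, ], length(idx), d, byrow = TRUE)
        Gu <- U * (-2 * ds[idx])
        Gd <- Gu %*% M
        gE <- gE + scatter_rows(rbind(Gd, -Gd), c(hi[idx], ti[idx]),
                                nrow(params$E))
        gR[rel, ] <- gR[rel, ] + colSums(Gu)
        gM[, , rel] <- gM[, , rel] + crossprod(Gu, Di)
      }
      list(E = gE, R = gR, M = gM)
    },
    RotatE = {
      cs <- cos(params$theta[ri, , drop = FALSE])
      sn <- sin(params$theta[ri, , drop = FALSE])
      Hre <- params$E_re[hi, , drop = FALSE]
      Him <- params$E_im[hi, , drop = FALSE]
      Are <- Hre * cs - Him * sn
      Aim <- Hre * sn + Him * cs
      Ure <- Are - params$E_re[ti, , drop = FALSE]
      Uim <- Aim - params$E_im[ti, , drop = FALSE]
      nrm <- sqrt(rowSums(Ure^2 + Uim^2) + eps)
      Gre <- Ure * (-ds / nrm)
      Gim <- Uim * (-ds / nrm)
      gHre <- Gre * cs + Gim * sn
      gHim <- -Gre * sn + Gim * cs
      gTheta <- Gre * (-Hre * sn - Him * cs) + Gim * (Hre * cs - Him * sn)
      n_e <- nrow(params$E_re)
      list(E_re = scatter_rows(rbind(gHre, -Gre), c(hi, ti), n_e),
           E_im = scatter_rows(rbind(gHim, -Gim), c(hi, ti), n_e),
           theta = scatter_rows(gTheta, ri, nrow(params$theta)))
    },
    ComplEx = {
      Hre <- params$E_re[hi, , drop = FALSE]; Him <- params$E_im[hi, , drop = FALSE]
      Tre <- params$E_re[ti, , drop = FALSE]; Tim <- params$E_im[ti, , drop = FALSE]
      Rre <- params$R_re[ri, , drop = FALSE]; Rim <- params$R_im[ri, , drop = FALSE]
      gHre <- ds * (Rre * Tre + Rim * Tim)
      gHim <- ds * (Rre * Tim - Rim * Tre)
      gTre <- ds * (Hre * Rre - Him * Rim)
      gTim <- ds * (Him * Rre + Hre * Rim)
      gRre <- ds * (Hre * Tre + Him * Tim)
      gRim <- ds * (Hre * Tim - Him * Tre)
      n_e <- nrow(params$E_re)
      list(E_re = scatter_rows(rbind(gHre, gTre), c(hi, ti), n_e),
           E_im = scatter_rows(rbind(gHim, gTim), c(hi, ti), n_e),
           R_re = scatter_rows(gRre, ri, nrow(params$R_re)),
           R_im = scatter_rows(gRim, ri, nrow(params$R_im)))
    },
    HolE = {
      H <- params$E[hi, , drop = FALSE]; T_ <- params$E[ti, , drop = FALSE]
      Rm <- params$R[ri, , drop = FALSE]
      gH <- ds * ccorr_rows(Rm, T_)
      gT <- ds * cconv_rows(H, Rm)
      gR <- ds * ccorr_rows(H, T_)
      n_e <- nrow(params$E)
      list(E = scatter_rows(rbind(gH, gT), c(hi, ti), n_e),
           R = scatter_rows(gR, ri, nrow(params$R)))
    },
    abort("unknown model: %s", model))
}

# Re-apply model constraints after a gradient step.
kge_apply_constraints <- function(model, params, normalize_entities) {
  if (model == "TransE" && isTRUE(normalize_entities)) {
    nrm <- pmax(sqrt(rowSums(params$E^2)), 1e-12)
    params$E <- params$E / nrm
  }
  params
}
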