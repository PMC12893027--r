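## Internal REML engine: dense mixed-model equations with the permanent-
## environment effect absorbed into a per-animal block residual covariance
## D_i = Phi_i P0 Phi_i' + sige I. All quantities the AI/EM updates need
## (restricted log-likelihood, exact score, average-information matrix,
## EM quantities) are computed from one Cholesky + inverse of the MME
## coefficient matrix per iteration.

reml_engine <- function(des, Kinv, logdetK, ns, use_pe) {
  y <- des$y
  X <- des$X
  N <- des$n_rec
  p <- ncol(X)
  nc <- des$nc
  n <- des$n_anim
  groups <- des$groups
  anim_idx <- des$anim_idx
  phi_rec <- des$phi_rec
  sire_idx <- des$sire_idx
  M <- p + nc * n + ns
  uoff <- p
  soff <- p + nc * n
  ucols <- uoff + seq_len(nc * n)

  apply_rinv <- function(Mat, Dinv_list) {
    Mat <- as.matrix(Mat)
    K <- ncol(Mat)
    out <- matrix(0, nrow(Mat), K)
    for (g in groups) {
      block <- Mat[g$rows, , drop = FALSE]
      tmp <- Dinv_list[[g$pattern]] %*% matrix(block, g$m, g$n_g * K)
      out[g$rows, ] <- matrix(tmp, g$m * g$n_g, K)
    }
    out
  }
  qtrans <- function(Mat) {
    Mat <- as.matrix(Mat)
    K <- ncol(Mat)
    out <- matrix(0, nc * n, K)
    for (g in groups) {
      block <- Mat[g$rows, , drop = FALSE]
      tmp <- crossprod(g$Phi, matrix(block, g$m, g$n_g * K))
      urows <- rep((g$animals - 1L) * nc, each = nc) + seq_len(nc)
      out[urows, ] <- matrix(tmp, nc * g$n_g, K)
    }
    out
  }
  qmul <- function(Z) {
    Z <- as.matrix(Z)
    K <- ncol(Z)
    out <- matrix(0, N, K)
    for (g in groups) {
      urows <- rep((g$animals - 1L) * nc, each = nc) + seq_len(nc)
      block <- Z[urows, , drop = FALSE]
      tmp <- g$Phi %*% matrix(block, nc, g$n_g * K)
      out[g$rows, ] <- matrix(tmp, g$m * g$n_g, K)
    }
    out
  }
  strans <- function(Mat) {
    Mat <- as.matrix(Mat)
    out <- matrix(0, ns, ncol(Mat))
    agg <- rowsum(Mat, sire_idx)
    out[as.integer(rownames(agg)), ] <- agg
    out
  }

  evaluate <- function(eta) {
    pars <- par_unpack(eta, nc, use_pe, ns)
    G0 <- pars$G0; P0 <- pars$P0; sigs <- pars$sigs; sige <- pars$sige
    G0inv <- solve(G0)
    Dinv_list <- list(); DinvPhi <- list(); B_list <- list()
    logdetR <- 0
    for (g in groups) {
      D <- diag(sige, g$m)
      if (use_pe) D <- D + g$Phi %*% P0 %*% t(g$Phi)
      cD <- chol(D)
      Dinv <- chol2inv(cD)
      Dinv_list[[g$pattern]] <- Dinv
      DinvPhi[[g$pattern]] <- Dinv %*% g$Phi
      B_list[[g$pattern]] <- crossprod(g$Phi, Dinv %*% g$Phi)
      logdetR <- logdetR + g$n_g * 2 * sum(log(diag(cD)))
    }

    RinvX <- apply_rinv(X, Dinv_list)
    Rinvy <- apply_rinv(y, Dinv_list)

    C <- matrix(0, M, M)
    C[seq_len(p), seq_len(p)] <- crossprod(X, RinvX)
    QtRX <- qtrans(RinvX)
    C[ucols, seq_len(p)] <- QtRX
    C[seq_len(p), ucols] <- t(QtRX)
    C[ucols, ucols] <- Kinv %x% G0inv
    for (g in groups) {
      B <- B_list[[g$pattern]]
      for (a in seq_len(nc)) {
        for (b in seq_len(nc)) {
          ia <- uoff + (g$animals - 1L) * nc + a
          ib <- uoff + (g$animals - 1L) * nc + b
          C[cbind(ia, ib)] <- C[cbind(ia, ib)] + B[a, b]
        }
      }
    }
    if (ns) {
      scols <- soff + seq_len(ns)
      StRX <- strans(RinvX)
      C[scols, seq_len(p)] <- StRX
      C[seq_len(p), scols] <- t(StRX)
      ## animal-by-sire coupling
      Grec <- matrix(0, N, nc)
      for (g in groups) {
        DP <- DinvPhi[[g$pattern]]
        Grec[g$rows, ] <- DP[rep(seq_len(g$m), g$n_g), ]
      }
      pair <- anim_idx + (sire_idx - 1L) * n
      agg <- rowsum(Grec, pair)
      ids <- as.integer(rownames(agg))
      ai <- (ids - 1L) %% n + 1L
      ki <- (ids - 1L) %/% n + 1L
      for (a in seq_len(nc)) {
        C[cbind(uoff + (ai - 1L) * nc + a, soff + ki)] <-
          C[cbind(uoff + (ai - 1L) * nc + a, soff + ki)] + agg[, a]
      }
      C[scols, ucols] <- t(C[ucols, scols])
      ## sire-by-sire within-animal blocks
      css <- numeric(ns * ns)
      for (g in groups) {
        Dinv <- Dinv_list[[g$pattern]]
        sm <- matrix(sire_idx[g$rows], g$m, g$n_g)
        for (r1 in seq_len(g$m)) {
          for (r2 in seq_len(g$m)) {
            idx <- sm[r1, ] + (sm[r2, ] - 1L) * ns
            css <- css + Dinv[r1, r2] * tabulate(idx, ns * ns)
          }
        }
      }
      C[scols, scols] <- matrix(css, ns, ns) + diag(1 / sigs, ns)
    }

    r <- c(crossprod(X, Rinvy), qtrans(Rinvy), if (ns) strans(Rinvy))
    cholC <- chol(C)
    sol <- backsolve(cholC, backsolve(cholC, r, transpose = TRUE))
    yRy <- sum(y * Rinvy)
    yPy <- yRy - sum(r * sol)
    logdetC <- 2 * sum(log(diag(cholC)))
    logdetG0 <- as.numeric(determinant(G0)$modulus)
    m2l <- logdetR + nc * logdetK + n * logdetG0 +
      (if (ns) ns * log(sigs) else 0) + logdetC + yPy +
      (N - p) * log(2 * pi)
    loglik <- -0.5 * m2l

    fitted <- X %*% sol[seq_len(p)] + qmul(sol[ucols])
    if (ns) fitted <- fitted + sol[soff + sire_idx]
    Py <- apply_rinv(y - fitted, Dinv_list)

    list(eta = eta, pars = pars, loglik = loglik, cholC = cholC, sol = sol,
         Dinv_list = Dinv_list, DinvPhi = DinvPhi, B_list = B_list,
         RinvX = RinvX, Py = drop(Py), yPy = yPy, G0inv = G0inv)
  }

  derivatives <- function(state) {
    pars <- state$pars
    G0 <- pars$G0; P0 <- pars$P0; sigs <- pars$sigs; sige <- pars$sige
    G0inv <- state$G0inv
    Cinv <- chol2inv(state$cholC)
    uhat <- state$sol[ucols]
    Uhat <- t(matrix(uhat, nc, n))
    KinvU <- Kinv %*% Uhat
    Qmat <- crossprod(Uhat, KinvU)
    Py <- state$Py

    ## K^-1-contracted block trace of the u-block of C^-1
    Ttil <- matrix(0, nc, nc)
    for (a in seq_len(nc)) {
      for (b in seq_len(nc)) {
        Sub <- Cinv[uoff + seq(a, by = nc, length.out = n),
                    uoff + seq(b, by = nc, length.out = n)]
        Ttil[a, b] <- sum(Kinv * Sub)
      }
    }

    Vmat <- t(matrix(qtrans(Py), nc, n))   # v_i = Phi_i' (Py)_i
    Vq <- crossprod(Vmat)

    ## per-animal diagonal blocks of the projection for tr(P) and PE traces
    trP <- 0
    SigmaPsi <- matrix(0, nc, nc)
    pcols <- seq_len(p)
    for (g in groups) {
      Dinv <- state$Dinv_list[[g$pattern]]
      DP <- state$DinvPhi[[g$pattern]]
      B <- state$B_list[[g$pattern]]
      trD <- sum(diag(Dinv))
      for (ii in seq_along(g$animals)) {
        ai <- g$animals[ii]
        rows_i <- g$rows[(ii - 1L) * g$m + seq_len(g$m)]
        Vi <- cbind(state$RinvX[rows_i, , drop = FALSE], DP)
        idx <- c(pcols, uoff + (ai - 1L) * nc + seq_len(nc))
        if (ns) {
          sid <- sire_idx[rows_i]
          us <- unique(sid)
          ind <- matrix(0, g$m, length(us))
          ind[cbind(seq_len(g$m), match(sid, us))] <- 1
          Vi <- cbind(Vi, Dinv %*% ind)
          idx <- c(idx, soff + us)
        }
        Cs <- Cinv[idx, idx]
        Mi <- crossprod(Vi)
        Gi <- crossprod(g$Phi, Vi)
        trP <- trP + trD - sum(Cs * Mi)
        SigmaPsi <- SigmaPsi + B - Gi %*% Cs %*% t(Gi)
      }
    }

    shat <- if (ns) state$sol[soff + seq_len(ns)] else NULL
    CssSum <- if (ns) sum(diag(Cinv)[soff + seq_len(ns)]) else NULL

    EG <- sym_basis(nc)
    score <- c()
    fmat <- NULL
    for (E in EG) {
      FG <- G0inv %*% E %*% G0inv
      trk <- n * sum(E * G0inv) - sum(FG * Ttil)
      quad <- sum(E * (G0inv %*% Qmat %*% G0inv))
      score <- c(score, -0.5 * (trk - quad))
      Mg <- Uhat %*% G0inv %*% E
      fmat <- cbind(fmat, rowSums(phi_rec * Mg[anim_idx, , drop = FALSE]))
    }
    if (use_pe) {
      for (E in EG) {
        trk <- sum(SigmaPsi * E)
        quad <- sum(Vq * E)
        score <- c(score, -0.5 * (trk - quad))
        Mp <- Vmat %*% E
        fmat <- cbind(fmat, rowSums(phi_rec * Mp[anim_idx, , drop = FALSE]))
      }
    }
    if (ns) {
      trk <- ns / sigs - CssSum / sigs^2
      quad <- sum((shat / sigs)^2)
      score <- c(score, -0.5 * (trk - quad))
      fmat <- cbind(fmat, shat[sire_idx] / sigs)
    }
    score <- c(score, -0.5 * (trP - sum(Py^2)))
    fmat <- cbind(fmat, Py)

    ## average information: 0.5 * f_k' P f_l
    g1 <- apply_rinv(fmat, state$Dinv_list)
    h <- rbind(crossprod(X, g1), qtrans(g1), if (ns) strans(g1))
    z <- Cinv %*% h
    Wz <- X %*% z[seq_len(p), , drop = FALSE] + qmul(z[ucols, , drop = FALSE])
    if (ns) Wz <- Wz + z[soff + sire_idx, , drop = FALSE]
    PF <- g1 - apply_rinv(Wz, state$Dinv_list)
    AI_raw <- 0.5 * crossprod(fmat, PF)
    AI_raw <- (AI_raw + t(AI_raw)) / 2

    ## Jacobian to the log-Cholesky scale
    eta <- state$eta
    ng <- nc * (nc + 1) / 2
    blocks <- list(chol_block_jac(eta[seq_len(ng)]))
    off <- ng
    if (use_pe) {
      blocks <- c(blocks, list(chol_block_jac(eta[off + seq_len(ng)])))
      off <- off + ng
    }
    if (ns) {
      blocks <- c(blocks, list(matrix(2 * sigs, 1, 1)))
      off <- off + 1
    }
    blocks <- c(blocks, list(matrix(2 * sige, 1, 1)))
    J <- as.matrix(Matrix_bdiag(blocks))

    list(score_raw = score, AI_raw = AI_raw,
         score_eta = drop(crossprod(J, score)),
         AI_eta = crossprod(J, AI_raw %*% J),
         Qmat = Qmat, Ttil = Ttil, Vq = Vq, SigmaPsi = SigmaPsi,
         trP = trP, sumPy2 = sum(Py^2), shat = shat, CssSum = CssSum,
         state = state)
  }

  em_update <- function(full) {
    st <- full$state
    pars <- st$pars
    G0_new <- (full$Qmat + (full$Ttil + t(full$Ttil)) / 2) / n
    P0_new <- NULL
    if (use_pe) {
      P0 <- pars$P0
      P0_new <- P0 + P0 %*% ((full$Vq - full$SigmaPsi) / n) %*% P0
      P0_new <- (P0_new + t(P0_new)) / 2
    }
    sigs_new <- if (ns) (sum(full$shat^2) + full$CssSum) / ns else NULL
    sige_new <- pars$sige + pars$sige^2 * (full$sumPy2 - full$trP) / N
    par_pack(G0_new, P0_new, sigs_new, sige_new, nc)
  }

  list(evaluate = evaluate, derivatives = derivatives, em_update = em_update)
}

## tiny block-diagonal helper (avoids a Matrix dependency for a 8x8 case)
Matrix_bdiag <- function(blocks) {
  sizes <- vapply(blocks, nrow, 1L)
  out <- matrix(0, sum(sizes), sum(sizes))
  off <- 0L
  for (b in blocks) {
    k <- nrow(b)
    out[off + seq_len(k), off + seq_len(k)] <- b
    off <- off + k
  }
  out
}
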