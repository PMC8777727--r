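#' JADE independent component analysis of the three colour traces
#'
#' Blind source separation by joint approximate diagonalization of
#' eigenmatrices (Cardoso's JADE): the channels are whitened, the
#' fourth-order cumulant matrices are estimated, and a sequence of Jacobi
#' rotations jointly diagonalizes them. One recovered source carries the
#' blood-volume pulse; the others absorb illumination and motion noise.
#'
#' Component order out of an ICA is arbitrary, so the sources are returned
#' in a deterministic order - descending magnitude of excess kurtosis - and
#' each source's sign is fixed so that its largest-magnitude sample is
#' positive. This makes "the second component" a reproducible notion.
#'
#' @param x1,x2,x3 `vital_ts` of equal length (>= 250 samples), typically
#'   the normalized, band-passed red, green and blue traces.
#' @return list with `sources` (list of three unit-variance `vital_ts`) and
#'   `unmixing` (3 x 3 matrix mapping centred channels to sources).
#' @references Cardoso, J.-F. and Souloumiac, A. (1993) Blind beamforming
#'   for non-Gaussian signals. IEE Proceedings F 140(6), 362-370.
#' @export
jade_ica <- function(x1, x2, x3) {
  fs <- x1$fs
  if (x2$fs != fs || x3$fs != fs)
    stop("channels must share a sampling rate", call. = FALSE)
  X <- rbind(x1$values, x2$values, x3$values)
  if (ncol(X) < 250)
    stop("need at least 250 samples for stable cumulant estimates",
         call. = FALSE)
  S <- jade_decompose(X)
  sources <- lapply(seq_len(nrow(S$S)), function(i)
    time_series(S$S[i, ], fs, x1$t0, label = sprintf("ica%d", i)))
  list(sources = sources, unmixing = S$B)
}

# Core JADE on an m x T data matrix (rows = channels). Returns unit-variance
# sources ordered by descending |excess kurtosis|, sign-fixed.
jade_decompose <- function(X, eig_tol = 1e-10) {
  m <- nrow(X); T <- ncol(X)
  X <- X - rowMeans(X)

  ## whitening
  C <- tcrossprod(X) / T
  ed <- eigen(C, symmetric = TRUE)
  if (min(ed$values) < eig_tol * max(ed$values))
    stop("rank-deficient input: channels are linearly dependent",
         call. = FALSE)
  W <- diag(1 / sqrt(ed$values)) %*% t(ed$vectors)
  Z <- W %*% X

  ## fourth-order cumulant matrices (m(m+1)/2 of them), stored side by side
  nbcm <- m * (m + 1) / 2
  CM <- matrix(0, m, m * nbcm)
  R <- diag(m)
  blk <- 0L
  for (im in seq_len(m)) {
    Zim <- Z[im, ]
    Q <- (Z * rep(Zim * Zim, each = m)) %*% t(Z) / T - R -
      2 * tcrossprod(R[, im])
    CM[, blk * m + seq_len(m)] <- Q
    blk <- blk + 1L
    for (jm in seq_len(im - 1)) {
      Zij <- Zim * Z[jm, ]
      Q <- sqrt(2) * ((Z * rep(Zij, each = m)) %*% t(Z) / T -
                        tcrossprod(R[, im], R[, jm]) -
                        tcrossprod(R[, jm], R[, im]))
      CM[, blk * m + seq_len(m)] <- Q
      blk <- blk + 1L
    }
  }

  ## joint diagonalization by Jacobi rotations
  V <- diag(m)
  seuil <- 1e-6 / sqrt(T)
  repeat {
    rotated <- FALSE
    for (p in seq_len(m - 1)) {
      for (q in seq.int(p + 1, m)) {
        Ip <- seq(p, m * nbcm, m)
        Iq <- seq(q, m * nbcm, m)
        g <- rbind(CM[p, Ip] - CM[q, Iq], CM[p, Iq] + CM[q, Ip])
        gg <- tcrossprod(g)
        ton <- gg[1, 1] - gg[2, 2]
        toff <- gg[1, 2] + gg[2, 1]
        theta <- 0.5 * atan2(toff, ton + sqrt(ton * ton + toff * toff))
        if (abs(sin(theta)) > seuil) {
          rotated <- TRUE
          cs <- cos(theta); sn <- sin(theta)
          G <- matrix(c(cs, sn, -sn, cs), 2, 2)  # [[cs, -sn], [sn, cs]]
          pair <- c(p, q)
          V[, pair] <- V[, pair] %*% G
          CM[pair, ] <- t(G) %*% CM[pair, ]
          tmp <- cs * CM[, Ip] + sn * CM[, Iq]
          CM[, Iq] <- -sn * CM[, Ip] + cs * CM[, Iq]
          CM[, Ip] <- tmp
        }
      }
    }
    if (!rotated) break
  }

  B <- t(V) %*% W
  S <- B %*% X
  ## exact unit sample variance per source
  sds <- apply(S, 1, stats::sd)
  S <- S / sds
  B <- B / sds
  ## deterministic order: descending |excess kurtosis|, then sign fix
  ek <- apply(S, 1, function(s) mean((s - mean(s))^4) / stats::var(s)^2 - 3)
  ord <- order(abs(ek), decreasing = TRUE)
  S <- S[ord, , drop = FALSE]
  B <- B[ord, , drop = FALSE]
  for (i in seq_len(nrow(S))) {
    sgn <- sign(S[i, which.max(abs(S[i, ]))])
    if (sgn < 0) {
      S[i, ] <- -S[i, ]
      B[i, ] <- -B[i, ]
    }
  }
  list(S = S, B = B)
}
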