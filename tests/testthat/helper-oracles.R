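## Independent brute-force oracles. These deliberately re-derive each
## quantity from its definition with a different algorithm than the
## package implementation.

## Maxima with noise tolerance: per-plateau exhaustive flood.
## A candidate plateau of value v is accepted iff the connected component
## of {value >= v - tol} containing it holds nothing higher than v.
oracle_find_maxima <- function(img, tol) {
  nr <- nrow(img); nc <- ncol(img)
  neighbors <- function(i, j) {
    out <- matrix(0L, 0, 2)
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      a <- i + dr; b <- j + dc
      if (a >= 1 && a <= nr && b >= 1 && b <= nc) out <- rbind(out, c(a, b))
    }
    out
  }
  cand <- matrix(FALSE, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    nb <- neighbors(i, j)
    cand[i, j] <- all(img[nb] <= img[i, j])
  }
  seen <- matrix(FALSE, nr, nc)
  res <- list()
  for (i in 1:nr) for (j in 1:nc) {
    if (!cand[i, j] || seen[i, j]) next
    v <- img[i, j]
    queue <- list(c(i, j)); seen[i, j] <- TRUE
    plat <- matrix(0L, 0, 2)
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      plat <- rbind(plat, p)
      nb <- neighbors(p[1], p[2])
      for (k in seq_len(nrow(nb))) {
        q <- nb[k, ]
        if (cand[q[1], q[2]] && !seen[q[1], q[2]] && img[q[1], q[2]] == v) {
          seen[q[1], q[2]] <- TRUE
          queue[[length(queue) + 1]] <- q
        }
      }
    }
    vis <- matrix(FALSE, nr, nc)
    stack <- lapply(seq_len(nrow(plat)), function(k) plat[k, ])
    for (k in seq_len(nrow(plat))) vis[plat[k, 1], plat[k, 2]] <- TRUE
    higher <- FALSE
    while (length(stack) && !higher) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (img[p[1], p[2]] > v) { higher <- TRUE; break }
      nb <- neighbors(p[1], p[2])
      for (k in seq_len(nrow(nb))) {
        q <- nb[k, ]
        if (!vis[q[1], q[2]] && img[q[1], q[2]] >= v - tol) {
          vis[q[1], q[2]] <- TRUE
          stack[[length(stack) + 1]] <- q
        }
      }
    }
    if (!higher) {
      res[[length(res) + 1]] <- data.frame(
        row = floor(mean(plat[, 1]) + 0.5),
        col = floor(mean(plat[, 2]) + 0.5),
        value = v)
    }
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(row = integer(0), col = integer(0), value = numeric(0))
  out <- out[order(-out$value, out$row, out$col), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## Maximum-entropy threshold: explicit entropy sum for each of the 256
## candidate bins, computed from scratch.
oracle_entropy_bin <- function(patch) {
  x <- as.numeric(patch)
  lo <- min(x); hi <- max(x)
  stopifnot(hi > lo)
  bins <- pmin(floor((x - lo) / (hi - lo) * 256), 255)
  p <- tabulate(bins + 1L, nbins = 256L) / length(x)
  best <- -Inf; tbest <- NA_integer_
  for (t in 0:254) {
    P0 <- sum(p[1:(t + 1)]); P1 <- 1 - P0
    if (P0 <= 0 || P1 <= 0) next
    q0 <- p[1:(t + 1)]; q0 <- q0[q0 > 0] / P0
    q1 <- p[(t + 2):256]; q1 <- q1[q1 > 0] / P1
    H <- -sum(q0 * log(q0)) - sum(q1 * log(q1))
    if (H > best + 1e-12) { best <- H; tbest <- t }
  }
  tbest
}

## Drift: direct per-offset loop over submatrices with the same scoring
## and tie-breaking definitions as the contract.
oracle_drift <- function(a, b, window, mode = "product_max") {
  nr <- nrow(a); nc <- ncol(a)
  offs <- expand.grid(dr = -window:window, dc = -window:window)
  score <- numeric(nrow(offs))
  for (k in seq_len(nrow(offs))) {
    dr <- offs$dr[k]; dc <- offs$dc[k]
    r1 <- max(1, 1 - dr):min(nr, nr - dr)
    c1 <- max(1, 1 - dc):min(nc, nc - dc)
    aa <- a[r1, c1]; bb <- b[r1 + dr, c1 + dc]
    score[k] <- if (mode == "product_max") {
      ea <- sum(aa^2); eb <- sum(bb^2)
      if (ea > 0 && eb > 0) sum(aa * bb) / sqrt(ea * eb) else 0
    } else {
      sum(aa * bb) / (length(r1) * length(c1))
    }
  }
  ord <- order(if (mode == "product_max") -score else score,
               offs$dr^2 + offs$dc^2, offs$dr, offs$dc)
  c(offs$dr[ord[1]], offs$dc[ord[1]])
}

## Direct spatial-domain convolution of an arbitrary structure image with a
## Gaussian kernel (no FFT), for PSF-rendering checks.
oracle_convolve_gauss <- function(img, sigma) {
  r <- ceiling(4 * sigma)
  k <- outer(dnorm(-r:r, sd = sigma), dnorm(-r:r, sd = sigma))
  k <- k / sum(k)
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (i in 1:nr) for (j in 1:nc) {
    if (img[i, j] == 0) next
    rs <- max(1, i - r):min(nr, i + r)
    cs <- max(1, j - r):min(nc, j + r)
    out[rs, cs] <- out[rs, cs] +
      img[i, j] * k[rs - i + r + 1, cs - j + r + 1]
  }
  out
}

## FWHM of a sampled profile by dense linear interpolation.
oracle_profile_fwhm <- function(prof, step = 1) {
  base <- min(prof); half <- base + (max(prof) - base) / 2
  fine_x <- seq(1, length(prof), by = 0.001)
  fine <- approx(seq_along(prof), prof, fine_x)$y
  above <- which(fine >= half)
  (fine_x[max(above)] - fine_x[min(above)]) * step
}

## Rasterized disc of diameter d (pixel-center sampling) on a padded frame.
rasterize_disc <- function(d, pad = 2) {
  n <- d + 2 * pad
  cen <- (n + 1) / 2
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  (rr - cen)^2 + (cc - cen)^2 <= (d / 2)^2
}

## Exhaustive pixel-set disc intersection test.
oracle_discs_overlap <- function(c1, c2, d) {
  offs <- disc_offsets(d)
  p1 <- paste(c1[1] + offs[, 1], c1[2] + offs[, 2])
  p2 <- paste(c2[1] + offs[, 1], c2[2] + offs[, 2])
  length(intersect(p1, p2)) > 0
}
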