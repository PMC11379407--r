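# Independent reference Monte Carlo, written entirely in (vectorized) R and
# driven by R's own RNG stream. Shares no code with the package's transport
# kernel; used as the cross-check oracle for reflectance/transmittance.
# Geometry: slab 0 <= z <= thickness (Inf for a half-space), photons start
# at the origin moving +z. Weight-based absorption, no roulette, no time cap.
oracle_mc <- function(mua, mus, spf = list(g = 0), n_medium = 1,
                      n_outside = 1, thickness = Inf, n_photons = 5000,
                      max_iter = 200000) {
  fres <- function(n1, n2, cosi) {
    out <- numeric(length(cosi))
    if (abs(n1 - n2) < 1e-12) return(out)
    sint <- n1 / n2 * sqrt(pmax(0, 1 - cosi^2))
    tir <- sint >= 1
    cost <- sqrt(pmax(0, 1 - sint^2))
    rs <- (n1 * cosi - n2 * cost) / (n1 * cosi + n2 * cost)
    rp <- (n1 * cost - n2 * cosi) / (n1 * cost + n2 * cosi)
    out <- 0.5 * (rs^2 + rp^2)
    out[tir] <- 1
    out
  }
  sample_ct <- function(m) {
    # HG closed form; two-lobe mixture when spf carries (alpha, gf, gb)
    g <- if (!is.null(spf$alpha)) {
      ifelse(runif(m) < spf$alpha, spf$gf, spf$gb)
    } else {
      rep(spf$g, m)
    }
    u <- runif(m)
    ct <- 2 * u - 1
    nz <- abs(g) > 1e-12
    if (any(nz)) {
      s <- (1 - g[nz]^2) / (1 - g[nz] + 2 * g[nz] * u[nz])
      ct[nz] <- (1 + g[nz]^2 - s^2) / (2 * g[nz])
    }
    pmin(pmax(ct, -1), 1)
  }
  n <- n_photons
  mut <- mua + mus
  albedo <- if (mut > 0) mus / mut else 0
  rsp <- if (n_medium == n_outside) 0 else
    ((n_medium - n_outside) / (n_medium + n_outside))^2
  z <- numeric(n)
  ux <- uy <- numeric(n)
  uz <- rep(1, n)
  w <- rep(1 - rsp, n)
  alive <- rep(TRUE, n)
  step <- numeric(n)  # remaining dimensionless step, 0 = draw a new one
  Rw <- Tw <- Aw <- 0
  for (iter in seq_len(max_iter)) {
    if (!any(alive)) break
    a <- which(alive)
    need <- a[step[a] <= 0]
    step[need] <- if (mut > 0) stats::rexp(length(need)) / mut else 1e30
    db <- rep(1e30, length(a))
    down <- uz[a] > 0
    up <- uz[a] < 0
    if (is.finite(thickness)) db[down] <- (thickness - z[a][down]) / uz[a][down]
    db[up] <- -z[a][up] / uz[a][up]
    d <- pmin(step[a], db)
    z[a] <- z[a] + uz[a] * d
    step[a] <- step[a] - d
    hit <- d >= db - 1e-15 & db < 1e29
    hb <- a[hit]
    if (length(hb)) {
      cosi <- abs(uz[hb])
      refl <- runif(length(hb)) < fres(n_medium, n_outside, cosi)
      esc <- hb[!refl]
      if (length(esc)) {
        top <- z[esc] < thickness / 2 | !is.finite(thickness)
        Rw <- Rw + sum(w[esc][top])
        Tw <- Tw + sum(w[esc][!top])
        alive[esc] <- FALSE
      }
      rb <- hb[refl]
      uz[rb] <- -uz[rb]
      z[rb] <- pmin(pmax(z[rb], 0), if (is.finite(thickness)) thickness else Inf)
    }
    sc <- a[!hit & step[a] <= 1e-15]
    sc <- sc[alive[sc]]
    if (length(sc)) {
      if (mua > 0) {
        Aw <- Aw + sum(w[sc]) * (1 - albedo)
        w[sc] <- w[sc] * albedo
        dead <- sc[w[sc] < 1e-6]
        if (length(dead)) {
          Aw <- Aw + sum(w[dead])
          alive[dead] <- FALSE
          sc <- setdiff(sc, dead)
        }
      }
      if (length(sc)) {
        ct <- sample_ct(length(sc))
        st <- sqrt(pmax(0, 1 - ct^2))
        phi <- 2 * pi * runif(length(sc))
        cp <- cos(phi)
        sp <- sin(phi)
        vert <- abs(uz[sc]) > 0.99999
        if (any(vert)) {
          v <- sc[vert]
          k <- which(vert)
          ux[v] <- st[k] * cp[k]
          uy[v] <- st[k] * sp[k]
          uz[v] <- sign(uz[v]) * ct[k]
        }
        if (any(!vert)) {
          o <- sc[!vert]
          k <- which(!vert)
          den <- sqrt(1 - uz[o]^2)
          nx <- st[k] * (ux[o] * uz[o] * cp[k] - uy[o] * sp[k]) / den +
            ux[o] * ct[k]
          ny <- st[k] * (uy[o] * uz[o] * cp[k] + ux[o] * sp[k]) / den +
            uy[o] * ct[k]
          nz <- -den * st[k] * cp[k] + uz[o] * ct[k]
          nrm <- sqrt(nx^2 + ny^2 + nz^2)
          ux[o] <- nx / nrm
          uy[o] <- ny / nrm
          uz[o] <- nz / nrm
        }
      }
    }
  }
  list(R = Rw / n, T = Tw / n, A = Aw / n, specular = rsp,
       unfinished = sum(w[alive]) / n)
}
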