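# Independent brute-force oracles. Everything here is written as plain
# loops over definitions, deliberately sharing no code with the package
# implementation.

# random quantised test image: levels 1..ng inside a random mask, NA outside
random_quantized <- function(dim, ng, p_roi = 0.8) {
  lev <- array(NA_integer_, dim)
  n <- prod(dim)
  roi <- runif(n) < p_roi
  if (!any(roi)) roi[sample(n, 1)] <- TRUE
  lev[roi] <- sample.int(ng, sum(roi), replace = TRUE)
  q <- list(levels = lev, ng = max(lev, na.rm = TRUE))
  class(q) <- "quantized_roi"
  q
}

# all 26 (or 8 in-plane) neighbour offsets
oracle_offsets <- function(dims) {
  out <- list()
  zr <- if (dims[3] == 1L) 0L else -1:1
  for (dx in -1:1) for (dy in -1:1) for (dz in zr) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out[[length(out) + 1L]] <- c(dx, dy, dz)
  }
  out
}

in_grid <- function(p, dims) {
  all(p >= 1) && p[1] <= dims[1] && p[2] <= dims[2] && p[3] <= dims[3]
}

# --- GLSZM: flood-fill zone enumeration ---------------------------------
oracle_glszm_matrix <- function(lev) {
  dims <- dim(lev)
  offs <- oracle_offsets(dims)
  seen <- array(FALSE, dims)
  zones <- list()
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    for (k in seq_len(dims[3])) {
      if (is.na(lev[i, j, k]) || seen[i, j, k]) next
      g <- lev[i, j, k]
      queue <- list(c(i, j, k))
      seen[i, j, k] <- TRUE
      size <- 0L
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        size <- size + 1L
        for (d in offs) {
          q <- p + d
          if (in_grid(q, dims) && !seen[q[1], q[2], q[3]] &&
              !is.na(lev[q[1], q[2], q[3]]) && lev[q[1], q[2], q[3]] == g) {
            seen[q[1], q[2], q[3]] <- TRUE
            queue[[length(queue) + 1L]] <- q
          }
        }
      }
      zones[[length(zones) + 1L]] <- c(level = g, size = size)
    }
  }
  do.call(rbind, zones)
}

oracle_glszm <- function(lev) {
  zm <- oracle_glszm_matrix(lev)
  nz <- nrow(zm)
  lahgle <- 0
  for (r in seq_len(nz)) lahgle <- lahgle + zm[r, 1]^2 * zm[r, 2]^2
  glnn <- 0
  for (g in unique(zm[, 1])) glnn <- glnn + sum(zm[, 1] == g)^2
  c(LAHGLE = unname(lahgle) / nz, GLNN = unname(glnn) / nz^2)
}

# --- GLCM: per-direction matrices, averaged features --------------------
oracle_glcm_dirs <- function(dims) {
  if (dims[3] == 1L) {
    list(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0), c(1, -1, 0))
  } else {
    offs <- oracle_offsets(dims)
    # one representative per +/- pair
    keep <- list()
    for (d in offs) {
      dup <- FALSE
      for (k in keep) if (all(k == -d)) dup <- TRUE
      if (!dup) keep[[length(keep) + 1L]] <- d
    }
    keep
  }
}

oracle_glcm_mcc <- function(lev) {
  dims <- dim(lev)
  ng <- max(lev, na.rm = TRUE)
  vals <- numeric(0)
  for (d in oracle_glcm_dirs(dims)) {
    M <- matrix(0, ng, ng)
    for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
      for (k in seq_len(dims[3])) {
        if (is.na(lev[i, j, k])) next
        q <- c(i, j, k) + d
        if (!in_grid(q, dims) || is.na(lev[q[1], q[2], q[3]])) next
        a <- lev[i, j, k]; b <- lev[q[1], q[2], q[3]]
        M[a, b] <- M[a, b] + 1
        M[b, a] <- M[b, a] + 1
      }
    }
    if (sum(M) == 0) next
    p <- M / sum(M)
    px <- rowSums(p)
    present <- which(px > 0)
    if (length(present) <= 1) { vals <- c(vals, 1); next }
    Q <- matrix(0, length(present), length(present))
    for (a in seq_along(present)) for (b in seq_along(present)) {
      s <- 0
      for (kk in seq_along(present)) {
        s <- s + p[present[a], present[kk]] * p[present[b], present[kk]] /
          (px[present[a]] * px[present[kk]])
      }
      Q[a, b] <- s
    }
    ev <- sort(Re(eigen(Q)$values), decreasing = TRUE)
    vals <- c(vals, sqrt(max(ev[2], 0)))
  }
  if (!length(vals)) return(1)
  mean(vals)
}

# --- GLDM: direct neighbour counting ------------------------------------
oracle_gldm_ldhgle <- function(lev) {
  dims <- dim(lev)
  offs <- oracle_offsets(dims)
  total <- 0
  nv <- 0L
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    for (k in seq_len(dims[3])) {
      if (is.na(lev[i, j, k])) next
      nv <- nv + 1L
      dep <- 1L
      for (d in offs) {
        q <- c(i, j, k) + d
        if (in_grid(q, dims) && !is.na(lev[q[1], q[2], q[3]]) &&
            lev[q[1], q[2], q[3]] == lev[i, j, k]) {
          dep <- dep + 1L
        }
      }
      total <- total + lev[i, j, k]^2 * dep^2
    }
  }
  total / nv
}

# --- NGTDM: direct summation --------------------------------------------
oracle_ngtdm_complexity <- function(lev) {
  dims <- dim(lev)
  offs <- oracle_offsets(dims)
  ng <- max(lev, na.rm = TRUE)
  s <- numeric(ng)
  n <- integer(ng)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) {
    for (k in seq_len(dims[3])) {
      if (is.na(lev[i, j, k])) next
      nb <- c()
      for (d in offs) {
        q <- c(i, j, k) + d
        if (in_grid(q, dims) && !is.na(lev[q[1], q[2], q[3]])) {
          nb <- c(nb, lev[q[1], q[2], q[3]])
        }
      }
      if (!length(nb)) next
      g <- lev[i, j, k]
      n[g] <- n[g] + 1L
      s[g] <- s[g] + abs(g - mean(nb))
    }
  }
  nvt <- sum(n)
  p <- n / nvt
  cx <- 0
  for (a in seq_len(ng)) for (b in seq_len(ng)) {
    if (p[a] > 0 && p[b] > 0) {
      cx <- cx + abs(a - b) * (p[a] * s[a] + p[b] * s[b]) / (p[a] + p[b])
    }
  }
  cx / nvt
}

# --- Harrell C: exhaustive pair loop ------------------------------------
oracle_cindex <- function(time, event, score) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (score[i] > score[j]) num <- num + 1
      if (score[i] == score[j]) num <- num + 0.5
    }
  }
  if (den == 0) return(NA_real_)
  num / den
}

# --- Kaplan-Meier: hand product-limit -----------------------------------
oracle_km <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  surv <- numeric(length(ts))
  s <- 1
  for (r in seq_along(ts)) {
    at_risk <- sum(time >= ts[r])
    d <- sum(time == ts[r] & event == 1)
    s <- s * (1 - d / at_risk)
    surv[r] <- s
  }
  data.frame(time = ts, survival = surv)
}

# --- extended Tofts: fine-grid quadrature -------------------------------
oracle_tofts <- function(ktrans, ve, vp, times, aif, n_fine = 20000) {
  tf <- seq(0, max(times), length.out = n_fine)
  cpf <- approx(times, aif, xout = tf)$y
  kep <- if (ktrans > 0) ktrans / ve else 0
  ct <- numeric(length(times))
  for (i in seq_along(times)) {
    sel <- tf <= times[i]
    tt <- tf[sel]
    integrand <- cpf[sel] * exp(-kep * (times[i] - tt))
    integral <- if (length(tt) > 1) {
      sum((integrand[-1] + integrand[-length(integrand)]) / 2 * diff(tt))
    } else 0
    ct[i] <- vp * approx(times, aif, xout = times[i])$y + ktrans * integral
  }
  ct
}
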