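# Independent brute-force oracles, deliberately naive and separate from the
# package's implementations.

# grayscale opening with a ball-height SE: explicit per-pixel erode then
# dilate, double loop over the structuring element
oracle_opening <- function(mat, radius) {
  r <- floor(radius)
  offs <- list()
  for (dy in -r:r) for (dx in -r:r)
    if (dy^2 + dx^2 <= radius^2)
      offs[[length(offs) + 1]] <- c(dy, dx, sqrt(radius^2 - dy^2 - dx^2))
  h <- nrow(mat); w <- ncol(mat)
  eroded <- matrix(NA_real_, h, w)
  for (i in 1:h) for (j in 1:w) {
    vals <- c()
    for (o in offs) {
      ii <- i + o[1]; jj <- j + o[2]
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w)
        vals <- c(vals, mat[ii, jj] - o[3])
    }
    eroded[i, j] <- min(vals)
  }
  opened <- matrix(NA_real_, h, w)
  for (i in 1:h) for (j in 1:w) {
    vals <- c()
    for (o in offs) {
      ii <- i - o[1]; jj <- j - o[2]
      if (ii >= 1 && ii <= h && jj >= 1 && jj <= w)
        vals <- c(vals, eroded[ii, jj] + o[3])
    }
    opened[i, j] <- max(vals)
  }
  opened
}

# per-pixel disc median with half-sample reflective padding
oracle_median <- function(mat, radius) {
  r <- floor(radius)
  h <- nrow(mat); w <- ncol(mat)
  ref <- function(n) c(r:1, 1:n, n:(n - r + 1))
  p <- mat[ref(h), ref(w)]
  out <- matrix(NA_real_, h, w)
  for (i in 1:h) for (j in 1:w) {
    vals <- c()
    for (dy in -r:r) for (dx in -r:r)
      if (dy^2 + dx^2 <= radius^2)
        vals <- c(vals, p[i + r + dy, j + r + dx])
    out[i, j] <- median(vals)
  }
  out
}

# recursive flood fill over 26-connected foreground voxels
oracle_flood_fill <- function(vox) {
  d <- dim(vox)
  lab <- array(0L, d)
  nxt <- 0L
  idx <- which(vox)
  for (start in idx) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      co <- arrayInd(cur, d)
      for (dy in -1:1) for (dx in -1:1) for (dz in -1:1) {
        if (dy == 0 && dx == 0 && dz == 0) next
        y <- co[1] + dy; x <- co[2] + dx; z <- co[3] + dz
        if (y < 1 || y > d[1] || x < 1 || x > d[2] || z < 1 || z > d[3]) next
        li <- y + (x - 1) * d[1] + (z - 1) * d[1] * d[2]
        if (vox[li] && lab[li] == 0L) {
          lab[li] <- nxt
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

# moment-preserving threshold re-derived through the Prony/Hankel route:
# the two representative levels satisfy the linear recurrence on the
# moments, so (c0, c1) come from solving the Hankel system and the levels
# from polyroot
oracle_moments_threshold <- function(histogram) {
  total <- sum(histogram)
  p <- histogram / total
  z <- seq_along(histogram) - 1
  m <- sapply(0:3, function(k) sum(z^k * p))
  cc <- solve(matrix(c(m[1], m[2], m[2], m[3]), 2), -c(m[3], m[4]))
  roots <- sort(Re(polyroot(c(cc[1], cc[2], 1))))
  p0 <- (roots[2] - m[2]) / (roots[2] - roots[1])
  cum <- cumsum(p)
  which(cum >= p0 - 1e-12)[1] - 1L
}

# Mann-Whitney U by explicit pair counting
oracle_U <- function(x, y) {
  sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
}

# stage-score reconstruction by exhaustive enumeration of all 3^n tuples
oracle_scores <- function(mean_val, sd_val, n, digits = 1) {
  grid <- do.call(expand.grid, rep(list(1:3), n))
  keep <- abs(round(rowMeans(grid), digits) - round(mean_val, digits)) < 1e-9
  grid <- grid[keep, , drop = FALSE]
  if (!nrow(grid)) return(list())
  key <- apply(grid, 1, function(v) paste(sort(v, decreasing = TRUE),
                                          collapse = ","))
  uniq <- grid[!duplicated(key), , drop = FALSE]
  sds <- apply(uniq, 1, sd)
  o <- order(abs(sds - sd_val))
  lapply(o, function(i) sort(as.numeric(uniq[i, ]), decreasing = TRUE))
}

# balanced two-factor ANOVA sums of squares by the classical closed-form
# decomposition (independent of lm)
oracle_balanced_anova <- function(y, a, b) {
  gm <- mean(y)
  ma <- tapply(y, a, mean); mb <- tapply(y, b, mean)
  mab <- tapply(y, interaction(a, b), mean)
  na <- table(a); nb <- table(b); nab <- table(interaction(a, b))
  ss_a <- sum(na * (ma - gm)^2)
  ss_b <- sum(nb * (mb - gm)^2)
  cell_a <- tapply(a, interaction(a, b), function(v) v[1])
  cell_b <- tapply(b, interaction(a, b), function(v) v[1])
  ss_ab <- sum(nab * (mab - ma[cell_a] - mb[cell_b] + gm)^2)
  ss_tot <- sum((y - gm)^2)
  ss_res <- ss_tot - ss_a - ss_b - ss_ab
  df_res <- length(y) - length(nab)
  list(F_a = (ss_a / (length(na) - 1)) / (ss_res / df_res),
       F_b = (ss_b / (length(nb) - 1)) / (ss_res / df_res),
       F_ab = (ss_ab / ((length(na) - 1) * (length(nb) - 1))) /
         (ss_res / df_res),
       ss = c(a = ss_a, b = ss_b, ab = ss_ab, res = ss_res, tot = ss_tot))
}

# systematic-random sampling draw from a uniform 3-D point process,
# returning the raw dissector count Q for the optical fractionator
sim_fractionator_count <- function(n_true, params, n_sections = 20,
                                   wx = 1000, wy = 1000) {
  th <- params$section_thickness
  step <- params$frame_side + params$frame_separation
  x <- runif(n_true, 0, wx); y <- runif(n_true, 0, wy)
  z <- runif(n_true, 0, n_sections * th)
  period <- round(1 / params$ssf)
  s0 <- sample.int(period, 1)
  sec <- floor(z / th) + 1
  keep_sec <- (sec - s0) %% period == 0
  ox <- runif(1, 0, step); oy <- runif(1, 0, step); oz <- runif(1, 0, th)
  in_frame <- ((x - ox) %% step) < params$frame_side &
    ((y - oy) %% step) < params$frame_side
  in_h <- ((z - oz) %% th) < params$hsf * th
  sum(keep_sec & in_frame & in_h)
}

# synthetic glial field: hard bright discs on a dark background; returns
# the image and the true painted coverage fraction
make_glia_image <- function(coverage, seed, n = 128, disc_r = 6,
                            noise_sd = 3) {
  set.seed(seed)
  img <- matrix(10, n, n)
  mask <- matrix(FALSE, n, n)
  disc <- which(outer((-disc_r):disc_r, (-disc_r):disc_r,
                      function(a, b) a^2 + b^2) <= disc_r^2, arr.ind = TRUE)
  disc <- disc - disc_r - 1L
  n_disc <- round(coverage * n^2 /
                    nrow(disc))
  for (i in seq_len(n_disc)) {
    cx <- sample(seq(disc_r + 1, n - disc_r), 1)
    cy <- sample(seq(disc_r + 1, n - disc_r), 1)
    img[cbind(cy + disc[, 1], cx + disc[, 2])] <- 200
    mask[cbind(cy + disc[, 1], cx + disc[, 2])] <- TRUE
  }
  img <- pmin(pmax(round(img + rnorm(n^2, 0, noise_sd)), 0), 255)
  list(image = image_stack(img, pixel_size = 0.3),
       coverage = mean(mask))
}

# small synthetic swelling scenario shared by detection tests
detection_config <- function(seed) {
  image_sim_config(width = 72, height = 72, depth = 8, n_fibres = 4,
                   n_swellings_large = 8, n_swellings_small = 4,
                   noise_sd = 4, seed = seed)
}

detection_params <- function() swelling_params(rolling_ball_radius = 12)
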