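# Independent brute-force implementations used as oracles for the landscape
# metrics: naive label propagation for connected components, double-loop
# perimeter and adjacency counts, and the class-level index formulas
# recomputed from those primitives.

brute_label <- function(v, code, connectivity = 8) {
  nr <- nrow(v); nc <- ncol(v)
  lab <- matrix(0L, nr, nc)
  lab[v == code] <- seq_len(sum(v == code))
  offs <- if (connectivity == 4)
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  else
    list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1),
         c(-1, -1), c(-1, 1), c(1, -1), c(1, 1))
  repeat {
    changed <- FALSE
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      if (lab[r, c] == 0L) next
      for (o in offs) {
        rr <- r + o[1]; cc <- c + o[2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (lab[rr, cc] > 0L && lab[rr, cc] < lab[r, c]) {
          lab[r, c] <- lab[rr, cc]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  lab
}

brute_patchset <- function(v, code, connectivity = 8) {
  lab <- brute_label(v, code, connectivity)
  ids <- sort(unique(lab[lab > 0L]))
  area <- numeric(length(ids)); peri <- numeric(length(ids))
  nr <- nrow(v); nc <- ncol(v)
  for (k in seq_along(ids)) {
    cells <- which(lab == ids[k], arr.ind = TRUE)
    area[k] <- nrow(cells)
    p <- 0
    for (i in seq_len(nrow(cells))) {
      r <- cells[i, 1]; c <- cells[i, 2]
      for (o in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + o[1]; cc <- c + o[2]
        if (rr < 1 || rr > nr || cc < 1 || cc > nc || v[rr, cc] != code)
          p <- p + 1
      }
    }
    peri[k] <- p
  }
  list(area = area, perimeter = peri, A = length(v))
}

brute_lpi <- function(ps) 100 * max(ps$area) / ps$A

brute_cohesion <- function(ps) {
  (1 - sum(ps$perimeter) / sum(ps$perimeter * sqrt(ps$area))) /
    (1 - 1 / sqrt(ps$A)) * 100
}

brute_split <- function(ps) ps$A^2 / sum(ps$area^2)

brute_ai <- function(v, code) {
  nr <- nrow(v); nc <- ncol(v)
  g <- 0
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    if (v[r, c] != code) next
    if (r < nr && v[r + 1, c] == code) g <- g + 1
    if (c < nc && v[r, c + 1] == code) g <- g + 1
  }
  a <- sum(v == code)
  n <- floor(sqrt(a)); m <- a - n^2
  gmax <- if (m == 0) 2 * n * (n - 1)
  else if (m <= n) 2 * n * (n - 1) + 2 * m - 1
  else 2 * n * (n - 1) + 2 * m - 2
  if (gmax == 0) return(100)
  100 * g / gmax
}

# random clustered test grid (majority-smoothed noise so patches exist)
random_class_grid <- function(nr = 30, nc = 30, k = 4) {
  v <- matrix(sample.int(k, nr * nc, replace = TRUE), nr, nc)
  v
}
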