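# Independent brute-force oracles. These deliberately avoid the package's
# vectorised code paths: plain per-pixel loops and fixpoint iteration.

# per-pixel cross-tabulation of two categorical matrices (areas in ha)
oracle_crosstab <- function(v0, v1, classes, pixel_area = 1) {
  A <- matrix(0, length(classes), length(classes),
              dimnames = list(classes, classes))
  for (p in seq_along(v0)) {
    if (is.na(v0[p]) || is.na(v1[p])) next
    i <- as.character(v0[p]); j <- as.character(v1[p])
    A[i, j] <- A[i, j] + pixel_area
  }
  A
}

# dominant class per zone by exhaustive tabulation, ties to lowest code
oracle_dominant <- function(vals, zones) {
  ids <- sort(unique(zones[!is.na(zones)]))
  out <- integer(length(ids)); names(out) <- ids
  for (z in ids) {
    cnt <- list()
    for (p in seq_along(zones)) {
      if (is.na(zones[p]) || zones[p] != z || is.na(vals[p])) next
      k <- as.character(vals[p])
      cnt[[k]] <- (cnt[[k]] %||% 0) + 1
    }
    cls <- as.integer(names(cnt))
    n <- unlist(cnt)
    best <- cls[n == max(n)]
    out[as.character(z)] <- min(best)
  }
  out
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# connected components (4-neighbour) by min-label propagation to fixpoint
oracle_components <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  lab[mask] <- which(mask)
  repeat {
    old <- lab
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      if (!mask[r, cc]) next
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        rr <- r + d[1]; c2 <- cc + d[2]
        if (rr >= 1 && rr <= nr && c2 >= 1 && c2 <= nc && mask[rr, c2])
          lab[r, cc] <- min(lab[r, cc], lab[rr, c2])
      }
    }
    if (identical(old, lab)) break
  }
  sizes <- table(lab[lab > 0L])
  as.numeric(sizes)
}

# accumulate runoff down a tree by repeated sweeps (no topological sort)
oracle_accumulate <- function(local_runoff, downstream) {
  inflow <- setNames(numeric(length(local_runoff)), names(local_runoff))
  contrib <- local_runoff
  repeat {
    moved <- FALSE
    nxt <- setNames(numeric(length(contrib)), names(contrib))
    for (u in names(contrib)) {
      d <- downstream[[u]]
      if (!is.na(d) && contrib[[u]] > 0) {
        inflow[[as.character(d)]] <- inflow[[as.character(d)]] + contrib[[u]]
        nxt[[as.character(d)]] <- nxt[[as.character(d)]] + contrib[[u]]
        moved <- TRUE
      }
    }
    contrib <- nxt
    if (!moved) break
  }
  inflow
}

# small helpers to build fixtures in code
toy_grid <- function(v, nr, nc, epoch = "t0")
  epoch_grid(matrix(v, nr, nc), epoch = epoch)

random_dlct_pair <- function(seed, nr = 20, nc = 20, n_classes = 10,
                             change_frac = 0.1) {
  set.seed(seed)
  v0 <- matrix(sample.int(n_classes, nr * nc, replace = TRUE), nr, nc)
  v1 <- v0
  k <- round(change_frac * nr * nc)
  idx <- sample.int(nr * nc, k)
  v1[idx] <- sample.int(n_classes, k, replace = TRUE)
  list(g0 = epoch_grid(v0, "t0"), g1 = epoch_grid(v1, "t1"))
}

random_zone_grid <- function(seed, nr = 20, nc = 20, n_zones = 4) {
  set.seed(seed)
  pts <- sample.int(nr * nc, n_zones)
  pr <- ((pts - 1) %% nr) + 1
  pc <- ((pts - 1) %/% nr) + 1
  z <- matrix(0L, nr, nc)
  for (r in seq_len(nr)) for (cc in seq_len(nc))
    z[r, cc] <- which.min((r - pr)^2 + (cc - pc)^2)
  epoch_grid(z, "frame")
}
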