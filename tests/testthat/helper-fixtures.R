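# shared fixtures: everything is generated in code at test time

# small atlas reused across tests (8^3 grid: mesial/pole/lateral blocks of
# 18 voxels per hemisphere, fillers of 6)
tiny_atlas <- function() make_toy_atlas(c(8, 8, 8), voxel_size = c(3, 3, 4))

# wrap a t x V matrix of series into a volume4d on a 1D-ish grid
series_vol <- function(mat, tr = 2) {
  v <- ncol(mat)
  volume4d(array(t(mat), dim = c(v, 1, 1, nrow(mat))), diag(4), tr = tr)
}

line_mask <- function(v) array(TRUE, dim = c(v, 1, 1))

# brute-force weighted degree: double loop over voxel pairs with cor()
wdc_bruteforce <- function(mat, r_threshold = 0.25) {
  v <- ncol(mat)
  raw <- numeric(v)
  for (i in seq_len(v)) {
    for (j in seq_len(v)) {
      if (i == j) next
      r <- stats::cor(mat[, i], mat[, j])
      if (r > r_threshold) raw[i] <- raw[i] + r
    }
  }
  raw
}

# independent connected-components labelling: repeated neighbourhood dilation
cc_oracle <- function(flag, connectivity) {
  d <- dim(flag)
  offs <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0 & offs$dz == 0), ]
  ord <- abs(offs$dx) + abs(offs$dy) + abs(offs$dz)
  offs <- as.matrix(offs[switch(as.character(connectivity),
                                `6` = ord == 1, `18` = ord <= 2,
                                `26` = ord <= 3), ])
  coords <- which(flag, arr.ind = TRUE)
  n <- nrow(coords)
  if (n == 0) return(array(0L, dim = d))
  # adjacency by pairwise coordinate differences, then transitive closure
  adj <- diag(TRUE, n)
  for (a in seq_len(n)) {
    dd <- sweep(coords, 2L, coords[a, ])
    for (o in seq_len(nrow(offs))) {
      hit <- dd[, 1] == offs[o, 1] & dd[, 2] == offs[o, 2] & dd[, 3] == offs[o, 3]
      adj[a, hit] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  comp <- integer(n); cur <- 0L
  for (a in seq_len(n)) {
    if (comp[a] == 0L) {
      cur <- cur + 1L
      comp[adj[a, ]] <- cur
    }
  }
  lab <- array(0L, dim = d)
  lab[flag] <- comp  # which(flag) linear order matches arr.ind order
  lab
}

# canonical multiset of cluster sizes from a label array
cluster_sizes <- function(labels) sort(tabulate(labels[labels > 0L]))
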