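# Independent oracles used to validate the implementation.

# Brute-force marker-controlled flooding by minimax path cost: for every
# label, the cost of reaching a pixel is the minimum over 8-connected
# paths (within the mask, from any of the label's marker pixels) of the
# maximum per-pixel entry cost along the path, where entering pixel q from
# region l costs surface(q) + compactness * ||q - centroid_l||. Iterated
# relaxation to the fixpoint; each pixel takes the label with the smallest
# cost. Returns the label matrix and a matrix flagging tie pixels (two
# labels within tolerance), which are order-dependent in any flooding.
ws_oracle <- function(surface, markers, mask, compactness = 0.001,
                      tol = 1e-9) {
  H <- nrow(surface); W <- ncol(surface)
  labs <- sort(unique(markers[markers > 0 & mask > 0]))
  costs <- array(Inf, c(H, W, length(labs)))
  for (li in seq_along(labs)) {
    l <- labs[li]
    sel <- which(markers == l & mask > 0)
    ci <- mean((sel - 1) %% H + 1)
    cj <- mean((sel - 1) %/% H + 1)
    entry <- surface + compactness *
      sqrt((matrix(seq_len(H), H, W) - ci)^2 +
             (matrix(seq_len(W), H, W, byrow = TRUE) - cj)^2)
    cm <- matrix(Inf, H, W)
    cm[sel] <- -Inf                       # marker pixels: already owned
    repeat {
      changed <- FALSE
      for (j in seq_len(W)) for (i in seq_len(H)) {
        if (mask[i, j] == 0) next
        best <- cm[i, j]
        for (dj in -1:1) for (di in -1:1) {
          if (di == 0 && dj == 0) next
          qi <- i + di; qj <- j + dj
          if (qi < 1 || qi > H || qj < 1 || qj > W) next
          if (mask[qi, qj] == 0) next
          cand <- max(cm[qi, qj], entry[i, j])
          if (cand < best - 1e-15) best <- cand
        }
        if (best < cm[i, j] - 1e-15) { cm[i, j] <- best; changed <- TRUE }
      }
      if (!changed) break
    }
    costs[, , li] <- cm
  }
  lab <- matrix(0L, H, W)
  tie <- matrix(FALSE, H, W)
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 0) next
    cs <- costs[i, j, ]
    o <- order(cs)
    lab[i, j] <- labs[o[1]]
    if (length(cs) > 1 && is.finite(cs[o[1]]) &&
        cs[o[2]] - cs[o[1]] < tol) tie[i, j] <- TRUE
  }
  list(labels = lab, tie = tie)
}

# Mann-Whitney pair-counting AUC: fraction of (positive, negative) score
# pairs ranked correctly, ties counted 1/2.
auc_pair_oracle <- function(pos, score) {
  ps <- score[pos]
  ns <- score[!pos]
  if (length(ps) == 0 || length(ns) == 0) return(NA_real_)
  tot <- 0
  for (a in ps) for (b in ns)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(ps) * length(ns))
}
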