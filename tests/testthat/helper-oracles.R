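# Independent brute-force oracles used to freeze expected values.

# --- Ward agglomeration by direct ESS minimization -------------------------
# Greedy Ward from first principles: clusters are point sets; at each step
# merge the pair whose union minimizes the increase in total within-cluster
# sum of squares. Returns the member sets merged at each step.
ward_oracle_merges <- function(x) {
  ess <- function(rows) {
    m <- x[rows, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }
  clusters <- as.list(seq_len(nrow(x)))
  merges <- list()
  while (length(clusters) > 1L) {
    best <- NULL; best_cost <- Inf
    for (i in seq_along(clusters)) for (j in seq_len(i - 1L)) {
      cost <- ess(c(clusters[[i]], clusters[[j]])) -
        ess(clusters[[i]]) - ess(clusters[[j]])
      if (cost < best_cost) { best_cost <- cost; best <- c(j, i) }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    merges[[length(merges) + 1L]] <- list(sort(a), sort(b))
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  merges
}

# member sets merged at each step of an hclust tree
hclust_merges <- function(hc) {
  members <- function(k) {
    if (k < 0) return(-k)
    sort(unlist(lapply(hc$merge[k, ], members)))
  }
  lapply(seq_len(nrow(hc$merge)), function(s) {
    a <- members(hc$merge[s, 1]); b <- members(hc$merge[s, 2])
    list(sort(a), sort(b))
  })
}

same_merge <- function(m1, m2) {
  (identical(m1[[1]], m2[[1]]) && identical(m1[[2]], m2[[2]])) ||
    (identical(m1[[1]], m2[[2]]) && identical(m1[[2]], m2[[1]]))
}

# --- Hard-margin linear SVM in 2-D by closest-hull-points ------------------
# The maximum-margin separator of two linearly separable point sets is the
# bisector of the segment joining the closest points of their convex hulls.
# Enumerates vertex-segment pairs in both directions (closed form, no
# optimizer).
closest_point_on_segment <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab * ab)
  t <- min(1, max(0, t))
  a + t * ab
}

hull_segments <- function(m) {
  ch <- chull(m)
  v <- m[ch, , drop = FALSE]
  n <- nrow(v)
  if (n == 1L) return(list(list(v[1, ], v[1, ])))
  lapply(seq_len(n), function(i) list(v[i, ], v[if (i == n) 1L else i + 1L, ]))
}

svm_oracle_2d <- function(xa, xb) {
  best <- NULL; best_d <- Inf
  consider <- function(u, v) {
    d <- sqrt(sum((u - v)^2))
    if (d < best_d) { best_d <<- d; best <<- list(u = u, v = v) }
  }
  for (seg in hull_segments(xb)) for (i in seq_len(nrow(xa)))
    consider(xa[i, ], closest_point_on_segment(xa[i, ], seg[[1]], seg[[2]]))
  for (seg in hull_segments(xa)) for (i in seq_len(nrow(xb)))
    consider(closest_point_on_segment(xb[i, ], seg[[1]], seg[[2]]), xb[i, ])
  w <- best$u - best$v
  m <- (best$u + best$v) / 2
  list(w = w, b = -sum(w * m), margin = best_d / 2)
}

# --- misc -------------------------------------------------------------------
# naive per-window percentile: sort and pick (median rule for even windows)
sort_pick_median <- function(v) {
  s <- sort(v); n <- length(s)
  if (n %% 2L == 1L) s[(n + 1L) / 2L] else (s[n / 2L] + s[n / 2L + 1L]) / 2
}
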