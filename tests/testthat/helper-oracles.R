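# Independent oracles and small fixture builders used across the suite.

# Brute-force O(n^2) segment-pair intersection check for polygon simplicity.
# Independent of the package's geometry code.
is_simple_polygon <- function(v) {
  if (all(v[1, ] == v[nrow(v), ])) v <- v[-nrow(v), , drop = FALSE]
  n <- nrow(v)
  seg <- cbind(v, v[c(2:n, 1), ])
  crosses <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) -
                           (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) {
    for (j in seq.int(i + 2, n)) {
      if (i == 1 && j == n) next # adjacent through closure
      if (crosses(seg[i, 1:2], seg[i, 3:4], seg[j, 1:2], seg[j, 3:4]))
        return(FALSE)
    }
  }
  TRUE
}

# BFS flood-fill component count (4-connectivity); oracle independent of
# EBImage::bwlabel.
count_components <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  n <- 0
  for (start in which(mask & !seen)) {
    if (seen[start]) next
    n <- n + 1
    queue <- start
    seen[start] <- TRUE
    nr <- nrow(mask)
    while (length(queue)) {
      cur <- queue[length(queue)]; queue <- queue[-length(queue)]
      i <- (cur - 1) %% nr + 1; j <- (cur - 1) %/% nr + 1
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        ii <- i + d[1]; jj <- j + d[2]
        if (ii >= 1 && ii <= nr && jj >= 1 && jj <= ncol(mask)) {
          idx <- (jj - 1) * nr + ii
          if (mask[idx] && !seen[idx]) {
            seen[idx] <- TRUE
            queue <- c(queue, idx)
          }
        }
      }
    }
  }
  n
}

# solid disc mask fixture
disc_mask <- function(n = 101, r = n / 3) {
  ctr <- (n + 1) / 2
  outer(seq_len(n), seq_len(n),
        function(i, j) (i - ctr)^2 + (j - ctr)^2 <= r^2)
}

parameterized_models <- function() lapply(model_names(), get_model)
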